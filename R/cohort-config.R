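#' Configuration for a synthetic accession cohort
#'
#' Bundles every generating parameter of [simulate_cohort()] into a single
#' validated object. The defaults describe a mid-size *Arabidopsis
#' thaliana*-like panel: a structured set of selfing accessions split into
#' genetic groups, TE insertion polymorphisms (TIPs) whose folded frequency
#' spectrum is skewed towards rare variants, a large-effect modifier allele
#' that multiplies transposition activity (an *NRPE1*-like RdDM mutant), and
#' climate gradients correlated with the genetic groups.
#'
#' @param n_accessions number of accessions in the panel (>= 2).
#' @param n_groups number of genetic groups.
#' @param kinship_strength scale of the between-group component of the latent
#'   genotype factors that build the kinship matrix; 0 gives an unstructured
#'   panel.
#' @param base_rate TE insertion substitution rate, events per genome per
#'   generation. Default 0.0763, i.e. roughly a third of the SNP rate. The
#'   implied TIP-per-SNP divergence slope is `base_rate / snp_rate`.
#' @param retention_prob long-term retention probability of a new insertion,
#'   in (0, 1]; `1 - retention_prob` is the fraction eventually eliminated by
#'   selection.
#' @param modifier_effect multiplicative fold-change on the very-recent
#'   transposition rate in modifier-allele carriers. Default 3.4 (a 240%
#'   increase).
#' @param modifier_freq carrier frequency of the modifier allele.
#' @param env_effects named numeric vector of fixed-effect coefficients (per
#'   z-scored unit) of bioclimatic variables on log very-recent counts, e.g.
#'   `c(BIO05 = 0.3)`.
#' @param gxe_effects named numeric vector of modifier-by-bio-variable
#'   interaction coefficients on log very-recent counts.
#' @param vr_mean baseline mean number of very recent insertions per
#'   non-carrier genome at average climate. Default 7, matching roughly 7
#'   very-recent TIPs per accession in a species-wide panel.
#' @param mu per-site per-generation base mutation rate. Default 7e-9.
#' @param snp_rate SNP substitutions per genome per generation. Default
#'   0.2511.
#' @param kappa_true ratio of synonymous-SNP fractions between distant and
#'   close accession pairs (the selection scaling on SNP divergence).
#' @param syn_frac_close synonymous fraction of SNP differences among close
#'   pairs.
#' @param close_snp_mean,distant_snp_mean expected genome-wide SNP differences
#'   for close and distant accession pairs.
#' @param n_close_pairs,n_distant_pairs numbers of simulated divergence pairs
#'   per class.
#' @param genome_length length in bp of the single toy chromosome.
#' @param centromere_frac central fraction of the chromosome flagged
#'   centromeric.
#' @param n_genes number of non-overlapping genes on the toy chromosome.
#' @param n_sites number of background (non-very-recent) TIP sites.
#' @param sfs_shape shape of the carrier-frequency law: site frequencies are
#'   drawn from Beta(`sfs_shape`, 1) scaled to (0, 0.5]; values < 1 skew the
#'   spectrum towards rare variants and at the extreme (near 0) all sites
#'   become private.
#' @param frac_absence fraction of background sites simulated as reference TE
#'   absence variants rather than non-reference presences.
#' @param na_rate per accession-site probability of an uninformative (low
#'   coverage) genotype.
#' @param frac_low_dp,frac_low_informative,frac_het_like,frac_flagged_absence
#'   fractions of background sites planted with, respectively, sub-threshold
#'   read support (max positive coverage 2), fewer informative genomes than
#'   `min_informative`, positive coverage never above negative coverage in
#'   any carrier (heterozygous-like), and fragmented/ancestral reference
#'   flags on absence sites. Planted violations are recorded in `truth`.
#' @param min_informative informative-genome threshold the planted
#'   low-informative sites are built to violate (and the genotyping filter is
#'   expected to use).
#' @param expr_effect_frac fraction of genic TIPs given a real expression
#'   effect in carriers.
#' @param expr_effect_size multiplicative expression effect in carriers of an
#'   effectful TIP (0 is a full knock-out).
#' @param future_shift named numeric vector of future-minus-current climate
#'   shifts, in units of the current standard deviation of each variable;
#'   variables not named are unshifted. Default warms the temperature
#'   variables (BIO01-BIO11) by 1.5 SD and dries the precipitation variables
#'   (BIO12-BIO19) by 0.5 SD.
#' @param seed integer seed; identical seed and configuration give a
#'   byte-identical cohort.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_accessions = 50, n_groups = 2, seed = 1)
#' cfg$base_rate / cfg$snp_rate   # implied TIP-per-SNP slope
#' @export
cohort_config <- function(n_accessions = 300,
                          n_groups = 3,
                          kinship_strength = 2,
                          base_rate = 0.0763,
                          retention_prob = 0.1,
                          modifier_effect = 3.4,
                          modifier_freq = 0.2,
                          env_effects = c(BIO05 = 0.3),
                          gxe_effects = c(BIO05 = 0.25),
                          vr_mean = 7,
                          mu = 7e-9,
                          snp_rate = 0.2511,
                          kappa_true = 1.2,
                          syn_frac_close = 0.3,
                          close_snp_mean = 250,
                          distant_snp_mean = 30000,
                          n_close_pairs = 500,
                          n_distant_pairs = 500,
                          genome_length = 1e6,
                          centromere_frac = 0.1,
                          n_genes = 120,
                          n_sites = 300,
                          sfs_shape = 0.25,
                          frac_absence = 0.1,
                          na_rate = 0.05,
                          frac_low_dp = 0.04,
                          frac_low_informative = 0.04,
                          frac_het_like = 0.04,
                          frac_flagged_absence = 0.3,
                          min_informative = 100,
                          expr_effect_frac = 0.3,
                          expr_effect_size = 0.25,
                          future_shift = NULL,
                          seed = 1L) {
  check_scalar(n_accessions, "n_accessions", lower = 2, integer = TRUE)
  check_scalar(n_groups, "n_groups", lower = 1, integer = TRUE)
  check_scalar(kinship_strength, "kinship_strength", lower = 0)
  check_scalar(base_rate, "base_rate", lower = 0)
  check_scalar(retention_prob, "retention_prob", lower = 1e-12, upper = 1)
  check_scalar(modifier_effect, "modifier_effect", lower = 0)
  check_scalar(modifier_freq, "modifier_freq", lower = 0, upper = 1)
  check_scalar(vr_mean, "vr_mean", lower = 0)
  check_scalar(mu, "mu", lower = 0)
  check_scalar(snp_rate, "snp_rate", lower = 0)
  check_scalar(kappa_true, "kappa_true", lower = 1e-12)
  check_scalar(syn_frac_close, "syn_frac_close", lower = 0, upper = 1)
  check_scalar(genome_length, "genome_length", lower = 1e4)
  check_scalar(sfs_shape, "sfs_shape", lower = 1e-6)
  check_scalar(seed, "seed", integer = TRUE)
  if (syn_frac_close * kappa_true > 1) {
    stop_temob("kappa_true * syn_frac_close must not exceed 1")
  }
  stopifnot(is.numeric(env_effects), is.numeric(gxe_effects))
  if (length(env_effects) && is.null(names(env_effects))) {
    stop_temob("'env_effects' must be a named vector of bio-variables")
  }
  if (length(gxe_effects) && is.null(names(gxe_effects))) {
    stop_temob("'gxe_effects' must be a named vector of bio-variables")
  }
  bad <- setdiff(c(names(env_effects), names(gxe_effects)), bio_names())
  if (length(bad)) {
    stop_temob("unknown bio-variables: ", paste(bad, collapse = ", "))
  }
  if (is.null(future_shift)) {
    future_shift <- c(stats::setNames(rep(1.5, 11), bio_names()[1:11]),
                      stats::setNames(rep(-0.5, 8), bio_names()[12:19]))
  }
  cfg <- list(
    n_accessions = as.integer(n_accessions), n_groups = as.integer(n_groups),
    kinship_strength = kinship_strength, base_rate = base_rate,
    retention_prob = retention_prob, modifier_effect = modifier_effect,
    modifier_freq = modifier_freq, env_effects = env_effects,
    gxe_effects = gxe_effects, vr_mean = vr_mean, mu = mu,
    snp_rate = snp_rate, kappa_true = kappa_true,
    syn_frac_close = syn_frac_close, close_snp_mean = close_snp_mean,
    distant_snp_mean = distant_snp_mean,
    n_close_pairs = as.integer(n_close_pairs),
    n_distant_pairs = as.integer(n_distant_pairs),
    genome_length = genome_length, centromere_frac = centromere_frac,
    n_genes = as.integer(n_genes), n_sites = as.integer(n_sites),
    sfs_shape = sfs_shape, frac_absence = frac_absence, na_rate = na_rate,
    frac_low_dp = frac_low_dp, frac_low_informative = frac_low_informative,
    frac_het_like = frac_het_like,
    frac_flagged_absence = frac_flagged_absence,
    min_informative = as.integer(min_informative),
    expr_effect_frac = expr_effect_frac, expr_effect_size = expr_effect_size,
    future_shift = future_shift, seed = as.integer(seed)
  )
  # derived: TIPs per SNP among close pairs
  cfg$slope_true <- base_rate / snp_rate
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d accessions in %d groups (kinship strength %.2g)\n",
              x$n_accessions, x$n_groups, x$kinship_strength))
  cat(sprintf("  substitution rate %.4g/genome/generation (slope %.3g TIPs/SNP), retention %.3g\n",
              x$base_rate, x$slope_true, x$retention_prob))
  cat(sprintf("  modifier x%.2g at frequency %.2g; %d env / %d GxE terms\n",
              x$modifier_effect, x$modifier_freq,
              length(x$env_effects), length(x$gxe_effects)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
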