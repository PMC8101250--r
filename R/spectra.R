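#' Frequency spectra, insertion dating and substitution-rate estimation
#'
#' @name spectra
NULL

#' Per-site frequencies from a TIP genotype matrix
#'
#' Frequency is carriers over informative (non-NA) genomes; MAF folds it at
#' 0.5; a site is private when carried by exactly one genome.
#'
#' @param tm a `tip_matrix`.
#' @return data.frame: site_id, informative, carriers, frequency, maf,
#'   private.
#' @export
site_frequencies <- function(tm) {
  stopifnot(inherits(tm, "tip_matrix"))
  tm <- refresh_site_stats(tm)
  s <- tm$sites
  if (any(s$informative == 0)) {
    stop_temob("sites with zero informative genomes present; ",
               "apply_population_filters() first")
  }
  data.frame(site_id = s$site_id, informative = s$informative,
             carriers = s$carriers, frequency = s$frequency, maf = s$maf,
             private = s$carriers == 1L, stringsAsFactors = FALSE)
}

#' Folded site frequency spectrum
#'
#' Histogram of minor allele frequencies over `n_bins` equal-width bins on
#' \[0, 0.5\]; the layout used as input for distribution-of-fitness-effects
#' estimation.
#'
#' @param frequencies numeric vector of site frequencies in (0, 1).
#' @param category label for the variant category.
#' @param n_bins number of bins, default 500.
#' @return an `sfs_table`: data.frame with bin_low, bin_high, count, plus
#'   attributes `category` and `n_sites`.
#' @export
folded_sfs <- function(frequencies, category = "TIP", n_bins = 500) {
  check_scalar(n_bins, "n_bins", lower = 1, integer = TRUE)
  if (length(frequencies) == 0) {
    out <- data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      count = integer(0))
  } else {
    if (any(frequencies <= 0 | frequencies >= 1)) {
      stop_temob("frequencies must lie strictly in (0, 1)")
    }
    maf <- pmin(frequencies, 1 - frequencies)
    breaks <- seq(0, 0.5, length.out = n_bins + 1)
    # maf in (0, 0.5]: bins are left-open so each count lands once
    idx <- pmax(1L, pmin(n_bins, as.integer(ceiling(maf / 0.5 * n_bins))))
    count <- tabulate(idx, nbins = n_bins)
    out <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                      count = count)
  }
  attr(out, "category") <- category
  attr(out, "n_sites") <- length(frequencies)
  class(out) <- c("sfs_table", "data.frame")
  out
}

#' Write a folded SFS in a DFE-estimation text layout
#'
#' One header line with the category and site count, then one line per bin
#' with the bin edges and count, tab-separated.
#'
#' @param sfs an `sfs_table`.
#' @param path output file.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# category=%s n_sites=%d n_bins=%d",
                     attr(sfs, "category"), attr(sfs, "n_sites"), nrow(sfs)),
             con)
  utils::write.table(as.data.frame(sfs), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Date a TE insertion from local haplotype divergence
#'
#' The age in generations of an insertion shared by at least two carriers is
#' the highest pairwise SNP divergence observed among carriers within the
#' dating window (70 kb: 35 kb on either side of the insertion), expressed
#' per site and divided by the mutation rate:
#' `age = (max_snps / window_length) / mu`. With `two_lineage = TRUE` the
#' divergence is halved first, attributing accumulation to both lineages
#' since their common ancestor.
#'
#' @param max_snps maximum pairwise SNP count among carriers in the window
#'   (vectorised; NA for single-carrier sites).
#' @param window_length window length in bp, default 70000.
#' @param mu per-site per-generation mutation rate, default 7e-9.
#' @param two_lineage halve the divergence before dating (off by default).
#' @return ages in generations (NA where `max_snps` is NA).
#' @export
estimate_tip_age <- function(max_snps, window_length = 70000, mu = 7e-9,
                             two_lineage = FALSE) {
  check_scalar(window_length, "window_length", lower = 1)
  check_scalar(mu, "mu", lower = 1e-15)
  age <- (max_snps / window_length) / mu
  if (two_lineage) age <- age / 2
  age
}

#' Classify very recent TIPs and count them per accession and family
#'
#' A site is *very recent* when its frequency is below `freq_max` (0.2% by
#' default) and it is either private or younger than `age_max` generations.
#' Per-accession counts are the numbers of very recent sites each genome
#' carries; per-family counts are restricted to families with more than
#' `min_family_tips` sites in the matrix.
#'
#' @param tm a filtered `tip_matrix`.
#' @param ages per-site ages aligned with `tm$sites` (NA allowed for private
#'   sites, where the private rule applies instead).
#' @param freq_max frequency ceiling, default 0.002. On panels much smaller
#'   than ~1000 genomes even private sites exceed 0.2%; scale the ceiling to
#'   roughly `2 / panel size` there.
#' @param age_max age ceiling in generations, default 1000.
#' @param min_family_tips minimum species-wide TIP count for a family to be
#'   reported, default 20.
#' @return list with `very_recent` (logical per site), `per_accession`
#'   (named integer vector) and `per_family` (data.frame family, n_sites,
#'   counts matrix rows = family).
#' @export
classify_very_recent <- function(tm, ages, freq_max = 0.002, age_max = 1000,
                                 min_family_tips = 20) {
  stopifnot(inherits(tm, "tip_matrix"))
  freqs <- site_frequencies(tm)
  if (length(ages) != nrow(freqs)) {
    stop_temob("'ages' must align with the site table")
  }
  young <- !is.na(ages) & ages < age_max
  vr <- freqs$frequency < freq_max & (freqs$private | young)
  car <- tm$states == 1L & !is.na(tm$states)
  per_acc <- colSums(car[vr, , drop = FALSE])
  fam_tot <- table(tm$sites$family)
  fams <- names(fam_tot)[fam_tot > min_family_tips]
  per_family <- do.call(rbind, lapply(fams, function(f) {
    sel <- vr & tm$sites$family == f
    data.frame(family = f, n_tips_total = as.integer(fam_tot[[f]]),
               n_very_recent = sum(sel), stringsAsFactors = FALSE)
  }))
  per_family <- per_family %||% data.frame(family = character(0),
                                           n_tips_total = integer(0),
                                           n_very_recent = integer(0))
  fam_counts <- do.call(rbind, lapply(fams, function(f) {
    colSums(car[vr & tm$sites$family == f, , drop = FALSE])
  }))
  rownames(fam_counts) <- fams
  list(very_recent = vr, per_accession = per_acc, per_family = per_family,
       per_accession_by_family = fam_counts)
}

#' No-intercept regression slope of TIP on SNP differences
#'
#' Closed-form least squares through the origin: `slope = sum(xy) / sum(x^2)`
#' with the standard no-intercept standard error.
#'
#' @param snp_diff,tip_diff aligned pairwise difference counts.
#' @return list with `slope`, `se`, `n`.
#' @export
fit_no_intercept_slope <- function(snp_diff, tip_diff) {
  stopifnot(length(snp_diff) == length(tip_diff))
  ok <- !is.na(snp_diff) & !is.na(tip_diff)
  x <- as.numeric(snp_diff[ok]); y <- as.numeric(tip_diff[ok])
  if (!length(x) || all(x == 0)) {
    stop_temob("slope undefined: no pairs with non-zero SNP difference")
  }
  sxx <- sum(x * x)
  slope <- sum(x * y) / sxx
  n <- length(x)
  se <- if (n > 1) sqrt(sum((y - slope * x)^2) / (n - 1) / sxx) else NA_real_
  list(slope = slope, se = se, n = n)
}

#' Estimate the TE insertion substitution rate and elimination fraction
#'
#' Fits no-intercept TIP-versus-SNP slopes separately over closely related
#' pairs and over all (mostly distant) pairs. The close-pair slope times the
#' genome-wide SNP substitution rate gives the TE insertion substitution
#' rate. Because selection also removes SNPs over long timescales, observed
#' distant-pair SNP divergence is rescaled to its neutral equivalent by
#' `kappa`, the ratio of synonymous-SNP fractions (distant over close). The
#' fraction of insertions eventually eliminated is then
#' `1 - slope_all / (kappa * slope_close)`, clipped to \[0, 1).
#'
#' @param pairs data.frame with columns snp_diff, syn_snp_diff, tip_diff and
#'   either a `class` column ("close" / "all") or nothing, in which case
#'   pairs with `snp_diff < close_threshold` form the close class and all
#'   pairs form the other.
#' @param snp_rate SNP substitutions per genome per generation, default
#'   0.2511.
#' @param close_threshold SNP-difference ceiling defining close pairs,
#'   default 500.
#' @return an object of class `rate_estimate`: list with `slope_close`,
#'   `slope_all` (each slope +/- se), `kappa`, `substitution_rate` (+/- se),
#'   `elimination_fraction` (+/- se).
#' @examples
#' p <- data.frame(snp_diff = c(100, 200), syn_snp_diff = c(30, 60),
#'                 tip_diff = c(30, 61), class = c("close", "close"))
#' fit_no_intercept_slope(p$snp_diff, p$tip_diff)$slope  # 0.304
#' @export
estimate_rates <- function(pairs, snp_rate = 0.2511, close_threshold = 500) {
  stopifnot(all(c("snp_diff", "syn_snp_diff", "tip_diff") %in% names(pairs)))
  if (!is.null(pairs$class)) {
    close <- pairs[pairs$class == "close", , drop = FALSE]
    all_p <- pairs[pairs$class == "all", , drop = FALSE]
  } else {
    close <- pairs[pairs$snp_diff < close_threshold, , drop = FALSE]
    all_p <- pairs
  }
  if (!nrow(close) || !nrow(all_p)) {
    stop_temob("both close and all pair classes are required")
  }
  f_close <- fit_no_intercept_slope(close$snp_diff, close$tip_diff)
  f_all <- fit_no_intercept_slope(all_p$snp_diff, all_p$tip_diff)
  syn_close <- sum(close$syn_snp_diff) / sum(close$snp_diff)
  syn_all <- sum(all_p$syn_snp_diff) / sum(all_p$snp_diff)
  kappa <- syn_all / syn_close
  if (!is.finite(kappa) || kappa <= 0) {
    stop_temob("selection scaling factor kappa is not positive")
  }
  subst <- f_close$slope * snp_rate
  subst_se <- f_close$se * snp_rate
  ratio <- f_all$slope / (kappa * f_close$slope)
  elim <- min(max(1 - ratio, 0), 1 - 1e-12)
  # delta-method SE treating kappa as fixed
  elim_se <- ratio * sqrt((f_all$se / f_all$slope)^2 +
                            (f_close$se / f_close$slope)^2)
  out <- list(slope_close = f_close, slope_all = f_all, kappa = kappa,
              syn_frac_close = syn_close, syn_frac_all = syn_all,
              substitution_rate = subst, substitution_rate_se = subst_se,
              elimination_fraction = elim, elimination_fraction_se = elim_se,
              snp_rate = snp_rate)
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate>\n")
  cat(sprintf("  slope close pairs: %.4g +/- %.2g (n=%d)\n",
              x$slope_close$slope, x$slope_close$se, x$slope_close$n))
  cat(sprintf("  slope all pairs:   %.4g +/- %.2g (n=%d)\n",
              x$slope_all$slope, x$slope_all$se, x$slope_all$n))
  cat(sprintf("  kappa (syn-frac distant/close): %.3f\n", x$kappa))
  cat(sprintf("  substitution rate: %.4g +/- %.2g per genome per generation\n",
              x$substitution_rate, x$substitution_rate_se))
  cat(sprintf("  elimination fraction: %.4f\n", x$elimination_fraction))
  invisible(x)
}
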