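#' Synthetic cohort generation
#'
#' These functions generate a synthetic accession cohort with the statistical
#' structure the downstream pipeline assumes: a structured panel with genetic
#' groups and kinship, a frequency-skewed TIP genotype matrix backed by
#' per-accession read evidence, pairwise SNP/TIP divergence consistent with a
#' tunable transposition rate and retention probability, climate gradients
#' correlated with the groups, a large-effect modifier allele with G-by-E
#' interactions, and carrier-shifted expression. Every generating parameter
#' is recorded in the `truth` component so parameter-recovery tests can be
#' written against it alone.
#'
#' @name synthgen
NULL

# Toy TE family table: family, superfamily, and whether the family is used
# for very recent (currently mobile) insertions.
te_family_table <- function() {
  data.frame(
    family = c("ATCOPIA78", "ATCOPIA93", "ATGP3", "ATHILA6A",
               "VANDAL21", "ATMU5", "ATHATN1", "TA11", "ATREP3"),
    superfamily = c("COPIA", "COPIA", "GYPSY", "GYPSY",
                    "MuDR", "MuDR", "hAT", "LINE", "HELITRON"),
    mobile = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Draw TIP site frequencies from the configured spectrum
#'
#' Site frequencies follow Beta(`shape`, 1) scaled to (0, 0.5], so that
#' `shape` < 1 skews the folded spectrum towards rare variants; as `shape`
#' approaches 0 essentially all sites become private.
#'
#' @param n number of draws.
#' @param shape Beta shape parameter (> 0).
#' @return numeric vector of frequencies in (0, 0.5].
#' @export
r_tip_frequency <- function(n, shape) {
  check_scalar(shape, "shape", lower = 1e-12)
  0.5 * stats::rbeta(n, shape, 1)
}

#' Simulate the accession panel and kinship structure
#'
#' Accessions are split into `n_groups` genetic groups. Latent genotype
#' factors are drawn as group centroids scaled by `kinship_strength` plus
#' isotropic noise; the kinship matrix is their centred cross-product and the
#' panel carries its top three principal components (the population-structure
#' covariates used by the downstream models), a modifier-allele indicator and
#' geographic coordinates correlated with the groups.
#'
#' @param config a [cohort_config()].
#' @return list with `panel` (data.frame: accession, group, PC1-PC3,
#'   modifier, latitude, longitude) and `kinship` (n x n matrix).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_accessions
    g <- as.integer(ceiling(seq_len(n) * config$n_groups / n))
    p <- 20L
    centers <- matrix(stats::rnorm(config$n_groups * p), config$n_groups, p)
    x <- centers[g, , drop = FALSE] * config$kinship_strength +
      matrix(stats::rnorm(n * p), n, p)
    xc <- scale(x, center = TRUE, scale = FALSE)
    kin <- tcrossprod(xc) / p
    acc <- sprintf("acc%04d", seq_len(n))
    dimnames(kin) <- list(acc, acc)
    ev <- eigen(kin, symmetric = TRUE)
    pcs <- ev$vectors[, 1:3, drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[1:3], 0)), 3)
    # deterministic sign: largest-|loading| entry positive
    for (j in 1:3) if (pcs[which.max(abs(pcs[, j])), j] < 0) pcs[, j] <- -pcs[, j]
    lat_centers <- seq(38, 60, length.out = config$n_groups)
    lon_centers <- seq(-8, 25, length.out = config$n_groups)
    panel <- data.frame(
      accession = acc,
      group = paste0("g", g),
      PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3],
      modifier = stats::rbinom(n, 1, config$modifier_freq),
      latitude = lat_centers[g] + stats::rnorm(n, 0, 2),
      longitude = lon_centers[g] + stats::rnorm(n, 0, 3),
      stringsAsFactors = FALSE
    )
    list(panel = panel, kinship = kin)
  })
}

#' Simulate current and future climate tables
#'
#' The 19 bioclimatic variables are generated from a three-factor latent
#' model (a group-level climatic driver, a latitudinal gradient and an
#' accession-specific factor) plus independent noise, so climate is
#' correlated with genetic structure as it is in a real range-wide panel.
#' Future values shift each variable by `config$future_shift` standard
#' deviations of its current distribution.
#'
#' @param panel panel data.frame from [simulate_panel()].
#' @param config a [cohort_config()].
#' @return data.frame with columns accession, epoch ("current"/"future") and
#'   BIO01..BIO19 on their raw scales.
#' @export
simulate_climate <- function(panel, config) {
  with_seed(config$seed + 4L, {
    n <- nrow(panel)
    gidx <- as.integer(factor(panel$group))
    gcenter <- stats::rnorm(max(gidx))
    f <- cbind(gcenter[gidx] + 0.3 * stats::rnorm(n),
               as.numeric(scale(panel$latitude)),
               stats::rnorm(n))
    loadings <- matrix(stats::rnorm(19 * 3), 19, 3)
    base_mean <- c(rep(12, 11), rep(600, 8))     # temperature-like, then precipitation-like
    base_sd <- c(rep(5, 11), rep(180, 8))
    z <- f %*% t(loadings) + 0.4 * matrix(stats::rnorm(n * 19), n, 19)
    raw <- sweep(sweep(z, 2, base_sd, "*"), 2, base_mean, "+")
    colnames(raw) <- bio_names()
    cur_sd <- apply(raw, 2, stats::sd)
    shift <- stats::setNames(rep(0, 19), bio_names())
    shift[names(config$future_shift)] <- config$future_shift
    fut <- sweep(raw, 2, shift * cur_sd, "+")
    out <- rbind(
      data.frame(accession = panel$accession, epoch = "current", raw,
                 stringsAsFactors = FALSE, check.names = FALSE),
      data.frame(accession = panel$accession, epoch = "future", fut,
                 stringsAsFactors = FALSE, check.names = FALSE)
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate a toy gene annotation
#'
#' Genes are laid out as non-overlapping intervals (>= 1 kb apart) on a
#' single linear chromosome with 0-based half-open coordinates, each with
#' 5'UTR / exon / intron / 3'UTR substructure, a strand, and pseudogene /
#' essentiality flags plus a pN/pS value. The central
#' `config$centromere_frac` of the chromosome is flagged centromeric.
#'
#' @param config a [cohort_config()].
#' @return a `gene_annotation` object: list with `genes` and `features`
#'   data.frames, `centromere` (start, end) and `genome_length`.
#' @export
simulate_genes <- function(config) {
  with_seed(config$seed + 6L, {
    L <- config$genome_length
    genes <- list(); feats <- list()
    pos <- 3000; i <- 0L
    while (i < config$n_genes && pos < L - 8000) {
      i <- i + 1L
      len <- sample(1500:4000, 1)
      start <- pos
      end <- start + len
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene%04d", i)
      # substructure along genomic coordinates; UTR identity follows strand
      n_ex <- sample(2:4, 1)
      cuts <- sort(sample(seq(start + 150, end - 150, by = 50), 2 * n_ex - 1))
      bounds <- c(start, cuts, end)
      blocks <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
      type <- rep(c("exon", "intron"), length.out = nrow(blocks))
      # first and last coding blocks become UTRs (strand decides which is 5')
      utr_low <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
      utr_high <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
      type[1] <- utr_low
      type[length(type)] <- utr_high
      feats[[i]] <- data.frame(gene_id = gid, type = type,
                               start = blocks$start, end = blocks$end,
                               stringsAsFactors = FALSE)
      genes[[i]] <- data.frame(
        gene_id = gid, chrom = "chr1", start = start, end = end,
        strand = strand,
        pseudogene = stats::runif(1) < 0.05,
        essential = stats::runif(1) < 0.10,
        pnps = stats::rgamma(1, shape = 2, rate = 10),
        stringsAsFactors = FALSE
      )
      pos <- end + sample(1500:6000, 1)
    }
    cen_len <- round(config$centromere_frac * L)
    ann <- list(
      genes = do.call(rbind, genes),
      features = do.call(rbind, feats),
      centromere = c(start = round((L - cen_len) / 2),
                     end = round((L + cen_len) / 2)),
      genome_length = L
    )
    class(ann) <- "gene_annotation"
    ann
  })
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes on a %.3g-bp chromosome (%d features)\n",
              nrow(x$genes), x$genome_length, nrow(x$features)))
  invisible(x)
}

# expected very-recent count per accession under the generating GLM
vr_lambda <- function(panel, climate_z, config) {
  eta <- log(config$vr_mean) + log(config$modifier_effect) * panel$modifier
  for (b in names(config$env_effects)) {
    eta <- eta + config$env_effects[[b]] * climate_z[, b]
  }
  for (b in names(config$gxe_effects)) {
    eta <- eta + config$gxe_effects[[b]] * panel$modifier * climate_z[, b]
  }
  exp(eta)
}

# z-score the current-epoch climate block (internal; mirrors zscore_climate)
current_climate_z <- function(climate) {
  cur <- climate[climate$epoch == "current", bio_names(), drop = FALSE]
  as.matrix(scale(cur))
}

#' Simulate TIP sites, genotype truth and per-accession read evidence
#'
#' Background TIP sites are placed on the toy chromosome with carrier
#' frequencies drawn from the configured spectrum ([r_tip_frequency()]).
#' Very recent insertions are added as private sites whose per-accession
#' counts are Poisson with a log link on the modifier allele and the
#' configured climate effects, so the expected count in modifier carriers is
#' `modifier_effect` times that in non-carriers at average climate. For every
#' accession-site pair, positive / negative / flanking coverages are drawn
#' as independent Poissons so that true carriers usually pass the genotyping
#' rules, and configured fractions of sites are planted with violations of
#' each filter (sub-threshold read depth, too few informative genomes,
#' positive never above negative coverage, fragmented/ancestral absence
#' flags, HELITRON presence calls). All planted structure is recorded in the
#' returned `truth`.
#'
#' @param panel panel data.frame from [simulate_panel()].
#' @param config a [cohort_config()].
#' @param climate optional climate table from [simulate_climate()]; generated
#'   on the fly when missing (climate only enters through the very-recent
#'   count model).
#' @return list with `candidates` (BED-like per-sample call records, one row
#'   per accession x site, including reference-supporting observations),
#'   `truth` (per-site truth table: true interval, family, class, carriers,
#'   frequency, age, window SNP count, violation label, very-recent flag)
#'   and `vr_counts` (true very-recent insertion count per accession).
#' @export
simulate_tip_data <- function(panel, config, climate = NULL) {
  if (is.null(climate)) climate <- simulate_climate(panel, config)
  climate_z <- current_climate_z(climate)
  with_seed(config$seed + 2L, {
    n <- nrow(panel)
    fam <- te_family_table()
    pres_fams <- fam[fam$superfamily != "HELITRON", ]
    mob_fams <- fam[fam$mobile, ]

    # --- background sites -------------------------------------------------
    ns <- config$n_sites
    lambda <- vr_lambda(panel, climate_z, config)
    vr_counts <- stats::rpois(n, if (config$base_rate > 0) lambda else 0)
    n_vr <- sum(vr_counts)
    slots <- seq(200L, config$genome_length - 400L, by = 200L)
    if (ns + n_vr > length(slots)) {
      stop_temob("too many sites for the configured genome length")
    }
    positions <- sample(slots, ns + n_vr)

    is_absence <- stats::runif(ns) < config$frac_absence
    fi <- ifelse(is_absence,
                 sample(which(fam$superfamily %in% c("HELITRON", "MuDR", "hAT")),
                        ns, replace = TRUE),
                 sample(which(fam$family %in% pres_fams$family), ns,
                        replace = TRUE))
    freq <- r_tip_frequency(ns, config$sfs_shape)
    ncar <- pmax(1L, stats::rbinom(ns, n, freq))
    carriers <- lapply(ncar, function(k) sample.int(n, k))

    # planted violations on disjoint background-site sets
    n_lo_dp <- round(config$frac_low_dp * ns)
    n_lo_inf <- if (n >= config$min_informative) {
      round(config$frac_low_informative * ns)
    } else 0L
    n_het <- round(config$frac_het_like * ns)
    pres_idx <- which(!is_absence)
    abs_idx <- which(is_absence)
    pick <- pres_idx[sample.int(length(pres_idx))]
    lo_dp <- utils::head(pick, n_lo_dp); pick <- utils::tail(pick, -n_lo_dp)
    het <- utils::head(pick, n_het); pick <- utils::tail(pick, -n_het)
    n_heli <- min(2L, length(pick))
    heli <- utils::head(pick, n_heli); pick <- utils::tail(pick, -n_heli)
    lo_inf <- utils::head(c(pick, abs_idx), n_lo_inf)
    flagged <- setdiff(abs_idx[stats::runif(length(abs_idx)) <
                                 config$frac_flagged_absence], lo_inf)
    fi[heli] <- which(fam$superfamily == "HELITRON")[1]

    violation <- rep("none", ns)
    violation[lo_dp] <- "low_dp"
    violation[lo_inf] <- "low_informative"
    violation[het] <- "het_like"
    violation[flagged] <- "flagged_absence"
    violation[heli] <- "helitron_presence"

    # --- very recent private sites ---------------------------------------
    vr_owner <- rep(seq_len(n), vr_counts)
    vr_fi <- sample(which(fam$family %in% mob_fams$family), n_vr, replace = TRUE)

    sites <- data.frame(
      truth_id = sprintf("ts%05d", seq_len(ns + n_vr)),
      chrom = "chr1",
      pos = c(positions[seq_len(ns)], positions[ns + seq_len(n_vr)]),
      family = fam$family[c(fi, vr_fi)],
      superfamily = fam$superfamily[c(fi, vr_fi)],
      class = c(ifelse(is_absence, "absence", "presence"),
                rep("presence", n_vr)),
      violation = c(violation, rep("none", n_vr)),
      very_recent = c(rep(FALSE, ns), rep(TRUE, n_vr)),
      stringsAsFactors = FALSE
    )
    carriers <- c(carriers, as.list(vr_owner))
    sites$n_carriers_true <- lengths(carriers)
    sites$freq_true <- sites$n_carriers_true / n
    # true ages: background ages grow with frequency; very recent < 1000
    sites$age_true <- c(
      pmax(200, 40000 * freq * exp(stats::rnorm(ns, 0, 0.3))),
      stats::runif(n_vr, 0, 1000)
    )
    sites$window_snps <- ifelse(
      sites$n_carriers_true >= 2,
      stats::rpois(nrow(sites), 70000 * config$mu * sites$age_true),
      NA_integer_
    )

    m <- nrow(sites)
    # --- evidence matrices (site x accession) -----------------------------
    carrier_m <- matrix(FALSE, m, n)
    for (s in seq_len(m)) carrier_m[s, carriers[[s]]] <- TRUE
    # uninformative genomes are drawn among non-carriers; carriers always get
    # callable variant evidence (depth >= 3) so planted clean sites survive
    na_m <- matrix(stats::runif(m * n) < config$na_rate, m, n) & !carrier_m
    if (length(lo_inf)) {
      # leave exactly min_informative - 1 informative genomes
      for (s in lo_inf) {
        keep <- sample.int(n, config$min_informative - 1L)
        na_m[s, ] <- TRUE
        na_m[s, keep] <- FALSE
        carrier_m[s, ] <- carrier_m[s, ] & !na_m[s, ]
        if (!any(carrier_m[s, ])) carrier_m[s, keep[1]] <- TRUE
      }
    }
    pos_cov <- matrix(0L, m, n)
    neg_cov <- matrix(stats::rpois(m * n, 10), m, n)
    flank_cov <- matrix(stats::rpois(m * n, 10), m, n)
    ci <- which(carrier_m)
    pos_cov[ci] <- 3L + stats::rpois(length(ci), 5)
    neg_cov[ci] <- stats::rpois(length(ci), 1)
    flank_cov[ci] <- 8L + stats::rpois(length(ci), 4)
    if (length(lo_dp)) {
      idx <- which(carrier_m[lo_dp, , drop = FALSE])
      pos_cov[lo_dp, ][idx] <- pmin(pos_cov[lo_dp, ][idx], 2L)
    }
    if (length(het)) {
      # heterozygous-like: still callable as present, but pos <= neg always
      idx <- which(carrier_m[het, , drop = FALSE])
      p0 <- 3L + stats::rpois(length(idx), 1)
      pos_cov[het, ][idx] <- p0
      neg_cov[het, ][idx] <- p0 + stats::rpois(length(idx), 1)
      flank_cov[het, ][idx] <- 5L * (neg_cov[het, ][idx] + 2L)
    }
    nai <- which(na_m)
    pos_cov[nai] <- 0L
    # uninformative genomes stay below callable depth by construction
    neg_cov[nai] <- pmin(stats::rpois(length(nai), 0.3), 2L)
    flank_cov[nai] <- stats::rpois(length(nai), 0.5)

    # --- flatten to candidate call records --------------------------------
    span <- 5L
    jit_l <- matrix(0L, m, n); jit_r <- matrix(0L, m, n)
    jit_l[ci] <- sample(0:20, length(ci), replace = TRUE)
    jit_r[ci] <- sample(0:20, length(ci), replace = TRUE)
    start_m <- matrix(sites$pos, m, n) - jit_l
    end_m <- matrix(sites$pos + span, m, n) + jit_r
    split_m <- matrix(0L, m, n)
    split_m[ci] <- pmax(0L, pos_cov[ci] - stats::rpois(length(ci), 2))
    cen <- simulate_genes(config)$centromere  # same centromere definition
    in_cen <- sites$pos >= cen["start"] & sites$pos < cen["end"]
    candidates <- data.frame(
      sample = rep(panel$accession, each = m),
      chrom = "chr1",
      start = as.vector(start_m),
      end = as.vector(end_m),
      family = rep(sites$family, n),
      superfamily = rep(sites$superfamily, n),
      class = rep(sites$class, n),
      split_left = as.vector(split_m),
      split_right = as.vector(pos_cov - split_m),
      disc_left = as.vector(split_m),
      disc_right = as.vector(pos_cov - split_m),
      pos_cov = as.vector(pos_cov),
      neg_cov = as.vector(neg_cov),
      flank_cov = as.vector(flank_cov),
      library = rep(paste0("lib_", panel$accession), each = m),
      centromeric = rep(in_cen, n),
      spans_donor = FALSE,
      fragmented_ref = rep(sites$violation == "flagged_absence" &
                             seq_len(m) %% 2L == 0L, n),
      ancestral_outgroup = rep(sites$violation == "flagged_absence" &
                                 seq_len(m) %% 2L == 1L, n),
      stringsAsFactors = FALSE
    )
    truth <- list(
      sites = sites,
      carriers = carriers,
      vr_counts = stats::setNames(vr_counts, panel$accession),
      lambda = stats::setNames(lambda, panel$accession),
      config = config
    )
    list(candidates = candidates, truth = truth, vr_counts = truth$vr_counts)
  })
}

#' Simulate pairwise SNP / TIP divergence tables
#'
#' Close pairs (recently diverged accessions) accumulate TIP differences in
#' proportion to SNP differences with the true slope
#' `base_rate / snp_rate`. Distant pairs have their observed SNP divergence
#' deflated by selection (factor `1 / kappa_true` relative to neutral), a
#' correspondingly higher synonymous fraction, and TIP differences attenuated
#' by the long-term retention probability, so the elimination fraction
#' recoverable downstream is `1 - retention_prob`.
#'
#' @param panel panel data.frame.
#' @param config a [cohort_config()].
#' @return data.frame with columns acc_a, acc_b, snp_diff, syn_snp_diff,
#'   tip_diff, class ("close"/"all").
#' @export
simulate_divergence_pairs <- function(panel, config) {
  with_seed(config$seed + 3L, {
    n <- nrow(panel)
    draw_pair <- function(k, same_group) {
      a <- sample.int(n, k, replace = TRUE)
      b <- vapply(a, function(i) {
        pool <- if (same_group) {
          setdiff(which(panel$group == panel$group[i]), i)
        } else setdiff(seq_len(n), i)
        if (!length(pool)) pool <- setdiff(seq_len(n), i)
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      cbind(a, b)
    }
    cl <- draw_pair(config$n_close_pairs, TRUE)
    di <- draw_pair(config$n_distant_pairs, FALSE)
    snp_cl <- stats::rpois(nrow(cl), config$close_snp_mean)
    snp_di <- stats::rpois(nrow(di), config$distant_snp_mean)
    tip_cl <- stats::rpois(nrow(cl), config$slope_true * snp_cl)
    tip_di <- stats::rpois(nrow(di), config$slope_true * config$retention_prob *
                             config$kappa_true * snp_di)
    syn_cl <- stats::rbinom(nrow(cl), snp_cl, config$syn_frac_close)
    syn_di <- stats::rbinom(nrow(di), snp_di,
                            min(1, config$syn_frac_close * config$kappa_true))
    data.frame(
      acc_a = panel$accession[c(cl[, 1], di[, 1])],
      acc_b = panel$accession[c(cl[, 2], di[, 2])],
      snp_diff = c(snp_cl, snp_di),
      syn_snp_diff = c(syn_cl, syn_di),
      tip_diff = c(tip_cl, tip_di),
      class = rep(c("close", "all"), c(nrow(cl), nrow(di))),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate SNP counts in dating windows
#'
#' Draws the maximum pairwise SNP count observed among carriers within the
#' dating window around an insertion of age `age`, under the generative model
#' SNPs ~ Poisson(window_length * mu * age).
#'
#' @param age insertion age in generations (recycled).
#' @param n number of windows.
#' @param window_length window length in bp (default 70 kb).
#' @param mu per-site per-generation mutation rate.
#' @return integer vector of SNP counts.
#' @export
simulate_window_snps <- function(age, n = length(age), window_length = 70000,
                                 mu = 7e-9) {
  stats::rpois(n, window_length * mu * rep_len(age, n))
}

#' Simulate a gene expression matrix with carrier-shifted genes
#'
#' Each gene gets a log-normal baseline; for a configured fraction of genic
#' TIPs, the expression of carrier accessions at the assigned gene is
#' multiplied by `config$expr_effect_size` (0 gives a full knock-out). The
#' affected site/gene pairs and their effects are recorded in the returned
#' `effects` table.
#'
#' @param panel panel data.frame.
#' @param tip_truth `truth` component of [simulate_tip_data()].
#' @param genes a `gene_annotation`.
#' @param config a [cohort_config()].
#' @return list with `expression` (genes x accessions matrix) and `effects`
#'   (data.frame: truth_id, gene_id, effect).
#' @export
simulate_expression <- function(panel, tip_truth, genes, config) {
  with_seed(config$seed + 5L, {
    n <- nrow(panel)
    gdf <- genes$genes
    ng <- nrow(gdf)
    base <- stats::rnorm(ng, 4, 0.5)
    expr <- exp(matrix(base, ng, n) + matrix(stats::rnorm(ng * n, 0, 0.2), ng, n))
    dimnames(expr) <- list(gdf$gene_id, panel$accession)
    sites <- tip_truth$sites
    # genic = within the gene body or within 250 bp of it
    gi <- findInterval(sites$pos, gdf$start - 250)
    gene_hit <- ifelse(gi >= 1 & gi <= ng & sites$pos < gdf$end[pmax(gi, 1)] + 250,
                       gdf$gene_id[pmax(gi, 1)], NA_character_)
    genic <- which(!is.na(gene_hit) & sites$class == "presence")
    eff <- genic[stats::runif(length(genic)) < config$expr_effect_frac]
    effects <- data.frame(truth_id = sites$truth_id[eff],
                          gene_id = gene_hit[eff],
                          effect = rep_len(config$expr_effect_size,
                                           length(eff)),
                          stringsAsFactors = FALSE)
    for (k in seq_along(eff)) {
      s <- eff[k]
      expr[gene_hit[s], tip_truth$carriers[[s]]] <-
        expr[gene_hit[s], tip_truth$carriers[[s]]] * config$expr_effect_size
    }
    list(expression = expr, effects = effects)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs every component generator under a single configuration and bundles
#' the results with a `truth` record sufficient for parameter-recovery tests.
#' Identical configuration (including seed) gives a byte-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `panel`,
#'   `kinship`, `candidates`, `pairs`, `climate`, `expression`, `genes` and
#'   `truth`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_accessions = 40, n_sites = 30,
#'                                      vr_mean = 1, min_informative = 20,
#'                                      seed = 7))
#' coh
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_accessions < 2) stop_temob("n_accessions must be >= 2")
  pk <- simulate_panel(config)
  climate <- simulate_climate(pk$panel, config)
  genes <- simulate_genes(config)
  td <- simulate_tip_data(pk$panel, config, climate = climate)
  pairs <- simulate_divergence_pairs(pk$panel, config)
  ex <- simulate_expression(pk$panel, td$truth, genes, config)
  truth <- td$truth
  truth$expr_effects <- ex$effects
  truth$pairs <- list(slope_true = config$slope_true,
                      retention_prob = config$retention_prob,
                      kappa_true = config$kappa_true)
  out <- list(panel = pk$panel, kinship = pk$kinship,
              candidates = td$candidates, pairs = pairs, climate = climate,
              expression = ex$expression, genes = genes, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d accessions, %d true sites (%d very recent), %d divergence pairs\n",
              nrow(x$panel), nrow(x$truth$sites), sum(x$truth$sites$very_recent),
              nrow(x$pairs)))
  invisible(x)
}

#' Match genotyped sites back to planted truth sites
#'
#' Links rows of a genotyped `tip_matrix` to the generator's truth table by
#' family, variant class and representative position (within `tol` bp), for
#' parameter-recovery analyses.
#'
#' @param tm a `tip_matrix`.
#' @param truth_sites the `sites` truth table of a `synthetic_cohort`.
#' @param tol maximum position discrepancy in bp, default 50.
#' @return integer vector, one entry per `tm` site: row index into
#'   `truth_sites`, or NA when unmatched.
#' @export
match_planted_sites <- function(tm, truth_sites, tol = 50) {
  stopifnot(inherits(tm, "tip_matrix"))
  vapply(seq_len(nrow(tm$sites)), function(i) {
    cand <- which(truth_sites$family == tm$sites$family[i] &
                    truth_sites$class == tm$sites$class[i] &
                    abs(truth_sites$pos - tm$sites$pos[i]) <= tol)
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(truth_sites$pos[cand] - tm$sites$pos[i]))]
  }, 1L)
}
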