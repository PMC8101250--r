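#' Gene-feature assignment, recurrence nulls and expression impact
#'
#' @name impact
NULL

#' Assign TIP positions to gene features
#'
#' Each position receives exactly one category, tested in precedence order:
#' exon > 5'UTR > 3'UTR > intron > promoter (strand-aware, <= 250 bp
#' upstream of the gene) > near (<= 250 bp downstream) > within_2kb
#' (<= 2 kb from the nearest gene) > intergenic (> 2 kb away).
#'
#' @param positions integer vector of TIP positions (0-based).
#' @param genes a `gene_annotation`.
#' @param near_bp promoter/near distance, default 250.
#' @param far_bp outer distance for `within_2kb`, default 2000.
#' @return data.frame: position, gene_id (NA for intergenic), category.
#' @export
assign_tip_to_feature <- function(positions, genes, near_bp = 250,
                                  far_bp = 2000) {
  stopifnot(inherits(genes, "gene_annotation"))
  if (any(positions < 0 | positions >= genes$genome_length)) {
    stop_temob("positions must lie on the chromosome [0, genome_length)")
  }
  gdf <- genes$genes[order(genes$genes$start), , drop = FALSE]
  feats <- genes$features
  cat_out <- character(length(positions))
  gene_out <- rep(NA_character_, length(positions))
  # precedence among overlapping features within the gene body
  prec <- c(exon = 1, five_prime_UTR = 2, three_prime_UTR = 3, intron = 4)
  for (i in seq_along(positions)) {
    p <- positions[i]
    gi <- findInterval(p, gdf$start)   # last gene starting at or before p
    inside <- gi >= 1 && p < gdf$end[max(gi, 1)]
    if (inside) {
      g <- gdf[gi, ]
      f <- feats[feats$gene_id == g$gene_id & feats$start <= p & p < feats$end, ]
      ftype <- if (nrow(f)) f$type[which.min(prec[f$type])] else "intron"
      cat_out[i] <- switch(ftype,
                           exon = "exon",
                           five_prime_UTR = "utr5",
                           three_prime_UTR = "utr3",
                           "intron")
      gene_out[i] <- g$gene_id
      next
    }
    # distance to the nearest genes on either side
    left <- if (gi >= 1) gdf[gi, ] else NULL       # gene ending before p
    right <- if (gi < nrow(gdf)) gdf[gi + 1, ] else NULL
    d_left <- if (!is.null(left)) p - left$end + 1 else Inf
    d_right <- if (!is.null(right)) right$start - p else Inf
    if (min(d_left, d_right) > far_bp) {
      cat_out[i] <- "intergenic"
      next
    }
    nearest <- if (d_left <= d_right) left else right
    d <- min(d_left, d_right)
    gene_out[i] <- nearest$gene_id
    if (d <= near_bp) {
      upstream <- (nearest$strand == "+" && p < nearest$start) ||
        (nearest$strand == "-" && p >= nearest$end)
      cat_out[i] <- if (upstream) "promoter" else "near"
    } else {
      cat_out[i] <- "within_2kb"
    }
  }
  data.frame(position = positions, gene_id = gene_out, category = cat_out,
             stringsAsFactors = FALSE)
}

#' Permutation null for the number of gene loci hit by TIPs
#'
#' Redistributes `n_tips` positions uniformly over the genome `replicates`
#' times and counts, per replicate, the gene loci with at least one TIP
#' inside or within `near_bp` of the gene, and those with at least
#' `multi_min` such TIPs. Returns the mean and SD over replicates.
#'
#' @param n_tips number of TIPs to redistribute.
#' @param genes a `gene_annotation`.
#' @param replicates number of random redistributions, default 10.
#' @param near_bp proximity window, default 250.
#' @param multi_min hit count defining a multi-hit gene, default 3.
#' @param seed integer seed.
#' @return list with `genes_hit` (mean, sd), `multi_hit` (mean, sd) and
#'   `per_replicate` data.frame.
#' @export
recurrence_null <- function(n_tips, genes, replicates = 10, near_bp = 250,
                            multi_min = 3, seed = 1) {
  stopifnot(inherits(genes, "gene_annotation"))
  check_scalar(n_tips, "n_tips", lower = 1, integer = TRUE)
  check_scalar(replicates, "replicates", lower = 1, integer = TRUE)
  gdf <- genes$genes[order(genes$genes$start), , drop = FALSE]
  L <- genes$genome_length
  ext_start <- pmax(0, gdf$start - near_bp)
  ext_end <- pmin(L, gdf$end + near_bp)
  if (any(utils::head(ext_end, -1) > utils::tail(ext_start, -1))) {
    stop_temob("extended gene intervals overlap; reduce near_bp or respace genes")
  }
  with_seed(seed, {
    res <- t(vapply(seq_len(replicates), function(r) {
      p <- stats::runif(n_tips, 0, L)
      gi <- findInterval(p, ext_start)
      hit_gene <- gi >= 1 & p < ext_end[pmax(gi, 1)]
      counts <- tabulate(gi[hit_gene], nbins = nrow(gdf))
      c(hit = sum(counts >= 1), multi = sum(counts >= multi_min))
    }, c(hit = 0, multi = 0)))
  })
  list(
    genes_hit = c(mean = mean(res[, "hit"]), sd = stats::sd(res[, "hit"])),
    multi_hit = c(mean = mean(res[, "multi"]), sd = stats::sd(res[, "multi"])),
    per_replicate = data.frame(replicate = seq_len(replicates),
                               genes_hit = res[, "hit"],
                               multi_hit = res[, "multi"])
  )
}

#' Fisher test for multi-hit gene enrichment
#'
#' Builds the 2x2 table \[multi-hit, other-hit\] for the observed counts
#' against the (rounded) permutation expectation and runs Fisher's exact
#' test.
#'
#' @param obs_multi observed number of multi-hit genes.
#' @param obs_total observed number of genes hit at least once.
#' @param null_multi expected number of multi-hit genes under the null.
#' @param null_total expected number of genes hit under the null.
#' @return list with `odds_ratio` (sample odds ratio of the table), `p`,
#'   `table`.
#' @export
multi_hit_enrichment <- function(obs_multi, obs_total, null_multi,
                                 null_total) {
  tab <- matrix(c(obs_multi, obs_total - obs_multi,
                  round(null_multi), round(null_total) - round(null_multi)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("multi_hit", "other_hit")))
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_temob("degenerate 2x2 table for multi-hit enrichment")
  }
  ft <- stats::fisher.test(tab)
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = odds, p = ft$p.value, table = tab)
}

#' Carrier versus non-carrier expression ratio for one TIP
#'
#' Compares mean expression of the assigned gene between carrier and
#' non-carrier accessions (NA-state genomes excluded). A pseudocount is
#' added to both means before forming the ratio; the TE-containing allele is
#' flagged as an effective knock-out when the ratio falls at or below
#' `knockout_threshold`.
#'
#' @param states integer vector of per-accession states (1/0/NA), named by
#'   accession.
#' @param expr numeric vector of per-accession expression of the gene, named
#'   by accession (accessions absent from `expr` have no expression data).
#' @param eps pseudocount on both means, default 0.5.
#' @param knockout_threshold C/NC ratio at or below which the allele counts
#'   as a knock-out, default 0.1.
#' @return one-row data.frame: n_carrier, n_noncarrier, carrier_mean,
#'   noncarrier_mean, ratio, log2_ratio, knockout, defined.
#' @export
expression_ratio <- function(states, expr, eps = 0.5,
                             knockout_threshold = 0.1) {
  common <- intersect(names(states)[!is.na(states)], names(expr)[!is.na(expr)])
  carr <- common[states[common] == 1L]
  ncar <- common[states[common] == 0L]
  if (!length(carr) || !length(ncar)) {
    return(data.frame(n_carrier = length(carr), n_noncarrier = length(ncar),
                      carrier_mean = NA_real_, noncarrier_mean = NA_real_,
                      ratio = NA_real_, log2_ratio = NA_real_,
                      knockout = NA, defined = FALSE))
  }
  cm <- mean(expr[carr]); nm <- mean(expr[ncar])
  ratio <- (cm + eps) / (nm + eps)
  data.frame(n_carrier = length(carr), n_noncarrier = length(ncar),
             carrier_mean = cm, noncarrier_mean = nm, ratio = ratio,
             log2_ratio = log2(ratio), knockout = ratio <= knockout_threshold,
             defined = TRUE)
}

#' Expression impact of every genic TIP in a matrix
#'
#' Assigns each site to a gene ([assign_tip_to_feature()]) and computes
#' [expression_ratio()] for sites with an assigned gene present in the
#' expression matrix.
#'
#' @param tm a `tip_matrix`.
#' @param expression genes x accessions expression matrix.
#' @param genes a `gene_annotation`.
#' @param ... passed to [expression_ratio()].
#' @return data.frame with site_id, gene_id, category and the
#'   [expression_ratio()] columns.
#' @export
expression_impacts <- function(tm, expression, genes, ...) {
  stopifnot(inherits(tm, "tip_matrix"))
  ann <- assign_tip_to_feature(tm$sites$pos, genes)
  rows <- lapply(seq_len(nrow(tm$sites)), function(i) {
    if (is.na(ann$gene_id[i]) || !(ann$gene_id[i] %in% rownames(expression))) {
      return(NULL)
    }
    r <- expression_ratio(tm$states[i, ], expression[ann$gene_id[i], ], ...)
    cbind(data.frame(site_id = tm$sites$site_id[i], gene_id = ann$gene_id[i],
                     category = ann$category[i], stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame()
}

#' Excess of extreme expression ratios over a carrier-resampling null
#'
#' For each TIP the null re-draws a pseudo-carrier set of the same size among
#' accessions with expression data and recomputes the log2 C/NC ratio;
#' `n_resamples` such null data sets are built. Extremeness thresholds are
#' the `probs` quantiles of the pooled null ratios. Per insertion category
#' and direction, the excess is the observed number of TIPs beyond the
#' threshold minus the null mean, with the resampling SD.
#'
#' @param impacts output of [expression_impacts()] (defined rows are used).
#' @param tm the `tip_matrix` the impacts came from.
#' @param expression genes x accessions expression matrix.
#' @param n_resamples number of null resamples (> 0), default 100.
#' @param probs lower/upper quantile thresholds, default c(0.025, 0.975).
#' @param eps pseudocount, as in [expression_ratio()].
#' @param seed integer seed.
#' @return data.frame per category x direction: observed, null_mean,
#'   null_sd, excess.
#' @export
extreme_ratio_excess <- function(impacts, tm, expression, n_resamples = 100,
                                 probs = c(0.025, 0.975), eps = 0.5,
                                 seed = 1) {
  check_scalar(n_resamples, "n_resamples", lower = 1, integer = TRUE)
  imp <- impacts[impacts$defined, , drop = FALSE]
  if (!nrow(imp)) return(data.frame())
  acc_expr <- colnames(expression)
  with_seed(seed, {
    null_log2 <- matrix(NA_real_, nrow(imp), n_resamples)
    for (i in seq_len(nrow(imp))) {
      ev <- expression[imp$gene_id[i], acc_expr]
      ev <- ev[!is.na(ev)]
      k <- imp$n_carrier[i]
      if (k >= length(ev)) next
      for (r in seq_len(n_resamples)) {
        idx <- sample.int(length(ev), k)
        cm <- mean(ev[idx]); nm <- mean(ev[-idx])
        null_log2[i, r] <- log2((cm + eps) / (nm + eps))
      }
    }
    lo <- stats::quantile(null_log2, probs[1], na.rm = TRUE)
    hi <- stats::quantile(null_log2, probs[2], na.rm = TRUE)
    cats <- sort(unique(imp$category))
    out <- do.call(rbind, lapply(cats, function(cc) {
      sel <- imp$category == cc
      obs_lo <- sum(imp$log2_ratio[sel] < lo)
      obs_hi <- sum(imp$log2_ratio[sel] > hi)
      null_lo <- colSums(null_log2[sel, , drop = FALSE] < lo, na.rm = TRUE)
      null_hi <- colSums(null_log2[sel, , drop = FALSE] > hi, na.rm = TRUE)
      data.frame(category = cc,
                 direction = c("negative", "positive"),
                 observed = c(obs_lo, obs_hi),
                 null_mean = c(mean(null_lo), mean(null_hi)),
                 null_sd = c(stats::sd(null_lo), stats::sd(null_hi)),
                 excess = c(obs_lo - mean(null_lo), obs_hi - mean(null_hi)),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Combined expression effect of all TIPs at a gene
#'
#' Pools every accession carrying any of the gene's TE-containing alleles
#' against accessions carrying none, forms the pooled-mean log2 ratio, tests
#' carrier versus non-carrier expression with a Wilcoxon rank-sum test, and
#' flags whether the per-allele effects are direction-concordant.
#'
#' @param site_ids sites (rows of `tm`) whose TIPs hit the gene.
#' @param tm a `tip_matrix`.
#' @param gene_expr named per-accession expression vector of the gene.
#' @param eps pseudocount, default 0.5.
#' @return one-row data.frame: n_alleles, n_carrier, n_noncarrier,
#'   log2_ratio, p, concordant.
#' @export
combined_gene_effect <- function(site_ids, tm, gene_expr, eps = 0.5) {
  idx <- match(site_ids, tm$sites$site_id)
  if (anyNA(idx)) stop_temob("unknown site ids")
  st <- tm$states[idx, , drop = FALSE]
  has_expr <- names(gene_expr)[!is.na(gene_expr)]
  carr <- intersect(colnames(st)[colSums(st == 1L, na.rm = TRUE) > 0], has_expr)
  nonc <- intersect(colnames(st)[colSums(st == 0L, na.rm = TRUE) == colSums(!is.na(st))
                                 & colSums(!is.na(st)) > 0], has_expr)
  if (!length(carr) || !length(nonc)) {
    stop_temob("combined effect undefined: need both carriers and non-carriers")
  }
  cm <- mean(gene_expr[carr]); nm <- mean(gene_expr[nonc])
  wt <- stats::wilcox.test(gene_expr[carr], gene_expr[nonc], exact = FALSE)
  per_allele <- vapply(seq_along(idx), function(k) {
    r <- expression_ratio(st[k, ], gene_expr, eps = eps)
    if (r$defined) r$log2_ratio else NA_real_
  }, 0)
  signs <- sign(per_allele[!is.na(per_allele) & per_allele != 0])
  data.frame(n_alleles = length(site_ids), n_carrier = length(carr),
             n_noncarrier = length(nonc),
             log2_ratio = log2((cm + eps) / (nm + eps)),
             p = wt$p.value,
             concordant = length(signs) > 0 && length(unique(signs)) == 1)
}

#' Rank correlation between per-gene TIP counts and pN/pS
#'
#' @param hits per-gene TIP counts.
#' @param pnps aligned pN/pS values.
#' @return list with `rho`, `p`, `n` (Spearman).
#' @export
correlate_hits_pnps <- function(hits, pnps) {
  ok <- !is.na(hits) & !is.na(pnps)
  if (sum(ok) < 3) stop_temob("need at least 3 genes with both values")
  if (stats::sd(hits[ok]) == 0 || stats::sd(pnps[ok]) == 0) {
    stop_temob("correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(hits[ok], pnps[ok],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
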