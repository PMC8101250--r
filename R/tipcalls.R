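#' Population-level TIP genotyping
#'
#' Builds a species-wide TIP genotype matrix from per-sample candidate call
#' records: overlapping candidate intervals of the same TE family and variant
#' class are merged transitively into population-level sites, each accession
#' is assigned a present / absent / NA state from its read evidence, and a
#' cascade of population filters removes unreliable sites while logging
#' per-filter removal counts.
#'
#' @name tipcalls
NULL

candidate_call_columns <- function() {
  c("sample", "chrom", "start", "end", "family", "superfamily", "class",
    "split_left", "split_right", "disc_left", "disc_right",
    "pos_cov", "neg_cov", "flank_cov", "library",
    "centromeric", "spans_donor", "fragmented_ref", "ancestral_outgroup")
}

validate_calls <- function(calls) {
  missing <- setdiff(candidate_call_columns(), names(calls))
  if (length(missing)) {
    stop_temob("candidate calls missing columns: ",
               paste(missing, collapse = ", "))
  }
  if (any(calls$start >= calls$end)) {
    stop_temob("candidate calls must have start < end (0-based half-open)")
  }
  counts <- c("split_left", "split_right", "disc_left", "disc_right",
              "pos_cov", "neg_cov", "flank_cov")
  if (any(as.matrix(calls[counts]) < 0)) {
    stop_temob("read counts and coverages must be non-negative")
  }
  invisible(TRUE)
}

#' Merge per-sample candidate calls into population-level TIP sites
#'
#' Candidate intervals on the same chromosome with the same TE family and
#' variant class that overlap are merged transitively (the union-find closure
#' of pairwise interval overlap) into a single site. The representative
#' position is the midpoint of the intersection of the member intervals, or
#' of their union when the intersection is empty. Per accession, the read
#' evidence of its member calls is aggregated with `aggregate` (max by
#' default). A site is retained at this stage only if at least one sample
#' has positive supporting coverage of at least `dp` reads.
#'
#' @param calls candidate call data.frame (see [candidate_call_columns()] and
#'   [read_candidate_calls()]); records with an empty/NA family are skipped
#'   with a warning.
#' @param dp minimum supporting-read depth (DP filter), default 3.
#' @param aggregate how per-accession evidence across member calls is
#'   combined: "max" (default) or "sum".
#' @return an object of class `merged_sites`: list with `sites` (data.frame:
#'   site_id, chrom, start, end, pos, family, superfamily, class,
#'   fragmented_ref, ancestral_outgroup), `accessions`, per-accession
#'   evidence matrices `pos_cov`, `neg_cov`, `flank_cov` (sites x
#'   accessions), and a `provenance` data.frame.
#' @export
merge_candidate_sites <- function(calls, dp = 3, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(calls) == 0) {
    return(empty_merged_sites())
  }
  validate_calls(calls)
  bad_family <- is.na(calls$family) | calls$family == ""
  if (any(bad_family)) {
    warning(sum(bad_family), " calls with unknown TE family skipped")
    calls <- calls[!bad_family, , drop = FALSE]
  }
  key <- paste(calls$chrom, calls$family, calls$class, sep = "\r")
  gr <- GenomicRanges::GRanges(
    seqnames = key,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end)
  )
  # transitive overlap closure; gapwidth 0 keeps book-ended intervals apart
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  member_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

  accessions <- sort(unique(calls$sample))
  m <- length(red)
  n <- length(accessions)
  acc_idx <- match(calls$sample, accessions)
  mf <- factor(member_of, levels = seq_len(m))  # numeric group order

  agg_mat <- function(v) {
    mat <- matrix(0, m, n)
    if (aggregate == "max") {
      # max per (site, accession) via ordered overwrite
      o <- order(v)
      idx <- cbind(member_of, acc_idx)[o, , drop = FALSE]
      mat[idx] <- v[o]
    } else {
      t1 <- tapply(v, list(mf, acc_idx), sum)
      mat[cbind(as.integer(rownames(t1))[row(t1)],
                as.integer(colnames(t1))[col(t1)])] <- ifelse(is.na(t1), 0, t1)
    }
    mat
  }
  pos_cov <- agg_mat(calls$pos_cov)
  neg_cov <- agg_mat(calls$neg_cov)
  flank_cov <- agg_mat(calls$flank_cov)

  # representative position: intersection midpoint, else union midpoint
  int_start <- as.vector(tapply(calls$start, mf, max))
  int_end <- as.vector(tapply(calls$end, mf, min))
  uni_start <- as.vector(tapply(calls$start, mf, min))
  uni_end <- as.vector(tapply(calls$end, mf, max))
  rep_pos <- ifelse(int_start < int_end,
                    floor((int_start + int_end) / 2),
                    floor((uni_start + uni_end) / 2))

  first <- match(seq_len(m), member_of)
  sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(m)),
    chrom = calls$chrom[first],
    start = as.integer(uni_start),
    end = as.integer(uni_end),
    pos = as.integer(rep_pos),
    family = calls$family[first],
    superfamily = calls$superfamily[first],
    class = calls$class[first],
    fragmented_ref = as.vector(tapply(calls$fragmented_ref, mf, any)),
    ancestral_outgroup = as.vector(tapply(calls$ancestral_outgroup, mf, any)),
    centromeric = as.vector(tapply(calls$centromeric, mf, any)),
    stringsAsFactors = FALSE
  )
  # order by genomic position for reproducibility regardless of input order
  o <- order(sites$chrom, sites$start, sites$family, sites$class)
  sites <- sites[o, , drop = FALSE]
  sites$site_id <- sprintf("site%05d", seq_len(m))
  rownames(sites) <- NULL
  pos_cov <- pos_cov[o, , drop = FALSE]
  neg_cov <- neg_cov[o, , drop = FALSE]
  flank_cov <- flank_cov[o, , drop = FALSE]

  keep <- apply(pos_cov, 1, max) >= dp
  prov <- data.frame(step = "dp_filter", removed = sum(!keep),
                     remaining = sum(keep), stringsAsFactors = FALSE)
  out <- list(
    sites = sites[keep, , drop = FALSE],
    accessions = accessions,
    pos_cov = pos_cov[keep, , drop = FALSE],
    neg_cov = neg_cov[keep, , drop = FALSE],
    flank_cov = flank_cov[keep, , drop = FALSE],
    dp = dp,
    provenance = prov
  )
  rownames(out$sites) <- NULL
  class(out) <- "merged_sites"
  out
}

empty_merged_sites <- function() {
  out <- list(sites = data.frame(), accessions = character(0),
              pos_cov = matrix(0, 0, 0), neg_cov = matrix(0, 0, 0),
              flank_cov = matrix(0, 0, 0), dp = 3,
              provenance = data.frame(step = "dp_filter", removed = 0L,
                                      remaining = 0L))
  class(out) <- "merged_sites"
  out
}

#' @export
print.merged_sites <- function(x, ...) {
  cat(sprintf("<merged_sites> %d sites x %d accessions (DP >= %d)\n",
              nrow(x$sites), length(x$accessions), x$dp))
  invisible(x)
}

#' Call per-accession presence / absence / NA states at merged sites
#'
#' A genome is called *present* when its positive (variant-supporting)
#' coverage reaches `dp` and a coverage drop is observed at the site:
#' reference-supporting coverage below `drop_ratio` times the mean flanking
#' coverage (100 bp up/downstream). It is called *absent* when, failing a
#' qualifying presence, the reference-supporting (negative) coverage reaches
#' `dp`. Genomes with too little coverage for either call are NA
#' (uninformative) and are excluded from the frequency denominator.
#'
#' @param merged a `merged_sites` object.
#' @param dp minimum read depth for either call (default: the DP used at
#'   merging).
#' @param drop_ratio site coverage must be below this fraction of flanking
#'   coverage for a presence call; default 0.8.
#' @return an object of class `tip_matrix`: list with `sites` (site table
#'   plus informative / carrier counts, frequency, MAF), `states` (sites x
#'   accessions integer matrix, 1 present / 0 absent / NA), `accessions`,
#'   the evidence matrices, and `provenance`.
#' @export
call_site_states <- function(merged, dp = NULL, drop_ratio = 0.8) {
  stopifnot(inherits(merged, "merged_sites"))
  dp <- dp %||% merged$dp
  present <- merged$pos_cov >= dp & merged$neg_cov < drop_ratio * merged$flank_cov
  absent <- !present & merged$neg_cov >= dp
  states <- matrix(NA_integer_, nrow(merged$sites), length(merged$accessions))
  states[present] <- 1L
  states[absent] <- 0L
  dimnames(states) <- list(merged$sites$site_id, merged$accessions)
  out <- list(
    sites = merged$sites,
    states = states,
    accessions = merged$accessions,
    pos_cov = merged$pos_cov,
    neg_cov = merged$neg_cov,
    flank_cov = merged$flank_cov,
    provenance = merged$provenance
  )
  class(out) <- "tip_matrix"
  refresh_site_stats(out)
}

# recompute informative / carrier counts, frequency and MAF
refresh_site_stats <- function(tm) {
  inf <- rowSums(!is.na(tm$states))
  car <- rowSums(tm$states == 1L, na.rm = TRUE)
  tm$sites$informative <- as.integer(inf)
  tm$sites$carriers <- as.integer(car)
  tm$sites$frequency <- ifelse(inf > 0, car / inf, NA_real_)
  tm$sites$maf <- pmin(tm$sites$frequency, 1 - tm$sites$frequency)
  tm
}

#' @export
print.tip_matrix <- function(x, ...) {
  cat(sprintf("<tip_matrix> %d sites x %d accessions\n",
              nrow(x$sites), length(x$accessions)))
  if (nrow(x$provenance)) {
    cat("  filters applied:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("   - %-22s removed %5d, remaining %5d\n",
                  x$provenance$step[i], x$provenance$removed[i],
                  x$provenance$remaining[i]))
    }
  }
  invisible(x)
}

subset_tip_matrix <- function(tm, keep, step) {
  removed <- sum(!keep)
  tm$sites <- tm$sites[keep, , drop = FALSE]
  tm$states <- tm$states[keep, , drop = FALSE]
  tm$pos_cov <- tm$pos_cov[keep, , drop = FALSE]
  tm$neg_cov <- tm$neg_cov[keep, , drop = FALSE]
  tm$flank_cov <- tm$flank_cov[keep, , drop = FALSE]
  rownames(tm$sites) <- NULL
  tm$provenance <- rbind(tm$provenance,
                         data.frame(step = step, removed = removed,
                                    remaining = nrow(tm$sites),
                                    stringsAsFactors = FALSE))
  tm
}

#' Apply the population-level filter cascade
#'
#' Removes, in order and with per-filter removal counts logged in the
#' provenance: (0) presence variants of blacklisted superfamilies (HELITRON
#' presences by default, which the detection pipeline cannot call reliably);
#' (1) sites with fewer than `min_informative` informative genomes;
#' (2) presence sites where no carrier has positive coverage strictly above
#' its negative coverage (heterozygous-like calls, unexpected in a selfer and
#' suggestive of very recent lab transposition); (3) absence sites flagged as
#' fragmented reference TE sequences or as ancestral (present in the
#' outgroup genome).
#'
#' @param tm a `tip_matrix` from [call_site_states()].
#' @param min_informative informative-genome threshold, default 100.
#' @param blacklist data.frame with columns superfamily, class; presence
#'   variants matching a row are dropped. NULL disables the blacklist.
#' @return the filtered `tip_matrix` with extended provenance.
#' @export
apply_population_filters <- function(tm, min_informative = 100,
                                     blacklist = data.frame(
                                       superfamily = "HELITRON",
                                       class = "presence")) {
  stopifnot(inherits(tm, "tip_matrix"))
  if (!is.null(blacklist) && nrow(tm$sites)) {
    bad <- interaction(tm$sites$superfamily, tm$sites$class) %in%
      interaction(blacklist$superfamily, blacklist$class)
    tm <- subset_tip_matrix(tm, !bad, "family_blacklist")
  }
  if (nrow(tm$sites)) {
    tm <- subset_tip_matrix(tm, tm$sites$informative >= min_informative,
                            "min_informative")
  }
  if (nrow(tm$sites)) {
    pos_gt_neg <- tm$pos_cov > tm$neg_cov & !is.na(tm$states) & tm$states == 1L
    ok <- rowSums(pos_gt_neg) > 0 | tm$sites$class != "presence"
    tm <- subset_tip_matrix(tm, ok, "het_like_presence")
  }
  if (nrow(tm$sites)) {
    flagged <- tm$sites$class == "absence" &
      (tm$sites$fragmented_ref | tm$sites$ancestral_outgroup)
    tm <- subset_tip_matrix(tm, !flagged, "flagged_absence")
  }
  refresh_site_stats(tm)
}

#' Genotype a cohort end to end
#'
#' Convenience wrapper chaining [merge_candidate_sites()],
#' [call_site_states()] and [apply_population_filters()].
#'
#' @param calls candidate call data.frame.
#' @param dp DP filter (default 3).
#' @param drop_ratio coverage-drop ratio for presence calls (default 0.8).
#' @param min_informative informative-genome threshold (default 100).
#' @param ... passed to [apply_population_filters()].
#' @return a filtered `tip_matrix`.
#' @export
genotype_tips <- function(calls, dp = 3, drop_ratio = 0.8,
                          min_informative = 100, ...) {
  merged <- merge_candidate_sites(calls, dp = dp)
  tm <- call_site_states(merged, dp = dp, drop_ratio = drop_ratio)
  apply_population_filters(tm, min_informative = min_informative, ...)
}

#' Filter TE-capture insertion calls
#'
#' Applies the sequence-capture filter for de novo insertions: per-side read
#' support (split plus discordant reads) must lie within
#' `[min_support, max_support]` on both sides, calls overlapping centromeric
#' repeats or spanning the donor TE sequence are excluded, and calls detected
#' in more than one library are discarded entirely (only sample-specific
#' insertions are retained).
#'
#' @param calls candidate call data.frame.
#' @param min_support minimum per-side read support, default 2.
#' @param max_support maximum per-side read support, default 15.
#' @return list with `retained` (the surviving calls) and `counts` (table of
#'   retained insertions per TE family per library).
#' @export
capture_filter <- function(calls, min_support = 2, max_support = 15) {
  validate_calls(calls)
  left <- calls$split_left + calls$disc_left
  right <- calls$split_right + calls$disc_right
  ok <- left >= min_support & left <= max_support &
    right >= min_support & right <= max_support &
    !calls$centromeric & !calls$spans_donor
  kept <- calls[ok, , drop = FALSE]
  # sample specificity: the same site seen in >1 library is excluded everywhere
  site_key <- paste(kept$chrom, kept$start, kept$end, kept$family, sep = "\r")
  nlib <- tapply(kept$library, site_key, function(l) length(unique(l)))
  kept <- kept[nlib[site_key] == 1L, , drop = FALSE]
  rownames(kept) <- NULL
  counts <- as.data.frame(table(family = kept$family, library = kept$library),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  list(retained = kept, counts = counts[counts$n > 0, , drop = FALSE])
}
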