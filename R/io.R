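#' Readers and writers for the pipeline's file formats
#'
#' Candidate calls, TIP matrices, divergence pairs and expression matrices
#' travel as TSV; climate tables as CSV; gene annotation as GFF3
#' (1-based closed on disk, 0-based half-open in memory); the synthetic
#' truth record as versioned JSON.
#'
#' @name temob-io
NULL

#' @rdname temob-io
#' @param calls candidate call data.frame.
#' @param path file path.
#' @export
write_candidate_calls <- function(calls, path) {
  validate_calls(calls)
  utils::write.table(calls[candidate_call_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname temob-io
#' @export
read_candidate_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_calls(calls)
  calls
}

#' @rdname temob-io
#' @param tm a `tip_matrix`.
#' @export
write_tip_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "tip_matrix"))
  meta <- tm$sites[, c("site_id", "chrom", "start", "end", "pos", "family",
                       "superfamily", "class", "informative", "carriers",
                       "frequency", "maf")]
  st <- tm$states
  utils::write.table(cbind(meta, st), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname temob-io
#' @export
read_tip_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("site_id", "chrom", "start", "end", "pos", "family",
                 "superfamily", "class", "informative", "carriers",
                 "frequency", "maf")
  acc <- setdiff(names(df), meta_cols)
  states <- as.matrix(df[acc])
  mode(states) <- "integer"
  dimnames(states) <- list(df$site_id, acc)
  sites <- df[meta_cols]
  sites$fragmented_ref <- FALSE
  sites$ancestral_outgroup <- FALSE
  out <- list(sites = sites, states = states, accessions = acc,
              pos_cov = NULL, neg_cov = NULL, flank_cov = NULL,
              provenance = data.frame(step = "read_from_file",
                                      removed = NA_integer_,
                                      remaining = nrow(sites)))
  class(out) <- "tip_matrix"
  refresh_site_stats(out)
}

#' @rdname temob-io
#' @param pairs divergence-pair data.frame.
#' @export
write_divergence_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname temob-io
#' @export
read_divergence_pairs <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname temob-io
#' @param climate climate data.frame.
#' @export
write_climate <- function(climate, path) {
  utils::write.csv(climate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname temob-io
#' @export
read_climate <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname temob-io
#' @param expression genes x accessions matrix.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname temob-io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname temob-io
#' @param genes a `gene_annotation`.
#' @export
write_gene_annotation <- function(genes, path) {
  stopifnot(inherits(genes, "gene_annotation"))
  gdf <- genes$genes
  fdf <- genes$features
  # 0-based half-open -> 1-based closed
  gr_gene <- GenomicRanges::GRanges(
    seqnames = gdf$chrom,
    ranges = IRanges::IRanges(start = gdf$start + 1L, end = gdf$end),
    strand = gdf$strand,
    type = "gene", ID = gdf$gene_id,
    pseudogene = tolower(as.character(gdf$pseudogene)),
    essential = tolower(as.character(gdf$essential)),
    pnps = sprintf("%.6g", gdf$pnps)
  )
  strand_of <- gdf$strand[match(fdf$gene_id, gdf$gene_id)]
  gr_feat <- GenomicRanges::GRanges(
    seqnames = gdf$chrom[match(fdf$gene_id, gdf$gene_id)],
    ranges = IRanges::IRanges(start = fdf$start + 1L, end = fdf$end),
    strand = strand_of,
    type = fdf$type,
    ID = sprintf("%s.f%03d", fdf$gene_id, stats::ave(seq_len(nrow(fdf)),
                                                     fdf$gene_id,
                                                     FUN = seq_along)),
    Parent = fdf$gene_id
  )
  gr_cen <- GenomicRanges::GRanges(
    seqnames = gdf$chrom[1],
    ranges = IRanges::IRanges(start = genes$centromere["start"] + 1L,
                              end = genes$centromere["end"]),
    type = "centromere", ID = "centromere1"
  )
  gr_region <- GenomicRanges::GRanges(
    seqnames = gdf$chrom[1],
    ranges = IRanges::IRanges(start = 1L, end = genes$genome_length),
    type = "region", ID = "chr1"
  )
  all_gr <- suppressWarnings(c(gr_region, gr_cen, gr_gene, gr_feat))
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

#' @rdname temob-io
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  first_chr <- function(x) vapply(x, function(v) {
    if (length(v)) as.character(v)[1] else NA_character_
  }, "")
  df$type <- as.character(df$type)
  region <- df[df$type == "region", ][1, ]
  cen <- df[df$type == "centromere", ][1, ]
  gdf <- df[df$type == "gene", ]
  fdf <- df[df$type %in% c("exon", "intron", "five_prime_UTR",
                           "three_prime_UTR"), ]
  genes <- data.frame(
    gene_id = as.character(gdf$ID), chrom = as.character(gdf$seqnames),
    start = gdf$start - 1L, end = gdf$end,
    strand = as.character(gdf$strand),
    pseudogene = tolower(first_chr(gdf$pseudogene)) == "true",
    essential = tolower(first_chr(gdf$essential)) == "true",
    pnps = as.numeric(first_chr(gdf$pnps)),
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    gene_id = first_chr(fdf$Parent), type = fdf$type,
    start = fdf$start - 1L, end = fdf$end, stringsAsFactors = FALSE
  )
  out <- list(genes = genes, features = features,
              centromere = c(start = cen$start - 1L, end = cen$end),
              genome_length = region$end)
  class(out) <- "gene_annotation"
  out
}

#' @rdname temob-io
#' @param truth truth record of a `synthetic_cohort`.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  tr$schema_version <- "1.0"
  tr$carriers <- lapply(tr$carriers, as.integer)
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write every component of a synthetic cohort to a directory
#'
#' Produces the downstream input files: `candidates.tsv`, `pairs.tsv`,
#' `climate.csv`, `expression.tsv`, `genes.gff3`, `panel.tsv`,
#' `kinship.tsv` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_candidate_calls(cohort$candidates, file.path(dir, "candidates.tsv"))
  write_divergence_pairs(cohort$pairs, file.path(dir, "pairs.tsv"))
  write_climate(cohort$climate, file.path(dir, "climate.csv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gene_annotation(cohort$genes, file.path(dir, "genes.gff3"))
  utils::write.table(cohort$panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$kinship, file.path(dir, "kinship.tsv"), sep = "\t",
                     quote = FALSE)
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
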