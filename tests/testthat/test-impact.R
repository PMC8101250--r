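# hand-laid toy annotation: two + strand genes and one - strand gene
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1",
    start = c(10000L, 20000L, 30000L),
    end = c(14000L, 23000L, 33000L),
    strand = c("+", "+", "-"),
    pseudogene = FALSE, essential = FALSE, pnps = 0.2,
    stringsAsFactors = FALSE
  )
  features <- rbind(
    data.frame(gene_id = "g1",
               type = c("five_prime_UTR", "exon", "intron", "exon",
                        "three_prime_UTR"),
               start = c(10000L, 10500L, 11500L, 12500L, 13500L),
               end = c(10500L, 11500L, 12500L, 13500L, 14000L)),
    data.frame(gene_id = "g2", type = c("five_prime_UTR", "exon",
                                        "three_prime_UTR"),
               start = c(20000L, 20600L, 22400L),
               end = c(20600L, 22400L, 23000L)),
    data.frame(gene_id = "g3", type = c("three_prime_UTR", "exon",
                                        "five_prime_UTR"),
               start = c(30000L, 30600L, 32400L),
               end = c(30600L, 32400L, 33000L))
  )
  structure(list(genes = genes, features = features,
                 centromere = c(start = 45000L, end = 55000L),
                 genome_length = 100000L),
            class = "gene_annotation")
}

test_that("feature assignment follows category precedence and distances", {
  g <- toy_genes()
  cases <- list(
    list(11000, "exon", "g1"),         # inside first exon
    list(10200, "utr5", "g1"),
    list(13700, "utr3", "g1"),
    list(12000, "intron", "g1"),
    list(19800, "promoter", "g2"),     # 200 bp upstream of + strand TSS
    list(14100, "near", "g1"),         # 101 bp downstream of + strand gene
    list(33100, "promoter", "g3"),     # upstream of - strand gene (high side)
    list(29800, "near", "g3"),         # downstream of - strand gene
    list(15000, "within_2kb", "g1"),
    list(36000, "intergenic", NA),     # > 2 kb from everything
    list(600, "intergenic", NA)
  )
  res <- assign_tip_to_feature(vapply(cases, `[[`, 0, 1), g)
  expect_identical(res$category, vapply(cases, `[[`, "", 2))
  expect_identical(res$gene_id, vapply(cases, function(c) {
    if (is.na(c[[3]])) NA_character_ else c[[3]]
  }, ""))
  expect_error(assign_tip_to_feature(-5, g), "chromosome")
  expect_error(assign_tip_to_feature(1e6, g), "chromosome")
})

test_that("every TIP receives exactly one category", {
  g <- simulate_genes(tiny_config())
  set.seed(2)
  pos <- sample.int(g$genome_length, 4000) - 1L
  res <- assign_tip_to_feature(pos, g)
  expect_equal(nrow(res), 4000L)
  expect_true(all(res$category %in% c("exon", "utr5", "utr3", "intron",
                                      "promoter", "near", "within_2kb",
                                      "intergenic")))
  expect_equal(sum(table(res$category)), 4000L)
})

test_that("recurrence null matches exact enumeration on tiling toy genomes", {
  # two equal genes tiling the genome: expected hits = 2 - 2 * (1/2)^n
  tile <- structure(list(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       start = c(0L, 50000L), end = c(50000L, 100000L),
                       strand = "+", pseudogene = FALSE, essential = FALSE,
                       pnps = 0.2, stringsAsFactors = FALSE),
    features = data.frame(gene_id = character(0), type = character(0),
                          start = integer(0), end = integer(0)),
    centromere = c(start = 0L, end = 0L), genome_length = 100000L),
    class = "gene_annotation")
  for (n in c(1L, 2L, 5L)) {
    r <- recurrence_null(n, tile, replicates = 4000, near_bp = 0, seed = 5)
    expect_equal(unname(r$genes_hit["mean"]), 2 - 2 * 0.5^n,
                 tolerance = 3 * unname(r$genes_hit["sd"]) / sqrt(4000) /
                   max(2 - 2 * 0.5^n, 1))
    if (n == 1L) expect_equal(unname(r$genes_hit["mean"]), 1)  # exactly
  }
  # one gene spanning the whole genome: always exactly 1
  whole <- tile; whole$genes <- tile$genes[1, ]; whole$genes$end <- 100000L
  r1 <- recurrence_null(10, whole, replicates = 50, near_bp = 0, seed = 1)
  expect_equal(unname(r1$genes_hit["mean"]), 1)
  expect_equal(unname(r1$genes_hit["sd"]), 0)
  # determinism under a fixed seed
  g <- toy_genes()
  expect_identical(recurrence_null(50, g, replicates = 10, seed = 3),
                   recurrence_null(50, g, replicates = 10, seed = 3))
})

test_that("multi-hit enrichment odds ratios and edge cases are exact", {
  r <- multi_hit_enrichment(60, 100, 30, 100)
  expect_equal(r$odds_ratio, (60 * 70) / (40 * 30))
  same <- multi_hit_enrichment(30, 100, 30, 100)
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p, 1)
  low <- multi_hit_enrichment(0, 100, 30, 100)
  expect_lt(low$odds_ratio, 1)
  expect_error(multi_hit_enrichment(0, 0, 0, 0), "degenerate")
})

test_that("expression ratios, pseudocounts and knock-out flags are exact", {
  states <- stats::setNames(c(1L, 1L, 0L, 0L, NA), paste0("a", 1:5))
  expr <- stats::setNames(c(2, 2, 8, 8, 100), paste0("a", 1:5))
  r <- expression_ratio(states, expr, eps = 0)
  expect_equal(r$ratio, 0.25)
  expect_equal(r$log2_ratio, -2)
  expect_false(r$knockout)
  # NA-state accession excluded even with extreme expression
  expect_equal(r$n_carrier + r$n_noncarrier, 4)
  # equal means: log2 ratio 0
  expect_equal(expression_ratio(states, stats::setNames(rep(3, 5),
                                                        paste0("a", 1:5)),
                                eps = 0.5)$log2_ratio, 0)
  # all-carriers-zero knock-out
  ko <- expression_ratio(states, stats::setNames(c(0, 0, 9, 11, 1),
                                                 paste0("a", 1:5)))
  expect_true(ko$knockout)
  # no carriers with data: undefined, not fabricated
  und <- expression_ratio(stats::setNames(c(0L, 0L), c("a1", "a2")),
                          expr[1:2])
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
})

test_that("planted expression effects are recovered through the pipeline", {
  cfg <- cohort_config(n_accessions = 150L, n_sites = 150L, vr_mean = 0,
                       sfs_shape = 2, expr_effect_frac = 1,
                       expr_effect_size = 0.25, min_informative = 50L,
                       seed = 77L)
  coh <- simulate_cohort(cfg)
  tm <- genotype_tips(coh$candidates, min_informative = 50)
  imp <- expression_impacts(tm, coh$expression, coh$genes)
  idx <- match_planted_sites(tm, coh$truth$sites)
  eff_sites <- coh$truth$sites$truth_id[idx] %in% coh$truth$expr_effects$truth_id
  hit <- imp[imp$defined & eff_sites[match(imp$site_id, tm$sites$site_id)], ]
  expect_gt(nrow(hit), 5)
  expect_lt(stats::median(hit$ratio), 0.4)  # planted 4-fold reductions
})

test_that("extreme-ratio excess detects planted effects and not noise", {
  cfg0 <- cohort_config(n_accessions = 120L, n_sites = 150L, vr_mean = 0,
                        sfs_shape = 2, expr_effect_frac = 0,
                        min_informative = 50L, seed = 55L)
  coh0 <- simulate_cohort(cfg0)
  tm0 <- genotype_tips(coh0$candidates, min_informative = 50)
  imp0 <- expression_impacts(tm0, coh0$expression, coh0$genes)
  ex0 <- extreme_ratio_excess(imp0, tm0, coh0$expression, n_resamples = 60,
                              seed = 2)
  expect_true(all(abs(ex0$excess) <= 2.5 * pmax(ex0$null_sd, 1)))
  # planted strong reductions give a positive negative-direction excess
  cfg1 <- cohort_config(n_accessions = 120L, n_sites = 150L, vr_mean = 0,
                        sfs_shape = 2, expr_effect_frac = 1,
                        expr_effect_size = 0.1, min_informative = 50L,
                        seed = 56L)
  coh1 <- simulate_cohort(cfg1)
  tm1 <- genotype_tips(coh1$candidates, min_informative = 50)
  imp1 <- expression_impacts(tm1, coh1$expression, coh1$genes)
  ex1 <- extreme_ratio_excess(imp1, tm1, coh1$expression, n_resamples = 60,
                              seed = 2)
  neg <- ex1[ex1$direction == "negative", ]
  expect_gt(sum(neg$excess), 0)
  expect_error(extreme_ratio_excess(imp1, tm1, coh1$expression,
                                    n_resamples = 0), "n_resamples")
})

test_that("combined gene effects pool carriers and flag concordance", {
  # three alleles all halving expression, disjoint carrier sets
  acc <- paste0("a", 1:60)
  states <- rbind(
    c(rep(1L, 5), rep(0L, 55)),
    c(rep(0L, 5), rep(1L, 5), rep(0L, 50)),
    c(rep(0L, 10), rep(1L, 5), rep(0L, 45))
  )
  colnames(states) <- acc
  tm <- structure(list(
    sites = data.frame(site_id = c("s1", "s2", "s3"), chrom = "chr1",
                       start = c(0L, 10L, 20L), end = c(5L, 15L, 25L),
                       pos = c(2L, 12L, 22L), family = "ATCOPIA78",
                       superfamily = "COPIA", class = "presence",
                       fragmented_ref = FALSE, ancestral_outgroup = FALSE),
    states = states, accessions = acc, provenance = data.frame()),
    class = "tip_matrix")
  expr <- stats::setNames(c(rep(4, 15), rep(8, 45)), acc)
  r <- combined_gene_effect(c("s1", "s2", "s3"), tm, expr, eps = 0)
  expect_equal(r$log2_ratio, -1)
  expect_true(r$concordant)
  expect_equal(r$n_carrier, 15)
  # single-allele reduction matches expression_ratio
  r1 <- combined_gene_effect("s1", tm, expr, eps = 0)
  e1 <- expression_ratio(states[1, ], expr, eps = 0)
  expect_equal(r1$log2_ratio, e1$log2_ratio)
  # opposite effects with equal carriers: near zero and non-concordant
  expr2 <- stats::setNames(c(rep(16, 5), rep(4, 5), rep(8, 50)), acc)
  r2 <- combined_gene_effect(c("s1", "s2"), tm, expr2, eps = 0)
  expect_equal(r2$log2_ratio, log2(10 / 8), tolerance = 1e-12)
  expect_false(r2$concordant)
  # all accessions carriers: undefined
  all_st <- tm; all_st$states[1, ] <- 1L
  expect_error(combined_gene_effect("s1", all_st, expr), "undefined")
})

test_that("hit-count / pN-pS correlation behaves at the boundaries", {
  expect_equal(correlate_hits_pnps(1:10, (1:10) / 10)$rho, 1)
  expect_error(correlate_hits_pnps(1:2, c(0.1, 0.2)), "at least 3")
  expect_error(correlate_hits_pnps(rep(1, 5), runif(5)), "constant")
  set.seed(31)
  r <- correlate_hits_pnps(rpois(1000, 2) + seq(0, 0.001, length.out = 1000),
                           runif(1000))
  expect_lt(abs(r$rho), 0.1)
})
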