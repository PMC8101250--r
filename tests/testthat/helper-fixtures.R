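# Shared fixtures and independent oracles used across the suite.

# small, fast cohort configuration for unit tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_accessions = 120L, n_groups = 3L, n_sites = 80L,
                   vr_mean = 1, seed = 42L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# One candidate-call record with sensible defaults.
call_rec <- function(sample, start, end, family = "ATCOPIA78",
                     superfamily = "COPIA", class = "presence",
                     split_left = 2, split_right = 2, disc_left = 0,
                     disc_right = 0, pos_cov = 6, neg_cov = 1,
                     flank_cov = 10, library = paste0("lib_", sample),
                     centromeric = FALSE, spans_donor = FALSE,
                     fragmented_ref = FALSE, ancestral_outgroup = FALSE) {
  data.frame(sample = sample, chrom = "chr1", start = start, end = end,
             family = family, superfamily = superfamily, class = class,
             split_left = split_left, split_right = split_right,
             disc_left = disc_left, disc_right = disc_right,
             pos_cov = pos_cov, neg_cov = neg_cov, flank_cov = flank_cov,
             library = library, centromeric = centromeric,
             spans_donor = spans_donor, fragmented_ref = fragmented_ref,
             ancestral_outgroup = ancestral_outgroup,
             stringsAsFactors = FALSE)
}

# Records for one population site: explicit carriers plus reference-state
# (absent) records to reach the requested number of informative genomes.
site_records <- function(start, end, carriers, n_informative, panel,
                         carrier_args = list(), site_args = list()) {
  absent_n <- n_informative - length(carriers)
  stopifnot(absent_n >= 0)
  non_car <- setdiff(panel, carriers)[seq_len(absent_n)]
  rows <- c(
    lapply(carriers, function(s) {
      do.call(call_rec, c(list(sample = s, start = start, end = end),
                          carrier_args, site_args))
    }),
    lapply(non_car, function(s) {
      do.call(call_rec, c(list(sample = s, start = start, end = end,
                               pos_cov = 0, neg_cov = 10, flank_cov = 10),
                          site_args))
    })
  )
  do.call(rbind, rows)
}

# Independent union-find closure of interval overlap (oracle for merging).
uf_merge_groups <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && starts[i] < ends[j] && starts[j] < ends[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Brute-force no-intercept least squares by iterated grid refinement.
grid_slope <- function(x, y, lo = -10, hi = 10, rounds = 6, points = 401) {
  sse <- function(b) sum((y - b * x)^2)
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = points)
    v <- vapply(grid, sse, 0)
    b <- grid[which.min(v)]
    step <- (hi - lo) / (points - 1)
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

# Brute-force 2-parameter Poisson ML by iterated grid refinement.
grid_poisson_ml <- function(y, x, lo = c(-3, -3), hi = c(3, 3), rounds = 7,
                            points = 61) {
  nll <- function(b0, b1) {
    lam <- exp(b0 + b1 * x)
    sum(lam - y * (b0 + b1 * x))
  }
  for (r in seq_len(rounds)) {
    g0 <- seq(lo[1], hi[1], length.out = points)
    g1 <- seq(lo[2], hi[2], length.out = points)
    v <- outer(g0, g1, Vectorize(nll))
    ix <- which(v == min(v), arr.ind = TRUE)[1, ]
    b <- c(g0[ix[1]], g1[ix[2]])
    step <- (hi - lo) / (points - 1)
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

# Mean silhouette of a 2-D embedding against known labels.
mean_silhouette <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

make_glm_data <- function(n, seed, b0 = log(5), b_mod = log(3.4),
                          b_env = 0.3, b_gxe = 0.25, bio = "BIO05") {
  set.seed(seed)
  data <- data.frame(accession = sprintf("a%04d", 1:n),
                     modifier = rbinom(n, 1, 0.25))
  for (b in bio_cols <- sprintf("BIO%02d", 1:19)) data[[b]] <- rnorm(n)
  eta <- b0 + b_mod * data$modifier + b_env * data[[bio]] +
    b_gxe * data$modifier * data[[bio]]
  data$.truth_eta <- eta
  counts <- rpois(n, exp(eta))
  list(data = data, counts = counts)
}

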