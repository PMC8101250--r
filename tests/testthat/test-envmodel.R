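test_that("climate z-scoring uses current-epoch statistics only", {
  coh <- simulate_cohort(tiny_config())
  cz <- zscore_climate(coh$climate)
  cur <- cz[cz$epoch == "current", ]
  for (b in c("BIO01", "BIO12", "BIO19")) {
    expect_equal(mean(cur[[b]]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(cur[[b]]), 1, tolerance = 1e-10)
  }
  # future value equal to the current mean maps to z-score 0
  fut_raw <- coh$climate[coh$climate$epoch == "future", ]
  fut_raw$BIO01[1] <- mean(coh$climate$BIO01[coh$climate$epoch == "current"])
  cz2 <- zscore_climate(rbind(coh$climate[coh$climate$epoch == "current", ],
                              fut_raw))
  expect_equal(cz2$BIO01[cz2$epoch == "future"][1], 0, tolerance = 1e-12)
  # constant column errors, naming the column
  bad <- coh$climate; bad$BIO07 <- 1
  expect_error(zscore_climate(bad), "BIO07")
  expect_error(zscore_climate(bad[bad$epoch == "future", ]), "current")
})

test_that("Poisson GLM matches an independent ML grid search and reports PVE", {
  set.seed(17)
  for (r in 1:5) {
    n <- 60
    x <- rnorm(n)
    y <- rpois(n, exp(0.8 + 0.5 * x))
    fit <- fit_poisson_glm(y, data.frame(x = x), "x")
    ref <- grid_poisson_ml(y, x)
    expect_equal(unname(fit$coefficients$estimate), ref, tolerance = 1e-6)
    expect_true(fit$pve >= 0 && fit$pve <= 1)
  }
  # intercept-only fit recovers log of the mean, PVE ~ 0
  y0 <- rpois(1000, 5)
  f0 <- fit_poisson_glm(y0, data.frame(x = rnorm(1000)), character(0))
  expect_equal(f0$coefficients$estimate[1], log(mean(y0)), tolerance = 1e-8)
  expect_equal(f0$pve, 0)
  # duplicated covariate: rank-deficiency error naming the term
  df <- data.frame(x = rnorm(50), x2 = 0)
  df$x2 <- df$x
  expect_error(fit_poisson_glm(rpois(50, 3), df, c("x", "x2")), "x2")
  expect_error(fit_poisson_glm(c(-1, 2, 3), data.frame(x = 1:3), "x"),
               "non-negative")
})

test_that("PVE is non-decreasing along nested designs", {
  gd <- make_glm_data(400, seed = 5)
  terms_seq <- list(character(0), "modifier", c("modifier", "BIO05"),
                    c("modifier", "BIO05", "modifier:BIO05"),
                    c("modifier", "BIO05", "modifier:BIO05", "BIO11"))
  pves <- vapply(terms_seq, function(tt) {
    fit_poisson_glm(gd$counts, gd$data, tt)$pve
  }, 0)
  expect_true(all(diff(pves) >= -1e-12))
})

test_that("planted coefficients are recovered with nominal CI coverage", {
  hits <- 0L
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    gd <- make_glm_data(800, seed = 1000 + s)
    fit <- fit_poisson_glm(gd$counts, gd$data,
                           c("modifier", "BIO05", "modifier:BIO05"))
    co <- fit$coefficients
    i <- co$term == "modifier"
    lo <- co$estimate[i] - 1.96 * co$se[i]
    hi <- co$estimate[i] + 1.96 * co$se[i]
    if (lo <= log(3.4) && log(3.4) <= hi) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.88)
  expect_lte(hits / n_seeds, 1)
})

test_that("stepwise selection adds the planted variable and respects the stop rule", {
  gd <- make_glm_data(1000, seed = 77)
  sel <- stepwise_select(gd$counts, gd$data, base_terms = "modifier",
                         candidates = sprintf("BIO%02d", 1:19))
  expect_identical(sel$selected, "modifierxBIO05")
  expect_true(all(c("BIO05", "modifier:BIO05") %in% sel$fit$terms))
  # trace honours the strict > 1% rule on every decision
  added <- sel$trace[sel$trace$added & sel$trace$round > 0, ]
  notadded <- sel$trace[!sel$trace$added, ]
  expect_true(all(added$delta > 0.01))
  expect_true(all(notadded$delta <= 0.01))
  # no candidate related to counts: no additions
  set.seed(9)
  y_null <- rpois(400, 5)
  gd0 <- make_glm_data(400, seed = 9)
  sel0 <- stepwise_select(y_null, gd0$data, base_terms = "modifier",
                          candidates = sprintf("BIO%02d", 1:19))
  expect_length(sel0$selected, 0)
})

test_that("hold-out validation flags planted outliers and ranks designs", {
  gd <- make_glm_data(300, seed = 21)
  counts <- gd$counts
  counts[17] <- counts[17] * 10 + 50      # corrupted accession
  res <- holdout_validation(counts, gd$data,
                            designs = list(G = "modifier"),
                            n_sets = 60, set_size = 30, seed = 4)
  expect_true(gd$data$accession[17] %in% res$outliers)
  expect_lt(length(res$outliers), 6)
  # models including the generating GxE term predict better than G alone
  res2 <- holdout_validation(gd$counts, gd$data,
                             designs = list(G = "modifier",
                                            GxE = c("modifier", "BIO05",
                                                    "modifier:BIO05")),
                             n_sets = 40, set_size = 30, seed = 5)
  expect_lte(res2$predictive_variance[["GxE"]],
             res2$predictive_variance[["G"]])
  expect_error(holdout_validation(gd$counts, gd$data, list(G = "modifier"),
                                  set_size = 300), "smaller")
})

test_that("restricted Mantel honours the permutation conventions", {
  set.seed(3)
  n <- 40
  kin <- tcrossprod(matrix(rnorm(n * 10), n)) / 10
  # monotone association, no kinship structure: p at the permutation floor
  env <- rnorm(n)
  cnt <- round(10 * env) + 50
  r <- restricted_mantel(cnt, env, kin, n_perm = 1000, seed = 8)
  expect_gt(r$statistic, 0.5)
  expect_equal(r$p, 1 / 1001)
  # p can never be zero and respects (1 + b) / (n_perm + 1)
  r0 <- restricted_mantel(rpois(n, 5), env, kin, n_perm = 99, seed = 2)
  expect_gte(r0$p, 1 / 100)
  expect_lte(r0$p, 1)
  expect_error(restricted_mantel(cnt, env, kin[, c(2:n, 1)]), "symmetric")
})

test_that("restricted Mantel agrees with an established partial Mantel", {
  skip_if_not_installed("vegan")
  set.seed(12)
  n <- 30
  kin <- tcrossprod(matrix(rnorm(n * 8), n)) / 8
  cnt <- rpois(n, 6) + round(3 * rowSums(kin))
  env <- rnorm(n) + 0.5 * rowSums(kin)
  ours <- restricted_mantel(cnt, env, kin, n_perm = 500, seed = 1)
  d_cnt <- dist(cnt); d_env <- dist(env)
  rng <- max(kin) - min(kin)
  d_kin <- stats::as.dist(1 - (kin - min(kin)) / rng)
  ref <- vegan::mantel.partial(d_cnt, d_env, d_kin, permutations = 500)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("climatic envelopes are orthonormal with a fixed sign convention", {
  coh <- simulate_cohort(tiny_config())
  cz <- zscore_climate(coh$climate)
  ce <- climatic_envelopes(cz)
  expect_equal(crossprod(ce$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(ce$variance_fraction) <= 1e-12))
  expect_lte(sum(ce$variance_fraction), 1)
  for (j in 1:3) {
    expect_gt(ce$loadings[which.max(abs(ce$loadings[, j])), j], 0)
  }
  # three-factor generative climate: 3 envelopes capture most variance
  expect_gt(sum(ce$variance_fraction), 0.8)
  # duplicated accession rows give identical scores
  dup <- which(ce$accessions %in% coh$panel$accession[1])
  clim2 <- rbind(cz, cz[cz$accession == coh$panel$accession[1], ])
  ce2 <- climatic_envelopes(clim2)
  sc <- ce2$scores[rownames(ce2$scores) == coh$panel$accession[1], ]
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-12)
})

test_that("near-isotropic climate spreads variance over all components", {
  set.seed(6)
  n <- 800
  clim <- data.frame(accession = sprintf("a%04d", 1:n), epoch = "current",
                     matrix(rnorm(n * 19), n, 19))
  names(clim)[3:21] <- sprintf("BIO%02d", 1:19)
  ce <- climatic_envelopes(zscore_climate(clim))
  expect_true(all(ce$variance_fraction < 2 / 19))
  expect_true(all(ce$variance_fraction > 0.5 / 19))
})

test_that("CE-shift associations recover planted shifts and pass controls", {
  coh <- simulate_cohort(tiny_config(n_accessions = 200L, seed = 14L))
  cz <- zscore_climate(coh$climate)
  ce <- climatic_envelopes(cz)
  pcs <- as.matrix(coh$panel[, c("PC1", "PC2", "PC3")])
  acc <- ce$accessions
  # carriers restricted to the top CE2 quartile: strong positive CE2 shift
  top <- acc[order(-ce$scores[, "CE2"])][1:50]
  set.seed(2)
  sets <- c(
    lapply(1:6, function(i) sample(top, 15)),
    lapply(1:6, function(i) sample(acc, 15))       # uniform carriers
  )
  names(sets) <- paste0("gene", seq_along(sets))
  res <- ce_shift_association(sets, ce, pcs)
  planted <- res[res$gene_id %in% paste0("gene", 1:6) & res$envelope == "CE2", ]
  expect_true(all(planted$delta > 0))
  expect_true(all(planted$q < 0.05))
  # BH q-values match an independent textbook step-up within each envelope
  for (env in unique(res$envelope)) {
    sel <- res$envelope == env
    expect_equal(res$q[sel], bh_stepup(res$p[sel]), tolerance = 1e-12)
  }
  # environment shuffling destroys the planted associations
  resp <- ce_shift_association(sets, ce, pcs, permute_env = TRUE, seed = 6)
  expect_lte(sum(resp$significant), 1)
  # genes with too few carriers are skipped with a warning
  small <- c(sets, list(tiny = acc[1:2]))
  expect_warning(ce_shift_association(small, ce, pcs), "fewer than 3")
})

test_that("forecasts satisfy the identity and closed-form log-link checks", {
  gd <- make_glm_data(200, seed = 8)
  fit <- fit_poisson_glm(gd$counts, gd$data,
                         c("modifier", "BIO05", "modifier:BIO05"))
  panel <- data.frame(accession = gd$data$accession, group = "g1",
                      modifier = gd$data$modifier)
  # future = current: every delta exactly 0
  fc0 <- forecast_transposition(fit, gd$data, gd$data, panel)
  expect_lte(max(abs(fc0$per_accession$delta)), 1e-12)
  # single-covariate model: log-count change = beta * delta_z exactly
  fit1 <- fit_poisson_glm(gd$counts, gd$data, "BIO05")
  beta <- fit1$coefficients$estimate[fit1$coefficients$term == "BIO05"]
  fut <- gd$data; fut$BIO05 <- fut$BIO05 + 0.7
  fc1 <- forecast_transposition(fit1, gd$data, fut, panel)
  expect_equal(log(fc1$per_accession$pred_future) -
                 log(fc1$per_accession$pred_current),
               rep(beta * 0.7, 200), tolerance = 1e-10)
  # opposite-sign main and interaction effects move carriers and
  # non-carriers in opposite directions under warming
  gd2 <- make_glm_data(600, seed = 30, b_env = 0.3, b_gxe = -0.6)
  fit2 <- fit_poisson_glm(gd2$counts, gd2$data,
                          c("modifier", "BIO05", "modifier:BIO05"))
  fut2 <- gd2$data; fut2$BIO05 <- fut2$BIO05 + 1
  fc2 <- forecast_transposition(fit2, gd2$data, fut2,
                                data.frame(accession = gd2$data$accession,
                                           group = "g1",
                                           modifier = gd2$data$modifier))
  bm <- fc2$by_modifier
  expect_gt(bm$mean_delta[bm$level == "0"], 0)
  expect_lt(bm$mean_delta[bm$level == "1"], 0)
  # missing future variable errors
  expect_error(forecast_transposition(fit1, gd$data,
                                      fut[, setdiff(names(fut), "BIO05")],
                                      panel), "BIO05")
})
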