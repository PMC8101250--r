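#' Genotype + environment + GxE modelling of very recent transposition
#'
#' @name envmodel
NULL

#' Z-score a climate table against the current epoch
#'
#' Current-epoch columns are standardised to mean 0 / SD 1; future-epoch
#' values are transformed with the *current* means and SDs, so they can be
#' fed to models trained on current climate.
#'
#' @param climate data.frame with columns accession, epoch
#'   ("current"/"future") and the bio-variables.
#' @param bio_cols names of the bio-variable columns; defaults to every
#'   column matching `^BIO`.
#' @return the climate table with bio-variable columns z-scored, plus
#'   attributes `center` and `scale` (current-epoch statistics).
#' @export
zscore_climate <- function(climate, bio_cols = grep("^BIO", names(climate),
                                                    value = TRUE)) {
  if (!"epoch" %in% names(climate) || !any(climate$epoch == "current")) {
    stop_temob("climate table must contain a 'current' epoch")
  }
  cur <- climate[climate$epoch == "current", bio_cols, drop = FALSE]
  ctr <- vapply(cur, mean, 0)
  scl <- vapply(cur, stats::sd, 0)
  if (any(scl == 0)) {
    stop_temob("zero-variance bio-variable(s): ",
               paste(bio_cols[scl == 0], collapse = ", "))
  }
  climate[bio_cols] <- sweep(sweep(climate[bio_cols], 2, ctr, "-"), 2, scl, "/")
  attr(climate, "center") <- ctr
  attr(climate, "scale") <- scl
  climate
}

# Build the model frame used by all fitting functions: counts + panel
# covariates + current-epoch z-scored climate, joined on accession.
model_frame <- function(counts, panel, climate = NULL) {
  df <- panel
  if (!is.null(climate)) {
    cur <- climate[climate$epoch == "current", , drop = FALSE]
    df <- merge(df, cur[, c("accession", grep("^BIO", names(cur), value = TRUE))],
                by = "accession", sort = FALSE)
  }
  df <- df[match(names(counts) %||% panel$accession, df$accession), ,
           drop = FALSE]
  df$.count <- as.vector(counts)
  df
}

#' Fit a Poisson (log link) GLM of very recent insertion counts
#'
#' Fits `counts ~ terms` with `stats::glm` and reports the percentage of
#' variance explained as the deviance pseudo-R-squared,
#' `PVE = 1 - residual deviance / null deviance`.
#'
#' @param counts non-negative integer vector, named by accession (or aligned
#'   with `data`).
#' @param data data.frame of covariates (one row per accession); typically
#'   the panel merged with the z-scored current climate (see
#'   [model_frame()]).
#' @param terms character vector of model terms, e.g.
#'   `c("PC1", "PC2", "PC3", "modifier", "BIO05", "modifier:BIO05")`.
#' @return an object of class `glm_fit`: list with the fitted `model`,
#'   `terms`, coefficient table, deviances and `pve`.
#' @export
fit_poisson_glm <- function(counts, data, terms) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_temob("counts must be non-negative integers")
  }
  df <- data
  df$.count <- as.vector(counts)
  fml <- stats::as.formula(paste(".count ~",
                                 if (length(terms)) paste(terms, collapse = " + ")
                                 else "1"))
  mm <- stats::model.matrix(fml, df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop_temob("rank-deficient design; collinear terms: ",
               paste(aliased, collapse = ", "))
  }
  fit <- stats::glm(fml, data = df, family = stats::poisson())
  if (!fit$converged) {
    stop_temob("Poisson GLM did not converge after ", fit$iter, " iterations")
  }
  co <- summary(fit)$coefficients
  out <- list(
    model = fit, family = "poisson-log", terms = terms,
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], row.names = NULL),
    null_deviance = fit$null.deviance, deviance = fit$deviance,
    pve = 1 - fit$deviance / fit$null.deviance
  )
  class(out) <- "glm_fit"
  out
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s: %s\n", x$family,
              paste(x$terms, collapse = " + ")))
  cat(sprintf("  PVE %.3f (null dev %.1f -> %.1f)\n", x$pve,
              x$null_deviance, x$deviance))
  invisible(x)
}

#' Greedy forward selection of bio-variables for the transposition GLM
#'
#' Starting from the base model (kinship PCs and the modifier allele),
#' candidate bio-variables are added sequentially, either as fixed effects
#' or (when `allow_gxe`) as modifier-interaction terms entering jointly with
#' their main effect. At each round the candidate with the largest PVE gain
#' is added; selection stops when no candidate improves PVE by more than
#' `stop_delta` (strictly), preventing hyperinflation of the model. Ties are
#' broken by candidate name order.
#'
#' @param counts,data as in [fit_poisson_glm()].
#' @param base_terms terms of the base model.
#' @param candidates character vector of candidate bio-variable names.
#' @param modifier name of the modifier-allele column used for interactions.
#' @param allow_gxe offer interaction candidates, default TRUE.
#' @param stop_delta PVE-gain threshold, default 0.01 (a variable must add
#'   more than 1%).
#' @return list with `fit` (final `glm_fit`), `selected` (added candidate
#'   labels) and `trace` (data.frame: round, candidate, pve, delta, added).
#' @export
stepwise_select <- function(counts, data, base_terms, candidates,
                            modifier = "modifier", allow_gxe = TRUE,
                            stop_delta = 0.01) {
  cand <- sort(candidates)
  pool <- c(stats::setNames(as.list(cand), cand),
            if (allow_gxe) stats::setNames(
              lapply(cand, function(b) c(b, paste0(modifier, ":", b))),
              paste0(modifier, "x", cand)))
  pool <- pool[order(names(pool))]
  current <- base_terms
  fit <- fit_poisson_glm(counts, data, current)
  trace <- data.frame(round = 0L, candidate = "(base)", pve = fit$pve,
                      delta = NA_real_, added = TRUE,
                      stringsAsFactors = FALSE)
  selected <- character(0)
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    remaining <- pool[!names(pool) %in% selected]
    if (!length(remaining)) break
    pves <- vapply(remaining, function(tt) {
      new_terms <- union(current, tt)
      tryCatch(fit_poisson_glm(counts, data, new_terms)$pve,
               error = function(e) NA_real_)
    }, 0)
    if (all(is.na(pves))) break
    best <- which.max(pves)  # first max wins: name-order tie-break
    delta <- pves[best] - fit$pve
    trace <- rbind(trace, data.frame(round = round_i,
                                     candidate = names(remaining)[best],
                                     pve = unname(pves[best]),
                                     delta = unname(delta),
                                     added = delta > stop_delta,
                                     stringsAsFactors = FALSE))
    if (!(delta > stop_delta)) break
    current <- union(current, remaining[[best]])
    selected <- c(selected, names(remaining)[best])
    fit <- fit_poisson_glm(counts, data, current)
    # drop the sibling candidate (fixed vs interaction) of an added variable
    b <- sub(paste0("^", modifier, "x"), "", names(remaining)[best])
    pool <- pool[!names(pool) %in% setdiff(c(b, paste0(modifier, "x", b)),
                                           selected)]
  }
  list(fit = fit, selected = selected, trace = trace)
}

#' Hold-out validation of competing transposition models
#'
#' Repeatedly holds out `set_size` random accessions (~10% of the panel),
#' refits every design on the remainder and predicts the held-out counts.
#' Per accession, predictions are aggregated over the draws that held it
#' out; accessions whose mean error exceeds `outlier_sd` standard deviations
#' of the mean-error distribution are flagged as outliers. The predictive
#' variance of each design is the variance of the per-accession mean
#' prediction errors.
#'
#' @param counts,data as in [fit_poisson_glm()].
#' @param designs named list of term vectors, e.g.
#'   `list(G = ..., GE = ..., GxE = ...)`; outliers are assessed on the last
#'   design.
#' @param n_sets number of hold-out draws, default 100.
#' @param set_size held-out accessions per draw, default 100.
#' @param outlier_sd outlier threshold in SD units, default 4.
#' @param seed integer seed.
#' @return list with `per_accession` (data.frame: accession, n_heldout, mean
#'   error per design), `predictive_variance` (named vector) and `outliers`
#'   (accession ids).
#' @export
holdout_validation <- function(counts, data, designs, n_sets = 100,
                               set_size = 100, outlier_sd = 4, seed = 1) {
  n <- nrow(data)
  if (set_size >= n) stop_temob("set_size must be smaller than the panel")
  stopifnot(is.list(designs), length(designs) >= 1)
  if (is.null(names(designs))) names(designs) <- paste0("design", seq_along(designs))
  with_seed(seed, {
    err_sum <- matrix(0, n, length(designs),
                      dimnames = list(NULL, names(designs)))
    err_n <- integer(n)
    for (s in seq_len(n_sets)) {
      test <- sample.int(n, set_size)
      train <- setdiff(seq_len(n), test)
      for (d in seq_along(designs)) {
        fit <- fit_poisson_glm(counts[train], data[train, , drop = FALSE],
                               designs[[d]])
        pred <- stats::predict(fit$model,
                               newdata = data[test, , drop = FALSE],
                               type = "response")
        err_sum[test, d] <- err_sum[test, d] + (pred - counts[test])
      }
      err_n[test] <- err_n[test] + 1L
    }
    seen <- err_n > 0
    mean_err <- sweep(err_sum[seen, , drop = FALSE], 1, err_n[seen], "/")
    last <- ncol(mean_err)
    sd_err <- stats::sd(mean_err[, last])
    out_flag <- abs(mean_err[, last] - mean(mean_err[, last])) >
      outlier_sd * sd_err
    acc <- data$accession %||% as.character(seq_len(n))
    list(
      per_accession = data.frame(accession = acc[seen], n_heldout = err_n[seen],
                                 mean_err, stringsAsFactors = FALSE),
      predictive_variance = apply(mean_err, 2, stats::var),
      outliers = acc[seen][out_flag]
    )
  })
}

#' Restricted (partial) Mantel test against a kinship matrix
#'
#' Correlates the pairwise distance matrix of per-accession very-recent
#' counts with that of a bio-variable after regressing both on the kinship
#' distance matrix (1 minus the normalised kinship). Significance comes from
#' row/column-coherent permutations of the count matrix with
#' `p = (1 + #permuted >= observed) / (n_perm + 1)` (one-sided).
#'
#' @param counts per-accession counts (e.g. one TE family), aligned to the
#'   kinship matrix.
#' @param env per-accession bio-variable values.
#' @param kinship square symmetric kinship matrix.
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed.
#' @return list with `statistic` (partial Mantel r), `p`, `n_perm`.
#' @export
restricted_mantel <- function(counts, env, kinship, n_perm = 1000, seed = 1) {
  n <- length(counts)
  if (!is.matrix(kinship) || nrow(kinship) != n || ncol(kinship) != n ||
      max(abs(kinship - t(kinship))) > 1e-8) {
    stop_temob("kinship must be a square symmetric matrix aligned to counts")
  }
  d_cnt <- abs(outer(counts, counts, "-"))
  d_env <- abs(outer(env, env, "-"))
  rng <- max(kinship) - min(kinship)
  d_kin <- 1 - (kinship - min(kinship)) / if (rng > 0) rng else 1
  lt <- lower.tri(d_kin)
  k <- d_kin[lt]
  kc <- k - mean(k)
  kss <- sum(kc * kc)
  # residuals of an intercept + kinship-distance regression, closed form
  resid_on <- function(y) {
    yc <- y - mean(y)
    if (kss > 0) yc - (sum(yc * kc) / kss) * kc else yc
  }
  r_env <- resid_on(d_env[lt])
  stat_for <- function(dc) {
    stats::cor(resid_on(dc[lt]), r_env)
  }
  obs <- stat_for(d_cnt)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stat_for(d_cnt[p, p])
    }, 0)
  })
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Climatic envelopes: PCA of the standardised bio-variables
#'
#' Principal components of the z-scored current-epoch bio-variables. The top
#' `n_components` components are the climatic envelopes (CE1..CEn); loading
#' signs are fixed deterministically so the largest-magnitude loading of
#' each envelope is positive.
#'
#' @param climate_z z-scored climate table ([zscore_climate()]).
#' @param n_components number of envelopes to retain, default 3.
#' @return an object of class `climatic_envelope`: list with `loadings`
#'   (19 x n), `scores` (accession x n, rownames = accession),
#'   `variance_fraction` (per retained envelope) and `accessions`.
#' @export
climatic_envelopes <- function(climate_z, n_components = 3) {
  bio <- grep("^BIO", names(climate_z), value = TRUE)
  cur <- climate_z[climate_z$epoch == "current", , drop = FALSE]
  x <- as.matrix(cur[, bio])
  nondeg <- apply(x, 2, stats::sd) > 1e-12
  if (sum(nondeg) < n_components) {
    stop_temob("fewer than ", n_components, " non-degenerate bio-variables")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(rot) <- colnames(scores) <- paste0("CE", seq_len(n_components))
  rownames(scores) <- cur$accession
  out <- list(loadings = rot, scores = scores,
              variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
              accessions = cur$accession)
  class(out) <- "climatic_envelope"
  out
}

#' @export
print.climatic_envelope <- function(x, ...) {
  cat(sprintf("<climatic_envelope> %d envelopes over %d accessions; variance fractions %s (total %.1f%%)\n",
              ncol(x$scores), nrow(x$scores),
              paste(sprintf("%.3f", x$variance_fraction), collapse = ", "),
              100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Climatic-envelope shifts of TE-carrier accessions
#'
#' For each recurrently hit gene and each climatic envelope, fits a logistic
#' GLM of carrier status on the envelope score with kinship PCs as
#' covariates, reports the carrier shift (mean CE score of carriers minus the
#' panel mean) and applies Benjamini-Hochberg correction across genes within
#' each envelope. With `permute_env = TRUE` the environment (CE scores) of
#' all accessions is shuffled once before testing, providing the negative
#' control.
#'
#' @param carrier_sets named list: gene id -> character vector of carrier
#'   accessions (genes with fewer than `min_carriers` are skipped with a
#'   warning).
#' @param envelopes a `climatic_envelope`.
#' @param pcs matrix/data.frame of kinship PCs, rownames or order matching
#'   the envelope accessions.
#' @param fdr BH false-discovery-rate threshold, default 0.05.
#' @param min_carriers minimum carriers per tested gene, default 3.
#' @param permute_env shuffle environments before testing, default FALSE.
#' @param seed integer seed (used only when permuting).
#' @return data.frame per gene x envelope: gene_id, envelope, n_carriers,
#'   delta (carrier shift), estimate, p, q, significant.
#' @export
ce_shift_association <- function(carrier_sets, envelopes, pcs, fdr = 0.05,
                                 min_carriers = 3, permute_env = FALSE,
                                 seed = 1) {
  stopifnot(inherits(envelopes, "climatic_envelope"))
  acc <- envelopes$accessions
  scores <- envelopes$scores
  if (permute_env) {
    scores <- with_seed(seed, scores[sample.int(nrow(scores)), , drop = FALSE])
    rownames(scores) <- acc
  }
  pcs <- as.matrix(pcs)
  small <- vapply(carrier_sets, function(s) length(intersect(s, acc)), 0) <
    min_carriers
  if (any(small)) {
    warning(sum(small), " gene(s) with fewer than ", min_carriers,
            " carriers skipped")
    carrier_sets <- carrier_sets[!small]
  }
  rows <- list()
  for (g in names(carrier_sets)) {
    carrier <- as.integer(acc %in% carrier_sets[[g]])
    for (ce in colnames(scores)) {
      df <- data.frame(carrier = carrier, score = scores[, ce], pcs)
      fit <- suppressWarnings(
        stats::glm(carrier ~ ., data = df, family = stats::binomial())
      )
      co <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, envelope = ce, n_carriers = sum(carrier),
        delta = mean(scores[carrier == 1, ce]) - mean(scores[, ce]),
        estimate = co["score", 1], p = co["score", 4],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- NA_real_
  for (ce in unique(out$envelope)) {
    sel <- out$envelope == ce
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}

#' Forecast very recent transposition under future climate
#'
#' Applies a fitted transposition GLM to the same panel under current and
#' future climates (genetic terms held fixed: genetic structure is assumed
#' unchanged over the forecast horizon) and reports per-accession predicted
#' counts, their change, and aggregations by genetic group and by
#' modifier-allele status.
#'
#' @param fit a `glm_fit` from [fit_poisson_glm()] / [stepwise_select()].
#' @param data_current,data_future covariate data.frames for the two epochs
#'   (same accessions and columns; only bio-variables may differ). Future
#'   bio-variables must be z-scored with current-epoch statistics
#'   ([zscore_climate()]).
#' @param panel panel data.frame (accession, group, modifier).
#' @return an object of class `forecast_result`: list with `per_accession`
#'   (accession, group, modifier, pred_current, pred_future, delta,
#'   pct_change), `by_group` and `by_modifier` summaries (mean +/- se of
#'   delta).
#' @export
forecast_transposition <- function(fit, data_current, data_future, panel) {
  stopifnot(inherits(fit, "glm_fit"))
  vars <- all.vars(stats::formula(fit$model))
  vars <- setdiff(vars, ".count")
  missing_f <- setdiff(vars, names(data_future))
  if (length(missing_f)) {
    stop_temob("future data lacks model variable(s): ",
               paste(missing_f, collapse = ", "))
  }
  pred_c <- stats::predict(fit$model, newdata = data_current, type = "response")
  pred_f <- stats::predict(fit$model, newdata = data_future, type = "response")
  per <- data.frame(
    accession = panel$accession, group = panel$group,
    modifier = panel$modifier,
    pred_current = as.vector(pred_c), pred_future = as.vector(pred_f),
    delta = as.vector(pred_f - pred_c),
    pct_change = 100 * (as.vector(pred_f) / as.vector(pred_c) - 1),
    stringsAsFactors = FALSE
  )
  agg <- function(by) {
    sp <- split(per$delta, by)
    data.frame(level = names(sp),
               mean_delta = vapply(sp, mean, 0),
               se_delta = vapply(sp, function(v) {
                 stats::sd(v) / sqrt(length(v))
               }, 0),
               n = lengths(sp), row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(per_accession = per, by_group = agg(per$group),
              by_modifier = agg(per$modifier))
  class(out) <- "forecast_result"
  out
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %d accessions; mean delta %.3f insertions/genome\n",
              nrow(x$per_accession), mean(x$per_accession$delta)))
  invisible(x)
}
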