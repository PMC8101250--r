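# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_temob <- function(...) stop(..., call. = FALSE)

# Column names of the 19 bioclimatic variables (BIO01..BIO19).
bio_names <- function() sprintf("BIO%02d", 1:19)

# Deterministic local RNG scope: evaluates `expr` under `seed` and restores
# the caller's RNG state afterwards, so package functions do not perturb
# user-level random streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# stopifnot() with a friendlier message for scalar checks
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0) return(invisible(TRUE))
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    stop_temob(sprintf("'%s' must be a single non-missing number", name))
  }
  if (integer && x != round(x)) {
    stop_temob(sprintf("'%s' must be an integer", name))
  }
  if (x < lower || x > upper) {
    stop_temob(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  }
  invisible(TRUE)
}
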