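# Internal validation and numeric helpers.

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "iettrack_invalid_argument")
  }
  if (finite && !is.finite(x) && !(is.infinite(x) && !positive)) {
    # Inf allowed only where the caller explicitly permits it.
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %s).", name, format(x)),
          class = "iettrack_invalid_argument")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "iettrack_invalid_argument")
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name),
          class = "iettrack_invalid_argument")
  }
  invisible(x)
}

# Fisher-Z clipping bound: keeps atanh finite while perturbing pooled values
# far below reporting precision.
FISHER_CLIP <- 1 - 1e-7

clip_r <- function(r) pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP)

#' Pool correlation coefficients through the Fisher-Z transform
#'
#' Averages correlations on the variance-stabilised atanh scale and maps the
#' mean back with tanh: `tanh(mean(atanh(r)))`. Values are clipped to
#' +/- (1 - 1e-7) beforehand so that correlations of exactly +/- 1 stay finite.
#' Missing values are dropped before pooling.
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return A single pooled correlation, strictly inside `(-1, 1)`.
#' @examples
#' pool_fisher_z(c(0.5, 0.5))   # 0.5
#' pool_fisher_z(c(0, 0.8))     # ~0.5
#' @export
pool_fisher_z <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) {
    abort("Cannot pool an empty set of correlations.",
          class = "iettrack_invalid_argument")
  }
  if (any(abs(r) > 1 + 1e-12)) {
    abort("Correlations must lie in [-1, 1].",
          class = "iettrack_invalid_argument")
  }
  tanh(mean(atanh(clip_r(r))))
}

# Draw a seed stream: deterministic child seeds below 2^31 derived from one
# parent seed, so that stages consuming randomness in parallel structures stay
# reproducible independently of evaluation order.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
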