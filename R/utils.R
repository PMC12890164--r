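# Internal numeric helpers shared across modules.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

# probabilities are clamped at this tolerance before logs
.PROB_EPS <- 1e-7

#' @keywords internal
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' @keywords internal
clamp_prob <- function(p) clamp(p, .PROB_EPS, 1 - .PROB_EPS)

# Derive a reproducible child seed from a run seed; stays below 2^31.
#' @keywords internal
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Linear index <-> (i,j,k) helpers for 3D arrays (1-based, array order).
#' @keywords internal
vox_index <- function(ijk, dims) {
  # ijk: n x 3 matrix
  (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
}

#' @keywords internal
vox_coords <- function(idx, dims) {
  idx0 <- idx - 1
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1, j + 1, k + 1)
}
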