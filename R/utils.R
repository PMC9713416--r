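#' Round half away from zero
#'
#' Deterministic rounding used wherever a sampled count is derived from a
#' fraction (e.g. deleterious-variant pool sizes), so pool sizes are
#' reproducible across platforms; \code{base::round} rounds half to even.
#'
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a child seed from a base seed and indices
#'
#' Keeps derived seeds inside the 32-bit integer range.
#'
#' @param base integer base seed
#' @param ... integer indices
#' @return integer seed
#' @keywords internal
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 3301 + 1013904223) %% 2147483647
  }
  as.integer(s)
}

# Stable truncation selection: indices of the k largest values, ties broken
# by original order (determinism contract for all selections).
top_k <- function(x, k) {
  ord <- order(-x, seq_along(x))
  ord[seq_len(min(k, length(x)))]
}

bottom_k <- function(x, k) {
  ord <- order(x, seq_along(x))
  ord[seq_len(min(k, length(x)))]
}
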