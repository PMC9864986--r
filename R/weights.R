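as_score_vector <- function(x, what) {
  v <- if (inherits(x, "similarity_scores") || inherits(x, "clarity_scores")) {
    x$normalized
  } else {
    as.numeric(x)
  }
  if (anyNA(v) || any(v < -1e-8) || any(v > 1 + 1e-8)) {
    abort_validation(sprintf("%s scores entering the weight must lie in [0, 1]",
                             what))
  }
  pmin(pmax(v, 0), 1)
}

new_weight_vector <- function(w, scheme) {
  structure(list(w = as.numeric(w), scheme = scheme), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("Evidence weights (scheme: ", x$scheme, ")\n  ", sep = "")
  cat(paste(sprintf("%.*f", digits, x$w), collapse = "  "), "\n")
  invisible(x)
}

#' Adaptive combined weight from similarity and clarity
#'
#' The package's central weighting rule. For each evidence with normalized
#' similarity `s` (low conflict) and normalized clarity `c` (low fuzziness):
#'
#'   `W = 0.5 * ( s + c * exp(-|c - s|) )`       (damping mode, default)
#'
#' The exponential damps the clarity term whenever clarity and similarity
#' disagree, so sharply-pointed evidence that conflicts with the consensus
#' cannot buy weight with its clarity alone — the failure mode of naive
#' product or average weights. When `s == c` the exponent vanishes and
#' `W = s`. `"amplifying"` mode multiplies the clarity term by
#' `exp(+|c - s|)` instead and is provided for sensitivity analysis only.
#'
#' @param sim A `similarity_scores` object (its normalized values are used)
#'   or a numeric vector in \[0, 1\].
#' @param clar A `clarity_scores` object or numeric vector in \[0, 1\].
#' @param exponent_mode `"damping"` (default) or `"amplifying"`.
#' @return A `weight_vector` with one weight per evidence, each in \[0, 1\].
#' @examples
#' combined_weight(c(0.743, 0.545), c(0.252, 0.457))
#' @export
combined_weight <- function(sim, clar,
                            exponent_mode = c("damping", "amplifying")) {
  exponent_mode <- match.arg(exponent_mode)
  s <- as_score_vector(sim, "similarity")
  c_ <- as_score_vector(clar, "clarity")
  if (length(s) != length(c_)) {
    abort_validation("similarity and clarity must cover the same evidences")
  }
  sign <- if (exponent_mode == "damping") -1 else 1
  w <- 0.5 * (s + c_ * exp(sign * abs(c_ - s)))
  new_weight_vector(pmin(pmax(w, 0), 1), "proposed")
}

#' Baseline weighting schemes
#'
#' Reference schemes against which the adaptive weight is compared:
#' \describe{
#'   \item{`conflict_only`}{`W` = normalized similarity (conflict alone).}
#'   \item{`clarity_only`}{`W` = normalized clarity (fuzziness alone).}
#'   \item{`product`}{`W` proportional to similarity times clarity, rescaled
#'     so the largest weight is 1.}
#'   \item{`arithmetic_mean`}{`W = (sim + clar) / 2`.}
#' }
#'
#' @inheritParams combined_weight
#' @param scheme One of the four scheme names above.
#' @return A `weight_vector`.
#' @export
baseline_weight <- function(sim, clar,
                            scheme = c("conflict_only", "clarity_only",
                                       "product", "arithmetic_mean")) {
  scheme <- match.arg(scheme)
  s <- as_score_vector(sim, "similarity")
  c_ <- as_score_vector(clar, "clarity")
  if (length(s) != length(c_)) {
    abort_validation("similarity and clarity must cover the same evidences")
  }
  w <- switch(scheme,
    conflict_only   = s,
    clarity_only    = c_,
    product         = {
      p <- s * c_
      if (max(p) > 0) p / max(p) else rep(0, length(p))
    },
    arithmetic_mean = (s + c_) / 2
  )
  new_weight_vector(w, scheme)
}

#' Trust-discount reallocation of a BPA
#'
#' Moves mass away from an evidence's stated distribution in proportion to
#' the distrust `1 - W`:
#'
#'   `NewBpa(theta) = m(theta) * W + ((1 - W) / c) * (1 - m(theta))`
#'
#' With the default divisor `c = |frame| - 1` the output sums to exactly 1
#' with no renormalization (algebraic identity). `divisor_mode =
#' "literal_two"` uses `c = 2` regardless of frame size and renormalizes;
#' because Dempster's rule cancels per-evidence scale factors, the two modes
#' differ only by the shape of the reallocation, not by any global scale.
#' Fully trusted evidence (`W = 1`) passes through unchanged, and the
#' uniform BPA is a fixed point for every `W`.
#'
#' @param m A singleton-only `mass_function`.
#' @param w A trust weight in \[0, 1\].
#' @param divisor_mode `"frame_minus_one"` (default) or `"literal_two"`.
#' @return A singleton-only `mass_function`.
#' @export
trust_discount <- function(m, w,
                           divisor_mode = c("frame_minus_one", "literal_two")) {
  divisor_mode <- match.arg(divisor_mode)
  stopifnot(inherits(m, "mass_function"))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    abort_validation("the trust weight must be a single number in [0, 1]")
  }
  if (!is_singleton_only(m)) {
    abort_unsupported("trust discounting requires a singleton-only BPA")
  }
  n <- m$frame$n
  if (n == 1L) {
    return(m)  # nothing to reallocate on a one-hypothesis frame
  }
  divisor <- if (divisor_mode == "frame_minus_one") n - 1 else 2
  p <- singleton_probs(m)
  q <- p * w + ((1 - w) / divisor) * (1 - p)
  singleton_mass(m$frame, q, normalize = TRUE)
}

#' Discount a list of evidences with per-evidence weights
#'
#' Element-wise [trust_discount()]; the weight vector and evidence list must
#' have equal length.
#'
#' @param evidence List of singleton-only `mass_function` objects.
#' @param weights A `weight_vector` or numeric vector of trust weights.
#' @param divisor_mode Passed to [trust_discount()].
#' @return A list of `mass_function` objects.
#' @export
discount_all <- function(evidence, weights,
                         divisor_mode = c("frame_minus_one", "literal_two")) {
  divisor_mode <- match.arg(divisor_mode)
  w <- if (inherits(weights, "weight_vector")) weights$w else as.numeric(weights)
  if (length(evidence) != length(w)) {
    abort_validation("evidence list and weight vector lengths differ")
  }
  Map(function(m, wi) trust_discount(m, wi, divisor_mode), evidence, w)
}
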