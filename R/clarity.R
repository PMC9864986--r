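#' Distance from a BPA to the uniform (maximum-entropy) reference
#'
#' Measures the clarity (inverse fuzziness) of a singleton-only BPA as its
#' distance to the uniform distribution over the frame. A uniform BPA is
#' maximally fuzzy (distance 0); a point mass is maximally clear.
#'
#' Metrics:
#' \describe{
#'   \item{`index_w1` (default)}{1-D Wasserstein-1 distance treating the
#'     classes as unit-spaced points in frame order, computed by the CDF
#'     closed form: the sum of absolute differences of the cumulative
#'     distributions.}
#'   \item{`total_variation`}{`0.5 * sum(|m - 1/n|)`.}
#'   \item{`euclidean`}{Euclidean norm of `m - 1/n`.}
#' }
#'
#' @param m A singleton-only `mass_function`. Compound focal sets are not
#'   supported — use [deng_entropy()] or [hohle_entropy()] for those.
#' @param metric One of `"index_w1"`, `"total_variation"`, `"euclidean"`.
#' @return A non-negative distance; 0 iff the BPA is uniform.
#' @examples
#' f <- ds_frame(c("A", "B"))
#' wasserstein_to_uniform(make_mass(f, c(A = 1)))          # 0.5
#' wasserstein_to_uniform(uniform_mass(f))                 # 0
#' @export
wasserstein_to_uniform <- function(m,
                                   metric = c("index_w1", "total_variation",
                                              "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "mass_function"))
  if (!is_singleton_only(m)) {
    abort_unsupported(paste(
      "distance-to-uniform clarity requires a singleton-only BPA;",
      "use deng_entropy() or hohle_entropy() for compound focal sets"))
  }
  p <- singleton_probs(m)
  u <- rep(1 / m$frame$n, m$frame$n)
  switch(metric,
    index_w1        = sum(abs(cumsum(p - u))),
    total_variation = 0.5 * sum(abs(p - u)),
    euclidean       = sqrt(sum((p - u)^2))
  )
}

#' Per-evidence clarity scores
#'
#' Raw clarity is each evidence's distance to the uniform reference
#' ([wasserstein_to_uniform()]); normalized clarity divides by the total so
#' the scores sum to 1. If every evidence is exactly uniform (all raw
#' distances 0), each gets the equal share `1/N`.
#'
#' @param evidence Non-empty list of singleton-only `mass_function` objects.
#' @param metric Passed to [wasserstein_to_uniform()].
#' @return A list of class `clarity_scores` with elements `raw`,
#'   `normalized` and `metric`.
#' @export
clarity_scores <- function(evidence,
                           metric = c("index_w1", "total_variation",
                                      "euclidean")) {
  metric <- match.arg(metric)
  if (!is.list(evidence) || length(evidence) < 1L) {
    abort_validation("clarity needs at least one evidence")
  }
  raw <- vapply(evidence, wasserstein_to_uniform, numeric(1), metric = metric)
  total <- sum(raw)
  normalized <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  structure(list(raw = raw, normalized = normalized, metric = metric),
            class = "clarity_scores")
}

#' @export
print.clarity_scores <- function(x, digits = 4, ...) {
  cat("Clarity scores (", x$metric, " metric)\n", sep = "")
  print(round(rbind(raw = x$raw, normalized = x$normalized), digits))
  invisible(x)
}

#' Hohle entropy of a mass function
#'
#' `-sum_A m(A) * log2(Bel(A))` over the focal elements: an early belief
#' entropy. Undefined when some focal element has zero belief (possible only
#' for non-focal singletons inside compound focal sets).
#'
#' @param m A `mass_function`.
#' @return Entropy in bits; 0 for a categorical (point-mass) BPA.
#' @export
hohle_entropy <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  bel <- vapply(m$focal,
                function(b) sum(m$mass[bitwAnd(m$focal, b) == m$focal]),
                numeric(1))
  if (any(bel <= 0)) {
    abort_degenerate("Hohle entropy is undefined: a focal element has zero belief")
  }
  -sum(m$mass * log2(bel))
}

#' Deng entropy of a mass function
#'
#' `-sum_A m(A) * log2( m(A) / (2^|A| - 1) )`: a belief entropy that
#' generalizes Shannon entropy, rewarding mass spread over large compound
#' focal sets. For singleton-only BPAs it equals the Shannon entropy of the
#' mass vector.
#'
#' @param m A `mass_function`.
#' @return Entropy in bits, non-negative.
#' @examples
#' f <- ds_frame(c("A", "B"))
#' deng_entropy(make_mass(f, c("A|B" = 1)))  # log2(3)
#' @export
deng_entropy <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  card <- popcount(m$focal)
  -sum(m$mass * log2(m$mass / (2^card - 1)))
}
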