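#' Jaccard similarity matrix over all non-empty subsets
#'
#' Entry (i, j) is `|Ai ∩ Aj| / |Ai ∪ Aj|` for subsets indexed by
#' bitmask. This is the weighting matrix `D` of the Jousselme distance:
#' symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @param frame A [ds_frame()] with at most 10 hypotheses (the matrix is
#'   dense of dimension `2^n - 1`).
#' @return A numeric matrix of dimension `(2^n - 1) x (2^n - 1)`.
#' @export
jaccard_matrix <- function(frame) {
  frame <- as_ds_frame(frame)
  if (frame$n > 10L) {
    abort_unsupported(
      "the subset similarity matrix is only materialized for frames of size <= 10")
  }
  subsets <- seq_len(bitwShiftL(1L, frame$n) - 1L)
  card <- popcount(subsets)
  inter <- outer(subsets, subsets, bitwAnd)
  icard <- matrix(popcount(as.integer(inter)), nrow = length(subsets))
  ucard <- outer(card, card, "+") - icard
  icard / ucard
}

#' Jousselme distance between two mass functions
#'
#' A metric between bodies of evidence:
#' `sqrt(0.5 * t(v1 - v2) %*% D %*% (v1 - v2))`, where `v` are mass vectors
#' over all non-empty subsets and `D` is the Jaccard-overlap matrix of
#' [jaccard_matrix()]. It is 0 iff the BPAs are equal and at most 1. Large
#' distance indicates conflicting evidence.
#'
#' For singleton-only BPAs `D` restricted to the support is the identity and
#' the distance reduces to the Euclidean distance of the mass vectors divided
#' by `sqrt(2)`; this fast path avoids materializing `D`.
#'
#' @param m1,m2 `mass_function` objects on the same frame.
#' @return A distance in \[0, 1\].
#' @examples
#' f <- ds_frame(c("A", "B"))
#' jousselme_distance(make_mass(f, c(A = 0.3, B = 0.7)),
#'                    make_mass(f, c(A = 0.9, B = 0.1)))  # 0.6
#' @export
jousselme_distance <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  check_same_frame(m1, m2)
  if (is_singleton_only(m1) && is_singleton_only(m2)) {
    d <- singleton_probs(m1) - singleton_probs(m2)
    return(sqrt(sum(d * d) / 2))
  }
  D <- jaccard_matrix(m1$frame)
  d <- full_mass_vector(m1) - full_mass_vector(m2)
  q <- 0.5 * drop(d %*% D %*% d)
  sqrt(max(q, 0))
}

#' Per-evidence similarity scores from pairwise Jousselme distances
#'
#' The raw similarity of evidence `i` is the sum over the other evidences of
#' one minus the Jousselme distance: high similarity means low conflict with
#' the rest of the evidence set. Raw scores lie in \[0, N-1\] for N
#' evidences.
#'
#' Two normalizations are offered. The default (`"sum"`) rescales the raw
#' scores to sum to `N - 1`, preserving their ratios; `"mean"` divides each
#' raw score by `N - 1`.
#'
#' @param evidence List of at least two `mass_function` objects on one frame.
#' @param normalization `"sum"` (default) or `"mean"`.
#' @return A list of class `similarity_scores` with elements `raw`,
#'   `normalized`, `normalization` and the pairwise `distance_matrix`.
#' @export
similarity_scores <- function(evidence, normalization = c("sum", "mean")) {
  normalization <- match.arg(normalization)
  if (!is.list(evidence) || length(evidence) < 2L) {
    abort_validation("similarity needs at least two evidences")
  }
  n <- length(evidence)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dmat[i, j] <- dmat[j, i] <- jousselme_distance(evidence[[i]],
                                                     evidence[[j]])
    }
  }
  raw <- rowSums(1 - dmat) - 1  # drop the diagonal's (1 - 0) terms
  total <- sum(raw)
  normalized <- switch(normalization,
    sum  = if (total > 0) raw * (n - 1) / total else rep((n - 1) / n, n),
    mean = raw / (n - 1)
  )
  structure(list(raw = raw, normalized = normalized,
                 normalization = normalization, distance_matrix = dmat),
            class = "similarity_scores")
}

#' @export
print.similarity_scores <- function(x, digits = 4, ...) {
  cat("Similarity scores (", x$normalization, " normalization)\n", sep = "")
  print(round(rbind(raw = x$raw, normalized = x$normalized), digits))
  invisible(x)
}

#' Cosine similarity between two mass vectors
#'
#' The inner product of the full mass vectors divided by the product of
#' their Euclidean norms; in \[0, 1\] for non-negative masses, 1 for
#' identical BPAs and 0 for BPAs with disjoint focal sets.
#'
#' @param m1,m2 `mass_function` objects on the same frame.
#' @return A similarity in \[0, 1\].
#' @export
cosine_similarity <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  check_same_frame(m1, m2)
  v1 <- full_mass_vector(m1)
  v2 <- full_mass_vector(m2)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort_degenerate("cosine similarity is undefined for a zero mass vector")
  }
  sum(v1 * v2) / (n1 * n2)
}
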