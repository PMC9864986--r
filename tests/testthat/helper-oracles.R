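# Independent oracles and fixture generators. Each oracle is written from
# the definition by a different route than the implementation it checks.

# random BPA on a frame: `n_focal` focal subsets (singletons if requested),
# masses from normalized exponentials
random_bpa <- function(frame, n_focal = NULL, singleton_only = FALSE) {
  n <- frame$n
  if (singleton_only) {
    w <- stats::rexp(n)
    return(singleton_mass(frame, w / sum(w)))
  }
  all_subsets <- seq_len(2^n - 1)
  if (is.null(n_focal)) n_focal <- sample(1:min(3, length(all_subsets)), 1)
  focal <- sample(all_subsets, n_focal)
  w <- stats::rexp(n_focal)
  masses <- w / sum(w)
  names(masses) <- vapply(focal, function(b) {
    paste(frame$labels[bitwAnd(b, 2^(seq_len(n) - 1)) != 0], collapse = "|")
  }, "")
  make_mass(frame, masses)
}

# brute-force Dempster rule: exhaustive double loop over ALL non-empty
# subsets via dense mass vectors (not just focal sets)
oracle_dempster <- function(m1, m2) {
  n <- m1$frame$n
  v1 <- numeric(2^n - 1); v1[m1$focal] <- m1$mass
  v2 <- numeric(2^n - 1); v2[m2$focal] <- m2$mass
  acc <- numeric(2^n - 1)
  k <- 0
  for (a in seq_len(2^n - 1)) {
    for (b in seq_len(2^n - 1)) {
      inter <- bitwAnd(a, b)
      if (inter == 0) k <- k + v1[a] * v2[b]
      else acc[inter] <- acc[inter] + v1[a] * v2[b]
    }
  }
  list(mass = acc / (1 - k), k = k)
}

# Jousselme distance by explicit matrix evaluation, with the Jaccard matrix
# built from label sets rather than bit arithmetic
oracle_jousselme <- function(m1, m2) {
  n <- m1$frame$n
  subsets <- lapply(seq_len(2^n - 1), function(b) {
    m1$frame$labels[bitwAnd(b, 2^(seq_len(n) - 1)) != 0]
  })
  N <- length(subsets)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      D[i, j] <- length(intersect(subsets[[i]], subsets[[j]])) /
        length(union(subsets[[i]], subsets[[j]]))
    }
  }
  v1 <- numeric(N); v1[m1$focal] <- m1$mass
  v2 <- numeric(N); v2[m2$focal] <- m2$mass
  d <- v1 - v2
  sqrt(max(0, 0.5 * drop(d %*% D %*% d)))
}

# exact 1-D optimal transport between discrete distributions on points
# 1..n with cost |i - j|: the north-west-corner coupling is optimal for
# this (Monge) cost, so the greedy sweep solves the transport LP exactly
oracle_transport_w1 <- function(p, q) {
  i <- 1L; j <- 1L
  pi <- p; qj <- q
  cost <- 0
  while (i <= length(p) && j <= length(q)) {
    flow <- min(pi[i], qj[j])
    cost <- cost + flow * abs(i - j)
    pi[i] <- pi[i] - flow
    qj[j] <- qj[j] - flow
    if (pi[i] <= 1e-15) i <- i + 1L
    if (j <= length(q) && qj[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# Cohen's kappa from long-format prediction pairs via marginal
# probabilities (no confusion matrix)
oracle_kappa <- function(truth, pred) {
  classes <- union(truth, pred)
  po <- mean(truth == pred)
  pe <- sum(vapply(classes, function(cl) {
    mean(truth == cl) * mean(pred == cl)
  }, numeric(1)))
  (po - pe) / (1 - pe)
}

mass_table <- function(m) {
  # comparable representation of a mass function: dense vector over subsets
  v <- numeric(2^m$frame$n - 1)
  v[m$focal] <- m$mass
  v
}
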