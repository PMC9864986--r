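#' Construct a basic probability assignment (mass function)
#'
#' A basic probability assignment (BPA) maps non-empty subsets of a frame of
#' discernment to masses in \[0, 1\] that sum to one; the empty set carries no
#' mass. Subsets with strictly positive mass are the focal elements.
#'
#' @param frame A [ds_frame()] (or character vector of labels).
#' @param assignments Named numeric vector. Names identify subsets as
#'   `|`-joined labels (`"A"`, `"A|B"`); values are non-negative masses.
#' @param normalize If `TRUE`, masses are divided by their sum; otherwise
#'   they must already sum to 1 within `1e-9`.
#' @return An object of class `mass_function`.
#' @examples
#' f <- ds_frame(c("A", "B"))
#' make_mass(f, c(A = 0.3, B = 0.7))
#' make_mass(f, c("A|B" = 1))            # vacuous BPA
#' make_mass(f, c(A = 2, B = 6), normalize = TRUE)
#' @seealso [belief()], [dempster_combine()], [singleton_mass()]
#' @export
make_mass <- function(frame, assignments, normalize = FALSE) {
  frame <- as_ds_frame(frame)
  if (length(assignments) == 0L) {
    abort_validation("a mass function needs at least one assignment")
  }
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    abort_validation("assignments must be a named numeric vector")
  }
  mass <- as.numeric(assignments)
  if (anyNA(mass) || any(!is.finite(mass))) {
    abort_validation("masses must be finite numbers")
  }
  if (any(mass < 0)) {
    abort_validation("masses must be non-negative")
  }
  focal <- vapply(names(assignments), parse_subset, integer(1), frame = frame)
  if (anyDuplicated(focal)) {
    # merge duplicate subset spellings ("A|B" vs "B|A")
    mass <- as.numeric(tapply(mass, focal, sum))
    focal <- sort(unique(focal))
  }
  total <- sum(mass)
  if (normalize) {
    if (total <= 0) {
      abort_degenerate("cannot normalize an all-zero mass assignment")
    }
    mass <- mass / total
  } else if (abs(total - 1) > 1e-9) {
    abort_validation(sprintf("masses must sum to 1 (got %.12g); use normalize = TRUE",
                             total))
  }
  new_mass_function(frame, focal, mass)
}

# internal constructor; assumes focal/mass are valid and sum to ~1
new_mass_function <- function(frame, focal, mass) {
  keep <- mass > 0
  focal <- as.integer(focal)[keep]
  mass <- mass[keep]
  o <- order(focal)
  structure(list(frame = frame, focal = focal[o], mass = mass[o]),
            class = "mass_function")
}

#' Construct a singleton-only BPA from per-class masses
#'
#' Convenience constructor for the pipeline regime where every focal element
#' is a single hypothesis: `probs` holds one mass per class in frame order.
#'
#' @param frame A [ds_frame()].
#' @param probs Numeric vector of length `frame$n`, non-negative.
#' @param normalize If `TRUE`, divide by the sum.
#' @return A `mass_function` whose focal sets are all singletons.
#' @export
singleton_mass <- function(frame, probs, normalize = FALSE) {
  frame <- as_ds_frame(frame)
  if (length(probs) != frame$n) {
    abort_validation("probs must have one entry per hypothesis")
  }
  names(probs) <- frame$labels
  make_mass(frame, probs, normalize = normalize)
}

#' The uniform (maximum-entropy) reference BPA
#'
#' Assigns mass `1/n` to every singleton of the frame — the maximum-entropy
#' distribution against which evidence clarity is measured.
#'
#' @param frame A [ds_frame()].
#' @return A singleton-only `mass_function`.
#' @export
uniform_mass <- function(frame) {
  frame <- as_ds_frame(frame)
  singleton_mass(frame, rep(1 / frame$n, frame$n))
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  cat("Mass function on ", format(x$frame), "\n", sep = "")
  lab <- format_subset(x$frame, x$focal)
  for (i in seq_along(x$focal)) {
    cat(sprintf("  m({%s}) = %.*f\n", lab[i], digits, x$mass[i]))
  }
  invisible(x)
}

is_singleton_only <- function(m) {
  all(popcount(m$focal) == 1L)
}

#' Singleton masses in frame order
#'
#' Returns the mass on each singleton hypothesis as a named numeric vector
#' in frame order, with 0 where a singleton is not focal. Compound focal
#' sets are ignored; for the singleton-only pipeline regime this is the
#' full distribution.
#'
#' @param m A `mass_function`.
#' @return Named numeric vector of length `frame$n`.
#' @export
singleton_probs <- function(m) {
  p <- numeric(m$frame$n)
  sing <- popcount(m$focal) == 1L
  idx <- as.integer(log2(m$focal[sing])) + 1L
  p[idx] <- m$mass[sing]
  names(p) <- m$frame$labels
  p
}

# full mass vector over all non-empty subsets, indexed by bitmask 1..2^n-1
full_mass_vector <- function(m) {
  v <- numeric(bitwShiftL(1L, m$frame$n) - 1L)
  v[m$focal] <- m$mass
  v
}

#' Belief of a subset
#'
#' The belief function `Bel(A)` sums the mass of all non-empty subsets
#' contained in `A`; `Bel(frame) = 1` for any valid BPA.
#'
#' @param m A `mass_function`.
#' @param subset A subset of the frame, as `|`-joined labels or a character
#'   vector of labels.
#' @return The belief mass in \[0, 1\].
#' @examples
#' f <- ds_frame(c("A", "B"))
#' m <- make_mass(f, c(A = 0.2, "A|B" = 0.8))
#' belief(m, "A")      # 0.2
#' belief(m, "A|B")    # 1
#' @export
belief <- function(m, subset) {
  stopifnot(inherits(m, "mass_function"))
  mask <- parse_subset(m$frame, subset)
  sum(m$mass[bitwAnd(m$focal, mask) == m$focal])
}
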