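# Synthetic PAMAP2-like data: class-conditional Gaussian features around the
# published prototypes. This is the stated world the test-suite runs in —
# no temporal correlation, drift or activity transitions.

#' Generate a synthetic labeled feature table
#'
#' Draws, for each class and sensor, `n_per_class` values from a Gaussian
#' centered at the class prototype with the sensor's noise standard
#' deviation, then shuffles the rows. The default noise levels (ACC 0.6
#' m/s^2, GYRO 0.25 rad/s, BPM 6 beats/min) keep within-class spread small
#' relative to most between-class separations while leaving the
#' near-degenerate ACC prototypes of the sedentary activities overlapping —
#' the conflict regime the fusion method targets.
#'
#' @param prototypes A `prototype_table`; defaults to
#'   [activity_prototypes()].
#' @param noise_sd Per-sensor standard deviations in sensor units: a single
#'   number recycled over sensors, or a vector (optionally named by sensor)
#'   of length equal to the number of sensors. Must be non-negative.
#' @param n_per_class Rows per class (>= 1).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param shuffle Shuffle row order (deterministically under `seed`).
#' @return A data.frame with one numeric column per sensor and a `label`
#'   column, `n_per_class * n_classes` rows.
#' @examples
#' d <- generate_dataset(n_per_class = 5, seed = 1)
#' fit_prototypes(d, frame = activity_frame())
#' @export
generate_dataset <- function(prototypes = activity_prototypes(),
                             noise_sd = c(ACC = 0.6, GYRO = 0.25, BPM = 6),
                             n_per_class = 200,
                             seed = NULL,
                             shuffle = TRUE) {
  stopifnot(inherits(prototypes, "prototype_table"))
  sensors <- prototypes$sensors
  if (length(noise_sd) == 1L) {
    noise_sd <- rep(noise_sd, length(sensors))
    names(noise_sd) <- sensors
  }
  if (!is.null(names(noise_sd))) {
    if (!setequal(names(noise_sd), sensors)) {
      # fall back to positional matching only for the default argument shape
      if (length(noise_sd) != length(sensors)) {
        abort_validation("noise_sd names do not match the sensors")
      }
      names(noise_sd) <- sensors
    }
    noise_sd <- noise_sd[sensors]
  } else if (length(noise_sd) == length(sensors)) {
    names(noise_sd) <- sensors
  } else {
    abort_validation("noise_sd must be length 1 or one value per sensor")
  }
  if (any(noise_sd < 0) || anyNA(noise_sd)) {
    abort_validation("noise_sd must be non-negative")
  }
  if (n_per_class < 1L) {
    abort_validation("n_per_class must be at least 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  classes <- prototypes$frame$labels
  rows <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    block <- lapply(sensors, function(s) {
      stats::rnorm(n_per_class, mean = prototypes$values[s, classes[ci]],
                   sd = noise_sd[[s]])
    })
    names(block) <- sensors
    block$label <- rep(classes[ci], n_per_class)
    rows[[ci]] <- as.data.frame(block)
  }
  out <- do.call(rbind, rows)
  if (shuffle) {
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Generate a parameterized conflict/fuzziness evidence scenario
#'
#' Generalizes the two-class counterexample: `n_evidence - 1` agreeing
#' "majority" BPAs peak on a target class with peak mass
#' `1 - fuzziness_level * (1 - 1/n)` (remaining mass uniform over the other
#' classes), and one dissenter interpolates between the majority BPA and a
#' point mass on another class:
#' `dissenter = (1 - conflict_level) * majority + conflict_level * point`.
#' At `conflict_level = 0` all evidences are identical; at
#' `fuzziness_level = 0` the majority is certain. With two classes,
#' `fuzziness_level = 0.6` and `conflict_level = 6/7` this reproduces the
#' counterexample of [counterexample_evidence()] exactly.
#'
#' The construction is deterministic; `seed` is accepted for interface
#' symmetry with [generate_dataset()].
#'
#' @param n_classes Number of classes (>= 2); labels are `A`, `B`, ...
#' @param n_evidence Number of evidences (>= 2); the last is the dissenter.
#' @param conflict_level,fuzziness_level Levels in \[0, 1\].
#' @param seed Ignored (deterministic construction); kept for API symmetry.
#' @return A list of `n_evidence` singleton-only `mass_function` objects.
#'   The majority peaks on the second class, the dissenter on the first.
#' @export
conflict_scenario <- function(n_classes = 2, n_evidence = 3,
                              conflict_level = 6 / 7,
                              fuzziness_level = 0.6,
                              seed = NULL) {
  if (n_classes < 2L || n_classes > 20L) {
    abort_validation("n_classes must be between 2 and 20")
  }
  if (n_evidence < 2L) {
    abort_validation("a conflict scenario needs at least two evidences")
  }
  if (conflict_level < 0 || conflict_level > 1 ||
      fuzziness_level < 0 || fuzziness_level > 1) {
    abort_validation("conflict_level and fuzziness_level must lie in [0, 1]")
  }
  f <- ds_frame(LETTERS[seq_len(n_classes)])
  target <- 2L    # the class the majority supports
  dissent <- 1L   # the class the dissenter supports
  peak <- 1 - fuzziness_level * (1 - 1 / n_classes)
  majority <- rep((1 - peak) / (n_classes - 1), n_classes)
  majority[target] <- peak
  point <- numeric(n_classes)
  point[dissent] <- 1
  dissenter <- (1 - conflict_level) * majority + conflict_level * point
  evidence <- c(
    replicate(n_evidence - 1L, singleton_mass(f, majority), simplify = FALSE),
    list(singleton_mass(f, dissenter))
  )
  names(evidence) <- paste0("m", seq_len(n_evidence))
  evidence
}
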