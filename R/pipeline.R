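#' Pipeline configuration
#'
#' Bundles the tunable choices of the fusion pipeline, validated against the
#' vocabulary of each component. The defaults are the package's reference
#' configuration: the adaptive weight with exponential damping, the
#' self-normalizing `|frame|-1` discount divisor, index-based Wasserstein
#' clarity, and sum-to-(N-1) similarity normalization.
#'
#' `weight_scheme = "ds"` bypasses weighting and discounting entirely
#' (classical Dempster fusion of the raw BPAs).
#'
#' @param weight_scheme One of `"proposed"`, `"ds"`, `"conflict_only"`,
#'   `"clarity_only"`, `"product"`, `"arithmetic_mean"`.
#' @param clarity_metric Passed to [clarity_scores()].
#' @param sim_normalization Passed to [similarity_scores()].
#' @param exponent_mode Passed to [combined_weight()].
#' @param divisor_mode Passed to [trust_discount()].
#' @param seed Optional integer seed recorded in the config (used by
#'   commands that generate data).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(weight_scheme = "proposed",
                          clarity_metric = "index_w1",
                          sim_normalization = "sum",
                          exponent_mode = "damping",
                          divisor_mode = "frame_minus_one",
                          seed = NULL) {
  schemes <- c("proposed", "ds", "conflict_only", "clarity_only", "product",
               "arithmetic_mean")
  if (!is.character(weight_scheme) || length(weight_scheme) != 1L ||
      !weight_scheme %in% schemes) {
    abort_validation(sprintf("unknown weight_scheme %s; valid schemes: %s",
                             deparse(weight_scheme),
                             paste(schemes, collapse = ", ")))
  }
  cfg <- list(
    weight_scheme = weight_scheme,
    clarity_metric = match.arg(clarity_metric,
                               c("index_w1", "total_variation", "euclidean")),
    sim_normalization = match.arg(sim_normalization, c("sum", "mean")),
    exponent_mode = match.arg(exponent_mode, c("damping", "amplifying")),
    divisor_mode = match.arg(divisor_mode, c("frame_minus_one", "literal_two")),
    seed = if (!is.null(seed)) as.integer(seed) else NULL
  )
  structure(cfg, class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("Fusion configuration\n")
  for (k in setdiff(names(x), "seed")) cat(sprintf("  %-18s %s\n", k, x[[k]]))
  if (!is.null(x$seed)) cat(sprintf("  %-18s %d\n", "seed", x$seed))
  invisible(x)
}

#' Fit per-class sensor prototypes from a labeled feature table
#'
#' The prototype of sensor `s` for class `c` is the arithmetic mean of `s`
#' over the windows labeled `c` — a nearest-mean characterization of each
#' activity. Every class in the frame must have at least one row.
#'
#' @param data A data.frame with one numeric column per sensor and a label
#'   column.
#' @param label_col Name of the label column (default `"label"`).
#' @param frame Optional [ds_frame()] fixing the class order; defaults to
#'   the order of first appearance in the data (factor levels if the label
#'   column is a factor).
#' @return An object of class `prototype_table`: a sensors-by-classes
#'   numeric matrix plus the frame and sensor names.
#' @export
fit_prototypes <- function(data, label_col = "label", frame = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort_validation("the feature table must be a non-empty data.frame")
  }
  if (!label_col %in% names(data)) {
    abort_validation(sprintf("label column '%s' not found", label_col))
  }
  labels <- as.character(data[[label_col]])
  frame <- if (is.null(frame)) {
    lv <- if (is.factor(data[[label_col]])) levels(data[[label_col]]) else unique(labels)
    ds_frame(lv)
  } else {
    as_ds_frame(frame)
  }
  missing_cls <- setdiff(frame$labels, labels)
  if (length(missing_cls) > 0L) {
    abort_validation(sprintf("class(es) with no rows: %s",
                             paste(missing_cls, collapse = ", ")))
  }
  extra <- setdiff(unique(labels), frame$labels)
  if (length(extra) > 0L) {
    abort_validation(sprintf("label(s) outside the frame: %s",
                             paste(extra, collapse = ", ")))
  }
  sensors <- setdiff(names(data), label_col)
  if (length(sensors) == 0L) {
    abort_validation("the feature table has no sensor columns")
  }
  feat <- data[sensors]
  if (!all(vapply(feat, is.numeric, logical(1))) ||
      any(!vapply(feat, function(x) all(is.finite(x)), logical(1)))) {
    abort_validation("sensor columns must be finite numerics")
  }
  values <- sapply(frame$labels, function(cl) {
    colMeans(feat[labels == cl, , drop = FALSE])
  })
  values <- matrix(values, nrow = length(sensors),
                   dimnames = list(sensors, frame$labels))
  new_prototype_table(frame, values)
}

new_prototype_table <- function(frame, values) {
  structure(list(frame = frame, sensors = rownames(values), values = values),
            class = "prototype_table")
}

#' @export
print.prototype_table <- function(x, digits = 4, ...) {
  cat("Prototype table (", length(x$sensors), " sensors x ", x$frame$n,
      " classes)\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Generate a BPA from one sensor reading
#'
#' Converts a scalar sensor reading into a singleton-only BPA by
#' inverse-distance normalization: the distance of the reading to each class
#' prototype is inverted and the reciprocals are normalized to sum to one.
#' A reading close to a prototype therefore concentrates mass on that class;
#' an exact prototype hit is handled by clipping distances below `1e-12`.
#'
#' @param reading Named numeric vector, one finite value per sensor.
#' @param prototypes A `prototype_table`.
#' @param sensor Name of the sensor whose reading generates the evidence.
#' @return A singleton-only `mass_function` with strictly positive masses.
#' @examples
#' proto <- activity_prototypes()
#' generate_bpa(example_reading(), proto, "BPM")
#' @export
generate_bpa <- function(reading, prototypes, sensor) {
  stopifnot(inherits(prototypes, "prototype_table"))
  if (!sensor %in% prototypes$sensors) {
    abort_validation(sprintf("unknown sensor '%s'", sensor))
  }
  x <- reading[[sensor]]
  if (is.null(x) || !is.finite(x)) {
    abort_validation(sprintf("reading for sensor '%s' must be finite", sensor))
  }
  d <- pmax(abs(x - prototypes$values[sensor, ]), 1e-12)
  inv <- 1 / d
  singleton_mass(prototypes$frame, inv / sum(inv))
}

#' Classify one multi-sensor reading by evidence fusion
#'
#' Runs the full decision-level fusion chain on a window of sensor readings:
#' per-sensor BPAs via [generate_bpa()], similarity and clarity scores,
#' per-evidence weights under the configured scheme, trust discounting, and
#' Dempster combination, ending in an argmax decision. All intermediates are
#' retained in the result for reporting. Ties in the fused masses are broken
#' by frame order (lowest index) with a warning.
#'
#' @param reading Named numeric vector covering every sensor of the
#'   prototype table.
#' @param prototypes A `prototype_table` with at least two sensors.
#' @param config A [fusion_config()].
#' @return A list of class `fusion_result`: `fused`, `conflict_k`,
#'   `decision`, `weights`, `similarity`, `clarity`, `bpas`, `config`.
#' @examples
#' classify(example_reading(), activity_prototypes(), fusion_config())
#' @export
classify <- function(reading, prototypes, config = fusion_config()) {
  stopifnot(inherits(prototypes, "prototype_table"),
            inherits(config, "fusion_config"))
  if (length(prototypes$sensors) < 2L) {
    abort_validation("fusion needs at least two sensors")
  }
  bpas <- lapply(prototypes$sensors, generate_bpa,
                 reading = reading, prototypes = prototypes)
  names(bpas) <- prototypes$sensors

  sim <- NULL; clar <- NULL; weights <- NULL
  if (config$weight_scheme == "ds") {
    fused <- combine_all(bpas)
  } else {
    sim <- similarity_scores(bpas, normalization = config$sim_normalization)
    clar <- clarity_scores(bpas, metric = config$clarity_metric)
    weights <- if (config$weight_scheme == "proposed") {
      combined_weight(sim, clar, exponent_mode = config$exponent_mode)
    } else {
      baseline_weight(sim, clar, scheme = config$weight_scheme)
    }
    fused <- combine_all(discount_all(bpas, weights,
                                      divisor_mode = config$divisor_mode))
  }

  p <- singleton_probs(fused$fused)
  top <- which(p == max(p))
  if (length(top) > 1L) {
    warning("tied fused masses; breaking the tie by frame order")
  }
  structure(list(fused = fused$fused,
                 conflict_k = fused$conflict_k,
                 decision = prototypes$frame$labels[top[1]],
                 weights = weights,
                 similarity = sim,
                 clarity = clar,
                 bpas = bpas,
                 config = config),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, digits = 4, ...) {
  cat("Fusion result (scheme: ", x$config$weight_scheme, ")\n", sep = "")
  p <- singleton_probs(x$fused)
  print(round(p, digits))
  cat(sprintf("conflict k = %.*f, decision: %s\n", digits, x$conflict_k,
              x$decision))
  invisible(x)
}

#' Evaluate the fusion pipeline on a labeled feature table
#'
#' Classifies every window, tabulates the confusion matrix over the frame,
#' and reports per-class accuracy, sample-size-weighted overall accuracy,
#' and Cohen's kappa `K = (P0 - Pe) / (1 - Pe)`, where `P0` is the overall
#' accuracy and `Pe` the chance agreement from the confusion-matrix
#' marginals. The kappa value is annotated with the conventional
#' interpretation band (slight / fair / moderate / substantial / almost
#' perfect in steps of 0.2).
#'
#' @param data Labeled feature table (see [fit_prototypes()]); its classes
#'   must all belong to the prototype frame.
#' @param prototypes A `prototype_table`.
#' @param config A [fusion_config()].
#' @param label_col Name of the label column.
#' @return A list of class `fusion_evaluation`: `confusion` (true x
#'   predicted counts), `per_class_accuracy`, `weighted_accuracy`, `kappa`,
#'   `kappa_band`, `n`.
#' @export
evaluate <- function(data, prototypes, config = fusion_config(),
                     label_col = "label") {
  stopifnot(inherits(prototypes, "prototype_table"))
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort_validation("the evaluation table must be a non-empty data.frame")
  }
  if (!label_col %in% names(data)) {
    abort_validation(sprintf("label column '%s' not found", label_col))
  }
  truth <- as.character(data[[label_col]])
  bad <- setdiff(unique(truth), prototypes$frame$labels)
  if (length(bad) > 0L) {
    abort_validation(sprintf("label(s) outside the prototype frame: %s",
                             paste(bad, collapse = ", ")))
  }
  sensors <- prototypes$sensors
  missing_s <- setdiff(sensors, names(data))
  if (length(missing_s) > 0L) {
    abort_validation(sprintf("sensor column(s) missing from data: %s",
                             paste(missing_s, collapse = ", ")))
  }
  pred <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    reading <- as.numeric(data[i, sensors])
    names(reading) <- sensors
    pred[i] <- classify(reading, prototypes, config)$decision
  }
  labels <- prototypes$frame$labels
  confusion <- table(factor(truth, levels = labels),
                     factor(pred, levels = labels),
                     dnn = c("true", "predicted"))
  row_tot <- rowSums(confusion)
  per_class <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  n <- sum(confusion)
  p0 <- sum(diag(confusion)) / n
  pe <- sum(row_tot * colSums(confusion)) / n^2
  kappa <- if (pe < 1) (p0 - pe) / (1 - pe) else 1
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 weighted_accuracy = p0,
                 kappa = kappa,
                 kappa_band = kappa_band(kappa),
                 n = n),
            class = "fusion_evaluation")
}

#' Interpretation band for a kappa coefficient
#'
#' Maps kappa to the conventional agreement labels: (0, 0.2\] slight,
#' (0.2, 0.4\] fair, (0.4, 0.6\] moderate, (0.6, 0.8\] substantial,
#' (0.8, 1\] almost perfect. Values at or below 0 are labeled
#' `"poor"` (no better than chance).
#'
#' @param kappa A kappa coefficient.
#' @return A band label.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, !is.na(kappa))
  if (kappa <= 0) return("poor")
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  bands[min(5L, ceiling(kappa / 0.2))]
}

#' @export
print.fusion_evaluation <- function(x, digits = 4, ...) {
  cat("Fusion evaluation on", x$n, "windows\n")
  print(x$confusion)
  cat("per-class accuracy:\n")
  print(round(x$per_class_accuracy, digits))
  cat(sprintf("weighted accuracy = %.*f, kappa = %.*f (%s)\n",
              digits, x$weighted_accuracy, digits, x$kappa, x$kappa_band))
  invisible(x)
}
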