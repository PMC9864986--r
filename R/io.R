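# File formats: all plain UTF-8 CSV.
#   BPA:        focal_set,mass        (focal sets as |-joined labels)
#   prototypes: sensor,class,value    (long format; class order = frame order)
#   features:   <sensor1>,...,label   (one window per row)
# Run config:   flat "key: value" (or "key=value") text.

#' Read a BPA from CSV
#'
#' Expects a header `focal_set,mass` with focal sets written as `|`-joined
#' hypothesis labels (e.g. `A|B`).
#'
#' @param path Path to the CSV file.
#' @param frame The [ds_frame()] the BPA is defined on.
#' @param normalize Passed to [make_mass()].
#' @return A `mass_function`.
#' @export
read_bpa_csv <- function(path, frame, normalize = FALSE) {
  df <- read_csv_checked(path, c("focal_set", "mass"))
  masses <- as.numeric(df$mass)
  names(masses) <- as.character(df$focal_set)
  make_mass(frame, masses, normalize = normalize)
}

#' Write a BPA to CSV
#'
#' @param m A `mass_function`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bpa_csv <- function(m, path) {
  stopifnot(inherits(m, "mass_function"))
  utils::write.csv(
    data.frame(focal_set = format_subset(m$frame, m$focal), mass = m$mass),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prototype table from CSV
#'
#' Long format `sensor,class,value`; the class order of first appearance
#' fixes the frame order unless `frame` is supplied.
#'
#' @param path Path to the CSV file.
#' @param frame Optional [ds_frame()] fixing the class order.
#' @return A `prototype_table`.
#' @export
read_prototypes_csv <- function(path, frame = NULL) {
  df <- read_csv_checked(path, c("sensor", "class", "value"))
  classes <- unique(as.character(df$class))
  sensors <- unique(as.character(df$sensor))
  frame <- if (is.null(frame)) ds_frame(classes) else as_ds_frame(frame)
  if (!setequal(classes, frame$labels)) {
    abort_validation("prototype classes do not match the frame")
  }
  values <- matrix(NA_real_, length(sensors), frame$n,
                   dimnames = list(sensors, frame$labels))
  values[cbind(as.character(df$sensor), as.character(df$class))] <-
    as.numeric(df$value)
  if (anyNA(values)) {
    abort_validation("prototype table has missing (sensor, class) cells")
  }
  new_prototype_table(frame, values)
}

#' Write a prototype table to CSV
#'
#' @param prototypes A `prototype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prototypes_csv <- function(prototypes, path) {
  stopifnot(inherits(prototypes, "prototype_table"))
  df <- data.frame(
    sensor = rep(prototypes$sensors, each = prototypes$frame$n),
    class = rep(prototypes$frame$labels, length(prototypes$sensors)),
    value = as.numeric(t(prototypes$values))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled feature table from CSV
#'
#' One window per row, one numeric column per sensor plus a `label` column.
#'
#' @param path Path to the CSV file.
#' @param label_col Name of the label column.
#' @return A data.frame.
#' @export
read_features_csv <- function(path, label_col = "label") {
  df <- read_csv_checked(path, label_col)
  if (ncol(df) < 2L) {
    abort_validation("feature CSV needs at least one sensor column")
  }
  df
}

#' Write a labeled feature table to CSV
#'
#' @param data The feature data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort_validation(sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8"),
    error = function(e) {
      abort_validation(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
    })
  if (nrow(df) == 0L) {
    abort_validation(sprintf("%s contains no data rows", path))
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    abort_validation(sprintf("%s is missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a run configuration file
#'
#' Flat key-value text, one `key: value` (or `key=value`) pair per line;
#' blank lines and `#` comments are ignored. Recognized keys are the
#' arguments of [fusion_config()]; unknown keys are a configuration error.
#'
#' @param path Path to the config file.
#' @return A [fusion_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("config file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[:=]", perl = TRUE)[[1]]
    if (length(parts) < 2L) {
      abort_validation(sprintf("malformed config line: '%s'", ln))
    }
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  known <- c("weight_scheme", "clarity_metric", "sim_normalization",
             "exponent_mode", "divisor_mode", "seed")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L) {
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  if (!is.null(kv$seed)) kv$seed <- as.integer(kv$seed)
  do.call(fusion_config, kv)
}
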