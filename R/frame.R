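#' Create a frame of discernment
#'
#' A frame of discernment (recognition framework) is the ordered, finite set
#' of mutually exclusive hypotheses over which evidence is expressed — here
#' typically activity classes such as `"walking"`. The ordering is fixed at
#' construction and determines singleton index positions; the index-based
#' clarity metric depends on it.
#'
#' Subsets of the frame are represented internally as integer bitmasks over
#' the ordered labels, so the frame size is capped at 20 hypotheses (the
#' activity pipeline uses 5).
#'
#' @param labels Character vector of distinct, non-empty hypothesis names.
#' @return An object of class `ds_frame`.
#' @examples
#' ds_frame(c("A", "B"))
#' ds_frame(c("lying", "standing", "walking", "upstairs", "running"))
#' @export
ds_frame <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    abort_validation("a frame needs at least one hypothesis")
  }
  if (length(labels) > 20L) {
    abort_validation("frame size is capped at 20 hypotheses")
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    abort_validation("frame labels must be non-empty strings")
  }
  if (anyDuplicated(labels)) {
    abort_validation("frame labels must be unique")
  }
  structure(list(labels = labels, n = length(labels)), class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("Frame of discernment (", x$n, " hypotheses): {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
format.ds_frame <- function(x, ...) {
  paste0("{", paste(x$labels, collapse = ", "), "}")
}

as_ds_frame <- function(x) {
  if (inherits(x, "ds_frame")) x else ds_frame(x)
}

frames_identical <- function(f1, f2) {
  identical(f1$labels, f2$labels)
}

check_same_frame <- function(m1, m2) {
  if (!frames_identical(m1$frame, m2$frame)) {
    abort_validation("mass functions are defined on different frames")
  }
}

# ---- bitmask subset helpers -------------------------------------------------
# Subsets of a frame of size n are integers in 1..(2^n - 1); bit i-1 set means
# label i is a member. 0 would be the empty set and is never stored.

popcount <- function(x) {
  # x is a non-negative integer vector, values < 2^20
  cnt <- integer(length(x))
  while (any(x > 0L)) {
    cnt <- cnt + (x %% 2L)
    x <- x %/% 2L
  }
  cnt
}

subset_labels <- function(frame, mask) {
  frame$labels[bitwAnd(mask, bitwShiftL(1L, seq_len(frame$n) - 1L)) != 0L]
}

format_subset <- function(frame, mask) {
  vapply(mask, function(b) paste(subset_labels(frame, b), collapse = "|"), "")
}

# Parse a subset given as "A|B", a character vector of labels, or an already
# valid bitmask integer. Returns the bitmask; 0 (empty set) is rejected.
parse_subset <- function(frame, x) {
  if (is.numeric(x) && length(x) == 1L && x == as.integer(x)) {
    mask <- as.integer(x)
    if (mask < 1L || mask > bitwShiftL(1L, frame$n) - 1L) {
      abort_validation("subset bitmask out of range for this frame")
    }
    return(mask)
  }
  labs <- if (length(x) == 1L && grepl("|", x, fixed = TRUE)) {
    strsplit(x, "|", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  labs <- trimws(labs)
  labs <- labs[nzchar(labs)]
  if (length(labs) == 0L) {
    abort_validation("the empty set cannot carry mass")
  }
  idx <- match(labs, frame$labels)
  if (anyNA(idx)) {
    abort_validation(sprintf("unknown hypothesis label(s): %s",
                             paste(labs[is.na(idx)], collapse = ", ")))
  }
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

# ---- structured conditions --------------------------------------------------

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("dsfusion_validation_error",
                                     "dsfusion_error")))
}

abort_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("dsfusion_degenerate_error",
                                     "dsfusion_error")))
}

abort_unsupported <- function(msg) {
  stop(errorCondition(msg, class = c("dsfusion_unsupported_error",
                                     "dsfusion_error")))
}

abort_conflict <- function(msg) {
  stop(errorCondition(msg, class = c("dsfusion_total_conflict_error",
                                     "dsfusion_error")))
}
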