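#' Per-event cytometry measurements
#'
#' An `event_table` is a tibble with one row per triggered event and the five
#' mandatory channels `fsc_h`, `fsc_w`, `ssc_h`, `ssc_w` (forward-/side-scatter
#' pulse heights and widths) and `fl_h` (fluorescence pulse height, the proxy
#' for total fluorescence). Pulse-area columns `fsc_a`, `ssc_a`, `fl_a` may be
#' present; they are used only for signal-redundancy QC, never for estimation.
#' Provenance labels (`sample_id`, `day_id`, `replicate_id`) are carried as
#' attributes.
#'
#' All stored values must be finite and the five mandatory channels strictly
#' positive (a triggered pulse cannot have non-positive height; widths are
#' durations).
#'
#' @param x data frame with at least the five mandatory channel columns.
#' @param sample_id,day_id,replicate_id provenance labels (single strings or
#'   `NA`).
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(x, sample_id = NA_character_, day_id = NA_character_,
                        replicate_id = NA_character_) {
  x <- as_tibble(x)
  missing_ch <- setdiff(.MANDATORY_CHANNELS, names(x))
  if (length(missing_ch) > 0L) {
    stop("event_table is missing mandatory channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(.MANDATORY_CHANNELS, .AREA_CHANNELS), names(x))
  x <- x[keep]
  for (ch in keep) {
    if (!is.numeric(x[[ch]])) stop("channel '", ch, "' is not numeric", call. = FALSE)
  }
  if (nrow(x) < 1L) stop("event_table must contain at least one event", call. = FALSE)
  bad <- !complete.cases(x) | Reduce(`|`, lapply(x[.MANDATORY_CHANNELS],
                                                 function(v) !is.finite(v) | v <= 0))
  if (any(bad)) {
    stop("event_table contains ", sum(bad),
         " non-finite or non-positive rows; clean them first (read_events does this)",
         call. = FALSE)
  }
  structure(x,
            class = c("event_table", class(x)),
            sample_id = sample_id, day_id = day_id, replicate_id = replicate_id)
}

#' Number of events in an event table
#' @param events an [event_table()].
#' @return Integer event count.
#' @export
n_events <- function(events) nrow(events)

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, channels: %s\n", nrow(x),
              paste(names(x), collapse = ", ")))
  meta <- c(sample = attr(x, "sample_id"), day = attr(x, "day_id"),
            replicate = attr(x, "replicate_id"))
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n")
  print(as_tibble(unclass_event_table(x)), ...)
  invisible(x)
}

unclass_event_table <- function(x) {
  class(x) <- setdiff(class(x), "event_table")
  x
}

# rebuild an event_table from a row subset, preserving provenance
subset_events <- function(events, idx) {
  out <- as_tibble(unclass_event_table(events))[idx, , drop = FALSE]
  event_table(out,
              sample_id = attr(events, "sample_id"),
              day_id = attr(events, "day_id"),
              replicate_id = attr(events, "replicate_id"))
}

#' Map canonical channel roles to source channel names
#'
#' @param fsc_h,fsc_w,ssc_h,ssc_w,fl_h source channel names (as they appear in
#'   the file) for the five mandatory roles.
#' @param fsc_a,ssc_a,fl_a optional area channels (QC only).
#' @return Named character vector of class `channel_map`.
#' @export
channel_map <- function(fsc_h, fsc_w, ssc_h, ssc_w, fl_h,
                        fsc_a = NULL, ssc_a = NULL, fl_a = NULL) {
  m <- c(fsc_h = fsc_h, fsc_w = fsc_w, ssc_h = ssc_h, ssc_w = ssc_w, fl_h = fl_h,
         fsc_a = fsc_a %||% character(0), ssc_a = ssc_a %||% character(0),
         fl_a = fl_a %||% character(0))
  validate_channel_map(m)
  structure(m, class = "channel_map")
}

validate_channel_map <- function(m) {
  missing_role <- setdiff(.MANDATORY_CHANNELS, names(m))
  if (length(missing_role) > 0L) {
    stop("channel map does not cover mandatory role(s): ",
         paste(missing_role, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(unlist(m))) {
    stop("channel map assigns the same source channel to two roles", call. = FALSE)
  }
  invisible(m)
}

# identity map over canonical names
default_channel_map <- function(include_areas = FALSE) {
  roles <- if (include_areas) c(.MANDATORY_CHANNELS, .AREA_CHANNELS) else .MANDATORY_CHANNELS
  structure(setNames(roles, roles), class = "channel_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
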