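#' Read per-event cytometry data into an event table
#'
#' Reads an FCS 3.0/3.1 file (detected by its magic bytes) or a delimited text
#' file (comma or tab, header row required, one event per row) and maps source
#' channels to the canonical roles via a [channel_map()]. Rows with non-finite
#' values in any mapped channel, or non-positive values in a mandatory
#' channel, cannot arise from a triggered pulse and are dropped with a logged
#' count (they are never imputed). Event order is preserved.
#'
#' @param path path to an FCS or delimited text file.
#' @param channel_map a [channel_map()]; defaults to the identity map over the
#'   canonical column names `fsc_h`, `fsc_w`, `ssc_h`, `ssc_w`, `fl_h` (plus
#'   any `*_a` columns present).
#' @param sample_id,day_id,replicate_id provenance labels; `sample_id`
#'   defaults to the file name.
#' @return An [event_table()].
#' @export
read_events <- function(path, channel_map = NULL, sample_id = NULL,
                        day_id = NA_character_, replicate_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% basename(path)

  magic <- tryCatch({
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    rawToChar(readBin(con, "raw", 5L))
  }, error = function(e) stop("cannot read file: ", path, call. = FALSE))

  if (identical(magic, "FCS3.")) {
    raw <- read_fcs(path)$data
    df <- as.data.frame(raw)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- tryCatch(read.delim(path, sep = sep, check.names = FALSE),
                   error = function(e) stop("unreadable file: ", path, " (",
                                            conditionMessage(e), ")", call. = FALSE))
  }
  if (is.null(channel_map)) {
    areas <- intersect(.AREA_CHANNELS, names(df))
    channel_map <- structure(setNames(c(.MANDATORY_CHANNELS, areas),
                                      c(.MANDATORY_CHANNELS, areas)),
                             class = "channel_map")
  }
  validate_channel_map(channel_map)

  absent <- names(channel_map)[!unlist(channel_map) %in% names(df)]
  absent_mand <- intersect(absent, .MANDATORY_CHANNELS)
  if (length(absent_mand) > 0L) {
    stop("source channel(s) for mandatory role(s) ",
         paste(absent_mand, collapse = ", "), " not present in ", path,
         call. = FALSE)
  }
  roles <- setdiff(names(channel_map), absent)
  out <- df[unlist(channel_map[roles])]
  names(out) <- roles
  out[] <- lapply(out, as.numeric)

  bad <- !complete.cases(out) |
    Reduce(`|`, lapply(out[.MANDATORY_CHANNELS], function(v) !is.finite(v) | v <= 0))
  if (any(bad)) {
    message("read_events: dropped ", sum(bad),
            " event(s) with non-finite or non-positive mandatory channels")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no events remain after cleaning: ", path, call. = FALSE)
  event_table(out, sample_id = sample_id, day_id = day_id,
              replicate_id = replicate_id)
}

#' Write an event table to disk
#'
#' @param events an [event_table()].
#' @param path output path; `format = "fcs"` writes a minimal FCS 3.0 file via
#'   [write_fcs()], `"tsv"`/`"csv"` write delimited text with the canonical
#'   column names.
#' @param format output format; guessed from the file extension by default.
#' @param fcs_datatype passed to [write_fcs()] (`"F"` float32 or `"D"` double).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "tsv", "csv"),
                         fcs_datatype = "F") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fcs = "fcs", csv = "csv", "tsv")
  }
  df <- as.data.frame(unclass_event_table(events))
  if (format == "fcs") {
    write_fcs(as.matrix(df), path, datatype = fcs_datatype)
  } else {
    write.table(df, path, sep = if (format == "csv") "," else "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Check that pulse areas are proportional to height x width
#'
#' For each signal (forward-scatter, side-scatter, fluorescence) that has
#' height, width and area channels available, fits the proportionality
#' constant `k` in `A = k * H * W` by least squares through the origin and
#' reports the relative residual spread `rms(A - k*H*W) / mean(A)`. On a
#' healthy instrument the area is redundant with height and width, so a large
#' spread flags a signal whose pulse statistics are inconsistent.
#'
#' @param events an [event_table()] with at least one `*_a` column.
#' @param tol flag threshold on the relative residual spread (default 0.05).
#' @return A tibble with one row per assessable signal (`signal`, `k`,
#'   `rel_spread`, `flagged`) and attribute `assessable`. When no area channel
#'   is present the report is returned empty with `assessable = FALSE` rather
#'   than erroring.
#' @export
check_area_consistency <- function(events, tol = 0.05) {
  signals <- c(fsc = "fsc", ssc = "ssc", fl = "fl")
  have_area <- vapply(signals, function(s) {
    all(paste0(s, c("_h", "_w", "_a")) %in% names(events))
  }, logical(1))
  if (!any(have_area)) {
    out <- tibble(signal = character(0), k = numeric(0),
                  rel_spread = numeric(0), flagged = logical(0))
    attr(out, "assessable") <- FALSE
    return(out)
  }
  if (nrow(events) < 10L) {
    stop("check_area_consistency needs at least 10 events", call. = FALSE)
  }
  rows <- lapply(signals[have_area], function(s) {
    a <- events[[paste0(s, "_a")]]
    hw <- events[[paste0(s, "_h")]] * events[[paste0(s, "_w")]]
    fit <- lm(a ~ 0 + hw)
    rel <- sqrt(mean(resid(fit)^2)) / mean(a)
    tibble(signal = s, k = unname(coef(fit)[1]), rel_spread = rel,
           flagged = rel > tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "assessable") <- TRUE
  out
}
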