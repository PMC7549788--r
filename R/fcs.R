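# Minimal FCS 3.0/3.1 list-mode support.
#
# Only what cytometry expression analysis needs: the TEXT segment keywords
# ($PAR, $TOT, $DATATYPE, $BYTEORD, $MODE, $PnN, $PnB, $BEGINDATA/$ENDDATA)
# and a list-mode DATA segment of type I (integer), F (float32) or D (double).
# Analysis segments, spillover matrices and log-amplifier transforms are out
# of scope.

#' Read a minimal FCS 3.0/3.1 file
#'
#' Parses the header, TEXT segment and list-mode DATA segment of an FCS file
#' and returns the raw event matrix with the channel names declared by the
#' `$PnN` keywords. Supports `$DATATYPE` I/F/D, both byte orders, and data
#' offsets given either in the header or in `$BEGINDATA`/`$ENDDATA`.
#'
#' @param path path to an FCS 3.0 or 3.1 file.
#' @return A list with `data` (numeric matrix, events x channels, named
#'   columns) and `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("not an FCS 3.0/3.1 file (magic '", version, "'): ", path, call. = FALSE)
  }
  offs <- suppressWarnings(as.numeric(c(
    substr(header, 11, 18), substr(header, 19, 26),   # TEXT begin/end
    substr(header, 27, 34), substr(header, 35, 42)))) # DATA begin/end
  if (any(is.na(offs[1:2]))) stop("corrupt FCS header in ", path, call. = FALSE)

  seek(con, offs[1])
  txt <- rawToChar(readBin(con, "raw", offs[2] - offs[1] + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), by = 2)],
                 toupper(trimws(parts[seq(1, length(parts), by = 2)])))

  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD")
  if (any(!need %in% names(kw))) {
    stop("FCS TEXT segment lacks keyword(s): ",
         paste(setdiff(need, names(kw)), collapse = ", "), call. = FALSE)
  }
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  if (!is.null(kw[["$MODE"]]) && toupper(kw[["$MODE"]]) != "L") {
    stop("only list-mode ($MODE/L) FCS data is supported", call. = FALSE)
  }

  data_beg <- offs[3]
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(kw[["$BEGINDATA"]])
  if (is.na(data_beg) || data_beg == 0) stop("cannot locate FCS DATA segment", call. = FALSE)

  bits <- vapply(seq_len(npar), function(p) {
    b <- kw[[sprintf("$P%dB", p)]]
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  chn <- vapply(seq_len(npar), function(p) {
    nm <- kw[[sprintf("$P%dN", p)]]
    if (is.null(nm)) sprintf("P%d", p) else nm
  }, character(1))

  seek(con, data_beg)
  nvals <- npar * ntot
  vals <- switch(dtype,
    "F" = readBin(con, "numeric", nvals, size = 4L, endian = endian),
    "D" = readBin(con, "numeric", nvals, size = 8L, endian = endian),
    "I" = {
      sz <- unique(bits) / 8L
      if (length(sz) != 1L || !sz %in% c(2L, 4L)) {
        stop("integer FCS data requires uniform $PnB of 16 or 32", call. = FALSE)
      }
      as.numeric(readBin(con, "integer", nvals, size = sz, signed = sz > 2L,
                         endian = endian))
    },
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  )
  if (length(vals) < nvals) stop("truncated FCS DATA segment in ", path, call. = FALSE)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
                dimnames = list(NULL, chn))
  list(data = mat, keywords = kw)
}

#' Write a minimal FCS 3.0 file
#'
#' Fixture-grade writer: float32 (or float64) list-mode data, little-endian,
#' with the mandatory keywords only. Intended for round-trip tests and for
#' exporting simulated populations; not a general-purpose FCS serializer.
#'
#' @param x numeric matrix or data frame (events x channels, named columns).
#' @param path output path.
#' @param datatype `"F"` (float32, default) or `"D"` (float64, lossless for R
#'   doubles).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, datatype = c("F", "D")) {
  datatype <- match.arg(datatype)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  npar <- ncol(x); ntot <- nrow(x)
  if (is.null(colnames(x))) stop("write_fcs requires named columns", call. = FALSE)
  bytes <- if (datatype == "F") 4L else 8L
  bits <- bytes * 8L

  kw <- c("$MODE" = "L", "$DATATYPE" = datatype, "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
          "$NEXTDATA" = "0")
  for (p in seq_len(npar)) {
    kw[sprintf("$P%dN", p)] <- colnames(x)[p]
    kw[sprintf("$P%dB", p)] <- as.character(bits)
    kw[sprintf("$P%dE", p)] <- "0,0"
    kw[sprintf("$P%dR", p)] <- format(ceiling(max(x[, p], 1)), scientific = FALSE)
  }

  build_text <- function(kw, data_beg, data_end) {
    kw2 <- c(kw, "$BEGINDATA" = format(data_beg, scientific = FALSE),
             "$ENDDATA" = format(data_end, scientific = FALSE),
             "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0", "$BEGINSTEXT" = "0",
             "$ENDSTEXT" = "0")
    paste0("/", paste0(names(kw2), "/", kw2, "/", collapse = ""))
  }
  # iterate until the offsets quoted in TEXT are self-consistent (the text
  # length itself depends on the number of digits in the offsets)
  text_beg <- 58L
  data_beg <- 0L
  for (pass in 1:6) {
    data_end <- data_beg + bytes * npar * ntot - 1L
    txt <- build_text(kw, data_beg, data_end)
    nb <- text_beg + nchar(txt, type = "bytes")
    if (nb == data_beg) break
    data_beg <- nb
  }
  stopifnot(text_beg + nchar(txt, type = "bytes") == data_beg)

  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, data_beg - 1L, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(x)), con, size = bytes, endian = "little")
  invisible(path)
}
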