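#' Export an event table as an FCS 3.0 list-mode file
#'
#' Writes a minimal standards-conforming FCS 3.0 file: `$DATATYPE F`
#' (little-endian float32), `$MODE L`, one parameter per numeric column.
#' Non-numeric columns (flags, phase labels) are skipped; integer cluster
#' labels export fine, so downstream viewers can gate on them.
#'
#' @param events `data.frame`; all numeric columns become FCS parameters.
#' @param destination output path.
#' @return `destination`, invisibly.
#' @export
export_fcs <- function(events, destination) {
  stopifnot(is.data.frame(events))
  num <- vapply(events, is.numeric, logical(1))
  df <- events[num]
  if (ncol(df) == 0) stop("event table has no numeric columns to export")
  if (any(grepl("[/\\\\]", names(df))))
    stop("parameter names must not contain the TEXT delimiter '/'")
  npar <- ncol(df)
  ntot <- nrow(df)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  for (j in seq_len(npar)) {
    rng <- if (ntot > 0) max(df[[j]], 0, na.rm = TRUE) else 0
    kw <- c(kw,
            sprintf("$P%dN", j), names(df)[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), sprintf("%d", ceiling(rng) + 1))
  }
  text_body <- function(bd, ed) {
    k <- kw
    k[k == "%BD%"] <- bd
    k[k == "%ED%"] <- ed
    paste0("/", paste(k, collapse = "/"), "/")
  }
  # fixed-width offsets so the TEXT length does not depend on their values
  probe <- text_body(sprintf("%010d", 0), sprintf("%010d", 0))
  header_len <- 58L  # "FCS3.0" + 4 spaces + 6 x 8-char offsets
  text_begin <- header_len
  text_end <- text_begin + nchar(probe) - 1L
  data_begin <- text_end + 1L
  data_len <- 4L * npar * ntot
  data_end <- if (data_len > 0) data_begin + data_len - 1L else 0L
  text <- text_body(sprintf("%010d", data_begin), sprintf("%010d", data_end))
  stopifnot(nchar(text) == nchar(probe))

  hdr_off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ",
                   hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(data_begin), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  con <- file(destination, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (ntot > 0) {
    # list mode: event-major, parameter fastest
    writeBin(as.numeric(t(as.matrix(df))), con, size = 4, endian = "little")
  }
  invisible(destination)
}

#' Read an FCS 3.0 list-mode file
#'
#' Minimal reader for the subset written by [export_fcs()] plus common
#' variants: `$DATATYPE F` or `I`, `$MODE L`, little- or big-endian.
#'
#' @param source path to an FCS file.
#' @return A list with `data` (`data.frame`, one column per parameter) and
#'   `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(source) {
  sz <- file.size(source)
  raw <- readBin(source, "raw", sz)
  hdr <- rawToChar(raw[1:58])
  if (substr(hdr, 1, 6) != "FCS3.0")
    stop("not an FCS 3.0 file")
  off <- function(i) as.integer(trimws(substr(hdr, 11 + (i - 1) * 8, 10 + i * 8)))
  text_begin <- off(1); text_end <- off(2)
  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0)
    stop("malformed TEXT segment: odd number of delimited fields")
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  data_begin <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_begin) || data_begin == 0) data_begin <- off(3)
  dtype <- kw[["$DATATYPE"]]
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  pnames <- vapply(seq_len(npar), function(j) kw[[sprintf("$P%dN", j)]],
                   character(1))
  if (ntot > 0) {
    con <- rawConnection(raw[(data_begin + 1):sz])
    on.exit(close(con))
    vals <- switch(dtype,
      F = readBin(con, "numeric", npar * ntot, size = 4, endian = endian),
      I = {
        bits <- as.integer(kw[["$P1B"]])
        readBin(con, "integer", npar * ntot, size = bits / 8,
                signed = bits > 16, endian = endian)
      },
      stop("unsupported $DATATYPE: ", dtype))
    m <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  } else {
    m <- matrix(numeric(0), nrow = 0, ncol = npar)
  }
  colnames(m) <- pnames
  list(data = as.data.frame(m, check.names = FALSE), keywords = kw)
}
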