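#' Read an FCS 3.0 file
#'
#' Minimal reader for list-mode FCS 3.0 files with 32-bit float data
#' (`$DATATYPE F`), the format cytometry acquisition software exports.
#' Parses the header offsets and TEXT segment, checks the declared event
#' count against the actual data segment length, and returns the event
#' matrix with channel names taken from the `$PnN` keywords.
#'
#' @param path Path to an FCS 3.0 file.
#' @return Events x channels numeric matrix with channel column names and
#'   the TEXT keywords attached as attribute `keywords`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (nchar(header) < 58 || substr(header, 1, 6) != "FCS3.0")
    stop("not an FCS 3.0 file (bad header)")
  off <- function(i) {
    s <- substr(header, 11 + (i - 1) * 8, 10 + i * 8)
    as.numeric(trimws(s))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (anyNA(c(text_beg, text_end, data_beg, data_end)))
    stop("malformed header offsets")
  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", text_end - text_beg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  if (is.na(n_par) || is.na(n_tot)) stop("missing $PAR/$TOT keywords")
  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("only $DATATYPE F (float) supported")
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  expected <- 4 * n_par * n_tot
  avail <- file.info(path)$size - data_beg
  if (avail < expected)
    stop(sprintf(
      "truncated data segment: expected %d bytes at offset %d, found %d",
      expected, data_beg, max(avail, 0)))
  seek(con, data_beg)
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4,
                  endian = endian)
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par),
                        function(i) kw[[sprintf("$P%dN", i)]] %||%
                          sprintf("P%d", i), character(1))
  attr(m, "keywords") <- kw
  m
}

#' Write a matrix as an FCS 3.0 file
#'
#' Companion writer (32-bit float, little-endian, list mode) so synthetic
#' event matrices can round-trip through the FCS reader.
#'
#' @param m Events x channels numeric matrix with column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(m, path) {
  m <- as.matrix(m)
  n_par <- ncol(m); n_tot <- nrow(m)
  cn <- colnames(m) %||% sprintf("P%d", seq_len(n_par))
  d <- "/"
  kv <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot,
          "$NEXTDATA", 0)
  for (i in seq_len(n_par))
    kv <- c(kv, sprintf("$P%dN", i), cn[i], sprintf("$P%dB", i), 32,
            sprintf("$P%dE", i), "0,0", sprintf("$P%dR", i),
            format(ceiling(max(m[, i], 1)), scientific = FALSE))
  text <- paste0(d, paste(kv, collapse = d), d)
  text_beg <- 58
  text_end <- text_beg + nchar(text) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * n_par * n_tot - 1
  fmt8 <- function(x) formatC(as.integer(x), width = 8, format = "d")
  header <- paste0("FCS3.0    ", fmt8(text_beg), fmt8(text_end),
                   fmt8(data_beg), fmt8(data_end), fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}
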