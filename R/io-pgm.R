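#' Read and write 8-bit grayscale images as PGM
#'
#' Images and lesion masks move through the pipeline as plain integer
#' matrices in `[0, 255]` (rows = image rows). On disk they are stored as
#' portable graymaps (PGM), the simplest widely supported grayscale format:
#' `P2` is plain ASCII text, `P5` is the binary variant. Masks are written
#' with 0 = background and 255 = lesion.
#'
#' @param image integer matrix with values in `[0, maxval]`.
#' @param path file path ending in `.pgm`.
#' @param ascii write the text (`P2`) variant; default `TRUE`.
#' @param maxval maximum gray value declared in the header (default 255).
#' @return `write_pgm` returns `path` invisibly; `read_pgm` returns an
#'   integer matrix.
#' @export
write_pgm <- function(image, path, ascii = TRUE, maxval = 255L) {
  stopifnot(is.matrix(image))
  v <- as.integer(round(image))
  if (anyNA(v) || any(v < 0L) || any(v > maxval)) {
    stop("image values must be integers in [0, ", maxval, "]")
  }
  h <- nrow(image); w <- ncol(image)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    # row-major pixel order per the PNM convention
    writeLines(apply(matrix(v, h, w), 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
    writeBin(as.raw(t(matrix(v, h, w))), con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  tokens <- integer(0)
  # header: width, height, maxval, with '#' comments allowed
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    v <- as.integer(scan(text = txt, what = integer(), quiet = TRUE))
    if (length(v) < w * h) stop("truncated P2 pixel data")
    v <- v[seq_len(w * h)]
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}
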