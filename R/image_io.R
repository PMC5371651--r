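#' Read a PGM grayscale image
#'
#' Supports the plain (`P2`) and raw (`P5`) netpbm formats with 8- or
#' 16-bit samples.  Pixel values are returned in `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (length(magic) != 1L || !magic %in% c("P2", "P5")) {
    stop("not a PGM file")
  }
  # header tokens, skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  if (w < 1L || h < 1L || maxval < 1L) stop("invalid PGM dimensions")
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256L) {
      v <- as.integer(readBin(con, "raw", n))
    } else {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                   endian = "big")
    }
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) < n) stop("truncated PGM pixel data")
  matrix(v / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image as raw (P5) PGM
#'
#' Values are clamped to `[0, 1]` and quantized to 8 bits.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path) {
  stopifnot(is.matrix(image))
  v <- round(pmin(pmax(image, 0), 1) * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(as.raw(as.integer(t(v))), con)
  invisible(path)
}

read_idx_header <- function(con, expect_dims) {
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  ndim <- magic %% 256L
  dtype <- (magic %/% 256L) %% 256L
  if (magic %/% 65536L != 0L || dtype != 8L || ndim != expect_dims) {
    stop("bad IDX magic number (expected unsigned-byte data with ",
         expect_dims, " dimensions)")
  }
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
  if (any(dims <= 0L)) stop("bad IDX dimensions")
  dims
}

#' Read an IDX image archive with matching labels
#'
#' Reads the big-endian IDX format used for handwritten-digit archives: an
#' image file (magic 0x00000803, dimensions n x rows x cols, unsigned
#' bytes) and a label file (magic 0x00000801, n unsigned bytes).
#'
#' @param image_path path to the IDX image file.
#' @param label_path path to the IDX label file.
#' @return list with `images` (list of numeric matrices in `[0, 1]`) and
#'   `labels` (character vector).
#' @export
read_idx_images <- function(image_path, label_path) {
  con <- file(image_path, "rb")
  on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, 3L)
  n <- dims[1L]; h <- dims[2L]; w <- dims[3L]
  raw <- readBin(con, "raw", n * h * w)
  if (length(raw) < n * h * w) stop("truncated IDX image file")
  lcon <- file(label_path, "rb")
  on.exit(close(lcon), add = TRUE)
  ldims <- read_idx_header(lcon, 1L)
  if (ldims[1L] != n) {
    stop("label count (", ldims[1L], ") does not match image count (", n, ")")
  }
  labels <- as.integer(readBin(lcon, "raw", n))
  if (length(labels) < n) stop("truncated IDX label file")
  v <- as.integer(raw) / 255
  images <- lapply(seq_len(n), function(i) {
    off <- (i - 1L) * h * w
    matrix(v[off + seq_len(h * w)], nrow = h, ncol = w, byrow = TRUE)
  })
  list(images = images, labels = as.character(labels))
}
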