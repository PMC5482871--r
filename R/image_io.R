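# Images are numeric arrays dim c(H, W, 3) with intensities in [0, 1].
# On-disk format is binary PPM (P6, 8-bit): lossless for 8-bit RGB and
# readable/writable with base readBin/writeBin, so the package needs no
# external image codec.

#' Write an RGB image as binary PPM (P6)
#'
#' @param img numeric array `c(H, W, 3)`, intensities in `[0, 1]` (values are
#'   clipped and quantised to 8 bits).
#' @param path output file; conventionally `.ppm`.
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("write_image: expected an H x W x 3 array")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- pmin(pmax(img, 0), 1)
  bytes <- as.integer(round(aperm(v, c(3L, 2L, 1L)) * 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(bytes), con)
  invisible(path)
}

#' Read a binary PPM (P6) image
#'
#' @param path file written by [write_image] (or any 8-bit P6 PPM).
#' @return Numeric array `c(H, W, 3)` with intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    # skip whitespace and '#' comments, return next token
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("read_image: truncated header in ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("^[[:space:]]$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("^[[:space:]]$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  if (magic != "P6") stop("read_image: unsupported format '", magic,
                          "' (only binary PPM/P6)")
  w <- as.integer(token()); h <- as.integer(token())
  maxval <- as.integer(token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval != 255L) {
    stop("read_image: malformed or non-8-bit PPM header in ", path)
  }
  bytes <- readBin(con, "raw", n = w * h * 3L)
  if (length(bytes) < w * h * 3L) stop("read_image: truncated pixel data in ",
                                       path)
  aperm(array(as.integer(bytes) / 255, dim = c(3L, w, h)), c(3L, 2L, 1L))
}

# Mirror-reflect out-of-range indices into 1..n (boundary pixel not doubled;
# degenerates to clamping for n <= 2).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

# Bilinear sample of one channel at fractional coordinates (rows yq, cols
# xq), reflect padding outside the frame.
bilinear_channel <- function(ch, yq, xq) {
  n <- dim(ch)[1]; m <- dim(ch)[2]
  y0 <- floor(yq); x0 <- floor(xq)
  fy <- yq - y0; fx <- xq - x0
  i0 <- reflect_index(y0, n); i1 <- reflect_index(y0 + 1, n)
  j0 <- reflect_index(x0, m); j1 <- reflect_index(x0 + 1, m)
  ch[cbind(i0, j0)] * (1 - fy) * (1 - fx) +
    ch[cbind(i1, j0)] * fy * (1 - fx) +
    ch[cbind(i0, j1)] * (1 - fy) * fx +
    ch[cbind(i1, j1)] * fy * fx
}

#' Bilinear resize of an RGB image
#'
#' @param img numeric array `c(H, W, 3)`.
#' @param size target side length (square output).
#' @return Numeric array `c(size, size, 3)`.
#' @export
resize_image <- function(img, size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == size && w == size) return(img)
  yq <- (seq_len(size) - 0.5) * h / size + 0.5
  xq <- (seq_len(size) - 0.5) * w / size + 0.5
  grid_y <- rep(yq, times = size)
  grid_x <- rep(xq, each = size)
  out <- array(0, dim = c(size, size, 3L))
  for (c in 1:3) {
    out[, , c] <- matrix(bilinear_channel(img[, , c], grid_y, grid_x),
                         size, size)
  }
  out
}
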