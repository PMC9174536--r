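#' Load an image as a gray-scale raster
#'
#' Reads a PNG, PGM, BMP or TIFF file and returns a single-channel intensity
#' matrix with values in \[0, 1\].  Three-channel inputs are converted to
#' luminance with the fixed Rec.601 weights (0.299, 0.587, 0.114); an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to an image file.  The format is chosen by extension
#'   (`.png`, `.pgm`, `.bmp`, `.tif`/`.tiff`, case-insensitive).
#' @return A numeric `H x W` matrix in \[0, 1\] (a `GrayImage`).
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- load_image(f)
#' range(img)
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = read_pgm(path),
    bmp  = read_bmp(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  as_gray(arr, path)
}

# Collapse an array read from disk to a gray matrix in [0,1].
as_gray <- function(arr, path = "<in-memory>") {
  if (is.matrix(arr)) return(clip01(arr))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 2L) return(clip01(arr[, , 1]))            # gray + alpha
    if (nc %in% c(3L, 4L)) {
      return(clip01(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]))
    }
    stop("unsupported channel count (", nc, ") in ", path)
  }
  stop("unsupported image layout in ", path)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Load a binary vessel mask
#'
#' Reads a mask image (any format supported by [load_image()]) and binarizes
#' it: intensities at or above 0.5 map to 1 (vessel), the rest to 0.
#'
#' @param path Path to the mask image.
#' @return An integer-valued `H x W` matrix with entries in \{0, 1\}.
#' @export
load_mask <- function(path) {
  m <- load_image(path)
  (m >= 0.5) * 1
}

#' Write a gray raster to an 8-bit PNG
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @export
save_image_png <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}

# Minimal PGM reader (P2 ascii and P5 binary, 8- or 16-bit).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  vals <- integer(0)
  # Read header tokens (width, height, maxval), skipping comments.
  tok <- character(0)
  buf <- character(0)
  while (length(tok) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header in ", path)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r")) break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(paste(buf, collapse = ""))) {
        tok <- c(tok, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); maxval <- as.integer(tok[3])
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

# Minimal BMP reader: uncompressed 8-bit (palette) or 24-bit BI_RGB.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(o) as.integer(raw[o + 1]) + 256L * as.integer(raw[o + 2])
  u32 <- function(o) sum(as.numeric(raw[o + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path)
  off <- u32(10L); w <- u32(18L); h0 <- u32(22L)
  bpp <- u16(28L); comp <- u32(30L)
  if (comp != 0) stop("compressed BMP not supported: ", path)
  flip <- h0 < 2^31 # positive height => bottom-up
  h <- h0
  row_bytes <- (((w * bpp / 8) + 3) %/% 4) * 4
  out <- matrix(0, h, w)
  if (bpp == 8) {
    hdr_size <- u32(14L)
    ncol_pal <- u32(46L); if (ncol_pal == 0) ncol_pal <- 256
    pal_off <- 14L + hdr_size
    pal <- sapply(seq_len(ncol_pal) - 1L, function(k) {
      b <- as.integer(raw[pal_off + 4 * k + 1])
      g <- as.integer(raw[pal_off + 4 * k + 2])
      r <- as.integer(raw[pal_off + 4 * k + 3])
      (0.299 * r + 0.587 * g + 0.114 * b) / 255
    })
    for (rw in seq_len(h)) {
      o <- off + (rw - 1) * row_bytes
      idx <- as.integer(raw[o + seq_len(w)])
      out[if (flip) h - rw + 1 else rw, ] <- pal[idx + 1L]
    }
  } else if (bpp == 24) {
    for (rw in seq_len(h)) {
      o <- off + (rw - 1) * row_bytes
      px <- as.integer(raw[o + seq_len(3 * w)])
      b <- px[seq(1, 3 * w, 3)]; g <- px[seq(2, 3 * w, 3)]; r <- px[seq(3, 3 * w, 3)]
      out[if (flip) h - rw + 1 else rw, ] <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
    }
  } else {
    stop("unsupported BMP bit depth (", bpp, ") in ", path)
  }
  out
}
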