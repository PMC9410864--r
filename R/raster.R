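#' Construct an image raster
#'
#' Light-weight container for a 2-D intensity grid. Grayscale and RGB images
#' store 8-bit intensities on the \code{[0, 255]} scale; mode \code{"lab"}
#' stores CIELAB floats (\code{L} in \code{[0, 100]}).
#'
#' @param pixels Numeric matrix (gray) or \code{H x W x 3} array (rgb/lab).
#' @param mode One of \code{"gray"}, \code{"rgb"}, \code{"lab"}.
#' @return An object of class \code{image_raster} with fields
#'   \code{pixels}, \code{height}, \code{width}, \code{mode}.
#' @export
image_raster <- function(pixels, mode = c("gray", "rgb", "lab")) {
  mode <- match.arg(mode)
  if (mode == "gray") {
    if (!is.matrix(pixels)) stop("gray raster requires a matrix of pixels")
  } else {
    if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
      stop(sprintf("%s raster requires an H x W x 3 array", mode))
  }
  if (!all(is.finite(pixels))) stop("raster pixels must be finite")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 1L || w < 1L) stop("raster must have height >= 1 and width >= 1")
  if (mode %in% c("gray", "rgb") &&
      (min(pixels) < 0 || max(pixels) > 255))
    stop("gray/rgb intensities must lie in [0, 255]")
  structure(list(pixels = pixels, height = h, width = w, mode = mode),
            class = "image_raster")
}

#' @export
print.image_raster <- function(x, ...) {
  cat(sprintf("<image_raster %d x %d, mode=%s>\n", x$height, x$width, x$mode))
  invisible(x)
}

#' Read an image from disk
#'
#' Reads BMP, PNG or TIFF images. 8-bit values are kept as-is; 16-bit inputs
#' are rescaled onto the \code{[0, 255]} scale. Alpha channels and other
#' channel counts are rejected.
#'
#' @param path Path to a BMP, PNG or TIFF file.
#' @return An [image_raster] with mode \code{"gray"} or \code{"rgb"}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG: ", path)),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("unreadable TIFF: ", path)),
    bmp  = return(read_bmp(path)),
    stop("unsupported image format '", ext, "': ", path)
  )
  # png/tiff readers return values in [0, 1]; map back to [0, 255]
  if (length(dim(arr)) == 2L)
    return(image_raster(round(arr * 255), "gray"))
  nc <- dim(arr)[3]
  if (nc == 1L) return(image_raster(round(arr[, , 1] * 255), "gray"))
  if (nc != 3L)
    stop("unsupported channel count (", nc, ") in ", path)
  image_raster(round(arr * 255), "rgb")
}

#' Write an image to disk
#'
#' Writes 8-bit BMP, PNG or TIFF according to the file extension.
#'
#' @param raster An [image_raster] with mode \code{"gray"} or \code{"rgb"}.
#' @param path Output path ending in .bmp, .png, .tif or .tiff.
#' @return The path, invisibly.
#' @export
save_image <- function(raster, path) {
  stopifnot(inherits(raster, "image_raster"))
  if (raster$mode == "lab")
    stop("cannot write a lab raster; convert to rgb/gray first")
  ext <- tolower(tools::file_ext(path))
  x <- raster$pixels / 255
  switch(ext,
    png  = png::writePNG(x, path),
    tif  = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    bmp  = write_bmp(raster, path),
    stop("unsupported output format '", ext, "'")
  )
  invisible(path)
}

# --- minimal BMP codec ------------------------------------------------------
# Uncompressed BI_RGB only: 8-bit palette (gray) and 24-bit color, the
# variants produced by common tooling. Rows are stored bottom-up and padded
# to 4-byte boundaries.

read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("unreadable BMP (bad magic): ", path)
  readBin(con, "integer", 2, size = 4)            # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  hdrsz  <- readBin(con, "integer", 1, size = 4)
  if (hdrsz < 40L) stop("unsupported BMP header in ", path)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)            # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (comp != 0L) stop("compressed BMP not supported: ", path)
  if (!bpp %in% c(8L, 24L))
    stop("unsupported BMP bit depth (", bpp, ") in ", path)
  flip <- h > 0; h <- abs(h)
  pal <- NULL
  if (bpp == 8L) {
    seek(con, 14 + hdrsz)
    ncol <- 256L
    pal <- matrix(as.integer(readBin(con, "raw", 4L * ncol)), ncol = 4,
                  byrow = TRUE)[, 3:1, drop = FALSE]     # BGRx -> RGB
  }
  seek(con, offset)
  stride <- ((w * bpp / 8 + 3) %/% 4) * 4
  raw <- matrix(as.integer(readBin(con, "raw", stride * h)), nrow = stride)
  rows <- if (flip) h:1 else 1:h
  if (bpp == 8L) {
    idx <- t(raw[seq_len(w), , drop = FALSE])[rows, , drop = FALSE]
    if (all(pal[, 1] == pal[, 2] & pal[, 2] == pal[, 3]))
      return(image_raster(matrix(pal[idx + 1L, 1], h, w), "gray"))
    arr <- array(0, c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- matrix(pal[idx + 1L, ch], h, w)
    return(image_raster(arr, "rgb"))
  }
  arr <- array(0, c(h, w, 3))
  for (ch in 1:3) {                                # pixels are BGR triples
    plane <- raw[seq(4 - ch, by = 3, length.out = w), , drop = FALSE]
    arr[, , ch] <- t(plane)[rows, , drop = FALSE]
  }
  image_raster(arr, "rgb")
}

write_bmp <- function(raster, path) {
  h <- raster$height; w <- raster$width
  gray <- raster$mode == "gray"
  bpp <- if (gray) 8L else 24L
  stride <- ((w * bpp / 8 + 3) %/% 4) * 4
  palsz <- if (gray) 1024L else 0L
  offset <- 54L + palsz
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(offset + stride * h), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(as.integer(offset), con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(w), con, size = 4)
  writeBin(as.integer(h), con, size = 4)
  writeBin(1L, con, size = 2); writeBin(as.integer(bpp), con, size = 2)
  writeBin(0L, con, size = 4)                      # BI_RGB
  writeBin(as.integer(stride * h), con, size = 4)
  writeBin(2835L, con, size = 4); writeBin(2835L, con, size = 4)
  writeBin(0L, con, size = 4); writeBin(0L, con, size = 4)
  if (gray)
    writeBin(as.raw(rbind(0:255, 0:255, 0:255, 0L)), con)
  px <- round(raster$pixels)
  pad <- raw(stride - w * bpp / 8)
  for (r in h:1) {                                 # bottom-up rows
    row <- if (gray) px[r, ] else as.vector(rbind(px[r, , 3], px[r, , 2],
                                                  px[r, , 1]))
    writeBin(c(as.raw(row), pad), con)
  }
  invisible(path)
}

#' Convert an RGB raster to CIELAB
#'
#' Uses the sRGB transfer function and the D65 white point; \code{L} lies in
#' \code{[0, 100]} and the chroma axes \code{a}, \code{b} are signed.
#'
#' @param raster An [image_raster] with mode \code{"rgb"}.
#' @return An [image_raster] with mode \code{"lab"}.
#' @export
rgb_to_lab <- function(raster) {
  stopifnot(inherits(raster, "image_raster"))
  if (raster$mode != "rgb")
    stop("rgb_to_lab expects an rgb raster, got mode '", raster$mode, "'")
  m <- cbind(as.vector(raster$pixels[, , 1]),
             as.vector(raster$pixels[, , 2]),
             as.vector(raster$pixels[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- array(lab, c(raster$height, raster$width, 3))
  structure(list(pixels = out, height = raster$height, width = raster$width,
                 mode = "lab"), class = "image_raster")
}

#' Convert a CIELAB raster back to RGB
#'
#' @param raster An [image_raster] with mode \code{"lab"}.
#' @return An [image_raster] with mode \code{"rgb"} (8-bit scale).
#' @export
lab_to_rgb <- function(raster) {
  stopifnot(inherits(raster, "image_raster"), raster$mode == "lab")
  m <- cbind(as.vector(raster$pixels[, , 1]),
             as.vector(raster$pixels[, , 2]),
             as.vector(raster$pixels[, , 3]))
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  image_raster(array(round(rgb * 255), c(raster$height, raster$width, 3)),
               "rgb")
}

# (l, a, b) channel stack consumed by the superpixel stage. Gray images are
# embedded as l = gray value, a = b = 0 so the 5-D pipeline is uniform.
feature_channels <- function(raster) {
  if (raster$mode == "lab") return(raster$pixels)
  if (raster$mode == "gray") {
    arr <- array(0, c(raster$height, raster$width, 3))
    arr[, , 1] <- raster$pixels
    return(arr)
  }
  feature_channels(rgb_to_lab(raster))
}

# 8-bit gray view used for entropy weighting: gray pixels directly, the L
# channel rescaled to [0, 255] otherwise.
gray_view <- function(raster) {
  if (raster$mode == "gray") return(round(raster$pixels))
  ch <- feature_channels(raster)
  round(pmin(pmax(ch[, , 1], 0), 100) * 255 / 100)
}

#' Read an integer label mask
#'
#' Reads a single-channel PNG (8-bit) or TIFF (8/16-bit) whose pixel values
#' are label ids (0 = background).
#'
#' @param path Path to the mask image.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("label masks are PNG or TIFF: ", path))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] != 1L) stop("label mask must be single-channel: ", path)
    arr <- arr[, , 1]
  }
  scale <- if (all(abs(arr * 255 - round(arr * 255)) < 1e-9)) 255 else 65535
  matrix(as.integer(round(arr * scale)), nrow(arr), ncol(arr))
}

#' Write an integer label mask
#'
#' Label ids up to 255 fit a single-channel 8-bit PNG (the usual case:
#' cluster counts are bounded by 30); wider id spaces, such as superpixel
#' maps, are written as 16-bit TIFF.
#'
#' @param labels Integer matrix of label ids (0 = background).
#' @param path Output path ending in .png (ids <= 255) or .tif/.tiff.
#' @return The path, invisibly.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(labels) > 255)
      stop("label ids above 255 need a 16-bit TIFF (.tif) target")
    png::writePNG(labels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    stop("label masks are PNG or TIFF: ", path)
  }
  invisible(path)
}
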