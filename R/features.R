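#' Feature-space scaling configuration
#'
#' The clustering universe is the joint (x, y, l, a, b) space. Spatial
#' coordinates are divided by \code{h_s} and color coordinates by \code{h_r}
#' before any distance is computed, which sets the relative weight of
#' position versus color in the density estimate. The defaults used by
#' [segment_image()] are \code{h_s = S} (the superpixel grid spacing, so one
#' superpixel step is one spatial unit) and \code{h_r = 1}.
#'
#' @param h_s Spatial divisor, > 0.
#' @param h_r Color (range) divisor, > 0.
#' @return A \code{scaling_config} object.
#' @export
scaling_config <- function(h_s = 1, h_r = 1) {
  if (!is.finite(h_s) || h_s <= 0) stop("h_s must be a positive number")
  if (!is.finite(h_r) || h_r <= 0) stop("h_r must be a positive number")
  structure(list(h_s = h_s, h_r = h_r), class = "scaling_config")
}

#' Scale a (row, col) + (l, a, b) point into feature space
#'
#' Divides the spatial pair by \code{cfg$h_s} and the color triple by
#' \code{cfg$h_r}, elementwise. Accepts matrices (one point per row) as well
#' as single points.
#'
#' @param centroid Numeric length-2 vector \code{(row, col)} or an
#'   \code{n x 2} matrix.
#' @param color Numeric length-3 vector \code{(l, a, b)} or an
#'   \code{n x 3} matrix.
#' @param cfg A [scaling_config()].
#' @return Numeric length-5 vector (or \code{n x 5} matrix) with columns
#'   \code{x, y, l, a, b}.
#' @export
scale_features <- function(centroid, color, cfg) {
  stopifnot(inherits(cfg, "scaling_config"))
  cm <- if (is.matrix(centroid)) centroid else matrix(centroid, nrow = 1)
  co <- if (is.matrix(color)) color else matrix(color, nrow = 1)
  if (ncol(cm) != 2L || ncol(co) != 3L || nrow(cm) != nrow(co))
    stop("centroid must be (row, col) and color must be (l, a, b)")
  if (!all(is.finite(cm)) || !all(is.finite(co)))
    stop("scale_features requires finite inputs")
  out <- cbind(cm / cfg$h_s, co / cfg$h_r)
  colnames(out) <- c("x", "y", "l", "a", "b")
  if (!is.matrix(centroid)) out[1, ] else out
}
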