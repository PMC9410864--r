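# Run code under a temporary RNG state so generators are pure functions of
# their seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom image specification
#'
#' Describes a synthetic multi-feature "biological" image: elliptical cell
#' blobs of uniform intensity on a darker background, with a 1-pixel
#' sigmoid edge, additive Gaussian noise of known variance, and per-feature
#' ground-truth masks that exclude the noise.
#'
#' @param size Image edge length in pixels.
#' @param n_features Number of elliptical blobs (>= 1).
#' @param radius_range Min and max semi-axis length in pixels.
#' @param intensity_contrast Gray gap between features and the background
#'   (background sits at gray 64).
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param color_mode \code{"gray"} or \code{"rgb"} (features get distinct
#'   hues).
#' @param seed Integer seed; generation is deterministic per spec.
#' @return A \code{phantom_spec} object.
#' @export
phantom_spec <- function(size = 256, n_features = 10,
                         radius_range = c(8, 20), intensity_contrast = 120,
                         noise_sigma = 10, color_mode = c("gray", "rgb"),
                         seed = 0L) {
  color_mode <- match.arg(color_mode)
  if (n_features < 1) stop("n_features must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(radius_range) != 2L || radius_range[1] <= 0 ||
      radius_range[2] < radius_range[1])
    stop("radius_range must be (min, max) with 0 < min <= max")
  if (n_features * pi * mean(radius_range)^2 > 0.4 * size^2)
    stop("requested blobs cover more than 40% of the image; placement ",
         "infeasible")
  structure(list(size = size, n_features = n_features,
                 radius_range = radius_range,
                 intensity_contrast = intensity_contrast,
                 noise_sigma = noise_sigma, color_mode = color_mode,
                 seed = as.integer(seed)), class = "phantom_spec")
}

#' Generate a phantom image with ground truth
#'
#' Blobs are placed by rejection sampling with a >= 2 px margin between
#' their circumscribed circles (and to the border), rendered with a 1-px
#' sigmoid edge on a gray-64 background, then additive N(0, sigma^2) noise
#' is applied and the result clipped to \code{[0, 255]} and rounded. The
#' truth mask is noise-free.
#'
#' @param spec A [phantom_spec()].
#' @return List with \code{image} (an [image_raster]), \code{truth}
#'   (integer grid, 0 = background, feature ids 1..n) and \code{features}
#'   (data frame of centers, semi-axes and orientations).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_features
    sz <- spec$size
    placed <- matrix(numeric(0), 0, 5,
                     dimnames = list(NULL, c("row", "col", "a", "b",
                                             "theta")))
    tries <- 0L
    max_tries <- 10L * n^2 + 100L
    while (nrow(placed) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("phantom placement infeasible after ", max_tries,
             " rejections")
      r1 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      r2 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      a <- max(r1, r2); b <- min(r1, r2)
      margin <- a + 2
      if (sz - 2 * margin < 1) stop("blob larger than image")
      ctr <- stats::runif(2, margin + 1, sz - margin)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, "row"] - ctr[1])^2 +
                     (placed[, "col"] - ctr[2])^2)
        if (any(dd < placed[, "a"] + a + 2)) next
      }
      placed <- rbind(placed, c(ctr, a, b, stats::runif(1, 0, pi)))
    }

    alpha <- matrix(0, sz, sz)
    truth <- matrix(0L, sz, sz)
    rowg <- matrix(seq_len(sz), sz, sz)
    colg <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    for (f in seq_len(n)) {
      p <- placed[f, ]
      rr <- max(1, floor(p["row"] - p["a"] - 4)):min(sz, ceiling(p["row"] +
                                                                   p["a"] + 4))
      cc <- max(1, floor(p["col"] - p["a"] - 4)):min(sz, ceiling(p["col"] +
                                                                   p["a"] + 4))
      dr <- rowg[rr, cc] - p["row"]
      dc <- colg[rr, cc] - p["col"]
      u <- cos(p["theta"]) * dr + sin(p["theta"]) * dc
      v <- -sin(p["theta"]) * dr + cos(p["theta"]) * dc
      q <- sqrt((u / p["a"])^2 + (v / p["b"])^2)
      s <- (1 - q) * p["b"]              # approximate signed distance, px
      alpha[rr, cc] <- pmax(alpha[rr, cc], stats::plogis(s / 0.5))
      tr <- truth[rr, cc]; tr[q <= 1] <- f; truth[rr, cc] <- tr
    }

    if (spec$color_mode == "gray") {
      img <- 64 + spec$intensity_contrast * alpha
      img <- img + stats::rnorm(sz * sz, 0, spec$noise_sigma)
      raster <- image_raster(matrix(round(pmin(pmax(img, 0), 255)), sz, sz),
                             "gray")
    } else {
      fg <- t(grDevices::col2rgb(grDevices::hsv(
        (seq_len(n) - 1) / n, 0.7, (64 + spec$intensity_contrast) / 255)))
      arr <- array(64, c(sz, sz, 3))
      for (ch in 1:3) {
        plane <- arr[, , ch]
        for (f in seq_len(n)) {
          sel <- truth == f
          af <- alpha[sel]
          plane[sel] <- 64 * (1 - af) + fg[f, ch] * af
        }
        plane <- plane + stats::rnorm(sz * sz, 0, spec$noise_sigma)
        arr[, , ch] <- round(pmin(pmax(plane, 0), 255))
      }
      raster <- image_raster(arr, "rgb")
    }
    list(image = raster, truth = truth,
         features = as.data.frame(placed))
  })
}

#' Point-cloud specification for clustering tests
#'
#' @param n_clusters Number of Gaussian clusters.
#' @param points_per_cluster Points drawn per cluster.
#' @param cluster_sigma Isotropic standard deviation of each cluster.
#' @param center_separation Pairwise distance between adjacent cluster
#'   centers (> 0); centers sit on the vertices of a regular polygon with
#'   this side length (two clusters: a segment; one: the origin).
#' @param n_outliers Uniform background points labeled \code{-1}.
#' @param seed Integer seed.
#' @return A \code{point_cloud_spec} object.
#' @export
point_cloud_spec <- function(n_clusters = 3, points_per_cluster = 100,
                             cluster_sigma = 0.5, center_separation = 5,
                             n_outliers = 0, seed = 0L) {
  if (center_separation <= 0) stop("center_separation must be > 0")
  if (n_clusters < 1 || points_per_cluster < 0 || n_outliers < 0)
    stop("counts must be non-negative (n_clusters >= 1)")
  structure(list(n_clusters = n_clusters,
                 points_per_cluster = points_per_cluster,
                 cluster_sigma = cluster_sigma,
                 center_separation = center_separation,
                 n_outliers = n_outliers, seed = as.integer(seed)),
            class = "point_cloud_spec")
}

#' Generate a 2-D Gaussian-mixture point cloud with outliers
#'
#' @param spec A [point_cloud_spec()].
#' @return List with \code{points} (n x 2 matrix), \code{labels} (cluster
#'   id per point, \code{-1} for outliers) and \code{centers}.
#' @export
generate_point_cloud <- function(spec) {
  stopifnot(inherits(spec, "point_cloud_spec"))
  with_seed(spec$seed, {
    k <- spec$n_clusters
    centers <- if (k == 1) matrix(0, 1, 2) else {
      R <- spec$center_separation / (2 * sin(pi / k))
      ang <- 2 * pi * (seq_len(k) - 1) / k
      cbind(R * cos(ang), R * sin(ang))
    }
    pts <- NULL; labs <- integer(0)
    for (i in seq_len(k)) {
      m <- spec$points_per_cluster
      if (m == 0) next
      pts <- rbind(pts, cbind(stats::rnorm(m, centers[i, 1],
                                           spec$cluster_sigma),
                              stats::rnorm(m, centers[i, 2],
                                           spec$cluster_sigma)))
      labs <- c(labs, rep(i, m))
    }
    if (spec$n_outliers > 0) {
      lim <- max(abs(centers)) + 2 * spec$center_separation
      pts <- rbind(pts, cbind(stats::runif(spec$n_outliers, -lim, lim),
                              stats::runif(spec$n_outliers, -lim, lim)))
      labs <- c(labs, rep(-1L, spec$n_outliers))
    }
    list(points = pts, labels = labs, centers = centers)
  })
}
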