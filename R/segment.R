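#' Spatial noise-isolation configuration
#'
#' After label propagation, each pixel is summarized by the mean feature of
#' its 8-neighbourhood; a pixel whose variance-weighted distance to its own
#' region's mean exceeds the threshold is reassigned to the nearest region
#' under the same distance.
#'
#' @param enabled Run the pass at all.
#' @param W Positive per-channel variance weights (length 3, for l, a, b).
#'   \code{NULL} uses the reciprocal per-channel variance of the
#'   neighbourhood means (a data-driven variance matrix).
#' @param threshold Isolation distance cutoff; \code{NULL} uses the 95th
#'   percentile of the own-region distances.
#' @param iterations Number of refinement sweeps (default 1).
#' @return A \code{noise_config} object.
#' @export
noise_config <- function(enabled = TRUE, W = NULL, threshold = NULL,
                         iterations = 1) {
  if (!is.null(W)) {
    if (length(W) != 3L || any(!is.finite(W)) || any(W <= 0))
      stop("W must be 3 positive per-channel weights")
  }
  structure(list(enabled = enabled, W = W, threshold = threshold,
                 iterations = iterations), class = "noise_config")
}

#' Full segmentation configuration
#'
#' Bundles the superpixel, scaling, clustering and noise-isolation settings
#' consumed by [segment_image()].
#'
#' @param superpixel A [superpixel_config()].
#' @param scaling A [scaling_config()], or \code{NULL} to use
#'   \code{h_s = S} (grid spacing) and \code{h_r = 1}.
#' @param dpc A [dpc_config()].
#' @param noise A [noise_config()].
#' @param seed Integer recorded in the manifest; the pipeline itself is
#'   deterministic.
#' @return A \code{segmentation_config} object.
#' @export
segmentation_config <- function(superpixel = superpixel_config(),
                                scaling = NULL,
                                dpc = dpc_config(),
                                noise = noise_config(),
                                seed = 0L) {
  stopifnot(inherits(superpixel, "superpixel_config"),
            is.null(scaling) || inherits(scaling, "scaling_config"),
            inherits(dpc, "dpc_config"),
            inherits(noise, "noise_config"))
  structure(list(superpixel = superpixel, scaling = scaling, dpc = dpc,
                 noise = noise, seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Expand per-superpixel cluster ids to the pixel grid
#'
#' @param sp A \code{superpixel_map}.
#' @param sp_labels Integer vector of cluster ids, one per superpixel.
#' @return Integer H x W matrix: \code{labels[p] = sp_labels[sp$labels[p]]}.
#' @export
pixels_from_superpixels <- function(sp, sp_labels) {
  stopifnot(inherits(sp, "superpixel_map"))
  if (length(sp_labels) != sp$K)
    stop("sp_labels must have one entry per superpixel (K = ", sp$K, ")")
  if (anyNA(sp_labels)) stop("sp_labels must not contain NA")
  matrix(as.integer(sp_labels)[sp$labels], nrow(sp$labels), ncol(sp$labels))
}

# Mean of each pixel's 8-neighbourhood, per channel, edge-replicated.
neighborhood_mean <- function(ch) {
  H <- dim(ch)[1]; W <- dim(ch)[2]
  up <- function(m) m[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- function(m) m[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- function(m) m[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  out <- array(0, dim(ch))
  for (f in seq_len(dim(ch)[3])) {
    m <- ch[, , f]
    out[, , f] <- (up(m) + dn(m) + lf(m) + rt(m) +
                     up(lf(m)) + up(rt(m)) + dn(lf(m)) + dn(rt(m))) / 8
  }
  out
}

#' Reassign spatially isolated noise pixels
#'
#' Each pixel i is summarized by the mean feature of its 8-neighbourhood,
#' \code{xbar_i}; its isolation distance to a region r is the
#' variance-weighted norm \code{sqrt(sum_f W_f (xbar_if - mu_rf)^2)}, where
#' \code{mu_r} is the mean of \code{xbar} over region r. Pixels whose
#' distance to their own region exceeds the threshold are reassigned to the
#' nearest region. The set of label ids is never enlarged.
#'
#' @param labels Integer pixel label grid.
#' @param raster The [image_raster] the labels segment.
#' @param cfg A [noise_config()].
#' @return Refined integer label grid of the same dimension.
#' @export
isolate_noise <- function(labels, raster, cfg = noise_config()) {
  stopifnot(inherits(raster, "image_raster"),
            all(dim(labels) == c(raster$height, raster$width)))
  if (!cfg$enabled) return(labels)
  ch <- feature_channels(raster)
  xbar <- neighborhood_mean(ch)
  n <- length(labels)
  X <- cbind(as.vector(xbar[, , 1]), as.vector(xbar[, , 2]),
             as.vector(xbar[, , 3]))
  W <- cfg$W
  if (is.null(W)) W <- 1 / pmax(apply(X, 2, stats::var), 1e-6)
  for (sweep in seq_len(cfg$iterations)) {
    lv <- as.vector(labels)
    ids <- sort(unique(lv))
    mu <- rowsum(X, lv, reorder = TRUE) / tabulate(match(lv, ids))
    d2 <- sapply(seq_along(ids), function(r) {
      (X[, 1] - mu[r, 1])^2 * W[1] + (X[, 2] - mu[r, 2])^2 * W[2] +
        (X[, 3] - mu[r, 3])^2 * W[3]
    })
    d <- sqrt(d2)
    own <- d[cbind(seq_len(n), match(lv, ids))]
    thr <- if (is.null(cfg$threshold)) stats::quantile(own, 0.95,
                                                       names = FALSE)
           else cfg$threshold
    move <- own > thr
    if (!any(move)) break
    nearest <- ids[max.col(-d[move, , drop = FALSE], ties.method = "first")]
    lv[move] <- nearest
    labels <- matrix(lv, nrow(labels), ncol(labels))
  }
  labels
}

#' Segment an image end to end
#'
#' Runs the full pipeline: color conversion (RGB to CIELAB; gray images are
#' embedded as (gray, 0, 0)), SLIC-style superpixels, scaled 5-D feature
#' extraction, density-peak clustering with entropy-weighted center
#' selection, pixel-level label expansion and the optional noise-isolation
#' pass. The result is deterministic for a fixed (raster, config).
#'
#' @param raster An [image_raster] (gray, rgb or lab).
#' @param cfg A [segmentation_config()].
#' @return A \code{segmentation_result}: list with \code{labels} (integer
#'   H x W grid, values \code{1..k}), \code{k}, \code{centers} (superpixel
#'   ids chosen as cluster centers), the \code{superpixels} map, the
#'   \code{dpc} result and a \code{manifest} recording every parameter
#'   actually used.
#' @export
segment_image <- function(raster, cfg = segmentation_config()) {
  stopifnot(inherits(raster, "image_raster"),
            inherits(cfg, "segmentation_config"))
  work <- if (raster$mode == "rgb") rgb_to_lab(raster) else raster
  sp <- generate_superpixels(work, cfg$superpixel)
  scal <- if (is.null(cfg$scaling)) scaling_config(h_s = sp$S, h_r = 1)
          else cfg$scaling
  feats <- superpixel_features(sp, scal)
  gv <- gray_view(raster)
  ent <- as.vector(tapply(as.vector(gv), as.vector(sp$labels),
                          gray_entropy))[seq_len(sp$K)]
  res <- dpc_cluster(as.matrix(feats[, c("x", "y", "l", "a", "b")]),
                     cfg = cfg$dpc, weights = feats$rho_sp, entropy = ent)
  labels <- pixels_from_superpixels(sp, res$labels)
  if (cfg$noise$enabled)
    labels <- isolate_noise(labels, work, cfg$noise)
  manifest <- list(
    image = list(height = raster$height, width = raster$width,
                 mode = raster$mode),
    superpixel = list(n_requested = cfg$superpixel$n_superpixels,
                      K = sp$K, S = sp$S, m = cfg$superpixel$m,
                      max_iter = cfg$superpixel$max_iter),
    scaling = list(h_s = scal$h_s, h_r = scal$h_r),
    dpc = list(d_c = res$d_c, k = res$k,
               density_kernel = cfg$dpc$density_kernel,
               decision_rule = cfg$dpc$decision_rule,
               use_entropy_weight = cfg$dpc$use_entropy_weight),
    noise = list(enabled = cfg$noise$enabled,
                 iterations = cfg$noise$iterations),
    centers = res$centers,
    entropy_per_center = ent[res$centers],
    seed = cfg$seed)
  structure(list(labels = labels, k = res$k, centers = res$centers,
                 superpixels = sp, dpc = res, manifest = manifest),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result %d x %d, k=%d clusters, K=%d superpixels>\n",
              nrow(x$labels), ncol(x$labels), x$k, x$superpixels$K))
  invisible(x)
}
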