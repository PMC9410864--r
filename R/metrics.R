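# Shared helpers -------------------------------------------------------------

# The predicted label with the largest overlap with the truth background is
# treated as background; all other labels are split into connected
# components, which are the predicted regions matched against per-feature
# masks.
pred_regions <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  bg_overlap <- tapply(as.vector(truth == 0L), as.vector(pred), sum)
  bg_label <- as.integer(names(bg_overlap)[which.max(bg_overlap)])
  comp <- matrix(0L, nrow(pred), ncol(pred))
  nc <- 0L
  for (lab in setdiff(sort(unique(as.vector(pred))), bg_label)) {
    mask <- pred == lab
    cc <- EBImage::bwlabel(mask + 0L)
    comp[mask] <- as.integer(cc[mask]) + nc
    nc <- nc + max(cc)
  }
  list(components = comp, n = nc, background_label = bg_label)
}

# Per-feature best IoU and best recall against the predicted regions, via a
# single contingency table.
feature_match <- function(pred, truth) {
  reg <- pred_regions(pred, truth)
  feats <- setdiff(sort(unique(as.vector(truth))), 0L)
  chi <- length(feats)
  best_iou <- stats::setNames(numeric(chi), feats)
  best_recall <- stats::setNames(numeric(chi), feats)
  if (reg$n > 0 && chi > 0) {
    cv <- as.vector(reg$components)
    tv <- as.vector(truth)
    keep <- cv > 0L & tv > 0L
    if (any(keep)) {
      tab <- table(component = cv[keep], feature = tv[keep])
      csize <- tabulate(cv, reg$n)
      fsize <- tabulate(tv, max(feats))
      for (f in as.character(feats)) {
        if (!f %in% colnames(tab)) next
        inter <- tab[, f]
        cids <- as.integer(rownames(tab))
        iou <- inter / (csize[cids] + fsize[as.integer(f)] - inter)
        best_iou[f] <- max(iou)
        best_recall[f] <- max(inter) / fsize[as.integer(f)]
      }
    }
  }
  list(chi = chi, best_iou = best_iou, best_recall = best_recall,
       background_label = reg$background_label)
}

#' Segmentation integrity rate
#'
#' A ground-truth feature counts as completely segmented when some predicted
#' region (a connected component of a non-background predicted label)
#' reaches IoU >= \code{iou_threshold} with the feature's mask. The
#' integrity rate is \code{R = chi_prime / chi * 100}.
#'
#' @param pred Integer predicted label grid.
#' @param truth Integer ground-truth grid: 0 = background, feature ids
#'   \code{1..chi}.
#' @param iou_threshold IoU required to count a feature as complete
#'   (default 0.7).
#' @return List with \code{R} (percent), \code{chi_prime}, \code{chi} and
#'   the per-feature best IoU vector.
#' @export
integrity_rate <- function(pred, truth, iou_threshold = 0.7) {
  fm <- feature_match(pred, truth)
  if (fm$chi == 0) stop("truth contains no features (chi = 0)")
  chi_prime <- sum(fm$best_iou >= iou_threshold)
  list(R = 100 * chi_prime / fm$chi, chi_prime = chi_prime, chi = fm$chi,
       iou = fm$best_iou)
}

#' Count ground-truth features missing from a segmentation
#'
#' A feature is missing when no predicted non-background region covers at
#' least \code{min_recall} of its mask.
#'
#' @inheritParams integrity_rate
#' @param min_recall Fraction of the feature mask that must be covered
#'   (default 0.5).
#' @return Integer count of missing features.
#' @export
count_missing_features <- function(pred, truth, min_recall = 0.5) {
  fm <- feature_match(pred, truth)
  sum(fm$best_recall < min_recall)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same
#' pixel (or point) set, computed from the contingency table; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b Equal-length label vectors (any label alphabet).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Segmentation accuracy: ARI and per-feature mean IoU
#'
#' @param pred Integer predicted label grid.
#' @param truth Integer ground-truth label grid (0 = background).
#' @return List with \code{ari} (over the full pixel partitions) and
#'   \code{mean_iou} (mean best-match IoU over truth features).
#' @export
segmentation_accuracy <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  ari <- adjusted_rand_index(pred, truth)
  fm <- feature_match(pred, truth)
  list(ari = ari,
       mean_iou = if (fm$chi) mean(fm$best_iou) else NA_real_)
}

#' Estimate image noise variance from low-variance blocks
#'
#' Partitions the image into non-overlapping \code{block x block} tiles
#' (ragged edges discarded), computes each tile's sample variance, sorts
#' them ascending, and returns the mean of the lowest
#' \code{ceil(fraction * n_blocks)} variances. Homogeneous tiles dominate
#' the low order statistics, so the result estimates the additive noise
#' variance.
#'
#' @param raster An [image_raster] or a numeric matrix of gray values.
#' @param block Tile edge length in pixels (>= 2; default 32).
#' @param fraction Share of lowest-variance tiles averaged (default 0.01).
#' @return The estimated noise variance (gray-level units squared).
#' @export
estimate_noise_variance <- function(raster, block = 32, fraction = 0.01) {
  x <- if (inherits(raster, "image_raster")) gray_view(raster) else raster
  stopifnot(is.matrix(x), block >= 2)
  Hb <- nrow(x) %/% block; Wb <- ncol(x) %/% block
  if (Hb < 1 || Wb < 1)
    stop("image (", nrow(x), " x ", ncol(x), ") smaller than one ",
         block, " x ", block, " block")
  x <- x[seq_len(Hb * block), seq_len(Wb * block), drop = FALSE]
  tiles <- array(x, c(block, Hb, block, Wb))
  v <- apply(tiles, c(2, 4), function(t) stats::var(as.vector(t)))
  v <- sort(as.vector(v))
  mean(v[seq_len(ceiling(fraction * length(v)))])
}

#' Evaluate a segmentation against ground truth
#'
#' Bundles the evaluation suite: integrity rate, missing-feature count,
#' adjusted Rand index, mean per-feature IoU, and (when the segmented image
#' is supplied) the block-variance noise estimate.
#'
#' @inheritParams integrity_rate
#' @param raster Optional [image_raster] for noise estimation.
#' @param min_recall Recall threshold for the missing-feature count.
#' @return An \code{evaluation_report} list with fields
#'   \code{integrity_rate}, \code{chi}, \code{chi_prime},
#'   \code{missing_features}, \code{ari}, \code{mean_iou},
#'   \code{noise_variance}.
#' @export
evaluate_segmentation <- function(pred, truth, raster = NULL,
                                  iou_threshold = 0.7, min_recall = 0.5) {
  ir <- integrity_rate(pred, truth, iou_threshold)
  acc <- segmentation_accuracy(pred, truth)
  structure(list(
    integrity_rate = ir$R, chi = ir$chi, chi_prime = ir$chi_prime,
    missing_features = count_missing_features(pred, truth, min_recall),
    ari = acc$ari, mean_iou = acc$mean_iou,
    noise_variance = if (is.null(raster)) NA_real_
                     else estimate_noise_variance(raster)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report R=%.1f%% (%d/%d), missing=%d, ",
                     "ARI=%.3f, mean IoU=%.3f, noise var=%s>\n"),
              x$integrity_rate, x$chi_prime, x$chi, x$missing_features,
              x$ari, x$mean_iou,
              if (is.na(x$noise_variance)) "NA"
              else sprintf("%.1f", x$noise_variance)))
  invisible(x)
}
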