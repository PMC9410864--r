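#' Superpixel configuration
#'
#' Controls the SLIC-style local clustering that compresses the image into
#' superpixels before density-peak clustering. The grid spacing
#' \code{S = round(sqrt(H * W / n_superpixels))} is derived from the image at
#' run time; each center searches a 2S x 2S window.
#'
#' @param n_superpixels Requested superpixel count (>= 2).
#' @param m Compactness index (> 0): weight of the spatial term in the joint
#'   distance \code{D_s = d_lab + (m / S) * d_xy}. Larger values give more
#'   regular, squarer superpixels; smaller values track color edges.
#' @param max_iter Iteration cap for the assign/update loop.
#' @param tol Convergence tolerance: stop when no center moves by more than
#'   this many pixels.
#' @param min_size_frac Connected components smaller than
#'   \code{min_size_frac * S^2} are merged into the dominant neighbouring
#'   superpixel.
#' @return A \code{superpixel_config} object.
#' @export
superpixel_config <- function(n_superpixels = 256, m = 10, max_iter = 10,
                              tol = 1, min_size_frac = 0.25) {
  if (n_superpixels < 2) stop("n_superpixels must be >= 2")
  if (m <= 0) stop("compactness m must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(n_superpixels = n_superpixels, m = m, max_iter = max_iter,
                 tol = tol, min_size_frac = min_size_frac),
            class = "superpixel_config")
}

grid_spacing <- function(raster, cfg) {
  max(1L, as.integer(round(sqrt(raster$height * raster$width /
                                  cfg$n_superpixels))))
}

# L-channel gradient used to nudge initial centers off edges: sum of absolute
# central differences, edge-replicated.
l_gradient <- function(L) {
  H <- nrow(L); W <- ncol(L)
  up <- L[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- L[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- L[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- L[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  abs(dn - up) + abs(rt - lf)
}

#' Initial superpixel centers on a regular grid
#'
#' Places centers on an S-spaced grid and moves each to the lowest-gradient
#' pixel in its 3 x 3 neighbourhood (ties keep the grid pixel), so no center
#' starts on a color edge.
#'
#' @param raster An [image_raster] in gray or lab mode.
#' @param cfg A [superpixel_config()].
#' @return Integer matrix of center positions, one \code{(row, col)} per row.
#' @export
init_grid_centers <- function(raster, cfg) {
  S <- grid_spacing(raster, cfg)
  H <- raster$height; W <- raster$width
  if (H < S || W < S)
    stop("image (", H, " x ", W, ") smaller than grid spacing S = ", S)
  ch <- feature_channels(raster)
  grad <- l_gradient(ch[, , 1])
  nr <- H %/% S; nc <- W %/% S
  rows <- pmin(H, floor((seq_len(nr) - 0.5) * S) + 1L)
  cols <- pmin(W, floor((seq_len(nc) - 0.5) * S) + 1L)
  centers <- as.matrix(expand.grid(row = rows, col = cols))
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]; c0 <- centers[i, 2]
    rr <- max(1, r - 1):min(H, r + 1)
    cc <- max(1, c0 - 1):min(W, c0 + 1)
    g <- grad[rr, cc, drop = FALSE]
    if (grad[r, c0] > min(g)) {        # strict improvement: ties keep center
      at <- which(g == min(g), arr.ind = TRUE)[1, ]
      centers[i, ] <- c(rr[at[1]], cc[at[2]])
    }
  }
  dimnames(centers) <- list(NULL, c("row", "col"))
  centers
}

#' Joint color-spatial SLIC distance
#'
#' \code{D_s = d_lab + (m / S) * d_xy}, where \code{d_xy} is the Euclidean
#' pixel distance and \code{d_lab} the Euclidean CIELAB distance.
#'
#' @param pixel,center Numeric length-5 vectors \code{(row, col, l, a, b)}.
#' @param m Compactness index (> 0).
#' @param S Grid spacing (>= 1).
#' @return The scalar joint distance.
#' @export
slic_distance <- function(pixel, center, m, S) {
  stopifnot(m > 0, S >= 1, length(pixel) == 5L, length(center) == 5L)
  d_xy <- sqrt(sum((pixel[1:2] - center[1:2])^2))
  d_lab <- sqrt(sum((pixel[3:5] - center[3:5])^2))
  d_lab + (m / S) * d_xy
}

#' Generate superpixels by local color-spatial clustering
#'
#' Iterative SLIC-style assignment: each pixel joins the nearest center by
#' the joint distance \code{D_s} among centers whose 2S x 2S window covers
#' it (ties to the lower center id); centers are then recomputed as cluster
#' means. Pixels covered by no window are attached to the globally nearest
#' center. After convergence, connected components smaller than
#' \code{min_size_frac * S^2} are merged into the dominant neighbouring
#' superpixel, and labels are compacted to \code{1..K}.
#'
#' @param raster An [image_raster] in gray or lab mode (RGB images must be
#'   converted with [rgb_to_lab()] first).
#' @param cfg A [superpixel_config()].
#' @return A \code{superpixel_map}: list with \code{labels} (H x W integer
#'   matrix, values \code{1..K}), \code{K}, \code{centroids} (K x 2),
#'   \code{mean_lab} (K x 3), \code{rho_sp} (per-superpixel pixel count) and
#'   \code{S}.
#' @export
generate_superpixels <- function(raster, cfg = superpixel_config()) {
  stopifnot(inherits(raster, "image_raster"))
  if (raster$mode == "rgb")
    stop("generate_superpixels expects a gray or lab raster; use rgb_to_lab()")
  H <- raster$height; W <- raster$width
  S <- grid_spacing(raster, cfg)
  ch <- feature_channels(raster)
  l <- ch[, , 1]; a <- ch[, , 2]; b <- ch[, , 3]
  centers <- init_grid_centers(raster, cfg)
  K <- nrow(centers)
  crow <- centers[, 1]; ccol <- centers[, 2]
  cl <- l[centers]; ca <- a[centers]; cb <- b[centers]
  labels <- matrix(0L, H, W)
  w <- cfg$m / S

  for (it in seq_len(cfg$max_iter)) {
    best <- matrix(Inf, H, W)
    labels[] <- 0L
    for (k in seq_len(K)) {
      r0 <- round(crow[k]); c0 <- round(ccol[k])
      rr <- max(1L, r0 - S):min(H, r0 + S)
      cc <- max(1L, c0 - S):min(W, c0 + S)
      dlab <- sqrt((l[rr, cc] - cl[k])^2 + (a[rr, cc] - ca[k])^2 +
                     (b[rr, cc] - cb[k])^2)
      dxy <- sqrt(outer((rr - crow[k])^2, (cc - ccol[k])^2, "+"))
      D <- dlab + w * dxy
      upd <- D < best[rr, cc]            # strict: earlier (lower) id wins ties
      if (any(upd)) {
        sl <- labels[rr, cc]; sl[upd] <- k; labels[rr, cc] <- sl
        sb <- best[rr, cc]; sb[upd] <- D[upd]; best[rr, cc] <- sb
      }
    }
    orphans <- which(labels == 0L)
    if (length(orphans)) {
      orow <- ((orphans - 1L) %% H) + 1L
      ocol <- ((orphans - 1L) %/% H) + 1L
      for (t in seq_along(orphans)) {
        p <- orphans[t]
        D <- sqrt((cl - l[p])^2 + (ca - a[p])^2 + (cb - b[p])^2) +
          w * sqrt((crow - orow[t])^2 + (ccol - ocol[t])^2)
        labels[p] <- which.min(D)
      }
    }
    rowg <- matrix(seq_len(H), H, W)
    colg <- matrix(seq_len(W), H, W, byrow = TRUE)
    lv <- as.vector(labels)
    cnt <- tabulate(lv, K)
    keep <- cnt > 0
    sums <- function(v) as.vector(rowsum(as.vector(v), lv, reorder = TRUE))
    nr <- crow; nc <- ccol
    nr[keep] <- sums(rowg)[keep] / cnt[keep]
    nc[keep] <- sums(colg)[keep] / cnt[keep]
    disp <- max(sqrt((nr - crow)^2 + (nc - ccol)^2))
    crow <- nr; ccol <- nc
    cl[keep] <- sums(l)[keep] / cnt[keep]
    ca[keep] <- sums(a)[keep] / cnt[keep]
    cb[keep] <- sums(b)[keep] / cnt[keep]
    if (disp < cfg$tol && it > 1L) break
  }

  labels <- enforce_connectivity(labels, floor(cfg$min_size_frac * S^2))
  # compact label ids and aggregate
  ids <- sort(unique(as.vector(labels)))
  labels <- matrix(match(labels, ids), H, W)
  K <- length(ids)
  lv <- as.vector(labels)
  cnt <- tabulate(lv, K)
  rowg <- matrix(seq_len(H), H, W)
  colg <- matrix(seq_len(W), H, W, byrow = TRUE)
  sums <- function(v) as.vector(rowsum(as.vector(v), lv, reorder = TRUE))
  centroids <- cbind(row = sums(rowg) / cnt, col = sums(colg) / cnt)
  mean_lab <- cbind(l = sums(l) / cnt, a = sums(a) / cnt, b = sums(b) / cnt)
  structure(list(labels = labels, K = K, centroids = centroids,
                 mean_lab = mean_lab, rho_sp = cnt, S = S),
            class = "superpixel_map")
}

# Merge connected components smaller than min_size into the neighbouring
# superpixel that shares the longest boundary with them. Vectorized over
# components; repeated passes absorb fragments freed by earlier merges.
enforce_connectivity <- function(labels, min_size, max_pass = 10L) {
  if (min_size < 2) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  for (pass in seq_len(max_pass)) {
    comp <- matrix(0L, H, W)
    nc <- 0L
    for (lab in sort(unique(as.vector(labels)))) {
      mask <- labels == lab
      cc <- EBImage::bwlabel(mask + 0L)
      comp[mask] <- as.integer(cc[mask]) + nc
      nc <- nc + max(cc)
    }
    compv <- as.vector(comp)
    lv <- as.vector(labels)
    sizes <- tabulate(compv, nc)
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small)) break
    K <- max(lv)
    sidx <- integer(nc)
    sidx[small] <- seq_along(small)
    ownlab <- integer(nc)
    ownlab[compv] <- lv                       # component id -> its label
    # neighbour pairs across the 4-connected grid edges
    pair <- rbind(
      cbind(as.vector(comp[-H, ]), as.vector(comp[-1, ]),
            as.vector(labels[-H, ]), as.vector(labels[-1, ])),
      cbind(as.vector(comp[, -W]), as.vector(comp[, -1]),
            as.vector(labels[, -W]), as.vector(labels[, -1])))
    pair <- pair[pair[, 1] != pair[, 2], , drop = FALSE]
    a <- rbind(pair[, c(1, 4)], pair[, c(2, 3)]) # component -> foreign label
    a <- a[sidx[a[, 1]] > 0L, , drop = FALSE]
    a <- a[a[, 2] != ownlab[a[, 1]], , drop = FALSE]
    if (!nrow(a)) break
    # boundary-length votes: row = small component, column = candidate label
    votes <- matrix(tabulate((sidx[a[, 1]] - 1L) * K + a[, 2],
                             length(small) * K),
                    nrow = length(small), byrow = TRUE)
    has <- rowSums(votes) > 0
    if (!any(has)) break
    tgt <- max.col(votes, ties.method = "first")
    newlab <- integer(nc)
    newlab[small[has]] <- tgt[has]
    sel <- newlab[compv] > 0L
    lv[sel] <- newlab[compv[sel]]
    labels <- matrix(lv, H, W)
  }
  labels
}

#' Per-superpixel feature vectors and density weights
#'
#' Scales each superpixel's centroid and mean color into the clustering
#' feature space and carries the superpixel pixel count as its initial
#' density weight.
#'
#' @param sp A \code{superpixel_map} from [generate_superpixels()].
#' @param cfg A [scaling_config()]; by default \code{h_s = S}, \code{h_r = 1}.
#' @return A data frame with columns \code{id, x, y, l, a, b, rho_sp}.
#' @export
superpixel_features <- function(sp, cfg = scaling_config(h_s = sp$S)) {
  stopifnot(inherits(sp, "superpixel_map"))
  f <- scale_features(sp$centroids, sp$mean_lab, cfg)
  data.frame(id = seq_len(sp$K), f, rho_sp = sp$rho_sp)
}
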