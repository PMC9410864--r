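#' Density-peak clustering configuration
#'
#' @param d_c Cutoff distance in scaled feature units, constrained to
#'   \code{(0, 10]}. \code{NULL} (default) selects the 2\% quantile of the
#'   off-diagonal pairwise distances, clamped into that interval.
#' @param k Number of cluster centers, \code{2 <= k <= 30}. \code{NULL}
#'   selects k at the largest gap in the sorted decision scores.
#' @param density_kernel One of \code{"weighted_cutoff"} (superpixel-size
#'   weighted neighbour count, the pipeline default), \code{"cutoff"}
#'   (plain neighbour count) or \code{"gaussian"} (continuous relaxation for
#'   blurred edges).
#' @param use_entropy_weight Multiply the decision score by each point's
#'   gray-level entropy when entropies are supplied.
#' @param decision_rule \code{"product"} (\code{gamma = rho * delta}) or
#'   \code{"sum"} (\code{rho + delta}).
#' @param strict_cutoff Use the strict inequality \code{d_ij < d_c} in the
#'   cutoff indicator instead of the default closed \code{d_ij <= d_c}.
#' @return A \code{dpc_config} object.
#' @export
dpc_config <- function(d_c = NULL, k = NULL,
                       density_kernel = c("weighted_cutoff", "cutoff",
                                          "gaussian"),
                       use_entropy_weight = TRUE,
                       decision_rule = c("product", "sum"),
                       strict_cutoff = FALSE) {
  density_kernel <- match.arg(density_kernel)
  decision_rule <- match.arg(decision_rule)
  if (!is.null(d_c) && (!is.finite(d_c) || d_c <= 0 || d_c > 10))
    stop("d_c must lie in (0, 10]")
  if (!is.null(k) && (k < 2 || k > 30))
    stop("k must satisfy 2 <= k <= 30")
  structure(list(d_c = d_c, k = k, density_kernel = density_kernel,
                 use_entropy_weight = use_entropy_weight,
                 decision_rule = decision_rule,
                 strict_cutoff = strict_cutoff),
            class = "dpc_config")
}

#' Pairwise Euclidean distances between feature vectors
#'
#' @param features Numeric matrix, one point per row (any dimension; the
#'   pipeline uses the scaled 5-D (x, y, l, a, b) space).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 points")
  if (!all(is.finite(features))) stop("features must be finite")
  as.matrix(stats::dist(features))
}

#' Local density by neighbour count within the cutoff distance
#'
#' \code{rho_i = #\{j != i : d_ij <= d_c\}} (closed indicator by default;
#' \code{strict = TRUE} counts \code{d_ij < d_c}).
#'
#' @param D Distance matrix.
#' @param d_c Cutoff distance (> 0).
#' @param strict Use the strict inequality variant.
#' @return Integer vector of densities.
#' @export
cutoff_density <- function(D, d_c, strict = FALSE) {
  stopifnot(is.matrix(D), d_c > 0)
  if (strict) rowSums(D < d_c) - 1L else rowSums(D <= d_c) - 1L
}

#' Local density under the Gaussian kernel
#'
#' \code{rho_i = sum_\{j != i\} exp(-(d_ij / d_c)^2)}: the continuous
#' relaxation of the cutoff count, preferred when edges are blurred and
#' integer counts tie heavily.
#'
#' @inheritParams cutoff_density
#' @return Numeric vector of densities.
#' @export
gaussian_density <- function(D, d_c) {
  stopifnot(is.matrix(D), d_c > 0)
  rowSums(exp(-(D / d_c)^2)) - 1
}

#' Weighted cutoff density
#'
#' Each qualifying neighbour contributes its weight \code{P_j} (the
#' superpixel pixel count in the pipeline), so the superpixel-level density
#' approximates the underlying pixel-level density:
#' \code{rho_i = sum_\{j != i, d_ij <= d_c\} P_j}.
#'
#' @inheritParams cutoff_density
#' @param P Non-negative per-point weights.
#' @param include_self Also count the point's own weight \code{P_i}. The
#'   full pipeline enables this: a superpixel stands for \code{P_i} pixels
#'   at its location, and those pixels lie within any \code{d_c > 0} of each
#'   other, so dropping the self term would erase exactly the mass of
#'   compact single-superpixel features (see the methods vignette).
#' @return Numeric vector of densities.
#' @export
weighted_density <- function(D, d_c, P, strict = FALSE,
                             include_self = FALSE) {
  stopifnot(is.matrix(D), d_c > 0, length(P) == nrow(D))
  if (any(P < 0)) stop("weights P must be non-negative")
  M <- if (strict) D < d_c else D <= d_c
  diag(M) <- include_self
  as.vector(M %*% P)
}

#' Separation distance and nearest higher-density neighbour
#'
#' For each point, \code{delta_i} is the minimum distance to any point of
#' strictly higher density (density ties broken by index: j outranks i when
#' \code{rho_j > rho_i} or \code{rho_j == rho_i && j < i}), and
#' \code{neigh_i} is the argmin (distance ties to the lowest index). The
#' unique top-ranked point gets \code{delta = max_j d_ij} and
#' \code{neigh = NA}.
#'
#' @param D Distance matrix.
#' @param rho Density vector.
#' @return List with numeric \code{delta} and integer \code{neigh}
#'   (\code{NA} for the density maximum).
#' @export
compute_delta <- function(D, rho) {
  n <- length(rho)
  stopifnot(nrow(D) == n, all(is.finite(rho)))
  ord <- order(-rho, seq_len(n))       # rank 1 = densest, ties by low index
  delta <- numeric(n)
  neigh <- rep(NA_integer_, n)
  top <- ord[1]
  delta[top] <- max(D[top, ])
  for (t in seq_len(n)[-1]) {
    i <- ord[t]
    cand <- ord[seq_len(t - 1L)]
    d <- D[i, cand]
    delta[i] <- min(d)
    neigh[i] <- min(cand[d == delta[i]])
  }
  list(delta = delta, neigh = neigh)
}

#' Decision scores from density and separation
#'
#' @param rho,delta Equal-length numeric vectors.
#' @param rule \code{"product"}: \code{gamma = rho * delta} (default);
#'   \code{"sum"}: \code{rho + delta}.
#' @return Numeric score vector.
#' @export
gamma_scores <- function(rho, delta, rule = c("product", "sum")) {
  rule <- match.arg(rule)
  stopifnot(length(rho) == length(delta))
  if (rule == "product") rho * delta else rho + delta
}

#' One-dimensional gray-level Shannon entropy
#'
#' Entropy (bits) of the 256-bin gray-level histogram,
#' \code{H = -sum p_i log2 p_i} with \code{0 log 0 := 0}. Constant regions
#' have H = 0; a perfectly uniform histogram has H = 8.
#'
#' @param x Gray values in \code{[0, 255]} (vector, matrix or gray
#'   [image_raster]).
#' @return Entropy in bits, in \code{[0, 8]}.
#' @export
gray_entropy <- function(x) {
  if (inherits(x, "image_raster")) x <- gray_view(x)
  x <- as.vector(x)
  if (!length(x)) stop("gray_entropy: empty region")
  if (min(x) < 0 || max(x) > 255) stop("gray values must lie in [0, 255]")
  p <- tabulate(as.integer(round(x)) + 1L, 256L)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Select cluster centers by top decision score
#'
#' Scores are \code{gamma_i * H_i} when entropy weights are supplied and
#' enabled (H_i = gray entropy of the point's pixel support), otherwise
#' \code{gamma_i}; the k largest scores (ties to the lower index) are the
#' centers.
#'
#' @param gamma Decision scores.
#' @param k Number of centers, \code{2 <= k <= min(30, n)}.
#' @param entropy Optional per-point entropy weights.
#' @return Integer vector of k distinct center indices, in descending score
#'   order.
#' @details Score ties fall back to the unweighted decision score, then to
#'   the lower index. The gamma fallback matters when the entropy weights
#'   are degenerate (e.g. every region of a noiseless synthetic image is
#'   constant, so all entropies — and all weighted scores — are zero).
#' @export
select_centers <- function(gamma, k, entropy = NULL) {
  n <- length(gamma)
  if (k > n) stop("k (", k, ") exceeds number of points (", n, ")")
  if (k < 2 || k > 30) stop("k must satisfy 2 <= k <= 30")
  score <- if (!is.null(entropy)) gamma * entropy else gamma
  order(-score, -gamma, seq_len(n))[seq_len(k)]
}

# Largest gap in the sorted scores picks k; the search is restricted to the
# valid [2, 30] range.
choose_k <- function(score) {
  n <- length(score)
  s <- sort(score, decreasing = TRUE)
  hi <- min(30L, n - 1L)
  if (hi < 2L) return(2L)
  gaps <- s[2:hi] - s[3:(hi + 1L)]
  which.max(gaps) + 1L
}

# Default cutoff: 2% quantile of off-diagonal distances, clamped to (0, 10].
choose_dc <- function(D) {
  off <- D[upper.tri(D)]
  q <- stats::quantile(off, 0.02, names = FALSE)
  if (q <= 0) {
    pos <- off[off > 0]
    q <- if (length(pos)) min(pos) else 1e-6
  }
  min(q, 10)
}

#' Propagate cluster labels from centers along density descent
#'
#' Centers receive labels \code{1..k} in their given (descending-score)
#' order; the remaining points are visited in decreasing-density order and
#' inherit the label of their nearest higher-density neighbour.
#'
#' @param neigh Nearest higher-density neighbour indices
#'   (from [compute_delta()]).
#' @param rho Density vector.
#' @param centers Center indices.
#' @param D Optional distance matrix, used to attach a point with no
#'   higher-density neighbour (the density maximum, if it is not a center)
#'   to its nearest center.
#' @return Integer label vector with values in \code{1..length(centers)}.
#' @export
assign_clusters <- function(neigh, rho, centers, D = NULL) {
  n <- length(rho)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  ord <- order(-rho, seq_len(n))
  for (i in ord) {
    if (!is.na(labels[i])) next
    if (is.na(neigh[i])) {
      if (is.null(D)) stop("density maximum is not a center and no distance ",
                           "matrix was supplied")
      labels[i] <- labels[centers[which.min(D[i, centers])]]
    } else {
      labels[i] <- labels[neigh[i]]
    }
  }
  labels
}

#' Run the full density-peak clustering core
#'
#' Computes pairwise distances, the configured density, separations,
#' decision scores, (entropy-weighted) center selection and label
#' propagation in one call.
#'
#' @param features Numeric point matrix (one point per row).
#' @param cfg A [dpc_config()].
#' @param weights Optional per-point weights for the weighted cutoff kernel
#'   (defaults to 1).
#' @param entropy Optional per-point gray-entropy weights for center
#'   selection.
#' @return A \code{dpc_result}: list with \code{rho}, \code{delta},
#'   \code{gamma}, \code{score}, \code{neigh}, \code{centers},
#'   \code{labels}, \code{outlier}, and the resolved \code{d_c} and
#'   \code{k}.
#' @export
dpc_cluster <- function(features, cfg = dpc_config(), weights = NULL,
                        entropy = NULL) {
  stopifnot(inherits(cfg, "dpc_config"))
  D <- pairwise_distances(features)
  n <- nrow(D)
  d_c <- if (is.null(cfg$d_c)) choose_dc(D) else cfg$d_c
  rho <- switch(cfg$density_kernel,
    cutoff = cutoff_density(D, d_c, strict = cfg$strict_cutoff),
    gaussian = gaussian_density(D, d_c),
    weighted_cutoff = weighted_density(
      D, d_c, if (is.null(weights)) rep(1, n) else weights,
      strict = cfg$strict_cutoff, include_self = TRUE))
  ds <- compute_delta(D, rho)
  gamma <- gamma_scores(rho, ds$delta, cfg$decision_rule)
  ent <- if (cfg$use_entropy_weight && !is.null(entropy)) entropy else NULL
  score <- if (!is.null(ent)) gamma * ent else gamma
  k <- if (is.null(cfg$k)) max(2L, min(choose_k(score), n)) else cfg$k
  centers <- select_centers(gamma, k, entropy = ent)
  labels <- assign_clusters(ds$neigh, rho, centers, D = D)
  structure(list(rho = rho, delta = ds$delta, gamma = gamma, score = score,
                 neigh = ds$neigh, centers = centers, labels = labels,
                 outlier = rho == 0, d_c = d_c, k = k),
            class = "dpc_result")
}
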