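# Brute-force reference implementations used as independent oracles.
# Deliberately written as plain elementwise loops, sharing no code with the
# package internals.

oracle_distances <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

oracle_cutoff <- function(D, d_c) {
  n <- nrow(D)
  rho <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) if (j != i && D[i, j] - d_c <= 0) cnt <- cnt + 1L
    rho[i] <- cnt
  }
  rho
}

oracle_gaussian <- function(D, d_c) {
  n <- nrow(D)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + exp(-(D[i, j] / d_c)^2)
    rho[i] <- s
  }
  rho
}

oracle_weighted <- function(D, d_c, P, include_self = FALSE) {
  n <- nrow(D)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (include_self) P[i] else 0
    for (j in seq_len(n)) if (j != i && D[i, j] <= d_c) s <- s + P[j]
    rho[i] <- s
  }
  rho
}

# Density rank: j outranks i iff rho_j > rho_i, ties broken by lower index.
oracle_delta <- function(D, rho) {
  n <- length(rho)
  delta <- numeric(n)
  neigh <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- Inf; who <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      if (rho[j] > rho[i] || (rho[j] == rho[i] && j < i)) {
        if (D[i, j] < best || (D[i, j] == best && j < who)) {
          best <- D[i, j]; who <- j
        }
      }
    }
    if (is.na(who)) {
      delta[i] <- max(D[i, ])
    } else {
      delta[i] <- best; neigh[i] <- who
    }
  }
  list(delta = delta, neigh = neigh)
}

oracle_topk <- function(score, k) {
  picked <- integer(0)
  s <- score
  for (t in seq_len(k)) {
    best <- -Inf; who <- NA_integer_
    for (i in seq_along(s)) {
      if (i %in% picked) next
      if (s[i] > best) { best <- s[i]; who <- i }
    }
    picked <- c(picked, who)
  }
  picked
}

oracle_assign <- function(neigh, rho, centers, D = NULL) {
  n <- length(rho)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  resolve <- function(i) {
    if (!is.na(labels[i])) return(labels[i])
    lab <- if (is.na(neigh[i])) {
      # density maximum that is not a center: nearest center wins
      best <- centers[1]
      for (c0 in centers) if (D[i, c0] < D[i, best]) best <- c0
      labels[best]
    } else {
      resolve(neigh[i])
    }
    labels[i] <<- lab
    lab
  }
  for (i in seq_len(n)) labels[i] <- resolve(i)
  labels
}

# Per-feature best IoU by explicit double loop over predicted components
# and truth features.
oracle_best_iou <- function(comp, truth) {
  feats <- setdiff(sort(unique(as.vector(truth))), 0L)
  out <- numeric(length(feats))
  comps <- setdiff(sort(unique(as.vector(comp))), 0L)
  for (fi in seq_along(feats)) {
    fmask <- truth == feats[fi]
    best <- 0
    for (cid in comps) {
      cmask <- comp == cid
      inter <- sum(cmask & fmask)
      if (inter == 0) next
      best <- max(best, inter / sum(cmask | fmask))
    }
    out[fi] <- best
  }
  out
}

# Closed-form ARI from the contingency table, written independently.
oracle_ari <- function(a, b) {
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(ct)
  sum_ij <- sum(comb2(ct))
  sum_i <- sum(comb2(rowSums(ct)))
  sum_j <- sum(comb2(colSums(ct)))
  exp_idx <- sum_i * sum_j / comb2(n)
  ((sum_ij - exp_idx) / ((sum_i + sum_j) / 2 - exp_idx))
}

# Fixtures ------------------------------------------------------------------

# Collinear worked example: 1-D points 0, 1, 2, 10 embedded in 5-D.
collinear_points <- function() {
  cbind(c(0, 1, 2, 10), 0, 0, 0, 0)
}

# Two homogeneous vertical halves with strongly different colors.
two_halves_raster <- function(H = 64, W = 64, lo = 40, hi = 200) {
  px <- matrix(lo, H, W)
  px[, (W %/% 2 + 1):W] <- hi
  image_raster(px, "gray")
}
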