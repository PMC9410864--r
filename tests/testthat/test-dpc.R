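test_that("pairwise distances match an elementwise loop exactly", {
  set.seed(2)
  X <- matrix(stats::rnorm(50 * 5), 50, 5)
  D <- pairwise_distances(X)
  expect_equal(D, oracle_distances(X), ignore_attr = TRUE)
  expect_equal(diag(D), rep(0, 50), ignore_attr = TRUE)
  expect_equal(D, t(D))
  two <- pairwise_distances(rbind(c(0, 0, 0, 0, 0), c(3, 4, 0, 0, 0)))
  expect_equal(two[1, 2], 5)
  same <- pairwise_distances(rbind(1:5, 1:5))
  expect_equal(unname(same), matrix(0, 2, 2))
  expect_error(pairwise_distances(matrix(1, 1, 5)), "at least 2")
})

test_that("cutoff density counts neighbours on the closed condition", {
  D <- pairwise_distances(collinear_points())
  expect_equal(cutoff_density(D, 1.5), c(1, 2, 1, 0), ignore_attr = TRUE)
  # saturation: d_c beyond the diameter reaches n - 1 everywhere
  expect_equal(cutoff_density(D, 100), rep(3, 4), ignore_attr = TRUE)
  # closed vs strict at an exact tie
  expect_equal(cutoff_density(D, 1), c(1, 2, 1, 0), ignore_attr = TRUE)
  expect_equal(cutoff_density(D, 1, strict = TRUE), c(0, 0, 0, 0),
               ignore_attr = TRUE)
  # far single point is neighbourless
  expect_equal(cutoff_density(D, 1.5)[4], 0, ignore_attr = TRUE)
})

test_that("gaussian density follows its closed form and breaks count ties", {
  two <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(gaussian_density(two, 3), rep(exp(-1), 2))
  expect_equal(gaussian_density(matrix(0, 2, 2), 1), rep(1, 2))
  # on a Gaussian mixture the two kernels rank points almost identically
  pc <- generate_point_cloud(point_cloud_spec(n_clusters = 2,
                                              points_per_cluster = 100,
                                              cluster_sigma = 1,
                                              center_separation = 6,
                                              seed = 0))
  D <- pairwise_distances(pc$points)
  dc <- stats::quantile(D[upper.tri(D)], 0.05, names = FALSE)
  rc <- cutoff_density(D, dc)
  rg <- gaussian_density(D, dc)
  expect_gt(stats::cor(rc, rg, method = "spearman"), 0.9)
})

test_that("weighted density sums qualifying neighbour weights", {
  D <- pairwise_distances(collinear_points())
  P <- c(1, 2, 3, 4)
  expect_equal(weighted_density(D, 1.5, P), c(2, 4, 2, 0))
  expect_equal(weighted_density(D, 1.5, rep(1, 4)),
               as.numeric(cutoff_density(D, 1.5)))
  expect_equal(weighted_density(D, 1.5, 2 * P),
               2 * weighted_density(D, 1.5, P))
  expect_equal(weighted_density(D, 1.5, P, include_self = TRUE),
               c(2, 4, 2, 0) + P)
  expect_error(weighted_density(D, 1.5, c(-1, 1, 1, 1)), "non-negative")
})

test_that("delta and neighbour follow the worked collinear example", {
  D <- pairwise_distances(collinear_points())
  rho <- cutoff_density(D, 1.5)
  ds <- compute_delta(D, rho)
  expect_equal(ds$delta, c(1, 9, 1, 8))
  expect_equal(ds$neigh, c(2L, NA, 2L, 3L))
})

test_that("delta handles two-point and degenerate coincident inputs", {
  D <- matrix(c(0, 4, 4, 0), 2, 2)
  ds <- compute_delta(D, c(1, 1))       # tie: point 1 outranks point 2
  expect_equal(ds$delta, c(4, 4))
  expect_equal(ds$neigh, c(NA, 1L))
  Dz <- matrix(0, 5, 5)
  dz <- compute_delta(Dz, rep(2, 5))
  expect_equal(dz$delta, rep(0, 5))     # top point's max distance is also 0
  expect_equal(dz$neigh, c(NA, 1L, 1L, 1L, 1L))
})

test_that("gamma combines density and separation under both rules", {
  expect_equal(gamma_scores(c(1, 2), c(3, 4)), c(3, 8))
  expect_equal(gamma_scores(c(1, 2), c(3, 4), rule = "sum"), c(4, 6))
  expect_equal(gamma_scores(c(0, 5), c(9, 1))[1], 0)
})

test_that("gray entropy matches its closed forms", {
  expect_equal(gray_entropy(matrix(7, 10, 10)), 0)
  expect_equal(gray_entropy(0:255), 8)
  expect_equal(gray_entropy(rep(c(0, 255), 50)), 1)
  expect_error(gray_entropy(integer(0)), "empty")
  expect_error(gray_entropy(c(-2, 5)), "\\[0, 255\\]")
})

test_that("center selection takes the top-k scores, entropy-weighted", {
  expect_equal(select_centers(c(5, 1, 4, 2), k = 2), c(1L, 3L))
  # uniform entropy cannot change the selection
  expect_equal(select_centers(c(5, 1, 4, 2), 2, entropy = rep(3, 4)),
               select_centers(c(5, 1, 4, 2), 2))
  # non-uniform entropy can
  expect_equal(select_centers(c(5, 1, 4, 2), 2,
                              entropy = c(0.1, 8, 8, 8)), c(3L, 4L))
  expect_error(select_centers(c(1, 2), k = 3), "exceeds")
})

test_that("labels propagate along nearest higher-density neighbours", {
  D <- pairwise_distances(collinear_points())
  rho <- cutoff_density(D, 1.5)
  ds <- compute_delta(D, rho)
  expect_equal(assign_clusters(ds$neigh, rho, centers = 2L),
               rep(1L, 4))
  # n == k: every point its own cluster
  expect_equal(assign_clusters(ds$neigh, rho, centers = c(2L, 1L, 3L, 4L)),
               c(2L, 1L, 3L, 4L))
  # idempotence: re-running with the same inputs changes nothing
  l1 <- assign_clusters(ds$neigh, rho, centers = c(2L, 4L))
  l2 <- assign_clusters(ds$neigh, rho, centers = c(2L, 4L))
  expect_identical(l1, l2)
})

test_that("three well-separated Gaussians are recovered with k = 3", {
  pc <- generate_point_cloud(point_cloud_spec(n_clusters = 3,
                                              points_per_cluster = 100,
                                              cluster_sigma = 0.5,
                                              center_separation = 5,
                                              seed = 1))
  res <- dpc_cluster(pc$points, dpc_config(k = 3, density_kernel = "cutoff"))
  # one center per true component
  expect_setequal(pc$labels[res$centers], 1:3)
  expect_gte(adjusted_rand_index(res$labels, pc$labels), 0.95)
})

test_that("points unreachable at d_c are flagged as outliers", {
  pts <- rbind(matrix(stats::rnorm(40, sd = 0.5), 20, 2),
               c(50, 50))                       # >= 10 sigma away
  res <- dpc_cluster(pts, dpc_config(d_c = 0.5, k = 2,
                                     density_kernel = "cutoff"))
  expect_true(res$outlier[21])
  expect_false(all(res$outlier))
  expect_false(anyNA(res$labels))               # outliers still labeled
})

test_that("cutoff density is permutation-equivariant and monotone in d_c", {
  set.seed(4)
  X <- matrix(stats::rnorm(60 * 5), 60, 5)
  D <- pairwise_distances(X)
  perm <- sample(60)
  Dp <- pairwise_distances(X[perm, ])
  expect_equal(cutoff_density(Dp, 2), cutoff_density(D, 2)[perm],
               ignore_attr = TRUE)
  r1 <- cutoff_density(D, 1)
  r2 <- cutoff_density(D, 2)
  expect_true(all(r2 >= r1))
})

test_that("config constraints on d_c and k are enforced", {
  expect_error(dpc_config(d_c = 0), "\\(0, 10\\]")
  expect_error(dpc_config(d_c = 11), "\\(0, 10\\]")
  expect_error(dpc_config(k = 1), "2 <= k <= 30")
  expect_error(dpc_config(k = 31), "2 <= k <= 30")
  expect_silent(dpc_config(d_c = 10, k = 30))
})
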