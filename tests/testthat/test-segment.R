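test_that("pixel labels expand superpixel labels exactly", {
  img <- two_halves_raster(32, 32)
  sp <- generate_superpixels(img, superpixel_config(n_superpixels = 16))
  ident <- pixels_from_superpixels(sp, seq_len(sp$K))
  expect_identical(ident, sp$labels)
  const <- pixels_from_superpixels(sp, rep(1L, sp$K))
  expect_true(all(const == 1L))
  # label mass per cluster equals summed superpixel weights
  two <- pixels_from_superpixels(sp, 1L + (seq_len(sp$K) %% 2L))
  mass <- tabulate(two, 2)
  wmass <- tapply(sp$rho_sp, 1L + (seq_len(sp$K) %% 2L), sum)
  expect_equal(mass, as.vector(wmass), ignore_attr = TRUE)
  expect_error(pixels_from_superpixels(sp, rep(1L, sp$K + 1)), "one entry")
})

test_that("noise isolation is a fixed point on piecewise-constant images", {
  img <- two_halves_raster(24, 24)
  labels <- matrix(1L, 24, 24); labels[, 13:24] <- 2L
  out <- isolate_noise(labels, img, noise_config(threshold = 5))
  expect_identical(out, labels)
})

test_that("an isolated salt pixel is reassigned to its surrounding region", {
  px <- matrix(50, 9, 9)
  px[, 7:9] <- 250                       # a genuine bright region
  px[5, 3] <- 250                        # salt inside the dark region
  img <- image_raster(px, "gray")
  labels <- matrix(1L, 9, 9)
  labels[, 7:9] <- 2L
  labels[5, 3] <- 2L                     # mislabelled with the bright region
  out <- isolate_noise(labels, img,
                       noise_config(W = c(1, 1, 1), threshold = 60))
  expect_equal(out[5, 3], 1L)            # pulled into its spatial context
  expect_true(all(out[, 7:9] == 2L))     # the true bright region survives
  expect_true(all(out[, 1:5] == 1L))
})

test_that("noise isolation never invents labels and scales with its W", {
  set.seed(9)
  px <- matrix(pmin(pmax(round(100 + stats::rnorm(400, 0, 30)), 0), 255),
               20, 20)
  img <- image_raster(px, "gray")
  labels <- matrix(sample(1:3, 400, TRUE), 20, 20)
  out <- isolate_noise(labels, img, noise_config())
  expect_true(all(out %in% 1:3))
  # scaling W by c and the threshold by sqrt(c) leaves the decision
  # (a comparison of the weighted norm) unchanged
  W <- c(2, 3, 4); thr <- 8; cc <- 5.5
  o1 <- isolate_noise(labels, img, noise_config(W = W, threshold = thr))
  o2 <- isolate_noise(labels, img,
                      noise_config(W = cc * W, threshold = sqrt(cc) * thr))
  expect_identical(o1, o2)
})

test_that("a constant image yields a valid, deterministic degenerate split", {
  # With k forced to 2 on a flat density field, the second center and its
  # basin are fixed purely by the index tie-breaking rules: the result must
  # be total, dominated by one cluster, and bit-identical across runs.
  img <- image_raster(matrix(90, 96, 96), "gray")
  cfg <- segmentation_config(dpc = dpc_config(k = 2),
                             noise = noise_config(enabled = FALSE))
  res <- segment_image(img, cfg)
  expect_equal(res$k, 2)
  expect_true(all(res$labels %in% 1:2))
  expect_gte(max(tabulate(res$labels, 2)) / (96 * 96), 0.5)
  expect_identical(segment_image(img, cfg)$labels, res$labels)
})

test_that("two homogeneous halves are segmented at pixel accuracy", {
  img <- two_halves_raster(64, 64)
  truth <- matrix(1L, 64, 64); truth[, 33:64] <- 2L
  cfg <- segmentation_config(
    superpixel = superpixel_config(n_superpixels = 16, m = 1),
    dpc = dpc_config(k = 2))
  res <- segment_image(img, cfg)
  agree <- max(mean(res$labels == truth), mean(res$labels == 3L - truth))
  expect_gte(agree, 0.99)
})

test_that("segment_image is deterministic for a fixed config", {
  ph <- generate_phantom(phantom_spec(size = 128, n_features = 4, seed = 5))
  r1 <- segment_image(ph$image)
  r2 <- segment_image(ph$image)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$manifest, r2$manifest)
})

test_that("every phantom blob separates from the background label", {
  ph <- generate_phantom(phantom_spec(seed = 42))
  res <- segment_image(ph$image)
  bg_dom <- function(mask) {
    tab <- tabulate(res$labels[mask], res$k)
    which.max(tab)
  }
  bg_label <- bg_dom(ph$truth == 0)
  for (f in seq_len(10)) {
    expect_false(bg_dom(ph$truth == f) == bg_label,
                 label = sprintf("blob %d separates from background", f))
  }
})

test_that("noise isolation does not multiply isolated single-pixel islands", {
  ph <- generate_phantom(phantom_spec(size = 128, n_features = 4, seed = 3))
  cfg_off <- segmentation_config(noise = noise_config(enabled = FALSE))
  res_off <- segment_image(ph$image, cfg_off)
  res_on <- segment_image(ph$image)
  islands <- function(labels) {
    n <- 0L
    for (lab in unique(as.vector(labels))) {
      cc <- EBImage::bwlabel((labels == lab) + 0L)
      n <- n + sum(tabulate(as.vector(cc)) == 1L)
    }
    n
  }
  expect_lte(islands(res_on$labels), islands(res_off$labels))
})

test_that("the manifest records the resolved parameters", {
  ph <- generate_phantom(phantom_spec(size = 128, n_features = 4, seed = 1))
  res <- segment_image(ph$image)
  m <- res$manifest
  expect_equal(m$superpixel$K, res$superpixels$K)
  expect_equal(m$dpc$k, res$k)
  expect_gt(m$dpc$d_c, 0)
  expect_lte(m$dpc$d_c, 10)
  expect_length(m$entropy_per_center, res$k)
})
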