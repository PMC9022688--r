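## Tensor fitting, FA, probabilistic tracking, connectome construction,
## voxel-wise FA comparison.

test_that("FA matches closed forms and is scale invariant", {
  expect_equal(fractional_anisotropy(1, 1, 1), 0)
  expect_equal(fractional_anisotropy(1, 0, 0), 1)
  expect_equal(fractional_anisotropy(2, 1, 1), sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(fractional_anisotropy(0, 0, 0), 0)
  set.seed(4)
  l <- matrix(runif(30, 0.1, 3), 10, 3)
  expect_equal(fractional_anisotropy(l[, 1], l[, 2], l[, 3]),
               fractional_anisotropy(5 * l[, 1], 5 * l[, 2], 5 * l[, 3]),
               tolerance = 1e-12)
  expect_error(fractional_anisotropy(-1, 1, 1), "nonnegative")
})

test_that("noiseless tensor fitting reproduces the ground-truth field", {
  sim <- simulate_dwi(default_dwi_spec(seed = 5, noise_sigma = 0))
  tf <- fit_tensor(sim$dwi)
  expect_lt(max(abs(tf$d6 - sim$tensors$d6), na.rm = TRUE), 1e-6)
  expect_equal(tf$n_clamped, 0L)
  ## background is isotropic: near-equal eigenvalues, FA ~ 0
  bg <- which(!sim$truth$bundle_masks[[1]])
  expect_lt(max(tf$fa[bg]), 1e-6)
  expect_equal(tf$evals[bg[1], ], rep(7e-4, 3), tolerance = 1e-9)
  ## eigenvalues sorted descending, e1 unit norm
  expect_true(all(tf$evals[, 1] >= tf$evals[, 2] &
                    tf$evals[, 2] >= tf$evals[, 3]))
  expect_equal(unname(rowSums(tf$e1^2)), rep(1, nrow(tf$e1)), tolerance = 1e-9)
})

test_that("under-determined or degenerate acquisitions are rejected", {
  sim <- simulate_dwi(default_dwi_spec(seed = 5))
  b0only <- sim$dwi
  keep <- b0only$b_values == 0
  b0only$data <- b0only$data[, , , keep, drop = FALSE]
  b0only$b_values <- b0only$b_values[keep]
  b0only$b_vectors <- b0only$b_vectors[keep, , drop = FALSE]
  expect_error(fit_tensor(b0only), "6 diffusion-weighted")
  few <- sim$dwi
  keep <- c(1, 2, 3, 4, 5)
  few$data <- few$data[, , , keep, drop = FALSE]
  few$b_values <- few$b_values[keep]
  few$b_vectors <- few$b_vectors[keep, , drop = FALSE]
  expect_error(fit_tensor(few), "6 diffusion-weighted")
})

test_that("nonpositive samples are dropped per voxel; too few means invalid", {
  sim <- simulate_dwi(default_dwi_spec(seed = 6, noise_sigma = 0))
  dwi <- sim$dwi
  ## corrupt one measurement at one voxel: still 13 usable, voxel stays valid
  dwi$data[5, 5, 5, 3] <- 0
  tf <- fit_tensor(dwi)
  expect_true(tf$valid[5, 5, 5])
  li <- 5 + 20 * (4 + 12 * 4)
  expect_lt(max(abs(tf$d6[li, ] - sim$tensors$d6[li, ])), 1e-6)
  ## corrupt 9 of 14: fewer than 7 usable, voxel marked invalid
  dwi$data[6, 6, 5, 1:9] <- 0
  tf2 <- fit_tensor(dwi)
  expect_false(tf2$valid[6, 6, 5])
})

test_that("straight-bundle streamlines connect end regions and are reproducible", {
  sim <- simulate_dwi(default_dwi_spec(seed = 7, noise_sigma = 0))
  tf <- fit_tensor(sim$dwi)
  seed_mask <- (sim$truth$endpoint_labels == 1L) & sim$truth$bundle_masks[[1]]
  sl <- track_probabilistic(tf, seed_mask,
                            params = list(dispersion_kappa = 1000,
                                          n_samples_per_seed = 5L),
                            seed = 21)
  cn <- build_connectome(sl, sim$truth$endpoint_labels)
  expect_gte(cn$counts[1, 2] / length(sl$streamlines), 0.95)
  expect_equal(cn$weights, log1p(cn$counts))
  expect_equal(cn$counts, t(cn$counts))
  expect_equal(diag(cn$counts), rep(0L, nrow(cn$counts)))
  ## determinism
  sl2 <- track_probabilistic(tf, seed_mask,
                             params = list(dispersion_kappa = 1000,
                                           n_samples_per_seed = 5L),
                             seed = 21)
  expect_identical(sl$streamlines, sl2$streamlines)
  expect_identical(sl$termination, sl2$termination)
})

test_that("tracking respects the angle limit along every streamline", {
  sim <- simulate_dwi(default_dwi_spec(seed = 8, geometry = "arc"))
  tf <- fit_tensor(sim$dwi)
  seed_mask <- (sim$truth$endpoint_labels == 1L) & sim$truth$bundle_masks[[1]]
  params <- list(dispersion_kappa = 200, n_samples_per_seed = 3L,
                 angle_limit_deg = 60)
  sl <- track_probabilistic(tf, seed_mask, params, seed = 9)
  worst <- 0
  for (pts in sl$streamlines) {
    if (nrow(pts) < 3) next
    segs <- diff(pts)
    segs <- segs / sqrt(rowSums(segs^2))
    cosang <- rowSums(segs[-nrow(segs), , drop = FALSE] *
                        segs[-1, , drop = FALSE])
    worst <- max(worst, max(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi)
  }
  expect_lte(worst, params$angle_limit_deg + 1e-6)
})

test_that("seeds in low-FA background stop immediately with the right reason", {
  sim <- simulate_dwi(default_dwi_spec(seed = 7, noise_sigma = 0))
  tf <- fit_tensor(sim$dwi)
  seed_mask <- array(FALSE, dim(tf$fa)); seed_mask[2, 2, 2] <- TRUE
  sl <- track_probabilistic(tf, seed_mask,
                            params = list(n_samples_per_seed = 3L), seed = 1)
  expect_true(all(vapply(sl$streamlines, nrow, integer(1)) == 1L))
  expect_true(all(sl$termination == "low-fa"))
  expect_error(track_probabilistic(tf, array(FALSE, dim(tf$fa))), "empty")
})

test_that("curved bundles connect far better than background ever does", {
  sim_arc <- simulate_dwi(default_dwi_spec(seed = 10, geometry = "arc"))
  tf_arc <- fit_tensor(sim_arc$dwi)
  seed_arc <- (sim_arc$truth$endpoint_labels == 1L) & sim_arc$truth$bundle_masks[[1]]
  sl_arc <- track_probabilistic(tf_arc, seed_arc,
                                params = list(dispersion_kappa = 1000,
                                              n_samples_per_seed = 5L),
                                seed = 2)
  cn_arc <- build_connectome(sl_arc, sim_arc$truth$endpoint_labels)
  rate_arc <- cn_arc$counts[1, 2] / length(sl_arc$streamlines)
  ## background seeding on the straight phantom: false-connection rate
  sim_st <- simulate_dwi(default_dwi_spec(seed = 10))
  tf_st <- fit_tensor(sim_st$dwi)
  bg_mask <- array(FALSE, dim(tf_st$fa)); bg_mask[2:3, 10:11, 6:7] <- TRUE
  sl_bg <- track_probabilistic(tf_st, bg_mask,
                               params = list(dispersion_kappa = 1000,
                                             n_samples_per_seed = 5L),
                               seed = 2)
  cn_bg <- build_connectome(sl_bg, sim_st$truth$endpoint_labels)
  rate_bg <- cn_bg$counts[1, 2] / length(sl_bg$streamlines)
  expect_gte(rate_arc, 10 * rate_bg)
  expect_gte(rate_arc, 0.5)
})

test_that("connectome handles empty input and large parcellations", {
  empty <- structure(list(streamlines = list(), seed_voxel = NULL,
                          termination = matrix(character(0), 0, 2),
                          params = list()),
                     class = "streamline_set")
  lab <- make_parcellation(c(20, 20, 20), 681, seed = 3)
  cn <- build_connectome(empty, lab)
  expect_equal(dim(cn$counts), c(681L, 681L))
  expect_true(all(cn$counts == 0L))
  expect_equal(cn$weights, matrix(0, 681, 681))
})

test_that("voxel-wise FA comparison detects a planted bundle reduction", {
  make_group <- function(lp, stream) lapply(1:4, function(i)
    fit_tensor(simulate_dwi(default_dwi_spec(
      seed = substream_seed(77, i, stream), noise_sigma = 20,
      lambda_perp = lp))$dwi)$fa)
  fa_a <- make_group(0.3e-3, 1)
  fa_b <- make_group(0.5e-3, 2)
  bm <- simulate_dwi(default_dwi_spec(seed = 1))$truth$bundle_masks[[1]]
  res <- voxelwise_fa_compare(fa_a, fa_b, mask = array(TRUE, dim(bm)))
  expect_gte(mean(res$rejected[bm]), 0.8)
  expect_lte(mean(res$rejected[!bm]), 0.02)
  ## sham-side FA is higher inside the bundle
  expect_gt(mean(res$t[bm]), 0)
  ## identical groups: all-zero t map; single-subject group errors
  res0 <- voxelwise_fa_compare(fa_a, fa_a, mask = array(TRUE, dim(bm)))
  expect_equal(max(abs(res0$t)), 0)
  expect_equal(sum(res0$rejected), 0L)
  expect_error(voxelwise_fa_compare(fa_a[1], fa_b), "at least 2")
})
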