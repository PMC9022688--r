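## Phantom generators: parcellation, functional time-course structure,
## cohort contrasts, diffusion signal model.

test_that("make_parcellation partitions the mask into connected labeled regions", {
  lab <- make_parcellation(c(8, 8, 8), 2, seed = 4)
  mask <- brain_mask(c(8, 8, 8))
  expect_setequal(unique(as.vector(lab[mask])), c(1L, 2L))
  expect_true(all(lab[!mask] == 0L))
  expect_true(all(table(lab[lab > 0]) >= 1))
  ## connectedness: flood fill from one voxel of each region covers it
  for (rg in 1:2) {
    vox <- which(lab == rg)
    comp <- vox[1]; frontier <- vox[1]
    d <- dim(lab)
    while (length(frontier)) {
      ijk <- arrayInd(frontier, d)
      nbr <- do.call(rbind, lapply(seq_len(nrow(ijk)), function(r) {
        t(ijk[r, ] + t(rbind(c(1,0,0), c(-1,0,0), c(0,1,0),
                             c(0,-1,0), c(0,0,1), c(0,0,-1))))
      }))
      keep <- nbr[, 1] >= 1 & nbr[, 1] <= d[1] & nbr[, 2] >= 1 &
        nbr[, 2] <= d[2] & nbr[, 3] >= 1 & nbr[, 3] <= d[3]
      lin <- unique(nbr[keep, 1] + d[1] * (nbr[keep, 2] - 1 +
                                             d[2] * (nbr[keep, 3] - 1)))
      frontier <- setdiff(intersect(lin, vox), comp)
      comp <- union(comp, frontier)
    }
    expect_setequal(comp, vox)
  }
})

test_that("a 681-region parcellation has all 681 labels and is deterministic", {
  lab1 <- make_parcellation(c(20, 20, 20), 681, seed = 11)
  lab2 <- make_parcellation(c(20, 20, 20), 681, seed = 11)
  expect_identical(unclass(lab1), unclass(lab2))
  expect_length(unique(as.vector(lab1[lab1 > 0])), 681L)
  expect_error(make_parcellation(c(4, 4, 4), 10000, seed = 1), "exceeds")
  expect_error(make_parcellation(c(8, 8, 8), 1, seed = 1), ">= 2")
})

test_that("degenerate loading w = 1 makes same-cluster time courses identical", {
  spec <- tiny_rsn_spec(w = 1)
  tc <- simulate_timecourses(spec)$timecourses
  expect_equal(cor(tc[, 1], tc[, 2]), 1, tolerance = 1e-12)
})

test_that("within- and between-cluster correlations are calibrated to the spec", {
  ## 4 clusters x 3 components, w = 0.6, uncorrelated factors, T = 300;
  ## Monte-Carlo average over 20 seeds
  spec0 <- default_rsn_spec(inter_cluster_corr = NULL)
  win <- btw <- numeric(20)
  for (s in 1:20) {
    tcl <- simulate_timecourses(spec0, seed = 1000 + s)
    r <- cor(tcl$timecourses[, !tcl$is_noise])
    same <- outer(tcl$cluster, tcl$cluster, `==`) & upper.tri(r)
    diff <- outer(tcl$cluster, tcl$cluster, `!=`) & upper.tri(r)
    win[s] <- mean(r[same]); btw[s] <- mean(r[diff])
  }
  expect_equal(mean(win), 0.6, tolerance = 0.05)
  expect_lt(abs(mean(btw)), 0.1)
})

test_that("correlation calibration tightens with series length", {
  spec <- default_rsn_spec(seed = 21, n_timepoints = 2000L,
                           inter_cluster_corr = NULL)
  tcl <- simulate_timecourses(spec)
  r <- cor(tcl$timecourses[, !tcl$is_noise])
  same <- outer(tcl$cluster, tcl$cluster, `==`) & upper.tri(r)
  expect_equal(mean(r[same]), 0.6, tolerance = 0.03)
})

test_that("anticorrelated cluster factors yield negative between-cluster correlation", {
  neg <- vapply(1:5, function(s) {
    tcl <- simulate_timecourses(tiny_rsn_spec(seed = s, rho = -0.5,
                                              n_timepoints = 300L))
    r <- cor(tcl$timecourses)
    mean(r[tcl$cluster == 1, tcl$cluster == 2])
  }, numeric(1))
  expect_true(all(neg < 0))
})

test_that("a non-positive-definite factor covariance is rejected", {
  comps <- list(component_spec(c(5, 5, 5), 1.5, cluster = 1),
                component_spec(c(11, 5, 5), 1.5, cluster = 2),
                component_spec(c(5, 11, 5), 1.5, cluster = 3))
  icc <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), rho = c(-0.9, -0.9, -0.9))
  spec <- functional_phantom_spec(c(16, 16, 10), 50, 1, comps, 0.5,
                                  inter_cluster_corr = icc)
  expect_error(simulate_timecourses(spec), "positive definite")
})

test_that("phantom realizations are bit-identical under a fixed seed", {
  spec <- tiny_rsn_spec(seed = 5, n_noise_components = 2L)
  a <- simulate_rsfmri(spec); b <- simulate_rsfmri(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$timecourses, b$truth$timecourses)
})

test_that("cohort simulation respects group parameters and degenerate cases", {
  spec_a <- tiny_rsn_spec(w = 0.7)
  expect_length(simulate_cohort(spec_a, spec_a, 0, seed = 1)$images, 0L)
  ## mismatched geometry errors
  spec_bad <- tiny_rsn_spec(w = 0.7)
  spec_bad$components[[1]]$center <- c(6, 5, 5)
  expect_error(simulate_cohort(spec_a, spec_bad, 2, seed = 1), "geometry")
  ## planted loading reduction lowers within-cluster-1 correlation (5 seeds)
  spec_b <- tiny_rsn_spec(w = c(`1` = 0.3, `2` = 0.7))
  lower <- vapply(1:5, function(s) {
    co <- simulate_cohort(spec_a, spec_b, 3, seed = 100 + s)
    r1 <- vapply(which(co$group == "sham"), function(i)
      cor(co$truth$subject_timecourses[[i]])[1, 2], numeric(1))
    r2 <- vapply(which(co$group == "hypo"), function(i)
      cor(co$truth$subject_timecourses[[i]])[1, 2], numeric(1))
    mean(r2) < mean(r1)
  }, logical(1))
  expect_gte(sum(lower), 4L)
})

test_that("diffusion signal follows the closed-form tensor model", {
  spec <- default_dwi_spec(seed = 2, noise_sigma = 0)
  sim <- simulate_dwi(spec)
  ## isotropic background voxel: S = S0 exp(-b d_bg) for any direction
  bg <- which(!sim$truth$bundle_masks[[1]])[1]
  ijk <- arrayInd(bg, spec$grid_shape)
  svals <- sim$dwi$data[ijk[1], ijk[2], ijk[3], ]
  expect_equal(svals[spec$b_values == 0], rep(spec$s0, 2))
  expect_equal(svals[spec$b_values > 0],
               rep(spec$s0 * exp(-1000 * spec$background_diffusivity), 12),
               tolerance = 1e-12)
  ## bundle voxel: signal along the fiber attenuates more than across it
  gx <- rbind(c(1, 0, 0), c(0, 1, 0))
  spec2 <- diffusion_phantom_spec(spec$grid_shape, spec$bundles,
                                  b_values = c(0, 1000, 1000),
                                  b_vectors = rbind(c(0, 0, 0), gx),
                                  noise_sigma = 0)
  sim2 <- simulate_dwi(spec2)
  core <- which(sim2$truth$bundle_masks[[1]])[10]
  ijk <- arrayInd(core, spec$grid_shape)
  s <- sim2$dwi$data[ijk[1], ijk[2], ijk[3], ]
  expect_lt(s[2], s[3])    # x-gradient attenuates the x-oriented bundle more
})

test_that("Rician noise is reproducible and absent at sigma = 0", {
  spec <- default_dwi_spec(seed = 9, noise_sigma = 30)
  a <- simulate_dwi(spec); b <- simulate_dwi(spec)
  expect_identical(a$dwi$data, b$dwi$data)
  expect_true(all(a$dwi$data > 0))     # magnitude signal
  clean <- simulate_dwi(default_dwi_spec(seed = 9, noise_sigma = 0))
  expect_false(identical(a$dwi$data, clean$dwi$data))
})
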