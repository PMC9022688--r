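## Component correlations, Fisher z, hierarchical clustering into networks,
## edge-wise group comparison, seed-based maps.

test_that("component correlation handles identities, sign flips and errors", {
  set.seed(1)
  x <- rnorm(50)
  tc <- cbind(a = x, b = x, c = -x)
  r <- component_correlation(tc)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  tc2 <- cbind(a = x, flat = rep(2, 50))
  expect_error(component_correlation(tc2), "flat")
  expect_error(component_correlation(tc[1:2, ]), "3 timepoints")
})

test_that("phantom within-cluster correlation matches the planted loading", {
  spec <- default_rsn_spec(seed = 31, n_timepoints = 2000L,
                           inter_cluster_corr = NULL)
  tcl <- simulate_timecourses(spec)
  r <- component_correlation(tcl$timecourses[, !tcl$is_noise])
  same <- outer(tcl$cluster, tcl$cluster, `==`) & upper.tri(r)
  expect_equal(mean(r[same]), 0.6, tolerance = 0.05)
})

test_that("fisher z matches the closed form and is odd and invertible", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2, tolerance = 1e-12)
  rr <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-rr), -fisher_z(rr), tolerance = 1e-12)
  expect_equal(tanh(fisher_z(rr)), rr, tolerance = 1e-12)
  expect_error(fisher_z(1.2), "not a correlation")
  expect_warning(z <- fisher_z(c(0.3, 1 - 1e-9)), "clipped")
  expect_true(is.finite(z[2]))
  ## matrix input keeps a zero diagonal without clipping warnings
  m <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_silent(zm <- fisher_z(m))
  expect_equal(diag(zm), c(0, 0))
})

test_that("clustering recovers an exact two-block correlation structure", {
  n <- 6
  blocks <- rep(1:2, each = 3)
  r <- matrix(-0.2, n, n)
  r[blocks == 1, blocks == 1] <- 0.8
  r[blocks == 2, blocks == 2] <- 0.8
  diag(r) <- 1
  z <- fisher_z(r)
  ca <- cluster_components(z, 2)
  ## brute-force best 2-partition: maximize mean within minus mean between r
  best <- NULL; best_score <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {
    part <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    same <- outer(part, part, `==`) & upper.tri(r)
    diffm <- outer(part, part, `!=`) & upper.tri(r)
    if (!any(same) || !any(diffm)) next
    score <- mean(r[same]) - mean(r[diffm])
    if (score > best_score) { best_score <- score; best <- part }
  }
  expect_equal(ari(ca$labels, best), 1)
  expect_equal(ari(ca$labels, blocks), 1)
})

test_that("cluster ids are ordered by size then smallest member, and k is validated", {
  set.seed(7)
  tc <- matrix(rnorm(200 * 5), 200, 5)
  z <- fisher_z(cor(tc)); diag(z) <- 0
  expect_equal(cluster_components(z, 1)$labels, rep(1L, 5))
  expect_error(cluster_components(z, 6), "exceeds")
  ## 2+3 block: the size-3 block must be cluster 1
  r <- matrix(0, 5, 5); diag(r) <- 1
  r[1:2, 1:2] <- 0.9; r[3:5, 3:5] <- 0.9; diag(r) <- 1
  ca <- cluster_components(fisher_z(r), 2)
  expect_equal(ca$labels, c(2L, 2L, 1L, 1L, 1L))
})

test_that("clustering is equivariant under component permutation", {
  spec <- default_rsn_spec(seed = 13)
  tcl <- simulate_timecourses(spec)
  z <- fisher_z(component_correlation(tcl$timecourses[, !tcl$is_noise]))
  diag(z) <- 0
  ca <- cluster_components(z, 4)
  set.seed(2)
  perm <- sample(ncol(z))
  ca_p <- cluster_components(z[perm, perm], 4)
  expect_equal(ari(ca_p$labels, ca$labels[perm]), 1)
})

test_that("planted 4-network structure is recovered from true time courses", {
  ok <- vapply(1:10, function(s) {
    spec <- default_rsn_spec(seed = 400 + s)
    tcl <- simulate_timecourses(spec)
    z <- fisher_z(component_correlation(tcl$timecourses[, !tcl$is_noise]))
    diag(z) <- 0
    ari(cluster_components(z, 4)$labels, tcl$cluster)
  }, numeric(1))
  expect_gte(sum(ok >= 0.9), 9L)
})

test_that("identical groups produce a null difference matrix with no rejections", {
  spec <- default_rsn_spec(seed = 51)
  zs <- lapply(1:3, function(i)
    fisher_z(cor(simulate_timecourses(spec, seed = i)$timecourses[, 1:12])))
  zdup <- c(zs, zs)
  ec <- group_difference_matrix(zdup, rep(c("a", "b"), each = 3))
  expect_equal(max(abs(ec$delta)), 0)
  expect_equal(sum(ec$rejected), 0L)
  expect_error(group_difference_matrix(zdup[1:3], c("a", "a", "b")),
               "at least 2")
})

test_that("a single planted edge difference is localized at small alpha", {
  n <- 6
  base <- matrix(0, n, n)
  za <- lapply(1:4, function(i) { m <- base; m[1, 2] <- m[2, 1] <- 0.8; m })
  zb <- lapply(1:4, function(i) base)
  ec <- group_difference_matrix(c(za, zb), rep(c("a", "b"), each = 4),
                                alpha = 0.01)
  rej <- which(ec$rejected & upper.tri(ec$rejected), arr.ind = TRUE)
  expect_equal(unname(rej), matrix(c(1L, 2L), 1))
  expect_equal(ec$delta[1, 2], 0.8)
})

test_that("group comparison has power on affected edges and controls null edges", {
  spec_a <- default_rsn_spec()
  spec_b <- default_rsn_spec(cluster_loading = c(`1` = 0.3, `2` = 0.6,
                                                 `3` = 0.6, `4` = 0.6))
  cl <- rep(1:4, each = 3)
  pow <- fpr <- numeric(5)
  for (rep_i in 1:5) {
    zl <- list(); grp <- character(0)
    for (i in 1:10) {
      zl[[i]] <- fisher_z(cor(simulate_timecourses(
        spec_a, substream_seed(600 + rep_i, i, 1))$timecourses[, 1:12]))
      zl[[10 + i]] <- fisher_z(cor(simulate_timecourses(
        spec_b, substream_seed(600 + rep_i, i, 2))$timecourses[, 1:12]))
      grp <- c(grp, "sham");
    }
    grp <- rep(c("sham", "hypo"), each = 10)
    ec <- group_difference_matrix(zl, factor(grp, c("sham", "hypo")), 0.05)
    aff <- outer(cl, cl, function(a, b) a == 1 & b == 1) & upper.tri(ec$p)
    nul <- outer(cl, cl, function(a, b) a != 1 & b != 1) & upper.tri(ec$p)
    pow[rep_i] <- mean(ec$rejected[aff])
    fpr[rep_i] <- mean(ec$rejected[nul])
  }
  expect_gte(mean(pow), 0.8)
  expect_lte(mean(fpr), 0.05)
  ## the sign of the difference is as planted (sham stronger)
  expect_gt(mean(ec$delta[aff]), 0)
})

test_that("Mann-Whitney variant runs and agrees directionally with Welch", {
  set.seed(3)
  za <- lapply(1:6, function(i) { m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.6 + rnorm(1, 0, 0.05); m })
  zb <- lapply(1:6, function(i) { m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.1 + rnorm(1, 0, 0.05); m })
  grp <- rep(c("a", "b"), each = 6)
  ec_t <- group_difference_matrix(c(za, zb), grp, 0.05, method = "t")
  ec_u <- group_difference_matrix(c(za, zb), grp, 0.05, method = "mwu")
  expect_true(ec_t$rejected[1, 2] && ec_u$rejected[1, 2])
})

test_that("seed maps order same-cluster above off-cluster components", {
  wins <- vapply(1:5, function(s) {
    spec <- default_rsn_spec(seed = 700 + s)
    sim <- simulate_rsfmri(spec)
    mvec <- sim$truth$maps[1, ]
    seed_mask <- array(mvec > 0.5 * max(mvec), dim(sim$truth$mask))
    zm <- seed_correlation_map(sim$image, seed_mask, sim$truth$mask)
    mean_on <- function(k) {
      m <- sim$truth$maps[k, ]
      mean(zm[array(m > 0.5 * max(m), dim(sim$truth$mask))])
    }
    same <- mean(vapply(2:3, mean_on, numeric(1)))
    off <- mean(vapply(4:12, mean_on, numeric(1)))
    c(same = same, off = off)
  }, numeric(2))
  expect_true(all(wins["same", ] > wins["off", ]))
  ## the seed region itself is strongly positive
  spec <- default_rsn_spec(seed = 701)
  sim <- simulate_rsfmri(spec)
  mvec <- sim$truth$maps[1, ]
  seed_mask <- array(mvec > 0.5 * max(mvec), dim(sim$truth$mask))
  zm <- seed_correlation_map(sim$image, seed_mask, sim$truth$mask)
  expect_gt(mean(zm[seed_mask]), fisher_z(0.5))
})

test_that("an all-noise image yields a flat seed map", {
  d <- c(16, 16, 10)
  mask <- brain_mask(d)
  set.seed(5)
  img <- image4d(array(rnorm(prod(d) * 300), c(d, 300)))
  seed_mask <- array(FALSE, d); seed_mask[8:9, 8:9, 5] <- TRUE
  zm <- seed_correlation_map(img, seed_mask, mask)
  frac <- mean(abs(zm[mask]) > atanh(0.3))
  expect_lte(frac, 0.01)
  expect_error(seed_correlation_map(img, array(FALSE, d), mask), "empty")
})
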