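## Functional phantom generator: parcellations, component maps, cluster-
## structured time courses and multi-subject BOLD-like 4D series.

#' Construct a 4D functional image object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix; default unit voxels.
#' @param tr repetition time in seconds.
#' @return An object of class \code{image4d}.
#' @export
image4d <- function(data, affine = diag(4), tr = 1) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)), tr > 0)
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "image4d")
}

#' @export
print.image4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image4d> %d x %d x %d voxels, %d timepoints, TR = %gs\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Random connected parcellation of the phantom brain
#'
#' Partitions the in-mask voxels into \code{n_regions} connected regions by
#' seeded multi-source region growing (6-connectivity): region seeds are
#' drawn at random, then labels are propagated one dilation at a time, in a
#' seeded random direction order, until every mask voxel is labeled.
#'
#' @param grid_shape 3 positive integers.
#' @param n_regions number of regions (>= 2).
#' @param seed integer seed.
#' @param mask optional logical 3D array; default \code{\link{brain_mask}}.
#' @return An integer 3D array of class \code{label_volume}: labels
#'   \code{1..n_regions}, 0 = background. Every label occupies at least one
#'   voxel and each region is a connected voxel set.
#' @export
make_parcellation <- function(grid_shape, n_regions, seed = 1L, mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (n_regions < 2L) stopf("n_regions must be >= 2")
  mask <- mask %||% brain_mask(grid_shape)
  idx_mask <- which(mask)
  if (n_regions > length(idx_mask))
    stopf("n_regions (%d) exceeds the number of mask voxels (%d)",
          n_regions, length(idx_mask))
  d <- grid_shape
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  labels <- array(0L, d)
  with_seed(seed, {
    seeds <- sample(idx_mask, n_regions)
    labels[seeds] <- seq_len(n_regions)
    repeat {
      grew <- FALSE
      for (s in sample(shifts)) {      # randomized order reduces shape bias
        src <- shift_labels(labels, s, d)
        take <- labels == 0L & mask & src > 0L
        if (any(take)) {
          labels[take] <- src[take]
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  })
  if (any(labels[mask] == 0L))   # isolated mask voxels cannot occur with 6-conn growth
    stopf("internal error: unlabeled mask voxels remain")
  structure(labels, class = c("label_volume", "array"), affine = diag(4))
}

## shift a label array by an integer offset, zero-filling
shift_labels <- function(labels, s, d) {
  out <- array(0L, d)
  src_x <- seq_len(d[1]) - s[1]; src_y <- seq_len(d[2]) - s[2]
  src_z <- seq_len(d[3]) - s[3]
  ok_x <- src_x >= 1 & src_x <= d[1]; ok_y <- src_y >= 1 & src_y <= d[2]
  ok_z <- src_z >= 1 & src_z <= d[3]
  out[ok_x, ok_y, ok_z] <- labels[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
  out
}

## Gaussian-profile sphere map (sd = radius/2, truncated at 2*radius),
## restricted to the mask, as a full-grid 3D array.
component_map <- function(center, radius, amplitude, grid_shape, mask) {
  ctr <- voxel_centers(grid_shape)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  sd2 <- (radius / 2)^2
  m <- amplitude * exp(-d2 / (2 * sd2))
  m[d2 > (2 * radius)^2] <- 0
  m[!as.vector(mask)] <- 0
  array(m, grid_shape)
}

## temporal Gaussian smoothing of the columns of a matrix, then
## standardization to zero mean / unit sd; sd_tr = 0 leaves columns white.
smooth_standardize <- function(x, sd_tr) {
  if (sd_tr > 0) {
    half <- ceiling(3 * sd_tr)
    k <- stats::dnorm(seq(-half, half), sd = sd_tr)
    k <- k / sum(k)
    x <- apply(x, 2, function(col) {
      padded <- c(rev(col[seq_len(half)]), col, rev(col[length(col) - seq_len(half) + 1]))
      stats::filter(padded, k, sides = 2)[(half + 1):(half + length(col))]
    })
  }
  scale(x)[, , drop = FALSE]
}

#' Generate the ground-truth component time courses of a functional phantom
#'
#' Latent cluster factors are built by mixing i.i.d. standard normal series
#' with the Cholesky factor of the target factor covariance, so the requested
#' inter-cluster correlations hold in expectation. Each signal component's
#' time course is \code{sign * (sqrt(w) f_c + sqrt(1-w) eta)}; noise
#' components get temporally white time courses. Signal series are low-pass
#' smoothed (see \code{tc_smooth_sd}) before standardization, which leaves
#' all correlations unchanged.
#'
#' @param spec a \code{\link{functional_phantom_spec}}.
#' @param seed integer seed; defaults to \code{spec$seed}.
#' @return A list with \code{timecourses} (T x n_components, signal
#'   components first), \code{factors} (T x n_clusters),
#'   \code{cluster} (per signal component), \code{is_noise} (per column).
#' @export
simulate_timecourses <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "functional_phantom_spec"))
  k <- length(spec$components)
  ncl <- length(spec$clusters)
  tt <- spec$n_timepoints
  C <- diag(ncl)
  dimnames(C) <- list(spec$clusters, spec$clusters)
  if (!is.null(spec$inter_cluster_corr)) {
    for (i in seq_len(nrow(spec$inter_cluster_corr))) {
      a <- as.character(spec$inter_cluster_corr$a[i])
      b <- as.character(spec$inter_cluster_corr$b[i])
      C[a, b] <- C[b, a] <- spec$inter_cluster_corr$rho[i]
    }
  }
  L <- tryCatch(chol(C), error = function(e)
    stopf("requested factor covariance is not positive definite"))
  cl_of <- vapply(spec$components, `[[`, integer(1), "cluster")
  cl_idx <- match(cl_of, spec$clusters)
  w <- spec$cluster_loading[as.character(cl_of)]
  sgn <- vapply(spec$components, `[[`, numeric(1), "sign")
  with_seed(seed, {
    f_raw <- matrix(stats::rnorm(tt * ncl), tt, ncl)
    eta <- matrix(stats::rnorm(tt * k), tt, k)
    noise_tc <- if (spec$n_noise_components > 0)
      matrix(stats::rnorm(tt * spec$n_noise_components), tt,
             spec$n_noise_components) else NULL
    f <- smooth_standardize(f_raw, spec$tc_smooth_sd) %*% L
    eta <- smooth_standardize(eta, spec$tc_smooth_sd)
    tc <- sweep(f[, cl_idx, drop = FALSE], 2, sqrt(w), `*`) +
      sweep(eta, 2, sqrt(1 - w), `*`)
    tc <- sweep(tc, 2, sgn, `*`)
    all_tc <- cbind(tc, noise_tc)
    colnames(all_tc) <- c(sprintf("comp%02d", seq_len(k)),
                          if (spec$n_noise_components > 0)
                            sprintf("noise%02d", seq_len(spec$n_noise_components)))
    list(timecourses = all_tc, factors = f, cluster = cl_of,
         is_noise = c(rep(FALSE, k), rep(TRUE, spec$n_noise_components)))
  })
}

#' Simulate one subject's resting-state functional phantom
#'
#' Voxel signal is \code{sum_k map_k(v) tc_k(t) + eps(v,t)} with
#' \code{eps ~ N(0, noise_sigma^2)}. Signal maps are Gaussian spheres inside
#' the brain mask; noise-component maps are small blobs restricted to the
#' outermost mask shell.
#'
#' @param spec a \code{\link{functional_phantom_spec}}.
#' @param seed integer seed; defaults to \code{spec$seed}.
#' @return A list with \code{image} (an \code{\link{image4d}}) and
#'   \code{truth} (maps as an n_components x n_voxel matrix over the full
#'   grid, time courses, cluster assignment, noise flags, mask).
#' @export
simulate_rsfmri <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "functional_phantom_spec"))
  mask <- brain_mask(spec$grid_shape)
  nv <- prod(spec$grid_shape)
  k <- length(spec$components)
  maps <- matrix(0, k + spec$n_noise_components, nv)
  for (i in seq_len(k)) {
    cs <- spec$components[[i]]
    maps[i, ] <- as.vector(component_map(cs$center, cs$radius, cs$amplitude,
                                         spec$grid_shape, mask))
  }
  tcres <- simulate_timecourses(spec, seed)
  img <- with_seed(substream_seed(seed, 1L, 9L), {
    if (spec$n_noise_components > 0) {
      edge <- mask_edge(mask)
      edge_idx <- which(edge)
      for (j in seq_len(spec$n_noise_components)) {
        ctr_idx <- sample(edge_idx, 1)
        ctr <- arrayInd(ctr_idx, spec$grid_shape)
        m <- component_map(as.numeric(ctr), radius = 2, amplitude = 1,
                           spec$grid_shape, edge)
        maps[k + j, ] <- as.vector(m)
      }
    }
    y <- tcres$timecourses %*% maps            # T x V
    if (spec$noise_sigma > 0)
      y <- y + matrix(stats::rnorm(length(y), sd = spec$noise_sigma),
                      nrow(y), ncol(y))
    array(t(y), c(spec$grid_shape, spec$n_timepoints))
  })
  truth <- list(maps = maps,
                timecourses = tcres$timecourses,
                cluster = tcres$cluster,
                is_noise = tcres$is_noise,
                factors = tcres$factors,
                mask = mask)
  list(image = image4d(img, tr = spec$tr_seconds), truth = truth)
}

#' Simulate a two-group cohort of functional phantoms
#'
#' Each subject is an independent realization of its group's phantom
#' specification; the two specifications must share component geometry
#' (centers, radii, amplitudes, clusters, signs) and may differ only in
#' distributional parameters such as cluster loadings or factor correlations
#' (e.g. a hypoperfused group with a weakened cluster).
#'
#' @param spec_a,spec_b \code{\link{functional_phantom_spec}} for the two
#'   groups (e.g. sham and hypoperfused).
#' @param n_per_group subjects per group; 0 gives an empty cohort.
#' @param seed integer master seed; expanded to per-subject substreams.
#' @param group_names length-2 character vector of group labels.
#' @return A list of class \code{cohort}: \code{images} (list of
#'   \code{image4d}), \code{group} (character vector), \code{truth}
#'   (shared geometry plus per-subject time courses).
#' @export
simulate_cohort <- function(spec_a, spec_b, n_per_group, seed = 1L,
                            group_names = c("sham", "hypo")) {
  stopifnot(inherits(spec_a, "functional_phantom_spec"),
            inherits(spec_b, "functional_phantom_spec"),
            n_per_group >= 0L)
  geom <- function(s) lapply(s$components, function(cs)
    cs[c("center", "radius", "cluster", "amplitude", "sign")])
  if (!identical(spec_a$grid_shape, spec_b$grid_shape) ||
      spec_a$n_timepoints != spec_b$n_timepoints ||
      !isTRUE(all.equal(geom(spec_a), geom(spec_b))))
    stopf("group specifications must share component geometry and dimensions")
  images <- list(); group <- character(0); subj_tc <- list()
  shared_truth <- NULL
  n_idx <- 0L
  for (g in 1:2) {
    spec <- if (g == 1L) spec_a else spec_b
    for (i in seq_len(n_per_group)) {
      n_idx <- n_idx + 1L
      res <- simulate_rsfmri(spec, seed = substream_seed(seed, n_idx, g))
      images[[n_idx]] <- res$image
      group[n_idx] <- group_names[g]
      subj_tc[[n_idx]] <- res$truth$timecourses
      if (is.null(shared_truth))
        shared_truth <- res$truth[c("maps", "cluster", "is_noise", "mask")]
    }
  }
  structure(list(images = images, group = group,
                 truth = c(shared_truth, list(subject_timecourses = subj_tc))),
            class = "cohort")
}
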