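## Functional connectome construction: component correlations, Fisher z,
## hierarchical clustering into resting-state networks, edge-wise group
## comparison, and seed-based correlation mapping.

#' Pearson correlation between component time courses
#'
#' For a single T x k time-course matrix, returns the k x k Pearson
#' correlation matrix. For a list (one matrix per subject), returns a list
#' of per-subject matrices. Zero-variance columns are an error naming the
#' offending component.
#'
#' @param timecourses T x k matrix, or list of such matrices.
#' @return Correlation matrix (or list of them) with unit diagonal.
#' @export
component_correlation <- function(timecourses) {
  if (is.list(timecourses))
    return(lapply(timecourses, component_correlation))
  stopifnot(is.matrix(timecourses))
  if (nrow(timecourses) < 3L) stopf("at least 3 timepoints are required")
  sdv <- apply(timecourses, 2, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(timecourses)[sdv == 0] %||% which(sdv == 0)
    stopf("zero-variance time course for component(s): %s",
          paste(bad, collapse = ", "))
  }
  stats::cor(timecourses)
}

#' Fisher z transform of correlation coefficients
#'
#' \code{z = atanh(r) = 0.5 * log((1 + r) / (1 - r))}. Values with
#' \code{|r| >= 1 - 1e-7} are clipped (with a warning); \code{|r| > 1} is an
#' error. Matrix inputs keep a zero diagonal.
#'
#' @param r correlation value(s), vector or matrix.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stopf("|r| > 1 is not a correlation")
  is_mat <- is.matrix(r)
  diag_idx <- if (is_mat && nrow(r) == ncol(r)) which(diag(nrow(r)) == 1) else integer(0)
  clip <- abs(r) >= 1 - 1e-7
  clip[diag_idx] <- FALSE
  if (any(clip, na.rm = TRUE)) {
    warnf("%d correlation(s) with |r| >= 1 - 1e-7 clipped", sum(clip, na.rm = TRUE))
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  z <- atanh(r)
  if (length(diag_idx)) z[diag_idx] <- 0
  z
}

#' Group-level z matrix by Fisher-z averaging
#'
#' Subject correlation matrices are Fisher transformed, averaged edge-wise,
#' and returned as a z matrix (symmetric, zero diagonal). Use
#' \code{tanh} to map back to a group correlation.
#'
#' @param r_list list of per-subject correlation matrices.
#' @return The mean z matrix.
#' @export
group_z <- function(r_list) {
  stopifnot(length(r_list) >= 1L)
  zs <- lapply(r_list, fisher_z)
  z <- Reduce(`+`, zs) / length(zs)
  diag(z) <- 0
  z
}

#' Hierarchical clustering of components into resting-state networks
#'
#' Agglomerative clustering with average linkage on the distance
#' \code{d_ij = 1 - r_ij} computed from the group z matrix (signed
#' correlation, so anticorrelated components are maximally distant), cut to
#' exactly \code{k} clusters. Cluster ids are ordered by descending cluster
#' size, ties broken by the smallest member id.
#'
#' @param z group-level z matrix (symmetric, zero diagonal).
#' @param k number of clusters (resting-state networks).
#' @return An object of class \code{cluster_assignment}: \code{labels}
#'   (integer per component), \code{k}, \code{hclust} (the full linkage for
#'   dendrogram inspection).
#' @export
cluster_components <- function(z, k) {
  check_symmetric(z, "z matrix")
  n <- nrow(z)
  if (k > n) stopf("k (%d) exceeds the number of components (%d)", k, n)
  if (k < 1L) stopf("k must be >= 1")
  r <- tanh(z)
  d <- 1 - r
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, k = k)
  ## relabel: descending size, then smallest member id
  sizes <- table(raw)
  first <- vapply(names(sizes), function(l) min(which(raw == as.integer(l))),
                  numeric(1))
  ord <- order(-as.integer(sizes), first)
  relab <- stats::setNames(seq_len(k), names(sizes)[ord])
  labels <- unname(relab[as.character(raw)])
  structure(list(labels = labels, k = k, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d components in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Edge-wise group comparison of functional connectivity
#'
#' For every unique component pair, compares the subjects' Fisher z values
#' between the two groups (\code{delta = mean(A) - mean(B)}) with a Welch t
#' test or Mann-Whitney U test, then applies Benjamini-Hochberg FDR over the
#' \code{n(n-1)/2} upper-triangle edges.
#'
#' @param z_subjects list of per-subject z matrices (symmetric, zero
#'   diagonal).
#' @param group character/factor vector, one of two levels per subject;
#'   each group needs >= 2 subjects.
#' @param alpha FDR level.
#' @param method \code{"t"} (Welch, default) or \code{"mwu"}.
#' @return A list of class \code{edge_comparison}: \code{delta}, \code{p}
#'   (symmetric matrices), \code{rejected} (logical matrix), \code{edges}
#'   (data frame of upper-triangle edges with statistics), \code{fdr}.
#' @export
group_difference_matrix <- function(z_subjects, group, alpha = 0.05,
                                    method = c("t", "mwu")) {
  method <- match.arg(method)
  stopifnot(is.list(z_subjects), length(z_subjects) == length(group))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stopf("exactly two groups are required")
  if (any(table(group) < 2L)) stopf("each group needs at least 2 subjects")
  n <- nrow(z_subjects[[1]])
  for (z in z_subjects) {
    check_symmetric(z, "subject z matrix")
    if (nrow(z) != n) stopf("subject z matrices are not conformable")
  }
  ga <- levels(group)[1]
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  zarr <- vapply(z_subjects, function(z) z[upper.tri(z)],
                 numeric(nrow(ut)))                       # edges x subjects
  if (nrow(ut) == 1L) zarr <- matrix(zarr, nrow = 1L)
  delta_v <- p_v <- stat_v <- numeric(nrow(ut))
  for (e in seq_len(nrow(ut))) {
    x <- zarr[e, group == ga]; y <- zarr[e, group != ga]
    tr <- two_sample_test(x, y, method)
    delta_v[e] <- mean(x) - mean(y)
    p_v[e] <- tr$p_value
    stat_v[e] <- tr$statistic
  }
  fdr <- bh_fdr(p_v, alpha)
  rej_v <- seq_len(nrow(ut)) %in% fdr$rejected
  sym_fill <- function(v, default = 0) {
    m <- matrix(default, n, n)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  dimn <- dimnames(z_subjects[[1]])
  delta <- sym_fill(delta_v); p <- sym_fill(p_v, 1)
  rejected <- sym_fill(rej_v, FALSE) > 0
  diag(rejected) <- FALSE
  dimnames(delta) <- dimnames(p) <- dimnames(rejected) <- dimn
  structure(list(delta = delta, p = p, rejected = rejected,
                 edges = data.frame(i = ut[, 1], j = ut[, 2],
                                    delta = delta_v, statistic = stat_v,
                                    p = p_v, rejected = rej_v),
                 fdr = fdr, method = method, alpha = alpha),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf("<edge_comparison> %d edges, %d rejected at BH alpha = %g (%s test)\n",
              nrow(x$edges), sum(x$edges$rejected), x$alpha,
              if (x$method == "t") "Welch t" else "Mann-Whitney U"))
  invisible(x)
}

#' Seed-based correlation (Fisher z) map
#'
#' The seed time course is the mean of the in-seed voxel time series; every
#' in-mask voxel's Pearson correlation with it is Fisher transformed. With
#' \code{concatenate = TRUE} the map is computed once on the temporally
#' concatenated, per-subject-normalized group matrix; otherwise per subject,
#' then z-averaged.
#'
#' @param images an \code{\link{image4d}} or list of them.
#' @param seed_mask logical 3D array marking the seed region; must be
#'   nonempty and inside the brain mask.
#' @param mask brain mask; default \code{\link{brain_mask}}.
#' @param concatenate compute on the concatenated group data.
#' @return A 3D array of z values (0 outside the mask) with attribute
#'   \code{mask}.
#' @export
seed_correlation_map <- function(images, seed_mask, mask = NULL,
                                 concatenate = FALSE) {
  if (inherits(images, "image4d")) images <- list(images)
  dims <- dim(images[[1]]$data)[1:3]
  mask <- mask %||% brain_mask(dims)
  if (!any(seed_mask)) stopf("seed mask is empty")
  if (any(seed_mask & !mask)) stopf("seed mask extends outside the brain mask")
  one_map <- function(mat, vidx) {
    seed_cols <- which(vidx %in% which(as.vector(seed_mask)))
    if (!length(seed_cols)) stopf("seed mask voxels were dropped (zero variance)")
    seed_tc <- rowMeans(mat[, seed_cols, drop = FALSE])
    if (stats::sd(seed_tc) == 0) stopf("seed time course has zero variance")
    r <- suppressWarnings(as.vector(stats::cor(seed_tc, mat)))
    r[is.na(r)] <- 0
    fisher_z(r)
  }
  if (concatenate) {
    cm <- concatenate_temporal(images, mask)
    zv <- one_map(cm, attr(cm, "voxel_index"))
    vidx <- attr(cm, "voxel_index")
  } else {
    zs <- lapply(images, function(im) {
      cm <- concatenate_temporal(im, mask)
      list(z = one_map(cm, attr(cm, "voxel_index")),
           vidx = attr(cm, "voxel_index"))
    })
    vidx <- zs[[1]]$vidx
    for (s in zs) if (!identical(s$vidx, vidx))
      stopf("subjects dropped different voxels; cannot average seed maps")
    zv <- Reduce(`+`, lapply(zs, `[[`, "z")) / length(zs)
  }
  out <- array(0, dims)
  out[vidx] <- zv
  attr(out, "mask") <- mask
  out
}
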