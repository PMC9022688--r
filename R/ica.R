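## Group spatial ICA: temporal concatenation, PCA reduction, fixed-point
## (FastICA) unmixing with the logcosh nonlinearity, per-subject time-course
## recovery by regression, and automated noise-component screening.

#' Temporally concatenate a group of functional images
#'
#' Extracts the in-mask voxel time series of every subject, demeans and
#' variance-normalizes each voxel's series within subject, and stacks the
#' subjects along the time axis. Voxels with zero variance in any subject
#' are dropped (and reported via an attribute and a warning) so that every
#' retained column is exactly standardized.
#'
#' @param images an \code{\link{image4d}} or list of them, all on the same
#'   grid.
#' @param mask logical 3D array; default \code{\link{brain_mask}} of the
#'   grid.
#' @return A numeric matrix with \code{sum(T_s)} rows and one column per
#'   retained voxel, with attributes \code{subject_rows} (list of row index
#'   vectors), \code{voxel_index} (linear indices into the grid),
#'   \code{dropped} (indices of zero-variance voxels), \code{dims},
#'   \code{mask}, \code{tr}.
#' @export
concatenate_temporal <- function(images, mask = NULL) {
  if (inherits(images, "image4d")) images <- list(images)
  if (!length(images)) stopf("at least one image is required")
  dims <- dim(images[[1]]$data)[1:3]
  for (im in images) {
    if (!inherits(im, "image4d")) stopf("inputs must be image4d objects")
    if (!identical(dim(im$data)[1:3], dims))
      stopf("images do not share a voxel grid")
  }
  mask <- mask %||% brain_mask(dims)
  if (!identical(dim(mask), dims)) stopf("mask does not match the image grid")
  vidx <- which(as.vector(mask))
  blocks <- list(); drop_all <- logical(length(vidx))
  mats <- vector("list", length(images))
  for (s in seq_along(images)) {
    arr <- images[[s]]$data
    tt <- dim(arr)[4]
    m <- t(matrix(arr, prod(dims), tt)[vidx, , drop = FALSE])  # T x V
    mu <- colMeans(m)
    m <- sweep(m, 2, mu)
    sdv <- sqrt(colSums(m^2) / (tt - 1))
    drop_all <- drop_all | sdv == 0
    m[, sdv > 0] <- sweep(m[, sdv > 0, drop = FALSE], 2, sdv[sdv > 0], `/`)
    mats[[s]] <- m
  }
  if (any(drop_all))
    warnf("%d zero-variance voxel(s) dropped from the concatenated matrix",
          sum(drop_all))
  keep <- !drop_all
  out <- do.call(rbind, lapply(mats, function(m) m[, keep, drop = FALSE]))
  r0 <- 0L
  for (s in seq_along(mats)) {
    blocks[[s]] <- r0 + seq_len(nrow(mats[[s]]))
    r0 <- r0 + nrow(mats[[s]])
  }
  structure(out,
            subject_rows = blocks,
            voxel_index = vidx[keep],
            dropped = vidx[drop_all],
            dims = dims, mask = mask,
            tr = images[[1]]$tr)
}

## symmetric decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  es <- eigen(W %*% t(W), symmetric = TRUE)
  es$vectors %*% diag(1 / sqrt(es$values), nrow(W)) %*% t(es$vectors) %*% W
}

#' Group spatial independent component analysis
#'
#' PCA-reduces the concatenated data to \code{n_components}, then runs
#' symmetric fixed-point ICA (logcosh nonlinearity) on the voxel dimension,
#' so the recovered sources are spatial maps (the MELODIC convention).
#' Per-subject time courses are recovered by least-squares regression of
#' each subject's data onto the group maps (the first dual-regression
#' stage). Each map is normalized to unit Euclidean norm and its sign fixed
#' so the largest-magnitude voxel is positive, which makes the output
#' deterministic given the seed.
#'
#' @param data concatenated matrix from \code{\link{concatenate_temporal}}
#'   (time by voxels, with its attributes).
#' @param n_components model order; \code{NULL} selects the number of
#'   principal components retaining 95% of the variance.
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing update.
#' @return An object of class \code{component_set}: \code{maps}
#'   (n_components x n_voxel, unit-norm rows), \code{timecourses} (list of
#'   per-subject T x n_components matrices), \code{explained_variance},
#'   \code{noise_flags} (NA until \code{\link{classify_noise}}),
#'   \code{voxel_index}, \code{dims}, \code{mask}, \code{tr}, \code{n_iter}.
#' @export
group_ica <- function(data, n_components = NULL, seed = 1L,
                      max_iter = 1000L, tol = 1e-6) {
  stopifnot(is.matrix(data))
  sv <- svd(data)
  ev <- sv$d^2 / sum(sv$d^2)
  if (is.null(n_components))
    n_components <- which(cumsum(ev) >= 0.95)[1]
  if (n_components > min(dim(data)))
    stopf("n_components (%d) exceeds the data rank bound (%d)",
          n_components, min(dim(data)))
  k <- n_components
  nv <- ncol(data)
  ## spatial PCA basis, centered over voxels (the ICA variables must be
  ## zero mean) and re-whitened exactly; centering can cost at most one
  ## rank-1 direction of the PCA subspace
  Z <- t(sv$v[, seq_len(k), drop = FALSE])
  Z <- Z - rowMeans(Z)
  ez <- eigen(Z %*% t(Z) / nv, symmetric = TRUE)
  Z <- ez$vectors %*% diag(1 / sqrt(ez$values), k) %*% t(ez$vectors) %*% Z
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  })
  iter <- 0L; delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    WX <- W %*% Z
    gwx <- tanh(WX)
    W_new <- gwx %*% t(Z) / nv - diag(rowMeans(1 - gwx^2), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- 1 - min(abs(diag(W_new %*% t(W))))
    W <- W_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    cond <- structure(
      class = c("mconn_ica_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "ICA did not converge after %d iterations (delta = %.3g)",
             iter, delta),
           call = sys.call(-1), iterations = iter))
    stop(cond)
  }
  S <- W %*% Z                                  # k x V spatial maps
  ## unit-norm rows, sign so the peak voxel is positive
  nrm <- sqrt(rowSums(S^2))
  S <- S / nrm
  peak_sign <- apply(S, 1, function(r) sign(r[which.max(abs(r))]))
  S <- S * peak_sign
  ## per-subject time courses: X_s S' (S S')^{-1}
  SSt_inv <- solve(S %*% t(S))
  blocks <- attr(data, "subject_rows") %||% list(seq_len(nrow(data)))
  tcs <- lapply(blocks, function(rows)
    data[rows, , drop = FALSE] %*% t(S) %*% SSt_inv)
  proj <- data %*% t(S)                         # maps have unit norm
  expl <- colSums(proj^2) / sum(data^2)
  ord <- order(expl, decreasing = TRUE)
  structure(list(maps = S[ord, , drop = FALSE],
                 timecourses = lapply(tcs, function(m) m[, ord, drop = FALSE]),
                 explained_variance = expl[ord],
                 noise_flags = rep(NA, k),
                 voxel_index = attr(data, "voxel_index"),
                 dims = attr(data, "dims"),
                 mask = attr(data, "mask"),
                 tr = attr(data, "tr") %||% 1,
                 n_iter = iter),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d voxels, %d subject(s)%s\n",
              nrow(x$maps), ncol(x$maps), length(x$timecourses),
              if (all(is.na(x$noise_flags))) ""
              else sprintf(", %d flagged as noise", sum(x$noise_flags, na.rm = TRUE))))
  invisible(x)
}

#' Automated screening of noise components
#'
#' Flags a component as noise when either criterion fires: (a) spatial --
#' more than \code{edge_fraction_max} of its supra-threshold voxels
#' (\code{|z-scored map| > z_thresh}) lie on the outermost shell of the
#' brain mask; (b) temporal -- the fraction of its time-course power above
#' \code{hf_cutoff_hz} exceeds \code{hf_fraction_max} (averaged over
#' subjects). Components with an empty supra-threshold set are marked
#' indeterminate, not noise.
#'
#' @param cs a \code{component_set}.
#' @param mask logical 3D array; default the mask stored on \code{cs}.
#' @param z_thresh spatial z threshold (default 2.3).
#' @param edge_fraction_max maximal tolerated edge fraction (default 0.5).
#' @param hf_cutoff_hz high-frequency cutoff in Hz (default 0.1).
#' @param hf_fraction_max maximal tolerated high-frequency power fraction
#'   (default 0.5).
#' @return The \code{component_set} with \code{noise_flags} filled in and a
#'   \code{diagnostics} data frame attached (edge fraction, high-frequency
#'   power fraction, per-criterion flags, indeterminate flag).
#' @export
classify_noise <- function(cs, mask = NULL, z_thresh = 2.3,
                           edge_fraction_max = 0.5, hf_cutoff_hz = 0.1,
                           hf_fraction_max = 0.5) {
  stopifnot(inherits(cs, "component_set"))
  mask <- mask %||% cs$mask
  if (!identical(dim(mask), cs$dims))
    stopf("mask does not match the component voxel space")
  edge <- mask_edge(mask)
  edge_v <- as.vector(edge)[cs$voxel_index]
  k <- nrow(cs$maps)
  edge_frac <- hf_frac <- rep(NA_real_, k)
  spatial_flag <- temporal_flag <- indeterminate <- logical(k)
  for (i in seq_len(k)) {
    m <- cs$maps[i, ]
    sdm <- stats::sd(m)
    z <- if (sdm > 0) (m - mean(m)) / sdm else rep(0, length(m))
    supra <- abs(z) > z_thresh
    if (!any(supra)) {
      indeterminate[i] <- TRUE
    } else {
      edge_frac[i] <- mean(edge_v[supra])
      spatial_flag[i] <- edge_frac[i] > edge_fraction_max
    }
    fr <- vapply(cs$timecourses, function(tc) {
      x <- tc[, i] - mean(tc[, i])
      n <- length(x)
      pw <- Mod(stats::fft(x))^2
      freq <- (seq_len(n) - 1) / (n * cs$tr)
      half <- freq > 0 & freq <= 0.5 / cs$tr
      sum(pw[half & freq > hf_cutoff_hz]) / sum(pw[half])
    }, numeric(1))
    hf_frac[i] <- mean(fr)
    temporal_flag[i] <- hf_frac[i] > hf_fraction_max
  }
  cs$noise_flags <- (spatial_flag | temporal_flag) & !indeterminate
  cs$diagnostics <- data.frame(component = seq_len(k),
                               edge_fraction = edge_frac,
                               hf_power_fraction = hf_frac,
                               spatial_flag = spatial_flag,
                               temporal_flag = temporal_flag,
                               indeterminate = indeterminate,
                               noise = cs$noise_flags)
  cs
}

#' Subset a component set
#'
#' @param cs a \code{component_set}.
#' @param keep integer or logical index of components to retain.
#' @return The reduced \code{component_set}.
#' @export
subset_components <- function(cs, keep) {
  stopifnot(inherits(cs, "component_set"))
  cs$maps <- cs$maps[keep, , drop = FALSE]
  cs$timecourses <- lapply(cs$timecourses, function(m) m[, keep, drop = FALSE])
  cs$explained_variance <- cs$explained_variance[keep]
  cs$noise_flags <- cs$noise_flags[keep]
  if (!is.null(cs$diagnostics)) cs$diagnostics <- cs$diagnostics[keep, ]
  cs
}
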