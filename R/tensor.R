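## Diffusion tensor model: log-linear least-squares fitting, eigensystem,
## fractional anisotropy, and voxel-wise FA group comparison.

#' Fractional anisotropy from tensor eigenvalues
#'
#' \code{FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))},
#' defined as 0 when all eigenvalues are zero. Inputs are vectorized.
#'
#' @param l1,l2,l3 eigenvalue vectors (nonnegative).
#' @return FA values in \[0, 1\].
#' @export
fractional_anisotropy <- function(l1, l2, l3) {
  if (any(c(l1, l2, l3) < 0)) stopf("eigenvalues must be nonnegative")
  m <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

## Build a tensor_field from per-voxel unique elements (xx,yy,zz,xy,xz,yz).
## Negative eigenvalues are clamped to zero and counted.
tensor_field_from_elements <- function(D6, s0, dims, mask,
                                       valid = NULL) {
  nv <- prod(dims)
  valid <- valid %||% array(TRUE, dims)
  evals <- matrix(NA_real_, nv, 3)
  e1 <- matrix(NA_real_, nv, 3)
  n_clamped <- 0L
  idx <- which(as.vector(mask) & as.vector(valid))
  for (v in idx) {
    Dm <- matrix(c(D6[v, 1], D6[v, 4], D6[v, 5],
                   D6[v, 4], D6[v, 2], D6[v, 6],
                   D6[v, 5], D6[v, 6], D6[v, 3]), 3, 3)
    es <- eigen(Dm, symmetric = TRUE)
    lam <- es$values
    if (any(lam < 0)) {
      n_clamped <- n_clamped + 1L
      lam <- pmax(lam, 0)
    }
    evals[v, ] <- lam
    e1[v, ] <- es$vectors[, 1]
  }
  fa <- array(0, dims)
  fa[idx] <- fractional_anisotropy(evals[idx, 1], evals[idx, 2], evals[idx, 3])
  structure(list(d6 = D6, evals = evals, e1 = e1, fa = fa,
                 s0 = s0, mask = mask, valid = valid, dims = dims,
                 affine = diag(4), n_clamped = n_clamped),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid, %d valid voxels, %d clamped eigenvalues\n",
              paste(x$dims, collapse = " x "),
              sum(x$valid & x$mask), x$n_clamped))
  invisible(x)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, solves \code{ln S = ln S0 - b g' D g} in the 7 unknowns
#' (\code{ln S0} and the 6 unique tensor elements) by ordinary least
#' squares. Nonpositive signal samples are dropped for that voxel; voxels
#' with fewer than 7 usable measurements are marked invalid. Negative
#' eigenvalues are clamped to zero with a per-volume count reported on the
#' returned object.
#'
#' @param dwi 4D array of signals, or the \code{dwi} list returned by
#'   \code{\link{simulate_dwi}} (in which case b-values/vectors are taken
#'   from it).
#' @param b_values vector of b-values (s/mm^2).
#' @param b_vectors matrix of gradient directions, one row per b-value.
#' @param mask optional logical 3D array; default all voxels.
#' @return A \code{tensor_field}: per-voxel tensor elements, eigenvalues
#'   (descending), principal eigenvector, FA, S0, validity flags.
#' @export
fit_tensor <- function(dwi, b_values = NULL, b_vectors = NULL, mask = NULL) {
  if (is.list(dwi) && !is.null(dwi$data)) {
    b_values <- b_values %||% dwi$b_values
    b_vectors <- b_vectors %||% dwi$b_vectors
    dwi <- dwi$data
  }
  stopifnot(is.array(dwi), length(dim(dwi)) == 4L)
  dims <- dim(dwi)[1:3]
  nmeas <- dim(dwi)[4]
  if (length(b_values) != nmeas || nrow(b_vectors) != nmeas)
    stopf("b_values/b_vectors do not match the number of volumes (%d)", nmeas)
  if (sum(b_values == 0) < 1L) stopf("at least one b=0 volume is required")
  if (sum(b_values > 0) < 6L)
    stopf("at least 6 diffusion-weighted directions are required (got %d)",
          sum(b_values > 0))
  g <- b_vectors; b <- b_values
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L)
    stopf("gradient scheme is rank deficient; tensor not identifiable")
  mask <- mask %||% array(TRUE, dims)
  nv <- prod(dims)
  Smat <- matrix(dwi, nv, nmeas)               # voxels x measurements
  valid <- array(FALSE, dims)
  D6 <- matrix(NA_real_, nv, 6)
  s0 <- array(NA_real_, dims)
  midx <- which(as.vector(mask))
  ok_all <- midx[rowSums(Smat[midx, , drop = FALSE] <= 0) == 0L]
  if (length(ok_all)) {
    beta <- t(solve(crossprod(X), t(X) %*% t(log(Smat[ok_all, , drop = FALSE]))))
    s0[ok_all] <- exp(beta[, 1])
    D6[ok_all, ] <- beta[, 2:7]
    valid[ok_all] <- TRUE
  }
  partial <- setdiff(midx, ok_all)
  for (v in partial) {
    usable <- Smat[v, ] > 0
    if (sum(usable) < 7L) next                  # marked invalid
    Xi <- X[usable, , drop = FALSE]
    if (qr(Xi)$rank < 7L) next
    beta <- solve(crossprod(Xi), crossprod(Xi, log(Smat[v, usable])))
    s0[v] <- exp(beta[1])
    D6[v, ] <- beta[2:7]
    valid[v] <- TRUE
  }
  tensor_field_from_elements(D6, s0, dims, mask, valid)
}

#' Voxel-wise two-sample comparison of FA maps
#'
#' Welch two-sample t test at every in-mask voxel, followed by
#' Benjamini-Hochberg FDR across voxels. Voxels with zero variance in both
#' groups get \code{t = 0}, \code{p = 1} and are flagged.
#'
#' @param fa_a,fa_b lists of co-registered 3D FA arrays (>= 2 per group).
#' @param mask logical 3D array of voxels to test.
#' @param alpha FDR level.
#' @return A list: \code{t} and \code{p} maps, \code{rejected} logical map,
#'   \code{flagged} logical map of degenerate voxels, and the
#'   \code{fdr_result}.
#' @export
voxelwise_fa_compare <- function(fa_a, fa_b, mask = NULL, alpha = 0.05) {
  if (length(fa_a) < 2L || length(fa_b) < 2L)
    stopf("each group needs at least 2 subjects")
  dims <- dim(fa_a[[1]])
  for (x in c(fa_a, fa_b)) if (!identical(dim(x), dims))
    stopf("FA volumes are not co-registered (dimension mismatch)")
  mask <- mask %||% array(TRUE, dims)
  idx <- which(as.vector(mask))
  A <- vapply(fa_a, function(x) as.vector(x)[idx], numeric(length(idx)))
  B <- vapply(fa_b, function(x) as.vector(x)[idx], numeric(length(idx)))
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  flagged <- se2 == 0
  fdr <- bh_fdr(p, alpha)
  out_t <- array(0, dims); out_p <- array(1, dims)
  out_rej <- array(FALSE, dims); out_flag <- array(FALSE, dims)
  out_t[idx] <- tt; out_p[idx] <- p
  out_rej[idx[fdr$rejected]] <- TRUE
  out_flag[idx] <- flagged
  list(t = out_t, p = out_p, rejected = out_rej, flagged = out_flag,
       fdr = fdr)
}
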