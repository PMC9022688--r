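## Diffusion phantom generator: tensor field with geometric fiber bundles
## and mono-exponential signal with Rician noise.

## For a set of points (n x 3), return distance to the bundle axis and the
## local unit tangent at the closest axis point.
bundle_geometry <- function(bundle, pts) {
  A <- bundle$from; B <- bundle$to
  if (bundle$geometry == "straight") {
    d <- B - A; L <- sqrt(sum(d^2)); u <- d / L
    t_par <- pmin(pmax((sweep(pts, 2, A) %*% u), 0), L)
    closest <- sweep(t_par %*% t(u), 2, A, `+`)
    dist <- sqrt(rowSums((pts - closest)^2))
    tangent <- matrix(u, nrow(pts), 3, byrow = TRUE)
  } else {                       # quarter arc from A to B
    M <- (A + B) / 2; d <- B - A; L <- sqrt(sum(d^2)); u <- d / L
    ## in-plane normal: pick the coordinate axis least aligned with u
    ax <- diag(3)[, which.min(abs(u))]
    n <- unit3(ax - sum(ax * u) * u)
    Cc <- M + n * (L / 2)                   # arc center, |C-A| = |C-B| = L/sqrt(2)
    R <- L / sqrt(2)
    u1 <- (A - Cc) / R; u2 <- (B - Cc) / R  # orthonormal, arc = C + R(cos t u1 + sin t u2)
    v <- sweep(pts, 2, Cc)
    c1 <- v %*% u1; c2 <- v %*% u2
    theta <- pmin(pmax(atan2(c2, c1), 0), pi / 2)
    closest <- sweep(cos(theta) %*% t(u1) * R + sin(theta) %*% t(u2) * R,
                     2, Cc, `+`)
    dist <- sqrt(rowSums((pts - closest)^2))
    tangent <- -sin(theta) %*% t(u1) + cos(theta) %*% t(u2)
    tangent <- tangent / sqrt(rowSums(tangent^2))
  }
  list(dist = as.vector(dist), tangent = tangent)
}

#' Simulate a diffusion-weighted phantom
#'
#' Builds the ground-truth per-voxel tensor field (principal axis along the
#' local bundle tangent inside bundles, isotropic background elsewhere),
#' evaluates \code{S(g, b) = S0 exp(-b g' D g)} for every gradient, and adds
#' Rician noise as the magnitude of the signal plus complex Gaussian noise
#' (noiseless when \code{noise_sigma = 0}).
#'
#' @param spec a \code{\link{diffusion_phantom_spec}}.
#' @param seed integer seed; defaults to \code{spec$seed}.
#' @return A list with \code{dwi} (list: \code{data} 4D array, \code{b_values},
#'   \code{b_vectors}, \code{affine}), \code{tensors} (the ground-truth
#'   \code{tensor_field}), and \code{truth} (per-bundle voxel masks and an
#'   endpoint \code{label_volume} giving region ids \code{2b-1, 2b} for the
#'   two ends of bundle \code{b}).
#' @export
simulate_dwi <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "diffusion_phantom_spec"))
  d <- spec$grid_shape
  nv <- prod(d)
  pts <- voxel_centers(d)
  ## six unique tensor elements per voxel: xx, yy, zz, xy, xz, yz
  D6 <- cbind(matrix(spec$background_diffusivity, nv, 3), matrix(0, nv, 3))
  bundle_masks <- list()
  endpoint_labels <- array(0L, d)
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    geo <- bundle_geometry(b, pts)
    inside <- geo$dist <= b$radius
    bundle_masks[[bi]] <- array(inside, d)
    t3 <- geo$tangent[inside, , drop = FALSE]
    lp <- b$lambda_par; lr <- b$lambda_perp
    ## D = lr I + (lp - lr) t t'
    D6[inside, 1] <- lr + (lp - lr) * t3[, 1]^2
    D6[inside, 2] <- lr + (lp - lr) * t3[, 2]^2
    D6[inside, 3] <- lr + (lp - lr) * t3[, 3]^2
    D6[inside, 4] <- (lp - lr) * t3[, 1] * t3[, 2]
    D6[inside, 5] <- (lp - lr) * t3[, 1] * t3[, 3]
    D6[inside, 6] <- (lp - lr) * t3[, 2] * t3[, 3]
    for (end in 1:2) {
      p <- if (end == 1) b$from else b$to
      d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
      roi <- d2 <= (b$radius + 0.5)^2
      endpoint_labels[roi] <- 2L * bi - 2L + end
    }
  }
  ## signal: n_meas x n_voxel
  g <- spec$b_vectors; bv <- spec$b_values
  quad <- bv * (g[, 1]^2 %o% D6[, 1] + g[, 2]^2 %o% D6[, 2] +
                g[, 3]^2 %o% D6[, 3] + 2 * g[, 1] * g[, 2] %o% D6[, 4] +
                2 * g[, 1] * g[, 3] %o% D6[, 5] +
                2 * g[, 2] * g[, 3] %o% D6[, 6])
  S <- spec$s0 * exp(-quad)
  if (spec$noise_sigma > 0) {
    S <- with_seed(seed, {
      re <- S + matrix(stats::rnorm(length(S), sd = spec$noise_sigma),
                       nrow(S), ncol(S))
      im <- matrix(stats::rnorm(length(S), sd = spec$noise_sigma),
                   nrow(S), ncol(S))
      sqrt(re^2 + im^2)
    })
  }
  data4d <- array(t(S), c(d, length(bv)))
  tensors <- tensor_field_from_elements(D6, array(spec$s0, d), d,
                                        mask = array(TRUE, d))
  truth <- list(bundle_masks = bundle_masks,
                endpoint_labels = structure(endpoint_labels,
                                            class = c("label_volume", "array"),
                                            affine = diag(4)))
  list(dwi = list(data = data4d, b_values = bv, b_vectors = g,
                  affine = diag(4)),
       tensors = tensors, truth = truth)
}
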