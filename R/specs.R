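## Phantom specifications: validated description objects consumed by the
## generators. These are deliberately plain lists with a class attribute so
## they serialize cleanly to YAML/JSON configuration.

#' Describe one spatial signal component of the functional phantom
#'
#' A component is a Gaussian-profile sphere (sd = radius/2, truncated at
#' 2*radius) whose time course loads on its cluster's latent factor.
#'
#' @param center voxel coordinates (length 3, 1-based).
#' @param radius sphere radius in voxels.
#' @param cluster integer cluster id (resting-state network) the component
#'   belongs to.
#' @param amplitude peak signal amplitude.
#' @param sign +1 or -1 loading on the cluster factor; -1 yields a component
#'   anticorrelated with its own cluster.
#' @return An object of class \code{component_spec}.
#' @export
component_spec <- function(center, radius, cluster, amplitude = 1, sign = 1) {
  stopifnot(length(center) == 3L, radius > 0, amplitude > 0,
            sign %in% c(-1, 1), cluster >= 1)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 cluster = as.integer(cluster), amplitude = as.numeric(amplitude),
                 sign = as.numeric(sign)),
            class = "component_spec")
}

#' Specify a multi-subject BOLD-like functional phantom
#'
#' Voxel signals are sums of component spatial maps weighted by cluster-
#' structured time courses plus white Gaussian noise. Each signal component's
#' time course is \code{sign * (sqrt(w) * f_c + sqrt(1-w) * eta)} where
#' \code{f_c} is the latent factor of its cluster and \code{eta} an
#' independent unique term, so the expected within-cluster correlation of
#' true time courses equals \code{w}. Latent factors of different clusters
#' can be given a target correlation (e.g. an anticorrelated pair).
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param n_timepoints number of time points per subject.
#' @param tr_seconds repetition time in seconds.
#' @param components list of \code{\link{component_spec}} objects.
#' @param cluster_loading squared loading \code{w} in \[0,1\] of each component
#'   time course on its cluster factor; scalar or one value per cluster id.
#' @param inter_cluster_corr data frame with columns \code{a}, \code{b},
#'   \code{rho} giving target correlations between named cluster factors;
#'   \code{NULL} for uncorrelated factors.
#' @param noise_sigma standard deviation of additive voxel noise.
#' @param n_noise_components number of edge-localized noise components with
#'   temporally white time courses.
#' @param seed integer seed driving all randomness of the phantom.
#' @param tc_smooth_sd temporal Gaussian smoothing (in units of TR) applied to
#'   signal time courses before standardization; gives signal components the
#'   low-frequency content typical of BOLD, while noise-component time courses
#'   stay white.
#' @return An object of class \code{functional_phantom_spec}.
#' @export
functional_phantom_spec <- function(grid_shape, n_timepoints, tr_seconds,
                                    components, cluster_loading,
                                    inter_cluster_corr = NULL,
                                    noise_sigma = 0.2,
                                    n_noise_components = 0L,
                                    seed = 1L,
                                    tc_smooth_sd = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            n_timepoints >= 2L, tr_seconds > 0, noise_sigma >= 0,
            n_noise_components >= 0L, tc_smooth_sd >= 0)
  if (!length(components)) stopf("at least one component is required")
  if (inherits(components, "component_spec")) components <- list(components)
  for (cs in components) {
    if (!inherits(cs, "component_spec")) stopf("components must be component_spec objects")
    if (any(cs$center - cs$radius < 1) || any(cs$center + cs$radius > grid_shape))
      stopf("component sphere at (%s) with radius %g does not lie inside the grid",
            paste(cs$center, collapse = ","), cs$radius)
  }
  clusters <- sort(unique(vapply(components, `[[`, integer(1), "cluster")))
  if (length(cluster_loading) == 1L)
    cluster_loading <- stats::setNames(rep(cluster_loading, length(clusters)),
                                       clusters)
  if (length(cluster_loading) != length(clusters))
    stopf("cluster_loading must be scalar or give one value per cluster")
  if (is.null(names(cluster_loading))) names(cluster_loading) <- clusters
  if (any(cluster_loading < 0 | cluster_loading > 1))
    stopf("cluster_loading w must lie in [0,1]")
  if (!is.null(inter_cluster_corr)) {
    inter_cluster_corr <- as.data.frame(inter_cluster_corr)
    stopifnot(all(c("a", "b", "rho") %in% names(inter_cluster_corr)))
    if (any(abs(inter_cluster_corr$rho) >= 1))
      stopf("|inter_cluster_corr| must be < 1")
    if (!all(c(inter_cluster_corr$a, inter_cluster_corr$b) %in% clusters))
      stopf("inter_cluster_corr names a cluster with no components")
  }
  structure(list(grid_shape = grid_shape,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = as.numeric(tr_seconds),
                 components = components,
                 cluster_loading = cluster_loading,
                 inter_cluster_corr = inter_cluster_corr,
                 noise_sigma = as.numeric(noise_sigma),
                 n_noise_components = as.integer(n_noise_components),
                 seed = as.integer(seed),
                 tc_smooth_sd = as.numeric(tc_smooth_sd),
                 clusters = clusters),
            class = "functional_phantom_spec")
}

#' Default resting-state-network phantom
#'
#' The reference functional phantom used throughout: 4 clusters
#' (resting-state networks) of 3 components each, arranged on a ring inside
#' the ellipsoidal brain mask of a 24 x 24 x 12 grid; within-cluster squared
#' loading \code{w = 0.6}; one anticorrelated cluster pair (1 vs 2, factor
#' correlation -0.5), mimicking the sensorimotor-visual vs limbic
#' anticorrelation seen in mouse resting-state data; 300 time points at
#' TR = 1 s; unit component amplitude with noise sd 0.2 (peak SNR about 5).
#'
#' @param seed integer seed.
#' @param n_timepoints time points per subject.
#' @param cluster_loading scalar or per-cluster \code{w}.
#' @param inter_cluster_corr factor-correlation table; the default
#'   anticorrelates clusters 1 and 2 at -0.5.
#' @param noise_sigma additive noise sd.
#' @param n_noise_components edge noise components (default 3).
#' @return A \code{\link{functional_phantom_spec}}.
#' @export
default_rsn_spec <- function(seed = 1L, n_timepoints = 300L,
                             cluster_loading = 0.6,
                             inter_cluster_corr = data.frame(a = 1L, b = 2L,
                                                             rho = -0.5),
                             noise_sigma = 0.2,
                             n_noise_components = 3L) {
  centers <- list(
    c(20, 13, 5), c(19, 16, 8), c(16, 19, 5),   # cluster 1
    c(13, 20, 8), c(9, 19, 5), c(6, 16, 8),     # cluster 2
    c(5, 13, 5), c(6, 9, 8), c(9, 6, 5),        # cluster 3
    c(13, 5, 8), c(16, 6, 5), c(19, 9, 8))      # cluster 4
  comps <- mapply(function(ctr, cl) component_spec(ctr, radius = 2, cluster = cl),
                  centers, rep(1:4, each = 3), SIMPLIFY = FALSE)
  functional_phantom_spec(grid_shape = c(24L, 24L, 12L),
                          n_timepoints = n_timepoints, tr_seconds = 1,
                          components = comps,
                          cluster_loading = cluster_loading,
                          inter_cluster_corr = inter_cluster_corr,
                          noise_sigma = noise_sigma,
                          n_noise_components = n_noise_components,
                          seed = seed)
}

#' Describe one fiber bundle of the diffusion phantom
#'
#' @param geometry \code{"straight"} (a cylinder around the segment between
#'   the endpoints) or \code{"arc"} (a quarter circular arc joining them).
#' @param from,to endpoint voxel coordinates (length 3, 1-based).
#' @param radius bundle radius in voxels.
#' @param lambda_par axial diffusivity (mm^2/s) along the local tangent.
#' @param lambda_perp radial diffusivity (mm^2/s); must satisfy
#'   \code{lambda_par >= lambda_perp > 0}.
#' @return An object of class \code{bundle_spec}.
#' @export
bundle_spec <- function(geometry = c("straight", "arc"), from, to, radius = 1.5,
                        lambda_par = 1.7e-3, lambda_perp = 0.3e-3) {
  geometry <- match.arg(geometry)
  stopifnot(length(from) == 3L, length(to) == 3L, radius > 0)
  if (!(lambda_par >= lambda_perp && lambda_perp > 0))
    stopf("diffusivities must satisfy lambda_par >= lambda_perp > 0")
  structure(list(geometry = geometry, from = as.numeric(from),
                 to = as.numeric(to), radius = as.numeric(radius),
                 lambda_par = lambda_par, lambda_perp = lambda_perp),
            class = "bundle_spec")
}

#' Specify a diffusion-weighted phantom
#'
#' Each voxel carries a known diffusion tensor: anisotropic with its
#' principal axis along the local bundle tangent inside a bundle, isotropic
#' with \code{background_diffusivity} elsewhere. The signal follows the
#' mono-exponential tensor model \code{S = S0 * exp(-b g' D g)} with optional
#' Rician noise.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param bundles list of \code{\link{bundle_spec}} objects.
#' @param background_diffusivity isotropic diffusivity (mm^2/s) outside
#'   bundles.
#' @param b_values vector of b-values (s/mm^2); at least one must be 0.
#' @param b_vectors matrix with one unit gradient direction per row, one row
#'   per b-value.
#' @param s0 non-diffusion-weighted signal level.
#' @param noise_sigma Rician noise scale; 0 gives noiseless data.
#' @param seed integer seed.
#' @return An object of class \code{diffusion_phantom_spec}.
#' @export
diffusion_phantom_spec <- function(grid_shape, bundles,
                                   background_diffusivity = 0.7e-3,
                                   b_values, b_vectors, s0 = 1000,
                                   noise_sigma = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            background_diffusivity > 0, s0 > 0, noise_sigma >= 0)
  if (inherits(bundles, "bundle_spec")) bundles <- list(bundles)
  for (b in bundles) if (!inherits(b, "bundle_spec"))
    stopf("bundles must be bundle_spec objects")
  b_vectors <- as.matrix(b_vectors)
  if (ncol(b_vectors) != 3L || nrow(b_vectors) != length(b_values))
    stopf("b_vectors must be a length(b_values) x 3 matrix")
  if (!any(b_values == 0)) stopf("at least one b=0 volume is required")
  nz <- b_values > 0
  norms <- sqrt(rowSums(b_vectors^2))
  if (any(abs(norms[nz] - 1) > 1e-6)) {
    warnf("non-unit b-vectors normalized")
    b_vectors[nz, ] <- b_vectors[nz, ] / norms[nz]
  }
  structure(list(grid_shape = grid_shape, bundles = bundles,
                 background_diffusivity = background_diffusivity,
                 b_values = as.numeric(b_values), b_vectors = b_vectors,
                 s0 = as.numeric(s0), noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "diffusion_phantom_spec")
}

#' Evenly spread gradient directions on the hemisphere
#'
#' Deterministic Fibonacci-spiral construction; adequate for tensor fitting
#' on phantoms.
#'
#' @param n number of directions.
#' @return An \code{n x 3} matrix of unit vectors.
#' @export
gradient_scheme <- function(n = 12L) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default single-bundle diffusion phantom
#'
#' A straight bundle along x connecting two end regions in a 20 x 12 x 8
#' grid, with white-matter-like diffusivities (axial 1.7e-3, radial 0.3e-3
#' mm^2/s; FA about 0.78), gray-matter-like isotropic background
#' (0.7e-3 mm^2/s), 12 gradient directions at b = 1000 s/mm^2 plus 2 b = 0
#' volumes.
#'
#' @param seed integer seed.
#' @param noise_sigma Rician noise scale (default 0).
#' @param geometry bundle geometry, \code{"straight"} or \code{"arc"}.
#' @param lambda_perp radial diffusivity of the bundle.
#' @return A \code{\link{diffusion_phantom_spec}}.
#' @export
default_dwi_spec <- function(seed = 1L, noise_sigma = 0,
                             geometry = "straight", lambda_perp = 0.3e-3) {
  grid <- c(20L, 12L, 8L)
  bund <- if (geometry == "straight") {
    bundle_spec("straight", from = c(4, 6, 4), to = c(17, 6, 4),
                radius = 1.6, lambda_perp = lambda_perp)
  } else {
    bundle_spec("arc", from = c(4, 9, 4), to = c(17, 9, 4),
                radius = 1.6, lambda_perp = lambda_perp)
  }
  dirs <- gradient_scheme(12L)
  diffusion_phantom_spec(grid_shape = grid, bundles = list(bund),
                         b_values = c(0, 0, rep(1000, 12)),
                         b_vectors = rbind(matrix(0, 2, 3), dirs),
                         noise_sigma = noise_sigma, seed = seed)
}
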