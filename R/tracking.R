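## Probabilistic streamline tractography on a fitted tensor field, and
## structural connectome construction from streamline endpoint regions.

## von Mises-Fisher sample on the sphere around unit vector mu
## (Ulrich/Wood inversion for the vMF marginal of cos(angle)).
sample_vmf <- function(mu, kappa) {
  if (kappa <= 0) {
    v <- stats::rnorm(3)
    return(unit3(v))
  }
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  theta <- stats::runif(1, 0, 2 * pi)
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- unit3(cross3(mu, a))
  v2 <- cross3(mu, v1)
  w * mu + sqrt(max(0, 1 - w^2)) * (cos(theta) * v1 + sin(theta) * v2)
}

#' Probabilistic streamline tractography
#'
#' From each seed voxel, propagates \code{n_samples_per_seed} streamlines in
#' both directions. At every step the direction is drawn from a von
#' Mises-Fisher cone (concentration \code{dispersion_kappa}) around the
#' principal eigenvector of the local tensor (nearest-voxel lookup),
#' sign-aligned with the previous direction. Propagation terminates on
#' FA below \code{fa_stop}, turning angle above \code{angle_limit_deg},
#' leaving the mask/grid, or \code{max_steps}. The two half-tracks share
#' their initial direction (one of them negated), so the joined polyline
#' also respects the angle limit.
#'
#' @param tf a \code{tensor_field} from \code{\link{fit_tensor}}.
#' @param seed_mask logical 3D array of seed voxels (must be nonempty and
#'   within the valid-tensor region).
#' @param params list overriding any of: \code{step_size} (0.5 voxel),
#'   \code{max_steps} (200 per direction), \code{angle_limit_deg} (60),
#'   \code{fa_stop} (0.15), \code{dispersion_kappa} (50),
#'   \code{n_samples_per_seed} (10).
#' @param seed integer RNG seed.
#' @return An object of class \code{streamline_set}: \code{streamlines}
#'   (list of point matrices, world coordinates), \code{seed_voxel}
#'   (matrix), \code{termination} (two reasons per streamline, one per
#'   direction), \code{params}.
#' @export
track_probabilistic <- function(tf, seed_mask, params = list(), seed = 1L) {
  stopifnot(inherits(tf, "tensor_field"))
  p <- utils::modifyList(list(step_size = 0.5, max_steps = 200L,
                              angle_limit_deg = 60, fa_stop = 0.15,
                              dispersion_kappa = 50, n_samples_per_seed = 10L),
                         params)
  if (!any(seed_mask)) stopf("seed mask is empty")
  ok <- tf$mask & tf$valid
  if (any(seed_mask & !ok)) stopf("seed mask contains invalid-tensor voxels")
  dims <- tf$dims
  cos_limit <- cos(p$angle_limit_deg * pi / 180)
  seeds <- which(seed_mask)
  seed_ijk <- arrayInd(seeds, dims)
  lin_index <- function(v) v[1] + dims[1] * (v[2] - 1 + dims[2] * (v[3] - 1))
  ## voxel ownership is half-open [i, i+1) in 0-based world coordinates;
  ## with unit voxels this is floor(x) + 1 in 1-based indices.
  vox_of <- function(pt) floor(pt) + 1
  in_grid <- function(v) all(v >= 1) && all(v <= dims)
  e1_at <- function(li, ref) {
    e <- tf$e1[li, ]
    if (sum(e * ref) < 0) -e else e
  }
  propagate <- function(start, dir0) {
    pts <- matrix(start, 1, 3)
    dir <- dir0
    reason <- "max-steps"
    for (s in seq_len(p$max_steps)) {
      nxt <- pts[nrow(pts), ] + p$step_size * dir
      v <- vox_of(nxt)
      if (!in_grid(v)) { reason <- "left-mask"; break }
      li <- lin_index(v)
      if (!ok[li]) { reason <- "left-mask"; break }
      if (tf$fa[li] < p$fa_stop) { reason <- "low-fa"; break }
      pts <- rbind(pts, nxt)
      mu <- e1_at(li, dir)
      cand <- sample_vmf(mu, p$dispersion_kappa)
      if (sum(cand * dir) < 0) cand <- -cand
      if (sum(cand * dir) < cos_limit) { reason <- "angle"; break }
      dir <- cand
    }
    list(pts = pts, reason = reason)
  }
  streamlines <- list(); term <- list(); seed_of <- list()
  with_seed(seed, {
    n <- 0L
    for (si in seq_along(seeds)) {
      ijk <- seed_ijk[si, ]
      start <- ijk - 0.5                       # voxel center, 0-based world
      li <- lin_index(ijk)
      for (rep in seq_len(p$n_samples_per_seed)) {
        n <- n + 1L
        if (tf$fa[li] < p$fa_stop) {
          streamlines[[n]] <- matrix(start, 1, 3)
          term[[n]] <- c("low-fa", "low-fa")
          seed_of[[n]] <- ijk
          next
        }
        d0 <- sample_vmf(e1_at(li, tf$e1[li, ]), p$dispersion_kappa)
        h1 <- propagate(start, d0)
        h2 <- propagate(start, -d0)
        pts <- rbind(h2$pts[rev(seq_len(nrow(h2$pts))[-1]), , drop = FALSE],
                     h1$pts)
        streamlines[[n]] <- unname(pts)
        term[[n]] <- c(h2$reason, h1$reason)
        seed_of[[n]] <- ijk
      }
    }
  })
  structure(list(streamlines = streamlines,
                 seed_voxel = do.call(rbind, seed_of),
                 termination = do.call(rbind, term),
                 params = p),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  len <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<streamline_set> %d streamlines, %d-%d points (median %g)\n",
              length(len), min(len), max(len), stats::median(len)))
  invisible(x)
}

#' Build a structural connectome from streamlines and a parcellation
#'
#' Each streamline increments the count of the unordered pair of the first
#' and the last labeled regions it passes through (endpoint convention).
#' Streamlines touching fewer than two labeled regions are ignored and
#' tallied. Edge weights are \code{ln(1 + count)}; the diagonal is forced to
#' zero (self-connections excluded).
#'
#' @param sl a \code{streamline_set}.
#' @param labels a \code{label_volume} (integer 3D array, 0 = background)
#'   sharing the tensor-field voxel space.
#' @return An object of class \code{connectome}: \code{counts} (R x R
#'   symmetric integer matrix), \code{weights} (\code{log1p} of counts),
#'   \code{region_ids}, \code{n_discarded}.
#' @export
build_connectome <- function(sl, labels) {
  stopifnot(inherits(sl, "streamline_set"), is.array(labels))
  dims <- dim(labels)
  nreg <- max(labels)
  if (nreg < 1L) stopf("label volume has no regions")
  counts <- matrix(0L, nreg, nreg)
  discarded <- 0L
  for (pts in sl$streamlines) {
    v <- floor(pts) + 1
    inb <- v[, 1] >= 1 & v[, 1] <= dims[1] & v[, 2] >= 1 & v[, 2] <= dims[2] &
      v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- v[inb, , drop = FALSE]
    if (!nrow(v)) { discarded <- discarded + 1L; next }
    labs <- labels[cbind(v[, 1], v[, 2], v[, 3])]
    hit <- labs > 0L
    if (!any(hit)) { discarded <- discarded + 1L; next }
    a <- labs[which(hit)[1]]
    b <- labs[which(hit)[sum(hit)]]
    if (a == b) { discarded <- discarded + 1L; next }
    counts[a, b] <- counts[a, b] + 1L
    counts[b, a] <- counts[b, a] + 1L
  }
  diag(counts) <- 0L
  structure(list(counts = counts, weights = log1p(counts),
                 region_ids = seq_len(nreg), n_discarded = discarded),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions, %d streamline hits, %d discarded\n",
              nrow(x$counts), sum(x$counts) / 2, x$n_discarded))
  invisible(x)
}
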