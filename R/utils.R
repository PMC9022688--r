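## Internal helpers: error formatting, seeded RNG scoping, geometry.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a deterministic substream seed from a master seed
#'
#' Expands one user-facing integer seed into independent per-subject /
#' per-stage seeds by fixed prime offsets, keeping the result a valid 32-bit
#' integer.
#'
#' @param seed master integer seed.
#' @param index substream index (e.g. subject number), nonnegative integer.
#' @param stream secondary stream id (e.g. group or stage), nonnegative integer.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, index = 0L, stream = 0L) {
  s <- (abs(as.double(seed)) %% 1000003) + 7919 * as.double(index) +
    104729 * as.double(stream)
  as.integer(s %% 2147483629)
}

## Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
## state; all exported stochastic operations go through this, which is what
## makes every stage bit-reproducible under a fixed seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("%s must be a square matrix", name)
  if (any(abs(m - t(m)) > tol, na.rm = TRUE))
    stopf("%s must be symmetric", name)
  invisible(TRUE)
}

#' Ellipsoidal brain mask for a voxel grid
#'
#' The phantom "brain" is a centered ellipsoid whose semi-axes are 90% of the
#' half-extent of the grid in each dimension. This leaves a well-defined
#' outermost shell used to place (and later detect) edge noise components.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @return A logical 3D array.
#' @export
brain_mask <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  ctr <- (grid_shape + 1) / 2
  semi <- 0.9 * grid_shape / 2
  x <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= 1, dim = grid_shape)
}

#' Outermost shell of a binary mask
#'
#' Mask voxels with at least one 6-neighbour outside the mask (or on the grid
#' boundary). Used by the noise-component generator and classifier.
#'
#' @param mask logical 3D array.
#' @return A logical 3D array, subset of \code{mask}.
#' @export
mask_edge <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  inner & !nb
}

## voxel-center coordinates (1-based indices) for all voxels of a grid
voxel_centers <- function(grid_shape) {
  as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                        y = seq_len(grid_shape[2]),
                        z = seq_len(grid_shape[3])))
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

md5_of_files <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}
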