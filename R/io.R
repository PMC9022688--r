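## File I/O: NIfTI volumes (via RNifti), TSV matrices and time courses,
## FSL-style bval/bvec files, and a plain-text streamline format.

#' Write a 3D/4D volume as NIfTI-1
#'
#' Accepts an \code{\link{image4d}}, a \code{label_volume}, or a bare 3D/4D
#' array (optionally with an \code{affine} attribute).
#'
#' @param x volume to write.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path) {
  affine <- diag(4)
  if (inherits(x, "image4d")) {
    affine <- x$affine
    arr <- x$data
  } else {
    arr <- unclass(x)
    affine <- attr(x, "affine") %||% diag(4)
    attr(arr, "affine") <- NULL
    attr(arr, "mask") <- NULL
  }
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  im <- RNifti::asNifti(arr)
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param tr repetition time to attach when reading a 4D series; default
#'   taken from the header pixdim.
#' @return For 4D input an \code{\link{image4d}}; for 3D input a plain array
#'   with an \code{affine} attribute.
#' @export
read_nifti <- function(path, tr = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  im <- RNifti::readNifti(path)
  affine <- structure(unclass(RNifti::xform(im)), imagedim = NULL, code = NULL)
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))      # strip RNifti header attributes
  if (length(dim(arr)) == 4L) {
    tr <- tr %||% {
      pd <- attr(im, "pixdim")
      if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    }
    image4d(arr, affine = affine[1:4, 1:4], tr = tr)
  } else {
    attr(arr, "affine") <- affine[1:4, 1:4]
    arr
  }
}

#' Write a matrix as TSV with a header of ids
#'
#' @param m matrix; column names are written as the header (generated as
#'   \code{V1..Vn} if absent).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV matrix written by \code{\link{write_matrix_tsv}}
#'
#' @param path input path.
#' @param symmetric require the matrix to be symmetric (error if not).
#' @return A numeric matrix with the header as column names.
#' @export
read_matrix_tsv <- function(path, symmetric = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("%s: matrix contains non-numeric entries", path)
  if (symmetric) {
    if (nrow(m) != ncol(m))
      stopf("%s: expected a square matrix, got %d x %d", path, nrow(m), ncol(m))
    if (any(abs(m - t(m)) > 1e-8))
      stopf("%s: matrix is not symmetric", path)
  }
  m
}

#' Read FSL-style bval/bvec files
#'
#' \code{bval}: one row of b-values. \code{bvec}: three rows (x, y, z
#' components), one column per volume. Non-unit vectors at nonzero b are
#' normalized with a warning.
#'
#' @param bval_path,bvec_path file paths.
#' @return A list with \code{b_values} and \code{b_vectors} (n x 3).
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec_rows) != 3L)
    stopf("%s: expected 3 rows of vector components, got %d",
          bvec_path, nrow(bvec_rows))
  if (ncol(bvec_rows) != length(bvals))
    stopf("bval/bvec mismatch: %d b-values vs %d vectors",
          length(bvals), ncol(bvec_rows))
  g <- t(bvec_rows)
  nz <- bvals > 0
  norms <- sqrt(rowSums(g^2))
  if (any(abs(norms[nz] - 1) > 1e-4)) {
    warnf("non-unit b-vectors normalized on read")
    g[nz, ] <- g[nz, ] / norms[nz]
  }
  list(b_values = bvals, b_vectors = unname(g))
}

#' Write FSL-style bval/bvec files
#'
#' @param b_values numeric vector.
#' @param b_vectors n x 3 matrix.
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_bvalbvec <- function(b_values, b_vectors, bval_path, bvec_path) {
  writeLines(paste(format(b_values, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(b_vectors), 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Write streamlines as plain text
#'
#' One streamline per block: a comment line with index and termination
#' reasons, then one \code{x y z} line per point; blocks separated by blank
#' lines.
#'
#' @param sl a \code{streamline_set}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_streamlines <- function(sl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sl$streamlines)) {
    writeLines(sprintf("# %d %s %s", i, sl$termination[i, 1],
                       sl$termination[i, 2]), con)
    pts <- sl$streamlines[[i]]
    writeLines(apply(pts, 1, function(r)
      paste(format(r, digits = 10, trim = TRUE), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read streamlines written by \code{\link{write_streamlines}}
#'
#' @param path input path.
#' @return A \code{streamline_set} (without seed-voxel information).
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  streamlines <- list(); term <- list()
  cur <- NULL; cur_term <- c(NA, NA); n <- 0L
  flush <- function() {
    if (!is.null(cur) && nrow(cur)) {
      n <<- n + 1L
      streamlines[[n]] <<- cur
      term[[n]] <<- cur_term
    }
  }
  for (ln in lines) {
    if (grepl("^#", ln)) {
      flush()
      parts <- strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]
      cur_term <- parts[2:3]
      cur <- matrix(numeric(0), 0, 3)
    } else if (nzchar(trimws(ln))) {
      cur <- rbind(cur, as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    }
  }
  flush()
  structure(list(streamlines = streamlines, seed_voxel = NULL,
                 termination = do.call(rbind, term), params = list()),
            class = "streamline_set")
}

#' Write phantom ground truth as a JSON sidecar plus TSV time courses
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulate_rsfmri}}.
#' @param json_path path for the JSON sidecar (cluster assignment, noise
#'   flags, mask summary).
#' @param tc_path path for the TSV of true time courses (one column per
#'   component, header = component id).
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, json_path, tc_path) {
  side <- list(cluster = truth$cluster,
               is_noise = truth$is_noise,
               n_mask_voxels = sum(truth$mask),
               grid_shape = dim(truth$mask))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(truth$timecourses, tc_path)
  invisible(c(json_path, tc_path))
}
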