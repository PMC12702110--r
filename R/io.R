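#' Write and read FSL-dialect bval/bvec files
#'
#' `write_bval_bvec()` writes the b-values as a single space-separated row
#' and the directions as three rows (x, y, z) of N columns.
#' `read_bval_bvec()` reads the pair back.
#'
#' @param bvals numeric vector of length N.
#' @param bvecs N x 3 matrix of unit directions.
#' @param bval_path,bvec_path file paths.
#' @return `read_bval_bvec()` returns `list(bvals, bvecs)` with `bvecs`
#'   N x 3.
#' @export
write_bval_bvec <- function(bvals, bvecs, bval_path, bvec_path) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3L)
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1, function(r) {
    paste(formatC(r, format = "g", digits = 15), collapse = " ")
  }), bvec_path)
  invisible(NULL)
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  bvecs <- t(do.call(rbind, rows))
  stopifnot(ncol(bvecs) == 3L, nrow(bvecs) == length(bvals))
  list(bvals = bvals, bvecs = bvecs)
}

#' Write a DWI stack to NIfTI with sidecars
#'
#' Writes the 4D magnitude data as NIfTI, the b-values/directions as
#' FSL-dialect `.bval`/`.bvec`, and the stratum metadata (direction index,
#' shell, stratum id, repetition, injected-outlier truth) as a JSON sidecar.
#'
#' @param stack a `dwi_stack`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`, `<prefix>.json`.
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(stack, prefix) {
  arr <- dwi_as_array(stack)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), nii)
  write_bval_bvec(stack$meta$b, as.matrix(stack$meta[, c("gx", "gy", "gz")]),
                  paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  side <- list(
    plan = stack$plan$name,
    sigma = stack$sigma,
    seed = stack$seed,
    volumes = stack$meta[, c("shell", "direction", "stratum", "repetition",
                             "b", "outlier", "bias")]
  )
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, c(".nii.gz", ".bval", ".bvec", ".json")))
}

#' Read a 4D DWI NIfTI with bval/bvec (real-data mode)
#'
#' Loads a 4D NIfTI stack, its FSL-dialect gradient files, and an optional
#' binary mask, and assembles a `dwi_stack` whose strata are defined by
#' unique (b-value, direction) pairs.
#'
#' @param nii_path 4D NIfTI path.
#' @param bval_path,bvec_path gradient table paths.
#' @param mask_path optional NIfTI mask; defaults to all voxels with
#'   positive signal in every volume.
#' @param slice which slice of a multi-slice stack to analyze.
#' @return a `dwi_stack`.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path, mask_path = NULL,
                     slice = 1L) {
  img <- as.array(RNifti::readNifti(nii_path))
  if (length(dim(img)) == 3L) dim(img) <- c(dim(img)[1:2], 1L, dim(img)[3])
  stopifnot(length(dim(img)) == 4L)
  grad <- read_bval_bvec(bval_path, bvec_path)
  nvol <- dim(img)[4]
  stopifnot(length(grad$bvals) == nvol)
  sl <- img[, , slice, , drop = FALSE]
  mask <- if (is.null(mask_path)) {
    apply(sl > 0, c(1, 2), all)[, , drop = TRUE]
  } else {
    as.array(RNifti::readNifti(mask_path))[, , slice] > 0
  }
  vox <- which(mask, arr.ind = TRUE)
  data <- matrix(0, nrow(vox), nvol)
  for (v in seq_len(nvol)) {
    data[, v] <- sl[, , 1L, v][vox]
  }
  key <- paste(round(grad$bvals), apply(round(abs(grad$bvecs), 5), 1, paste,
                                        collapse = ","))
  stratum <- as.integer(factor(key, levels = unique(key)))
  meta <- data.frame(
    shell = ifelse(grad$bvals >= 100, 2L, 1L),
    direction = stratum, stratum = stratum,
    repetition = stats::ave(seq_len(nvol), stratum, FUN = seq_along),
    b = grad$bvals,
    gx = grad$bvecs[, 1], gy = grad$bvecs[, 2], gz = grad$bvecs[, 3],
    outlier = FALSE, bias = 1
  )
  structure(
    list(data = data, meta = meta, mask = mask, voxels = vox,
         plan = NULL, s0 = NA_real_, sigma = NA_real_, seed = NA_integer_),
    class = "dwi_stack"
  )
}

#' Write a direction scheme as bvec/bval plus JSON
#'
#' @param scheme a `direction_scheme`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_scheme <- function(scheme, prefix) {
  n <- nrow(scheme$directions)
  write_bval_bvec(rep(scheme$b_value, n), scheme$directions,
                  paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  jsonlite::write_json(
    list(name = scheme$name, b_value = scheme$b_value, n_directions = n,
         condition_number = if (n >= 6) condition_number(scheme) else NULL,
         directions = scheme$directions),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(prefix, c(".bval", ".bvec", ".json")))
}

#' Read a direction scheme from a JSON scheme file
#'
#' @param path JSON file written by [write_scheme()].
#' @return a `direction_scheme`.
#' @export
read_scheme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  direction_scheme(j$directions, as.numeric(j$b_value), j$name)
}
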