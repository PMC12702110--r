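#' Center of mass of a mask
#'
#' Unweighted centroid of the masked voxel coordinates of one slice; origin
#' of the cylindrical ventricular coordinate system.
#'
#' @param mask logical matrix.
#' @return numeric `c(x, y)` in voxel coordinates.
#' @export
center_of_mass <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  colMeans(idx)
}

#' Local cylindrical frame at a voxel
#'
#' Radial = in-plane unit vector from the LV center to the voxel;
#' longitudinal = slice normal; circumferential = longitudinal x radial
#' (counter-clockwise when viewed from base, i.e. along +z). The triad is
#' orthonormal and right-handed: `det(radial, circ, long) = +1`.
#'
#' @param voxel `c(x, y)` voxel coordinates.
#' @param center LV center from [center_of_mass()].
#' @param slice_normal unit 3-vector, default `c(0, 0, 1)`.
#' @return list with unit 3-vectors `radial`, `circ`, `long`.
#' @export
local_frame <- function(voxel, center, slice_normal = c(0, 0, 1)) {
  d <- c(voxel[1] - center[1], voxel[2] - center[2], 0)
  if (sqrt(sum(d^2)) < 1e-9) stop("voxel coincides with the LV center")
  radial <- d / sqrt(sum(d^2))
  long <- slice_normal / sqrt(sum(slice_normal^2))
  circ <- cross3(long, radial)
  list(radial = radial, circ = circ, long = long)
}

#' Mean diffusivity and fractional anisotropy of a tensor
#'
#' `tensor_md()` is the trace divided by 3. `tensor_fa()` is the normalized
#' eigenvalue dispersion `sqrt(3/2) * ||l - mean(l)|| / ||l||`, with
#' negative eigenvalues clipped to 0 first (prevents FA > 1 on noisy fits);
#' the zero tensor has FA 0 by convention.
#'
#' @param tensor 3x3 symmetric matrix, or length-6 vector
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @return scalar MD (mm^2/s) or FA (dimensionless).
#' @export
tensor_md <- function(tensor) {
  D <- as_tensor_matrix(tensor)
  sum(diag(D)) / 3
}

#' @rdname tensor_md
#' @export
tensor_fa <- function(tensor) {
  D <- as_tensor_matrix(tensor)
  l <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  fa_from_eigenvalues(l)
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor) && all(dim(tensor) == c(3, 3))) {
    if (max(abs(tensor - t(tensor))) > 1e-9 * max(1, max(abs(tensor)))) {
      stop("tensor must be symmetric")
    }
    return(tensor)
  }
  d <- as.numeric(tensor)
  stopifnot(length(d) == 6L)
  matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
}

## map an angle in degrees to (-90, 90]
wrap_halfcircle <- function(a) {
  a <- (a + 90) %% 180 - 90
  ifelse(a == -90, 90, a)
}

#' Helix angle of the primary eigenvector
#'
#' Projects `e1` onto the circumferential-longitudinal (wall-tangent) plane
#' and returns the signed angle from circumferential toward longitudinal,
#' in `(-90, 90]`. Invariant to the eigenvector sign (`e1` and `-e1` give
#' the same angle). If `e1` is (numerically) parallel to the radial
#' direction the projection is undefined and `NA` is returned.
#'
#' @param e1 unit 3-vector, primary eigenvector.
#' @param frame local frame from [local_frame()].
#' @return helix angle in degrees, or `NA`.
#' @export
helix_angle <- function(e1, frame) {
  pc <- sum(e1 * frame$circ)
  pl <- sum(e1 * frame$long)
  if (sqrt(pc^2 + pl^2) < 1e-6) return(NA_real_)
  wrap_halfcircle(atan2(pl, pc) * 180 / pi)
}

#' Sheetlet angle of the secondary eigenvector
#'
#' The cross-myocyte direction is the wall-tangent vector orthogonal to the
#' projection of `e1` into the wall-tangent plane. E2A is the signed angle
#' between the projection of `e2` onto the cross-myocyte-radial plane and
#' the cross-myocyte direction, positive toward radial, in `(-90, 90]`.
#' Invariant to sign flips of both eigenvectors.
#'
#' @param e2 unit 3-vector, secondary eigenvector.
#' @param e1 unit 3-vector, primary eigenvector (defines cross-myocyte).
#' @param frame local frame from [local_frame()].
#' @return sheetlet angle in degrees, or `NA` when degenerate.
#' @export
sheetlet_angle <- function(e2, e1, frame) {
  ha <- helix_angle(e1, frame)
  if (is.na(ha)) return(NA_real_)
  har <- ha * pi / 180
  cm <- -sin(har) * frame$circ + cos(har) * frame$long
  pcm <- sum(e2 * cm)
  pr <- sum(e2 * frame$radial)
  if (sqrt(pcm^2 + pr^2) < 1e-6) return(NA_real_)
  wrap_halfcircle(atan2(pr, pcm) * 180 / pi)
}

#' Cardiac metric maps from fitted tensors
#'
#' Computes MD, FA, helix angle, sheetlet angle and its magnitude for every
#' voxel of a tensor set in its local cylindrical frames. Negative fitted
#' eigenvalues are clipped to zero for the scalar metrics.
#'
#' @param tensors V x 6 matrix (`Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`), or a
#'   `dti_fit`.
#' @param frames V x 9 matrix of local frames (radial, circumferential,
#'   longitudinal), as stored in an `lv_phantom`.
#' @param engine `"cpp"` (default, compiled) or `"r"` (plain R path built
#'   from [helix_angle()] and [sheetlet_angle()]; same results, used as a
#'   cross-check).
#' @return list of numeric vectors `md`, `fa`, `ha`, `e2a`, `abs_e2a`
#'   (length V; angles `NA` where degenerate).
#' @export
metric_maps <- function(tensors, frames, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(tensors, "dti_fit")) tensors <- tensors$tensors
  tensors <- rbind(tensors)
  nv <- nrow(tensors)
  stopifnot(nrow(frames) == nv, ncol(frames) == 9L)
  if (engine == "cpp") {
    out <- .metric_maps_engine(tensors, as.matrix(frames))
    return(list(md = as.numeric(out$md), fa = as.numeric(out$fa),
                ha = as.numeric(out$ha), e2a = as.numeric(out$e2a),
                abs_e2a = abs(as.numeric(out$e2a))))
  }
  md <- fa <- ha <- e2a <- numeric(nv)
  for (i in seq_len(nv)) {
    D <- as_tensor_matrix(tensors[i, ])
    eg <- eigen(D, symmetric = TRUE)
    l <- pmax(eg$values, 0)
    md[i] <- mean(eg$values)
    fa[i] <- fa_from_eigenvalues(l)
    fr <- list(radial = frames[i, 1:3], circ = frames[i, 4:6],
               long = frames[i, 7:9])
    ha[i] <- helix_angle(eg$vectors[, 1], fr)
    e2a[i] <- sheetlet_angle(eg$vectors[, 2], eg$vectors[, 1], fr)
  }
  list(md = md, fa = fa, ha = ha, e2a = e2a, abs_e2a = abs(e2a))
}
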