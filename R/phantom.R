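#' Specification of the digital left-ventricle phantom
#'
#' Describes a single short-axis mid-ventricular slice as an annulus with
#' transmurally varying myocyte orientation. The helix angle varies linearly
#' from `ha_epi` at the epicardium to `ha_endo` at the endocardium; the
#' sheetlet angle has constant magnitude with sign alternating between
#' angular sectors (so that signed sheetlet angles cancel in slice averages,
#' as observed in vivo). Diffusivity defaults reproduce healthy myocardium:
#' MD 1.46e-3 mm^2/s, FA 0.35.
#'
#' @param grid_size voxels per side of the square slice.
#' @param voxel_size_mm in-plane voxel size (2.3 mm).
#' @param center voxel coordinates of the LV long axis (defaults to the grid
#'   center).
#' @param r_endo_mm,r_epi_mm endocardial/epicardial radii in mm.
#' @param ha_endo,ha_epi helix angle at endo/epicardium, degrees.
#' @param e2a_magnitude sheetlet angle magnitude, degrees.
#' @param e2a_sectors number of angular sectors over which the sheetlet
#'   angle sign alternates.
#' @param md mean diffusivity, mm^2/s.
#' @param fa fractional anisotropy.
#' @param rho secondary/tertiary eigenvalue ratio lambda2/lambda3.
#' @return object of class `lv_phantom_spec`.
#' @export
lv_phantom_spec <- function(grid_size = 64L, voxel_size_mm = 2.3,
                            center = NULL,
                            r_endo_mm = 11.5, r_epi_mm = 29.9,
                            ha_endo = 60, ha_epi = -60,
                            e2a_magnitude = 33, e2a_sectors = 6L,
                            md = 1.46e-3, fa = 0.35, rho = 1.55) {
  if (r_endo_mm >= r_epi_mm) stop("endocardial radius must be below epicardial")
  if (fa <= 0 || fa >= 1) stop("fa must lie in (0, 1)")
  if (md <= 0) stop("md must be positive")
  if (r_epi_mm > grid_size / 2 * voxel_size_mm) {
    stop("epicardial radius exceeds the grid")
  }
  structure(
    list(
      grid_size = as.integer(grid_size), voxel_size_mm = voxel_size_mm,
      center = center %||% rep((grid_size + 1) / 2, 2),
      r_endo_mm = r_endo_mm, r_epi_mm = r_epi_mm,
      ha_endo = ha_endo, ha_epi = ha_epi,
      e2a_magnitude = e2a_magnitude, e2a_sectors = as.integer(e2a_sectors),
      md = md, fa = fa, rho = rho
    ),
    class = "lv_phantom_spec"
  )
}

#' Eigenvalues with prescribed mean diffusivity and anisotropy
#'
#' Solves for `(lambda1, lambda2, lambda3)` with `lambda2 = rho * lambda3`,
#' mean equal to `md` and fractional anisotropy equal to `fa`, by a 1-D root
#' search on `lambda3`. Errors if no ordered positive solution exists for
#' the requested anisotropy at the given shape ratio.
#'
#' @param md mean diffusivity (mm^2/s).
#' @param fa target fractional anisotropy in `[0, 1)`.
#' @param rho ratio `lambda2 / lambda3 >= 1`.
#' @return numeric vector `c(l1, l2, l3)`, decreasing, positive; achieved FA
#'   within 1e-8 of the target.
#' @export
eigenvalues_for <- function(md, fa, rho = 1.55) {
  stopifnot(md > 0, fa >= 0, fa < 1, rho >= 1)
  if (fa == 0) {
    if (rho > 1) stop("fa = 0 requires rho = 1 (isotropic)")
    return(rep(md, 3))
  }
  lam <- function(l3) c(3 * md - (rho + 1) * l3, rho * l3, l3)
  f <- function(l3) fa_from_eigenvalues(lam(l3)) - fa
  ## l3 ranges over (0, l3_iso]; l3_iso makes the tensor as isotropic as the
  ## shape ratio allows. FA decreases monotonically in l3 on this interval.
  l3_iso <- 3 * md / (1 + rho + max(rho, 1)) # l1 = l2 at this l3
  l3_hi <- min(l3_iso, 3 * md / (rho + 1) * 0.999999)
  if (f(l3_hi) > 0) stop("fa too low to achieve with this rho")
  l3_lo <- 1e-12 * md
  if (f(l3_lo) < 0) stop("fa infeasible for given rho")
  r <- stats::uniroot(f, c(l3_lo, l3_hi), tol = 1e-16 * md)
  l <- lam(r$root)
  if (any(l <= 0) || is.unsorted(rev(l))) stop("fa infeasible for given rho")
  if (abs(fa_from_eigenvalues(l) - fa) > 1e-8) stop("eigenvalue solve failed")
  l
}

fa_from_eigenvalues <- function(l) {
  l <- pmax(l, 0)
  m <- mean(l)
  den <- sqrt(sum(l^2))
  if (den == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((l - m)^2)) / den
}

#' Assemble a diffusion tensor from orientation angles
#'
#' Builds the symmetric positive-definite tensor whose primary eigenvector
#' lies in the circumferential-longitudinal (wall-tangent) plane at helix
#' angle `ha` from circumferential, and whose secondary eigenvector sits at
#' sheetlet angle `e2a` from the cross-myocyte direction within the
#' cross-myocyte-radial plane.
#'
#' @param eigenvalues decreasing positive `c(l1, l2, l3)`.
#' @param frame list or 3x3 matrix with unit columns/elements `radial`,
#'   `circumferential`, `longitudinal` (orthonormal, right-handed).
#' @param ha helix angle, degrees.
#' @param e2a sheetlet angle, degrees.
#' @return 3x3 symmetric positive-definite matrix.
#' @export
tensor_from_orientation <- function(eigenvalues, frame, ha, e2a) {
  l <- eigenvalues
  stopifnot(length(l) == 3, all(l > 0), !is.unsorted(rev(l)))
  fr <- as_frame(frame)
  if (abs(l[2] - l[3]) < 1e-15 * l[1] && abs(e2a) > 1e-12) {
    stop("e2a is unidentifiable when lambda2 = lambda3")
  }
  har <- ha * pi / 180
  e2r <- e2a * pi / 180
  e1 <- cos(har) * fr$circ + sin(har) * fr$long
  ## cross-myocyte: orthogonal to e1 within the wall-tangent plane
  cm <- -sin(har) * fr$circ + cos(har) * fr$long
  e2 <- cos(e2r) * cm + sin(e2r) * fr$radial
  e3 <- cross3(e1, e2)
  l[1] * tcrossprod(e1) + l[2] * tcrossprod(e2) + l[3] * tcrossprod(e3)
}

as_frame <- function(frame) {
  if (is.list(frame)) {
    fr <- list(radial = frame$radial, circ = frame$circ %||% frame$circumferential,
               long = frame$long %||% frame$longitudinal)
  } else {
    frame <- as.matrix(frame)
    fr <- list(radial = frame[, 1], circ = frame[, 2], long = frame[, 3])
  }
  M <- cbind(fr$radial, fr$circ, fr$long)
  if (max(abs(crossprod(M) - diag(3))) > 1e-9) stop("frame is not orthonormal")
  fr
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the left-ventricle phantom volume
#'
#' Rasterizes the annular mask, computes the transmural depth
#' `d = (r_epi - r) / (r_epi - r_endo)` (0 at epi, 1 at endo, clipped to
#' `[0, 1]`), assigns local cylindrical frames, orientation angles and the
#' ground-truth tensor field, and records the ground-truth metric maps.
#'
#' @param spec an [lv_phantom_spec()].
#' @return object of class `lv_phantom`: `mask` (logical matrix), `depth`,
#'   ground-truth maps `md`, `fa`, `ha`, `e2a` (matrices, `NA` off-mask),
#'   `frames` (V x 9 matrix: radial, circumferential, longitudinal per masked
#'   voxel), `tensors` (V x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `voxels`
#'   (V x 2 voxel indices), `center`, `spec`.
#' @export
make_lv_phantom <- function(spec = lv_phantom_spec()) {
  stopifnot(inherits(spec, "lv_phantom_spec"))
  n <- spec$grid_size
  vx <- spec$voxel_size_mm
  ix <- rep(seq_len(n), times = n)
  iy <- rep(seq_len(n), each = n)
  dx <- (ix - spec$center[1]) * vx
  dy <- (iy - spec$center[2]) * vx
  r <- sqrt(dx^2 + dy^2)
  inside <- r >= spec$r_endo_mm & r <= spec$r_epi_mm
  mask <- matrix(inside, n, n)

  vox <- cbind(ix[inside], iy[inside])
  rv <- r[inside]
  az <- atan2(dy[inside], dx[inside])
  depth_v <- pmin(pmax((spec$r_epi_mm - rv) / (spec$r_epi_mm - spec$r_endo_mm), 0), 1)

  ## local cylindrical frames: radial outward, longitudinal = +z (slice
  ## normal), circumferential = long x radial (counter-clockwise seen from
  ## base, i.e. +z)
  radial <- cbind(cos(az), sin(az), 0)
  long <- matrix(rep(c(0, 0, 1), each = length(az)), ncol = 3)
  circ <- cbind(-sin(az), cos(az), 0)

  ha_v <- spec$ha_epi + depth_v * (spec$ha_endo - spec$ha_epi)
  sector <- floor((az + pi) / (2 * pi / spec$e2a_sectors))
  e2a_v <- spec$e2a_magnitude * ifelse(sector %% 2 == 0, 1, -1)

  lam <- eigenvalues_for(spec$md, spec$fa, spec$rho)
  nv <- nrow(vox)
  tensors <- matrix(0, nv, 6)
  for (i in seq_len(nv)) {
    fr <- list(radial = radial[i, ], circ = circ[i, ], long = long[i, ])
    D <- tensor_from_orientation(lam, fr, ha_v[i], e2a_v[i])
    tensors[i, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }

  fill <- function(v) {
    m <- matrix(NA_real_, n, n)
    m[vox] <- v
    m
  }
  structure(
    list(
      mask = mask,
      depth = fill(depth_v),
      md = fill(rep(spec$md, nv)),
      fa = fill(rep(spec$fa, nv)),
      ha = fill(ha_v),
      e2a = fill(e2a_v),
      frames = cbind(radial, circ, long),
      tensors = tensors,
      voxels = vox,
      center = spec$center,
      spec = spec
    ),
    class = "lv_phantom"
  )
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf(
    "<lv_phantom> %dx%d grid (%.1f mm voxels), %d masked voxels, MD %.3g mm^2/s, FA %.2f\n",
    x$spec$grid_size, x$spec$grid_size, x$spec$voxel_size_mm,
    nrow(x$voxels), x$spec$md, x$spec$fa
  ))
  invisible(x)
}
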