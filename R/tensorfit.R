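#' Diffusion tensor design matrix
#'
#' Builds the N x 7 log-linear design: a leading column of ones (for
#' `ln S0`) followed by
#' `-b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` per volume, so that
#' `log(S) = X %*% c(ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`. Low b-value
#' volumes are ordinary diffusion-weighted rows — the protocol has no b = 0
#' reference.
#'
#' @param bvals numeric vector of b-values (s/mm^2), length N.
#' @param bvecs N x 3 matrix of unit directions (FSL-style 3 x N also
#'   accepted).
#' @return N x 7 design matrix.
#' @export
dti_design <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3L)
  cbind(1, -bvals * encoding_matrix(bvecs))
}

## design for every volume of a dwi_stack
stack_design <- function(stack) {
  dti_design(stack$meta$b, as.matrix(stack$meta[, c("gx", "gy", "gz")]))
}

#' Fit the diffusion tensor per voxel
#'
#' Fits the log-linear tensor signal representation to each voxel's signals
#' by one of three estimators:
#' \describe{
#'   \item{`"lls"`}{ordinary least squares on log-signals (closed form).}
#'   \item{`"wls"`}{weighted least squares with weights equal to the squared
#'     predicted signals of the previous iterate (LLS start, `wls_iter`
#'     passes, default 2); mitigates the signal-rectification bias of
#'     magnitude data.}
#'   \item{`"robust"`}{iteratively reweighted least squares combining the
#'     WLS weights with a Geman-McClure M-estimator weight
#'     `1 / (1 + u^2)^2` on residuals standardized by the MAD scale
#'     `1.4826 * mad`; iterates until the largest tensor-element change
#'     drops below `tol` (default 1e-8 mm^2/s) or `max_iter` iterations.
#'     Volumes whose final robust weight falls below `outlier_cutoff`
#'     (default 0.1) are flagged as outliers.}
#' }
#' Non-positive signals cannot be log-transformed and are clamped to
#' `floor_frac` times the voxel's maximum signal, with the affected voxels
#' flagged in `clamped`.
#'
#' @param signals V x N matrix of magnitude signals (rows = voxels), a
#'   vector for a single voxel, or a `dwi_stack` (in which case `design`
#'   is derived from its metadata).
#' @param design N x 7 matrix from [dti_design()].
#' @param method `"robust"`, `"wls"` or `"lls"`.
#' @param freq optional length-N non-negative frequency weights (bootstrap
#'   multiplicities); 0 removes a volume from the fit.
#' @param wls_iter WLS passes.
#' @param max_iter robust iteration cap.
#' @param tol convergence tolerance on tensor elements (mm^2/s).
#' @param outlier_cutoff robust weight below which a volume is an outlier.
#' @param floor_frac clamp floor for non-positive signals, as a fraction of
#'   the voxel maximum.
#' @return object of class `dti_fit` with `coefficients` (V x 7:
#'   `lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`), `tensors` (V x 6), `lnS0`,
#'   `weights` and `outliers` (V x N), `iterations`, `converged`,
#'   `clamped`, `method`, `design`, `freq`.
#' @examples
#' ph <- make_lv_phantom(lv_phantom_spec(grid_size = 16, r_endo_mm = 4.6,
#'                                       r_epi_mm = 13.8))
#' plan <- build_plan(icosahedral_scheme(), 30, 3)
#' stk <- simulate_dwi(ph, plan, noise = NULL)
#' fit <- dti_fit(stk)
#' max(abs(fit$tensors - ph$tensors)) # ~1e-18: exact recovery
#' @export
dti_fit <- function(signals, design = NULL,
                    method = c("robust", "wls", "lls"),
                    freq = NULL, wls_iter = 2L, max_iter = 50L,
                    tol = 1e-8, outlier_cutoff = 0.1,
                    floor_frac = 1e-6) {
  method <- match.arg(method)
  if (inherits(signals, "dwi_stack")) {
    if (is.null(design)) design <- stack_design(signals)
    signals <- signals$data
  }
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  design <- as.matrix(design)
  N <- nrow(design)
  stopifnot(ncol(signals) == N, ncol(design) == 7L)
  if (is.null(freq)) freq <- rep(1, N)
  stopifnot(length(freq) == N, all(freq >= 0))
  if (sum(freq > 0) < 7L) stop("need at least 7 active volumes to fit")
  if (method == "robust" && sum(freq > 0) < 10L) {
    warning("robust fitting with fewer than 10 volumes is unreliable")
  }

  ## volumes with zero frequency weight play no role in the fit; drop them
  ## before the per-voxel engine and re-expand afterwards
  active <- which(freq > 0)
  sig_a <- signals[, active, drop = FALSE]
  floor_v <- pmax(apply(sig_a, 1, max), 0) * floor_frac
  floor_v[floor_v <= 0] <- .Machine$double.xmin
  clamped <- sig_a < rep(floor_v, length(active))
  sig_a <- pmax(sig_a, rep(floor_v, length(active)))
  logS <- t(log(sig_a)) # N_active x V

  mcode <- match(method, c("lls", "wls", "robust")) - 1L
  eng <- .dti_fit_engine(logS, design[active, , drop = FALSE], freq[active],
                         mcode, as.integer(wls_iter),
                         as.integer(max_iter), tol, outlier_cutoff)
  coefs <- t(eng$coef) # V x 7
  V <- nrow(coefs)
  weights <- matrix(1, V, N)
  weights[, active] <- t(eng$weights)
  outl <- matrix(FALSE, V, N)
  outl[, active] <- t(eng$outliers) == 1
  structure(
    list(
      coefficients = coefs,
      tensors = coefs[, 2:7, drop = FALSE],
      lnS0 = coefs[, 1],
      weights = weights,
      outliers = outl,
      iterations = as.integer(eng$iterations),
      converged = as.logical(eng$converged),
      clamped = rowSums(clamped) > 0,
      method = method,
      design = design,
      freq = freq
    ),
    class = "dti_fit"
  )
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf(
    "<dti_fit> %s fit of %d voxels x %d volumes (%d active)\n",
    x$method, nrow(x$coefficients), nrow(x$design), sum(x$freq > 0)
  ))
  if (x$method == "robust") {
    cat(sprintf(
      "  converged: %d/%d; voxels with outlier volumes: %d\n",
      sum(x$converged), length(x$converged), sum(rowSums(x$outliers) > 0)
    ))
  }
  invisible(x)
}

#' @export
summary.dti_fit <- function(object, ...) {
  ev <- tensor_eigenvalues(object$tensors)
  out <- list(
    method = object$method,
    n_voxels = nrow(object$coefficients),
    n_volumes = nrow(object$design),
    md = rowMeans(ev),
    fa = apply(ev, 1, fa_from_eigenvalues),
    converged = object$converged,
    outlier_fraction = mean(object$outliers)
  )
  class(out) <- "summary.dti_fit"
  out
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit (%s), %d voxels, %d volumes\n",
              x$method, x$n_voxels, x$n_volumes))
  cat(sprintf("  MD: median %.4g mm^2/s (IQR %.4g-%.4g)\n",
              stats::median(x$md), stats::quantile(x$md, .25),
              stats::quantile(x$md, .75)))
  cat(sprintf("  FA: median %.3f (IQR %.3f-%.3f)\n",
              stats::median(x$fa), stats::quantile(x$fa, .25),
              stats::quantile(x$fa, .75)))
  cat(sprintf("  outlier volume fraction: %.3f\n", x$outlier_fraction))
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) object$coefficients

#' Predict signals from a tensor fit
#'
#' Evaluates `exp(design %*% parameters)` per voxel, reproducing the model
#' signal for every volume (always positive).
#'
#' @param object a `dti_fit`.
#' @param design optional alternative design matrix (defaults to the one
#'   used for fitting).
#' @param ... unused.
#' @return V x N matrix of predicted signals.
#' @export
predict.dti_fit <- function(object, design = NULL, ...) {
  X <- if (is.null(design)) object$design else as.matrix(design)
  exp(object$coefficients %*% t(X))
}

#' @export
fitted.dti_fit <- function(object, ...) predict.dti_fit(object)

#' Residuals of a tensor fit
#'
#' @param object a `dti_fit`.
#' @param signals the V x N signal matrix the fit was computed from.
#' @param type `"log"` for log-signal residuals, `"signal"` for raw.
#' @param ... unused.
#' @return V x N matrix of residuals.
#' @export
residuals.dti_fit <- function(object, signals, type = c("log", "signal"), ...) {
  type <- match.arg(type)
  if (inherits(signals, "dwi_stack")) signals <- signals$data
  pred <- predict.dti_fit(object)
  if (type == "signal") signals - pred else log(pmax(signals, 1e-300)) - log(pred)
}

## eigenvalues (descending) for rows of a V x 6 tensor matrix
tensor_eigenvalues <- function(tensors, clip = TRUE) {
  tensors <- rbind(tensors)
  ev <- t(apply(tensors, 1, function(d) {
    D <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  }))
  if (clip) ev <- pmax(ev, 0)
  ev
}
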