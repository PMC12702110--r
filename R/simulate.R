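#' Noise and corruption model for simulated DWI
#'
#' Describes the stochastic components added to the noiseless tensor signal:
#' Rician magnitude noise calibrated to a target b500 SNR, a multiplicative
#' per-direction bias (lognormal, one draw per direction, emulating
#' direction-specific image quality such as eddy-current effects), and
#' per-volume outliers (uniform attenuation of a whole volume, emulating
#' residual motion corruption).
#'
#' @param snr_b500 target magnitude SNR of the high b-value myocardial
#'   signal (default 9.6).
#' @param bias_sigma lognormal sigma of the per-direction bias (0 disables).
#' @param outlier_prob probability that a volume is an outlier.
#' @param outlier_range attenuation factor range for outlier volumes.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(snr_b500 = 9.6, bias_sigma = 0.03,
                        outlier_prob = 0.05, outlier_range = c(0.3, 0.7)) {
  stopifnot(snr_b500 > 0, bias_sigma >= 0,
            outlier_prob >= 0, outlier_prob <= 1,
            length(outlier_range) == 2, all(outlier_range > 0))
  structure(
    list(snr_b500 = snr_b500, bias_sigma = bias_sigma,
         outlier_prob = outlier_prob, outlier_range = outlier_range),
    class = "noise_model"
  )
}

## Expand a plan into per-volume metadata. Strata are direction x shell;
## volumes are ordered shell by shell, direction by direction, repetition by
## repetition (acquisition order does not matter downstream, strata do).
plan_volumes <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"))
  rows <- list()
  stratum <- 0L
  for (si in seq_along(plan$shells)) {
    sh <- plan$shells[[si]]
    nd <- nrow(sh$scheme$directions)
    for (di in seq_len(nd)) {
      stratum <- stratum + 1L
      cnt <- sh$counts[di]
      if (cnt == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        shell = si,
        direction = di,
        stratum = stratum,
        repetition = seq_len(cnt),
        b = sh$scheme$b_value,
        gx = sh$scheme$directions[di, 1],
        gy = sh$scheme$directions[di, 2],
        gz = sh$scheme$directions[di, 3]
      )
    }
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  meta
}

#' Simulate a diffusion-weighted stack from the phantom
#'
#' Generates magnitude DWI volumes for every acquisition in `plan` using the
#' monoexponential tensor signal `S = s0 * exp(-b g' D g)` per voxel, then
#' applies (in order) the per-direction bias, per-volume outlier
#' attenuation, and Rician magnitude noise
#' `sqrt((S + e1)^2 + e2^2)` with Gaussian `e` of standard deviation
#' `sigma = mean noiseless b500 myocardial signal / snr_b500`. All
#' randomness is governed by `seed`; the noiseless component is independent
#' of the seed.
#'
#' @param phantom an [make_lv_phantom()] volume.
#' @param plan an [build_plan()] acquisition plan.
#' @param s0 non-diffusion-weighted signal level.
#' @param noise a [noise_model()], or `NULL` for noiseless data.
#' @param seed integer seed.
#' @return object of class `dwi_stack`: `data` (V x N matrix of masked-voxel
#'   signals), `array()` accessor via [dwi_as_array()], `meta` (per-volume
#'   data frame with direction, b-value, stratum, repetition, outlier flag
#'   and bias factor), `mask`, `voxels`, `plan`, `sigma`.
#' @export
simulate_dwi <- function(phantom, plan, s0 = 1, noise = noise_model(),
                         seed = 1L) {
  stopifnot(inherits(phantom, "lv_phantom"))
  meta <- plan_volumes(plan)
  nvol <- nrow(meta)
  Dv <- phantom$tensors # V x 6
  g <- as.matrix(meta[, c("gx", "gy", "gz")])
  ## b g' D g  per voxel/volume: quadratic form through the 6-component rows
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  expo <- Dv %*% t(q * meta$b) # V x N
  S <- s0 * exp(-expo)

  hi <- meta$b >= 100
  sigma <- 0
  meta$outlier <- FALSE
  meta$bias <- 1
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    sigma <- mean(S[, hi]) / noise$snr_b500
    set.seed(as.integer(seed))
    ## one bias per stratum (direction x shell), applied to its volumes
    strata <- sort(unique(meta$stratum))
    bias_by_stratum <- stats::setNames(
      exp(stats::rnorm(length(strata), 0, noise$bias_sigma)), strata
    )
    if (noise$bias_sigma > 0) {
      meta$bias <- bias_by_stratum[as.character(meta$stratum)]
    }
    meta$outlier <- stats::runif(nvol) < noise$outlier_prob
    atten <- stats::runif(nvol, noise$outlier_range[1], noise$outlier_range[2])
    fac <- meta$bias * ifelse(meta$outlier, atten, 1)
    S <- sweep(S, 2, fac, `*`)
    e1 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S), ncol(S))
    e2 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S), ncol(S))
    S <- sqrt((S + e1)^2 + e2^2)
  }
  structure(
    list(
      data = S, meta = meta, mask = phantom$mask, voxels = phantom$voxels,
      plan = plan, s0 = s0, sigma = sigma, seed = seed
    ),
    class = "dwi_stack"
  )
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf(
    "<dwi_stack> %d volumes x %d masked voxels (plan %s, sigma = %.4g)\n",
    nrow(x$meta), nrow(x$data), x$plan$name, x$sigma
  ))
  invisible(x)
}

#' Expand a dwi_stack into a 4D array
#'
#' Lays the masked-voxel signal matrix back onto the full grid as an
#' `(x, y, slice, volume)` array with zeros outside the mask (magnitude
#' data are non-negative).
#'
#' @param stack a `dwi_stack`.
#' @return 4D numeric array.
#' @export
dwi_as_array <- function(stack) {
  n <- nrow(stack$mask)
  nvol <- nrow(stack$meta)
  arr <- array(0, c(n, ncol(stack$mask), 1L, nvol))
  for (v in seq_len(nvol)) {
    sl <- matrix(0, n, ncol(stack$mask))
    sl[stack$voxels] <- stack$data[, v]
    arr[, , 1L, v] <- sl
  }
  arr
}

#' Measure SNR from repeated acquisitions
#'
#' Computes, for every masked voxel and high b-value direction with at least
#' two repetitions, the mean over repetitions divided by the SD over
#' repetitions, then averages across directions and voxels. Zero-SD
#' (noiseless) data report `Inf`.
#'
#' @param stack a `dwi_stack`.
#' @param b_min directions with b-value at or above this threshold are used
#'   (default restricts to the high b-value shell).
#' @return scalar SNR estimate.
#' @export
measure_snr <- function(stack, b_min = 100) {
  meta <- stack$meta
  use <- which(meta$b >= b_min)
  strata <- split(use, meta$stratum[use])
  strata <- strata[vapply(strata, length, 1L) >= 2L]
  if (!length(strata)) stop("need >= 2 repetitions per direction to measure SNR")
  per_dir <- vapply(strata, function(idx) {
    m <- rowMeans(stack$data[, idx, drop = FALSE])
    s <- apply(stack$data[, idx, drop = FALSE], 1, stats::sd)
    mean(ifelse(s == 0, Inf, m / s))
  }, numeric(1))
  mean(per_dir)
}
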