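test_that("noiseless fits recover the ground-truth tensor exactly", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 30, 3)
  stk <- simulate_dwi(ph, plan, noise = NULL)
  for (m in c("lls", "wls", "robust")) {
    fit <- dti_fit(stk, method = m)
    expect_lt(max(abs(fit$tensors - ph$tensors)) / max(ph$tensors), 1e-9)
    expect_true(all(abs(fit$lnS0) < 1e-9))
  }
  ## and the three estimators coincide without noise
  f_l <- dti_fit(stk, method = "lls")
  f_w <- dti_fit(stk, method = "wls")
  f_r <- dti_fit(stk, method = "robust")
  expect_equal(f_w$coefficients, f_l$coefficients, tolerance = 1e-12)
  expect_equal(f_r$coefficients, f_w$coefficients, tolerance = 1e-9)
  expect_identical(sum(f_r$outliers), 0L)
})

test_that("LLS matches an independent normal-equations oracle", {
  ## 7-volume minimal design on a hand-picked tensor
  dirs <- rbind(diag(3), c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                c(0, 1, 1) / sqrt(2), c(1, -1, 0) / sqrt(2))
  X <- dti_design(c(50, rep(500, 6)), dirs)
  D <- c(1.8e-3, 1.2e-3, 0.9e-3, 2e-4, -1e-4, 5e-5)
  beta_true <- c(log(120), D)
  set.seed(3)
  s <- exp(drop(X %*% beta_true)) * exp(rnorm(7, 0, 0.02))
  fit <- dti_fit(s, X, method = "lls")
  expect_equal(drop(fit$coefficients), unname(lls_oracle(s, X)),
               tolerance = 1e-10)
  ## isotropic signals give zero off-diagonal elements
  iso <- exp(drop(X %*% c(0, rep(1e-3, 3), 0, 0, 0)))
  fit_iso <- dti_fit(iso, X, method = "lls")
  expect_lt(max(abs(fit_iso$tensors[, 4:6])), 1e-12)
})

test_that("WLS weighting matches the squared-signal oracle and orders weights", {
  dirs <- rbind(diag(3), c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                c(0, 1, 1) / sqrt(2), c(1, -1, 1) / sqrt(3),
                c(-1, 1, 1) / sqrt(3))
  bv <- c(50, 50, rep(500, 6))
  X <- dti_design(bv, dirs)
  set.seed(11)
  beta_true <- c(log(50), 1.5e-3, 1.4e-3, 1.0e-3, 1e-4, 0, -1e-4)
  s <- exp(drop(X %*% beta_true)) + rnorm(8, 0, 0.5)
  fit <- dti_fit(s, X, method = "wls", wls_iter = 2)
  ## oracle: two passes of weights = squared predicted signals
  b0 <- lls_oracle(s, X)
  b1 <- lls_oracle(s, X, weights = exp(2 * drop(X %*% b0)))
  b2 <- lls_oracle(s, X, weights = exp(2 * drop(X %*% b1)))
  expect_equal(drop(fit$coefficients), unname(b2), tolerance = 1e-9)
  ## decaying signal implies low-b volumes carry the larger weights
  w <- drop(fit$weights)
  expect_gte(min(w[bv == 50]), max(w[bv == 500]))
})

test_that("robust fitting outperforms WLS under volume corruption", {
  ph <- small_phantom()
  des30 <- generate_repulsion_scheme(30, seed = 2, iters = 2000)
  plan <- build_plan(des30, 120, 3) # NA_all = 160
  nm <- noise_model(snr_b500 = 9.6, bias_sigma = 0, outlier_prob = 0)
  stk <- simulate_dwi(ph, plan, noise = nm, seed = 21)
  ## corrupt 10% of volumes by halving
  set.seed(22)
  bad <- sample(nrow(stk$meta), round(0.1 * nrow(stk$meta)))
  stk$data[, bad] <- stk$data[, bad] * 0.5
  X <- cdtiopt:::stack_design(stk)
  f_w <- dti_fit(stk$data, X, method = "wls")
  f_r <- dti_fit(stk$data, X, method = "robust")
  rms <- function(f) sqrt(mean((f$tensors - ph$tensors)^2))
  expect_lt(rms(f_r), rms(f_w))
  ## corrupted volumes are down-weighted relative to clean ones
  expect_lt(median(f_r$weights[, bad]), median(f_r$weights[, -bad]))
})

test_that("injected outlier volumes are flagged with high sensitivity", {
  ph <- small_phantom()
  des30 <- generate_repulsion_scheme(30, seed = 2, iters = 2000)
  plan <- build_plan(des30, 120, 3)
  nm <- noise_model(snr_b500 = 9.6, bias_sigma = 0, outlier_prob = 0.1,
                    outlier_range = c(0.3, 0.30001))
  stk <- simulate_dwi(ph, plan, noise = nm, seed = 31)
  fit <- dti_fit(stk, method = "robust")
  truth <- stk$meta$outlier
  expect_gt(sum(truth), 0)
  ## per outlier volume: fraction of voxels flagging it; majority vote
  sens <- mean(colMeans(fit$outliers[, truth, drop = FALSE]) > 0.5)
  expect_gt(sens, 0.8)
})

test_that("signal prediction round-trips and exposes outlier residuals", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 30, 3)
  stk <- simulate_dwi(ph, plan, noise = NULL)
  fit <- dti_fit(stk, method = "lls")
  pred <- predict(fit)
  expect_equal(pred, stk$data, tolerance = 1e-9)
  expect_true(all(pred > 0))
  ## attenuated volumes show larger residuals than clean ones
  nm <- noise_model(snr_b500 = 9.6, bias_sigma = 0, outlier_prob = 0.15,
                    outlier_range = c(0.4, 0.5))
  stk2 <- simulate_dwi(ph, build_plan(icosahedral_scheme(), 120, 2),
                       noise = nm, seed = 17)
  fit2 <- dti_fit(stk2, method = "robust")
  res <- abs(residuals(fit2, stk2))
  expect_gt(median(res[, stk2$meta$outlier]), median(res[, !stk2$meta$outlier]))
})

test_that("fits are permutation invariant and scale equivariant", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 60, 3)
  stk <- simulate_dwi(ph, plan, noise = noise_model(outlier_prob = 0.1),
                      seed = 12)
  X <- cdtiopt:::stack_design(stk)
  fit <- dti_fit(stk$data, X, method = "robust")
  set.seed(5)
  perm <- sample(ncol(stk$data))
  fit_p <- dti_fit(stk$data[, perm], X[perm, ], method = "robust")
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  ## volume j of the permuted fit is original volume perm[j]
  expect_equal(fit_p$outliers, fit$outliers[, perm])
  expect_equal(fit_p$weights, fit$weights[, perm], tolerance = 1e-9)
  ## scaling all signals by c shifts only ln S0, by log(c)
  fit_s <- dti_fit(stk$data * 7, X, method = "robust")
  expect_equal(fit_s$tensors, fit$tensors, tolerance = 1e-9)
  expect_equal(fit_s$lnS0, fit$lnS0 + log(7), tolerance = 1e-9)
})

test_that("degenerate inputs are clamped or rejected informatively", {
  X <- dti_design(rep(500, 12),
                  generate_repulsion_scheme(12, seed = 3, iters = 1000)$directions)
  s <- exp(drop(X %*% c(0, rep(1e-3, 3), 0, 0, 0)))
  s_bad <- s
  s_bad[4] <- -0.5 # negative magnitude cannot happen physically; clamp
  fit <- dti_fit(s_bad, X, method = "lls")
  expect_true(fit$clamped[1])
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(dti_fit(s[1:6], X[1:6, ], method = "lls"), "at least 7")
  expect_warning(dti_fit(s[1:8], X[1:8, ], method = "robust"), "fewer than 10")
})
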