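test_that("noiseless signals follow the monoexponential tensor model", {
  ph <- tiny_phantom()
  ## single-direction scheme along the local primary eigenvector of one voxel
  i <- 1L
  fr <- list(radial = ph$frames[i, 1:3], circ = ph$frames[i, 4:6],
             long = ph$frames[i, 7:9])
  D <- cdtiopt:::as_tensor_matrix(ph$tensors[i, ])
  e1 <- eigen(D, symmetric = TRUE)$vectors[, 1]
  l1 <- eigen(D, symmetric = TRUE)$values[1]
  plan <- build_plan(icosahedral_scheme(), 30, 3)
  stk <- simulate_dwi(ph, plan, s0 = 100, noise = NULL)
  ## b50 volume along +x at this voxel
  q <- as.matrix(stk$meta[, c("gx", "gy", "gz")])
  for (v in c(1L, nrow(stk$meta))) {
    g <- q[v, ]
    expect_equal(stk$data[i, v],
                 100 * exp(-stk$meta$b[v] * drop(g %*% D %*% g)),
                 tolerance = 1e-12)
  }
  ## along e1 the closed form is s0 exp(-b l1)
  sc1 <- direction_scheme(rbind(e1, -e1, diag(3), c(1, 1, 1) / sqrt(3)), 500)
  stk1 <- simulate_dwi(ph, build_plan(sc1, 30, 3, low_b_scheme = direction_scheme(diag(3), 0)),
                       s0 = 1, noise = NULL)
  v1 <- which(stk1$meta$b == 500 & stk1$meta$direction == 1)[1]
  expect_equal(stk1$data[i, v1], exp(-500 * l1), tolerance = 1e-12)
  ## b = 0 rows return s0 everywhere
  v0 <- which(stk1$meta$b == 0)[1]
  expect_true(all(abs(stk1$data[, v0] - 1) < 1e-14))
})

test_that("simulation is seed-deterministic with a seed-independent mean field", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 30, 3)
  a <- simulate_dwi(ph, plan, noise = noise_model(), seed = 5)
  b <- simulate_dwi(ph, plan, noise = noise_model(), seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(a$meta$outlier, b$meta$outlier)
  c2 <- simulate_dwi(ph, plan, noise = noise_model(), seed = 6)
  expect_false(identical(a$data, c2$data))
  expect_identical(simulate_dwi(ph, plan, noise = NULL)$data,
                   simulate_dwi(ph, plan, noise = NULL)$data)
})

test_that("Rician magnitude noise has the positive floor bias", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 60, 3)
  nm <- noise_model(snr_b500 = 3, bias_sigma = 0, outlier_prob = 0)
  clean <- simulate_dwi(ph, plan, noise = NULL)
  noisy_mean <- Reduce(`+`, lapply(1:40, function(s) {
    simulate_dwi(ph, plan, noise = nm, seed = s)$data
  })) / 40
  ## at SNR 3 the rectification bias is well above the Monte-Carlo noise
  expect_gt(mean(noisy_mean - clean$data), 0)
  ## and it shrinks as SNR grows
  nm_hi <- noise_model(snr_b500 = 50, bias_sigma = 0, outlier_prob = 0)
  noisy_hi <- Reduce(`+`, lapply(1:40, function(s) {
    simulate_dwi(ph, plan, noise = nm_hi, seed = s)$data
  })) / 40
  expect_lt(mean(noisy_hi - clean$data), mean(noisy_mean - clean$data))
})

test_that("outlier and bias corruption are recorded in the metadata", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 120, 2)
  nm <- noise_model(outlier_prob = 0.2, bias_sigma = 0.05)
  stk <- simulate_dwi(ph, plan, noise = nm, seed = 8)
  expect_identical(nrow(stk$meta), nrow(stk$meta))
  expect_gt(sum(stk$meta$outlier), 0)
  expect_true(all(stk$data >= 0))
  ## bias is shared within a stratum
  by_stratum <- split(stk$meta$bias, stk$meta$stratum)
  expect_true(all(vapply(by_stratum, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("SNR measurement recovers the simulation target", {
  ph <- small_phantom()
  plan <- build_plan(icosahedral_scheme(), 72, 3) # 12 repetitions per direction
  nm <- noise_model(snr_b500 = 9.6, bias_sigma = 0, outlier_prob = 0)
  stk <- simulate_dwi(ph, plan, noise = nm, seed = 7)
  snr <- measure_snr(stk)
  expect_lt(abs(snr - 9.6) / 9.6, 0.10)
  ## noiseless data report the +Inf sentinel
  expect_identical(measure_snr(simulate_dwi(ph, plan, noise = NULL)), Inf)
  ## single repetition per direction is an error
  p1 <- build_plan(direction_scheme(diag(3), 500), 3, 3,
                   low_b_scheme = orthogonal3_scheme())
  expect_error(measure_snr(simulate_dwi(ph, p1, noise = nm, seed = 1)),
               "repetitions")
})

test_that("Gaussian noise on a constant signal reproduces S/sigma", {
  ## measure_snr on pure Gaussian (not Rician) data is the textbook ratio
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 144, 3) # 24 reps per direction
  stk <- simulate_dwi(ph, plan, noise = NULL, s0 = 10)
  set.seed(99)
  sigma <- 0.4
  stk$data <- matrix(10, nrow(stk$data), ncol(stk$data)) +
    matrix(rnorm(length(stk$data), 0, sigma), nrow(stk$data))
  expect_lt(abs(measure_snr(stk) - 10 / sigma) / (10 / sigma), 0.15)
})
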