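test_that("bootknife samples respect the removal-then-resample contract", {
  pools <- list(
    list(label = "a", b = 500, direction = 1, pool = c(4L, 9L, 17L), requested = 3L),
    list(label = "b", b = 500, direction = 2, pool = c(2L, 5L), requested = 4L)
  )
  for (s in 1:50) {
    bs <- bootknife_sample(pools, seed = 7, sample_id = s)
    sel_a <- bs$indices[1:3]
    sel_b <- bs$indices[4:7]
    expect_true(all(sel_a %in% setdiff(pools[[1]]$pool, bs$removed[1])))
    expect_true(all(sel_b %in% setdiff(pools[[2]]$pool, bs$removed[2])))
    expect_false(bs$removed[1] %in% sel_a)
    expect_identical(length(sel_a), 3L)
    expect_identical(length(sel_b), 4L)
  }
  expect_identical(bootknife_sample(pools, seed = 7, sample_id = 3),
                   bootknife_sample(pools, seed = 7, sample_id = 3))
  expect_error(
    bootknife_sample(list(list(label = "x", b = 500, direction = 1,
                               pool = 5L, requested = 1L)), seed = 1),
    "single volume"
  )
})

test_that("each pool member is excluded with frequency 1/m", {
  m <- 6L
  pools <- list(list(label = "t", b = 500, direction = 1,
                     pool = seq_len(m), requested = 2L))
  n_rep <- 10000L
  removed <- vapply(seq_len(n_rep), function(s) {
    bootknife_sample(pools, seed = 13, sample_id = s)$removed
  }, integer(1))
  freq <- tabulate(removed, m) / n_rep
  se <- sqrt((1 / m) * (1 - 1 / m) / n_rep)
  expect_true(all(abs(freq - 1 / m) <= 3 * se))
})

test_that("per-stratum substreams are stable when strata are added", {
  p1 <- list(list(label = "a", b = 500, direction = 1,
                  pool = 1:5, requested = 3L))
  p2 <- c(p1, list(list(label = "b", b = 500, direction = 2,
                        pool = 6:10, requested = 3L)))
  a_alone <- bootknife_sample(p1, seed = 3, sample_id = 1)
  a_with_b <- bootknife_sample(p2, seed = 3, sample_id = 1)
  expect_identical(a_alone$indices[1:3], a_with_b$indices[1:3])
  expect_identical(a_alone$removed[1], a_with_b$removed[1])
})

test_that("plan strata carry the plan's repetition counts", {
  ph <- tiny_phantom()
  des <- cached_des_panel()
  ses <- simulate_dwi(ph, reference_plan(des), noise = NULL)
  ## 30-direction plan at NA_b500 = 90: every stratum requests 3
  p30 <- build_plan(des$incr61_30, 90, 3, seed = 1)
  pools <- plan_strata(ses, p30, seed = 1)
  hi <- Filter(function(p) p$b == 500, pools)
  expect_identical(length(hi), 30L)
  expect_true(all(vapply(hi, `[[`, integer(1), "requested") == 3L))
  ## 18-direction plan at NA_b500 = 30: twelve strata of 2, six of 1
  p18 <- build_plan(des$incr61_18, 30, 3, seed = 1)
  req <- vapply(Filter(function(p) p$b == 500, plan_strata(ses, p18, seed = 1)),
                `[[`, integer(1), "requested")
  expect_identical(sort(unique(req)), c(1L, 2L))
  expect_identical(sum(req == 2L), 12L)
  ## conservation: total requested equals NA_all
  all_req <- sum(vapply(pools, `[[`, integer(1), "requested"))
  expect_identical(all_req, p30$na_all)
  ## requesting more than acquired errors with the stratum named
  too_big <- build_plan(des$repulsion30, 30 * 5, 5, seed = 1) # NR 5 > 4 acquired
  expect_error(plan_strata(ses, too_big, seed = 1), "available in the stack")
})

test_that("degenerate resampling of identical volumes has zero spread", {
  ph <- tiny_phantom()
  plan <- build_plan(icosahedral_scheme(), 30, 3)
  clean <- simulate_dwi(ph, plan, noise = NULL)
  ## replicate each volume so that every stratum pool holds identical copies
  idx <- rep(seq_len(ncol(clean$data)), each = 3)
  stack3 <- clean
  stack3$data <- clean$data[, idx]
  stack3$meta <- clean$meta[idx, ]
  stack3$meta$repetition <- ave(idx, idx, FUN = seq_along)
  run <- run_bootstrap(stack3, plan, ph$frames, method = "lls",
                       n_samples = 8, seed = 2)
  sds <- sd_map(run$samples$md, "md")
  expect_lt(max(sds), 1e-12)
})

test_that("bootknife SD of a stratum mean matches sampling theory", {
  sigma <- 1
  k <- 12L
  pools <- list(list(label = "toy", b = 500, direction = 1,
                     pool = seq_len(k), requested = k))
  v <- vapply(1:50, function(r) {
    set.seed(4000 + r)
    x <- rnorm(k, 0, sigma)
    means <- vapply(1:500, function(s) {
      mean(x[bootknife_sample(pools, seed = r, sample_id = s)$indices])
    }, numeric(1))
    var(means)
  }, numeric(1))
  ## E[bootknife variance] = sigma^2 / k; compare on the RMS scale
  expect_lt(abs(sqrt(mean(v)) - sigma / sqrt(k)) / (sigma / sqrt(k)), 0.10)
})
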