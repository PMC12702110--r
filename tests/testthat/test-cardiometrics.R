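test_that("center of mass matches coordinate averaging", {
  ph <- small_phantom()
  cm <- center_of_mass(ph$mask)
  expect_lt(max(abs(cm - (32 + 1) / 2)), 0.5) # symmetric annulus
  single <- matrix(FALSE, 5, 5)
  single[2, 4] <- TRUE
  expect_equal(center_of_mass(single), c(row = 2, col = 4),
               ignore_attr = TRUE)
  ## C-shaped mask vs brute-force oracle
  cshape <- matrix(FALSE, 9, 9)
  cshape[3:7, 3] <- TRUE
  cshape[3, 3:6] <- TRUE
  cshape[7, 3:6] <- TRUE
  idx <- which(cshape, arr.ind = TRUE)
  expect_equal(center_of_mass(cshape), colMeans(idx), ignore_attr = TRUE)
  expect_error(center_of_mass(matrix(FALSE, 3, 3)), "empty")
})

test_that("local frames are right-handed and rotate smoothly", {
  center <- c(10, 10)
  fr <- local_frame(c(15, 10), center)
  expect_equal(fr$radial, c(1, 0, 0))
  expect_equal(fr$circ, c(0, 1, 0)) # counter-clockwise seen from +z
  expect_equal(fr$long, c(0, 0, 1))
  ## determinant +1 for a ring of voxels, and adjacent frames differ little
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circs <- t(vapply(th, function(t) {
    f <- local_frame(center + 6 * c(cos(t), sin(t)), center)
    expect_equal(det(cbind(f$radial, f$circ, f$long)), 1, tolerance = 1e-12)
    f$circ
  }, numeric(3)))
  steps <- acos(pmin(rowSums(circs * circs[c(2:72, 1), ]), 1)) * 180 / pi
  expect_lt(max(steps), 10)
  expect_error(local_frame(c(10, 10), center), "center")
})

test_that("MD and FA follow their closed forms", {
  expect_equal(tensor_md(diag(3) * 1e-3), 1e-3)
  expect_equal(tensor_fa(diag(3) * 1e-3), 0)
  expect_equal(tensor_fa(diag(c(1, 0, 0))), 1)
  expect_equal(tensor_fa(diag(c(2, 1, 1))), sqrt(1 / 6), tolerance = 1e-12)
  expect_equal(tensor_md(c(1e-3, 2e-3, 3e-3, 0, 0, 0)), 2e-3)
  expect_identical(tensor_fa(matrix(0, 3, 3)), 0)
})

test_that("helix and sheetlet angles pin the documented conventions", {
  fr <- list(radial = c(1, 0, 0), circ = c(0, 1, 0), long = c(0, 0, 1))
  expect_equal(helix_angle(c(0, 1, 0), fr), 0)
  expect_equal(helix_angle(c(0, 0, 1), fr), 90)
  expect_equal(helix_angle(c(0, -1, 0), fr), 0) # antipodal invariance
  expect_true(is.na(helix_angle(c(1, 0, 0), fr)))
  ## e2 = radial gives |E2A| = 90; e2 = cross-myocyte gives 0
  e1 <- c(0, 1, 0) # circumferential, HA = 0, cross-myocyte = longitudinal
  expect_equal(abs(sheetlet_angle(c(1, 0, 0), e1, fr)), 90)
  expect_equal(sheetlet_angle(c(0, 0, 1), e1, fr), 0)
  ## sign flips of either eigenvector leave both angles unchanged
  l <- eigenvalues_for(1.5e-3, 0.4, 1.5)
  D <- tensor_from_orientation(l, fr, 41, -27)
  eg <- eigen(D, symmetric = TRUE)
  for (s1 in c(1, -1)) {
    for (s2 in c(1, -1)) {
      expect_equal(helix_angle(s1 * eg$vectors[, 1], fr), 41, tolerance = 1e-6)
      expect_equal(sheetlet_angle(s2 * eg$vectors[, 2], s1 * eg$vectors[, 1], fr),
                   -27, tolerance = 1e-4)
    }
  }
})

test_that("metrics are equivariant under joint rotation of tensor and frame", {
  l <- eigenvalues_for(1.46e-3, 0.35, 1.55)
  fr <- list(radial = c(1, 0, 0), circ = c(0, 1, 0), long = c(0, 0, 1))
  D <- tensor_from_orientation(l, fr, -50, 33)
  for (s in 1:5) {
    R <- random_rotation(100 + s)
    Dr <- R %*% D %*% t(R)
    frr <- list(radial = drop(R %*% fr$radial), circ = drop(R %*% fr$circ),
                long = drop(R %*% fr$long))
    egr <- eigen(Dr, symmetric = TRUE)
    expect_equal(tensor_md(Dr), tensor_md(D), tolerance = 1e-12)
    expect_equal(tensor_fa(Dr), tensor_fa(D), tolerance = 1e-12)
    expect_equal(helix_angle(egr$vectors[, 1], frr), -50, tolerance = 1e-6)
    expect_equal(sheetlet_angle(egr$vectors[, 2], egr$vectors[, 1], frr), 33,
                 tolerance = 1e-4)
  }
})

test_that("noiseless pipeline reproduces ground truth end to end", {
  ph <- tiny_phantom()
  plan <- build_plan(generate_repulsion_scheme(12, seed = 6, iters = 1500),
                     36, 3)
  stk <- simulate_dwi(ph, plan, noise = NULL)
  fit <- dti_fit(stk, method = "robust")
  mm <- metric_maps(fit, ph$frames)
  vox <- ph$voxels
  expect_lt(max(abs(mm$md - ph$md[vox]) / ph$md[vox]), 1e-9)
  expect_lt(max(abs(mm$fa - ph$fa[vox]) / ph$fa[vox]), 1e-9)
  expect_lt(max(abs(mm$ha - ph$ha[vox])), 1e-6)
  expect_lt(max(abs(mm$e2a - ph$e2a[vox])), 1e-6)
})
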