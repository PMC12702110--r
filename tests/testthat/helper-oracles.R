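# Independent oracles and shared fixtures for the test suite.

# Plain-R log-linear least squares via QR, independent of the compiled
# fitting engine.
lls_oracle <- function(signals, design, weights = NULL) {
  y <- log(signals)
  if (is.null(weights)) {
    qr.coef(qr(design), y)
  } else {
    w <- sqrt(weights)
    qr.coef(qr(design * w), y * w)
  }
}

# Random rotation matrix (Haar-ish via QR of a Gaussian matrix).
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q * sign(diag(qr.R(qrd)))[col(Q)] * det(Q * sign(diag(qr.R(qrd)))[col(Q)])
}

# Brute-force circular-window enumeration: all starts, all condition
# numbers, written directly in the orthonormal tensor basis.
window_cns_oracle <- function(dirs, nd) {
  n <- nrow(dirs)
  vapply(seq_len(n), function(s) {
    idx <- (s - 1L + 0:(nd - 1L)) %% n + 1L
    A <- cbind(
      dirs[idx, 1]^2, dirs[idx, 2]^2, dirs[idx, 3]^2,
      sqrt(2) * dirs[idx, 1] * dirs[idx, 2],
      sqrt(2) * dirs[idx, 1] * dirs[idx, 3],
      sqrt(2) * dirs[idx, 2] * dirs[idx, 3]
    )
    sv <- svd(A, nu = 0, nv = 0)$d
    max(sv) / min(sv)
  }, numeric(1))
}

# Small phantoms shared across files (cheap to build).
tiny_phantom <- function() {
  make_lv_phantom(lv_phantom_spec(grid_size = 16, r_endo_mm = 4.6,
                                  r_epi_mm = 13.8))
}

small_phantom <- function() {
  make_lv_phantom(lv_phantom_spec(grid_size = 32, r_endo_mm = 5.75,
                                  r_epi_mm = 14.95))
}

# The study scheme panel is expensive enough to build once per run.
cached_des_panel <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- study_direction_schemes(seed = 1L)
    val
  }
})
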