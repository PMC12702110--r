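#' Diffusion-encoding direction scheme
#'
#' A direction scheme (DES) is an ordered set of unit diffusion-encoding
#' directions sharing one b-value. Order is meaningful: incrementally
#' optimized schemes are designed so that early prefixes are already usable,
#' and circular subsampling operates on consecutive (wrapped) runs of
#' directions. Directions are axial quantities: `d` and `-d` encode the same
#' diffusion weighting.
#'
#' @param directions numeric matrix, one unit 3-vector per row.
#' @param b_value diffusion weighting in s/mm^2.
#' @param name label used in plan names and reports.
#' @return An object of class `direction_scheme` with elements `directions`,
#'   `b_value`, `name`.
#' @examples
#' sc <- direction_scheme(diag(3), b_value = 500, name = "orth3")
#' condition_number(sc)
#' @export
direction_scheme <- function(directions, b_value, name = "scheme") {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) {
    stop("`directions` must have 3 columns")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("all directions must be unit vectors (|norm - 1| <= 1e-9)")
  }
  if (!is.numeric(b_value) || length(b_value) != 1L || b_value < 0) {
    stop("`b_value` must be a single non-negative number")
  }
  structure(
    list(directions = unname(directions), b_value = b_value, name = name),
    class = "direction_scheme"
  )
}

#' @export
print.direction_scheme <- function(x, ...) {
  cat(sprintf(
    "<direction_scheme> %s: %d directions, b = %g s/mm^2\n",
    x$name, nrow(x$directions), x$b_value
  ))
  if (nrow(x$directions) >= 6) {
    cat(sprintf("  condition number: %.4f\n", condition_number(x)))
  }
  invisible(x)
}

#' @export
length.direction_scheme <- function(x) nrow(x$directions)

#' Second-moment encoding matrix of a direction scheme
#'
#' Maps unit gradient directions to the six independent tensor components:
#' row i is `(gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`. The condition
#' number of this matrix governs noise propagation into the fitted tensor;
#' the b-value scales all rows equally and is therefore omitted (it enters
#' only at fitting time through the design matrix).
#'
#' @param scheme a `direction_scheme`, or a numeric matrix of unit row
#'   vectors.
#' @return N x 6 numeric matrix, rows ordered as the directions.
#' @seealso [condition_number()], [dti_design()]
#' @export
encoding_matrix <- function(scheme) {
  g <- if (inherits(scheme, "direction_scheme")) scheme$directions else as.matrix(scheme)
  if (nrow(g) < 1L) stop("scheme is empty")
  nrm <- sqrt(rowSums(g^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit norm")
  cbind(
    g[, 1]^2, g[, 2]^2, g[, 3]^2,
    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]
  )
}

#' Condition number of a direction scheme
#'
#' Ratio of the largest to smallest singular value of the direction-set
#' transformation matrix, evaluated in the orthonormal tensor basis (cross
#' terms scaled by sqrt(2) instead of 2). In that basis a rotation of the
#' direction set acts orthogonally on the rows, so the condition number is
#' exactly rotation-invariant, while the classic published values are
#' reproduced (2.00 for the dual-gradient set, sqrt(5/2) = 1.5811 for the
#' icosahedral set). Always >= 1; lower values indicate better noise
#' performance of tensor estimation. A set of coplanar directions cannot
#' determine all six tensor components and is reported as `Inf`.
#'
#' @inheritParams encoding_matrix
#' @return positive scalar (possibly `Inf` for rank-deficient schemes).
#' @examples
#' dual <- rbind(
#'   c(1, 1, 0), c(1, -1, 0), c(0, 1, 1),
#'   c(0, 1, -1), c(1, 0, 1), c(-1, 0, 1)
#' ) / sqrt(2)
#' condition_number(direction_scheme(dual, 500, "dual6")) # 2.00
#' @export
condition_number <- function(scheme) {
  A <- encoding_matrix(scheme)
  if (nrow(A) < 6L) stop("need at least 6 directions for a condition number")
  ## isometric rescaling of the doubled cross-term columns
  A[, 4:6] <- A[, 4:6] / sqrt(2)
  s <- svd(A, nu = 0, nv = 0)$d
  if (min(s) < max(s) * 1e-12) {
    return(Inf)
  }
  max(s) / min(s)
}

## Antipodally symmetrized electrostatic energy of a set of unit vectors:
## sum over pairs of 1/|di - dj| + 1/|di + dj|. With unit vectors,
## |di - dj|^2 = 2 - 2 di.dj and |di + dj|^2 = 2 + 2 di.dj.
scheme_energy <- function(P) {
  C <- tcrossprod(P)
  iu <- upper.tri(C)
  d1 <- sqrt(pmax(2 - 2 * C[iu], 1e-24))
  d2 <- sqrt(pmax(2 + 2 * C[iu], 1e-24))
  sum(1 / d1) + sum(1 / d2)
}

## Interaction energy between direction u and each row of P.
pair_energy <- function(u, P) {
  P <- rbind(P)
  dot <- drop(P %*% u)
  1 / sqrt(pmax(2 - 2 * dot, 1e-24)) + 1 / sqrt(pmax(2 + 2 * dot, 1e-24))
}

## Seeded uniform points on the unit sphere.
random_directions <- function(n, seed) {
  set.seed(as.integer(seed))
  z <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  cbind(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
}

## Projected gradient descent on the antipodal electrostatic energy with
## backtracking step control. Rows 1..n_fixed are held immovable (used to
## grow a scheme around an already-optimized core). Deterministic given the
## starting points.
repulsion_optimize <- function(P, iters = 10000L, step = 0.01, n_fixed = 0L) {
  E <- scheme_energy(P)
  stall <- 0L
  free <- setdiff(seq_len(nrow(P)), seq_len(n_fixed))
  if (!length(free)) return(P)
  for (it in seq_len(iters)) {
    C <- tcrossprod(P)
    A <- pmax(2 - 2 * C, 1e-12)^(-1.5)
    diag(A) <- 0
    B <- pmax(2 + 2 * C, 1e-12)^(-1.5)
    diag(B) <- 0
    G <- -(rowSums(A + B) * P - (A - B) %*% P)
    G <- G - rowSums(G * P) * P # tangent to the sphere
    if (n_fixed > 0L) G[seq_len(n_fixed), ] <- 0
    Pn <- P - step * G
    Pn <- Pn / sqrt(rowSums(Pn^2))
    En <- scheme_energy(Pn)
    if (En < E) {
      stall <- if (E - En < 1e-12 * E) stall + 1L else 0L
      P <- Pn
      E <- En
      step <- step * 1.1
    } else {
      step <- step * 0.5
      stall <- stall + 1L
    }
    if (step < 1e-14 || stall > 200L) break
  }
  P
}

#' Generate an electrostatic-repulsion direction scheme
#'
#' Places `n` unit directions by minimizing the antipodally symmetrized
#' electrostatic energy (sum over pairs of `1/|di - dj| + 1/|di + dj|`)
#' with projected gradient descent from a seeded random start. Antipodal
#' symmetrization reflects the symmetry of diffusion encoding. The result is
#' deterministic for a given seed.
#'
#' @param n number of directions (>= 6).
#' @param seed integer seed for the random start.
#' @param iters maximum optimizer iterations (converges much earlier for
#'   typical n; kept high so the energy is at its local floor).
#' @param b_value b-value attached to the scheme (s/mm^2).
#' @param name scheme label.
#' @return a `direction_scheme`.
#' @examples
#' sc <- generate_repulsion_scheme(6, seed = 1)
#' condition_number(sc) # ~1.581, the icosahedral optimum
#' @export
generate_repulsion_scheme <- function(n, seed = 1L, iters = 10000L,
                                      b_value = 500, name = NULL) {
  if (n < 6L) stop("need n >= 6 directions")
  P <- repulsion_optimize(random_directions(n, seed), iters = iters)
  direction_scheme(P, b_value, name %||% sprintf("repulsion%d", n))
}

## Exchange-optimize a subset of size k from candidate rows of P under an
## objective (condition number by default). Returns row indices. Used to
## make the first prefix of an incremental ordering near-optimal rather
## than greedy.
best_subset_exchange <- function(P, k, start_idx,
                                 objective = function(Q) condition_number(Q)) {
  idx <- start_idx
  repeat {
    improved <- FALSE
    out <- setdiff(seq_len(nrow(P)), idx)
    for (i in seq_along(idx)) {
      e_cur <- objective(P[idx, , drop = FALSE])
      for (j in out) {
        cand <- idx
        cand[i] <- j
        if (objective(P[cand, , drop = FALSE]) < e_cur - 1e-12) {
          idx <- cand
          out <- setdiff(seq_len(nrow(P)), idx)
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  idx
}

## Energy-greedy ordering of all rows of P (used below the size at which a
## condition number exists).
order_by_energy <- function(P) {
  n <- nrow(P)
  ord <- 1L
  cum <- pair_energy(P[1L, ], P)
  cum[1L] <- Inf
  while (length(ord) < n) {
    k <- which.min(cum)
    ord <- c(ord, k)
    cum <- cum + pair_energy(P[k, ], P)
    cum[ord] <- Inf
  }
  ord
}

## Extend an existing prefix ordering over all rows of P: each next position
## takes the remaining direction minimizing the prefix condition number,
## with interaction energy as the tie-break. This mirrors how subsampled
## direction runs are selected: by condition number.
order_continuation <- function(P, ord) {
  n <- nrow(P)
  cum <- rep(0, n)
  for (i in ord) cum <- cum + pair_energy(P[i, ], P)
  cum[ord] <- Inf
  while (length(ord) < n) {
    rem <- setdiff(seq_len(n), ord)
    cns <- vapply(rem, function(j) {
      condition_number(P[c(ord, j), , drop = FALSE])
    }, numeric(1))
    best <- cns <= min(cns) + 1e-9
    k <- rem[best][which.min(cum[rem[best]])]
    ord <- c(ord, k)
    cum <- cum + pair_energy(P[k, ], P)
    cum[ord] <- Inf
  }
  ord
}

#' Generate an incrementally ordered direction scheme
#'
#' Produces `n_total` unit directions ordered so that every prefix is itself
#' a well-spread scheme, making the scheme robust to premature scan
#' termination and amenable to consecutive-run subsampling.
#'
#' The scheme is grown in stages through the core sizes (default 6 and 30,
#' the subsample sizes the study designs care most about): the first core
#' is repulsion-optimized unconstrained, each later stage
#' repulsion-optimizes the added directions around the earlier ones held
#' fixed. Positions within a stage are ordered greedily by prefix condition
#' number (interaction energy as tie-break; pure energy ordering below six
#' directions, where no condition number exists). Prefixes at the core
#' sizes are therefore fully optimized sets — subsampling the first 6 or a
#' 30-long run recovers an optimal scheme — and every other prefix stays
#' well conditioned.
#'
#' @inheritParams generate_repulsion_scheme
#' @param n_total total number of directions (>= 6).
#' @param core_sizes increasing stage sizes at which prefixes are fully
#'   optimized sets.
#' @return a `direction_scheme` whose row order is the acquisition order.
#' @seealso [best_circular_subsample()]
#' @export
generate_incremental_scheme <- function(n_total, seed = 1L, iters = 10000L,
                                        b_value = 500, name = NULL,
                                        core_sizes = c(6L, 30L)) {
  if (n_total < 6L) stop("need n_total >= 6 directions")
  stages <- unique(c(core_sizes[core_sizes < n_total], n_total))
  P <- repulsion_optimize(random_directions(stages[1], seed), iters = iters)
  P <- P[order_by_energy(P), , drop = FALSE]
  for (sz in stages[-1]) {
    extra <- random_directions(sz - nrow(P), seed + 131L * sz)
    head_n <- nrow(P)
    P2 <- repulsion_optimize(rbind(P, extra), iters = iters, n_fixed = head_n)
    ord <- order_continuation(P2, seq_len(head_n))
    P <- P2[ord, , drop = FALSE]
  }
  direction_scheme(P, b_value, name %||% sprintf("incr%d", n_total))
}

#' Best circular subsample of a direction scheme
#'
#' Evaluates every circular (wrapping) window of `nd` consecutive directions
#' and returns the start index minimizing the window's condition number.
#' Ties are broken by the smallest start index.
#'
#' @param scheme a `direction_scheme`.
#' @param nd window length, `6 <= nd <= length(scheme)`.
#' @return list with `start` (1-based index of the first direction), `cn`
#'   (the minimal condition number) and `scheme` (the winning window as a
#'   `direction_scheme`).
#' @export
best_circular_subsample <- function(scheme, nd) {
  stopifnot(inherits(scheme, "direction_scheme"))
  n <- nrow(scheme$directions)
  if (nd < 6L) stop("need nd >= 6")
  if (nd > n) stop("nd exceeds scheme size")
  cns <- vapply(seq_len(n), function(s) {
    idx <- (s - 1L + 0:(nd - 1L)) %% n + 1L
    condition_number(scheme$directions[idx, , drop = FALSE])
  }, numeric(1))
  s <- which.min(cns) # which.min returns the first (smallest) index on ties
  idx <- (s - 1L + 0:(nd - 1L)) %% n + 1L
  list(
    start = s, cn = cns[s],
    scheme = direction_scheme(scheme$directions[idx, , drop = FALSE],
                              scheme$b_value,
                              sprintf("%s_sub%d", scheme$name, nd))
  )
}

#' Canonical small schemes
#'
#' `orthogonal3_scheme()` returns the three orthogonal axes used for low
#' b-value sampling. `icosahedral_scheme()` returns the six icosahedral
#' vertex directions (one per antipodal pair), the optimal 6-direction set
#' with condition number sqrt(5/2) = 1.5811. `dual_gradient_scheme()` returns
#' the classic 6-direction dual-gradient set with condition number 2.00.
#'
#' @param b_value b-value in s/mm^2.
#' @return a `direction_scheme`.
#' @export
orthogonal3_scheme <- function(b_value = 50) {
  direction_scheme(diag(3), b_value, "orth3")
}

#' @rdname orthogonal3_scheme
#' @export
icosahedral_scheme <- function(b_value = 500) {
  phi <- (1 + sqrt(5)) / 2
  P <- rbind(
    c(1, phi, 0), c(-1, phi, 0),
    c(0, 1, phi), c(0, -1, phi),
    c(phi, 0, 1), c(phi, 0, -1)
  )
  direction_scheme(P / sqrt(rowSums(P^2)), b_value, "icosa6")
}

#' @rdname orthogonal3_scheme
#' @export
dual_gradient_scheme <- function(b_value = 500) {
  P <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(0, 1, 1),
    c(0, 1, -1), c(1, 0, 1), c(-1, 0, 1)
  ) / sqrt(2)
  direction_scheme(P, b_value, "dual6")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
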