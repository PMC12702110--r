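#' Allocate acquisition volumes across directions
#'
#' Distributes `na` volumes over `nd` directions as evenly as possible:
#' every direction gets `floor(na/nd)`, and the `na %% nd` remaining volumes
#' go to distinct directions chosen uniformly at random, so per-direction
#' counts differ by at most 1.
#'
#' @param na number of volumes to allocate.
#' @param nd number of directions.
#' @param seed integer seed controlling the remainder assignment.
#' @return integer vector of length `nd` summing to `na`, `max - min <= 1`.
#' @export
allocate_per_direction <- function(na, nd, seed = 1L) {
  stopifnot(na >= 0, nd >= 1)
  base <- na %/% nd
  r <- na %% nd
  counts <- rep.int(base, nd)
  if (r > 0L) {
    set.seed(as.integer(seed))
    extra <- sample.int(nd, r)
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

new_acquisition_plan <- function(shells, nominal_tr_s, name) {
  bvals <- vapply(shells, function(sh) sh$scheme$b_value, numeric(1))
  counts <- lapply(shells, `[[`, "counts")
  na_shell <- vapply(counts, sum, numeric(1))
  na_b50 <- sum(na_shell[bvals < 100])
  na_b500 <- sum(na_shell[bvals >= 100])
  na_all <- na_b50 + na_b500
  high <- which(bvals >= 100)
  nr_b500 <- if (length(high) == 1L) {
    na_b500 / nrow(shells[[high]]$scheme$directions)
  } else {
    NA_real_
  }
  structure(
    list(
      shells = shells,
      na_b50 = as.integer(na_b50),
      na_b500 = as.integer(na_b500),
      na_all = as.integer(na_all),
      nr_b500 = nr_b500,
      nominal_tr_s = nominal_tr_s,
      nominal_time_s = na_all * nominal_tr_s,
      name = name
    ),
    class = "acquisition_plan"
  )
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(
    "<acquisition_plan> %s: NA_b50 = %d, NA_b500 = %d, NA_all = %d, time = %s\n",
    x$name, x$na_b50, x$na_b500, x$na_all,
    sprintf("%d:%02d min", x$nominal_time_s %/% 60, x$nominal_time_s %% 60)
  ))
  invisible(x)
}

#' Build an acquisition plan from a direction scheme
#'
#' A plan pairs a high b-value direction scheme (repetition counts allocated
#' evenly, at most 1 apart) with a low b-value shell whose volume count is a
#' fixed fraction of the high b-value count: `na_b50 = na_b500 / b50_divisor`
#' with divisors 10, 5, 3 or 2. The nominal time assumes one volume per
#' `nominal_tr_s` seconds (3 s = 3 RR intervals at 60 bpm).
#'
#' @param des high b-value `direction_scheme`.
#' @param na_b500 number of high b-value volumes; must be divisible by
#'   `b50_divisor` (no silent rounding).
#' @param b50_divisor divisor giving the low b-value volume count.
#' @param low_b_scheme low b-value `direction_scheme`; defaults to the three
#'   orthogonal axes at b = 50 s/mm^2.
#' @param seed seed for remainder allocation in incomplete shells.
#' @param nominal_tr_s seconds per volume (default 3).
#' @return an `acquisition_plan` named `"DES_NAb500_NAb50"`.
#' @examples
#' p <- build_plan(icosahedral_scheme(), na_b500 = 30, b50_divisor = 2)
#' p$na_b50 # 15
#' @export
build_plan <- function(des, na_b500, b50_divisor,
                       low_b_scheme = orthogonal3_scheme(),
                       seed = 1L, nominal_tr_s = 3) {
  stopifnot(inherits(des, "direction_scheme"))
  if (na_b500 %% b50_divisor != 0) {
    stop(sprintf("na_b500 = %d is not divisible by %d", na_b500, b50_divisor))
  }
  na_b50 <- na_b500 %/% b50_divisor
  nd_hi <- nrow(des$directions)
  nd_lo <- nrow(low_b_scheme$directions)
  shells <- list(
    list(scheme = low_b_scheme,
         counts = allocate_per_direction(na_b50, nd_lo, seed = seed)),
    list(scheme = des,
         counts = allocate_per_direction(na_b500, nd_hi, seed = seed + 1L))
  )
  new_acquisition_plan(
    shells, nominal_tr_s,
    name = sprintf("%s_%d_%d", des$name, na_b500, na_b50)
  )
}

#' The six study direction schemes
#'
#' Constructs the direction-scheme panel compared by the study: an
#' incrementally ordered 61-direction scheme circularly subsampled by
#' condition number to 6, 10, 18 and 30 consecutive directions, the
#' icosahedral 6-direction scheme, and an independent 30-direction
#' repulsion scheme.
#'
#' With `nested = TRUE` (the default) the 30-direction window is chosen
#' freely over all 61 circular start positions, and the 18-, 10- and
#' 6-direction windows are then each condition-number-minimized among the
#' windows contained in the next larger one. Nesting guarantees that every
#' subsampled scheme's directions are acquired within a single reference
#' session (the 6-direction scheme can pool its own shell's repetitions with
#' the 30-direction shell's), which the session-subsampling design relies
#' on. `nested = FALSE` minimizes every window independently.
#'
#' @param seed seed for the stochastic scheme generators.
#' @param iters optimizer iterations passed to the generators.
#' @param nested constrain the 18/10/6 windows inside the 30 window.
#' @return named list of six `direction_scheme`s
#'   (`incr61_6/10/18/30`, `icosa6`, `repulsion30`) plus the parent
#'   scheme as attribute `"parent61"`.
#' @export
study_direction_schemes <- function(seed = 1L, iters = 10000L, nested = TRUE) {
  parent <- generate_incremental_scheme(61L, seed = seed, iters = iters)
  n <- nrow(parent$directions)
  window_idx <- function(start, nd) (start - 1L + 0:(nd - 1L)) %% n + 1L
  subs <- list()
  if (nested) {
    outer_start <- best_circular_subsample(parent, 30L)$start
    for (nd in c(6L, 10L, 18L, 30L)) {
      ## admissible starts: windows of length nd inside the 30 window
      offs <- 0:(30L - nd)
      cand <- (outer_start - 1L + offs) %% n + 1L
      cns <- vapply(cand, function(s) {
        condition_number(parent$directions[window_idx(s, nd), , drop = FALSE])
      }, numeric(1))
      s <- cand[which.min(cns)]
      subs[[sprintf("incr61_%d", nd)]] <- direction_scheme(
        parent$directions[window_idx(s, nd), , drop = FALSE],
        parent$b_value, sprintf("incr61_%d", nd)
      )
    }
  } else {
    for (nd in c(6L, 10L, 18L, 30L)) {
      sc <- best_circular_subsample(parent, nd)$scheme
      sc$name <- sprintf("incr61_%d", nd)
      subs[[sc$name]] <- sc
    }
  }
  out <- c(subs, list(
    icosa6 = icosahedral_scheme(),
    repulsion30 = generate_repulsion_scheme(30L, seed = seed + 1L, iters = iters)
  ))
  attr(out, "parent61") <- parent
  out
}

#' Enumerate the study's acquisition plans
#'
#' Crosses the six study direction schemes with four high b-value volume
#' counts (30, 60, 90, 120) and four low b-value divisors (10, 5, 3, 2),
#' yielding 96 subsampled plans, and appends the fully sampled reference
#' plan of 720 volumes.
#'
#' @param des_set the scheme panel from [study_direction_schemes()]; built
#'   with `seed` if omitted.
#' @param seed seed used both for scheme generation (when `des_set` is
#'   missing) and shell allocation.
#' @return list of 97 `acquisition_plan`s; the last one is the reference,
#'   also available as attribute `"reference"`.
#' @export
enumerate_study_plans <- function(des_set = NULL, seed = 1L) {
  if (is.null(des_set)) des_set <- study_direction_schemes(seed = seed)
  plans <- list()
  for (des in des_set) {
    for (na_b500 in c(30L, 60L, 90L, 120L)) {
      for (div in c(10L, 5L, 3L, 2L)) {
        p <- build_plan(des, na_b500, div, seed = seed)
        plans[[p$name]] <- p
      }
    }
  }
  ref <- reference_plan(des_set)
  plans[[ref$name]] <- ref
  attr(plans, "reference") <- ref$name
  plans
}

#' The fully sampled reference plan
#'
#' Composes the single-session reference acquisition: 24 repetitions of the
#' 3 orthogonal low b-value directions plus high b-value shells of 12 x 30,
#' 8 x 6, 20 x 6 (icosahedral) and 4 x 30 (repulsion) volumes — 720 volumes,
#' 36 min at a 3 s nominal TR.
#'
#' @inheritParams enumerate_study_plans
#' @param nominal_tr_s seconds per volume.
#' @return an `acquisition_plan` named `"all_648_72"`.
#' @export
reference_plan <- function(des_set, nominal_tr_s = 3) {
  shells <- list(
    list(scheme = orthogonal3_scheme(), counts = rep.int(24L, 3L)),
    list(scheme = des_set$incr61_30, counts = rep.int(12L, 30L)),
    list(scheme = des_set$incr61_6, counts = rep.int(8L, 6L)),
    list(scheme = des_set$icosa6, counts = rep.int(20L, 6L)),
    list(scheme = des_set$repulsion30, counts = rep.int(4L, 30L))
  )
  new_acquisition_plan(shells, nominal_tr_s, name = "all_648_72")
}
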