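#' Stratum pools for a plan over an acquired stack
#'
#' Matches each stratum (direction x shell) requested by `plan` against the
#' volumes available in `stack`, returning the pool of volume indices and
#' the requested repetition count per stratum. Directions are matched up to
#' antipodal sign within 1e-6; volumes from different shells with the same
#' b-value and direction pool together. A stratum whose pool cannot supply
#' the bootknife (fewer than 2 volumes when at least one is requested)
#' raises an error naming the stratum.
#'
#' @param stack a `dwi_stack` (typically the simulated reference session).
#' @param plan an `acquisition_plan` to be drawn from the stack.
#' @param seed seed for remainder allocation of requested counts.
#' @return list of pools, each `list(label, b, direction, pool, requested)`.
#' @export
plan_strata <- function(stack, plan, seed = 1L) {
  meta <- stack$meta
  gstack <- as.matrix(meta[, c("gx", "gy", "gz")])
  pools <- list()
  for (si in seq_along(plan$shells)) {
    sh <- plan$shells[[si]]
    nd <- nrow(sh$scheme$directions)
    counts <- sh$counts
    for (di in seq_len(nd)) {
      if (counts[di] == 0L) next
      g <- sh$scheme$directions[di, ]
      same_b <- abs(meta$b - sh$scheme$b_value) < 0.5
      dot <- abs(gstack %*% g)
      match_dir <- same_b & (1 - dot) < 1e-6
      pool <- which(match_dir)
      label <- sprintf("%s[b%g,d%d]", plan$name, sh$scheme$b_value, di)
      if (length(pool) < 2L || counts[di] > length(pool)) {
        stop(sprintf(
          "stratum %s needs %d volumes but only %d available in the stack",
          label, counts[di], length(pool)
        ))
      }
      pools[[length(pools) + 1L]] <- list(
        label = label, b = sh$scheme$b_value, direction = di,
        pool = pool, requested = as.integer(counts[di])
      )
    }
  }
  pools
}

## Per-stratum substream seed: each stratum's draws depend only on (seed,
## stratum position), so adding strata does not perturb the others.
stratum_seed <- function(seed, stratum, sample_id = 0L) {
  (as.integer(seed) %% 100003L) * 10007L + stratum * 211L + sample_id
}

#' Draw one bootknife sample
#'
#' For each stratum: remove one uniformly chosen volume from the pool, then
#' draw the requested count with replacement from the remainder. The
#' jackknife-style removal corrects the variance underestimation of the
#' plain stratified bootstrap at small per-stratum counts. Each stratum
#' consumes its own seeded substream, so draws are reproducible per stratum.
#'
#' @param pools stratum pools from [plan_strata()].
#' @param seed integer seed.
#' @param sample_id bootstrap sample index (keeps samples independent while
#'   preserving per-stratum substreams).
#' @return list with `indices` (integer vector of selected volume indices,
#'   with multiplicity) and `removed` (one removed index per stratum).
#' @export
bootknife_sample <- function(pools, seed = 1L, sample_id = 0L) {
  sel <- vector("list", length(pools))
  removed <- integer(length(pools))
  for (k in seq_along(pools)) {
    p <- pools[[k]]
    if (length(p$pool) < 2L && p$requested > 0L) {
      stop(sprintf("stratum %s has a single volume; bootknife undefined", p$label))
    }
    set.seed(stratum_seed(seed, k, sample_id))
    rm_i <- sample.int(length(p$pool), 1L)
    removed[k] <- p$pool[rm_i]
    rest <- p$pool[-rm_i]
    sel[[k]] <- rest[sample.int(length(rest), p$requested, replace = TRUE)]
  }
  list(indices = unlist(sel), removed = removed)
}

#' Run a stratified bootknife bootstrap of the tensor pipeline
#'
#' Generates `n_samples` bootknife samples of `plan` drawn from `stack`,
#' fits the diffusion tensor to each sample (volume multiplicities enter the
#' fit as frequency weights), computes the cardiac metric maps, and collects
#' them per metric. The default sample count of 500 matches common practice
#' for stable accuracy/precision estimates.
#'
#' @param stack a `dwi_stack`.
#' @param plan an `acquisition_plan`.
#' @param frames V x 9 local frame matrix (e.g. `phantom$frames`).
#' @param method fit method passed to [dti_fit()].
#' @param n_samples number of bootstrap samples.
#' @param seed integer seed.
#' @param metrics which metric maps to collect.
#' @return object of class `bootstrap_run`: `samples` — a named list of
#'   V x n_samples matrices (one per metric), `plan`, `n_samples`, `seed`,
#'   `method`.
#' @export
run_bootstrap <- function(stack, plan, frames, method = "robust",
                          n_samples = 500L, seed = 1L,
                          metrics = c("md", "fa", "ha", "e2a", "abs_e2a")) {
  pools <- plan_strata(stack, plan, seed = seed)
  X <- stack_design(stack)
  nvol <- nrow(stack$meta)
  nv <- nrow(stack$data)
  out <- lapply(metrics, function(m) matrix(NA_real_, nv, n_samples))
  names(out) <- metrics
  for (s in seq_len(n_samples)) {
    bs <- bootknife_sample(pools, seed = seed, sample_id = s)
    freq <- tabulate(bs$indices, nbins = nvol)
    fit <- tryCatch(
      dti_fit(stack$data, X, method = method, freq = freq),
      error = function(e) {
        stop(sprintf("bootstrap sample %d: %s", s, conditionMessage(e)))
      }
    )
    mm <- metric_maps(fit, frames)
    for (m in metrics) out[[m]][, s] <- mm[[m]]
  }
  structure(
    list(samples = out, plan = plan, n_samples = n_samples,
         seed = seed, method = method),
    class = "bootstrap_run"
  )
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_run> plan %s: %d samples x %d voxels (%s fit)\n",
    x$plan$name, x$n_samples, nrow(x$samples[[1]]), x$method
  ))
  invisible(x)
}
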