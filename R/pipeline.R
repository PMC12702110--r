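#' Experiment configuration
#'
#' Bundles everything needed for a reproducible scheme-comparison
#' experiment: phantom specification, noise model, the plans to evaluate,
#' fit method, bootstrap settings and per-replicate seeds. Replicates play
#' the role of independent subjects: each is a fresh noise realization of
#' one simulated reference session from which every plan is subsampled
#' (preserving the non-independence of subsampled schemes inherent to
#' single-session designs).
#'
#' @param phantom_spec an [lv_phantom_spec()].
#' @param noise a [noise_model()].
#' @param plans named list of `acquisition_plan`s to evaluate; all must be
#'   drawable from the reference session.
#' @param reference the reference `acquisition_plan` (fit once per
#'   replicate; bootstrap pools are built on its stack).
#' @param method fit method.
#' @param n_samples bootstrap samples per plan.
#' @param n_replicates number of independent noise realizations.
#' @param seed master integer seed; replicate r uses `seed + 1000 * r`.
#' @param excluded_sectors,n_sectors ROI sector exclusion settings.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(phantom_spec = lv_phantom_spec(),
                              noise = noise_model(),
                              plans = NULL,
                              reference = NULL,
                              method = "robust",
                              n_samples = 500L,
                              n_replicates = 5L,
                              seed = 1L,
                              excluded_sectors = integer(0),
                              n_sectors = 12L) {
  if (is.null(plans)) {
    des <- study_direction_schemes(seed = seed)
    plans <- enumerate_study_plans(des, seed = seed)
    reference <- plans[[attr(plans, "reference")]]
    plans[[attr(plans, "reference")]] <- NULL
  }
  if (is.null(reference)) stop("a reference plan is required")
  structure(
    list(
      phantom_spec = phantom_spec, noise = noise, plans = plans,
      reference = reference, method = method,
      n_samples = as.integer(n_samples),
      n_replicates = as.integer(n_replicates), seed = as.integer(seed),
      excluded_sectors = excluded_sectors, n_sectors = as.integer(n_sectors)
    ),
    class = "experiment_config"
  )
}

#' Run a scheme-comparison experiment
#'
#' For every replicate: simulate the reference session from the phantom,
#' fit the full session for the reference metric maps, then for every plan
#' run the stratified bootknife bootstrap and aggregate ROI mean/RMSD/SD of
#' each metric. The result carries both the per-replicate long table and
#' paired comparison matrices across plans per metric and statistic.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return object of class `experiment_result`: `summary` (long data frame:
#'   replicate, scheme, metric, statistic, value), `comparisons` (nested
#'   list metric -> statistic -> `comparison_report`), `reference_summary`,
#'   `manifest` (seeds, sizes, config echo).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  phantom <- make_lv_phantom(config$phantom_spec)
  center <- center_of_mass(phantom$mask)
  rows <- list()
  ref_rows <- list()
  for (r in seq_len(config$n_replicates)) {
    rseed <- config$seed + 1000L * r
    if (verbose) message(sprintf("replicate %d (seed %d)", r, rseed))
    session <- simulate_dwi(phantom, config$reference,
                            noise = config$noise, seed = rseed)
    ref_fit <- dti_fit(session, method = config$method)
    ref_maps <- metric_maps(ref_fit, phantom$frames)
    for (m in names(ref_maps)) {
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        replicate = r, metric = m,
        value = roi_summary(ref_maps[[m]], phantom$voxels, center,
                            config$excluded_sectors, config$n_sectors)$mean
      )
    }
    for (p in names(config$plans)) {
      if (verbose) message(sprintf("  plan %s", p))
      run <- run_bootstrap(session, config$plans[[p]], phantom$frames,
                           method = config$method,
                           n_samples = config$n_samples, seed = rseed)
      tb <- summarize_bootstrap(run, ref_maps, phantom$voxels, center,
                                config$excluded_sectors, config$n_sectors)
      tb$replicate <- r
      rows[[length(rows) + 1L]] <- tb
    }
  }
  summary_tb <- do.call(rbind, rows)
  comparisons <- list()
  if (length(config$plans) >= 2L && config$n_replicates >= 3L) {
    for (m in unique(summary_tb$metric)) {
      comparisons[[m]] <- list()
      for (st in c("rmsd", "sd")) {
        sub <- summary_tb[summary_tb$metric == m & summary_tb$statistic == st, ]
        wide <- stats::reshape(
          sub[, c("replicate", "scheme", "value")],
          direction = "wide", idvar = "replicate", timevar = "scheme"
        )
        mat <- as.matrix(wide[, -1, drop = FALSE])
        colnames(mat) <- sub("^value\\.", "", colnames(mat))
        comparisons[[m]][[st]] <- paired_comparison_matrix(mat)
      }
    }
  }
  structure(
    list(
      summary = summary_tb,
      reference_summary = do.call(rbind, ref_rows),
      comparisons = comparisons,
      manifest = list(
        seed = config$seed, n_replicates = config$n_replicates,
        n_samples = config$n_samples, method = config$method,
        plans = names(config$plans), reference = config$reference$name,
        grid_size = config$phantom_spec$grid_size,
        n_voxels = nrow(phantom$voxels),
        snr_b500 = if (is.null(config$noise)) Inf else config$noise$snr_b500
      )
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<experiment_result> %d plans x %d replicates x %d bootstrap samples (%s fit, %d voxels)\n",
    length(m$plans), m$n_replicates, m$n_samples, m$method, m$n_voxels
  ))
  invisible(x)
}
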