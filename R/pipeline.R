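# Run configuration and the end-to-end pipeline driver.

#' Default run configuration
#'
#' Every tunable of the analysis stages, keyed per module. Unknown keys are
#' rejected by [validate_run_config()]; file-based configs
#' ([read_run_config()]) are merged over these defaults.
#'
#' @return nested named list
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    staging = list(),
    trajectory = list(grid_n = 200L, min_cells = 2000L, ell_bins = 20L,
                      size_bins = 15L, min_cells_per_bin = 20L),
    turnover = list(well_stat = "median", n_boot = 400L, conf = 0.95),
    growth = list(smooth_window = 5L, trim = 6L, min_tracks = 10L,
                  conf = 0.95, size_percentiles = c(0.2, 0.8))
  )
}

#' Validate a run configuration against the defaults
#'
#' @param config nested list
#' @return the config, invisibly; errors on unknown keys
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  walk <- function(cfg, def, prefix) {
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown))
      stop_field(sprintf("run config: unknown key(s): %s",
                         paste0(prefix, unknown, collapse = ", ")))
    for (k in names(cfg))
      if (is.list(def[[k]]) && !is.null(names(def[[k]])))
        walk(cfg[[k]], def[[k]], paste0(prefix, k, "."))
  }
  walk(config, defaults, "")
  invisible(config)
}

#' Read a run configuration from YAML and merge over the defaults
#'
#' @param path YAML file
#' @return merged, validated configuration
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_run_config(user)
  merged <- default_run_config()
  for (k in names(user)) {
    if (is.list(user[[k]])) {
      for (k2 in names(user[[k]])) merged[[k]][[k2]] <- user[[k]][[k2]]
    } else merged[[k]] <- user[[k]]
  }
  merged
}

#' Run the staged analysis pipeline
#'
#' Executes staging, trajectory, turnover and growth on the supplied
#' tables, writing result tables with provenance headers and a plain-text
#' log under `out_dir`. Stages whose inputs are missing are skipped with a
#' logged warning (e.g. turnover without a +CFZ arm); a stage error aborts
#' with that stage's message.
#'
#' @param out_dir output directory (created if needed)
#' @param cells optional per-cell table (see [read_cells()])
#' @param tracks optional track table
#' @param bulk optional bulk table
#' @param config run configuration, see [default_run_config()]
#' @return invisible list of results
#' @export
run_pipeline <- function(out_dir, cells = NULL, tracks = NULL, bulk = NULL,
                         config = default_run_config()) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
    writeLines(log_lines, log_path)
  }
  set.seed(config$seed)
  results <- list()
  emit <- function(df, name) {
    write_table(df, file.path(out_dir, paste0(name, ".csv")),
                config = config, seed = config$seed)
  }

  if (!is.null(cells)) {
    logf("staging: %d cells", nrow(cells))
    thr <- detect_thresholds(cells)
    cells <- assign_stage(cells, thr)
    results$thresholds <- thr
    yaml::write_yaml(list(dna_2n_upper = thr$dna_2n_upper,
                          dna_4n_lower = thr$dna_4n_lower,
                          geminin_log_cut = thr$geminin_log_cut,
                          geminin_available = thr$geminin_available),
                     file.path(out_dir, "thresholds.yaml"))
    logf("staging: %s",
         paste(sprintf("%s=%d", levels(cells$stage), table(cells$stage)),
               collapse = " "))

    tcfg <- config$trajectory
    if (nrow(cells) >= tcfg$min_cells) {
      curve <- fit_ridge(cells, grid_n = tcfg$grid_n,
                         min_cells = tcfg$min_cells)
      cells <- project_cells(curve, cells)
      results$curve <- curve
      emit(cbind(curve$points, ell = curve$ell), "trajectory_curve")
      if ("k48" %in% names(cells)) {
        hm <- ell_size_heatmap(cells, "k48", normalize_by_size = TRUE,
                               ell_bins = tcfg$ell_bins,
                               size_bins = tcfg$size_bins,
                               min_cells_per_bin = tcfg$min_cells_per_bin)
        results$heatmap <- hm
        emit(hm, "ell_size_k48")
      }
      logf("trajectory: %d-vertex ridge, %d cells projected",
           nrow(curve$points), nrow(cells))
    } else {
      logf("trajectory: skipped (fewer than %d cells)", tcfg$min_cells)
    }
    emit(cells, "cells_staged")

    if ("k48" %in% names(cells)) {
      turn <- NULL
      for (cond in unique(cells$condition)) {
        sub <- cells[cells$condition == cond & !cells$chx_flag, ]
        plus <- sub[sub$cfz_flag, ]
        minus <- sub[!sub$cfz_flag, ]
        if (!nrow(plus) || !nrow(minus)) {
          logf("turnover: skipped for '%s' (missing a CFZ arm)", cond)
          next
        }
        res <- delta_k48(plus, minus, per_stage = TRUE,
                         well_stat = config$turnover$well_stat,
                         conf = config$turnover$conf)
        results$turnover[[cond]] <- res
        turn <- rbind(turn, res)
      }
      if (!is.null(turn)) emit(turn, "delta_k48")
      conds <- names(results$turnover)
      if ("control" %in% conds && length(conds) > 1) {
        for (cond in setdiff(conds, "control")) {
          sc <- scaling_analysis(results$turnover$control,
                                 results$turnover[[cond]],
                                 n_boot = config$turnover$n_boot,
                                 seed = config$seed)
          results$scaling[[cond]] <- sc
          logf("turnover: %s vs control excess ratio %.3f (P[<=1] = %.3f)",
               cond, sc$excess_ratio, sc$superlinear_p)
        }
      }
    }
  }

  if (!is.null(tracks)) {
    gcfg <- config$growth
    tr <- track_growth_rates(tracks, smooth_window = gcfg$smooth_window,
                             trim = gcfg$trim)
    results$track_rates <- tr
    emit(tr, "track_rates")
    for (msg in attr(tr, "excluded")) logf("tracks: excluded %s", msg)
    pd <- phase_durations(tracks, conf = gcfg$conf)
    results$phase_durations <- pd
    emit(pd$stats, "phase_durations")
    al <- align_tracks(tracks, anchor = "birth", min_tracks = gcfg$min_tracks,
                       conf = gcfg$conf)
    emit(al, "aligned_birth")
    logf("tracks: %d tracks summarized", nrow(tr))
  }

  if (!is.null(bulk)) {
    fit <- fit_cycle_length(bulk, conf = config$growth$conf)
    results$growth_fit <- fit
    nu <- bulk_growth_rate(bulk)
    results$nu <- nu
    emit(nu, "bulk_nu")
    emit(data.frame(alpha = fit$alpha, tau = fit$tau,
                    alpha_lo = fit$alpha_ci[1], alpha_hi = fit$alpha_ci[2]),
         "bulk_fit")
    logf("bulk: alpha = %.4g /h, tau = %.3g h", fit$alpha, fit$tau)
  }

  logf("pipeline complete: outputs in %s", out_dir)
  invisible(results)
}
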