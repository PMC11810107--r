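# Shared fixtures: small configurations and constructed tracks.

# Default-condition config at moderate size; ... overrides any default.
test_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_wells = 9, cells_per_well = 80)
  user <- list(...)
  for (k in names(user)) args[[k]] <- user[[k]]
  do.call(sim_config, args)
}

# Quiescent population: synthesis balances degradation, checkpoint off, so
# masses, fluxes and the K48 pool are exactly stationary. Isolates the
# flux estimators from growth/division dynamics.
quiescent_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_wells = 9, cells_per_well = 60,
               synthesis_rate_per_mass = 0.025,
               basal_degradation_per_mass = 0.025,
               compensation_exponent = 0, g1_checkpoint_strength = 0,
               burn_in_h = 2)
  user <- list(...)
  for (k in names(user)) args[[k]] <- user[[k]]
  do.call(sim_config, args)
}

# One constructed track in the long table format.
make_track <- function(id, area_fun, t_end = 24, dt = 0.25, g1s = 10,
                       condition = "ctrl") {
  tt <- seq(0, t_end, by = dt)
  data.frame(track_id = id, condition = condition, time_h = tt,
             nuclear_area = area_fun(tt), geminin = ifelse(tt < g1s, 0.01,
                                                           0.01 + (tt - g1s) / 12),
             birth_time_h = 0, g1s_time_h = g1s, division_time_h = t_end,
             complete = TRUE, stringsAsFactors = FALSE)
}

# Minimal cell table with one k48 value per well (so well summaries are the
# values themselves) for hand-computable delta-K48 examples.
wells_table <- function(values, cfz, condition = "control", stage = NULL,
                        size = 1, n_rep = 4) {
  values <- unname(values)
  size <- unname(size)
  rows <- lapply(seq_along(values), function(i) {
    data.frame(
      cell_id = sprintf("c%02d_%d", i, seq_len(n_rep)),
      well_id = sprintf("%s_%s_w%02d", condition, if (cfz) "p" else "m", i),
      condition = condition, fixation_time_h = 24,
      cfz_flag = cfz, chx_flag = FALSE,
      dna = 100, geminin = 0.01,
      size_se = size, k48 = values[i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(stage)) out$stage <- factor(stage, levels = STAGE_LEVELS)
  out
}

# Manually constructed trajectory curve (unit square diagonal-free shapes)
# for projection unit tests.
manual_curve <- function(px, py) {
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  structure(list(
    points = data.frame(dna = px, log_geminin = py),
    points_std = cbind(px, py),
    ell = c(0, cumsum(seg)) / sum(seg),
    center = c(dna = 0, log_geminin = 0),
    scale = c(dna = 1, log_geminin = 1),
    bandwidth = c(0.1, 0.1), grid_n = 100
  ), class = "trajectory_curve")
}
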