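# Agent-based growth/division engine.
#
# Cells carry mass M (a.u., the quantity measured by the protein dye),
# a cycle phase in {G1, G1/S, S, G2+M}, a phase age, sampled timers for the
# timed phases, a K48-polyUb pool U and a Geminin reporter level. Mass obeys
#   dM/dt = [s - d0 (M/M_target)^beta] * M
# integrated by forward Euler at dt_h. G1 exit is sizer-gated (hazard
# increasing in relative mass), G1/S, S and G2+M are Gamma timers, and
# division halves mass with asymmetry noise; the engine follows one random
# daughter unless branching is requested (bulk time courses).

STAGE_LEVELS <- c("G1", "G1/S", "S", "G2+M")

# Approximate-steady-state initial population; a burn-in refines it.
new_population <- function(n, pars, cfg, well = rep(1L, n)) {
  nominal_g1 <- 11
  durs <- c(nominal_g1, pars$g1s_mean, pars$s_mean, pars$g2m_mean)
  phase <- sample.int(4L, n, replace = TRUE, prob = durs / sum(durs))
  timer <- rep(Inf, n)
  for (ph in 2:4) {
    i <- which(phase == ph)
    if (length(i))
      timer[i] <- switch(ph - 1L,
        rdur(length(i), pars$g1s_mean, pars$g1s_cv),
        rdur(length(i), pars$s_mean, pars$s_cv),
        rdur(length(i), pars$g2m_mean, pars$g2m_cv))
  }
  age <- stats::runif(n) * ifelse(is.finite(timer), timer, nominal_g1)
  offset <- c(0, cumsum(durs))[phase]
  M <- stats::rlnorm(n, meanlog = log(0.95 * pars$target_eff), sdlog = 0.2)
  gem <- ifelse(phase >= 2L, cfg$gem_baseline + cfg$gem_rate * (offset + age - nominal_g1),
                cfg$gem_baseline)
  gem <- pmax(gem, cfg$gem_baseline)
  flux <- pars$d0_eff * (M / pars$target_eff)^pars$beta * M
  list(n = n, well = well, M = M, phase = phase, age = age, timer = timer,
       U = flux / cfg$k48_pool_turnover, gem = gem,
       cycle_age = offset + age, flux = flux, syn = pars$s_eff * M)
}

# One Euler step; returns the state plus indices of this step's events.
step_population <- function(st, pars, cfg, dt, cfz = FALSE, chx = FALSE,
                            branch = FALSE) {
  phase <- st$phase
  M <- st$M
  rel <- M / pars$target_eff
  comp <- pars$d0_eff * rel^pars$beta
  if (pars$comp_pre_g1s)
    comp <- ifelse(phase <= 2L, comp, pars$d0_eff)
  flux <- comp * M
  if (pars$g1s_hyper != 1)
    flux <- flux * ifelse(phase == 2L, pars$g1s_hyper, 1)
  if (chx) flux <- flux * (1 - cfg$nascent_fraction)
  syn <- if (chx) numeric(st$n) else pars$s_eff * M
  blocked <- cfz || pars$proteasome_off
  deg <- if (blocked) numeric(st$n) else flux
  st$M <- M + (syn - deg) * dt
  st$U <- st$U + (flux - (if (blocked) 0 else cfg$k48_pool_turnover) * st$U) * dt
  st$flux <- flux
  st$syn <- syn
  events <- list(g1s = integer(0), division = integer(0))
  if (chx) {
    # no protein synthesis: cycle progression (cyclin-driven) and reporter
    # accumulation pause; only mass decay and the K48 pool evolve
    st$events <- events
    return(st)
  }
  acc <- phase >= 2L
  st$gem[acc] <- st$gem[acc] + cfg$gem_rate * dt
  st$age <- st$age + dt
  st$cycle_age <- st$cycle_age + dt

  g1 <- which(phase == 1L)
  if (length(g1)) {
    hz <- pars$kchk_eff * pmax(0, st$M[g1] / pars$target_eff - pars$theta)
    go <- g1[stats::runif(length(g1)) < 1 - exp(-hz * dt)]
    if (length(go)) {
      st$phase[go] <- 2L
      st$age[go] <- 0
      st$timer[go] <- rdur(length(go), pars$g1s_mean, pars$g1s_cv)
      events$g1s <- go
    }
  }
  adv2 <- which(phase == 2L & st$age >= st$timer)
  if (length(adv2)) {
    st$phase[adv2] <- 3L
    st$age[adv2] <- 0
    st$timer[adv2] <- rdur(length(adv2), pars$s_mean, pars$s_cv)
  }
  adv3 <- which(phase == 3L & st$age >= st$timer)
  if (length(adv3)) {
    st$phase[adv3] <- 4L
    st$age[adv3] <- 0
    st$timer[adv3] <- rdur(length(adv3), pars$g2m_mean, pars$g2m_cv)
  }
  div <- which(phase == 4L & st$age >= st$timer)
  if (length(div)) {
    f <- 0.5 * (1 + stats::rnorm(length(div)) * cfg$division_asymmetry_cv)
    f <- pmin(pmax(f, 0.3), 0.7)
    if (branch) {
      k <- length(div)
      st$well <- c(st$well, st$well[div])
      st$M <- c(st$M, st$M[div] * (1 - f))
      st$phase <- c(st$phase, rep(1L, k))
      st$age <- c(st$age, numeric(k))
      st$timer <- c(st$timer, rep(Inf, k))
      st$U <- c(st$U, st$U[div] * (1 - f))
      st$gem <- c(st$gem, rep(cfg$gem_baseline, k))
      st$cycle_age <- c(st$cycle_age, numeric(k))
      st$flux <- c(st$flux, st$flux[div] * (1 - f))
      st$syn <- c(st$syn, st$syn[div] * (1 - f))
      st$n <- st$n + k
    }
    st$M[div] <- st$M[div] * f
    st$U[div] <- st$U[div] * f
    st$gem[div] <- cfg$gem_baseline
    st$phase[div] <- 1L
    st$age[div] <- 0
    st$timer[div] <- Inf
    st$cycle_age[div] <- 0
    events$division <- div
  }
  st$events <- events
  st
}

# Advance a population for `hours`; optionally collect event times.
advance_population <- function(st, pars, cfg, hours, cfz = FALSE, chx = FALSE,
                               branch = FALSE, collect_events = FALSE,
                               t0 = 0, cond_t0 = Inf) {
  steps <- max(0L, as.integer(round(hours / cfg$dt_h)))
  ev_cell <- integer(0); ev_time <- numeric(0); ev_type <- character(0)
  ev_mass <- numeric(0)
  ramping <- !is.null(pars$ramp) && is.finite(cond_t0)
  for (k in seq_len(steps)) {
    pk <- if (ramping) pars_at(pars, cond_t0 + k * cfg$dt_h) else pars
    st <- step_population(st, pk, cfg, cfg$dt_h, cfz = cfz, chx = chx,
                          branch = branch)
    if (collect_events) {
      e <- st$events
      if (length(e$g1s)) {
        ev_cell <- c(ev_cell, e$g1s)
        ev_time <- c(ev_time, rep(t0 + k * cfg$dt_h, length(e$g1s)))
        ev_type <- c(ev_type, rep("g1s", length(e$g1s)))
        ev_mass <- c(ev_mass, st$M[e$g1s])
      }
      if (length(e$division)) {
        ev_cell <- c(ev_cell, e$division)
        ev_time <- c(ev_time, rep(t0 + k * cfg$dt_h, length(e$division)))
        ev_type <- c(ev_type, rep("division", length(e$division)))
        ev_mass <- c(ev_mass, st$M[e$division])
      }
    }
  }
  if (collect_events)
    st$event_log <- data.frame(cell = ev_cell, time_h = ev_time,
                               event = ev_type, mass = ev_mass)
  st
}

# Instantaneous ubiquitination flux given the current state (same rules as
# the step kernel, evaluated at readout).
current_flux <- function(st, pars, cfg, chx = FALSE) {
  comp <- pars$d0_eff * (st$M / pars$target_eff)^pars$beta
  if (pars$comp_pre_g1s)
    comp <- ifelse(st$phase <= 2L, comp, pars$d0_eff)
  flux <- comp * st$M
  if (pars$g1s_hyper != 1)
    flux <- flux * ifelse(st$phase == 2L, pars$g1s_hyper, 1)
  if (chx) flux <- flux * (1 - cfg$nascent_fraction)
  flux
}

# True DNA content in 2N..4N units given phase state.
dna_content <- function(st) {
  dna <- rep(2, st$n)
  s <- st$phase == 3L
  dna[s] <- 2 * (1 + pmin(1, st$age[s] / st$timer[s]))
  dna[st$phase == 4L] <- 4
  dna
}

#' Advance a single cell state by one time step
#'
#' Scalar interface to the population engine, mainly for inspection and
#' unit-level checks of the growth law. `state` is a list with fields
#' `mass`, `phase` (one of "G1", "G1/S", "S", "G2+M"), `phase_age`,
#' `geminin`, `k48_pool` and, for timed phases, `timer`.
#'
#' @param state cell state list
#' @param cfg a [sim_config()]
#' @param dt time step (h), at most 0.1
#' @param condition perturbation arm (default "control")
#' @param cfz,chx logical; proteasome / translation blockade active
#' @return updated state list
#' @export
step_cell <- function(state, cfg, dt, condition = "control",
                      cfz = FALSE, chx = FALSE) {
  if (dt > 0.1) stop_field("step_cell: dt must be <= 0.1 h")
  validate_sim_config(cfg)
  for (f in c("mass", "phase_age", "geminin", "k48_pool")) {
    v <- state[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_field(sprintf("step_cell: field '%s' is missing or non-finite", f))
  }
  ph <- match(state$phase, STAGE_LEVELS)
  if (is.na(ph))
    stop_field("step_cell: field 'phase' must be one of G1, G1/S, S, G2+M")
  if (state$mass <= 0)
    stop_field("step_cell: field 'mass' must be positive")
  pars <- resolve_condition(cfg, condition)
  st <- list(n = 1L, well = 1L, M = state$mass, phase = ph,
             age = state$phase_age,
             timer = state$timer %||% Inf,
             U = state$k48_pool, gem = state$geminin,
             cycle_age = state$cycle_age %||% state$phase_age,
             flux = 0, syn = 0)
  st <- step_population(st, pars, cfg, dt, cfz = cfz, chx = chx)
  list(mass = st$M, phase = STAGE_LEVELS[st$phase], phase_age = st$age,
       timer = st$timer, geminin = st$gem, k48_pool = st$U,
       cycle_age = st$cycle_age, dna = dna_content(st),
       degradation_flux = st$flux)
}

# Split the treatment window into (plain / chx / chx+cfz) segments and
# advance through them.
advance_treatment <- function(st, pars, cfg, treat_h, cfz, chx, chx_h,
                              collect_events = FALSE, t0 = 0) {
  cfz_h <- if (cfz) cfg$cfz_block_min / 60 else 0
  chx_w <- if (chx) min(chx_h, treat_h) else 0
  cfz_h <- min(cfz_h, treat_h)
  plain <- treat_h - max(chx_w, cfz_h)
  seg2 <- max(0, max(chx_w, cfz_h) - cfz_h)   # chx only
  ev <- NULL
  run <- function(st, hours, fcfz, fchx, tt) {
    if (hours <= 0) return(st)
    st <- advance_population(st, pars, cfg, hours, cfz = fcfz, chx = fchx,
                             collect_events = collect_events, t0 = tt,
                             cond_t0 = tt - t0)
    if (collect_events) {
      ev <<- rbind(ev, st$event_log)
      st$event_log <- NULL
    }
    st
  }
  st <- run(st, plain, FALSE, FALSE, t0)
  st <- run(st, seg2, FALSE, chx_w > 0, t0 + plain)
  st <- run(st, cfz_h, cfz, chx_w > 0 && chx_w >= cfz_h, t0 + plain + seg2)
  if (collect_events) st$event_log <- ev
  st
}

#' Simulate a fixed-cell snapshot arm
#'
#' Evolves an asynchronous steady-state population through a control burn-in
#' and then `treat_h` hours under a perturbation arm, optionally blocking
#' translation (`chx`) for the final `chx_h` hours and the proteasome
#' (`cfz`) for the final `cfz_block_min` minutes, then reads out per-cell
#' integrated intensities with multiplicative lognormal staining noise.
#' Ground-truth columns (`true_*`) for phase, cycle age, mass and
#' ubiquitination flux ride along for validation.
#'
#' @param cfg a [sim_config()]
#' @param condition perturbation arm name
#' @param treat_h treatment duration before fixation (h)
#' @param cfz logical; proteasome blockade during the last
#'   `cfg$cfz_block_min` minutes
#' @param chx logical; translation blockade during the last `chx_h` hours
#' @param chx_h translation-blockade window (h); default `cfg$chx_block_h`
#' @param n_wells,cells_per_well replicate structure; defaults from `cfg`
#' @param well_prefix optional prefix for well ids
#' @return data.frame of cell records (one row per cell)
#' @export
simulate_snapshot <- function(cfg, condition = "control", treat_h = 24,
                              cfz = FALSE, chx = FALSE, chx_h = NULL,
                              n_wells = NULL, cells_per_well = NULL,
                              well_prefix = NULL) {
  validate_sim_config(cfg)
  n_wells <- n_wells %||% cfg$n_wells
  cells_per_well <- cells_per_well %||% cfg$cells_per_well
  if (cells_per_well < 50)
    stop_field("simulate_snapshot: cells_per_well must be >= 50 (downstream density estimation is undefined below that)")
  chx_h <- chx_h %||% cfg$chx_block_h
  pars <- resolve_condition(cfg, condition)
  ctrl <- resolve_condition(cfg, "control")
  set.seed(derive_seed(cfg$seed,
                       paste(condition, treat_h, cfz, chx, chx_h, n_wells,
                             cells_per_well, well_prefix %||% "", sep = "|")))
  n <- n_wells * cells_per_well
  well <- rep(seq_len(n_wells), each = cells_per_well)
  st <- new_population(n, ctrl, cfg, well = well)
  st <- advance_population(st, ctrl, cfg, cfg$burn_in_h)
  st <- advance_treatment(st, pars, cfg, treat_h, cfz, chx, chx_h)

  cv <- cfg$staining_noise_cv
  arm <- if (cfz) "cfz" else "veh"
  if (chx) arm <- paste0(arm, "_chx")
  prefix <- well_prefix %||% gsub("[^A-Za-z0-9]", "", condition)
  well_id <- sprintf("%s_%s_w%02d", prefix, arm, st$well)
  dna_true <- dna_content(st)
  flux_true <- current_flux(st, pars, cfg, chx = chx)
  syn_true <- if (chx) numeric(st$n) else pars$s_eff * st$M
  data.frame(
    cell_id = sprintf("%s_c%05d", prefix, seq_len(st$n)),
    well_id = well_id,
    condition = condition,
    fixation_time_h = treat_h,
    cfz_flag = cfz,
    chx_flag = chx,
    dna = dna_true * cfg$dna_unit * rlnoise(st$n, cfg$dna_noise_cv),
    geminin = st$gem * rlnoise(st$n, cv),
    size_se = st$M * rlnoise(st$n, cv),
    aha = syn_true * 3 * rlnoise(st$n, cv),
    k48 = st$U * rlnoise(st$n, cv),
    mv151 = (if (pars$proteasome_off) 0 else st$M) * rlnoise(st$n, cv),
    true_phase = STAGE_LEVELS[st$phase],
    true_cycle_age = st$cycle_age,
    true_mass = st$M,
    true_flux = flux_true,
    stringsAsFactors = FALSE
  )
}

#' Simulate a paired +/-CFZ well experiment
#'
#' Convenience wrapper producing the matched vehicle and proteasome-blocked
#' arms of one condition at one fixation time, as used by [delta_k48()].
#'
#' @inheritParams simulate_snapshot
#' @return combined data.frame of both arms
#' @export
simulate_experiment <- function(cfg, condition = "control", treat_h = 24,
                                chx = FALSE, n_wells = NULL,
                                cells_per_well = NULL) {
  rbind(
    simulate_snapshot(cfg, condition, treat_h, cfz = FALSE, chx = chx,
                      n_wells = n_wells, cells_per_well = cells_per_well),
    simulate_snapshot(cfg, condition, treat_h, cfz = TRUE, chx = chx,
                      n_wells = n_wells, cells_per_well = cells_per_well)
  )
}

#' Simulate single-cell time-lapse tracks
#'
#' Records complete birth-to-division cycles under a condition at steady
#' state (control burn-in, then `treat_h` under the arm before recording).
#' The nuclear-area proxy is `area_scale * M^area_exponent` with per-frame
#' multiplicative noise; Geminin is recorded with the same noise CV.
#' Landmark times (birth, G1/S commitment, division) come from the
#' simulation events; times are rebased so that birth = 0.
#'
#' @param cfg a [sim_config()]
#' @param condition perturbation arm
#' @param n_tracks number of complete tracks to return
#' @param record_h recording window (h)
#' @param treat_h pre-recording treatment duration (h)
#' @return long data.frame: track_id, time_h, nuclear_area, geminin,
#'   birth_time_h, g1s_time_h, division_time_h, complete
#' @export
simulate_tracks <- function(cfg, condition = "control", n_tracks = 100,
                            record_h = 60, treat_h = 24) {
  validate_sim_config(cfg)
  pars <- resolve_condition(cfg, condition)
  ctrl <- resolve_condition(cfg, "control")
  set.seed(derive_seed(cfg$seed, paste("tracks", condition, n_tracks,
                                       record_h, treat_h, sep = "|")))
  n <- ceiling(n_tracks * 1.8) + 10
  st <- new_population(n, ctrl, cfg)
  st <- advance_population(st, ctrl, cfg, cfg$burn_in_h)
  st <- advance_population(st, pars, cfg, treat_h, cond_t0 = 0)

  dt <- cfg$dt_h
  frame_h <- cfg$frame_interval_min / 60
  frame_every <- max(1L, as.integer(round(frame_h / dt)))
  steps <- as.integer(round(record_h / dt))
  n_frames <- steps %/% frame_every + 1L
  Mrec <- matrix(NA_real_, n, n_frames)
  Grec <- matrix(NA_real_, n, n_frames)
  ftimes <- (0:(n_frames - 1)) * frame_every * dt
  Mrec[, 1] <- st$M
  Grec[, 1] <- st$gem
  birth <- rep(NA_real_, n); g1s <- rep(NA_real_, n)
  divide <- rep(NA_real_, n)
  for (k in seq_len(steps)) {
    pk <- if (is.null(pars$ramp)) pars else pars_at(pars, treat_h + k * dt)
    st <- step_population(st, pk, cfg, dt)
    tnow <- k * dt
    e <- st$events
    if (length(e$division)) {
      i <- e$division
      fresh <- i[is.na(birth[i])]
      birth[fresh] <- tnow
      done <- i[!is.na(birth[i]) & !is.na(g1s[i]) & is.na(divide[i]) &
                  birth[i] < tnow]
      divide[done] <- tnow
    }
    if (length(e$g1s)) {
      i <- e$g1s
      mark <- i[!is.na(birth[i]) & is.na(g1s[i]) & is.na(divide[i])]
      g1s[mark] <- tnow
    }
    if (k %% frame_every == 0L) {
      col <- k %/% frame_every + 1L
      Mrec[, col] <- st$M
      Grec[, col] <- st$gem
    }
  }
  ok <- which(!is.na(birth) & !is.na(g1s) & !is.na(divide))
  if (length(ok) < n_tracks)
    stop_field(sprintf(
      "simulate_tracks: only %d complete tracks in %g h window (need %d); increase record_h",
      length(ok), record_h, n_tracks))
  ok <- ok[seq_len(n_tracks)]
  out <- vector("list", length(ok))
  for (j in seq_along(ok)) {
    i <- ok[j]
    sel <- which(ftimes >= birth[i] & ftimes <= divide[i])
    nf <- length(sel)
    out[[j]] <- data.frame(
      track_id = sprintf("trk%04d", j),
      condition = condition,
      time_h = ftimes[sel] - birth[i],
      nuclear_area = cfg$area_scale * Mrec[i, sel]^cfg$area_exponent *
        rlnoise(nf, cfg$track_noise_cv),
      geminin = Grec[i, sel] * rlnoise(nf, cfg$track_noise_cv),
      birth_time_h = 0,
      g1s_time_h = g1s[i] - birth[i],
      division_time_h = divide[i] - birth[i],
      complete = TRUE,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate a bulk proliferation time course
#'
#' Branching population (both daughters kept) under a condition, reporting
#' cell counts and mean sizes at the requested fixation times, as in a
#' plate-based proliferation assay. Ground-truth columns ride along.
#'
#' @param cfg a [sim_config()]
#' @param condition perturbation arm
#' @param timepoints fixation times (h), from treatment start
#' @param founders number of founding cells
#' @param count_noise_cv,size_noise_cv readout noise CVs for counts and
#'   mean size
#' @return data.frame: time_h, cell_count, mean_size, condition, true_*
#' @export
simulate_bulk <- function(cfg, condition = "control",
                          timepoints = seq(0, 72, by = 12), founders = 150,
                          count_noise_cv = 0.03, size_noise_cv = 0.01) {
  validate_sim_config(cfg)
  stopifnot(all(diff(timepoints) > 0), all(timepoints >= 0))
  pars <- resolve_condition(cfg, condition)
  ctrl <- resolve_condition(cfg, "control")
  set.seed(derive_seed(cfg$seed, paste("bulk", condition, founders,
                                       paste(timepoints, collapse = ","),
                                       sep = "|")))
  st <- new_population(founders, ctrl, cfg)
  st <- advance_population(st, ctrl, cfg, cfg$burn_in_h)
  tp <- sort(timepoints)
  rows <- vector("list", length(tp))
  tprev <- 0
  for (i in seq_along(tp)) {
    st <- advance_population(st, pars, cfg, tp[i] - tprev, branch = TRUE,
                             cond_t0 = tprev)
    tprev <- tp[i]
    rows[[i]] <- data.frame(
      time_h = tp[i],
      cell_count = st$n * rlnoise(1, count_noise_cv),
      mean_size = mean(st$M) * rlnoise(1, size_noise_cv),
      condition = condition,
      true_count = st$n,
      true_mean_size = mean(st$M),
      true_mass_flux = mean((st$syn - st$flux)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
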