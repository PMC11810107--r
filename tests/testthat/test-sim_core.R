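# Growth law, phase logic, readouts and determinism of the simulator.

cell0 <- function(mass = 1, phase = "G1", gem = 0.01, U = 0.01) {
  list(mass = mass, phase = phase, phase_age = 0, geminin = gem,
       k48_pool = U, timer = Inf)
}

test_that("mass integrates the growth law: doubling, balance, flux", {
  # pure synthesis at ln2/20 per hour doubles mass in 20 h (up to the
  # documented first-order integration error)
  cfg <- sim_config(synthesis_rate_per_mass = log(2) / 20,
                    basal_degradation_per_mass = 0,
                    g1_checkpoint_strength = 0, staining_noise_cv = 0,
                    seed = 1)
  st <- cell0()
  for (i in 1:400) st <- step_cell(st, cfg, 0.05)
  expect_equal(st$mass, 2, tolerance = 1e-3)

  # synthesis equal to degradation leaves mass constant
  cfg2 <- sim_config(synthesis_rate_per_mass = 0.03,
                     basal_degradation_per_mass = 0.03,
                     compensation_exponent = 0,
                     g1_checkpoint_strength = 0, seed = 1)
  st <- cell0()
  for (i in 1:100) st <- step_cell(st, cfg2, 0.05)
  expect_equal(st$mass, 1, tolerance = 1e-12)

  # beta = 1, M = 2 M_target, d0 = 0.01/h: flux = d0 * (M/Mt)^1 * M
  #   = 0.01 * 2 * 2 = 0.04 Mt/h
  cfg3 <- sim_config(basal_degradation_per_mass = 0.01,
                     compensation_exponent = 1, target_size = 1,
                     g1_checkpoint_strength = 0, seed = 1)
  st <- step_cell(cell0(mass = 2), cfg3, 0.05)
  expect_equal(st$degradation_flux, 0.04, tolerance = 1e-12)
})

test_that("step_cell rejects bad input naming the offending field", {
  cfg <- sim_config(seed = 1)
  st <- cell0()
  st$mass <- NaN
  expect_error(step_cell(st, cfg, 0.05), "mass")
  st <- cell0()
  st$k48_pool <- Inf
  expect_error(step_cell(st, cfg, 0.05), "k48_pool")
  expect_error(step_cell(cell0(), cfg, 0.2), "dt")
  bad <- cell0(); bad$phase <- "M"
  expect_error(step_cell(bad, cfg, 0.05), "phase")
})

test_that("Euler mass update converges at first order", {
  cfg <- sim_config(compensation_exponent = 0.8,
                    g1_checkpoint_strength = 0, seed = 1)
  run <- function(dt) {
    st <- cell0(mass = 1.4)
    for (i in seq_len(round(5 / dt))) st <- step_cell(st, cfg, dt)
    st$mass
  }
  m1 <- run(0.05); m2 <- run(0.005); m3 <- run(0.0005)
  ratio <- (m1 - m2) / (m2 - m3)
  expect_gt(ratio, 8)   # ~10 for a first-order scheme
  expect_lt(ratio, 12)
})

test_that("identical seed and config give bit-identical outputs", {
  cfg <- test_cfg(seed = 7)
  a <- simulate_snapshot(cfg, "control", n_wells = 2, cells_per_well = 60)
  b <- simulate_snapshot(cfg, "control", n_wells = 2, cells_per_well = 60)
  expect_identical(a, b)
  ta <- simulate_tracks(cfg, "control", 10, record_h = 50)
  tb <- simulate_tracks(cfg, "control", 10, record_h = 50)
  expect_identical(ta, tb)
  expect_false(identical(
    a, simulate_snapshot(test_cfg(seed = 8), "control",
                         n_wells = 2, cells_per_well = 60)))
})

test_that("degradation flux scales as mass^(1+beta) in the ground truth", {
  cfg <- sim_config(seed = 11, n_wells = 9, cells_per_well = 600)
  snap <- simulate_snapshot(cfg, "control")  # control beta = 0.3
  fit <- stats::lm(log(true_flux) ~ log(true_mass), data = snap)
  expect_equal(unname(coef(fit)[2]), 1.3, tolerance = 1e-6)
  snap0 <- simulate_snapshot(cfg, "null0")   # beta = 0: exact proportionality
  fit0 <- stats::lm(log(true_flux) ~ log(true_mass), data = snap0)
  expect_equal(unname(coef(fit0)[2]), 1.0, tolerance = 1e-6)
})

test_that("proteasome blockade plants an excess of flux x block time", {
  cfg <- quiescent_cfg(seed = 3, staining_noise_cv = 0)
  plus <- simulate_snapshot(cfg, "control", treat_h = 2, cfz = TRUE)
  minus <- simulate_snapshot(cfg, "control", treat_h = 2, cfz = FALSE)
  # stationary pool: excess = flux * 0.5 h per cell (small growth during
  # the blockade, as degradation itself is blocked)
  expect_equal(median(plus$k48) - median(minus$k48),
               0.5 * median(minus$true_flux), tolerance = 0.02)
})

test_that("snapshot population reaches size homeostasis", {
  cfg <- test_cfg(seed = 13)
  pars <- compgrowth:::resolve_condition(cfg, "control")
  set.seed(5)
  st <- compgrowth:::new_population(250, pars, cfg)
  st <- compgrowth:::advance_population(st, pars, cfg, 230,
                                        collect_events = TRUE)
  ev <- st$event_log
  ev <- ev[ev$event == "division", ]
  gen <- cut(ev$time_h, breaks = seq(0, 230, by = 23))
  cvs <- tapply(ev$mass, gen, function(m) stats::sd(m) / mean(m))
  late <- tail(cvs[!is.na(cvs)], 5)
  # newborn CV bounded (< 2x the division asymmetry CV) and stationary
  expect_lt(mean(late), 2 * 2 * cfg$division_asymmetry_cv)
  expect_lt(abs(late[5] - late[4]) / late[4], 0.2)
})

test_that("CDK2i arm lengthens G1 by about a third", {
  cfg <- test_cfg(seed = 21)
  ctrl <- simulate_tracks(cfg, "control", 120, record_h = 60)
  cdk <- simulate_tracks(cfg, "CDK2i", 120, record_h = 75)
  g1c <- mean(unique(ctrl[, c("track_id", "g1s_time_h")])$g1s_time_h)
  g1p <- mean(unique(cdk[, c("track_id", "g1s_time_h")])$g1s_time_h)
  expect_gt(g1p / g1c, 1.18)
  expect_lt(g1p / g1c, 1.46)
})

test_that("noise-free tracks are exactly exponential with Geminin marking G1/S", {
  cfg <- sim_config(seed = 31, track_noise_cv = 0, n_wells = 9,
                    cells_per_well = 80)
  tr <- simulate_tracks(cfg, "null0", 20, record_h = 60)
  for (id in unique(tr$track_id)[1:5]) {
    one <- tr[tr$track_id == id, ]
    d <- diff(log(one$nuclear_area))
    expect_lt(stats::sd(d), 1e-10)  # geometric growth, beta = 0
    # first Geminin rise above baseline marks the recorded G1/S time
    rise <- one$time_h[which(one$geminin > cfg$gem_baseline * 1.5)[1]]
    expect_lt(abs(rise - one$g1s_time_h[1]), 0.75)
  }
})

test_that("bulk counts grow log-linearly at the population rate", {
  cfg <- test_cfg(seed = 41)
  b <- simulate_bulk(cfg, "control", founders = 300)
  fit <- stats::lm(log(true_count) ~ time_h, data = b)
  expect_gt(summary(fit)$r.squared, 0.99)
  slope <- unname(coef(fit)[2])
  expect_gt(slope, log(2) / 26)  # cycle ~23 h
  expect_lt(slope, log(2) / 20)
  ck <- simulate_bulk(cfg, "CDK2i", founders = 300)
  slope_ck <- unname(coef(stats::lm(log(true_count) ~ time_h, ck))[2])
  expect_lt(slope_ck, slope)     # longer cycle, slower proliferation
})

test_that("snapshot guards its preconditions", {
  cfg <- test_cfg(seed = 1)
  expect_error(simulate_snapshot(cfg, "control", cells_per_well = 30), "50")
  expect_error(simulate_snapshot(cfg, "no-such-arm"), "condition")
})
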