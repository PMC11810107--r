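# Growth-rate and cycle-length inference from bulk curves and tracks.

test_that("exponential count fits give exact cycle lengths", {
  bulk <- data.frame(time_h = c(0, 24, 48), cell_count = c(1000, 2000, 4000))
  fit <- fit_cycle_length(bulk)
  expect_equal(fit$tau, 24, tolerance = 1e-10)
  expect_equal(fit$alpha * fit$tau, log(2), tolerance = 1e-12)

  flat <- data.frame(time_h = c(0, 24, 48), cell_count = c(1000, 1000, 1000))
  f2 <- fit_cycle_length(flat)
  expect_true(is.na(f2$tau))
  expect_match(f2$diagnostic, "undefined")
  expect_error(fit_cycle_length(bulk[1:2, ]), "3")
})

test_that("noisy cycle-length recovery stays within two percent", {
  tau <- 20; alpha <- log(2) / tau
  tt <- seq(0, 72, by = 12)
  errs <- vapply(1:25, function(i) {
    set.seed(400 + i)
    counts <- 500 * exp(alpha * tt) *
      rlnorm(7, -log(1 + 0.05^2) / 2, sqrt(log(1 + 0.05^2)))
    abs(fit_cycle_length(data.frame(time_h = tt, cell_count = counts))$tau -
          tau) / tau
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("bulk growth rate nu matches the analytic derivative", {
  s <- 1.7; alpha <- 0.03
  tt <- seq(0, 72, by = 12)
  bulk <- data.frame(time_h = tt, cell_count = 1000 * exp(alpha * tt),
                     mean_size = s)
  nu <- bulk_growth_rate(bulk)
  interior <- 2:(length(tt) - 1)
  # central difference of an exponential: s*alpha*sinh(a dt)/(a dt)
  expected <- s * alpha * sinh(alpha * 12) / (alpha * 12)
  expect_equal(nu$nu[interior], rep(expected, length(interior)),
               tolerance = 1e-10)
  expect_lt(max(abs(nu$nu[interior] - s * alpha)), s * alpha * 0.05)

  const <- data.frame(time_h = tt, cell_count = 1000, mean_size = s)
  expect_true(all(bulk_growth_rate(const)$nu == 0))
  bad <- bulk; bad$time_h[3] <- bad$time_h[2]
  expect_error(bulk_growth_rate(bad), "increasing")
})

test_that("nu recovers the simulator's mass flux without count noise", {
  cfg <- test_cfg(seed = 81)
  b <- simulate_bulk(cfg, "control", founders = 400, count_noise_cv = 0,
                     size_noise_cv = 0)
  nu <- bulk_growth_rate(b)
  interior <- 2:(nrow(b) - 1)
  rel <- abs(nu$nu[interior] - b$true_mass_flux[interior]) /
    b$true_mass_flux[interior]
  expect_lt(stats::median(rel), 0.05)
})

test_that("track rates are exact on linear and exponential areas", {
  lin <- make_track("a", function(t) 50 + 3 * t)
  r <- track_growth_rate(lin)
  expect_equal(r$rate, rep(3, length(r$rate)), tolerance = 1e-10)
  expect_equal(r$mean_rate, 3, tolerance = 1e-10)

  g <- 0.02
  ex <- make_track("b", function(t) 80 * exp(g * t))
  re <- track_growth_rate(ex)
  a_true <- 80 * exp(g * re$time)
  expect_lt(max(abs(re$rate - g * a_true) / (g * a_true)), 0.01)

  # scale equivariance: area x c scales rates x c exactly
  ex2 <- ex; ex2$nuclear_area <- ex2$nuclear_area * 3.2
  re2 <- track_growth_rate(ex2)
  expect_equal(re2$rate, re$rate * 3.2, tolerance = 1e-12)

  short <- make_track("c", function(t) t + 10, t_end = 3)
  expect_error(track_growth_rate(short), "short")
  both <- rbind(ex, short)
  rr <- track_growth_rates(both)
  expect_equal(nrow(rr), 1)
  expect_length(attr(rr, "excluded"), 1)
})

test_that("smoothing window choice barely moves the recovered rates", {
  cfg <- test_cfg(seed = 82)
  tr <- simulate_tracks(cfg, "null0", 40, record_h = 60)
  means <- vapply(c(3, 5, 9), function(w) {
    mean(track_growth_rates(tr, smooth_window = w)$mean_specific_rate)
  }, numeric(1))
  expect_lt(diff(range(means)) / mean(means), 0.02)
})

test_that("aligned identical tracks reproduce the track with zero-width CI", {
  tr <- do.call(rbind, lapply(1:12, function(i)
    transform(make_track(sprintf("t%02d", i), function(t) 50 + 2 * t),
              track_id = sprintf("t%02d", i))))
  al <- align_tracks(tr, anchor = "birth")
  expect_equal(al$mean, 50 + 2 * (al$aligned_time), tolerance = 1e-10)
  expect_true(all(al$ci_high - al$ci_low < 1e-10))
  expect_true(all(al$n == 12))
})

test_that("birth-aligned synthetic tracks show the planted growth", {
  cfg <- sim_config(seed = 83, track_noise_cv = 0, n_wells = 9,
                    cells_per_well = 80)
  tr <- simulate_tracks(cfg, "null0", 40, record_h = 60)
  al <- align_tracks(tr, anchor = "birth")
  # rising mean curve whose log-slope matches the planted area rate
  core <- al$mean[al$n >= 30]
  expect_gt(core[length(core)], core[1])
  expect_gt(mean(diff(core) > 0), 0.8)
  g_area <- (2 / 3) * (cfg$synthesis_rate_per_mass -
                         cfg$basal_degradation_per_mass)
  sel <- al$n >= 35
  fit <- stats::lm(log(al$mean[sel]) ~ al$aligned_time[sel])
  expect_equal(unname(coef(fit)[2]), g_area, tolerance = 0.15)
})

test_that("the size checkpoint converges birth-size classes by G1/S", {
  cfg <- test_cfg(seed = 84, track_noise_cv = 0)
  tc <- simulate_tracks(cfg, "control", 150, record_h = 65)
  rr <- track_growth_rates(tc)
  q <- stats::quantile(rr$birth_area, c(0.25, 0.75))
  small <- tc[tc$track_id %in% rr$track_id[rr$birth_area <= q[1]], ]
  large <- tc[tc$track_id %in% rr$track_id[rr$birth_area >= q[2]], ]
  near0 <- function(al) al$mean[which.min(abs(al$aligned_time))]
  gap_birth <- near0(align_tracks(large, "birth", min_tracks = 5)) -
    near0(align_tracks(small, "birth", min_tracks = 5))
  gap_g1s <- near0(align_tracks(large, "g1s", min_tracks = 5)) -
    near0(align_tracks(small, "g1s", min_tracks = 5))
  expect_gt(gap_birth, 0)
  expect_lt(abs(gap_g1s), 0.5 * gap_birth)
})

test_that("phase durations recover planted arm differences", {
  cfg <- test_cfg(seed = 85)
  tc <- simulate_tracks(cfg, "control", 100, record_h = 60)
  tk <- simulate_tracks(cfg, "CDK2i", 100, record_h = 75)
  pd <- phase_durations(rbind(tc, tk))
  g1row <- pd$comparison[pd$comparison$measure == "G1", ]
  target <- 0.32 * pd$stats$mean[pd$stats$condition == "control" &
                                   pd$stats$measure == "G1"]
  expect_gt(g1row$diff, 0)
  expect_gte(g1row$ci_high, target)
  expect_lte(g1row$ci_low, target)

  # identical arms: difference CI covers zero
  half <- unique(tc$track_id)[1:50]
  ta <- tc[tc$track_id %in% half, ]
  tb <- tc[!tc$track_id %in% half, ]
  tb$condition <- "mock"
  pd2 <- phase_durations(rbind(ta, tb))
  g2 <- pd2$comparison[pd2$comparison$measure == "G1", ]
  expect_lte(g2$ci_low, 0)
  expect_gte(g2$ci_high, 0)
})

test_that("planted growth-rate reduction is recovered from tracks", {
  cfg <- test_cfg(seed = 86)
  t1 <- simulate_tracks(cfg, "null0", 100, record_h = 60)
  t2 <- simulate_tracks(cfg, "growth_slow", 100, record_h = 70)
  r1 <- track_growth_rates(t1)
  r2 <- track_growth_rates(t2)
  ratio <- mean(r2$mean_specific_rate) / mean(r1$mean_specific_rate)
  expect_lt(abs(ratio - 0.79) / 0.79, 0.03)
})

test_that("size classes compare as expected on constructed tracks", {
  # homogeneous population: no difference
  set.seed(9)
  hom <- do.call(rbind, lapply(1:30, function(i)
    make_track(sprintf("h%02d", i),
               function(t) 80 * exp(0.02 * t) * (1 + rnorm(length(t), 0, 0.01)))))
  r0 <- percentile_growth_compare(hom, split = "whole")
  expect_lt(abs(r0$difference) / mean(r0$stats$mean_rate), 0.03)

  # common specific rate, spread birth sizes: large grows faster everywhere
  het <- do.call(rbind, lapply(1:30, function(i) {
    a0 <- 60 + 2 * i
    make_track(sprintf("g%02d", i), function(t) a0 * exp(0.02 * t))
  }))
  for (sp in c("whole", "pre_g1s", "post_g1s")) {
    r <- percentile_growth_compare(het, split = sp)
    expect_gt(r$difference, 0)
    expect_lt(r$p, 0.05)
  }

  # planted mechanism: rates equalized before G1/S, proportional after
  mech <- do.call(rbind, lapply(1:30, function(i) {
    a0 <- 60 + 2 * i
    make_track(sprintf("m%02d", i), function(t)
      ifelse(t < 10, a0 + 1.6 * t, (a0 + 16) * exp(0.02 * (t - 10))))
  }))
  pre <- percentile_growth_compare(mech, split = "pre_g1s")
  post <- percentile_growth_compare(mech, split = "post_g1s")
  # equalized before the transition (any leak is from smoothing across the
  # kink), strongly size-ordered after it
  expect_lt(abs(pre$difference), 0.1 * post$difference)
  expect_gt(post$ci_low, 0)
})
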