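# delta-K48 statistics, scaling, CHX analyses, marker fits, G1/S deviation.

test_that("cross-pair delta-K48 matches the hand-computed example", {
  plus <- wells_table(c(130, 132, 128), cfz = TRUE)
  minus <- wells_table(c(100, 101, 99), cfz = FALSE)
  d <- delta_k48(plus, minus)
  expect_equal(d$delta_k48[1], 30.0, tolerance = 1e-12)
  expect_equal(d$n_pairs[1], 9)
  # cross-pair mean equals the difference of arm means (identity)
  expect_equal(d$delta_k48[1], mean(c(130, 132, 128)) - mean(c(100, 101, 99)),
               tolerance = 1e-12)
})

test_that("identical arms give zero with a CI spanning zero", {
  plus <- wells_table(c(100, 103, 98, 101), cfz = TRUE)
  minus <- wells_table(c(100, 103, 98, 101), cfz = FALSE)
  d <- delta_k48(plus, minus)
  expect_equal(d$delta_k48[1], 0, tolerance = 1e-12)
  expect_lte(d$ci_low[1], 0)
  expect_gte(d$ci_high[1], 0)
})

test_that("the estimator is location-equivariant in background", {
  plus <- wells_table(c(130, 135, 128), cfz = TRUE)
  minus <- wells_table(c(101, 99, 104), cfz = FALSE)
  d0 <- delta_k48(plus, minus)
  plus$k48 <- plus$k48 + 57
  minus$k48 <- minus$k48 + 57
  d1 <- delta_k48(plus, minus)
  expect_equal(d1$delta_k48[1], d0$delta_k48[1], tolerance = 1e-12)
  expect_equal(d1$ci_low[1], d0$ci_low[1], tolerance = 1e-12)
})

test_that("mismatched arms and single pairs are handled", {
  plus <- wells_table(c(130), cfz = TRUE)
  minus <- wells_table(c(100), cfz = FALSE)
  d <- delta_k48(plus, minus)
  expect_true(is.na(d$ci_low[1]))   # single pair: CI undefined, flagged
  minus2 <- wells_table(c(100), cfz = FALSE, condition = "CDK2i")
  expect_error(delta_k48(plus, minus2), "condition")
})

test_that("planted clearance flux is recovered within the estimator's CI", {
  cfg <- quiescent_cfg(seed = 71)
  e <- simulate_experiment(cfg, "control", treat_h = 2)
  plus <- e[e$cfz_flag, ]; minus <- e[!e$cfz_flag, ]
  d <- delta_k48(plus, minus, well_stat = "mean")
  D <- mean(c(mean(plus$true_flux), mean(minus$true_flux))) * 0.5
  expect_gt(D, d$ci_low[1])
  expect_lt(D, d$ci_high[1])
})

test_that("scaling analysis reproduces the fold-change arithmetic", {
  # folds 1.30 on clearance and 1.034 on size give an excess ratio of
  # 1.30 / 1.034 = 1.257
  ctrl_p <- wells_table(c(10, 10.2, 9.8), cfz = TRUE, size = 1)
  ctrl_m <- wells_table(c(0.05, -0.05, 0), cfz = FALSE, size = 1)
  pert_p <- wells_table(c(13.05, 13.2, 12.75), cfz = TRUE,
                        condition = "pert", size = 1.034)
  pert_m <- wells_table(c(0.02, -0.02, 0), cfz = FALSE,
                        condition = "pert", size = 1.034)
  dc <- delta_k48(ctrl_p, ctrl_m)
  dp <- delta_k48(pert_p, pert_m)
  sc <- scaling_analysis(dc, dp, n_boot = 50, seed = 1)
  expect_equal(sc$fold_delta, 1.3, tolerance = 1e-9)
  expect_equal(sc$fold_size, 1.034, tolerance = 1e-9)
  expect_equal(sc$excess_ratio, 1.3 / 1.034, tolerance = 1e-9)
})

test_that("proportional changes are not called superlinear", {
  cfg1 <- quiescent_cfg(seed = 72)
  cfg2 <- quiescent_cfg(seed = 73)
  e1 <- simulate_experiment(cfg1, "control", treat_h = 2)
  e2 <- simulate_experiment(cfg2, "control", treat_h = 2)
  d1 <- delta_k48(e1[e1$cfz_flag, ], e1[!e1$cfz_flag, ])
  d2 <- delta_k48(e2[e2$cfz_flag, ], e2[!e2$cfz_flag, ])
  sc <- scaling_analysis(d1, d2, n_boot = 400, seed = 2)
  expect_gt(sc$superlinear_p, 0.1)
  expect_lt(sc$superlinear_p, 0.9)
  expect_equal(sc$excess_ratio, 1, tolerance = 0.1)
})

test_that("CHX decomposition covers its edge cases and planted share", {
  mk <- function(delta) data.frame(condition = "control", stage = "all",
                                   delta_k48 = delta, stringsAsFactors = FALSE)
  expect_equal(chx_decomposition(mk(5), mk(5))$nascent_share, 0)
  expect_equal(chx_decomposition(mk(0), mk(5))$nascent_share, 1)
  expect_false(chx_decomposition(mk(1), mk(-2))$defined)
  clip <- chx_decomposition(mk(7), mk(5))
  expect_true(clip$clipped)
  expect_equal(clip$nascent_share, 0)

  # quiescent population: planted 40% nascent fraction recovered
  cfg <- quiescent_cfg(seed = 74, n_wells = 18)
  ew <- simulate_experiment(cfg, "control", treat_h = 4, chx = TRUE)
  eo <- simulate_experiment(cfg, "control", treat_h = 4)
  dw <- delta_k48(ew[ew$cfz_flag, ], ew[!ew$cfz_flag, ])
  do <- delta_k48(eo[eo$cfz_flag, ], eo[!eo$cfz_flag, ])
  dec <- chx_decomposition(dw, do)
  expect_lt(abs(dec$nascent_share - 0.4), 0.05)
})

test_that("chase slopes are zero without degradation and recover a planted rate", {
  set.seed(6)
  base <- expand.grid(rep = 1:200, chase_time_h = c(0, 1.5, 3, 6, 9))
  base$stage <- "G1"
  base$well_id <- sprintf("w%02d", base$rep %% 8)
  base$size_se <- rep(exp(rnorm(200, 0, 0.25)), 5)
  still <- base
  ch0 <- chx_chase_slopes(still)
  expect_true(all(abs(ch0$slopes$slope_per_h) < 1e-12))

  # first-order loss at rate d for every cell: fractional slope ~ -d
  d <- 0.01
  lost <- base
  lost$size_se <- lost$size_se * exp(-d * lost$chase_time_h)
  ch1 <- chx_chase_slopes(lost)
  expect_true(all(abs(ch1$slopes$slope_per_h + d) < 0.1 * d))
})

test_that("larger cells lose protein faster under compensation", {
  snaps <- do.call(rbind, lapply(c(0, 1.5, 3, 6, 9), function(ct) {
    cfg <- sim_config(seed = 301, n_wells = 22, cells_per_well = 120,
                      compensation_exponent = 0.8)
    s <- simulate_snapshot(cfg, "control", treat_h = 24, chx = ct > 0,
                           chx_h = ct, well_prefix = paste0("t", ct * 10))
    s$chase_time_h <- ct
    s
  }))
  thr <- detect_thresholds(snaps[snaps$chase_time_h == 0, ])
  snaps <- assign_stage(snaps, thr)
  ch <- chx_chase_slopes(snaps)
  g1 <- ch$comparison[ch$comparison$stage == "G1", ]
  expect_lt(g1$slope_diff, 0)
  expect_lt(g1$p_large_faster, 0.05)
})

test_that("marker-size fits recover exact and null relations", {
  set.seed(7)
  cells <- data.frame(size_se = exp(rnorm(500, 0, 0.3)))
  cells$m <- 2 * cells$size_se
  f <- marker_size_fit(cells, "m")
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$pearson_r, 1, tolerance = 1e-9)
  cells$ind <- rnorm(500)
  set.seed(8)
  big <- data.frame(size_se = exp(rnorm(1e4, 0, 0.3)), ind = rnorm(1e4))
  expect_lt(abs(marker_size_fit(big, "ind")$pearson_r), 0.05)
  expect_error(marker_size_fit(data.frame(size_se = rep(1, 200), m = 1:200),
                               "m"), "variance")
})

test_that("nascent-protein readout correlates with size as in fixed cells", {
  cfg <- sim_config(seed = 75, n_wells = 18, cells_per_well = 300)
  snap <- simulate_snapshot(cfg, "control")
  f <- marker_size_fit(snap, "aha")
  expect_gt(f$pearson_r, 0.85)
  expect_lt(f$pearson_r, 0.95)
  fp <- marker_size_fit(snap, "mv151")  # active proteasomes track size
  expect_gt(fp$pearson_r, 0.8)
})

test_that("G1/S deviation is zero on the trend and detects planted excess", {
  # three stages on an exact line and G1/S exactly on it
  mk_arm <- function(cfz) {
    do.call(rbind, lapply(c("G1", "S", "G2+M", "G1/S"), function(sg) {
      sz <- c(G1 = 1, S = 1.3, `G2+M` = 1.6, `G1/S` = 1.15)[sg]
      base <- if (cfz) 10 + 5 * sz else 10
      wells_table(base + c(0, 0, 0), cfz = cfz, stage = sg, size = sz)
    }))
  }
  plus <- mk_arm(TRUE); minus <- mk_arm(FALSE)
  plus$well_id <- paste0(plus$well_id, "_", plus$stage)
  minus$well_id <- paste0(minus$well_id, "_", minus$stage)
  # rebuild with stage-constant wells via per_stage summaries
  d <- delta_k48(plus, minus, per_stage = TRUE)
  g <- g1s_deviation(d, n_boot = 50, seed = 1)
  expect_lt(abs(g$residual), 1e-9)

  cfg <- sim_config(seed = 123, n_wells = 9, cells_per_well = 100)
  e <- simulate_experiment(cfg, "G1S_hyper")
  e <- assign_stage(e, detect_thresholds(e))
  dh <- delta_k48(e[e$cfz_flag, ], e[!e$cfz_flag, ], per_stage = TRUE)
  gh <- g1s_deviation(dh, n_boot = 400, seed = 2)
  expect_gt(gh$residual, 0)
  expect_gt(gh$ci_low, 0)
})
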