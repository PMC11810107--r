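# Growth-rate and cell-cycle-length inference from bulk time courses and
# single-cell nuclear-area tracks.

#' Cell-cycle length from an exponential fit to cell counts
#'
#' Fits log cell count against time by unweighted least squares (log-space
#' fit: count noise is multiplicative), giving the proliferation rate
#' alpha and the cycle length tau = ln(2)/alpha, with a CI from the
#' regression standard error.
#'
#' @param bulk data.frame with `time_h` and `cell_count`
#' @param conf confidence level
#' @return list of class `growth_fit`: alpha, alpha_ci, tau, tau_ci,
#'   n; `tau` is NA with a diagnostic when alpha <= 0
#' @export
fit_cycle_length <- function(bulk, conf = 0.95) {
  if (!all(c("time_h", "cell_count") %in% names(bulk)))
    stop_field("fit_cycle_length: need columns 'time_h' and 'cell_count'")
  if (nrow(bulk) < 3)
    stop_field("fit_cycle_length: need >= 3 timepoints")
  if (any(bulk$cell_count <= 0))
    stop_field("fit_cycle_length: counts must be positive")
  fit <- stats::lm(log(cell_count) ~ time_h, data = bulk)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  alpha <- co["time_h", "Estimate"]
  se <- co["time_h", "Std. Error"]
  tq <- stats::qt(1 - (1 - conf) / 2, df = nrow(bulk) - 2)
  alpha_ci <- alpha + c(-1, 1) * tq * se
  out <- list(alpha = alpha, alpha_ci = alpha_ci, n = nrow(bulk),
              diagnostic = NULL)
  if (alpha > 0) {
    out$tau <- log(2) / alpha
    out$tau_ci <- sort(log(2) / alpha_ci)
  } else {
    out$tau <- NA_real_
    out$tau_ci <- c(NA_real_, NA_real_)
    out$diagnostic <- "non-positive proliferation rate: cycle length undefined"
  }
  structure(out, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Proliferation: alpha = %.4g /h (CI %.4g-%.4g), tau = %.3g h\n",
              x$alpha, x$alpha_ci[1], x$alpha_ci[2], x$tau))
  if (!is.null(x$diagnostic)) cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' Per-cell bulk growth rate nu(t)
#'
#' Total mass M_t = mean size x cell count; dM/dt by central differences
#' (one-sided at the ends); nu_t = (1/N_t) dM/dt.
#'
#' @param bulk data.frame with `time_h`, `cell_count`, `mean_size`
#' @return data.frame: time_h, nu
#' @export
bulk_growth_rate <- function(bulk) {
  if (!all(c("time_h", "cell_count", "mean_size") %in% names(bulk)))
    stop_field("bulk_growth_rate: need time_h, cell_count, mean_size")
  if (nrow(bulk) < 3)
    stop_field("bulk_growth_rate: need >= 3 timepoints")
  if (any(diff(bulk$time_h) <= 0))
    stop_field("bulk_growth_rate: times must be strictly increasing")
  M <- bulk$mean_size * bulk$cell_count
  dM <- central_diff(M, bulk$time_h)
  data.frame(time_h = bulk$time_h, nu = dM / bulk$cell_count)
}

#' Growth-rate series of one nuclear-area track
#'
#' Moving-average smoothing of the area series followed by a
#' central-difference derivative; the first and last `trim` frames are
#' excluded from all summaries (nuclear envelope breakdown/reformation).
#' The specific rate divides the derivative by the smoothed area, making
#' cross-condition rate ratios independent of the absolute area scale.
#'
#' @param track data.frame of one track: `time_h`, `nuclear_area`
#' @param smooth_window moving-average window (frames)
#' @param trim frames removed at each end
#' @return list: time, rate (a.u./h), specific_rate (1/h), mean_rate,
#'   mean_specific_rate
#' @export
track_growth_rate <- function(track, smooth_window = 5, trim = 6) {
  n <- nrow(track)
  if (n <= 2 * trim + smooth_window)
    stop_field(sprintf("track_growth_rate: track too short (%d frames <= 2*%d + %d)",
                       n, trim, smooth_window))
  o <- order(track$time_h)
  tt <- track$time_h[o]
  a <- moving_average(track$nuclear_area[o], smooth_window)
  r <- central_diff(a, tt)
  keep <- (trim + 1):(n - trim)
  list(time = tt[keep], rate = r[keep], specific_rate = r[keep] / a[keep],
       mean_rate = mean(r[keep]), mean_specific_rate = mean(r[keep] / a[keep]))
}

#' Growth-rate summaries for a table of tracks
#'
#' Applies [track_growth_rate()] per track; too-short tracks are excluded
#' with a logged reason (attribute `excluded`).
#'
#' @param tracks long track table (column `track_id`)
#' @inheritParams track_growth_rate
#' @return data.frame per track: track_id, mean_rate, mean_specific_rate,
#'   birth_area, g1s_time_h, division_time_h
#' @export
track_growth_rates <- function(tracks, smooth_window = 5, trim = 6) {
  out <- NULL
  excluded <- character(0)
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    res <- tryCatch(track_growth_rate(tr, smooth_window, trim),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded <- c(excluded, sprintf("%s: %s", id, res))
      next
    }
    o <- order(tr$time_h)
    keep <- (trim + 1):(nrow(tr) - trim)
    out <- rbind(out, data.frame(
      track_id = id, mean_rate = res$mean_rate,
      mean_specific_rate = res$mean_specific_rate,
      birth_area = mean(tr$nuclear_area[o][keep[1:min(3, length(keep))]]),
      g1s_time_h = tr$g1s_time_h[1], division_time_h = tr$division_time_h[1],
      stringsAsFactors = FALSE))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Mean growth trajectory over aligned tracks
#'
#' Shifts every track so its anchor (birth or the G1/S transition) sits at
#' time 0, snaps frames to the common frame grid, and reports the
#' pointwise mean area with a 95% t CI wherever at least `min_tracks`
#' tracks contribute; sparser tails are masked.
#'
#' @param tracks long track table
#' @param anchor "birth" or "g1s"
#' @param min_tracks minimum tracks per grid point
#' @param conf confidence level
#' @return data.frame: aligned_time, mean, ci_low, ci_high, n
#' @export
align_tracks <- function(tracks, anchor = c("birth", "g1s"),
                         min_tracks = 10, conf = 0.95) {
  anchor <- match.arg(anchor)
  acol <- if (anchor == "birth") "birth_time_h" else "g1s_time_h"
  ids <- unique(tracks$track_id)
  # frame spacing from within-track differences (tracks may carry
  # sub-frame offsets relative to each other)
  dtf <- stats::median(unlist(tapply(tracks$time_h, tracks$track_id,
                                     function(t) diff(sort(t)))))
  vals <- list()
  dropped <- character(0)
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    a0 <- tr[[acol]][1]
    if (!is.finite(a0)) {
      dropped <- c(dropped, id)
      next
    }
    g <- round((tr$time_h - a0) / dtf)
    vals[[id]] <- data.frame(g = g, area = tr$nuclear_area)
  }
  if (!length(vals))
    stop_field(sprintf("align_tracks: no track has a defined %s anchor", anchor))
  all <- do.call(rbind, vals)
  gs <- sort(unique(all$g))
  rows <- lapply(gs, function(gg) {
    v <- all$area[all$g == gg]
    if (length(v) < min_tracks) return(NULL)
    se <- stats::sd(v) / sqrt(length(v))
    tq <- stats::qt(1 - (1 - conf) / 2, df = length(v) - 1)
    data.frame(aligned_time = gg * dtf, mean = mean(v),
               ci_low = mean(v) - tq * se, ci_high = mean(v) + tq * se,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_field("align_tracks: no grid point reaches min_tracks")
  attr(out, "dropped") <- dropped
  out
}

#' G1 and total cycle durations, with a two-sample comparison
#'
#' G1 duration = G1/S time - birth; cycle duration = division - birth.
#' Per condition: mean with 95% t CI. With exactly two conditions a Welch
#' (unequal-variance) t-test compares them for each duration.
#'
#' @param tracks long track table with a `condition` column
#' @param conf confidence level
#' @return list: `stats` (condition, measure, mean, ci_low, ci_high, n),
#'   `comparison` (measure, diff, ci_low, ci_high, p) or NULL
#' @export
phase_durations <- function(tracks, conf = 0.95) {
  if (is.null(tracks$condition))
    tracks$condition <- "all"
  per <- unique(tracks[, c("track_id", "condition", "g1s_time_h",
                           "birth_time_h", "division_time_h")])
  per$g1 <- per$g1s_time_h - per$birth_time_h
  per$cycle <- per$division_time_h - per$birth_time_h
  per <- per[is.finite(per$g1) & is.finite(per$cycle), ]
  stats_rows <- NULL
  for (cond in unique(per$condition)) {
    for (m in c("g1", "cycle")) {
      v <- per[[m]][per$condition == cond]
      se <- stats::sd(v) / sqrt(length(v))
      tq <- stats::qt(1 - (1 - conf) / 2, df = length(v) - 1)
      stats_rows <- rbind(stats_rows, data.frame(
        condition = cond, measure = if (m == "g1") "G1" else "cycle",
        mean = mean(v), ci_low = mean(v) - tq * se,
        ci_high = mean(v) + tq * se, n = length(v),
        stringsAsFactors = FALSE))
    }
  }
  comparison <- NULL
  conds <- unique(per$condition)
  if (length(conds) == 2) {
    for (m in c("g1", "cycle")) {
      tt <- stats::t.test(per[[m]][per$condition == conds[2]],
                          per[[m]][per$condition == conds[1]],
                          conf.level = conf)  # Welch by default
      comparison <- rbind(comparison, data.frame(
        measure = if (m == "g1") "G1" else "cycle",
        contrast = sprintf("%s - %s", conds[2], conds[1]),
        diff = unname(diff(rev(tt$estimate))),
        ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
        p = tt$p.value, stringsAsFactors = FALSE))
    }
  }
  list(stats = stats_rows, comparison = comparison)
}

#' Growth-rate comparison between small and large cells
#'
#' Tracks are classed by birth size (area at the first retained frames):
#' small = at or below the lower percentile, large = at or above the upper
#' percentile. Mean trimmed growth rates are compared within the requested
#' interval (before the G1/S transition, after it, or the whole cycle)
#' with a Welch t-test.
#'
#' @param tracks long track table
#' @param size_percentiles percentile pair, default c(0.2, 0.8)
#' @param split "whole", "pre_g1s" or "post_g1s"
#' @param smooth_window,trim passed to [track_growth_rate()]
#' @param conf confidence level
#' @return list: `stats` per class, `difference` (large - small), ci, p
#' @export
percentile_growth_compare <- function(tracks, size_percentiles = c(0.2, 0.8),
                                      split = c("whole", "pre_g1s", "post_g1s"),
                                      smooth_window = 5, trim = 6,
                                      conf = 0.95) {
  split <- match.arg(split)
  ids <- unique(tracks$track_id)
  rates <- numeric(0)
  births <- numeric(0)
  kept <- character(0)
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    res <- tryCatch(track_growth_rate(tr, smooth_window, trim),
                    error = function(e) NULL)
    if (is.null(res)) next
    g1s <- tr$g1s_time_h[1]
    sel <- switch(split,
                  whole = rep(TRUE, length(res$time)),
                  pre_g1s = res$time < g1s,
                  post_g1s = res$time >= g1s)
    if (!any(sel)) next
    rates <- c(rates, mean(res$rate[sel]))
    o <- order(tr$time_h)
    keep1 <- (trim + 1):min(trim + 3, nrow(tr) - trim)
    births <- c(births, mean(tr$nuclear_area[o][keep1]))
    kept <- c(kept, id)
  }
  if (length(kept) < 10)
    stop_field("percentile_growth_compare: fewer than 10 usable tracks")
  q <- stats::quantile(births, size_percentiles, names = FALSE)
  small <- rates[births <= q[1]]
  large <- rates[births >= q[2]]
  if (!length(small) || !length(large))
    stop_field("percentile_growth_compare: empty size class")
  tt <- stats::t.test(large, small, conf.level = conf)
  list(
    stats = data.frame(class = c("small", "large"),
                       mean_rate = c(mean(small), mean(large)),
                       n = c(length(small), length(large))),
    difference = unname(diff(rev(tt$estimate))),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    p = tt$p.value, split = split
  )
}
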