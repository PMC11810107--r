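# Proteasome-flux statistics from paired +/-CFZ wells: delta-K48-polyUb,
# size-scaling analyses, CHX decomposition and chase slopes, marker-size
# linear fits, and the G1/S deviation from the stage-wise size trend.

# Per-well summaries of the K48 channel and size, overall and per stage.
well_summaries <- function(cells, well_stat, per_stage) {
  stat_fun <- if (well_stat == "median") stats::median else mean
  one <- function(df, stage) {
    data.frame(well_id = unique(df$well_id)[1], stage = stage,
               stat = stat_fun(df$k48), msize = stats::median(df$size_se),
               n = nrow(df), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(split(cells, cells$well_id), one, stage = "all"))
  if (per_stage) {
    if (is.null(cells$stage))
      stop_field("delta_k48: per_stage = TRUE needs a 'stage' column (run assign_stage first)")
    for (sg in levels(factor(cells$stage))) {
      sub <- cells[cells$stage == sg, ]
      if (!nrow(sub)) next
      res <- rbind(res, do.call(rbind, lapply(split(sub, sub$well_id), one,
                                              stage = sg)))
    }
  }
  rownames(res) <- NULL
  res
}

#' K48-polyUb clearance rate from paired proteasome-blockade wells
#'
#' The clearance statistic is the excess K48-polyUb accumulated during the
#' short proteasome blockade: every blocked well is paired with every
#' vehicle well of the same condition and fixation time, the difference of
#' well-level summaries (median per well by default) is taken per pair,
#' and the central estimate is the mean over all cross pairs — identical
#' to the difference of arm means of the well summaries. The 95% CI uses
#' the t distribution over pair values with a conservative effective
#' sample size (min wells per arm, minus one), so that the many cross
#' pairs are not treated as independent.
#'
#' @param plus_cfz cell records of the blocked arm
#' @param minus_cfz cell records of the vehicle arm
#' @param per_stage also compute per cell-cycle stage (requires a `stage`
#'   column)
#' @param well_stat "median" (default) or "mean" within wells
#' @param conf confidence level
#' @return data.frame with one row per stage ("all" first): condition,
#'   stage, delta_k48, ci_low, ci_high, n_pairs, median_size. Per-arm
#'   well summaries ride along in `attr(, "wells")` for resampling.
#' @export
delta_k48 <- function(plus_cfz, minus_cfz, per_stage = FALSE,
                      well_stat = c("median", "mean"), conf = 0.95) {
  well_stat <- match.arg(well_stat)
  for (df in list(plus_cfz, minus_cfz))
    if (!all(c("well_id", "condition", "fixation_time_h", "k48", "size_se")
             %in% names(df)))
      stop_field("delta_k48: arms need well_id, condition, fixation_time_h, k48, size_se")
  cond <- unique(c(plus_cfz$condition, minus_cfz$condition))
  if (length(cond) != 1)
    stop_field(sprintf("delta_k48: arms mix conditions (%s)",
                       paste(cond, collapse = ", ")))
  ft <- unique(c(plus_cfz$fixation_time_h, minus_cfz$fixation_time_h))
  if (length(ft) != 1)
    stop_field("delta_k48: arms mix fixation times")
  wp <- well_summaries(plus_cfz, well_stat, per_stage)
  wm <- well_summaries(minus_cfz, well_stat, per_stage)
  stages <- intersect(unique(wp$stage), unique(wm$stage))
  stages <- c("all", setdiff(stages, "all"))
  rows <- lapply(stages, function(sg) {
    a <- wp[wp$stage == sg, ]
    b <- wm[wm$stage == sg, ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    pairs <- as.vector(outer(a$stat, b$stat, "-"))
    n_eff <- min(nrow(a), nrow(b))
    est <- mean(pairs)
    if (n_eff > 1) {
      # conservative small-sample SE: effective n = min arm size, with a
      # -1 correction so cross-pair CIs are not anti-conservative
      se <- stats::sd(pairs) / sqrt(n_eff - 1)
      tq <- stats::qt(1 - (1 - conf) / 2, df = n_eff - 1)
      ci <- est + c(-1, 1) * tq * se
    } else {
      ci <- c(NA_real_, NA_real_)  # single pair: CI undefined
    }
    data.frame(condition = cond, stage = sg, delta_k48 = est,
               ci_low = ci[1], ci_high = ci[2], n_pairs = length(pairs),
               median_size = mean(c(a$msize, b$msize)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "wells") <- list(plus = wp, minus = wm)
  attr(out, "well_stat") <- well_stat
  attr(out, "conf") <- conf
  out
}

# Recompute per-stage delta and size from well summaries restricted to a
# well resample (indices into the unique well ids of each arm).
delta_from_wells <- function(wells, stages, plus_ids, minus_ids) {
  sapply(stages, function(sg) {
    a <- wells$plus[wells$plus$stage == sg, ]
    b <- wells$minus[wells$minus$stage == sg, ]
    av <- a$stat[match(plus_ids, a$well_id)]
    bv <- b$stat[match(minus_ids, b$well_id)]
    as <- a$msize[match(plus_ids, a$well_id)]
    bs <- b$msize[match(minus_ids, b$well_id)]
    c(delta = mean(av, na.rm = TRUE) - mean(bv, na.rm = TRUE),
      size = mean(c(as, bs), na.rm = TRUE))
  })
}

#' Fold-change scaling of degradation flux versus cell size
#'
#' Compares a perturbed arm to control: fold change in delta-K48-polyUb
#' against fold change in median size, with the excess ratio
#' (fold_delta / fold_size) quantifying superlinearity — a value of 1
#' means the clearance flux scaled proportionally with size. The one-sided
#' probability that the excess ratio is <= 1 is estimated by resampling
#' replicate wells (within each of the four well sets) `n_boot` times.
#'
#' @param control,perturbed [delta_k48()] results (with well attributes)
#' @param n_boot bootstrap replicates
#' @param stage stage row to compare (default "all")
#' @param seed optional seed for the resampling
#' @return list of class `scaling_fit`: fold_delta, fold_size,
#'   excess_ratio, superlinear_p, n_boot
#' @export
scaling_analysis <- function(control, perturbed, n_boot = 400,
                             stage = "all", seed = NULL) {
  for (r in list(control, perturbed))
    if (is.null(attr(r, "wells")))
      stop_field("scaling_analysis: inputs must be delta_k48() results")
  if (!stage %in% control$stage || !stage %in% perturbed$stage)
    stop_field(sprintf("scaling_analysis: stage '%s' missing from an arm", stage))
  dc <- control$delta_k48[control$stage == stage]
  dp <- perturbed$delta_k48[perturbed$stage == stage]
  sc <- control$median_size[control$stage == stage]
  sp <- perturbed$median_size[perturbed$stage == stage]
  fold_delta <- dp / dc
  fold_size <- sp / sc
  if (!is.finite(fold_delta) || !is.finite(fold_size) ||
      fold_delta <= 0 || fold_size <= 0)
    stop_field("scaling_analysis: non-positive fold change")
  if (!is.null(seed)) set.seed(seed)
  wc <- attr(control, "wells")
  wp <- attr(perturbed, "wells")
  ids <- list(cp = unique(wc$plus$well_id), cm = unique(wc$minus$well_id),
              pp = unique(wp$plus$well_id), pm = unique(wp$minus$well_id))
  excess_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rc <- delta_from_wells(wc, stage, sample(ids$cp, replace = TRUE),
                           sample(ids$cm, replace = TRUE))
    rp <- delta_from_wells(wp, stage, sample(ids$pp, replace = TRUE),
                           sample(ids$pm, replace = TRUE))
    excess_b[b] <- (rp["delta", 1] / rc["delta", 1]) /
      (rp["size", 1] / rc["size", 1])
  }
  structure(list(fold_delta = fold_delta, fold_size = fold_size,
                 excess_ratio = fold_delta / fold_size,
                 superlinear_p = mean(excess_b <= 1, na.rm = TRUE),
                 n_boot = n_boot),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Flux/size scaling: fold delta-K48 = %.3f, fold size = %.3f, excess ratio = %.3f (P[<=1] = %.3f, %d resamples)\n",
              x$fold_delta, x$fold_size, x$excess_ratio, x$superlinear_p,
              x$n_boot))
  invisible(x)
}

#' Decompose clearance into nascent and long-lived shares
#'
#' Blocking translation for a few hours before the flux measurement
#' removes the nascent-protein contribution: the CHX-sensitive (nascent)
#' share is (delta_without - delta_with) / delta_without, the long-lived
#' share its complement. Shares are clipped to [0, 1] with a flag.
#'
#' @param delta_with_chx,delta_without_chx single rows of [delta_k48()]
#'   results for the same condition and stage
#' @return list: nascent_share, long_lived_share, clipped, defined
#' @export
chx_decomposition <- function(delta_with_chx, delta_without_chx) {
  dw <- delta_with_chx$delta_k48[1]
  dwo <- delta_without_chx$delta_k48[1]
  if (!identical(delta_with_chx$condition[1], delta_without_chx$condition[1]) ||
      !identical(delta_with_chx$stage[1], delta_without_chx$stage[1]))
    stop_field("chx_decomposition: arms must match in condition and stage")
  if (!is.finite(dwo) || dwo <= 0)
    return(list(nascent_share = NA_real_, long_lived_share = NA_real_,
                clipped = FALSE, defined = FALSE))
  raw <- (dwo - dw) / dwo
  clipped <- raw < 0 || raw > 1
  share <- min(max(raw, 0), 1)
  list(nascent_share = share, long_lived_share = 1 - share,
       clipped = clipped, defined = TRUE)
}

#' Protein-loss slopes from a translation-blockade chase
#'
#' Within each stage, the small (below the lower size percentile) and
#' large (above the upper percentile) classes are summarized per chase
#' time as the median size expressed as a fraction of that class's median
#' at time zero; the loss rate is the least-squares slope of this fraction
#' over time. With a `well_id` column, per-well medians give the slope its
#' replicate structure.
#'
#' @param snapshots cell records across chase times with columns
#'   `chase_time_h`, `size_se`, `stage` (and optionally `well_id`)
#' @param size_percentiles lower/upper percentile pair, default c(0.2, 0.8)
#' @return list: `slopes` data.frame (stage, class, slope_per_h, se, n),
#'   `comparison` data.frame per stage with one-sided p that the large
#'   class loses size faster
#' @export
chx_chase_slopes <- function(snapshots, size_percentiles = c(0.2, 0.8)) {
  need <- c("chase_time_h", "size_se", "stage")
  if (!all(need %in% names(snapshots)))
    stop_field(sprintf("chx_chase_slopes: missing columns: %s",
                       paste(setdiff(need, names(snapshots)), collapse = ", ")))
  times <- sort(unique(snapshots$chase_time_h))
  if (length(times) < 3)
    stop_field("chx_chase_slopes: need >= 3 chase timepoints")
  has_wells <- !is.null(snapshots$well_id)
  rows <- NULL
  comp <- NULL
  for (sg in unique(as.character(snapshots$stage))) {
    sub <- snapshots[snapshots$stage == sg, ]
    fits <- list()
    for (cls in c("small", "large")) {
      pts <- NULL
      for (tt in times) {
        cur <- sub[sub$chase_time_h == tt, ]
        q <- stats::quantile(cur$size_se, size_percentiles, names = FALSE)
        sel <- if (cls == "small") cur$size_se <= q[1] else cur$size_se >= q[2]
        cur <- cur[sel, ]
        if (!nrow(cur))
          stop_field(sprintf("chx_chase_slopes: empty %s class (stage %s, t = %g h)",
                             cls, sg, tt))
        if (has_wells) {
          med <- tapply(cur$size_se, cur$well_id, stats::median)
          pts <- rbind(pts, data.frame(time = tt, value = as.numeric(med)))
        } else {
          pts <- rbind(pts, data.frame(time = tt,
                                       value = stats::median(cur$size_se)))
        }
      }
      ref <- stats::median(pts$value[pts$time == times[1]])
      pts$fraction <- pts$value / ref
      fit <- stats::lm(fraction ~ time, data = pts)
      co <- summary(fit)$coefficients
      fits[[cls]] <- co["time", ]
      rows <- rbind(rows, data.frame(
        stage = sg, class = cls, slope_per_h = co["time", "Estimate"],
        se = co["time", "Std. Error"], n = nrow(pts),
        stringsAsFactors = FALSE))
    }
    z <- (fits$large["Estimate"] - fits$small["Estimate"]) /
      sqrt(fits$large["Std. Error"]^2 + fits$small["Std. Error"]^2)
    comp <- rbind(comp, data.frame(
      stage = sg, slope_diff = unname(fits$large["Estimate"] -
                                        fits$small["Estimate"]),
      p_large_faster = unname(stats::pnorm(z)),  # one-sided: more negative
      stringsAsFactors = FALSE))
  }
  list(slopes = rows, comparison = comp)
}

#' Linear scaling of a marker with cell size
#'
#' Ordinary least squares of a per-cell marker on the size channel, plus
#' the Pearson correlation. Negative marker values are permitted
#' (background-subtracted quantification).
#'
#' @param cells cell records with `size_se` and the marker column
#' @param marker marker column name
#' @return list of class `scaling_fit`: slope, intercept, pearson_r, n
#' @export
marker_size_fit <- function(cells, marker) {
  if (!all(c("size_se", marker) %in% names(cells)))
    stop_field(sprintf("marker_size_fit: missing column '%s' or 'size_se'", marker))
  ok <- is.finite(cells$size_se) & is.finite(cells[[marker]])
  x <- cells$size_se[ok]
  y <- cells[[marker]][ok]
  if (length(x) < 100)
    stop_field("marker_size_fit: need >= 100 cells with finite values")
  if (stats::sd(x) <= 0)
    stop_field("marker_size_fit: zero size variance")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(x, y), n = length(x)),
            class = "scaling_fit")
}

#' Deviation of G1/S clearance from the stage-wise size trend
#'
#' Fits delta-K48-polyUb against median size across the G1, S and G2+M
#' stages and reports the G1/S residual (observed minus predicted), with a
#' CI from well resampling: wells are drawn with replacement within each
#' arm, per-stage estimates recomputed, and the interval taken as
#' residual +/- t * bootstrap SE (t with min-arm-wells - 1 df).
#'
#' @param results a per-stage [delta_k48()] result containing all four
#'   stages
#' @param n_boot bootstrap replicates
#' @param conf confidence level
#' @param seed optional seed for the resampling
#' @return list: residual, ci_low, ci_high, slope, intercept, n_boot
#' @export
g1s_deviation <- function(results, n_boot = 500, conf = 0.95, seed = NULL) {
  wells <- attr(results, "wells")
  if (is.null(wells))
    stop_field("g1s_deviation: 'results' must be a delta_k48() result")
  ref_stages <- c("G1", "S", "G2+M")
  if (sum(ref_stages %in% results$stage) < 3)
    stop_field("g1s_deviation: need all of G1, S and G2+M")
  if (!"G1/S" %in% results$stage)
    stop_field("g1s_deviation: G1/S stage missing")
  fit_resid <- function(delta, size) {
    fit <- stats::lm(delta[ref_stages] ~ size[ref_stages])
    unname(delta["G1/S"] - (stats::coef(fit)[1] + stats::coef(fit)[2] *
                              size["G1/S"]))
  }
  est_delta <- stats::setNames(results$delta_k48, results$stage)
  est_size <- stats::setNames(results$median_size, results$stage)
  residual <- fit_resid(est_delta, est_size)
  base_fit <- stats::lm(est_delta[ref_stages] ~ est_size[ref_stages])

  if (!is.null(seed)) set.seed(seed)
  plus_ids <- unique(wells$plus$well_id[wells$plus$stage == "all"])
  minus_ids <- unique(wells$minus$well_id[wells$minus$stage == "all"])
  stages <- c(ref_stages, "G1/S")
  res_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    r <- delta_from_wells(wells, stages,
                          sample(plus_ids, replace = TRUE),
                          sample(minus_ids, replace = TRUE))
    res_b[b] <- fit_resid(r["delta", ], r["size", ])
  }
  n_eff <- min(length(plus_ids), length(minus_ids))
  tq <- stats::qt(1 - (1 - conf) / 2, df = n_eff - 1)
  se <- stats::sd(res_b, na.rm = TRUE)
  list(residual = residual,
       ci_low = residual - tq * se,
       ci_high = residual + tq * se,
       slope = unname(stats::coef(base_fit)[2]),
       intercept = unname(stats::coef(base_fit)[1]),
       n_boot = n_boot)
}
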