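# Continuous cell-cycle axis: ridge of the DNA x log(Geminin) density,
# arc-length parameter ell in [0, 1], nearest-point projection, and
# (ell, size) summaries.

# Bilinear interpolation of a kde2d grid at arbitrary points.
interp_grid <- function(k, x, y) {
  ix <- findInterval(x, k$x, all.inside = TRUE)
  iy <- findInterval(y, k$y, all.inside = TRUE)
  x0 <- k$x[ix]; x1 <- k$x[ix + 1]
  y0 <- k$y[iy]; y1 <- k$y[iy + 1]
  tx <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  ty <- pmin(pmax((y - y0) / (y1 - y0), 0), 1)
  z00 <- k$z[cbind(ix, iy)]; z10 <- k$z[cbind(ix + 1, iy)]
  z01 <- k$z[cbind(ix, iy + 1)]; z11 <- k$z[cbind(ix + 1, iy + 1)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Conditional-mode ridge tracing: starting from the global density mode,
# walk the y grid one row at a time in the given direction, placing the
# ridge at the within-row density argmax restricted to a continuity window
# around the previous row's position. Rows whose best density falls below
# the floor are bridged for up to `gap_max` consecutive rows (a wider gap
# means the ridge is disconnected at this bandwidth and the trace stops);
# trailing sub-floor rows are trimmed. Returns grid indices.
trace_slices <- function(z, start_ix, start_iy, dir, floor_dens, window,
                         gap_max) {
  nx <- nrow(z); ny <- ncol(z)
  ix <- start_ix
  out <- NULL
  gap <- 0L
  iy <- start_iy + dir
  while (iy >= 1 && iy <= ny) {
    lo <- max(1, ix - window)
    hi <- min(nx, ix + window)
    col <- z[lo:hi, iy]
    best <- which.max(col)
    gap <- if (col[best] < floor_dens) gap + 1L else 0L
    if (gap > gap_max) break
    ix <- lo + best - 1L
    out <- rbind(out, c(ix, iy, gap))
    iy <- iy + dir
  }
  if (is.null(out)) return(NULL)
  while (nrow(out) && out[nrow(out), 3] > 0)  # trim trailing sub-floor rows
    out <- out[-nrow(out), , drop = FALSE]
  out[, 1:2, drop = FALSE]
}

#' Fit the cell-cycle density ridge
#'
#' Estimates a 2-D kernel density of (DNA, log Geminin) on standardized
#' (z-scored) channels — Silverman's rule-of-thumb bandwidth per channel,
#' regular grid — and traces the probability density ridge as a polyline.
#' The tracer exploits the monotone accumulation of the Geminin reporter
#' along cycle progression: from the global density mode it walks the
#' log-Geminin axis row by row in both directions, placing the ridge at
#' each row's conditional density mode within a continuity window around
#' the previous position, and stopping at a data-driven density floor
#' (10th percentile of the per-cell density). Three passes of
#' local-averaging smoothing (principal-curve style) follow. The endpoint
#' in the low-Geminin (early G1) region is anchored at ell = 0 and arc
#' length is normalized to [0, 1].
#'
#' @param cells data.frame with positive `dna` and `geminin` columns
#' @param grid_n grid resolution per axis
#' @param min_cells minimum number of usable cells
#' @return object of class `trajectory_curve`: `points` (dna,
#'   log_geminin in original units), `ell`, standardization constants,
#'   bandwidths
#' @export
fit_ridge <- function(cells, grid_n = 200, min_cells = 2000) {
  if (!all(c("dna", "geminin") %in% names(cells)))
    stop_field("fit_ridge: 'cells' needs columns 'dna' and 'geminin'")
  keep <- is.finite(cells$dna) & is.finite(cells$geminin) &
    cells$dna > 0 & cells$geminin > 0
  if (sum(keep) < min_cells)
    stop_field(sprintf("fit_ridge: need >= %d cells with positive channels", min_cells))
  x <- cells$dna[keep]
  y <- log(cells$geminin[keep])
  cx <- mean(x); sx <- stats::sd(x)
  cy <- mean(y); sy <- stats::sd(y)
  if (sx <= 0 || sy <= 0)
    stop_field("fit_ridge: a channel has zero variance")
  xs <- (x - cx) / sx
  ys <- (y - cy) / sy
  hx <- stats::bw.nrd0(xs); hy <- stats::bw.nrd0(ys)
  pad <- 3 * max(hx, hy)
  k <- MASS::kde2d(xs, ys, h = c(4 * hx, 4 * hy), n = grid_n,
                   lims = c(range(xs) + c(-pad, pad),
                            range(ys) + c(-pad, pad)))
  cell_dens <- interp_grid(k, xs, ys)
  floor_dens <- stats::quantile(cell_dens, 0.02, names = FALSE)

  start <- which(k$z == max(k$z), arr.ind = TRUE)[1, ]
  window <- max(3L, ceiling(grid_n * 0.08))
  gap_max <- ceiling(grid_n * 0.5)
  up <- trace_slices(k$z, start[1], start[2], +1L, floor_dens, window, gap_max)
  down <- trace_slices(k$z, start[1], start[2], -1L, floor_dens, window, gap_max)
  idx <- rbind(down[rev(seq_len(NROW(down))), , drop = FALSE],
               matrix(start, 1, 2),
               up)
  if (nrow(idx) < 5)
    stop_field("fit_ridge: no simple ridge found (degenerate or near-symmetric density)")
  px <- k$x[idx[, 1]]
  py <- k$y[idx[, 2]]
  for (it in 1:3) {  # principal-curve style local averaging
    px <- moving_average(px, 5)
    py <- moving_average(py, 5)
  }
  dup <- c(FALSE, sqrt(diff(px)^2 + diff(py)^2) < 1e-12)
  px <- px[!dup]; py <- py[!dup]
  # orient: low-Geminin end is ell = 0
  if (py[1] > py[length(py)]) {
    px <- rev(px); py <- rev(py)
  }
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  ell <- c(0, cumsum(seg)) / sum(seg)

  curve <- structure(list(
    points = data.frame(dna = px * sx + cx, log_geminin = py * sy + cy),
    points_std = cbind(px, py),
    ell = ell,
    center = c(dna = cx, log_geminin = cy),
    scale = c(dna = sx, log_geminin = sy),
    bandwidth = c(hx, hy),
    grid_n = grid_n
  ), class = "trajectory_curve")

  # quality: a 1-D ridge should carry the data close to it
  perp <- project_points_std(curve, xs, ys)$dist
  bwm <- mean(c(hx, hy))
  if (stats::median(perp) > 2 * bwm)
    stop_field("fit_ridge: no simple ridge (data not concentrated along a curve)")
  if (mean(perp > 6 * bwm) > 0.30)
    stop_field("fit_ridge: ridge appears disconnected from part of the data; try a larger bandwidth (coarser grid or more cells)")
  curve
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("Cell-cycle trajectory: %d vertices, DNA span %.3g-%.3g, log-Geminin span %.3g-%.3g\n",
              nrow(x$points), min(x$points$dna), max(x$points$dna),
              min(x$points$log_geminin), max(x$points$log_geminin)))
  invisible(x)
}

# Nearest point on the polyline for standardized coordinates.
# Ties resolve to the smaller ell because segments are scanned in order
# and only strict improvements are kept.
project_points_std <- function(curve, xs, ys) {
  px <- curve$points_std[, 1]
  py <- curve$points_std[, 2]
  ell <- curve$ell
  n <- length(xs)
  best_d2 <- rep(Inf, n)
  best_ell <- rep(NA_real_, n)
  for (i in seq_len(length(px) - 1)) {
    ax <- px[i]; ay <- py[i]
    bx <- px[i + 1]; by <- py[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmin(pmax(((xs - ax) * vx + (ys - ay) * vy) / L2, 0), 1)
    d2 <- (xs - (ax + t * vx))^2 + (ys - (ay + t * vy))^2
    upd <- d2 < best_d2 - 1e-15
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_ell[upd] <- ell[i] + t[upd] * (ell[i + 1] - ell[i])
    }
  }
  list(ell = best_ell, dist = sqrt(best_d2))
}

#' Project cells onto the trajectory
#'
#' Each cell receives the arc-length coordinate ell of its nearest point on
#' the ridge polyline; distances are computed in the standardized channel
#' units used to fit the curve, and reported for QC. A cell equidistant
#' from two parts of the curve takes the smaller ell (documented
#' tie-break).
#'
#' @param curve a [fit_ridge()] result
#' @param cells data.frame with `dna` and `geminin` columns
#' @return `cells` with `ell` and `ell_dist` columns
#' @export
project_cells <- function(curve, cells) {
  if (!inherits(curve, "trajectory_curve"))
    stop_field("project_cells: 'curve' must come from fit_ridge()")
  xs <- (cells$dna - curve$center["dna"]) / curve$scale["dna"]
  ys <- (log(pmax(cells$geminin, .Machine$double.xmin)) -
           curve$center["log_geminin"]) / curve$scale["log_geminin"]
  pr <- project_points_std(curve, xs, ys)
  cells$ell <- pr$ell
  cells$ell_dist <- pr$dist
  cells
}

#' Joint (ell, size) grid with a per-bin feature summary
#'
#' Bins cells on the continuous cell-cycle axis and on log-scale size bins,
#' reporting the joint frequency (summing to 1 over occupied bins) and the
#' per-bin mean of a feature, optionally normalized per cell by size
#' (feature per unit mass). Bins with fewer than `min_cells_per_bin` cells
#' have their feature summary masked (NA).
#'
#' @param cells data.frame with `ell`, `size_se` and the feature column
#' @param feature name of the per-cell feature column
#' @param normalize_by_size divide the feature per cell by `size_se`
#' @param ell_bins,size_bins bin counts
#' @param min_cells_per_bin mask threshold
#' @return long data.frame: ell_bin, size_bin, ell_mid, size_mid, n,
#'   density, stat
#' @export
ell_size_heatmap <- function(cells, feature, normalize_by_size = FALSE,
                             ell_bins = 20, size_bins = 15,
                             min_cells_per_bin = 20) {
  need <- c("ell", "size_se", feature)
  if (!all(need %in% names(cells)))
    stop_field(sprintf("ell_size_heatmap: missing columns: %s",
                       paste(setdiff(need, names(cells)), collapse = ", ")))
  val <- cells[[feature]]
  if (normalize_by_size) val <- val / cells$size_se
  ok <- is.finite(cells$ell) & is.finite(val) & is.finite(cells$size_se) &
    cells$size_se > 0
  if (!any(ok)) stop_field("ell_size_heatmap: no usable cells (empty grid)")
  ell <- cells$ell[ok]; size <- cells$size_se[ok]; val <- val[ok]
  eb <- seq(0, 1, length.out = ell_bins + 1)
  sb <- exp(seq(log(min(size)), log(max(size)), length.out = size_bins + 1))
  # half-open [lo, hi); top edge inclusive
  ei <- pmin(findInterval(ell, eb, rightmost.closed = TRUE), ell_bins)
  si <- pmin(findInterval(size, sb, rightmost.closed = TRUE), size_bins)
  key <- (ei - 1) * size_bins + si
  n <- tabulate(key, nbins = ell_bins * size_bins)
  sums <- rep(0, ell_bins * size_bins)
  agg <- tapply(val, key, sum)
  sums[as.integer(names(agg))] <- agg
  grid <- expand.grid(size_bin = seq_len(size_bins),
                      ell_bin = seq_len(ell_bins))[, 2:1]
  out <- data.frame(
    ell_bin = grid$ell_bin,
    size_bin = grid$size_bin,
    ell_mid = (eb[grid$ell_bin] + eb[grid$ell_bin + 1]) / 2,
    size_mid = sqrt(sb[grid$size_bin] * sb[grid$size_bin + 1]),
    n = n,
    density = n / sum(n),
    stat = ifelse(n >= min_cells_per_bin, sums / pmax(n, 1), NA_real_)
  )
  attr(out, "ell_breaks") <- eb
  attr(out, "size_breaks") <- sb
  out
}
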