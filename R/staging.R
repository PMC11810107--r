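# Discrete cell-cycle staging from integrated DNA and Geminin intensities.

# Local maxima/minima of a density object (interior grid points).
kde_extrema <- function(d) {
  y <- d$y
  s <- diff(sign(diff(y)))
  list(max = which(s == -2) + 1L, min = which(s == 2) + 1L)
}

# The two dominant, genuinely separated modes of a 1-D KDE, or NULL.
two_modes <- function(d, min_rel_height = 0.1, max_rel_dip = 0.95) {
  ex <- kde_extrema(d)
  pk <- ex$max
  if (length(pk) < 2) return(NULL)
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  top <- pk[1]
  for (cand in pk[-1]) {
    if (d$y[cand] < min_rel_height * d$y[top]) break
    lo <- min(top, cand); hi <- max(top, cand)
    dip <- min(d$y[lo:hi])
    if (dip <= max_rel_dip * min(d$y[top], d$y[cand]))
      return(sort(c(top, cand)))
  }
  NULL
}

# Global minimum of the KDE between two grid indices; ties broken by
# proximity to the midpoint of the modes.
valley_between <- function(d, i1, i2) {
  sel <- i1:i2
  y <- d$y[sel]
  cand <- sel[which(y <= min(y) * (1 + 1e-12))]
  mid <- (d$x[i1] + d$x[i2]) / 2
  cand[which.min(abs(d$x[cand] - mid))]
}

# Component center re-estimated from its uncontaminated outer flank: the
# positions where the flank passes 0.8 and 0.5 of the peak height pin a
# Gaussian's center and sd independently of the (contamination-shifted)
# raw mode. Falls back to the raw mode for spike-like components.
flank_center <- function(d, ipk, side = c("left", "right")) {
  side <- match.arg(side)
  h <- d$y[ipk]
  cross <- function(frac) {
    if (side == "left") {
      below <- which(d$y[1:ipk] <= h * frac)
      if (!length(below)) return(NA_real_)
      i <- max(below)
      if (i >= ipk) return(NA_real_)
      stats::approx(d$y[i:(i + 1)], d$x[i:(i + 1)], xout = h * frac)$y
    } else {
      n <- length(d$y)
      below <- which(d$y[ipk:n] <= h * frac) + ipk - 1L
      if (!length(below)) return(NA_real_)
      i <- min(below)
      if (i <= ipk) return(NA_real_)
      stats::approx(d$y[(i - 1):i], d$x[(i - 1):i], xout = h * frac)$y
    }
  }
  fr <- seq(0.35, 0.85, by = 0.1)
  xs <- vapply(fr, cross, numeric(1))
  zs <- sqrt(-2 * log(fr))          # flank offset in sd units
  ok <- is.finite(xs)
  if (sum(ok) < 3 || stats::sd(xs[ok]) == 0) return(d$x[ipk])
  fit <- stats::lm(xs[ok] ~ zs[ok])  # x = center -/+ z * sd
  unname(stats::coef(fit)[1])
}

# Component boundary next to a mode by flank reflection: the mode's outer
# flank is mirrored across the component center as an estimate of the pure
# component's density on the contaminated side; the cut is the first point
# (moving into the inter-mode region) where that estimate drops to half
# the total density — the point where the component stops dominating, i.e.
# the Bayes crossing against whatever fills the inter-mode region. Falls
# back to the inter-mode valley when the ratio never drops (clean bimodal
# case).
# `n` is the sample size behind the KDE: the non-component residual
# (total minus reflected) must clear 3x the KDE's local sampling SE, so
# that small center-estimation errors on a clean, well-separated mode do
# not manufacture a spurious boundary.
reflect_cut <- function(d, ipk, iv, center = d$x[ipk], n) {
  idx <- if (iv > ipk) (ipk + 1):iv else (ipk - 1):iv
  x <- d$x[idx]
  dens <- d$y[idx]
  refl <- stats::approx(d$x, d$y, xout = 2 * center - x, rule = 2)$y
  ratio <- refl / pmax(dens, max(d$y) * 1e-9)
  se <- sqrt(dens * 0.2821 / (n * d$bw))   # Gaussian kernel: int K^2 = .2821
  hit <- which(ratio <= 0.5 & (dens - refl) >= 3 * se)
  if (length(hit)) x[hit[1]] else d$x[iv]
}

# Re-locate the local maximum of a refined density nearest a coarse mode
# position.
nearest_mode <- function(d, x0) {
  pk <- kde_extrema(d)$max
  if (!length(pk)) return(which.min(abs(d$x - x0)))
  pk[which.min(abs(d$x[pk] - x0))]
}

#' Detect cell-cycle staging thresholds
#'
#' DNA cuts are found in two passes. A coarse kernel density (Silverman's
#' rule-of-thumb bandwidth) locates the two dominant modes (2N and 4N) and
#' verifies bimodality; the density is then re-estimated with a bandwidth
#' scaled to the mode separation (1/30 of the 2N-4N gap), fine enough to
#' resolve each mode against the S-phase ramp between them. On this
#' refined density each cut is the smaller (respectively larger) of
#' (i) the global density valley between the modes (tie-break: closest to
#' the mode midpoint) and (ii) the flank-reflection boundary: the mode's
#' uncontaminated outer flank is mirrored across the mode as an estimate
#' of the pure component density, and the cut is placed where that
#' estimate falls to half the total density — the point where the mode's
#' component stops dominating. For well-separated bimodal DNA (empty
#' inter-mode region) both cuts coincide at the valley; with a populated
#' S ramp they tighten toward the modes, where the flanking valleys sit.
#'
#' The Geminin cut applies the same construction to log intensity,
#' between the baseline (G1) mode and the accumulating mode; when no
#' second mode is separable the cut falls back to (baseline mode +
#' 3 x one-sided MAD). With no usable Geminin signal the cut is marked
#' unavailable and early G1 / G1-S are merged downstream.
#'
#' All cuts are scale-equivariant: scaling the intensities by c scales the
#' thresholds by c.
#'
#' @param cells data.frame with columns `dna` and `geminin`
#' @return object of class `stage_thresholds`: list with `dna_2n_upper`,
#'   `dna_4n_lower`, `geminin_log_cut` (natural-log scale; NA when
#'   unavailable), `geminin_available`
#' @export
detect_thresholds <- function(cells) {
  if (!all(c("dna", "geminin") %in% names(cells)))
    stop_field("detect_thresholds: 'cells' needs columns 'dna' and 'geminin'")
  dna <- cells$dna[is.finite(cells$dna)]
  if (length(dna) < 500)
    stop_field("detect_thresholds: need >= 500 cells")
  d0 <- stats::density(dna, bw = "nrd0", n = 1024)
  modes0 <- two_modes(d0)
  if (is.null(modes0))
    stop_field("detect_thresholds: cannot resolve 2N/4N (DNA distribution not bimodal)")
  gap <- d0$x[modes0[2]] - d0$x[modes0[1]]
  d <- stats::density(dna, bw = gap / 40, n = 1024)
  i1 <- nearest_mode(d, d0$x[modes0[1]])
  i2 <- nearest_mode(d, d0$x[modes0[2]])
  iv <- valley_between(d, i1, i2)
  v <- d$x[iv]
  c1 <- flank_center(d, i1, "left")
  # DNA doubling: the 4N component center is exactly twice the 2N center,
  # and the tall, uncontaminated 2N left flank pins it far better than the
  # sparse 4N flank does.
  c2 <- 2 * c1
  lo <- unname(min(reflect_cut(d, i1, iv, c1, n = length(dna)), v))
  hi <- unname(max(reflect_cut(d, i2, iv, c2, n = length(dna)), v))
  if (lo >= hi) {  # clean valley: both cuts collapse onto it
    eps <- diff(d$x[1:2]) / 2
    lo <- v - eps
    hi <- v + eps
  }

  gem <- cells$geminin[is.finite(cells$geminin) & cells$geminin > 0]
  gem_cut <- NA_real_
  gem_ok <- length(gem) >= 0.1 * nrow(cells) && stats::sd(log(gem)) > 1e-8
  if (gem_ok) {
    lg <- log(gem)
    dg0 <- stats::density(lg, bw = "nrd0", n = 1024)
    gm0 <- two_modes(dg0, max_rel_dip = 0.9)
    if (!is.null(gm0)) {
      ggap <- dg0$x[gm0[2]] - dg0$x[gm0[1]]
      dg <- stats::density(lg, bw = ggap / 30, n = 1024)
      g1 <- nearest_mode(dg, dg0$x[gm0[1]])
      g2 <- nearest_mode(dg, dg0$x[gm0[2]])
      ivg <- valley_between(dg, g1, g2)
      gem_cut <- unname(min(dg$x[ivg],
                            reflect_cut(dg, g1, ivg,
                                        flank_center(dg, g1, "left"),
                                        n = length(lg))))
    } else {
      m_low <- dg0$x[which.max(dg0$y)]
      left <- m_low - lg[lg < m_low]
      spread <- if (length(left) >= 10) stats::median(left) * 1.4826
                else stats::mad(lg)
      gem_cut <- m_low + 3 * spread
    }
  }
  structure(list(dna_2n_upper = lo, dna_4n_lower = hi,
                 geminin_log_cut = gem_cut, geminin_available = gem_ok),
            class = "stage_thresholds")
}

#' @export
print.stage_thresholds <- function(x, ...) {
  cat("Stage thresholds:\n")
  cat(sprintf("  DNA 2N upper   : %.4g\n", x$dna_2n_upper))
  cat(sprintf("  DNA 4N lower   : %.4g\n", x$dna_4n_lower))
  if (x$geminin_available)
    cat(sprintf("  log(Geminin) cut: %.4g (=%.4g)\n",
                x$geminin_log_cut, exp(x$geminin_log_cut)))
  else cat("  Geminin cut    : unavailable (early G1 and G1/S merged)\n")
  invisible(x)
}

#' Assign discrete cell-cycle stages
#'
#' DNA rule first: cells at or below the 2N upper cut form the 2N class,
#' cells at or above the 4N lower cut are G2+M, the remainder are S. The
#' Geminin cut then subdivides the 2N class into G1 (baseline Geminin) and
#' G1/S (accumulating Geminin). With no Geminin cut available the 2N class
#' is labeled G1 as a whole.
#'
#' @param cells data.frame with columns `dna` and `geminin`
#' @param thresholds a [detect_thresholds()] result
#' @return `cells` with a `stage` factor column
#'   (levels G1, G1/S, S, G2+M)
#' @export
assign_stage <- function(cells, thresholds) {
  if (!inherits(thresholds, "stage_thresholds"))
    stop_field("assign_stage: 'thresholds' must come from detect_thresholds()")
  if (!all(c("dna", "geminin") %in% names(cells)))
    stop_field("assign_stage: 'cells' needs columns 'dna' and 'geminin'")
  stage <- rep("S", nrow(cells))
  two_n <- cells$dna <= thresholds$dna_2n_upper
  stage[two_n] <- "G1"
  stage[cells$dna >= thresholds$dna_4n_lower] <- "G2+M"
  if (thresholds$geminin_available) {
    hi_gem <- two_n & log(pmax(cells$geminin, .Machine$double.xmin)) >
      thresholds$geminin_log_cut
    stage[hi_gem] <- "G1/S"
  }
  cells$stage <- factor(stage, levels = STAGE_LEVELS)
  cells
}
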