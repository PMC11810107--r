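#' Default perturbation arms
#'
#' Each arm is a list of multipliers applied on top of the control
#' parameterization while a condition is active:
#' \describe{
#'   \item{g1_hazard_divisor}{divides the G1-exit hazard; >1 lengthens G1
#'     (CDK2 inhibition).}
#'   \item{beta}{overrides the compensation exponent for the arm.}
#'   \item{d0_mult}{multiplies the basal per-mass degradation rate constant
#'     (activation state of the degradation machinery).}
#'   \item{target_mult}{multiplies the homeostatic size target as a whole
#'     (sizer set point and degradation reference together): CDK4/6
#'     inhibition shifts cells to a larger adopted target, so flux scales
#'     proportionally with the new size.}
#'   \item{sizer_mult}{multiplies only the G1-exit size threshold, leaving
#'     the degradation reference unchanged: cells overgrow past their
#'     original target and compensation engages (CDK2 inhibition).}
#'   \item{synthesis_mult}{multiplies the synthesis rate only
#'     (mTOR/translation inhibition).}
#'   \item{growth_mult}{multiplies synthesis and degradation jointly, i.e.
#'     scales the net mass flux exactly.}
#'   \item{s_mult, g2m_mult, g1s_mult}{multiply the S, G2+M and G1/S-phase
#'     timer means (S-phase and G2/M delay drugs).}
#'   \item{g1s_hyper}{multiplies the ubiquitination/degradation flux of
#'     cells in the G1/S window (planted G1/S hyperactivity).}
#'   \item{compensation_onset_h}{length-2 vector c(start, full): the
#'     activated-degradation components (d0_mult, g1s_hyper) ramp linearly
#'     from baseline at `start` hours of treatment to full strength at
#'     `full` hours, reproducing the delayed onset of compensatory
#'     degradation; absent means immediate.}
#'   \item{proteasome_off}{logical; blocks all proteasome clearance and
#'     zeroes the active-proteasome readout (bortezomib).}
#'   \item{compensation_phases}{"all" (default) or "pre_g1s": phases in
#'     which the superlinear compensation term acts.}
#' }
#'
#' The CDK2i arm defaults are calibrated so that, at steady state under
#' treatment, mean G1 duration is ~32% longer than control and the measured
#' K48-polyUb clearance is ~30% above control while mean size rises only a
#' few percent, i.e. a strongly superlinear flux/size relationship.
#'
#' @return named list of perturbation arms
#' @export
default_perturbations <- function() {
  list(
    control    = list(),
    # raised G1-exit set point + compensatory degradation (superlinear,
    # activated, hyperactive at G1/S)
    CDK2i      = list(sizer_mult = 1.07, beta = 0.8, d0_mult = 1.13,
                      g1s_hyper = 1.4, compensation_onset_h = c(8, 24)),
    # larger size target, proportional scaling (no compensation change)
    `CDK4/6i`  = list(target_mult = 1.35),
    # aurora-B-like G2/M delay and S-phase delay arms
    barasertib = list(g2m_mult = 1.5),
    JNJ        = list(s_mult = 1.5),
    # proteasome inhibition: clearance off, active-proteasome probe dark
    bortezomib = list(proteasome_off = TRUE),
    # translation inhibition with compensation confined before G1/S
    mTORi      = list(synthesis_mult = 0.8, beta = 0.8,
                      compensation_phases = "pre_g1s"),
    # planted net growth-rate reduction (scales s and d0 jointly)
    growth_slow = list(growth_mult = 0.79, beta = 0),
    # proportional-degradation null (flux exactly proportional to mass)
    null0      = list(beta = 0),
    # planted G1/S degradation hyperactivity
    G1S_hyper  = list(g1s_hyper = 1.4)
  )
}

#' Construct a simulation configuration
#'
#' Full generative parameterization of the single-cell growth/division
#' simulator. Defaults emulate an RPE1-like epithelial line: ~23 h cycle
#' (~11 h G1 before the Geminin rise, ~1.5 h G1/S window, ~7 h S, ~3.5 h
#' G2+M), exponential mass growth with a size-dependent degradation term,
#' a sizer-gated G1 exit, and the staining/readout noise of integrated
#' intensities in high-content imaging.
#'
#' Mass dynamics: dM/dt = [s - d0 (M/M_target)^beta] * M, so `beta = 0`
#' gives degradation flux exactly proportional to mass and `beta > 0` gives
#' superlinear (compensatory) degradation. The K48-polyUb pool U relaxes
#' toward flux/k48_pool_turnover and accumulates linearly while the
#' proteasome is blocked, so a 30-min blockade plants an excess of
#' flux * 0.5 h.
#'
#' @param synthesis_rate_per_mass synthesis rate s (1/h)
#' @param basal_degradation_per_mass basal degradation rate d0 (1/h)
#' @param compensation_exponent beta >= 0 (dimensionless)
#' @param target_size sizer target M_target (a.u.)
#' @param g1_checkpoint_strength G1-exit hazard slope (1/h per unit
#'   relative mass excess); hazard = strength * max(0, M/M_target - theta)
#' @param g1_theta relative mass at which the G1-exit hazard switches on
#' @param g1s_duration_h,s_duration_h,g2m_duration_h mean timer durations (h)
#' @param g1s_duration_cv,s_duration_cv,g2m_duration_cv timer CVs
#' @param division_asymmetry_cv CV of the daughter mass fraction around 0.5
#' @param staining_noise_cv multiplicative lognormal CV of fixed-cell
#'   intensity readouts (stains and immunostains)
#' @param dna_noise_cv multiplicative lognormal CV of the integrated DNA
#'   (DAPI) readout, typically tighter than immunostains
#' @param track_noise_cv per-frame multiplicative CV of live readouts
#' @param frame_interval_min time-lapse frame interval (min)
#' @param k48_pool_turnover clearance rate constant of the K48-polyUb pool
#'   (1/h)
#' @param nascent_fraction fraction of the degradation flux drawn from
#'   nascent (CHX-sensitive) proteins
#' @param cfz_block_min duration of the proteasome blockade before
#'   fixation (min)
#' @param chx_block_h duration of the translation blockade before fixation
#'   (h) used by the CHX-sensitivity assay
#' @param gem_baseline,gem_rate Geminin reporter baseline (a.u.) and
#'   accumulation rate after the G1/S commitment (a.u./h)
#' @param dna_unit a.u. per haploid genome copy (2N reads 2*dna_unit)
#' @param area_scale,area_exponent nuclear-area proxy: area =
#'   area_scale * M^area_exponent
#' @param perturbations named list of condition arms
#'   (see [default_perturbations()])
#' @param n_wells replicate wells per arm
#' @param cells_per_well cells sampled per well
#' @param burn_in_h control-medium burn-in before treatment (h)
#' @param dt_h Euler time step (h)
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output tables
#' @return object of class `sim_config`
#' @export
sim_config <- function(synthesis_rate_per_mass = 0.055,
                       basal_degradation_per_mass = 0.025,
                       compensation_exponent = 0.3,
                       target_size = 1.0,
                       g1_checkpoint_strength = 2.7,
                       g1_theta = 0.85,
                       g1s_duration_h = 1.5, g1s_duration_cv = 0.2,
                       s_duration_h = 7.0, s_duration_cv = 0.15,
                       g2m_duration_h = 3.5, g2m_duration_cv = 0.15,
                       division_asymmetry_cv = 0.05,
                       staining_noise_cv = 0.08,
                       dna_noise_cv = 0.03,
                       track_noise_cv = 0.05,
                       frame_interval_min = 15,
                       k48_pool_turnover = 2.0,
                       nascent_fraction = 0.4,
                       cfz_block_min = 30,
                       chx_block_h = 3,
                       gem_baseline = 0.01,
                       gem_rate = 1 / 12,
                       dna_unit = 50,
                       area_scale = 100,
                       area_exponent = 2 / 3,
                       perturbations = default_perturbations(),
                       n_wells = 9,
                       cells_per_well = 80,
                       burn_in_h = 30,
                       dt_h = 0.05,
                       seed = 1L) {
  cfg <- list(
    synthesis_rate_per_mass = synthesis_rate_per_mass,
    basal_degradation_per_mass = basal_degradation_per_mass,
    compensation_exponent = compensation_exponent,
    target_size = target_size,
    g1_checkpoint_strength = g1_checkpoint_strength,
    g1_theta = g1_theta,
    g1s_duration_h = g1s_duration_h, g1s_duration_cv = g1s_duration_cv,
    s_duration_h = s_duration_h, s_duration_cv = s_duration_cv,
    g2m_duration_h = g2m_duration_h, g2m_duration_cv = g2m_duration_cv,
    division_asymmetry_cv = division_asymmetry_cv,
    staining_noise_cv = staining_noise_cv,
    dna_noise_cv = dna_noise_cv,
    track_noise_cv = track_noise_cv,
    frame_interval_min = frame_interval_min,
    k48_pool_turnover = k48_pool_turnover,
    nascent_fraction = nascent_fraction,
    cfz_block_min = cfz_block_min,
    chx_block_h = chx_block_h,
    gem_baseline = gem_baseline,
    gem_rate = gem_rate,
    dna_unit = dna_unit,
    area_scale = area_scale,
    area_exponent = area_exponent,
    perturbations = perturbations,
    n_wells = n_wells,
    cells_per_well = cells_per_well,
    burn_in_h = burn_in_h,
    dt_h = dt_h,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_nonneg <- c("synthesis_rate_per_mass", "basal_degradation_per_mass",
                  "compensation_exponent", "g1_checkpoint_strength",
                  "staining_noise_cv", "dna_noise_cv", "track_noise_cv",
                  "nascent_fraction", "division_asymmetry_cv")
  for (f in num_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop_field(sprintf("sim_config: '%s' must be a finite non-negative number", f))
  }
  pos <- c("target_size", "g1s_duration_h", "s_duration_h", "g2m_duration_h",
           "k48_pool_turnover", "cfz_block_min", "dt_h", "frame_interval_min",
           "gem_rate", "dna_unit", "area_scale")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_field(sprintf("sim_config: '%s' must be a finite positive number", f))
  }
  if (cfg$dt_h > 0.1)
    stop_field("sim_config: 'dt_h' must be <= 0.1 h")
  if (cfg$nascent_fraction > 1)
    stop_field("sim_config: 'nascent_fraction' must be <= 1")
  if (!is.list(cfg$perturbations) || is.null(names(cfg$perturbations)))
    stop_field("sim_config: 'perturbations' must be a named list")
  invisible(cfg)
}

# Resolve the effective parameters of a condition arm.
resolve_condition <- function(cfg, condition) {
  if (!condition %in% names(cfg$perturbations))
    stop_field(sprintf("unknown condition '%s' (not in cfg$perturbations)", condition))
  p <- cfg$perturbations[[condition]]
  growth_mult <- p$growth_mult %||% 1
  list(
    condition = condition,
    s_eff = cfg$synthesis_rate_per_mass * (p$synthesis_mult %||% 1) * growth_mult,
    d0_eff = cfg$basal_degradation_per_mass * (p$d0_mult %||% 1) * growth_mult,
    beta = p$beta %||% cfg$compensation_exponent,
    target_eff = cfg$target_size * (p$target_mult %||% 1),
    kchk_eff = cfg$g1_checkpoint_strength / (p$g1_hazard_divisor %||% 1),
    theta = cfg$g1_theta * (p$sizer_mult %||% 1),
    g1s_mean = cfg$g1s_duration_h * (p$g1s_mult %||% 1),
    g1s_cv = cfg$g1s_duration_cv,
    s_mean = cfg$s_duration_h * (p$s_mult %||% 1),
    s_cv = cfg$s_duration_cv,
    g2m_mean = cfg$g2m_duration_h * (p$g2m_mult %||% 1),
    g2m_cv = cfg$g2m_duration_cv,
    g1s_hyper = p$g1s_hyper %||% 1,
    d0_eff_base = cfg$basal_degradation_per_mass * growth_mult,
    ramp = p$compensation_onset_h,
    proteasome_off = isTRUE(p$proteasome_off),
    comp_pre_g1s = identical(p$compensation_phases %||% "all", "pre_g1s")
  )
}

# Parameters at a given elapsed treatment time: the activated-degradation
# components interpolate from baseline to full over the onset window.
pars_at <- function(pars, elapsed_h) {
  if (is.null(pars$ramp) || !is.finite(elapsed_h)) return(pars)
  frac <- min(1, max(0, (elapsed_h - pars$ramp[1]) /
                       (pars$ramp[2] - pars$ramp[1])))
  pars$d0_eff <- pars$d0_eff_base + frac * (pars$d0_eff - pars$d0_eff_base)
  pars$g1s_hyper <- 1 + frac * (pars$g1s_hyper - 1)
  pars
}
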