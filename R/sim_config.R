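#' Simulation configuration for the synthetic cohort
#'
#' Builds the single configuration object consumed by all generators.
#' Defaults describe the experimental world the analyses assume: dual-site
#' (DG and MS) fiber photometry sampled at 10 Hz synchronised to 20 Hz video,
#' home-cage sessions of 10 min, a 45 x 45 cm novel-place-recognition arena,
#' voltage-clamp sIPSC recordings at 10 kHz with 20-s light epochs delivered
#' every 60 s, current-clamp step protocols from -20 to +280 pA in 20 pA
#' increments, and tracing image stacks sectioned at 40 um with every 6th
#' section sampled.
#'
#' Genotype parameters encode the direction of the modelled phenotype:
#' DG interneuron hyperactivity in the AD group (home-cage calcium event rate
#' doubled relative to WT) and an MS-DG bout-response coupling of 0.8 during
#' memory encoding that collapses to 0 during retrieval.  Values the source
#' experiments do not pin down (transient kinetics, noise levels, effect
#' sizes) are free parameters with field-typical defaults; see the methods
#' vignette for the rationale of each.
#'
#' @param seed integer global seed; all stage seeds derive from it via
#'   [child_seed()].
#' @param n_animals_per_group named counts, e.g. `c(WT = 7, AD = 5)`.
#' @param genotype_params named list per genotype with elements
#'   `event_rate` (calcium events/min), `amplitude` (transient peak, dF/F
#'   units), `coupling` (MS-DG bout-response correlation, in `[-1, 1]`).
#' @param photometry list: `duration_s`, `fs_photo` (Hz), `fs_video` (Hz),
#'   `baseline` (a.u.), `drift_amp` (fractional), `motion_amp` (a.u.),
#'   `noise_sd` (dF/F units), `rise_s`, `decay_s` (transient kinetics),
#'   `bout_gain` (event-rate multiplier inside exploration bouts).
#' @param behavior list: `duration_s`, `arena_cm`, `n_bouts`, `bout_dur_s`,
#'   `corner_cm`, `speed_cm_s`.
#' @param ephys list: `fs` (Hz), `sipsc_rate` (Hz), `amp_meanlog`,
#'   `amp_sdlog` (lognormal sIPSC amplitude, pA), `rise_ms`, `decay_ms`,
#'   `opto_mod` (multiplicative modulation inside light epochs),
#'   `noise_sd_pA`, `baseline_pA`, `R_Mohm`, `tau_ms`, `rmp_mV`,
#'   `rheobase_pA`, `noise_sd_mV`.
#' @param imaging list: `voxel_um` (z, y, x), `shape` (z, y, x voxels),
#'   `n_processes`, `tube_radius_um`, `tube_len_um`, `n_somata`,
#'   `soma_radius_um`, `coloc_frac`, `signal`, `background`, `noise_sd`,
#'   `section_um` (40), `section_step` (every 6th section).
#' @return an object of class `septodg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_animals_per_group = c(WT = 7L, AD = 5L),
                       genotype_params = list(
                         WT = list(event_rate = 4, amplitude = 0.5, coupling = 0.8),
                         AD = list(event_rate = 8, amplitude = 0.5, coupling = 0.8)
                       ),
                       photometry = list(),
                       behavior = list(),
                       ephys = list(),
                       imaging = list()) {
  photometry <- utils::modifyList(list(
    duration_s = 600, fs_photo = 10, fs_video = 20, baseline = 100,
    drift_amp = 0.02, motion_amp = 1.0, noise_sd = 0.02,
    rise_s = 0.1, decay_s = 0.4, bout_gain = 2
  ), photometry)
  behavior <- utils::modifyList(list(
    duration_s = 300, arena_cm = 45, n_bouts = 20, bout_dur_s = 3,
    corner_cm = 10, speed_cm_s = 8
  ), behavior)
  ephys <- utils::modifyList(list(
    fs = 10000, sipsc_rate = 5, amp_meanlog = log(40), amp_sdlog = 0.4,
    rise_ms = 0.5, decay_ms = 8, opto_mod = 0.5,
    noise_sd_pA = 2, baseline_pA = 0,
    R_Mohm = 150, tau_ms = 20, rmp_mV = -70, rheobase_pA = 110,
    noise_sd_mV = 0
  ), ephys)
  imaging <- utils::modifyList(list(
    voxel_um = c(1, 1, 1), shape = c(40L, 100L, 100L),
    n_processes = 30L, tube_radius_um = 1, tube_len_um = 40,
    n_somata = 200L, soma_radius_um = 5, coloc_frac = 0.64,
    signal = 200, background = 10, noise_sd = 5,
    section_um = 40, section_step = 6L
  ), imaging)

  cfg <- structure(list(
    seed = as.integer(seed),
    n_animals_per_group = n_animals_per_group,
    genotype_params = genotype_params,
    photometry = photometry, behavior = behavior,
    ephys = ephys, imaging = imaging
  ), class = "septodg_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$photometry
  if (p$fs_video %% p$fs_photo != 0)
    stop("fs_video must be an integer multiple of fs_photo", call. = FALSE)
  stop_if_not_scalar_pos(p$duration_s, "photometry$duration_s")
  stop_if_not_scalar_pos(p$noise_sd, "photometry$noise_sd", allow_zero = TRUE)
  stop_if_not_scalar_pos(p$drift_amp, "photometry$drift_amp", allow_zero = TRUE)
  for (g in names(cfg$genotype_params)) {
    gp <- cfg$genotype_params[[g]]
    stop_if_not_scalar_pos(gp$event_rate, paste0(g, "$event_rate"), allow_zero = TRUE)
    if (abs(gp$coupling) > 1)
      stop("coupling must lie in [-1, 1]", call. = FALSE)
  }
  e <- cfg$ephys
  stop_if_not_scalar_pos(e$fs, "ephys$fs")
  stop_if_not_scalar_pos(e$sipsc_rate, "ephys$sipsc_rate", allow_zero = TRUE)
  stop_if_not_scalar_pos(e$R_Mohm, "ephys$R_Mohm")
  stop_if_not_scalar_pos(e$tau_ms, "ephys$tau_ms")
  im <- cfg$imaging
  if (any(im$voxel_um <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  if (any(im$shape <= 0)) stop("volume shape must be positive", call. = FALSE)
  stop_if_not_scalar_pos(im$tube_radius_um, "imaging$tube_radius_um", allow_zero = TRUE)
  if (im$coloc_frac < 0 || im$coloc_frac > 1)
    stop("coloc_frac must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.septodg_sim_config <- function(x, ...) {
  cat("<septodg_sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  groups:", paste(sprintf("%s(n=%d)", names(x$n_animals_per_group),
                                 x$n_animals_per_group), collapse = ", "), "\n")
  for (g in names(x$genotype_params)) {
    gp <- x$genotype_params[[g]]
    cat(sprintf("  %s: event_rate=%.3g/min amplitude=%.3g coupling=%.3g\n",
                g, gp$event_rate, gp$amplitude, gp$coupling))
  }
  cat(sprintf("  photometry: %gs @ %g Hz | ephys @ %g Hz | volume %s\n",
              x$photometry$duration_s, x$photometry$fs_photo, x$ephys$fs,
              paste(x$imaging$shape, collapse = "x")))
  invisible(x)
}
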