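#' Spectrum noise model
#'
#' Measurement noise applied to forward-modelled spectra: multiplicative
#' log-normal-equivalent Gaussian noise on the magnitude (relative SD
#' `magnitude_cv`) and additive Gaussian noise on the phase (`phase_sd_deg`).
#' The same seed always reproduces the same draws.
#'
#' @param magnitude_cv Relative SD of the multiplicative magnitude noise.
#' @param phase_sd_deg SD of the additive phase noise, degrees.
#' @param seed Integer seed.
#' @return A list of class `spectrum_noise_model`.
#' @export
noise_model <- function(magnitude_cv = 0.01, phase_sd_deg = 1.0, seed = 1L) {
  stopifnot(magnitude_cv >= 0, phase_sd_deg >= 0)
  structure(list(magnitude_cv = magnitude_cv, phase_sd_deg = phase_sd_deg,
                 seed = as.integer(seed)),
            class = "spectrum_noise_model")
}

#' Default ground truth for the staged synthetic device
#'
#' One shared parameter set for stages i-iv: elements present in several
#' stages carry identical values, so staged fits can be validated against a
#' single truth. The barrier resistance defaults to `R_TEER` such that
#' `R_TEER * 2.35e-3 cm^2 = 17.83 ohm cm^2`, the TEER scale of a mature
#' barrier in this device; the immature variant uses roughly a third of that.
#'
#' @param r_teer_ohm Barrier resistance in ohm.
#' @return Named list of per-stage parameter vectors plus assay/time-course
#'   truths, class `ground_truth`.
#' @export
bbb_ground_truth <- function(r_teer_ohm = 17.83 / 2.35e-3) {
  shared <- c(R_medium = 500)
  stage_i <- c(CPE_electrode_Q = 1e-5, CPE_electrode_n = 0.85, shared,
               R_matrix = 5000, CPE_matrix_Q = 1e-6, CPE_matrix_n = 0.9)
  stage_ii <- c(stage_i,
                R_cells = 2000, CPE_cells_Q = 5e-6, CPE_cells_n = 0.9)
  lumped <- c(R_matrix_cells = 7000, CPE_matrix_cells_Q = 2e-6,
              CPE_matrix_cells_n = 0.9)
  endo <- c(CPE_cells_E_Q = 8e-6, CPE_cells_E_n = 0.85)
  stage_iii <- c(endo, shared, lumped)
  stage_iv <- c(endo, shared,
                R_TEER = r_teer_ohm, CPE_BBB_Q = 3e-6, CPE_BBB_n = 0.85,
                lumped)
  structure(list(
    stages = list(i = stage_i[stage_parameter_names("i")],
                  ii = stage_ii[stage_parameter_names("ii")],
                  iii = stage_iii[stage_parameter_names("iii")],
                  iv = stage_iv[stage_parameter_names("iv")]),
    p_app_control_cm_s = 1e-5,
    p_app_barrier_cm_s = 2e-6,
    drug_plateau_percent = 96,
    drug_rate_per_min = -log(1 - 78 / 96) / 15
  ), class = "ground_truth")
}

#' Generate a noisy spectrum from a circuit preset
#'
#' Forward-evaluates the preset on the grid, then applies the noise model.
#' With zero noise the output equals [circuit_impedance()] exactly. The raw
#' noise draws are stored in the `"noise_draws"` attribute for audit.
#'
#' @param preset A [stage_preset()].
#' @param freq_hz Frequency grid (default [frequency_grid()]).
#' @param noise A [noise_model()].
#' @return An `eis_spectrum` with metadata `stage` and `amplitude_mV = 10`.
#' @export
generate_spectrum <- function(preset, freq_hz = frequency_grid(),
                              noise = noise_model()) {
  stopifnot(inherits(preset, "stage_preset"),
            inherits(noise, "spectrum_noise_model"))
  clean <- circuit_impedance(preset$model, freq_hz,
                             metadata = list(stage = preset$stage,
                                             amplitude_mV = 10))
  if (noise$magnitude_cv == 0 && noise$phase_sd_deg == 0) return(clean)
  draws <- withr::with_seed(noise$seed, list(
    mag = stats::rnorm(nrow(clean), 0, 1),
    phase = stats::rnorm(nrow(clean), 0, 1)))
  zmod <- clean$z_mod_ohm * exp(noise$magnitude_cv * draws$mag -
                                  noise$magnitude_cv^2 / 2)
  zphase <- clean$z_phase_deg + noise$phase_sd_deg * draws$phase
  zphase <- pmin(pmax(zphase, -89.999), 89.999)
  out <- impedance_spectrum(clean$freq_hz, zmod, zphase,
                            metadata = attr(clean, "metadata"))
  attr(out, "noise_draws") <- draws
  attr(out, "true_spectrum") <- clean
  out
}

#' Generate a four-stage synthetic dataset from one shared truth
#'
#' Produces the stage i-iv spectra a staged characterisation would acquire,
#' all derived from a single [bbb_ground_truth()] so shared elements (medium,
#' matrix, endothelial interface) are identical across stages. Each stage is
#' noised with an independent sub-seed derived from `noise$seed`.
#'
#' @param truth A [bbb_ground_truth()].
#' @param freq_hz Frequency grid.
#' @param noise A [noise_model()]; per-stage seeds are `seed + 0:3`.
#' @return List with `spectra` (named list i-iv) and `truth`.
#' @export
generate_staged_dataset <- function(truth = bbb_ground_truth(),
                                    freq_hz = frequency_grid(),
                                    noise = noise_model()) {
  stopifnot(inherits(truth, "ground_truth"))
  stages <- names(truth$stages)
  spectra <- purrr::imap(truth$stages, function(params, st) {
    sub <- noise
    sub$seed <- noise$seed + match(st, stages) - 1L
    generate_spectrum(stage_preset(st, params), freq_hz, sub)
  })
  list(spectra = spectra, truth = truth)
}

#' Generate a synthetic tracer assay with known permeability
#'
#' Inverts the apparent-permeability formula as a forward model:
#' `dC_rec = P_app * A * dt * C_t0 / V_rec`, converts the recovered
#' concentration to a fluorescence signal through a known calibration line,
#' and adds Gaussian signal noise. Running [apparent_permeability()] on the
#' noiseless output returns `true_papp` to floating precision.
#'
#' @param true_papp True apparent permeability, cm/s (>= 0).
#' @param v_rec_ml,a_cm2,dt_s,c_t0_mg_ml Assay geometry and conditions.
#' @param cal_slope,cal_intercept Calibration line mapping mg/mL to signal.
#' @param signal_noise_sd SD of additive signal noise.
#' @param n_samples Number of replicate samples.
#' @param seed Integer seed.
#' @param role Role label for the generated rows.
#' @return List with `assay` (tibble in the assay-table dialect), `standards`
#'   (6-point calibration table, noiseless) and `truth`.
#' @export
generate_permeability_assay <- function(true_papp, v_rec_ml = 0.05,
                                        a_cm2 = 0.01, dt_s = 3600,
                                        c_t0_mg_ml = 1,
                                        cal_slope = 1000, cal_intercept = 50,
                                        signal_noise_sd = 0, n_samples = 3,
                                        seed = 1L, role = "barrier") {
  stopifnot(true_papp >= 0, v_rec_ml > 0, a_cm2 > 0, dt_s > 0, c_t0_mg_ml > 0,
            cal_slope != 0, signal_noise_sd >= 0, n_samples >= 1)
  dc_rec <- true_papp * a_cm2 * dt_s * c_t0_mg_ml / v_rec_ml
  signal_clean <- cal_slope * dc_rec + cal_intercept
  noise <- if (signal_noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n_samples, 0, signal_noise_sd))
  } else rep(0, n_samples)
  assay <- tibble::tibble(
    sample_id = sprintf("%s_%02d", role, seq_len(n_samples)),
    v_rec_ml = v_rec_ml, signal = signal_clean + noise,
    a_cm2 = a_cm2, dt_s = dt_s, c_t0_mg_ml = c_t0_mg_ml, role = role)
  conc <- seq(0, c_t0_mg_ml / 50, length.out = 6)
  standards <- tibble::tibble(conc_mg_ml = conc,
                              signal = cal_slope * conc + cal_intercept)
  list(assay = assay, standards = standards,
       truth = list(p_app_cm_s = true_papp, dc_rec_mg_ml = dc_rec,
                    cal_slope = cal_slope, cal_intercept = cal_intercept))
}

#' Generate a normalized drug-crossing time course
#'
#' Saturating-exponential family
#' `fraction(t) = plateau * (1 - exp(-rate * t)) + noise`, emulating the
#' normalized percentage of drug crossing the barrier over time (plateau
#' reached after about an hour). A shape emulation only: no mechanistic
#' transport model is implied.
#'
#' @param plateau_percent Plateau crossing fraction, percent, in (0, 100].
#' @param rate_per_min First-order approach rate, 1/min (> 0).
#' @param timepoints_min Sampling times in minutes.
#' @param noise_sd SD of additive Gaussian noise on the percent scale.
#' @param seed Integer seed.
#' @return Tibble with `time_min`, `crossing_percent`,
#'   `crossing_percent_clean`.
#' @export
generate_drug_timecourse <- function(plateau_percent = 96,
                                     rate_per_min = -log(1 - 78 / 96) / 15,
                                     timepoints_min = c(0, 15, 30, 60),
                                     noise_sd = 0, seed = 1L) {
  stopifnot(plateau_percent > 0, plateau_percent <= 100, rate_per_min > 0,
            noise_sd >= 0)
  clean <- plateau_percent * (1 - exp(-rate_per_min * timepoints_min))
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(timepoints_min), 0, noise_sd))
  } else rep(0, length(timepoints_min))
  tibble::tibble(time_min = timepoints_min,
                 crossing_percent = clean + noise,
                 crossing_percent_clean = clean)
}
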