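#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal against concentration,
#' `signal = slope * concentration + intercept`, as used to convert plate
#' reader fluorescence (or HPLC peak areas) into tracer concentrations.
#'
#' @param standards Data frame with columns `conc_mg_ml` and `signal`.
#' @return A `calibration_curve`: list with `slope`, `intercept`, `r_squared`
#'   and the standards used.
#' @examples
#' fit_calibration(data.frame(conc_mg_ml = 0:2, signal = c(0, 10, 20)))
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("conc_mg_ml", "signal") %in% names(standards))) {
    stop("standards must have columns conc_mg_ml and signal", call. = FALSE)
  }
  if (length(unique(standards$conc_mg_ml)) < 2) {
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(signal ~ conc_mg_ml, data = standards)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standards$signal - mean(standards$signal))^2)
  slope <- unname(stats::coef(fit)[["conc_mg_ml"]])
  if (slope == 0) stop("degenerate calibration: zero slope", call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 standards = tibble::as_tibble(standards)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve: signal = %.6g * conc + %.6g, r^2 = %.4f>\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_standards = nrow(x$standards))
}

#' Invert a calibration curve
#'
#' `(signal - intercept) / slope`; negative concentrations (blank noise below
#' the intercept) are clipped to zero with a warning.
#'
#' @param curve A [fit_calibration()] result.
#' @param signal Numeric signal value(s).
#' @return Concentration(s) in mg/mL, >= 0.
#' @export
concentration_from_signal <- function(curve, signal) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a calibration_curve", call. = FALSE)
  }
  if (curve$slope == 0) stop("degenerate calibration: zero slope", call. = FALSE)
  conc <- (signal - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative inverted concentration(s) clipped to 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Apparent permeability coefficient
#'
#' For a tracer diffusing from the vascular (donor) to the cerebral
#' (receiver) compartment,
#' `P_app = (V_rec * dC_rec) / (A * dt * C_t0)` in cm/s, where `V_rec` is the
#' recovered receiver volume (mL), `dC_rec` the rise of the tracer
#' concentration in the receiver over the assay (mg/mL), `A` the diffusion
#' area (cm^2), `dt` the assay duration (s) and `C_t0` the donor concentration
#' at t = 0 (mg/mL). By default `dC_rec = c_rec - c_background` with a zero
#' background, which keeps `P_app >= 0`; `signed = TRUE` instead takes the
#' literal receiver-minus-donor difference (negative for any barrier).
#'
#' @param assays Data frame with columns `v_rec_ml`, `c_rec_mg_ml`, `a_cm2`,
#'   `dt_s`, `c_t0_mg_ml`, optional `c_background_mg_ml` (default 0).
#' @param signed Use the signed receiver-minus-donor concentration difference.
#' @return The input as a tibble with columns `dc_rec_mg_ml` and
#'   `p_app_cm_s` appended.
#' @examples
#' apparent_permeability(data.frame(
#'   v_rec_ml = 0.1, c_rec_mg_ml = 0.01, a_cm2 = 0.01,
#'   dt_s = 3600, c_t0_mg_ml = 1))$p_app_cm_s # 2.78e-5
#' @export
apparent_permeability <- function(assays, signed = FALSE) {
  need <- c("v_rec_ml", "c_rec_mg_ml", "a_cm2", "dt_s", "c_t0_mg_ml")
  if (!is.data.frame(assays) || !all(need %in% names(assays))) {
    stop("assays must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  assays <- tibble::as_tibble(assays)
  if (!"c_background_mg_ml" %in% names(assays)) assays$c_background_mg_ml <- 0
  with(assays, {
    if (any(c_t0_mg_ml == 0)) {
      stop("c_t0_mg_ml must be non-zero (division by the donor concentration)",
           call. = FALSE)
    }
    if (any(v_rec_ml <= 0) || any(a_cm2 <= 0) || any(dt_s <= 0) ||
        any(c_rec_mg_ml < 0)) {
      stop("assay quantities must be positive (c_rec_mg_ml >= 0)", call. = FALSE)
    }
  })
  dc <- if (signed) {
    assays$c_rec_mg_ml - assays$c_t0_mg_ml
  } else {
    assays$c_rec_mg_ml - assays$c_background_mg_ml
  }
  dplyr::mutate(assays,
                dc_rec_mg_ml = dc,
                p_app_cm_s = (.data$v_rec_ml * dc) /
                  (.data$a_cm2 * .data$dt_s * .data$c_t0_mg_ml))
}

#' Percent reduction of permeability relative to a control
#'
#' `100 * (1 - P_app_barrier / P_app_control)`. A mature barrier in this
#' device shows about an 80 percent reduction relative to the cell-free
#' control; an immature one only about 30 percent.
#'
#' @param p_app_barrier,p_app_control Apparent permeabilities in cm/s;
#'   `p_app_control > 0`.
#' @return Percent reduction, in `(-Inf, 100]`.
#' @export
percent_reduction <- function(p_app_barrier, p_app_control) {
  if (any(p_app_control <= 0)) {
    stop("p_app_control must be > 0", call. = FALSE)
  }
  100 * (1 - p_app_barrier / p_app_control)
}

#' Summarise a tracer assay table against its control
#'
#' Computes per-sample apparent permeabilities and the percent reduction of
#' the mean barrier permeability relative to the mean control permeability.
#'
#' @param assays Assay table as in [apparent_permeability()], plus a `role`
#'   column with values `"barrier"` or `"control"`.
#' @param ... Passed to [apparent_permeability()].
#' @return List with `per_sample` (tibble) and `percent_reduction` (scalar, or
#'   `NA` if either role is absent).
#' @export
permeability_summary <- function(assays, ...) {
  if (!"role" %in% names(assays)) {
    stop("assays must have a role column (barrier/control)", call. = FALSE)
  }
  per_sample <- apparent_permeability(assays, ...)
  mean_by <- function(r) {
    v <- per_sample$p_app_cm_s[per_sample$role == r]
    if (length(v)) mean(v) else NA_real_
  }
  pb <- mean_by("barrier"); pc <- mean_by("control")
  list(per_sample = per_sample,
       mean_barrier = pb, mean_control = pc,
       percent_reduction = if (is.na(pb) || is.na(pc)) NA_real_
                           else percent_reduction(pb, pc))
}
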