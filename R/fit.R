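#' Amplitude deviation between observed and modelled spectra
#'
#' The fit objective: the mean, over frequencies, of the relative magnitude
#' residual, expressed in percent,
#' `100 * mean(| |Z|_obs - |Z|_mod | / |Z|_obs)`. Phase is excluded from the
#' objective (it is still reported by the fitter for diagnostics). A fit is
#' conventionally accepted when the deviation is strictly below 2 percent.
#'
#' @param observed,modeled Spectra on identical frequency grids.
#' @return Deviation in percent (>= 0).
#' @export
amplitude_deviation <- function(observed, modeled) {
  check_spectrum(observed)
  check_spectrum(modeled)
  if (nrow(observed) != nrow(modeled) ||
      any(abs(observed$freq_hz - modeled$freq_hz) >
          1e-9 * pmax(observed$freq_hz, modeled$freq_hz))) {
    stop("observed and modeled spectra must share the same frequency grid",
         call. = FALSE)
  }
  100 * mean(abs(observed$z_mod_ohm - modeled$z_mod_ohm) / observed$z_mod_ohm)
}

#' Fit configuration
#'
#' @param initial_values Optional named vector of starting parameter values;
#'   anything not supplied is initialised from spectrum features (see
#'   [initial_values_from_features()]).
#' @param bounds Optional named list of `c(low, high)` pairs per parameter.
#'   Defaults: three decades either side of the initial value for resistances
#'   and CPE coefficients; `[0.3, 1]` for CPE exponents.
#' @param max_iterations Powell sweep budget.
#' @param tolerance Relative objective-decrease tolerance for convergence.
#' @param n_starts Number of optimizer starts; starts beyond the first jitter
#'   the initial values log-uniformly by up to +/-50 percent.
#' @param seed Seed for the multi-start jitter (ignored when `n_starts = 1`).
#' @param restarts Direction-set resets allowed per start (see
#'   [powell_minimize()]); narrow curved valleys in the amplitude objective
#'   need several.
#' @param start_grid Optional list of named multiplier vectors; each entry
#'   adds a deterministic extra start with the initial values scaled by the
#'   multipliers. Used to scan directions along which the amplitude objective
#'   is multimodal (e.g. how the low-frequency resistance splits between two
#'   parallel blocks); the start with the best final deviation wins.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(initial_values = NULL, bounds = NULL,
                       max_iterations = 500, tolerance = 1e-12,
                       n_starts = 1, seed = NULL, restarts = 20,
                       start_grid = NULL) {
  stopifnot(tolerance > 0, max_iterations >= 1, n_starts >= 1, restarts >= 0)
  structure(list(initial_values = initial_values, bounds = bounds,
                 max_iterations = max_iterations, tolerance = tolerance,
                 n_starts = n_starts, seed = seed, restarts = restarts,
                 start_grid = start_grid),
            class = "fit_config")
}

#' Feature-based starting values for a staged fit
#'
#' Deterministic initialisation from Bode-curve features: the medium
#' resistance from the high-frequency magnitude plateau (mean `|Z|` over the
#' top half decade); parallel-block resistances from the mid-band magnitude
#' in excess of the plateau, split equally across blocks; the series
#' (electrode/endothelial) CPE coefficient from the low-frequency magnitude in
#' excess of the mid-band value; block CPE coefficients placed so the block
#' corner frequency sits mid-band. All CPE exponents start at 0.9.
#'
#' @param spectrum An `eis_spectrum`.
#' @param stage Stage label (`"i"`-`"iv"`).
#' @return Named numeric vector over [stage_parameter_names()].
#' @export
initial_values_from_features <- function(spectrum, stage) {
  check_spectrum(spectrum)
  f <- spectrum$freq_hz
  zmod <- spectrum$z_mod_ohm
  lf <- log10(f)
  hi <- lf >= max(lf) - 0.5
  r_medium <- mean(zmod[hi])
  f_mid <- sqrt(min(f) * max(f))
  z_mid <- zmod[which.min(abs(lf - log10(f_mid)))]
  z_low <- zmod[1]
  w_min <- 2 * pi * min(f)
  w_mid <- 2 * pi * f_mid
  n0 <- 0.9

  pnames <- stage_parameter_names(stage)
  block_r <- grep("^R_", pnames, value = TRUE)
  block_r <- setdiff(block_r, "R_medium")
  series_cpe <- intersect(c("CPE_electrode_Q", "CPE_cells_E_Q"), pnames)
  series_cpe <- sub("_Q$", "", series_cpe)
  block_cpe <- setdiff(sub("_n$", "", grep("_n$", pnames, value = TRUE)),
                       series_cpe)

  init <- c(R_medium = r_medium)
  r_each <- max((z_mid - r_medium), 0.2 * r_medium) / max(length(block_r), 1)
  for (r in block_r) init[r] <- r_each
  for (s in series_cpe) {
    z_cpe <- max(z_low - z_mid, 0.05 * z_low)
    init[paste0(s, "_Q")] <- 1 / (z_cpe * w_min^n0)
    init[paste0(s, "_n")] <- n0
  }
  for (b in block_cpe) {
    # place the block corner frequency mid-band
    init[paste0(b, "_Q")] <- 1 / (r_each * w_mid^n0)
    init[paste0(b, "_n")] <- n0
  }
  init[pnames]
}

default_bounds <- function(init) {
  lapply(stats::setNames(names(init), names(init)), function(nm) {
    if (grepl("_n$", nm)) c(0.3, 1) else c(init[[nm]] / 1e3, init[[nm]] * 1e3)
  })
}

# Bijection between bounded positive parameters and unconstrained optimizer
# coordinates: logistic on the log scale, so the start sits mid-interval when
# bounds are symmetric decades around it.
to_unconstrained <- function(theta, bounds) {
  vapply(names(theta), function(nm) {
    lo <- log(bounds[[nm]][1]); hi <- log(bounds[[nm]][2])
    p <- (log(theta[[nm]]) - lo) / (hi - lo)
    stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  }, numeric(1))
}

from_unconstrained <- function(x, bounds) {
  vapply(names(x), function(nm) {
    lo <- log(bounds[[nm]][1]); hi <- log(bounds[[nm]][2])
    exp(lo + (hi - lo) * stats::plogis(x[[nm]]))
  }, numeric(1))
}

#' Fit an equivalent circuit to a spectrum
#'
#' Minimises the amplitude deviation (mean relative magnitude residual,
#' percent) with Powell's direction-set method in a transformed parameter
#' space that enforces the box bounds. The returned deviation is never larger
#' than the deviation at the starting values; a fit is `accepted` when its
#' deviation is strictly below `accept_threshold` (2 percent by default).
#'
#' @param spectrum Observed `eis_spectrum`.
#' @param preset A [stage_preset()] (topology; its bound values are ignored
#'   in favour of the optimisation variables).
#' @param config A [fit_config()].
#' @param accept_threshold Acceptance bound on the deviation, percent.
#' @return An object of class `eis_fit`: fitted `parameters`,
#'   `deviation_percent`, `initial_deviation_percent`, `accepted`,
#'   `converged`, `iterations`, plus the stage label, grid and modelled
#'   spectrum.
#' @export
fit_circuit <- function(spectrum, preset, config = fit_config(),
                        accept_threshold = 2) {
  check_spectrum(spectrum)
  stopifnot(inherits(preset, "stage_preset"), inherits(config, "fit_config"))
  topo <- preset$model
  pnames <- circuit_parameter_names(topo)

  feats <- initial_values_from_features(spectrum, preset$stage)
  init <- feats[intersect(names(feats), pnames)]
  if (!is.null(config$initial_values)) {
    user <- unlist(config$initial_values)
    init[intersect(names(user), pnames)] <-
      user[intersect(names(user), pnames)]
  }
  # custom topologies may carry element names the feature heuristics do not
  # know; give those generic spectrum-scale starts
  for (nm in setdiff(pnames, names(init))) {
    init[nm] <- if (grepl("_n$", nm)) 0.9
    else if (grepl("_Q$", nm)) {
      1 / (stats::median(spectrum$z_mod_ohm) * 2 * pi *
             sqrt(min(spectrum$freq_hz) * max(spectrum$freq_hz)))
    } else stats::median(spectrum$z_mod_ohm)
  }
  init <- init[pnames]
  bounds <- default_bounds(init)
  if (!is.null(config$bounds)) {
    for (nm in intersect(names(config$bounds), pnames)) {
      bounds[[nm]] <- config$bounds[[nm]]
    }
  }
  # keep starts strictly inside their boxes
  for (nm in pnames) {
    init[nm] <- min(max(init[[nm]], bounds[[nm]][1] * (1 + 1e-9)),
                    bounds[[nm]][2] * (1 - 1e-9))
  }

  omega <- 2 * pi * spectrum$freq_hz
  obs_mod <- spectrum$z_mod_ohm
  rel_residuals <- function(x) {
    theta <- from_unconstrained(x, bounds)
    z <- eval_impedance(set_parameters(topo, theta), omega)
    (obs_mod - Mod(z)) / obs_mod
  }
  # reported objective: mean relative amplitude deviation, percent (L1)
  objective <- function(x) 100 * mean(abs(rel_residuals(x)))
  # optimisation surrogate: its smooth squared counterpart. The L1 mean is
  # non-differentiable wherever a residual crosses zero, which litters the
  # valley floor with spurious direction-set stalls; the squared form shares
  # the same minimiser on well-specified data and descends cleanly.
  objective_sq <- function(x) mean(rel_residuals(x)^2)

  clamp <- function(v) {
    pmin(pmax(v, vapply(bounds[names(init)], `[`, numeric(1), 1) * (1 + 1e-9)),
         vapply(bounds[names(init)], `[`, numeric(1), 2) * (1 - 1e-9))
  }
  starts <- list(to_unconstrained(init, bounds))
  for (g in config$start_grid) {
    alt <- init
    alt[names(g)] <- alt[names(g)] * g
    starts <- c(starts, list(to_unconstrained(clamp(alt), bounds)))
  }
  if (config$n_starts > 1) {
    jitters <- withr::with_seed(
      if (is.null(config$seed)) 1L else config$seed,
      replicate(config$n_starts - 1,
                init * exp(stats::runif(length(init), log(1/1.5), log(1.5))),
                simplify = FALSE))
    for (j in jitters) {
      starts <- c(starts, list(to_unconstrained(clamp(j), bounds)))
    }
  }

  restarts <- if (is.null(config$restarts)) 20 else config$restarts
  # the unmoved start is always a candidate, so the returned deviation can
  # never exceed the deviation at the initial values
  best <- list(par = starts[[1]], value = objective(starts[[1]]),
               iterations = 0L, converged = FALSE, function_evaluations = 1L)
  for (x0 in starts) {
    smooth <- powell_minimize(objective_sq, x0, tol = 1e-16,
                              max_iterations = config$max_iterations,
                              restarts = restarts)
    polish <- powell_minimize(objective, smooth$par, tol = config$tolerance,
                              max_iterations = 50, restarts = 2)
    cand <- list(par = polish$par, value = polish$value,
                 iterations = smooth$iterations + polish$iterations,
                 converged = smooth$converged && polish$converged,
                 function_evaluations = smooth$function_evaluations +
                   polish$function_evaluations)
    if (cand$value < best$value ||
        (cand$value == best$value && cand$iterations < best$iterations)) {
      best <- cand
    }
  }

  theta <- from_unconstrained(stats::setNames(best$par, pnames), bounds)
  fitted_model <- set_parameters(topo, theta)
  modeled <- circuit_impedance(fitted_model, spectrum$freq_hz,
                               metadata = list(stage = preset$stage))
  dev <- amplitude_deviation(spectrum, modeled)
  structure(list(
    stage = preset$stage,
    parameters = theta,
    deviation_percent = dev,
    initial_deviation_percent = objective(starts[[1]]),
    accepted = dev < accept_threshold,
    converged = best$converged,
    iterations = best$iterations,
    function_evaluations = best$function_evaluations,
    model = fitted_model,
    observed = spectrum,
    modeled = modeled,
    bounds = bounds
  ), class = "eis_fit")
}

#' @export
print.eis_fit <- function(x, ...) {
  cat(sprintf("<eis_fit stage %s: deviation %.3f%% (%s), %d sweeps%s>\n",
              x$stage, x$deviation_percent,
              if (x$accepted) "accepted" else "not accepted",
              x$iterations, if (x$converged) "" else ", not converged"))
  print(tibble::enframe(x$parameters, name = "term", value = "estimate"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eis_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @export
glance.eis_fit <- function(x, ...) {
  tibble::tibble(stage = x$stage,
                 deviation_percent = x$deviation_percent,
                 accepted = x$accepted,
                 converged = x$converged,
                 iterations = x$iterations)
}

#' @export
autoplot.eis_fit <- function(object, ...) {
  plot_bode(observed = object$observed, fitted = object$modeled) +
    ggplot2::ggtitle(sprintf("stage %s fit, deviation %.2f%%",
                             object$stage, object$deviation_percent))
}

#' Staged calibration across partial and complete barrier models
#'
#' Fits the staged spectra in order i -> ii -> iii -> iv. Parameters fitted at
#' an earlier stage become bounded priors for every later stage that contains
#' an element of the same name: the later fit starts at the earlier estimate
#' and is constrained to `estimate * (1 +/- propagation_width)` (CPE exponents
#' additionally capped at 1). Heuristic cross-stage starts are also derived
#' for the lumped stage-iii block (matrix + brain-cell resistances add).
#' Missing intermediate stages produce a warning and are skipped.
#'
#' @param spectra Named list of spectra; names among `"i"`, `"ii"`, `"iii"`,
#'   `"iv"`.
#' @param base_config [fit_config()] applied to every stage.
#' @param propagation_width Relative half-width of the propagated bounds.
#' @return Named list of `eis_fit` objects, one per supplied stage.
#' @export
staged_calibration <- function(spectra, base_config = fit_config(),
                               propagation_width = 0.2) {
  stages <- intersect(c("i", "ii", "iii", "iv"), names(spectra))
  if (!length(stages)) stop("no recognisable stages in `spectra`", call. = FALSE)
  if (!"i" %in% stages) stop("staged calibration requires stage i", call. = FALSE)
  gaps <- setdiff(c("i", "ii", "iii", "iv"), stages)
  if (length(gaps)) {
    warning("missing stage(s): ", paste(gaps, collapse = ", "),
            "; proceeding with available stages", call. = FALSE)
  }

  carry <- c()
  fits <- list()
  for (st in stages) {
    pnames <- stage_parameter_names(st)
    cfg <- base_config
    shared <- intersect(names(carry), pnames)
    inits <- carry[shared]
    bnds <- lapply(stats::setNames(shared, shared), function(nm) {
      b <- carry[[nm]] * c(1 - propagation_width, 1 + propagation_width)
      if (grepl("_n$", nm)) b[2] <- min(b[2], 1)
      b
    })
    # lumped-block heuristics for stage iii/iv starts (no bound attached)
    if ("R_matrix_cells" %in% pnames && !"R_matrix_cells" %in% shared &&
        all(c("R_matrix", "R_cells") %in% names(carry))) {
      inits["R_matrix_cells"] <- carry[["R_matrix"]] + carry[["R_cells"]]
    }
    # barrier block start: the low-band |Z| rise of the complete model over
    # the previous partial model estimates the barrier resistance scale
    if ("R_TEER" %in% pnames && length(fits)) {
      prev <- fits[[length(fits)]]$observed
      band <- function(sp) mean(sp$z_mod_ohm[sp$freq_hz >= 5 &
                                               sp$freq_hz <= 50])
      rise <- band(spectra[[st]]) - band(prev)
      if (is.finite(rise) && rise > 0) inits["R_TEER"] <- rise
    }
    cfg$initial_values <- c(cfg$initial_values[setdiff(names(cfg$initial_values),
                                                       names(inits))], inits)
    cfg$bounds <- c(cfg$bounds[setdiff(names(cfg$bounds), names(bnds))], bnds)

    # Spectra of stacked parallel RC/CPE blocks are nearly degenerate in how
    # the low-frequency resistance splits between blocks (their CPE exponents
    # barely differ), so a stage that adds a new block over several carried
    # parameters is fitted in two passes: a pre-pass fits only the new
    # elements with every carried parameter pinned to its earlier-stage
    # estimate (a well-conditioned few-parameter problem, scanned over
    # new-block resistance scales), and the full fit then releases all
    # parameters within the propagated bounds from that starting point.
    new_params <- setdiff(pnames, shared)
    if (length(shared) >= 4 && length(new_params) >= 1) {
      r_new <- grep("^R_", new_params, value = TRUE)
      q_new <- grep("_Q$", new_params, value = TRUE)
      pre <- cfg
      if (length(r_new) == 1 && length(q_new) == 1) {
        pre$start_grid <- lapply(c(0.5, 1.5, 2.5), function(m) {
          stats::setNames(c(m, 1 / m), c(r_new, q_new))
        })
      }
      pre$bounds <- c(pre$bounds[setdiff(names(pre$bounds), shared)],
                      lapply(stats::setNames(shared, shared), function(nm) {
                        carry[[nm]] * c(1 - 1e-4, 1 + 1e-4)
                      }))
      pre_fit <- fit_circuit(spectra[[st]], stage_preset_from_init(st), pre)
      cfg$initial_values <- pre_fit$parameters
      cfg$start_grid <- NULL
    }
    fit <- fit_circuit(spectra[[st]], stage_preset_from_init(st), cfg)
    fits[[st]] <- fit
    carry[names(fit$parameters)] <- fit$parameters
  }
  fits
}

# topology-only preset (placeholder values; fit_circuit rebinds them)
stage_preset_from_init <- function(stage) {
  structure(list(stage = stage, model = stage_topology(stage)),
            class = "stage_preset")
}

#' Area-normalised TEER from a fitted barrier resistance
#'
#' TEER is reported as barrier resistance times the sensing area,
#' `TEER = R_TEER * area` in ohm cm^2. The default area is the device's
#' measured sensing area, 2.35e-3 cm^2.
#'
#' @param fit An `eis_fit` whose parameters include `R_TEER`, or a named
#'   vector containing `R_TEER`.
#' @param area_cm2 Sensing area in cm^2 (> 0).
#' @return A tibble with `r_teer_ohm`, `area_cm2`, `teer_ohm_cm2`.
#' @examples
#' extract_teer(c(R_TEER = 7587.2)) # ~17.83 ohm cm^2
#' @export
extract_teer <- function(fit, area_cm2 = 2.35e-3) {
  if (!is.numeric(area_cm2) || length(area_cm2) != 1 || area_cm2 <= 0) {
    stop("area_cm2 must be a single value > 0", call. = FALSE)
  }
  params <- if (inherits(fit, "eis_fit")) fit$parameters else unlist(fit)
  if (!"R_TEER" %in% names(params)) {
    stop("fit does not contain an R_TEER parameter; ",
         "TEER extraction needs the complete (stage iv) model", call. = FALSE)
  }
  r <- unname(params[["R_TEER"]])
  if (r < 0) stop("R_TEER must be non-negative", call. = FALSE)
  tibble::tibble(r_teer_ohm = r, area_cm2 = area_cm2,
                 teer_ohm_cm2 = r * area_cm2)
}

#' Barrier maturity assessment from magnitude ratios
#'
#' A mature barrier raises the impedance magnitude relative to the cell-free
#' control at frequencies above a crossover (about 50 Hz in this device). The
#' assessment takes the mean `|Z|` ratio test/reference over the common
#' frequencies above the crossover and classifies the barrier as `"mature"`
#' when the ratio reaches `ratio_threshold`.
#'
#' @param reference Cell-free control spectrum.
#' @param test Spectrum of the barrier under assessment.
#' @param crossover_hz Crossover frequency in Hz.
#' @param ratio_threshold Classification threshold on the mean ratio.
#' @return A tibble with `crossover_hz`, `n_frequencies`,
#'   `mean_magnitude_ratio`, `ratio_threshold`, `classification`.
#' @export
assess_barrier <- function(reference, test, crossover_hz = 50,
                           ratio_threshold = 1.02) {
  check_spectrum(reference)
  check_spectrum(test)
  common <- dplyr::inner_join(
    bode_table(reference), bode_table(test),
    by = "freq_hz", suffix = c("_ref", "_test"))
  common <- dplyr::filter(common, .data$freq_hz > crossover_hz)
  if (nrow(common) == 0) {
    stop("no shared frequencies above the crossover of ", crossover_hz, " Hz",
         call. = FALSE)
  }
  ratio <- mean(common$z_mod_ohm_test / common$z_mod_ohm_ref)
  tibble::tibble(
    crossover_hz = crossover_hz,
    n_frequencies = nrow(common),
    mean_magnitude_ratio = ratio,
    ratio_threshold = ratio_threshold,
    classification = if (ratio >= ratio_threshold) "mature" else "immature")
}
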