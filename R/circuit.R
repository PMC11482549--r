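#' Logarithmic frequency grid
#'
#' Builds the frequency grid used for two-electrode impedance sweeps. The
#' default covers 1 Hz to 100 kHz at 10 points per decade, the sweep used to
#' interrogate barrier-on-chip devices under 10 mV AC excitation.
#'
#' @param f_min,f_max Frequency limits in Hz (both > 0, `f_min < f_max`).
#' @param points_per_decade Grid density on a log10 axis.
#' @return A numeric vector of strictly ascending frequencies in Hz.
#' @examples
#' f <- frequency_grid()
#' length(f) # 51
#' @export
frequency_grid <- function(f_min = 1, f_max = 1e5, points_per_decade = 10) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), f_min > 0, f_max > f_min,
            points_per_decade >= 1)
  n_dec <- log10(f_max / f_min)
  10^seq(log10(f_min), log10(f_max), length.out = round(n_dec * points_per_decade) + 1)
}

validate_frequencies <- function(freq_hz) {
  if (length(freq_hz) == 0) {
    stop("frequency grid is empty", call. = FALSE)
  }
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  }
  if (is.unsorted(freq_hz, strictly = TRUE)) {
    stop("frequencies must be strictly ascending", call. = FALSE)
  }
  invisible(freq_hz)
}

#' Impedance spectrum container
#'
#' An impedance spectrum is a tibble with one row per frequency and columns
#' `freq_hz`, `z_mod_ohm` (magnitude, ohm) and `z_phase_deg` (phase, degrees,
#' negative for capacitive behaviour). Metadata (stage label, electrode pair,
#' AC amplitude) travels in the `"metadata"` attribute.
#'
#' @param freq_hz Frequencies in Hz, strictly positive and ascending.
#' @param z_mod_ohm Impedance magnitudes in ohm, strictly positive.
#' @param z_phase_deg Phase angles in degrees, within (-90, 90).
#' @param metadata Optional named list of metadata.
#' @return A tibble of class `eis_spectrum`.
#' @export
impedance_spectrum <- function(freq_hz, z_mod_ohm, z_phase_deg,
                               metadata = list()) {
  validate_frequencies(freq_hz)
  if (length(z_mod_ohm) != length(freq_hz) ||
      length(z_phase_deg) != length(freq_hz)) {
    stop("magnitude and phase must have one value per frequency", call. = FALSE)
  }
  if (any(!is.finite(z_mod_ohm)) || any(z_mod_ohm <= 0)) {
    stop("impedance magnitude must be finite and > 0 at every frequency",
         call. = FALSE)
  }
  if (any(!is.finite(z_phase_deg)) || any(abs(z_phase_deg) >= 90 + 1e-9)) {
    stop("phase must lie within (-90, 90) degrees", call. = FALSE)
  }
  out <- tibble::tibble(freq_hz = as.numeric(freq_hz),
                        z_mod_ohm = as.numeric(z_mod_ohm),
                        z_phase_deg = as.numeric(z_phase_deg))
  attr(out, "metadata") <- metadata
  class(out) <- c("eis_spectrum", class(out))
  out
}

#' @export
print.eis_spectrum <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<eis_spectrum: %d frequencies, %.3g-%.3g Hz>\n",
              nrow(x), min(x$freq_hz), max(x$freq_hz)))
  if (length(md)) {
    cat("metadata:", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Circuit elements: resistor and constant-phase element
#'
#' `resistor()` is an ideal ohmic element, `Z = R`. `cpe()` is a constant
#' phase element with `Z = 1 / (Q (j w)^n)`: magnitude `1/(Q w^n)` and constant
#' phase `-n * 90` degrees. `n = 1` reduces to an ideal capacitor of
#' capacitance `Q`. CPEs model distributed (non-ideal) capacitance at
#' electrode/medium interfaces, hydrogel matrices and cell layers.
#'
#' @param name Unique leaf label; doubles as the parameter name (`name` for a
#'   resistor, `name_Q` / `name_n` for a CPE).
#' @param R Resistance in ohm (> 0).
#' @param Q CPE coefficient in S s^n (> 0).
#' @param n CPE exponent, dimensionless, in (0, 1].
#' @return An `eis_circuit` leaf node.
#' @examples
#' el <- cpe("CPE_matrix", Q = 1e-6, n = 0.9)
#' circuit_series(resistor("R_medium", 500), el)
#' @export
resistor <- function(name, R) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (!is.numeric(R) || length(R) != 1 || !is.finite(R) || R <= 0) {
    stop("resistance R must be a single finite value > 0", call. = FALSE)
  }
  structure(list(kind = "resistor", name = name, R = as.numeric(R)),
            class = "eis_circuit")
}

#' @rdname resistor
#' @export
cpe <- function(name, Q, n) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (!is.numeric(Q) || length(Q) != 1 || !is.finite(Q) || Q <= 0) {
    stop("CPE coefficient Q must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n <= 0 || n > 1) {
    stop("CPE exponent n must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = "cpe", name = name, Q = as.numeric(Q), n = as.numeric(n)),
            class = "eis_circuit")
}

#' Series and parallel composition of circuit nodes
#'
#' Series nodes add impedances; parallel nodes add admittances and invert.
#' Compositions nest arbitrarily, so any ladder of resistors and
#' constant-phase elements can be expressed.
#'
#' @param ... Two or more `eis_circuit` nodes.
#' @return An `eis_circuit` internal node.
#' @export
circuit_series <- function(...) make_node("series", list(...))

#' @rdname circuit_series
#' @export
circuit_parallel <- function(...) make_node("parallel", list(...))

make_node <- function(kind, children) {
  if (length(children) == 0) {
    stop("circuit composition needs at least one child", call. = FALSE)
  }
  ok <- vapply(children, inherits, logical(1), what = "eis_circuit")
  if (!all(ok)) stop("all children must be eis_circuit nodes", call. = FALSE)
  node <- structure(list(kind = kind, children = children), class = "eis_circuit")
  nms <- circuit_leaf_names(node)
  if (anyDuplicated(nms)) {
    stop("leaf names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  node
}

#' Leaf names of a circuit tree
#' @param model An `eis_circuit`.
#' @return Character vector of leaf (element) names, left-to-right.
#' @export
circuit_leaf_names <- function(model) {
  if (model$kind %in% c("resistor", "cpe")) return(model$name)
  unlist(lapply(model$children, circuit_leaf_names))
}

#' Parameter names of a circuit tree
#'
#' Resistor leaves contribute their name; CPE leaves contribute `name_Q` and
#' `name_n`.
#' @param model An `eis_circuit`.
#' @return Character vector of parameter names.
#' @export
circuit_parameter_names <- function(model) {
  if (model$kind == "resistor") return(model$name)
  if (model$kind == "cpe") return(paste0(model$name, c("_Q", "_n")))
  unlist(lapply(model$children, circuit_parameter_names))
}

#' Rebind circuit parameters by name
#'
#' Returns a copy of `model` with leaf values taken from a named numeric
#' vector (resistors by leaf name; CPEs by `name_Q` and `name_n`). Used by the
#' fitting engine to evaluate candidate parameter sets on a fixed topology.
#'
#' @param model An `eis_circuit`.
#' @param parameters Named numeric vector covering every parameter of `model`.
#' @return An `eis_circuit` with updated values.
#' @export
set_parameters <- function(model, parameters) {
  need <- circuit_parameter_names(model)
  missing <- setdiff(need, names(parameters))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rebind <- function(node) {
    if (node$kind == "resistor") {
      return(resistor(node$name, parameters[[node$name]]))
    }
    if (node$kind == "cpe") {
      return(cpe(node$name, parameters[[paste0(node$name, "_Q")]],
                 parameters[[paste0(node$name, "_n")]]))
    }
    node$children <- lapply(node$children, rebind)
    node
  }
  rebind(model)
}

#' Complex impedance of a single element
#'
#' @param element A `resistor()` or `cpe()` leaf.
#' @param omega Angular frequencies in rad/s (> 0); vectorized.
#' @return Complex impedance in ohm, one value per `omega`.
#' @examples
#' element_impedance(cpe("c", 1e-6, 1), 1000) # 1/(j w C): -1000i
#' @export
element_impedance <- function(element, omega) {
  if (!inherits(element, "eis_circuit") ||
      !element$kind %in% c("resistor", "cpe")) {
    stop("element must be a resistor or constant-phase element", call. = FALSE)
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("angular frequency must be finite and > 0", call. = FALSE)
  }
  eval_impedance(element, omega)
}

eval_impedance <- function(node, omega) {
  switch(node$kind,
    resistor = rep(complex(real = node$R, imaginary = 0), length(omega)),
    cpe = 1 / (node$Q * (1i * omega)^node$n),
    series = Reduce(`+`, lapply(node$children, eval_impedance, omega = omega)),
    parallel = 1 / Reduce(`+`, lapply(node$children,
                                      function(ch) 1 / eval_impedance(ch, omega))),
    stop("unknown node kind: ", node$kind, call. = FALSE)
  )
}

#' Evaluate a circuit over a frequency grid
#'
#' Computes the complex impedance of the whole network at each frequency and
#' returns it as a Bode-style spectrum (magnitude and phase). Passivity of
#' resistor/CPE networks guarantees `Re(Z) >= 0` and phase in `[-90, 0]`
#' degrees.
#'
#' @param model An `eis_circuit`.
#' @param freq_hz Frequencies in Hz (strictly positive, ascending).
#' @param metadata Optional metadata list attached to the spectrum.
#' @return An [impedance_spectrum()] tibble.
#' @examples
#' m <- circuit_parallel(resistor("R", 1000), cpe("C", 1e-6, 1))
#' circuit_impedance(m, c(10, 159.155, 1000))
#' @export
circuit_impedance <- function(model, freq_hz, metadata = list()) {
  if (!inherits(model, "eis_circuit")) {
    stop("model must be an eis_circuit", call. = FALSE)
  }
  validate_frequencies(freq_hz)
  z <- eval_impedance(model, 2 * pi * freq_hz)
  impedance_spectrum(freq_hz, Mod(z), Arg(z) * 180 / pi, metadata = metadata)
}

#' Tabulate a spectrum as plain Bode rows
#'
#' @param spectrum An `eis_spectrum`.
#' @return A plain tibble with columns `freq_hz`, `z_mod_ohm`, `z_phase_deg`.
#' @export
bode_table <- function(spectrum) {
  check_spectrum(spectrum)
  tibble::as_tibble(spectrum[c("freq_hz", "z_mod_ohm", "z_phase_deg")])
}

check_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum) ||
      !all(c("freq_hz", "z_mod_ohm", "z_phase_deg") %in% names(spectrum))) {
    stop("expected a spectrum with columns freq_hz, z_mod_ohm, z_phase_deg",
         call. = FALSE)
  }
  if (nrow(spectrum) == 0) stop("spectrum is empty", call. = FALSE)
  invisible(spectrum)
}

#' Bode plot of one or more spectra
#'
#' Magnitude and phase against frequency on a log10 frequency axis, faceted by
#' panel, one colour per spectrum.
#'
#' @param ... Named `eis_spectrum` objects (names become legend labels).
#' @return A ggplot object.
#' @export
plot_bode <- function(...) {
  spectra <- list(...)
  if (is.null(names(spectra)) || any(names(spectra) == "")) {
    names(spectra) <- paste0("spectrum_", seq_along(spectra))
  }
  long <- purrr::imap_dfr(spectra, function(sp, nm) {
    check_spectrum(sp)
    tibble::tibble(series = nm, freq_hz = sp$freq_hz,
                   `|Z| (ohm)` = sp$z_mod_ohm, `phase (deg)` = sp$z_phase_deg)
  }) |>
    tidyr::pivot_longer(c("|Z| (ohm)", "phase (deg)"),
                        names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eis_spectrum <- function(object, ...) plot_bode(spectrum = object)
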