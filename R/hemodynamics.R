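#' Channel geometry and flow conditions
#'
#' `channel_geometry()` describes the rectangular perfusion channel (SI
#' units). The device's vascular channel is 15 mm long, 1 mm wide and 50 um
#' high. `flow_conditions()` holds the volumetric flow rate and the fluid
#' properties; defaults are cell culture medium at 37 C
#' (rho = 1012 kg/m^3, mu = 0.964 mPa s) perfused at 40 uL/min.
#'
#' @param width_m,height_m,length_m Channel dimensions in m (> 0).
#' @param q_m3_s Volumetric flow rate in m^3/s (>= 0).
#' @param q_ul_min Alternative flow-rate input in uL/min (used when `q_m3_s`
#'   is missing).
#' @param rho_kg_m3 Fluid density in kg/m^3.
#' @param mu_pa_s Dynamic viscosity in Pa s.
#' @return A list of class `channel_geometry` / `flow_conditions`.
#' @examples
#' g <- channel_geometry()
#' fc <- flow_conditions()
#' mean_inlet_velocity(g, fc) # ~0.013 m/s
#' @export
channel_geometry <- function(width_m = 1e-3, height_m = 50e-6,
                             length_m = 15e-3) {
  stopifnot(width_m > 0, height_m > 0, length_m > 0)
  structure(list(width_m = width_m, height_m = height_m, length_m = length_m,
                 aspect_ratio = width_m / height_m),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @export
flow_conditions <- function(q_m3_s = NULL, q_ul_min = 40,
                            rho_kg_m3 = 1012, mu_pa_s = 0.964e-3) {
  if (is.null(q_m3_s)) q_m3_s <- q_ul_min * 1e-9 / 60
  stopifnot(q_m3_s >= 0, rho_kg_m3 > 0, mu_pa_s > 0)
  structure(list(q_m3_s = q_m3_s, rho_kg_m3 = rho_kg_m3, mu_pa_s = mu_pa_s),
            class = "flow_conditions")
}

check_geom_flow <- function(geom, flow) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(flow, "flow_conditions"))
  invisible(NULL)
}

#' Mean inlet velocity
#'
#' `u = Q / (w h)`: the plug velocity imposed at the channel inlet. At the
#' default conditions (40 uL/min through 1 mm x 50 um) this is 0.0133 m/s.
#'
#' @param geom A [channel_geometry()].
#' @param flow A [flow_conditions()].
#' @return Mean velocity in m/s.
#' @export
mean_inlet_velocity <- function(geom, flow) {
  check_geom_flow(geom, flow)
  flow$q_m3_s / (geom$width_m * geom$height_m)
}

#' Wall shear stress in the wide-channel (parallel-plates) limit
#'
#' `tau = 6 mu Q / (w h^2)`, the developed-flow wall shear between infinite
#' parallel plates, valid for wide shallow channels (warns when `w/h < 5`).
#' Reported in dyn/cm^2 (1 Pa = 10 dyn/cm^2). The physiological target range
#' for brain capillary endothelium is about 11-13 dyn/cm^2.
#'
#' @inheritParams mean_inlet_velocity
#' @return Wall shear stress in dyn/cm^2.
#' @export
plates_wall_shear <- function(geom, flow) {
  check_geom_flow(geom, flow)
  if (geom$aspect_ratio < 5) {
    warning("parallel-plates formula assumes w >> h (w/h = ",
            signif(geom$aspect_ratio, 3), ")", call. = FALSE)
  }
  tau_pa <- 6 * flow$mu_pa_s * flow$q_m3_s /
    (geom$width_m * geom$height_m^2)
  10 * tau_pa
}

#' Flow rate that produces a target wall shear
#'
#' Inverts [plates_wall_shear()]: `Q = tau w h^2 / (6 mu)`.
#'
#' @inheritParams mean_inlet_velocity
#' @param target_shear_dyn_cm2 Target wall shear in dyn/cm^2 (> 0).
#' @return Flow rate in uL/min.
#' @export
design_flow_rate <- function(geom, flow, target_shear_dyn_cm2) {
  check_geom_flow(geom, flow)
  if (!is.numeric(target_shear_dyn_cm2) || target_shear_dyn_cm2 <= 0) {
    stop("target shear must be > 0", call. = FALSE)
  }
  tau_pa <- target_shear_dyn_cm2 / 10
  q_m3_s <- tau_pa * geom$width_m * geom$height_m^2 / (6 * flow$mu_pa_s)
  q_m3_s * 60 / 1e-9
}

#' Reynolds number of the channel flow
#'
#' `Re = rho u l / mu` with `u` the mean velocity and `l` either the
#' hydraulic diameter `2 w h / (w + h)` or the channel height. The
#' characteristic length is an explicit argument because conventions differ.
#'
#' @inheritParams mean_inlet_velocity
#' @param characteristic_length One of `"hydraulic_diameter"`, `"height"`.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(geom, flow,
                            characteristic_length = c("hydraulic_diameter",
                                                      "height")) {
  check_geom_flow(geom, flow)
  characteristic_length <- match.arg(characteristic_length)
  ell <- switch(characteristic_length,
                hydraulic_diameter = 2 * geom$width_m * geom$height_m /
                  (geom$width_m + geom$height_m),
                height = geom$height_m)
  flow$rho_kg_m3 * mean_inlet_velocity(geom, flow) * ell / flow$mu_pa_s
}

# Overflow-safe cosh(a)/cosh(b) for 0 <= |a| <= b.
cosh_ratio <- function(a, b) {
  a <- abs(a)
  exp(a - b) * (1 + exp(-2 * a)) / (1 + exp(-2 * b))
}

# Pressure gradient G = -dp/dx that carries flow rate Q through a w x h duct.
duct_pressure_gradient <- function(geom, flow, n_terms = 101) {
  w <- geom$width_m; h <- geom$height_m; mu <- flow$mu_pa_s
  n <- seq(1, n_terms, by = 2)
  series <- sum(tanh(n * pi * w / (2 * h)) / n^5)
  q_unit <- (h^3 * w / (12 * mu)) * (1 - 192 * h / (pi^5 * w) * series)
  flow$q_m3_s / q_unit
}

#' Fully developed velocity field in a rectangular duct
#'
#' Analytic Fourier-series solution of the Poisson problem for pressure-driven
#' laminar flow in a rectangular duct with no-slip walls,
#' `u(y, z) = (4 h^2 G / (pi^3 mu)) * sum over odd n of
#' (1/n^3) (1 - cosh(n pi (y - w/2)/h) / cosh(n pi w / (2 h))) sin(n pi z/h)`,
#' with the pressure gradient `G` set so the cross-section integral of `u`
#' equals the prescribed flow rate. `y` spans the width `[0, w]`, `z` the
#' height `[0, h]`.
#'
#' @inheritParams mean_inlet_velocity
#' @param n_y,n_z Sample counts across width and height (interior + walls).
#' @param n_terms Number of series terms (odd harmonics used).
#' @return A tibble with columns `y_m`, `z_m`, `u_m_s`.
#' @export
duct_velocity_field <- function(geom, flow, n_y = 65, n_z = 65,
                                n_terms = 101) {
  check_geom_flow(geom, flow)
  if (n_z < 8) warning("fewer than 8 samples across the channel height",
                       call. = FALSE)
  w <- geom$width_m; h <- geom$height_m; mu <- flow$mu_pa_s
  G <- duct_pressure_gradient(geom, flow, n_terms)
  y <- seq(0, w, length.out = n_y)
  z <- seq(0, h, length.out = n_z)
  n <- seq(1, n_terms, by = 2)
  beta <- n * pi / h
  # u(y,z) = sum_n A_n [1 - cosh(beta (y - w/2)) / cosh(beta w/2)] sin(beta z)
  amp <- 4 * h^2 * G / (pi^3 * mu * n^3)
  ycost <- outer(y - w / 2, seq_along(n),
                 function(yy, k) 1 - cosh_ratio(beta[k] * yy, beta[k] * w / 2))
  zsin <- outer(seq_along(n), z, function(k, zz) sin(beta[k] * zz))
  u <- ycost %*% (amp * zsin)   # n_y x n_z
  # boundary samples are exactly zero analytically; enforce it so no-slip
  # holds bit-for-bit despite sin(n*pi) rounding
  u[1, ] <- 0; u[n_y, ] <- 0; u[, 1] <- 0; u[, n_z] <- 0
  out <- tidyr::expand_grid(y_m = y, z_m = z)
  # expand_grid varies z fastest within y; t(u) flattens in the same order
  out$u_m_s <- as.vector(t(u))
  out
}

#' Wall shear-stress profiles of the rectangular duct
#'
#' Evaluates `tau = mu du/dn` at the walls from the term-wise derivative of
#' the series solution. On the bottom/top walls the shear varies along the
#' width and peaks at the wall centre; on the side walls it varies along the
#' height. Shear vanishes at the duct corners.
#'
#' @inheritParams duct_velocity_field
#' @param n_samples Samples along each wall.
#' @return A tibble with columns `wall` (`"bottom"` or `"side"`),
#'   `position_m` (along the wall), `shear_dyn_cm2`.
#' @export
duct_wall_shear_profile <- function(geom, flow, n_samples = 129,
                                    n_terms = 201) {
  check_geom_flow(geom, flow)
  w <- geom$width_m; h <- geom$height_m
  G <- duct_pressure_gradient(geom, flow, n_terms)
  n <- seq(1, n_terms, by = 2)
  beta <- n * pi / h
  # bottom wall z = 0: tau(y) = (4 h G / pi^2) sum (1/n^2) [1 - cosh/cosh]
  y <- seq(0, w, length.out = n_samples)
  coef_b <- 4 * h * G / (pi^2 * n^2)
  tau_bottom <- vapply(y, function(yy) {
    sum(coef_b * (1 - cosh_ratio(beta * (yy - w / 2), beta * w / 2)))
  }, numeric(1))
  # side wall y = 0: tau(z) = (4 h G / pi^2) sum (1/n^2) tanh(beta w/2) sin(beta z)
  z <- seq(0, h, length.out = n_samples)
  tanh_w <- tanh(beta * w / 2)
  tau_side <- vapply(z, function(zz) {
    sum(coef_b * tanh_w * sin(beta * zz))
  }, numeric(1))
  dplyr::bind_rows(
    tibble::tibble(wall = "bottom", position_m = y,
                   shear_dyn_cm2 = 10 * tau_bottom),
    tibble::tibble(wall = "side", position_m = z,
                   shear_dyn_cm2 = 10 * tau_side))
}

#' Plot the duct velocity field
#'
#' @param field Output of [duct_velocity_field()].
#' @return A ggplot raster of the cross-section velocity magnitude.
#' @export
plot_velocity_field <- function(field) {
  ggplot2::ggplot(field, ggplot2::aes(x = .data$y_m, y = .data$z_m,
                                      fill = .data$u_m_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "u (m/s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "width (m)", y = "height (m)") +
    ggplot2::theme_minimal()
}
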