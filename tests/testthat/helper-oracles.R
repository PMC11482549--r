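# Independent oracles used across the test files.

# Brute-force circuit evaluator: one frequency at a time, real/imaginary
# arithmetic written out by hand (no complex type), so it shares no code path
# with the package's vectorized complex evaluator.
oracle_impedance <- function(node, omega_scalar) {
  add <- function(a, b) c(a[1] + b[1], a[2] + b[2])
  inv <- function(a) {
    d <- a[1]^2 + a[2]^2
    c(a[1] / d, -a[2] / d)
  }
  if (node$kind == "resistor") return(c(node$R, 0))
  if (node$kind == "cpe") {
    # 1/(Q (j w)^n): magnitude 1/(Q w^n), phase -n * pi/2
    mag <- 1 / (node$Q * omega_scalar^node$n)
    ph <- -node$n * pi / 2
    return(c(mag * cos(ph), mag * sin(ph)))
  }
  parts <- lapply(node$children, oracle_impedance, omega_scalar = omega_scalar)
  if (node$kind == "series") return(Reduce(add, parts))
  if (node$kind == "parallel") return(inv(Reduce(add, lapply(parts, inv))))
  stop("unknown node kind")
}

oracle_spectrum <- function(model, freq_hz) {
  rows <- t(vapply(freq_hz, function(f) oracle_impedance(model, 2 * pi * f),
                   numeric(2)))
  list(z_mod_ohm = sqrt(rowSums(rows^2)),
       z_phase_deg = atan2(rows[, 2], rows[, 1]) * 180 / pi)
}

# Random valid R/CPE tree with unique leaf names.
random_circuit <- function(max_depth = 3, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  new_leaf <- function() {
    counter$i <- counter$i + 1L
    if (stats::runif(1) < 0.5) {
      resistor(paste0("R", counter$i), 10^stats::runif(1, 1, 5))
    } else {
      cpe(paste0("C", counter$i), 10^stats::runif(1, -8, -4),
          stats::runif(1, 0.3, 1))
    }
  }
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.4) return(new_leaf())
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) build(depth + 1))
    if (stats::runif(1) < 0.5) do.call(circuit_series, kids)
    else do.call(circuit_parallel, kids)
  }
  build(0)
}

# Finite-difference Poisson oracle for fully developed duct flow:
# solves -lap(u) = 1 on [0,w]x[0,h] with u = 0 on the boundary; the
# max/mean velocity ratio is invariant to the forcing scale.
fd_duct_ratio <- function(w, h, n = 121) {
  ny <- n
  nz <- max(round(n * h / w), 15)
  dy <- w / (ny + 1)
  dz <- h / (nz + 1)
  Iy <- Matrix::Diagonal(ny)
  Iz <- Matrix::Diagonal(nz)
  T1 <- function(m, d) {
    Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                       diagonals = list(rep(1, m - 1), rep(-2, m),
                                        rep(1, m - 1))) / d^2
  }
  A <- Matrix::kronecker(Iz, T1(ny, dy)) + Matrix::kronecker(T1(nz, dz), Iy)
  u <- Matrix::solve(-A, rep(1, ny * nz))
  # cross-section mean via the trapezoid-consistent cell sum (boundary is 0)
  mean_u <- sum(u) * dy * dz / (w * h)
  max(u) / mean_u
}

# Shared noiseless staged dataset: generating and fitting it is expensive, so
# tests reuse one copy per session.
staged_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- bbb_ground_truth()
      cache <<- list(
        truth = truth,
        noiseless = generate_staged_dataset(truth, noise = noise_model(0, 0)))
    }
    cache
  }
})

staged_fits_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- staged_fixture()
      cache <<- staged_calibration(fx$noiseless$spectra)
    }
    cache
  }
})
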