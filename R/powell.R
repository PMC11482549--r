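#' Powell direction-set minimisation
#'
#' Derivative-free minimisation of a scalar function by Powell's method:
#' successive Brent line minimisations along a maintained set of directions,
#' replacing at each sweep the direction of largest single-step decrease with
#' the overall displacement of the sweep. When a cycle converges, the
#' direction set is reset to the coordinate axes and minimisation resumes
#' (up to `restarts` times) — this guards against the direction set becoming
#' linearly dependent in narrow curved valleys. The iterate never moves
#' uphill, so the returned objective is always `<=` the objective at `par`.
#'
#' @param fn Objective, `fn(x) -> scalar`.
#' @param par Numeric start vector.
#' @param tol Relative decrease per sweep below which a cycle stops.
#' @param max_iterations Maximum total number of direction-set sweeps.
#' @param step Initial half-width of the line-search bracket, in the scale of
#'   `par`'s coordinates.
#' @param line_tol Brent tolerance of each line minimisation.
#' @param restarts Direction-set resets allowed after a cycle converges.
#' @return List with `par`, `value`, `iterations`, `converged`,
#'   `function_evaluations`.
#' @export
powell_minimize <- function(fn, par, tol = 1e-10, max_iterations = 200,
                            step = 1, line_tol = 1e-8, restarts = 3) {
  n <- length(par)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; fn(x) }
  x <- par
  fx <- f(x)
  if (!is.finite(fx)) stop("objective not finite at the start", call. = FALSE)
  iter <- 0L
  converged <- FALSE

  line_min <- function(x, d, fx) {
    # Brent minimisation on an expanding symmetric bracket.
    s <- step
    best <- list(minimum = 0, objective = fx)
    for (k in 1:8) {
      opt <- stats::optimize(function(t) f(x + t * d), c(-s, s),
                             tol = line_tol)
      if (opt$objective < best$objective) best <- opt
      # expand only while the minimiser presses against the bracket
      if (abs(opt$minimum) < 0.9 * s) break
      s <- s * 4
    }
    if (best$objective >= fx) return(list(x = x, fx = fx))
    list(x = x + best$minimum * d, fx = best$objective)
  }

  for (cycle in seq_len(restarts + 1)) {
    dirs <- diag(n)
    f_cycle_start <- fx
    cycle_converged <- FALSE
    while (iter < max_iterations) {
      iter <- iter + 1L
      x0 <- x
      f0 <- fx
      biggest_drop <- 0
      biggest_idx <- 1L
      for (i in seq_len(n)) {
        res <- line_min(x, dirs[, i], fx)
        drop <- fx - res$fx
        if (drop > biggest_drop) { biggest_drop <- drop; biggest_idx <- i }
        x <- res$x
        fx <- res$fx
      }
      if (2 * (f0 - fx) <= tol * (abs(f0) + abs(fx) + .Machine$double.eps)) {
        cycle_converged <- TRUE
        break
      }
      d_new <- x - x0
      if (sqrt(sum(d_new^2)) > .Machine$double.eps) {
        # extrapolate along the average direction, keep if it helps
        res <- line_min(x, d_new, fx)
        x <- res$x
        fx <- res$fx
        dirs[, biggest_idx] <- dirs[, n]
        dirs[, n] <- d_new / sqrt(sum(d_new^2))
      }
    }
    converged <- cycle_converged
    # stop restarting once a whole cycle no longer improves the objective
    if (!cycle_converged ||
        2 * (f_cycle_start - fx) <=
          tol * (abs(f_cycle_start) + abs(fx) + .Machine$double.eps)) {
      break
    }
  }
  list(par = x, value = fx, iterations = iter, converged = converged,
       function_evaluations = evals)
}
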