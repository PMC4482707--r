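#' Vector field of the reduced polyp-medusa system
#'
#' Evaluates the right-hand side
#' \deqn{F_1 = aP + bM - b_1 P^2, \qquad F_2 = cP - dM - b_2 M^2}
#' at a given state.
#'
#' @param rp a [reduced_params()] object.
#' @param P polyp abundance (individuals, >= 0).
#' @param M medusa abundance (individuals, >= 0).
#' @return Named numeric vector `c(dP, dM)` (individuals per day).
#' @export
#' @examples
#' vector_field(reduce_params(scypho_preset("V1")), P = 100, M = 50)
vector_field <- function(rp, P, M) {
  validate_reduced_params(rp)
  c(dP = rp$a * P + rp$b * M - rp$b1 * P^2,
    dM = rp$c * P - rp$d * M - rp$b2 * M^2)
}

#' Positively invariant region of the flow
#'
#' The open box \eqn{\Omega = (0, l) \times (0, cl/d)} with
#' \eqn{l = (|a|d + bc)/(b_1 d)} is positively invariant: trajectories
#' starting inside it never leave. Its extent bounds every coexistence
#' equilibrium.
#'
#' @param rp a [reduced_params()] object.
#' @return A list with components `l` (polyp extent) and `M_bound`
#'   (`c * l / d`, the medusa extent).
#' @export
invariant_region <- function(rp) {
  validate_reduced_params(rp)
  l <- (abs(rp$a) * rp$d + rp$b * rp$c) / (rp$b1 * rp$d)
  list(l = l, M_bound = rp$c * l / rp$d)
}

#' Simulate the polyp-medusa dynamics
#'
#' Integrates the reduced planar system with an adaptive integrator
#' (`deSolve::lsoda`, stiff-capable). The model is non-stiff at typical
#' parameter scales but the competition coefficients span several orders
#' of magnitude, which warrants adaptivity. States are clamped at zero
#' on output; an interior negative excursion beyond `10 * atol` is
#' treated as solver failure. The trajectory is flagged as converged to
#' a steady state when the vector-field sup-norm at the final state
#' satisfies \eqn{\|F\|_\infty < 10^{-6}(1 + \|state\|_\infty)}, a
#' relative criterion that handles equilibria from O(10^2) to O(10^4).
#'
#' @param rp a [reduced_params()] object.
#' @param init initial state, numeric `c(P, M)` with both components
#'   nonnegative.
#' @param t_end final time (days, > `t0`).
#' @param t0 initial time (days), default 0.
#' @param n_out number of equally spaced output points (>= 2); ignored
#'   when `times` is given.
#' @param times optional explicit strictly increasing output time grid
#'   (overrides `t0`, `t_end`, `n_out`).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return A `scypho_trajectory`: a data frame with columns `t`, `P`,
#'   `M` and attributes `converged` (logical), `rtol`, `atol`, and
#'   `termination` (character).
#' @export
#' @examples
#' tr <- simulate_dynamics(reduce_params(scypho_preset("V1")),
#'                         init = c(P = 0, M = 2), t_end = 3000)
#' tail(tr, 1)  # near the coexistence equilibrium (248.4, 58.4)
simulate_dynamics <- function(rp, init = c(P = 0, M = 2), t_end,
                              t0 = 0, n_out = 401, times = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  validate_reduced_params(rp)
  init <- as.numeric(init)
  if (length(init) != 2L || any(!is.finite(init)) || any(init < 0)) {
    stop("init must be a nonnegative (P, M) pair", call. = FALSE)
  }
  if (is.null(times)) {
    if (!is.finite(t_end) || t_end <= t0) {
      stop("t_end must exceed the initial time", call. = FALSE)
    }
    times <- seq(t0, t_end, length.out = max(2L, n_out))
  } else {
    if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
      stop("times must be a strictly increasing grid of length >= 2",
           call. = FALSE)
    }
  }
  rhs <- function(t, y, parms) {
    list(c(parms$a * y[1] + parms$b * y[2] - parms$b1 * y[1]^2,
           parms$c * y[1] - parms$d * y[2] - parms$b2 * y[2]^2))
  }
  sol <- deSolve::lsoda(y = c(P = init[1], M = init[2]), times = times,
                        func = rhs, parms = rp, rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("t", "P", "M")
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", max(out$t),
         " (step-size underflow); partial trajectory discarded",
         call. = FALSE)
  }
  if (any(out$P < -10 * atol) || any(out$M < -10 * atol)) {
    stop("integration failed: negative excursion beyond tolerance",
         call. = FALSE)
  }
  out$P <- pmax(out$P, 0)
  out$M <- pmax(out$M, 0)
  fin <- c(out$P[nrow(out)], out$M[nrow(out)])
  f <- vector_field(rp, fin[1], fin[2])
  converged <- max(abs(f)) < 1e-6 * (1 + max(abs(fin)))
  structure(out,
            class = c("scypho_trajectory", "data.frame"),
            converged = converged, rtol = rtol, atol = atol,
            termination = if (converged) "steady-state" else "t_end")
}

#' @export
print.scypho_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Polyp-medusa trajectory: %d points, t in [%g, %g]\n",
              n, x$t[1], x$t[n]))
  cat(sprintf("  final state (P, M) = (%.6g, %.6g); %s\n",
              x$P[n], x$M[n],
              if (isTRUE(attr(x, "converged"))) "converged to steady state"
              else "not converged"))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes the time grid and both abundances with header `t,P,M`.
#'
#' @param traj a `scypho_trajectory` from [simulate_dynamics()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.csv(as.data.frame(traj)[, c("t", "P", "M")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
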