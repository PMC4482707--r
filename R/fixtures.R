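# Synthetic data generators. These emulate the structure of per-day
# standardized laboratory rate measurements (a smooth thermal response
# plus additive observation noise) and of observed population time
# series, so fitting and estimation code is testable without any
# external data.

# Run expr with a private RNG stream; the caller's .Random.seed is
# untouched.
with_fixture_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification of a synthetic fixture
#'
#' Bundles everything needed to generate a reproducible synthetic
#' dataset: the RNG seed, the generating family, the noise level, the
#' sampling grid (temperatures for rate data, times for trajectories),
#' and the generating ("truth") parameters.
#'
#' @param seed integer seed; one seed drives one private random stream
#'   per fixture, leaving global RNG state untouched.
#' @param family `"gaussian"`, `"cubic_offset"`, or `"trajectory"`.
#' @param noise_sd standard deviation of the observation noise
#'   (additive for rates, multiplicative lognormal for abundances);
#'   `>= 0`.
#' @param grid sampling points: temperatures (degrees C) for rate
#'   fixtures, output times (days) for trajectory fixtures.
#' @param truth generating parameters: a temperature response object
#'   for rate fixtures; unused for trajectories (the reduced
#'   parameters are passed to [make_observed_trajectory()]).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed, family, noise_sd, grid, truth = NULL) {
  family <- match.arg(family, c("gaussian", "cubic_offset", "trajectory"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(grid) == 0L) stop("grid must be nonempty", call. = FALSE)
  structure(list(seed = seed, family = family, noise_sd = noise_sd,
                 grid = as.numeric(grid), truth = truth),
            class = "fixture_spec")
}

#' Generate a synthetic rate dataset
#'
#' Samples the truth response on the temperature grid and adds
#' independent Gaussian observation noise, clamping at zero (rates are
#' nonnegative; near-zero rates may clamp). Bit-identical output for
#' identical specs.
#'
#' @param spec a [fixture_spec()] with family `"gaussian"` or
#'   `"cubic_offset"` and a temperature response as `truth`.
#' @return A data frame with columns `T`, `rate`; the generating
#'   response is attached as attribute `truth`.
#' @export
#' @examples
#' sp <- fixture_spec(1, "gaussian", 0.005, 7:22,
#'                    truth = strobilation_response())
#' head(make_rate_dataset(sp))
make_rate_dataset <- function(spec) {
  if (!inherits(spec, "fixture_spec")) {
    stop("spec must be a fixture_spec", call. = FALSE)
  }
  if (!spec$family %in% c("gaussian", "cubic_offset")) {
    stop("rate datasets require family 'gaussian' or 'cubic_offset'",
         call. = FALSE)
  }
  if (!inherits(spec$truth, "temperature_response")) {
    stop("truth must be a temperature response object", call. = FALSE)
  }
  mu <- eval_response(spec$truth, spec$grid, warn_outside = FALSE)
  rate <- with_fixture_seed(spec$seed, {
    pmax(mu + stats::rnorm(length(mu), 0, spec$noise_sd), 0)
  })
  structure(data.frame(T = spec$grid, rate = rate), truth = spec$truth)
}

#' Generate a noisy observed trajectory
#'
#' Simulates the reduced system on the spec's time grid, then applies
#' multiplicative lognormal observation noise to both abundances
#' (noise must respect positivity). With `noise_sd = 0` the exact
#' simulated trajectory is returned.
#'
#' @param spec a [fixture_spec()] with family `"trajectory"`; the grid
#'   holds the observation times (days, strictly increasing, starting
#'   at the initial time).
#' @param rp a [reduced_params()] object.
#' @param init initial state `c(P, M)`.
#' @return A data frame with columns `t`, `P`, `M`; the noiseless
#'   trajectory is attached as attribute `truth`.
#' @export
make_observed_trajectory <- function(spec, rp, init = c(P = 0, M = 2)) {
  if (!inherits(spec, "fixture_spec") || spec$family != "trajectory") {
    stop("spec must be a fixture_spec with family 'trajectory'",
         call. = FALSE)
  }
  times <- spec$grid
  if (is.unsorted(times, strictly = TRUE)) {
    stop("trajectory grid must be strictly increasing times",
         call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("trajectory grid needs at least two times", call. = FALSE)
  }
  tr <- simulate_dynamics(rp, init = init, times = times)
  base <- data.frame(t = tr$t, P = tr$P, M = tr$M)
  noisy <- with_fixture_seed(spec$seed, {
    data.frame(
      t = base$t,
      P = base$P * stats::rlnorm(nrow(base), 0, spec$noise_sd),
      M = base$M * stats::rlnorm(nrow(base), 0, spec$noise_sd))
  })
  structure(noisy, truth = base)
}

#' Synthetic budding-rate dataset
#'
#' A deterministic synthetic dataset of per-day budding rates on the
#' integer temperatures 7 to 22 degrees C, constructed to lie in the
#' biological range (0.03 to 0.15 ind per polyp per day) and to peak
#' near 12.5 degrees C. It stands in for laboratory budding-rate
#' measurements when calibrating a range-consistent cubic response;
#' it is synthetic, not digitized from any experiment.
#'
#' @return A data frame with columns `T`, `rate`.
#' @export
synthetic_budding_data <- function() {
  T <- 7:22
  data.frame(T = T, rate = 0.03 + 0.12 * exp(-((T - 12.5) / 5)^2))
}
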