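#' Temperature-response curves
#'
#' Two parametric families describe how the temperature `T` (degrees
#' Celsius) modulates the polyp vital rates over the study window
#' `[7, 22]`:
#' a Gaussian thermal-performance curve
#' \deqn{\beta(T) = A \exp\{-((T - T_0)/w)^2\}}
#' for the strobilation rate (amplitude `A`, peak temperature `T_0`,
#' width `w`), and a cubic polynomial with an additive offset
#' \deqn{\alpha(T) = c_3 T^3 + c_2 T^2 + c_1 T + c_0 + o}
#' for the budding rate.
#'
#' @param amplitude peak rate (same units as the modelled rate, > 0).
#' @param center peak temperature (degrees C).
#' @param width Gaussian scale (degrees C, > 0).
#' @param domain temperature interval over which the fit is valid.
#' @return An object of class `gaussian_response` or
#'   `cubic_offset_response`.
#' @seealso [eval_response()], [fit_response()], [growth_stairs()]
#' @export
gaussian_response <- function(amplitude, center, width,
                              domain = c(7, 22)) {
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("domain must be a nonempty interval", call. = FALSE)
  }
  structure(list(amplitude = amplitude, center = center, width = width,
                 domain = as.numeric(domain)),
            class = c("gaussian_response", "temperature_response"))
}

#' @rdname gaussian_response
#' @param c3,c2,c1,c0 cubic coefficients.
#' @param offset additive constant.
#' @export
cubic_offset_response <- function(c3, c2, c1, c0, offset = 0,
                                  domain = c(7, 22)) {
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("domain must be a nonempty interval", call. = FALSE)
  }
  structure(list(c3 = c3, c2 = c2, c1 = c1, c0 = c0, offset = offset,
                 domain = as.numeric(domain)),
            class = c("cubic_offset_response", "temperature_response"))
}

#' Evaluate a temperature response
#'
#' Evaluates the curve at the given temperatures. Evaluation outside
#' the fitted domain is permitted but raises a warning, since neither
#' family is intended to extrapolate.
#'
#' @param resp a `gaussian_response` or `cubic_offset_response`.
#' @param T temperatures (degrees C, vectorized).
#' @param warn_outside warn when any `T` falls outside the domain.
#' @return Rate values at `T`.
#' @export
#' @examples
#' eval_response(strobilation_response(), 16.8108)  # peak, 0.1430
eval_response <- function(resp, T, warn_outside = TRUE) {
  UseMethod("eval_response")
}

.check_domain <- function(resp, T, warn_outside) {
  if (warn_outside && any(T < resp$domain[1] | T > resp$domain[2])) {
    warning("temperature outside fitted domain [", resp$domain[1], ", ",
            resp$domain[2], "]; extrapolating", call. = FALSE)
  }
}

#' @export
eval_response.gaussian_response <- function(resp, T, warn_outside = TRUE) {
  .check_domain(resp, T, warn_outside)
  resp$amplitude * exp(-((T - resp$center) / resp$width)^2)
}

#' @export
eval_response.cubic_offset_response <- function(resp, T,
                                                warn_outside = TRUE) {
  .check_domain(resp, T, warn_outside)
  resp$c3 * T^3 + resp$c2 * T^2 + resp$c1 * T + resp$c0 + resp$offset
}

#' @export
print.temperature_response <- function(x, ...) {
  if (inherits(x, "gaussian_response")) {
    cat(sprintf(
      "Gaussian temperature response: %g * exp(-((T - %g)/%g)^2)\n",
      x$amplitude, x$center, x$width))
  } else {
    cat(sprintf(
      "Cubic+offset temperature response: %g T^3 + %g T^2 + %g T + %g + %g\n",
      x$c3, x$c2, x$c1, x$c0, x$offset))
  }
  cat(sprintf("  domain [%g, %g] degrees C\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' Default fitted strobilation response
#'
#' The Gaussian strobilation-rate curve fitted to laboratory rates
#' standardized per day: amplitude 0.1430 ephyrae per polyp per day,
#' peak at 16.8108 degrees C, width 10.5302 degrees C, valid on
#' `[7, 22]`.
#'
#' @return A [gaussian_response()].
#' @export
strobilation_response <- function() {
  gaussian_response(0.1430, 16.8108, 10.5302, domain = c(7, 22))
}

#' Published cubic budding response (verbatim coefficients)
#'
#' The cubic-plus-offset budding-rate curve with the published
#' coefficients, `1.9272 T^3 - 30.3904 T^2 + 294.7234 T - 871.29 +
#' 0.0378`. As printed, these coefficients yield values of order 10^3
#' on `[7, 22]` and the cubic is monotone there, which is inconsistent
#' with the biological budding range (0.03 to 0.15 per day) and with a
#' 12.5 degree C polyp peak; the curve is provided verbatim for
#' transparency. For range-consistent sweeps use
#' [budding_response_synthetic()].
#'
#' @return A [cubic_offset_response()].
#' @export
budding_response_printed <- function() {
  cubic_offset_response(1.9272, -30.3904, 294.7234, -871.29, 0.0378,
                        domain = c(7, 22))
}

#' Synthetic range-consistent budding response
#'
#' A cubic-plus-offset budding curve obtained by least-squares fitting
#' the cubic family to a synthetic budding-rate dataset constructed to
#' lie in the biological range (0.03 to 0.15 ind per polyp per day)
#' with a peak near 12.5 degrees C. It is a synthetic stand-in for a
#' laboratory-calibrated budding curve, suitable for temperature sweeps
#' where the verbatim published coefficients are out of range.
#'
#' @return A fitted [cubic_offset_response()].
#' @export
budding_response_synthetic <- function() {
  obs <- synthetic_budding_data()
  fit_response(obs, family = "cubic_offset")$response
}

#' Fit a temperature-response curve by least squares
#'
#' Fits either family to observed `(T, rate)` pairs minimizing the
#' summed square of residuals (SSE). The Gaussian family is fitted by
#' nonlinear least squares (Levenberg-Marquardt via
#' `minpack.lm::nlsLM`) with moment-based starting values (amplitude =
#' max rate, center = argmax temperature, width = half the temperature
#' range) unless `init` is supplied. The cubic family is fitted by
#' linear least squares on the monomial basis, with the additive offset
#' absorbed into the fitted intercept (reported as `c0`, offset 0).
#'
#' @param obs a data frame with columns `T`, `rate` and optionally
#'   `weight`.
#' @param family `"gaussian"` or `"cubic_offset"`.
#' @param init optional named list of starting values
#'   (`amplitude`, `center`, `width`) for the Gaussian family.
#' @param domain domain recorded on the fitted response; defaults to
#'   the observed temperature range.
#' @return A list with `response` (the fitted object), `sse`, and
#'   `fitted` (fitted values at the observed temperatures).
#' @export
#' @examples
#' obs <- data.frame(T = 7:22,
#'                   rate = eval_response(strobilation_response(), 7:22))
#' fit_response(obs, "gaussian")$sse  # ~0: noiseless recovery
fit_response <- function(obs, family = c("gaussian", "cubic_offset"),
                         init = NULL, domain = NULL) {
  family <- match.arg(family)
  if (!all(c("T", "rate") %in% names(obs))) {
    stop("obs must have columns 'T' and 'rate'", call. = FALSE)
  }
  if (any(obs$rate < 0)) {
    stop("observed rates must be nonnegative", call. = FALSE)
  }
  n_par <- if (family == "gaussian") 3L else 4L
  if (nrow(obs) < n_par) {
    stop("need at least ", n_par, " observations to fit the ", family,
         " family", call. = FALSE)
  }
  if (length(unique(obs$T)) < n_par) {
    stop("rank deficiency: need at least ", n_par,
         " distinct temperatures", call. = FALSE)
  }
  w <- if ("weight" %in% names(obs)) obs$weight else rep(1, nrow(obs))
  if (is.null(domain)) domain <- range(obs$T)

  if (family == "gaussian") {
    if (is.null(init)) {
      init <- list(amplitude = max(obs$rate),
                   center = obs$T[which.max(obs$rate)],
                   width = diff(range(obs$T)) / 2)
    }
    fit <- minpack.lm::nlsLM(
      rate ~ amplitude * exp(-((T - center) / width)^2),
      data = obs, start = init, weights = w,
      lower = c(amplitude = 1e-12, center = -Inf, width = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    resp <- gaussian_response(cf[["amplitude"]], cf[["center"]],
                              abs(cf[["width"]]), domain = domain)
  } else {
    fit <- stats::lm(rate ~ I(T^3) + I(T^2) + T, data = obs, weights = w)
    cf <- stats::coef(fit)
    resp <- cubic_offset_response(cf[["I(T^3)"]], cf[["I(T^2)"]],
                                  cf[["T"]], cf[["(Intercept)"]],
                                  offset = 0, domain = domain)
  }
  fitted_vals <- eval_response(resp, obs$T, warn_outside = FALSE)
  list(response = resp, sse = sum((fitted_vals - obs$rate)^2),
       fitted = fitted_vals)
}

#' Read rate observations from delimited text
#'
#' Expects a header `T,rate` with an optional third `weight` column.
#'
#' @param file path to a delimited text file (comma, tab, or whitespace
#'   separated).
#' @param sep field separator passed to [utils::read.table()];
#'   default `","`.
#' @return A data frame with columns `T`, `rate` (and `weight` if
#'   present).
#' @export
read_rate_observations <- function(file, sep = ",") {
  obs <- utils::read.table(file, header = TRUE, sep = sep,
                           strip.white = TRUE)
  if (!all(c("T", "rate") %in% names(obs))) {
    stop("rate observation file must have header 'T,rate[,weight]'",
         call. = FALSE)
  }
  if (any(obs$rate < 0)) {
    stop("observed rates must be nonnegative", call. = FALSE)
  }
  obs
}

#' Per-degree relative growth stairs
#'
#' For each integer temperature `T` in `[T_start, T_end - 1]`, computes
#' the relative change of the response under one degree of warming,
#' `100 * (g(T + 1) - g(T)) / g(T)` in percent. For the fitted
#' strobilation curve this quantifies how much one degree of warming
#' changes ephyra production.
#'
#' @param resp a temperature response (typically
#'   [strobilation_response()]).
#' @param T_start,T_end integer temperatures, `T_start < T_end`.
#' @return A data frame with columns `T_from`, `T_to`,
#'   `relative_growth_pct`.
#' @export
#' @examples
#' growth_stairs(strobilation_response(), 7, 9)  # 18.3%, 16.2%
growth_stairs <- function(resp, T_start, T_end) {
  if (T_start != round(T_start) || T_end != round(T_end)) {
    stop("stairs require integer-degree endpoints", call. = FALSE)
  }
  if (T_start >= T_end) stop("T_start must be < T_end", call. = FALSE)
  from <- seq(T_start, T_end - 1)
  g0 <- eval_response(resp, from, warn_outside = FALSE)
  g1 <- eval_response(resp, from + 1, warn_outside = FALSE)
  if (any(g0 == 0)) {
    stop("relative growth undefined: response is zero at T = ",
         from[g0 == 0][1], call. = FALSE)
  }
  data.frame(T_from = from, T_to = from + 1,
             relative_growth_pct = 100 * (g1 - g0) / g0)
}

#' Steady-state sensitivity sweep
#'
#' Varies one biological parameter (or the temperature) over a grid
#' and, for each value, reduces the system, classifies the global
#' regime, and records the attractor as the steady state. When
#' `vary = "temperature"`, the budding and strobilation rates are taken
#' from the supplied response curves before reduction. Grid values that
#' violate a parameter invariant are flagged invalid and skipped; the
#' sweep continues.
#'
#' @param params a [scypho_params()] base set.
#' @param vary name of the varied parameter (one of the twelve field
#'   names) or `"temperature"`.
#' @param grid numeric grid of values for the varied quantity; must be
#'   strictly monotone.
#' @param alpha_response,beta_response temperature responses used when
#'   `vary = "temperature"`; default [budding_response_synthetic()] and
#'   [strobilation_response()].
#' @return A `scypho_sweep` data frame with columns `param`,
#'   `param_value`, `P_star`, `M_star`, `regime`, `valid`.
#' @export
#' @examples
#' sweep_steady_state(scypho_preset("V2"), "d4",
#'                    grid = c(0.0001, 0.01, 0.05))
sweep_steady_state <- function(params, vary, grid,
                               alpha_response = NULL,
                               beta_response = NULL) {
  validate_scypho_params(params)
  if (is.unsorted(grid, strictly = TRUE) &&
      is.unsorted(rev(grid), strictly = TRUE)) {
    stop("grid must be strictly monotone", call. = FALSE)
  }
  is_temp <- identical(vary, "temperature")
  if (!is_temp && !vary %in% names(unclass(params))) {
    stop("unknown parameter to vary: ", vary, call. = FALSE)
  }
  if (is_temp) {
    if (is.null(alpha_response)) alpha_response <- budding_response_synthetic()
    if (is.null(beta_response)) beta_response <- strobilation_response()
  }
  rows <- lapply(grid, function(v) {
    p <- unclass(params)
    if (is_temp) {
      p$alpha <- eval_response(alpha_response, v, warn_outside = FALSE)
      p$beta <- eval_response(beta_response, v, warn_outside = FALSE)
    } else {
      p[[vary]] <- v
    }
    ok <- tryCatch({
      reg <- classify_regime(reduce_params(do.call(scypho_params, p)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      return(data.frame(param = vary, param_value = v, P_star = NA_real_,
                        M_star = NA_real_, regime = NA_character_,
                        valid = FALSE))
    }
    loc <- if (is.null(reg$attractor)) c(P = NA_real_, M = NA_real_) else
      reg$attractor$location
    data.frame(param = vary, param_value = v, P_star = loc[["P"]],
               M_star = loc[["M"]], regime = reg$regime, valid = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scypho_sweep", "data.frame")
  out
}

#' Export a sweep as CSV
#'
#' Writes the header `param_value,P_star,M_star,regime` (invalid rows
#' keep their flag in a trailing `valid` column).
#'
#' @param sweep a `scypho_sweep` from [sweep_steady_state()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_sweep <- function(sweep, file) {
  utils::write.csv(
    as.data.frame(sweep)[, c("param_value", "P_star", "M_star",
                             "regime", "valid")],
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
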