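#' Biological parameter set for the polyp-medusa model
#'
#' Constructs and validates the full set of twelve biological rates that
#' govern the two-stage scyphozoan life-history model. Polyps (benthic
#' stage) gain individuals through asexual budding and through planula
#' recruitment from medusae, and lose them to natural mortality, silt
#' cover / nudibranch predation, and intraspecific competition for
#' substrate. Medusae (pelagic stage) are recruited as ephyrae via
#' strobilation and lost to natural mortality, predation, and
#' intraspecific competition.
#'
#' @param alpha asexual (budding) reproduction rate of polyps
#'   (ind d^-1 per polyp); typically temperature dependent.
#' @param beta strobilation rate (ind d^-1 time^-1 per polyp); typically
#'   temperature dependent.
#' @param gamma sexual reproduction rate (planulae d^-1 per medusa).
#' @param s1 survival and successful settlement fraction of planulae
#'   (dimensionless, in \[0, 1\]).
#' @param s2 survival fraction of ephyrae (dimensionless, in \[0, 1\]).
#' @param n number of strobilation times (>= 1).
#' @param d1 natural mortality rate of polyps (d^-1).
#' @param d2 polyp mortality from silt cover or nudibranch consumption
#'   (d^-1).
#' @param d3 natural mortality rate of medusae (d^-1).
#' @param d4 medusa mortality induced by predation (d^-1).
#' @param b1 intraspecific competition between polyps (d^-1 ind^-1);
#'   must be strictly positive.
#' @param b2 intraspecific competition between medusae (d^-1 ind^-1);
#'   must be strictly positive.
#'
#' @return An object of class `scypho_params`: a named list of the twelve
#'   rates.
#' @seealso [scypho_preset()] for the two shipped presets,
#'   [reduce_params()] for the collapse to the six-parameter system.
#' @export
#' @examples
#' p <- scypho_preset("V1")
#' reduce_params(p)
scypho_params <- function(alpha, beta, gamma, s1, s2, n,
                          d1, d2, d3, d4, b1, b2) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma,
            s1 = s1, s2 = s2, n = n,
            d1 = d1, d2 = d2, d3 = d3, d4 = d4,
            b1 = b1, b2 = b2)
  p <- lapply(p, as.numeric)
  class(p) <- "scypho_params"
  validate_scypho_params(p)
  p
}

#' Validate a biological parameter set
#'
#' Checks all field invariants: every rate nonnegative and finite,
#' `b1 > 0`, `b2 > 0`, `d3 + d4 > 0`, `s1 <= 1`, `s2 <= 1`, `n >= 1`.
#' The error message names the offending field.
#'
#' @param p a `scypho_params` object (or a plain named list with the
#'   same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_scypho_params <- function(p) {
  fields <- c("alpha", "beta", "gamma", "s1", "s2", "n",
              "d1", "d2", "d3", "d4", "b1", "b2")
  missing <- setdiff(fields, names(p))
  if (length(missing) > 0L) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in fields) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
    if (v < 0) {
      stop("parameter invariant violated: ", f, " >= 0", call. = FALSE)
    }
  }
  if (p$b1 <= 0) stop("parameter invariant violated: b1 > 0", call. = FALSE)
  if (p$b2 <= 0) stop("parameter invariant violated: b2 > 0", call. = FALSE)
  if (p$d3 + p$d4 <= 0) {
    stop("parameter invariant violated: d3 + d4 > 0", call. = FALSE)
  }
  if (p$s1 > 1) stop("parameter invariant violated: s1 <= 1", call. = FALSE)
  if (p$s2 > 1) stop("parameter invariant violated: s2 <= 1", call. = FALSE)
  if (p$n < 1) stop("parameter invariant violated: n >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.scypho_params <- function(x, ...) {
  cat("Scyphozoan life-history parameters\n")
  cat(sprintf("  %-6s %g\n", names(x), unlist(x)), sep = "")
  invisible(x)
}

# Default parameter columns used for the numerical studies.  V1 is a
# moderate-conditions set; V2 has high reproduction/survival and low
# losses and competition, the bloom-favourable scenario.
.scypho_presets <- list(
  V1 = list(alpha = 0.12, beta = 0.108, gamma = 100, s1 = 0.008,
            s2 = 0.2, n = 1, d1 = 0.0001, d2 = 0.01, d3 = 0.006,
            d4 = 0.08, b1 = 0.0012, b2 = 0.0001),
  V2 = list(alpha = 0.15, beta = 0.122, gamma = 170, s1 = 0.01,
            s2 = 0.8, n = 1, d1 = 0.0001, d2 = 0.01, d3 = 0.004,
            d4 = 0.0001, b1 = 0.0001, b2 = 0.0001)
)

#' Shipped parameter presets
#'
#' Returns one of the two default parameter columns used throughout the
#' numerical studies: `"V1"` (moderate conditions) or `"V2"` (favourable
#' conditions: high reproduction and survival, low mortality and
#' competition).
#'
#' @param name `"V1"` or `"V2"`.
#' @return A validated [scypho_params()] object.
#' @export
scypho_preset <- function(name = c("V1", "V2")) {
  name <- match.arg(name)
  do.call(scypho_params, .scypho_presets[[name]])
}

#' Reduced six-parameter system
#'
#' Collapses the twelve biological rates to the six parameters of the
#' planar system
#' \deqn{dP/dt = aP + bM - b_1 P^2, \quad dM/dt = cP - dM - b_2 M^2}
#' with `a = alpha - d1 - d2` (net polyp per-capita growth, any sign),
#' `b = s1 * gamma` (planula recruitment per medusa), `c = s2 * beta * n`
#' (ephyra recruitment per polyp), and `d = d3 + d4` (total medusa
#' mortality). `b1` and `b2` carry over unchanged.
#'
#' @param params a validated [scypho_params()] object.
#' @return A `reduced_params` object with fields `a`, `b`, `c`, `d`,
#'   `b1`, `b2`.
#' @export
#' @examples
#' reduce_params(scypho_preset("V1"))  # a = 0.1099, b = 0.8, ...
reduce_params <- function(params) {
  validate_scypho_params(params)
  reduced_params(a = params$alpha - params$d1 - params$d2,
                 b = params$s1 * params$gamma,
                 c = params$s2 * params$beta * params$n,
                 d = params$d3 + params$d4,
                 b1 = params$b1, b2 = params$b2)
}

#' Construct a reduced parameter set directly
#'
#' @param a net polyp per-capita growth rate (d^-1, any sign).
#' @param b planula recruitment rate (ind d^-1 per medusa, >= 0).
#' @param c ephyra recruitment rate (ind d^-1 per polyp, >= 0).
#' @param d total medusa mortality (d^-1, > 0).
#' @param b1,b2 intraspecific competition coefficients (> 0).
#' @return A `reduced_params` object.
#' @export
reduced_params <- function(a, b, c, d, b1, b2) {
  rp <- list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d), b1 = as.numeric(b1), b2 = as.numeric(b2))
  class(rp) <- "reduced_params"
  validate_reduced_params(rp)
  rp
}

#' @rdname reduced_params
#' @param rp a `reduced_params` object.
#' @export
validate_reduced_params <- function(rp) {
  for (f in c("a", "b", "c", "d", "b1", "b2")) {
    v <- rp[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop("reduced parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (rp$b < 0) stop("reduced parameter invariant violated: b >= 0",
                     call. = FALSE)
  if (rp$c < 0) stop("reduced parameter invariant violated: c >= 0",
                     call. = FALSE)
  if (rp$d <= 0) stop("reduced parameter invariant violated: d > 0",
                      call. = FALSE)
  if (rp$b1 <= 0) stop("reduced parameter invariant violated: b1 > 0",
                       call. = FALSE)
  if (rp$b2 <= 0) stop("reduced parameter invariant violated: b2 > 0",
                       call. = FALSE)
  invisible(rp)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("Reduced polyp-medusa system parameters\n")
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g, b1 = %g, b2 = %g\n",
              x$a, x$b, x$c, x$d, x$b1, x$b2))
  cat(sprintf("  discriminant ad + bc = %g\n", x$a * x$d + x$b * x$c))
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameter files are flat `key = value` text with the twelve field
#' names as keys (one per line, `#` comments allowed), keeping the
#' symbol-to-code mapping one-to-one. Written files round-trip exactly.
#'
#' @param file path to a parameter file.
#' @return `read_params()` returns a validated [scypho_params()] object.
#' @export
read_params <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2L, logical(1))
  if (any(bad)) {
    stop("malformed parameter line: ", lines[bad][1], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) {
    stop("non-numeric value for parameter '", keys[is.na(vals)][1], "'",
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated parameter key: ", keys[duplicated(keys)][1],
         call. = FALSE)
  }
  do.call(scypho_params, as.list(stats::setNames(vals, keys)))
}

#' @rdname read_params
#' @param params a [scypho_params()] object to write.
#' @export
write_params <- function(params, file) {
  validate_scypho_params(params)
  writeLines(sprintf("%s = %.17g", names(unclass(params)),
                     unlist(params)), file)
  invisible(file)
}
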