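#' Jacobian of the reduced system at a point
#'
#' The linearization of the planar polyp-medusa system at `(P, M)` is
#' \deqn{J = \begin{pmatrix} a - 2 b_1 P & b \\ c & -d - 2 b_2 M
#' \end{pmatrix}.}
#' Eigenvalues are computed from the closed-form 2x2 characteristic
#' polynomial (exact trace/determinant arithmetic) rather than a general
#' numerical solver.
#'
#' @param rp a [reduced_params()] object.
#' @param P,M coordinates of the evaluation point.
#' @return A list with `matrix` (2x2) and `eigenvalues` (complex pair,
#'   sorted by decreasing real part).
#' @export
jacobian_at <- function(rp, P, M) {
  validate_reduced_params(rp)
  J <- matrix(c(rp$a - 2 * rp$b1 * P, rp$b,
                rp$c, -rp$d - 2 * rp$b2 * M),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("dP", "dM"), c("P", "M")))
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  if (disc >= 0) {
    s <- sqrt(disc)
    ev <- complex(real = c((tr + s) / 2, (tr - s) / 2), imaginary = 0)
  } else {
    s <- sqrt(-disc) / 2
    ev <- complex(real = tr / 2, imaginary = c(s, -s))
  }
  list(matrix = J, eigenvalues = ev)
}

.stability_label <- function(ev) {
  re <- Re(ev)
  if (all(re < 0)) "stable-node"
  else if (any(abs(re) < .Machine$double.eps^0.5)) "saddle-node-degenerate"
  else if (re[1] > 0 && re[2] < 0) "saddle"
  else "unstable"
}

.make_equilibrium <- function(rp, P, M, label) {
  j <- jacobian_at(rp, P, M)
  structure(list(location = c(P = P, M = M), label = label,
                 eigenvalues = j$eigenvalues,
                 local_stability = .stability_label(j$eigenvalues)),
            class = "scypho_equilibrium")
}

#' @export
print.scypho_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (P, M) = (%.6g, %.6g): %s\n",
              x$label, x$location["P"], x$location["M"],
              x$local_stability))
  invisible(x)
}

#' Medusa nullcline
#'
#' Solves \eqn{cP - dM - b_2 M^2 = 0} for the nonnegative medusa
#' abundance at given polyp abundance:
#' \eqn{M(P) = (-d + \sqrt{d^2 + 4 b_2 c P}) / (2 b_2)}.
#'
#' @param rp a [reduced_params()] object.
#' @param P polyp abundance (vectorized).
#' @return Medusa abundance on the nullcline.
#' @export
medusa_nullcline <- function(rp, P) {
  (-rp$d + sqrt(rp$d^2 + 4 * rp$b2 * rp$c * P)) / (2 * rp$b2)
}

#' Find all equilibria of the reduced system
#'
#' The extinction state `E0 = (0, 0)` always exists. The polyp-only
#' boundary state `E1 = (a/b1, 0)` exists when there is no ephyra
#' recruitment (`c = 0`) and net polyp growth is positive (`a > 0`).
#' The coexistence state `E*` exists if and only if `ad + bc > 0` and
#' `c != 0`; it is located by eliminating M via the medusa nullcline and
#' root-finding the polyp-nullcline residual
#' \eqn{g(P) = aP + b M(P) - b_1 P^2} on `(0, l)` with Brent's method
#' (`stats::uniroot`), where `l` is the invariant-region extent.
#' The bracket `g(eps) > 0`, `g(l) < 0` with `eps = 1e-12 * l` is
#' asserted before solving. When `b = 0` the root agrees with the closed
#' form \eqn{(a/b_1,\; (-b_1 d + \sqrt{b_1^2 d^2 + 4 a c b_1 b_2}) /
#' (2 b_1 b_2))} to near machine precision.
#'
#' @param rp a [reduced_params()] object.
#' @param equality_tol absolute tolerance for treating `c` or the
#'   discriminant `ad + bc` as zero.
#' @return A list of `scypho_equilibrium` objects (labels `EXTINCTION`,
#'   `POLYP_ONLY`, `COEXISTENCE`).
#' @export
#' @examples
#' find_equilibria(reduce_params(scypho_preset("V1")))
find_equilibria <- function(rp, equality_tol = 1e-12) {
  validate_reduced_params(rp)
  eq <- list(.make_equilibrium(rp, 0, 0, "EXTINCTION"))
  disc <- rp$a * rp$d + rp$b * rp$c
  c_zero <- abs(rp$c) <= equality_tol
  if (c_zero && rp$a > 0) {
    eq <- c(eq, list(.make_equilibrium(rp, rp$a / rp$b1, 0, "POLYP_ONLY")))
  }
  if (disc > equality_tol && !c_zero) {
    l <- invariant_region(rp)$l
    g <- function(P) rp$a * P + rp$b * medusa_nullcline(rp, P) -
      rp$b1 * P^2
    eps <- 1e-12 * l
    # g > 0 near the origin and g < 0 beyond the root; when b = 0 the
    # root sits exactly at l, so widen the upper bracket marginally.
    upper <- l
    k <- 0L
    while (g(upper) >= 0 && k < 60L) {
      upper <- upper * (1 + 2^k * 1e-12)
      k <- k + 1L
    }
    if (!(g(eps) > 0 && g(upper) < 0)) {
      stop("internal inconsistency: coexistence root not bracketed in ",
           "(0, l) although ad + bc > 0 and c > 0", call. = FALSE)
    }
    Pstar <- stats::uniroot(g, c(eps, upper),
                            tol = .Machine$double.eps^0.75,
                            maxiter = 2000L)$root
    eq <- c(eq, list(.make_equilibrium(rp, Pstar,
                                       medusa_nullcline(rp, Pstar),
                                       "COEXISTENCE")))
  }
  eq
}

#' Closed-form coexistence equilibrium when planula recruitment is absent
#'
#' With `b = 0` (no planula survival or no sexual reproduction) and
#' `ad + bc > 0`, `c != 0`, the coexistence equilibrium is
#' \eqn{P^* = a/b_1} and
#' \eqn{M^* = (-b_1 d + \sqrt{b_1^2 d^2 + 4 a c b_1 b_2})/(2 b_1 b_2)}.
#'
#' @param rp a [reduced_params()] object with `b == 0` and `a > 0`.
#' @return Named numeric `c(P, M)`.
#' @export
coexistence_closed_form <- function(rp) {
  validate_reduced_params(rp)
  if (rp$b != 0) stop("closed form requires b = 0", call. = FALSE)
  if (rp$a <= 0 || rp$c <= 0) {
    stop("closed form requires a > 0 and c > 0", call. = FALSE)
  }
  c(P = rp$a / rp$b1,
    M = (-rp$b1 * rp$d +
           sqrt(rp$b1^2 * rp$d^2 + 4 * rp$a * rp$c * rp$b1 * rp$b2)) /
      (2 * rp$b1 * rp$b2))
}

#' Classify the global dynamical regime
#'
#' The planar system admits a global trichotomy governed by the sign of
#' the discriminant `ad + bc` and whether ephyra recruitment `c`
#' vanishes:
#' \describe{
#'   \item{GLOBAL_EXTINCTION}{`ad + bc < 0`: extinction is globally
#'     asymptotically stable; no other equilibria exist.}
#'   \item{SADDLE_NODE_THRESHOLD}{`ad + bc = 0`: degenerate saddle-node
#'     transition at the origin; no attractor is designated.}
#'   \item{POLYP_ONLY_GAS}{`ad + bc > 0`, `c = 0`: the polyp-only state
#'     `(a/b1, 0)` is globally asymptotically stable.}
#'   \item{COEXISTENCE_GAS}{`ad + bc > 0`, `c != 0`: the coexistence
#'     state is globally asymptotically stable.}
#' }
#'
#' @param rp a [reduced_params()] object.
#' @param equality_tol absolute tolerance for `|ad + bc| = 0` (the
#'   threshold regime is measure-zero and only reachable by
#'   construction).
#' @return A `scypho_regime` object with fields `regime`,
#'   `discriminant`, and `attractor` (a `scypho_equilibrium`, or `NULL`
#'   at the degenerate threshold).
#' @export
#' @examples
#' classify_regime(reduce_params(scypho_preset("V1")))
classify_regime <- function(rp, equality_tol = 1e-12) {
  validate_reduced_params(rp)
  disc <- rp$a * rp$d + rp$b * rp$c
  c_zero <- abs(rp$c) <= equality_tol
  eq <- find_equilibria(rp, equality_tol = equality_tol)
  labels <- vapply(eq, `[[`, "", "label")
  if (abs(disc) <= equality_tol) {
    regime <- "SADDLE_NODE_THRESHOLD"
    attractor <- NULL
  } else if (disc < 0) {
    regime <- "GLOBAL_EXTINCTION"
    attractor <- eq[[which(labels == "EXTINCTION")]]
  } else if (c_zero) {
    regime <- "POLYP_ONLY_GAS"
    attractor <- eq[[which(labels == "POLYP_ONLY")]]
  } else {
    regime <- "COEXISTENCE_GAS"
    attractor <- eq[[which(labels == "COEXISTENCE")]]
  }
  structure(list(regime = regime, discriminant = disc,
                 attractor = attractor, equilibria = eq),
            class = "scypho_regime")
}

#' @export
print.scypho_regime <- function(x, ...) {
  cat(sprintf("Global regime: %s (ad + bc = %g)\n",
              x$regime, x$discriminant))
  if (!is.null(x$attractor)) {
    cat("  globally stable attractor: ")
    print(x$attractor)
  } else {
    cat("  degenerate saddle-node threshold; no attractor designation\n")
  }
  invisible(x)
}

#' Numerical check of the heteroclinic connection from extinction
#'
#' In the polyp-only and coexistence regimes the extinction state is a
#' saddle whose unstable manifold connects to the global attractor.
#' This check displaces the origin along the unstable eigenvector by a
#' small perturbation, simulates forward, and reports whether the
#' trajectory reaches the designated attractor (final distance below 1%
#' of the attractor norm).
#'
#' @param rp a [reduced_params()] object in regime `POLYP_ONLY_GAS` or
#'   `COEXISTENCE_GAS`.
#' @param perturbation displacement along the unstable eigenvector.
#' @param t_end integration horizon (days).
#' @return A list with `converged` (logical), `attractor` (named
#'   location), `final_state`, `distance`, and the trajectory.
#' @export
heteroclinic_check <- function(rp, perturbation = 1e-3, t_end = 3000) {
  reg <- classify_regime(rp)
  if (!reg$regime %in% c("POLYP_ONLY_GAS", "COEXISTENCE_GAS")) {
    stop("heteroclinic check requires a regime with a nontrivial ",
         "attractor, got ", reg$regime, call. = FALSE)
  }
  j <- jacobian_at(rp, 0, 0)
  ev <- j$eigenvalues
  lam <- Re(ev[1])  # sorted by decreasing real part; saddle => ev[1] > 0
  J <- j$matrix
  # unstable eigenvector of [[a, b], [c, -d]] for eigenvalue lam
  v <- if (abs(J[1, 2]) > .Machine$double.eps) {
    c(J[1, 2], lam - J[1, 1])
  } else {
    c(lam + J[2, 2], J[2, 1])
  }
  v <- abs(v) / sqrt(sum(v^2))  # unstable direction points into quadrant
  init <- perturbation * v
  tr <- simulate_dynamics(rp, init = init, t_end = t_end)
  target <- reg$attractor$location
  fin <- c(tr$P[nrow(tr)], tr$M[nrow(tr)])
  dist <- sqrt(sum((fin - target)^2))
  list(converged = dist < 0.01 * sqrt(sum(target^2)),
       attractor = target, final_state = c(P = fin[1], M = fin[2]),
       distance = dist, trajectory = tr)
}

#' Export equilibria as CSV
#'
#' Writes one row per equilibrium with header
#' `label,P,M,eig_re1,eig_im1,eig_re2,eig_im2,stability`.
#'
#' @param eq a list of equilibria from [find_equilibria()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_equilibria <- function(eq, file) {
  df <- do.call(rbind, lapply(eq, function(e) {
    data.frame(label = e$label,
               P = e$location[["P"]], M = e$location[["M"]],
               eig_re1 = Re(e$eigenvalues[1]),
               eig_im1 = Im(e$eigenvalues[1]),
               eig_re2 = Re(e$eigenvalues[2]),
               eig_im2 = Im(e$eigenvalues[2]),
               stability = e$local_stability)
  }))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
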