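#' Constants of the closed-form mean cross-link count
#'
#' The expected cross-link count is \eqn{C(t) = k_2 \int_0^t x_3(s) ds},
#' where `x3` solves the dimeric binding/cross-linking ODEs linearized by
#' holding the free-ligand pool at its initial value (the ligand is in
#' large excess over the complexes formed before a response). Eliminating
#' `x1` through receptor conservation leaves a two-variable linear system
#' for `(x3, x5)` whose relaxation rates `lambda1 > lambda2` (both
#' negative) are the roots of
#' \deqn{\lambda^2 + (4 k_{on}\rho + k_{off} + k_2 + 2k_{-2})\lambda +
#'       (4 k_{on}\rho k_2 + 2 k_{off} k_{-2} + 8 k_{on}\rho k_{-2}) = 0.}
#' The steady states are `a1` (singly bound) and `a2 = k2 a1 / (2 k_minus2)`
#' (cross-linked):
#' \deqn{a_1 = \frac{8 k_{-2} k_{on} \rho N_B}{4 k_{on}\rho k_2 +
#'       2 k_{off} k_{-2} + 8 k_{on}\rho k_{-2}}.}
#' The amplitudes `c1`, `c2` are fixed by the empty initial condition
#' `x3(0) = x5(0) = 0`:
#' \deqn{c_{1} = \frac{-4 \lambda_2 k_{on}\rho N_B (\lambda_1+2k_{-2})^2}
#'      {(\lambda_2-\lambda_1) \lambda_1 \lambda_2}}
#' and `c2` with indices swapped (and opposite sign), so that
#' \eqn{x_3(t) = a_1 + \frac{c_1}{\lambda_1 + 2k_{-2}} e^{\lambda_1 t}
#'       + \frac{c_2}{\lambda_2 + 2k_{-2}} e^{\lambda_2 t}.}
#'
#' As the concentration vanishes, `a1 -> 4 k_on rho N_B / k_off`, which
#' underpins the low-concentration MTSI branch.
#'
#' @param params A [kinetic_parameters()] object with `rho > 0`.
#' @return Object of class `ct_constants`: list with `c1`, `c2`, `lambda1`,
#'   `lambda2`, `a1`, `a2`, plus `k2` and `k_minus2` carried along for
#'   [c_of_t()].
#' @export
#' @examples
#' ct_constants(kinetic_parameters("4P", rho = 1e-9, b = 0.32))$a1
ct_constants <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (params$rho < 0) stop("'rho' must be >= 0")
  kon <- params$ligand$k_on; koff <- params$ligand$k_off
  k2 <- params$k2; km2 <- params$k_minus2
  rho <- params$rho; NB <- params$n_dimers
  alpha <- 4 * kon * rho
  D <- alpha * k2 + 2 * koff * km2 + 2 * alpha * km2
  s <- alpha + koff + k2 + 2 * km2
  disc <- (alpha + koff - k2 - 2 * km2)^2 + 4 * koff * k2
  l1 <- (-s + sqrt(disc)) / 2
  l2 <- (-s - sqrt(disc)) / 2
  if (l1 == l2)
    stop("degenerate relaxation rates (lambda1 == lambda2); use the ODE path")
  a1 <- 2 * km2 * alpha * NB / D
  a2 <- k2 * alpha * NB / D
  b1 <- l1 + 2 * km2
  b2 <- l2 + 2 * km2
  c1 <- -4 * l2 * kon * rho * NB * b1^2 / ((l2 - l1) * D)
  c2 <-  4 * l1 * kon * rho * NB * b2^2 / ((l2 - l1) * D)
  structure(list(c1 = c1, c2 = c2, lambda1 = l1, lambda2 = l2,
                 a1 = a1, a2 = a2, k2 = k2, k_minus2 = km2),
            class = "ct_constants")
}

#' Analytic mean number of cross-linking events up to time t
#'
#' \deqn{C(t) = k_2 \left[ \frac{c_1}{\lambda_1(\lambda_1+2k_{-2})}
#'   (e^{\lambda_1 t}-1) + \frac{c_2}{\lambda_2(\lambda_2+2k_{-2})}
#'   (e^{\lambda_2 t}-1) + a_1 t \right].}
#' `C` is nonnegative, nondecreasing and convex-then-linear: quadratic
#' (`C ~ 2 k_on rho N_B k_2 t^2`) at short times and linear with slope
#' `k2 * a1` at long times. The `k2` factor multiplies the whole bracket,
#' including `a1 * t` — forced by the low-concentration limit
#' `C(t) ~ k2 a1 t`.
#'
#' @param constants A [ct_constants()] object.
#' @param t Times (s), `>= 0`; vectorized.
#' @param k2,k_minus2 Optional overrides of the rates stored in
#'   `constants`.
#' @return Expected cross-link event count at each `t`.
#' @export
c_of_t <- function(constants, t, k2 = constants$k2,
                   k_minus2 = constants$k_minus2) {
  stopifnot(inherits(constants, "ct_constants"))
  if (any(t < 0)) stop("'t' must be >= 0")
  l1 <- constants$lambda1; l2 <- constants$lambda2
  k2 * (constants$c1 / (l1 * (l1 + 2 * k_minus2)) * (exp(l1 * t) - 1) +
        constants$c2 / (l2 * (l2 + 2 * k_minus2)) * (exp(l2 * t) - 1) +
        constants$a1 * t)
}

#' Analytic MTSI from the cross-link count root equation
#'
#' The response fires when `N` cross-link episodes have each survived the
#' dwell time `tau`. Each episode survives with probability
#' `exp(-2 k_minus2 tau)`, so on average `N' = N exp(2 k_minus2 tau)` raw
#' cross-linking events are needed, and the mean time to signal initiation
#' solves
#' \deqn{C(T - \tau) = N e^{2 k_{-2} \tau}.}
#' Since `C` grows without bound with slope `k2 a1 > 0` (for `rho > 0`),
#' the root exists and is found by geometric bracket growth from the
#' low-concentration estimate followed by monotone root refinement.
#'
#' @param params A [kinetic_parameters()] object with `rho > 0`.
#' @param criterion A [response_criterion()].
#' @param rel_tol Relative tolerance of the root (default 1e-10).
#' @return The time `T >= tau` in seconds. If the event target
#'   `N exp(2 k_minus2 tau)` overflows double precision, returns `Inf`
#'   with attribute `log_target = log(N) + 2 k_minus2 tau`.
#' @export
#' @examples
#' p <- kinetic_parameters("4P", rho = 1e-9, b = 0.32)
#' solve_mtsi(p, response_criterion(10, 1))
solve_mtsi <- function(params, criterion, rel_tol = 1e-10) {
  stopifnot(inherits(criterion, "response_criterion"))
  N <- criterion$n_events; tau <- criterion$tau
  if (N == 0) return(0)
  if (params$rho <= 0) stop("'rho' must be > 0 for a reachable criterion")
  log_target <- log(N) + 2 * params$k_minus2 * tau
  if (log_target > 700) {
    out <- Inf
    attr(out, "log_target") <- log_target
    return(out)
  }
  target <- exp(log_target)
  cc <- ct_constants(params)
  f <- function(s) c_of_t(cc, s) - target
  s0 <- max(target / (cc$k2 * cc$a1), .Machine$double.eps)
  s_hi <- s0
  while (f(s_hi) < 0) s_hi <- s_hi * 2
  root <- uniroot(f, lower = 0, upper = s_hi, tol = max(rel_tol * s_hi, 1e-14))$root
  tau + root
}

#' Asymptotic MTSI in the three concentration regimes
#'
#' Closed-form limits of the MTSI root equation:
#' \describe{
#'   \item{high}{`T = tau`: ligand is in such excess that the N-th
#'     signaling unit forms essentially immediately.}
#'   \item{intermediate}{`T = tau + sqrt(N exp(2 k_minus2 tau) /
#'     (2 rho N_B k_on k2))`: the quadratic short-time growth of the
#'     cross-link count dominates.}
#'   \item{low}{`T = tau + N exp(2 k_minus2 tau) /
#'     (4 rho N_B k_on k2 / k_minus2)`: binding is limiting and the
#'     cross-link count grows linearly.}
#' }
#' No automatic regime classification is attempted (the regime boundaries
#' are not sharply defined); callers pick a branch, and
#' [regime_relative_errors()] reports how far each branch is from the full
#' root.
#'
#' @inheritParams solve_mtsi
#' @param regime One of `"high"`, `"intermediate"`, `"low"`.
#' @return Time `T` in seconds.
#' @export
#' @examples
#' p <- kinetic_parameters("4P", rho = 1e-12, b = 0.32)
#' asymptotic_mtsi(p, response_criterion(10, 1), "low")  # ~ 176 s
asymptotic_mtsi <- function(params, criterion,
                            regime = c("high", "intermediate", "low")) {
  regime <- match.arg(regime)
  N <- criterion$n_events; tau <- criterion$tau
  if (regime == "high") return(tau)
  kon <- params$ligand$k_on
  NB <- params$n_dimers; rho <- params$rho
  nprime_val <- N * exp(2 * params$k_minus2 * tau)
  if (regime == "intermediate") {
    tau + sqrt(nprime_val / (2 * rho * NB * kon * params$k2))
  } else {
    tau + nprime_val / (4 * rho * NB * kon * (params$k2 / params$k_minus2))
  }
}

#' Relative error of each asymptotic branch against the full root
#'
#' @inheritParams solve_mtsi
#' @return Named numeric vector of `(T_branch - T_root) / T_root` for the
#'   three regimes.
#' @export
regime_relative_errors <- function(params, criterion) {
  T_root <- solve_mtsi(params, criterion)
  branches <- vapply(c("high", "intermediate", "low"), function(r)
    asymptotic_mtsi(params, criterion, r), numeric(1))
  (branches - T_root) / T_root
}

#' Expected number of raw cross-linking events for a response
#'
#' `N' = N exp(2 k_minus2 tau)`: each cross-link episode survives to the
#' dwell time with probability `exp(-2 k_minus2 tau)`, so `N'` raw events
#' are needed on average for `N` survivors.
#'
#' @param criterion A [response_criterion()].
#' @param k_minus2 Reverse cross-linking rate (s^-1).
#' @param log Return the natural logarithm of `N'` instead? Useful for
#'   antagonist ligands, where the exponent reaches hundreds.
#' @return `N'` (or `log(N')`). When the exponent exceeds 700 and
#'   `log = FALSE`, returns `Inf` with attribute `log_nprime`.
#' @export
#' @examples
#' nprime(response_criterion(10, 4), 8.6643)            # ~ 1e31
#' nprime(response_criterion(10, 8), 8.6643, log = TRUE)  # ~ 140.9
nprime <- function(criterion, k_minus2, log = FALSE) {
  stopifnot(inherits(criterion, "response_criterion"), k_minus2 >= 0)
  lg <- log(criterion$n_events) + 2 * k_minus2 * criterion$tau
  if (log) return(lg)
  if (lg > 700) {
    out <- Inf
    attr(out, "log_nprime") <- lg
    return(out)
  }
  criterion$n_events * exp(2 * k_minus2 * criterion$tau)
}

#' Dimer-to-trimer correction pre-factor
#'
#' Aggregating dimeric and trimeric clusters into common signaling-unit
#' dynamics multiplies the cross-linking drive by `(1 + 2b) / (1 + b)`,
#' which increases strictly from 1 (as `b -> 0`) to 3/2 (as `b -> 1`). The
#' mixed-size system therefore behaves like the dimeric one up to at most
#' a 50% rate correction.
#'
#' @param b Clustering parameter in `(0, 1)`; vectorized.
#' @return `(1 + 2 * b) / (1 + b)`.
#' @export
trimer_prefactor <- function(b) {
  if (any(b <= 0) || any(b >= 1)) stop("'b' must be in (0, 1)")
  (1 + 2 * b) / (1 + b)
}
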