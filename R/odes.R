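#' Deterministic dimer/trimer binding and cross-linking ODEs
#'
#' Mean-field rate equations for a cell carrying both dimeric and trimeric
#' TCR clusters exposed to a bivalent ligand, in the low-concentration
#' truncation (multi-ligand species on the same cluster are neglected):
#' \deqn{\dot x_1 = -4k_+ x_1 x_2 + k_{off} x_3}
#' \deqn{\dot x_3 = 4k_+ x_1 x_2 - k_{off} x_3 - k_2 x_3 + 2k_{-2} x_5}
#' \deqn{\dot x_5 = k_2 x_3 - 2k_{-2} x_5}
#' \deqn{\dot y_1 = -6k_+ y_1 x_2 + k_{off} y_3}
#' \deqn{\dot y_3 = 6k_+ y_1 x_2 - k_{off} y_3 - 2k_2 y_3 + 2k_{-2} y_5}
#' \deqn{\dot y_5 = 2k_2 y_3 - 2k_{-2} y_5}
#' The `y2` ligand variable of the trimeric block is the same physical
#' free-ligand pool as `x2`, so a single ligand equation collects both
#' sinks: \eqn{\dot x_2 = -4k_+x_1x_2 - 6k_+y_1x_2 + k_{off}(x_3 + y_3)}.
#' The statistical factors count binding configurations: a dimer offers
#' 2 receptors x 2 ligand arms = 4, a trimer 3 x 2 = 6; a ligand singly
#' bound to a trimer has (on average over end/middle positions counted as
#' the two available neighbor pairs) 2 cross-linking targets, and every
#' cross-linked ligand opens either bond at rate `k_minus2`.
#'
#' @param params A [kinetic_parameters()] object (sets the dimer count,
#'   rates and ligand pool).
#' @param trimer_count Initial number of free trimeric clusters. Default
#'   `round(b * n_dimers)`, the stationary-law ratio of trimers to dimers.
#' @param times Increasing time grid (s) starting at 0.
#' @param ... Passed to [deSolve::ode()].
#'
#' @return A data.frame with columns `time`, `x1`, `x2`, `x3`, `x5`, `y1`,
#'   `y3`, `y5` and the aggregates `S3 = x3 + y3`, `S5 = x5 + y5`.
#' @export
#' @examples
#' p <- kinetic_parameters("4P", rho = 1e-12, b = 0.32)
#' tr <- integrate_dimer_trimer_odes(p, times = seq(0, 100, 1))
#' tail(tr$S5, 1)
integrate_dimer_trimer_odes <- function(params,
                                        trimer_count = round(params$b *
                                                             params$n_dimers),
                                        times, ...) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (trimer_count < 0) stop("'trimer_count' must be >= 0")
  kp <- params$k_plus; koff <- params$ligand$k_off
  k2 <- params$k2; km2 <- params$k_minus2
  y0 <- c(x1 = params$n_dimers, x2 = params$ligand_copies, x3 = 0, x5 = 0,
          y1 = trimer_count, y3 = 0, y5 = 0)
  rhs <- function(t, y, p) {
    bd <- 4 * kp * y["x1"] * y["x2"]
    bt <- 6 * kp * y["y1"] * y["x2"]
    list(c(
      x1 = -bd + koff * y["x3"],
      x2 = -bd - bt + koff * (y["x3"] + y["y3"]),
      x3 =  bd - koff * y["x3"] - k2 * y["x3"] + 2 * km2 * y["x5"],
      x5 =  k2 * y["x3"] - 2 * km2 * y["x5"],
      y1 = -bt + koff * y["y3"],
      y3 =  bt - koff * y["y3"] - 2 * k2 * y["y3"] + 2 * km2 * y["y5"],
      y5 =  2 * k2 * y["y3"] - 2 * km2 * y["y5"]
    ))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12, ...)
  df <- as.data.frame(sol)
  if (any(df[, -1] < -1e-6 * max(abs(df[, -1]))))
    stop("integrator produced negative trajectory values beyond tolerance")
  df$S3 <- df$x3 + df$y3
  df$S5 <- df$x5 + df$y5
  df
}

#' Reduced signaling-unit equation driven by an aggregate trajectory
#'
#' Integrates the single reduced equation
#' \deqn{\dot S_5 = k_2 \frac{1+2b}{1+b} S_3(t) - 2 k_{-2} S_5}
#' with `S3(t)` supplied (typically from the full dimer/trimer system), to
#' quantify how well the mixed-size dynamics collapse onto the dimeric
#' form with the [trimer_prefactor()] correction.
#'
#' @param params A [kinetic_parameters()] object.
#' @param times Time grid on which `S3` is tabulated.
#' @param S3 Aggregate singly bound trajectory on `times`.
#' @return Numeric vector `S5(t)` on `times`, starting at 0.
#' @export
reduced_s5 <- function(params, times, S3) {
  stopifnot(length(times) == length(S3))
  S3_fun <- approxfun(times, S3, rule = 2)
  pref <- trimer_prefactor(params$b)
  rhs <- function(t, y, p)
    list(params$k2 * pref * S3_fun(t) - 2 * params$k_minus2 * y[1])
  sol <- deSolve::ode(y = c(S5 = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(sol[, 2])
}
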