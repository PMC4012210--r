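#' Initial state of the stochastic cross-linking model
#'
#' All dimeric clusters free, all ligand in solution:
#' `x1 = n_dimers`, `x2 = round(rho * volume * avogadro)`,
#' `x3 = x4 = x5 = 0` at time 0.
#'
#' @param params A [kinetic_parameters()] object.
#' @return Named list with integer counts `x1, x2, x3, x4, x5`, `time = 0`,
#'   an empty `crosslink_ages` vector and `completed_events = 0`.
#' @export
#' @examples
#' initial_state(kinetic_parameters("4P", rho = 1e-9, b = 0.32))$x2
initial_state <- function(params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (params$ligand_copies < 1L) {
    stop(sprintf(
      "ligand copy number rounds to 0 at rho = %.3g M; need rho >= %.3g M",
      params$rho, 0.5 / (params$volume * params$avogadro)))
  }
  list(x1 = params$n_dimers, x2 = params$ligand_copies,
       x3 = 0L, x4 = 0L, x5 = 0L, time = 0,
       crosslink_ages = numeric(0), completed_events = 0L)
}

#' Reaction propensities of the cross-linking network
#'
#' The six channels of the bivalent-ligand / dimeric-receptor network with
#' their combinatorial statistical factors: binding carries a factor 4
#' (two receptors in the cluster times two ligand arms), the reverse
#' cross-link a factor 2 (either bond of the doubly engaged ligand can
#' open), and the optional second-ligand unbinding a factor 2 (either
#' singly bound ligand can leave).
#'
#' @param state A state as returned by [initial_state()] or [ssa_step()].
#' @param params A [kinetic_parameters()] object.
#' @return Named numeric vector of propensities (s^-1): `bind`, `unbind`,
#'   `crosslink`, `reverse`, `bind2`, `unbind2`.
#' @export
ssa_propensities <- function(state, params) {
  dbl <- params$allow_double_binding
  c(bind      = 4 * params$k_plus * state$x1 * state$x2,
    unbind    = params$ligand$k_off * state$x3,
    crosslink = params$k2 * state$x3,
    reverse   = 2 * params$k_minus2 * state$x5,
    bind2     = if (dbl) params$k_plus * state$x3 * state$x2 else 0,
    unbind2   = if (dbl) 2 * params$ligand$k_off * state$x4 else 0)
}

#' One exact SSA event (reference implementation)
#'
#' Advances the state by a single Gillespie event: an exponential waiting
#' time at the total propensity, then one reaction chosen proportionally to
#' its propensity. Cross-link formation appends the current time to
#' `crosslink_ages`; a reverse cross-link removes one entry uniformly at
#' random. This R-level stepper is the readable reference for the compiled
#' trajectory loop used by [simulate_mtsi()]; it does not process
#' dwell-completion events (see `simulate_mtsi` for the full criterion).
#'
#' @inheritParams ssa_propensities
#' @return The updated state; if every propensity is zero the state is
#'   returned unchanged with attribute `absorbing = TRUE`.
#' @export
ssa_step <- function(state, params) {
  a <- ssa_propensities(state, params)
  total <- sum(a)
  if (total <= 0) {
    attr(state, "absorbing") <- TRUE
    return(state)
  }
  state$time <- state$time + rexp(1, total)
  channel <- sample(names(a), 1, prob = a / total)
  switch(channel,
    bind = {
      state$x1 <- state$x1 - 1L; state$x2 <- state$x2 - 1L
      state$x3 <- state$x3 + 1L
    },
    unbind = {
      state$x1 <- state$x1 + 1L; state$x2 <- state$x2 + 1L
      state$x3 <- state$x3 - 1L
    },
    crosslink = {
      state$x3 <- state$x3 - 1L; state$x5 <- state$x5 + 1L
      state$crosslink_ages <- c(state$crosslink_ages, state$time)
    },
    reverse = {
      state$x3 <- state$x3 + 1L; state$x5 <- state$x5 - 1L
      drop <- sample.int(length(state$crosslink_ages), 1)
      state$crosslink_ages <- state$crosslink_ages[-drop]
    },
    bind2 = {
      state$x3 <- state$x3 - 1L; state$x2 <- state$x2 - 1L
      state$x4 <- state$x4 + 1L
    },
    unbind2 = {
      state$x4 <- state$x4 - 1L; state$x3 <- state$x3 + 1L
      state$x2 <- state$x2 + 1L
    })
  state
}

# Deterministic per-realization substream seed, kept within 32-bit range.
realization_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * i) %% 2147483647)
}

#' Simulate the mean time to signal initiation (MTSI)
#'
#' Runs the exact stochastic simulation of ligand binding and cross-linking
#' for `n_realizations` independent realizations. In each, every
#' cross-link episode whose age reaches the dwell time `tau` counts once
#' toward the response; the first-passage time `T` is recorded at the
#' instant the `n_events`-th episode's age reaches `tau`. Complexes remain
#' in the kinetics after counting (no internalization); an episode that
#' reverses and re-forms starts a fresh episode that may count again.
#'
#' Realizations that reach `horizon` without responding are censored and
#' excluded from the mean and SD (with a warning).
#'
#' @param params A [kinetic_parameters()] object.
#' @param criterion A [response_criterion()].
#' @param n_realizations Number of independent realizations (>= 1).
#' @param horizon Maximum simulated time per realization (s), `> tau`.
#' @param seed Integer seed; realization `i` runs on a substream derived
#'   deterministically from `(seed, i)`, so results are reproducible and
#'   independent of `n_realizations` ordering.
#' @param record_trajectory Keep the full event-by-event state sequence of
#'   each realization (memory heavy; for diagnostics and invariant checks).
#'
#' @return Object of class `mtsi_result`: list with `times` (per
#'   realization; `NA` when censored), `censored` (logical), `mean_t`,
#'   `sd_t`, `se_t`, `n_realizations`, `censored_count`, `seed`, `params`,
#'   `criterion` and (optionally) `trajectories`.
#' @export
#' @examples
#' p <- kinetic_parameters("4P", rho = 1e-9, b = 0.32)
#' r <- simulate_mtsi(p, response_criterion(10, 1), n_realizations = 5,
#'                    horizon = 1e4, seed = 1)
#' r$mean_t
simulate_mtsi <- function(params, criterion, n_realizations = 100L,
                          horizon = 1e6, seed = 1L,
                          record_trajectory = FALSE) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(criterion, "response_criterion"),
            n_realizations >= 1)
  if (horizon <= criterion$tau && criterion$n_events > 0)
    stop("'horizon' must exceed the dwell time tau")
  st0 <- initial_state(params)  # validates ligand copy number
  times <- numeric(n_realizations)
  censored <- logical(n_realizations)
  trajectories <- if (record_trajectory) vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    set.seed(realization_seed(seed, i))
    out <- ssa_mtsi_realization(
      k_plus = params$k_plus, k_off = params$ligand$k_off, k2 = params$k2,
      k_minus2 = params$k_minus2, n_dimers = st0$x1, n_ligand = st0$x2,
      allow_double = params$allow_double_binding,
      n_events = criterion$n_events, tau = criterion$tau, horizon = horizon,
      record_trajectory = record_trajectory)
    times[i] <- if (out$censored) NA_real_ else out$T
    censored[i] <- out$censored
    if (record_trajectory) trajectories[[i]] <- out$trajectory
  }
  nc <- sum(censored)
  if (nc > 0)
    warning(sprintf("%d of %d realizations censored at horizon %g s; excluded from mean",
                    nc, n_realizations, horizon))
  ok <- times[!censored]
  structure(
    list(times = times, censored = censored,
         mean_t = if (length(ok)) mean(ok) else NA_real_,
         sd_t = if (length(ok) > 1) sd(ok) else NA_real_,
         se_t = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else NA_real_,
         n_realizations = n_realizations, censored_count = nc,
         seed = seed, params = params, criterion = criterion,
         trajectories = trajectories),
    class = "mtsi_result"
  )
}

#' @export
print.mtsi_result <- function(x, ...) {
  cat(sprintf("mtsi_result: mean T = %.4g s (sd %.4g, se %.4g) over %d realizations (%d censored)\n",
              x$mean_t, x$sd_t, x$se_t, x$n_realizations, x$censored_count))
  invisible(x)
}

#' @export
as.data.frame.mtsi_result <- function(x, ...) {
  data.frame(realization = seq_along(x$times),
             seed = vapply(seq_along(x$times), function(i)
               realization_seed(x$seed, i), integer(1)),
             T = x$times, censored = x$censored)
}

#' Fraction of cross-link episodes surviving the dwell time
#'
#' Each cross-linked complex reverts after an exponential lifetime with
#' rate `2 * k_minus2`; the probability that an episode persists at least
#' `tau` is `exp(-2 * k_minus2 * tau)`, the thinning factor that relates
#' the raw cross-link count to productive signaling events. This Monte
#' Carlo estimate is the simulation-side check of that factor.
#'
#' @param params A [kinetic_parameters()] object (only `k_minus2` is used).
#' @param tau Dwell time (s).
#' @param n_episodes Number of simulated episodes (>= 100).
#' @param seed Integer seed.
#' @return Fraction in `[0, 1]`.
#' @export
episode_survival_fraction <- function(params, tau, n_episodes = 1e5,
                                      seed = 1L) {
  stopifnot(n_episodes >= 100)
  if (tau == 0) return(1.0)
  set.seed(seed)
  mean(rexp(n_episodes, rate = 2 * params$k_minus2) >= tau)
}
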