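test_that("initial state carries the derived copy numbers", {
  p <- params_4p(rho = 1e-9, b = 0.32)
  st <- initial_state(p)
  # rho * V_C * N_A with V_C = 50 uL / 1e5 cells = 0.5 nL
  expect_equal(st$x2, round(1e-9 * 5e-10 * 6.023e23))
  expect_equal(st$x1, 9600)  # N_B = b * N_R = 0.32 * 30000
  expect_equal(st$x3 + st$x4 + st$x5, 0)
  expect_error(kinetic_parameters("4P", rho = -1, b = 0.32), "rho")
  expect_error(initial_state(kinetic_parameters("4P", rho = 1e-18, b = 0.32)),
               "rounds to 0")
})

test_that("propensities carry the bivalent/dimeric statistical factors", {
  p <- params_4p()
  st <- initial_state(p)
  a <- ssa_propensities(st, p)
  # fresh state: only the binding channel can fire
  expect_true(a["bind"] > 0)
  expect_true(all(a[c("unbind", "crosslink", "reverse", "bind2", "unbind2")] == 0))

  st$x1 <- 1L; st$x2 <- 1L
  expect_equal(unname(ssa_propensities(st, p)["bind"]), 4 * p$k_plus)

  st$x5 <- 5L
  expect_equal(unname(ssa_propensities(st, p)["reverse"]), 10 * p$k_minus2)

  st$x3 <- 3L
  expect_equal(unname(ssa_propensities(st, p)["crosslink"]), 3 * p$k2)
  expect_equal(unname(ssa_propensities(st, p)["unbind"]), 3 * p$ligand$k_off)

  # optional second-ligand channel
  p2 <- params_4p(allow_double_binding = TRUE)
  st$x2 <- 10L; st$x4 <- 2L
  a2 <- ssa_propensities(st, p2)
  expect_equal(unname(a2["bind2"]), p2$k_plus * 3 * 10)
  expect_equal(unname(a2["unbind2"]), 2 * p2$ligand$k_off * 2)
})

test_that("the reference stepper conserves receptors and ligand", {
  p <- params_4p(rho = 1e-9)
  set.seed(99)
  st <- initial_state(p)
  nd <- st$x1; nl <- st$x2
  for (i in 1:400) {
    st <- ssa_step(st, p)
    expect_identical(st$x1 + st$x3 + st$x4 + st$x5, nd)
    expect_identical(st$x2 + st$x3 + 2L * st$x4 + st$x5, nl)
    expect_identical(length(st$crosslink_ages), as.integer(st$x5))
  }
  expect_true(all(c(st$x1, st$x2, st$x3, st$x4, st$x5) >= 0))
})

test_that("a trivial criterion responds immediately and censoring is flagged", {
  p <- params_4p(rho = 1e-9)
  r0 <- simulate_mtsi(p, response_criterion(0, 1), n_realizations = 5,
                      horizon = 10, seed = 1)
  expect_equal(r0$times, rep(0, 5))

  # antagonist at short horizon: all realizations censored
  pn <- kinetic_parameters("4N", rho = 1e-12, b = 0.32)
  expect_warning(
    rn <- simulate_mtsi(pn, response_criterion(10, 1), n_realizations = 3,
                        horizon = 50, seed = 1),
    "censored")
  expect_equal(rn$censored_count, 3)
  expect_true(is.na(rn$mean_t))
})

test_that("simulation is reproducible under seed and realization order", {
  p <- params_4p(rho = 1e-9)
  crit <- response_criterion(5, 1)
  r1 <- simulate_mtsi(p, crit, n_realizations = 8, horizon = 1e4, seed = 42)
  r2 <- simulate_mtsi(p, crit, n_realizations = 8, horizon = 1e4, seed = 42)
  expect_identical(r1$times, r2$times)
  # first realizations unchanged when more are appended (substreams)
  r3 <- simulate_mtsi(p, crit, n_realizations = 12, horizon = 1e4, seed = 42)
  expect_identical(r3$times[1:8], r1$times)
  expect_identical(as.data.frame(r1)$T, r1$times)
})

test_that("cross-link episode lifetimes are exponential with rate 2 k_minus2", {
  # population-level uniform removal must reproduce per-complex
  # exponential clocks; checked against the closed-form law by a
  # Kolmogorov-Smirnov test on >= 1e4 completed episodes
  p <- kinetic_parameters("4A", rho = 1e-8, b = 0.32)
  st <- initial_state(p)
  set.seed(1234)
  out <- tcrclust:::ssa_mtsi_realization(
    k_plus = p$k_plus, k_off = p$ligand$k_off, k2 = p$k2,
    k_minus2 = p$k_minus2, n_dimers = st$x1, n_ligand = st$x2,
    allow_double = FALSE, n_events = .Machine$integer.max, tau = 1,
    horizon = 400, record_episodes = TRUE)
  lens <- out$episode_lengths
  expect_gte(length(lens), 1e4)
  ks <- suppressWarnings(stats::ks.test(lens, "pexp", rate = 2 * p$k_minus2))
  expect_gt(ks$p.value, 0.01)
})

test_that("episode survival fraction matches the exponential thinning factor", {
  p <- params_4p()
  expect_equal(episode_survival_fraction(p, 0), 1.0)
  f <- episode_survival_fraction(p, tau = 1, n_episodes = 1e5, seed = 8)
  expect_equal(f, exp(-2 * 0.0169), tolerance = 0.005)
  pa <- kinetic_parameters("4A", rho = 1e-9, b = 0.32)
  f4 <- episode_survival_fraction(pa, tau = 4, n_episodes = 1e5, seed = 8)
  p_true <- exp(-2 * 0.8664 * 4)
  expect_lt(abs(f4 - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("ensemble-averaged SSA trajectories track the mean-field ODEs", {
  p <- params_4p(rho = 1e-9, b = 0.32)
  probe_times <- c(10, 25, 50)
  n_traj <- 200
  x3m <- matrix(NA_real_, n_traj, length(probe_times))
  x5m <- matrix(NA_real_, n_traj, length(probe_times))
  r <- suppressWarnings(
    simulate_mtsi(p, response_criterion(.Machine$integer.max, 1),
                  n_realizations = n_traj, horizon = max(probe_times),
                  seed = 21, record_trajectory = TRUE))
  for (i in seq_len(n_traj)) {
    tr <- r$trajectories[[i]]
    idx <- findInterval(probe_times, tr[, "time"])
    x3m[i, ] <- tr[idx, "x3"]
    x5m[i, ] <- tr[idx, "x5"]
  }
  ode <- integrate_dimer_trimer_odes(p, trimer_count = 0,
                                     times = c(0, probe_times))
  for (j in seq_along(probe_times)) {
    se3 <- sd(x3m[, j]) / sqrt(n_traj)
    se5 <- sd(x5m[, j]) / sqrt(n_traj)
    expect_lt(abs(mean(x3m[, j]) - ode$x3[j + 1]), 3.5 * se3)
    expect_lt(abs(mean(x5m[, j]) - ode$x5[j + 1]), 3.5 * se5 + 0.05)
  }
})

test_that("mean MTSI decreases with ligand concentration toward the dwell time", {
  crit <- response_criterion(10, 1)
  means <- vapply(c(1e-8, 1e-7, 1e-6), function(rho) {
    simulate_mtsi(params_4p(rho = rho), crit, n_realizations = 50,
                  horizon = 1e4, seed = 17)$mean_t
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_gt(means[3], crit$tau)  # T can approach but not undercut tau
})
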