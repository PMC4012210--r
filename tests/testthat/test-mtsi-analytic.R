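test_that("relaxation rates are negative and the steady source has the right limits", {
  cc <- ct_constants(params_4p(rho = 1e-9))
  expect_lt(cc$lambda1, 0)
  expect_lt(cc$lambda2, cc$lambda1)
  expect_gt(cc$a1, 0)
  # cross-linked steady state is k2/(2 k_minus2) times the singly bound one
  expect_equal(cc$a2, cc$k2 * cc$a1 / (2 * cc$k_minus2))

  # vanishing-concentration limit of a1: 4 k_on rho N_B / k_off
  p_lo <- params_4p(rho = 1e-15)
  cc_lo <- ct_constants(p_lo)
  expect_equal(cc_lo$a1, 4 * 153691 * 1e-15 * 9600 / 0.0169,
               tolerance = 1e-3)

  # no ligand: no events at any time
  cc0 <- ct_constants(params_4p(rho = 0))
  expect_equal(cc0$a1, 0)
  expect_equal(cc0$c1, 0)
  expect_equal(cc0$c2, 0)
  expect_equal(c_of_t(cc0, c(0, 10, 1e3)), c(0, 0, 0))
})

test_that("the analytic cross-link count matches the quadrature oracle", {
  tg <- seq(0, 100, by = 0.5)
  for (lig in c("4P", "4A")) {
    for (k2f in c(10, 40)) {
      p <- kinetic_parameters(lig, rho = 1e-9, b = 0.32, k2_factor = k2f)
      ct <- c_of_t(ct_constants(p), tg)
      expect_equal(ct[1], 0)
      expect_true(all(diff(ct) > 0))
      oracle <- quadrature_crosslink_count(p, tg)
      expect_lt(max(abs(ct[-1] - oracle[-1]) / oracle[-1]), 1e-6)
    }
  }
  expect_error(c_of_t(ct_constants(params_4p()), -1), ">= 0")
})

test_that("the cross-link count grows linearly with slope k2 a1 at long times", {
  cc <- ct_constants(params_4p(rho = 1e-9))
  t_far <- 1e5
  slope <- (c_of_t(cc, t_far + 1) - c_of_t(cc, t_far))
  expect_equal(slope, cc$k2 * cc$a1, tolerance = 1e-9)
})

test_that("the MTSI root equation is solved consistently and monotonically", {
  crit <- response_criterion(10, 1)
  # T decreases with rho
  Ts <- vapply(c(1e-10, 1e-9, 1e-8, 1e-7), function(r)
    solve_mtsi(params_4p(rho = r), crit), numeric(1))
  expect_true(all(diff(Ts) < 0))
  # T increases with N and with tau
  p <- params_4p(rho = 1e-9)
  expect_lt(solve_mtsi(p, response_criterion(5, 1)),
            solve_mtsi(p, response_criterion(20, 1)))
  expect_lt(solve_mtsi(p, response_criterion(10, 1)),
            solve_mtsi(p, response_criterion(10, 4)))
  # T >= tau always; root consistency: C(T - tau) = N exp(2 k-2 tau)
  T1 <- solve_mtsi(p, crit)
  expect_gte(T1, crit$tau)
  expect_equal(c_of_t(ct_constants(p), T1 - crit$tau),
               10 * exp(2 * p$k_minus2 * 1), tolerance = 1e-8)
  expect_equal(solve_mtsi(p, response_criterion(0, 1)), 0)
})

test_that("the asymptotic branches are attained in their regimes", {
  crit <- response_criterion(10, 1)
  # high concentration: T -> tau
  expect_equal(asymptotic_mtsi(params_4p(), crit, "high"), 1)
  rel_high <- vapply(c(1e-7, 1e-6, 1e-5), function(r)
    abs(regime_relative_errors(params_4p(rho = r), crit)["high"]), numeric(1))
  expect_true(all(diff(rel_high) < 0))
  expect_lt(rel_high[3], 0.05)

  # low concentration: linear-growth branch within 5% deep in the regime,
  # with error decreasing as rho -> 0
  rel_low <- vapply(c(1e-13, 1e-14, 1e-15), function(r)
    abs(regime_relative_errors(params_4p(rho = r), crit)["low"]), numeric(1))
  expect_true(all(diff(rel_low) < 0))
  expect_lt(rel_low[2], 0.05)

  # frozen example: 4P, N=10, tau=1, rho=1e-12, N_B=9600, k2/k-2=10
  p <- params_4p(rho = 1e-12)
  T_low <- asymptotic_mtsi(p, crit, "low")
  expect_equal(T_low - 1, 10 * exp(0.0338) / (4e-12 * 9600 * 153691 * 10),
               tolerance = 1e-12)
  expect_equal(T_low - 1, 175.3, tolerance = 1e-3)

  # phenotype scalings: (T - tau) ~ 1/b in the low regime, 1/sqrt(b)
  # in the intermediate regime
  pn <- params_4p(rho = 1e-12, b = 0.32)
  pm <- params_4p(rho = 1e-12, b = 0.55)
  expect_equal((asymptotic_mtsi(pn, crit, "low") - 1) /
                 (asymptotic_mtsi(pm, crit, "low") - 1),
               round(0.55 * 30000) / round(0.32 * 30000),  # = b ratio
               tolerance = 1e-12)
  expect_equal((asymptotic_mtsi(pn, crit, "intermediate") - 1) /
                 (asymptotic_mtsi(pm, crit, "intermediate") - 1),
               sqrt(round(0.55 * 30000) / round(0.32 * 30000)),
               tolerance = 1e-12)
})

test_that("expected raw event counts follow N' = N exp(2 k_minus2 tau)", {
  expect_equal(nprime(response_criterion(10, 0), 5), 10)
  expect_equal(nprime(response_criterion(100, 1), 0.0169), 100 * exp(0.0338))
  # antagonist: ln N' = ln 10 + 2 * 8.6643 * 4 ~ 71.6 (N' ~ 1e31)
  expect_equal(nprime(response_criterion(10, 4), 8.6643, log = TRUE),
               log(10) + 2 * 8.6643 * 4)
  expect_equal(log10(nprime(response_criterion(10, 4), 8.6643)), 31.1,
               tolerance = 0.01)
  # overflow policy
  huge <- nprime(response_criterion(10, 45), 8.6643)
  expect_identical(unclass(huge)[1], Inf)
  expect_equal(attr(huge, "log_nprime"), log(10) + 2 * 8.6643 * 45)
  inf_T <- solve_mtsi(kinetic_parameters("4N", rho = 1e-9, b = 0.32,
                                         k_minus2 = 8.6643),
                      response_criterion(10, 45))
  expect_identical(unclass(inf_T)[1], Inf)
  expect_gt(attr(inf_T, "log_target"), 700)
})

test_that("the dimer-to-trimer prefactor rises from 1 to 3/2", {
  expect_equal(trimer_prefactor(0.5), 4 / 3)
  b <- seq(1e-6, 1 - 1e-6, length.out = 400)
  f <- trimer_prefactor(b)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 1 & f < 1.5))
  expect_equal(trimer_prefactor(1e-9), 1, tolerance = 1e-8)
  expect_equal(trimer_prefactor(1 - 1e-9), 1.5, tolerance = 1e-8)
})

test_that("the mixed dimer/trimer ODE system nests the dimer-only model", {
  p <- params_4p(rho = 1e-10)
  tg <- seq(0, 50, 1)
  mixed0 <- integrate_dimer_trimer_odes(p, trimer_count = 0, times = tg)
  expect_true(all(mixed0[, c("y1", "y3", "y5")] == 0))
  expect_equal(mixed0$S3, mixed0$x3)
  expect_equal(mixed0$S5, mixed0$x5)
  # receptor and ligand conservation in the deterministic limit
  mixed <- integrate_dimer_trimer_odes(p, times = tg)
  expect_equal(mixed$x1 + mixed$x3 + mixed$x5, rep(p$n_dimers, length(tg)),
               tolerance = 1e-8)
  nt <- round(p$b * p$n_dimers)
  expect_equal(mixed$y1 + mixed$y3 + mixed$y5, rep(nt, length(tg)),
               tolerance = 1e-8)
  expect_equal(mixed$x2 + mixed$x3 + mixed$x5 + mixed$y3 + mixed$y5,
               rep(p$ligand_copies, length(tg)), tolerance = 1e-6)
})

test_that("aggregated signaling units approximately follow the reduced equation", {
  p <- params_4p(rho = 1e-12, b = 0.32)
  tg <- seq(0, 300, 0.5)
  full <- integrate_dimer_trimer_odes(p, times = tg)
  s5_red <- reduced_s5(p, tg, full$S3)
  after <- tg >= 10
  rel <- abs(s5_red[after] - full$S5[after]) / full$S5[after]
  expect_lt(max(rel), 0.05)
})
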