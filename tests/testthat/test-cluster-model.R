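test_that("stationary law has the geometric form in both truncated and unbounded cases", {
  # no growth: all monomers
  d0 <- stationary_distribution(0, n_max = 25)
  expect_equal(unname(d0$probabilities[1]), 1)
  expect_true(all(d0$probabilities[-1] == 0))

  # unbounded geometric law at b = 0.5
  d <- stationary_distribution(0.5)
  expect_equal(unname(d$probabilities[1:3]), c(0.5, 0.25, 0.125))

  # a physiological truncation (~3e4 receptors) is numerically
  # indistinguishable from the unbounded law
  b <- 0.32
  dt <- stationary_distribution(b, n_max = 30000)
  du_p <- stationary_pmf(b, seq_len(30000))
  expect_lt(max(abs(dt$probabilities - du_p)), 1e-12)

  # removable singularity of the finite law at b = 1: uniform
  d1 <- stationary_distribution(1, n_max = 100)
  expect_equal(unname(d1$probabilities), rep(1 / 100, 100))

  # no normalizable unbounded law at b >= 1
  expect_error(stationary_distribution(1), "normalizable")
  expect_error(stationary_distribution(0.3, n_max = -2), "positive integer")
})

test_that("stationary law is normalized, geometric in ratio, and in detailed balance", {
  for (b in seq(0, 0.99, by = 0.09)) {
    pu <- stationary_distribution(b)$probabilities
    pt <- stationary_distribution(b, n_max = 500)$probabilities
    expect_equal(sum(pt), 1, tolerance = 1e-12)
    expect_equal(sum(pu), 1, tolerance = 1e-10)  # analytic tail < 1e-15
    if (b > 0) {
      # successive ratio is b, i.e. detailed balance q+ pi_n = q- pi_{n+1}
      expect_equal(unname(pu[-1] / pu[-length(pu)]),
                   rep(b, length(pu) - 1), tolerance = 1e-12)
    }
  }
  # mean cluster size of the unbounded law is 1/(1-b)
  for (b in c(0.1, 0.32, 0.55, 0.9)) {
    n <- seq_len(5000)
    expect_equal(sum(n * stationary_pmf(b, n)), 1 / (1 - b),
                 tolerance = 1e-10)
  }
})

test_that("transient probabilities solve the forward equations and relax to the stationary law", {
  m <- birth_death_model(q_plus = 0.5, q_minus = 1)
  pi_b <- stationary_distribution(0.5, n_max = 45)$probabilities

  # stationarity: starting from pi, the law does not move
  tr <- transient_probabilities(birth_death_model(0.5, 1, n_max = 45),
                                pi_b, times = c(0, 5, 50))
  expect_lt(max(abs(sweep(tr$p, 2, pi_b))), 1e-8)

  # from all-monomer start, total-variation distance to pi is
  # non-increasing and falls below 1e-6 at long times
  tr2 <- transient_probabilities(m, c(1), times = c(0, 1, 5, 10, 50, 100, 200))
  expect_equal(unname(rowSums(tr2$p)), rep(1, 7), tolerance = 1e-8)
  expect_true(all(tr2$p > -1e-12))
  tv <- apply(tr2$p, 1, function(p)
    total_variation(p, stationary_pmf(0.5, seq_along(p))))
  expect_true(all(diff(tv) <= 1e-10))
  expect_lt(tv[length(tv)], 1e-6)

  # pure death chain collapses toward monomers
  tr3 <- transient_probabilities(birth_death_model(0, 1, n_max = 20),
                                 c(0, 0, 0, 0, 1), times = c(0, 50))
  expect_gt(tr3$p[2, 1], 1 - 1e-6)

  expect_error(transient_probabilities(m, c(0.5, 0.4), times = c(0, 1)),
               "sum")
})

test_that("multimeric fraction equals b and phenotype ratio is the b ratio", {
  expect_equal(multimeric_fraction(0), 0)
  expect_equal(multimeric_fraction(0.55), 0.55)
  for (b in c(0.1, 0.32, 0.9)) {
    expect_equal(multimeric_fraction(b),
                 1 - stationary_distribution(b)$probabilities[[1]])
  }
  expect_equal(phenotype_ratio(0.25, 0.5), 2)
  expect_equal(phenotype_ratio(0.4, 0.4), 1)
  expect_equal(round(phenotype_ratio(0.32, 0.55), 2), 1.72)
  expect_error(phenotype_ratio(0, 0.5), "\\(0, 1\\)")
})
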