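test_that("reduce_params recovers the dimensionless triple from full units", {
  # growth phase of 50 ln2 time units at r_null = 1 is 50 doubling times
  p <- competition_params(r_wt = 0.9, r_null = 1, carrying_capacity = 1e7,
                          stress_period = 100 * log(2), growth_fraction = 0.5,
                          death_rate = -log(1 - 0.8) / (50 * log(2)))
  rp <- reduce_params(p)
  expect_equal(rp$alpha, 0.9)
  expect_equal(rp$beta, 50)
  expect_equal(rp$death_fraction, 0.8)

  same <- competition_params(r_wt = 2, r_null = 2, carrying_capacity = 1e7,
                             stress_period = 10, growth_fraction = 0.5,
                             death_rate = 1)
  expect_equal(reduce_params(same)$alpha, 1)

  no_kill <- competition_params(r_wt = 0.9, r_null = 1,
                                carrying_capacity = 1e7, stress_period = 10,
                                growth_fraction = 0.5, death_rate = 0)
  expect_equal(reduce_params(no_kill)$death_fraction, 0)

  degenerate <- competition_params(r_wt = 0.9, r_null = 0,
                                   carrying_capacity = 1e7,
                                   stress_period = 10, growth_fraction = 0.5,
                                   death_rate = 1)
  expect_error(reduce_params(degenerate), "relative fitness")
})

test_that("classify_state reproduces the three phase regimes", {
  # equal fitness: state II bound collapses to 0, any killing favors WT
  expect_equal(classify_state(reduced_params(1, 10, 0.5))$label,
               "WT_ALWAYS_WINS")
  # killing beyond what 5 doublings replace (bound 1 - 2^-5 = 0.96875)
  expect_equal(classify_state(reduced_params(0.9, 5, 0.999))$label,
               "MUTANT_NONVIABLE")
  st <- classify_state(reduced_params(0.9, 50, 0.9))
  expect_equal(st$label, "RATIO_DEPENDENT")
  expect_equal(st$threshold_ratio, 0.5612778, tolerance = 1e-6)
  expect_error(reduced_params(0.9, 10, 1), "death_fraction")
})

test_that("state I bound dominates state II bound for alpha < 1", {
  for (alpha in c(0.5, 0.9, 0.99)) {
    beta <- exp(seq(log(0.5), log(200), length.out = 40))
    b1 <- 1 - exp(-beta * log(2))
    b2 <- 1 - exp((alpha - 1) * beta * log(2))
    expect_true(all(b1 >= b2))
  }
})

test_that("threshold ratio is monotone in beta and in death fraction", {
  thr <- function(b, m)
    classify_state(reduced_params(0.9, b, m))$threshold_ratio
  betas <- c(40, 60, 80, 100)
  expect_true(all(diff(vapply(betas, thr, 0, m = 0.9)) > 0))
  ms <- c(0.85, 0.9, 0.95)
  expect_true(all(diff(vapply(ms, thr, 0, b = 50)) < 0))
  # limit alpha -> 1: the always-wins bound collapses to 0, so any killing
  # puts the system in state II regardless of the starting ratio
  expect_equal(classify_state(reduced_params(0.999999, 50, 0.9))$label,
               "WT_ALWAYS_WINS")
})

test_that("critical death fraction solves the dominance boundary", {
  m1 <- critical_death_fraction(0.9, 50, 1)
  expect_equal(m1, 0.8386326, tolerance = 1e-5)
  m2 <- critical_death_fraction(0.9, 100, 25)
  expect_equal(m2, 0.2554358, tolerance = 1e-5)
  # self-consistency: the threshold at the root equals the starting ratio
  expect_equal(classify_state(reduced_params(0.9, 50, m1))$threshold_ratio,
               1, tolerance = 1e-4)
  # decreasing in start_ratio
  ms <- vapply(c(1, 5, 25), function(r)
    critical_death_fraction(0.9, 100, r), 0)
  expect_true(all(diff(ms) < 0))
  # near-equal fitness: negligible killing suffices
  expect_lt(critical_death_fraction(0.999999, 50, 1), 1e-3)
})

test_that("simulation respects the piecewise structure and capacity", {
  K <- 1e7
  p <- params_from_reduced(0.9, 5, 0.6, K = K)
  tr <- simulate_competition(p, n_cycles = 12)
  s <- tr$states
  expect_true(all(s$n_wt >= 0 & s$n_null >= 0))
  expect_true(all(s$n_wt + s$n_null <= K * (1 + 1e-6)))
  expect_true(all(diff(s$t) >= 0))
  # wild-type frozen during every stress window
  omega <- p$stress_period
  for (cyc in 0:4) {
    in_stress <- s$t >= cyc * omega &
      s$t <= cyc * omega + (1 - p$growth_fraction) * omega
    expect_lt(diff(range(s$n_wt[in_stress])), 1e-6 * K)
  }
})

test_that("no killing freezes the saturated culture; only the mutant dies", {
  p0 <- params_from_reduced(0.9, 5, 0, K = 1e7)
  tr0 <- simulate_competition(p0, n_cycles = 12)
  late <- tr0$states[tr0$states$t > 6 * p0$stress_period, ]
  expect_lt(diff(range(late$n_wt)), 1e-3 * 1e7)
  expect_lt(diff(range(late$n_null)), 1e-3 * 1e7)
  expect_equal(winner(tr0), "COEXIST_FROZEN")

  # equal rates with killing: log ratio strictly increases every cycle
  p1 <- params_from_reduced(1, 5, 0.3)
  tr1 <- simulate_competition(p1, n_cycles = 12)
  expect_true(all(tr1$cycle_log_ratio_changes > 0))
  expect_equal(winner(tr1), "WT")

  expect_error(winner(simulate_competition(p1, n_cycles = 5)), "10 cycles")
})

test_that("integrator conserves ln(n_wt) - alpha ln(n_null) within growth", {
  # exact per-cycle increment of the invariant is alpha * |ln(1 - m)|
  alpha <- 0.9; m <- 0.5; beta <- 10
  p <- params_from_reduced(alpha, beta, m)
  tr <- simulate_competition(p, n_cycles = 15)
  s <- tr$states
  omega <- p$stress_period
  idx <- vapply(0:15, function(k) which.min(abs(s$t - k * omega)), 0L)
  Q <- log(s$n_wt[idx]) - alpha * log(s$n_null[idx])
  expect_equal(diff(Q), rep(alpha * -log(1 - m), 15), tolerance = 1e-6)
})

test_that("dilute-regime winner flips at the always-wins boundary", {
  # in exponential (non-saturating) growth the per-cycle log-ratio change is
  # (alpha-1) beta ln2 - ln(1-m); its sign flips at m = 1 - e^((alpha-1) beta ln2)
  alpha <- 0.9; beta <- 10
  m_star <- 1 - exp((alpha - 1) * beta * log(2))
  run <- function(m) {
    p <- params_from_reduced(alpha, beta, m, K = 1e40)
    winner(simulate_competition(p, init = c(n_wt = 1, n_null = 1),
                                n_cycles = 12),
           extinction_floor = 1e-12)
  }
  expect_equal(run(m_star - 0.05), "MUTANT")
  expect_equal(run(m_star + 0.05), "WT")
})

test_that("state I killing drives the mutant extinct in simulation", {
  p <- params_from_reduced(0.9, 3, 0.95)  # state I: bound is 1 - 2^-3 = 0.875
  expect_equal(classify_state(reduce_params(p))$label, "MUTANT_NONVIABLE")
  tr <- simulate_competition(p, n_cycles = 15)
  expect_equal(winner(tr), "MUTANT_EXTINCT")
})

test_that("phase map covers the grid with contours and the m = 0 sentinel", {
  pm <- phase_map(0.9, beta_grid = c(5, 20, 50), m_grid = c(0, 0.3, 0.9, 0.99),
                  ratios = c(1, 25))
  expect_equal(nrow(pm$grid), 12)
  zero_col <- pm$grid[pm$grid$m == 0, ]
  expect_true(all(zero_col$state == "RATIO_DEPENDENT"))
  expect_true(all(is.infinite(zero_col$threshold_ratio)))
  # severe/frequent killing is state I; contours for larger ratios lie lower
  expect_equal(pm$grid$state[pm$grid$beta == 5 & pm$grid$m == 0.99],
               "MUTANT_NONVIABLE")
  m1 <- pm$contours$m_critical[pm$contours$ratio == 1]
  m25 <- pm$contours$m_critical[pm$contours$ratio == 25]
  expect_true(all(m25 < m1))
})
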