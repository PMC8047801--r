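# Dual-cutoff labeling, transition counting, the closed-form rate, block
# errors, and the TST comparator.

test_that("indicator cutoffs are validated", {
  expect_error(shell_indicator(0.4, 0.3), "smaller")
  expect_error(shell_indicator(-0.1, 0.3), "positive")
})

test_that("hysteresis labeling commits and carries states as specified", {
  ind <- shell_indicator(0.28, 0.40)
  # permanently bound water: no transitions
  s <- label_states(radial_water_traj(rep(0.21, 20)), ind)
  expect_true(all(s$states == 1L))
  expect_identical(count_transitions(s), 0L)
  # full excursion and return: two transitions (one each way)
  s2 <- label_states(radial_water_traj(c(0.27, 0.27, 0.41, 0.41, 0.27)), ind)
  expect_identical(count_transitions(s2), 2L)
  # oscillation inside the hysteresis band: no recrossing noise
  s3 <- label_states(radial_water_traj(c(0.27, rep(c(0.30, 0.38), 10), 0.27)),
                     ind)
  expect_identical(count_transitions(s3), 0L)
  # initial state between cutoffs resolves to the nearer cutoff
  s4 <- label_states(radial_water_traj(c(0.30, 0.30)), ind)  # nearer r_bound
  expect_true(all(s4$states == 1L))
  s5 <- label_states(radial_water_traj(c(0.38, 0.38)), ind)  # nearer r_unbound
  expect_true(all(s5$states == 0L))
})

test_that("transition counts are additive under concatenation", {
  ind <- shell_indicator(0.28, 0.40)
  p1 <- c(0.21, 0.45, 0.21, 0.21)
  p2 <- c(0.45, 0.45, 0.21, 0.45)
  s1 <- label_states(radial_water_traj(p1), ind)
  s2 <- label_states(radial_water_traj(p2), ind)
  s12 <- label_states(radial_water_traj(c(p1, p2)), ind)
  boundary <- count_transitions(s12) - count_transitions(s1) - count_transitions(s2)
  expect_true(boundary %in% 0:1)
})

test_that("counts of a two-state Markov series match the renewal expectation", {
  set.seed(101)
  k12 <- 0.02; k21 <- 0.05   # per frame
  nf <- 20000L; nw <- 10L
  states <- matrix(0L, nf, nw)
  states[1, ] <- rbinom(nw, 1, k12 / (k12 + k21))
  for (t in 2:nf) {
    u <- runif(nw)
    s <- states[t - 1, ]
    states[t, ] <- ifelse(s == 1L, ifelse(u < k21, 0L, 1L),
                          ifelse(u < k12, 1L, 0L))
  }
  N <- count_transitions(states)
  expected <- 2 * nf * nw / (1 / k12 + 1 / k21)
  expect_lt(abs(N - expected), 3 * sqrt(expected))
})

test_that("the closed-form rate reproduces the benchmark transition counts", {
  comp <- ideal_composition()   # 55.5:1, N_H2O = 2160
  # microsecond-set count from a 1 us, 1 M box
  k1 <- exchange_rate(376, comp$N_H2O, comp$N_Mg, t_sim = 1e-6, N_err = 56)
  expect_lt(abs(k1$k - 8.04e5), 1.20e5)
  expect_lt(abs(k1$k_err - 1.20e5), 0.3e5)
  # nanosecond-set count
  k2 <- exchange_rate(52086, comp$N_H2O, comp$N_Mg, t_sim = 1e-6)
  expect_lt(abs(k2$k - 1.11e8), 0.003e8)
  # 12-6-4 literature count
  k3 <- exchange_rate(6720, comp$N_H2O, comp$N_Mg, t_sim = 1e-6)
  expect_lt(abs(k3$k - 1.44e7), 0.03e7)
  # experimental rate inverts to ~248 expected events
  expect_equal(round(expected_transitions(5.3e5, comp$N_H2O, comp$N_Mg, 1e-6)),
               248)
  # edge cases
  expect_equal(exchange_rate(0, comp$N_H2O, comp$N_Mg, 1e-6)$k, 0)
  expect_error(exchange_rate(10, 5, 1, 1e-6), "exceed")
})

test_that("rate is proportional to the transition count", {
  comp <- ideal_composition()
  k1 <- exchange_rate(100, comp$N_H2O, comp$N_Mg, 1e-6)$k
  k2 <- exchange_rate(700, comp$N_H2O, comp$N_Mg, 1e-6)$k
  expect_equal(k2 / k1, 7)
})

test_that("block errors follow the spread-over-sqrt-blocks rule", {
  be <- block_error(c(160, 216), n_blocks = 2)
  expect_equal(be$mean, 188)
  expect_equal(be$error, 28)
  expect_equal(block_error(c(216, 160), 2)$error, 28)   # permutation invariant
  expect_equal(block_error(c(5, 5, 5, 5), 4)$error, 0)  # identical blocks
  expect_error(block_error(c(1), 2), "fewer")
  # with independent same-quality blocks the error of the mean shrinks
  # like 1/sqrt(n_blocks)
  set.seed(9)
  mean_err <- function(n) mean(replicate(300, block_error(rnorm(n), n)$error))
  expect_equal(mean_err(16) / mean_err(4), 0.5, tolerance = 0.1)
})

test_that("hopping pipeline recovers the generator rate, insensitive to cutoffs", {
  spec <- hopping_spec(k_true = 1e8, N_Mg = 4, N_H2O = 120, t_sim = 2e-7,
                       dt = 1e-10, seed = 5)
  tr <- gen_hopping_traj(spec)
  st <- water_exchange(tr, shell_indicator(0.28, 0.40))
  expect_equal(st$k, 1e8, tolerance = 0.15)
  # +-10% cutoff variation moves the rate by < 5%
  k_lo <- water_exchange(tr, shell_indicator(0.28 * 0.9, 0.40 * 0.9))$k
  k_hi <- water_exchange(tr, shell_indicator(0.28 * 1.1, 0.40 * 1.1))$k
  expect_lt(abs(k_lo / st$k - 1), 0.05)
  expect_lt(abs(k_hi / st$k - 1), 0.05)
})

test_that("TST on a harmonic well with a sharp barrier matches the closed form", {
  kappa <- 2000; r0 <- 0.21; rc <- 0.31
  r <- seq(0.06, 0.40, by = 5e-4)
  F <- ifelse(r <= rc, 0.5 * kappa * (r - r0)^2,
              0.5 * kappa * (rc - r0)^2 - 30 * (r - rc))
  prof <- free_energy_profile(r, F, T = 300)
  mu <- 10.3   # Mg-water reduced mass, g/mol
  k <- tst_rate(prof, mu)
  Fb <- 0.5 * kappa * (rc - r0)^2
  k_analytic <- sqrt(0.008314462618 * 300 / (2 * pi * mu)) *
    sqrt(kappa / (2 * pi)) * exp(-Fb) * 1e12
  expect_equal(k, k_analytic, tolerance = 0.005)
})

test_that("raising the barrier by one k_BT scales the TST rate by exp(-1)", {
  f <- double_well_fun(depth = 8, barrier = 4)
  r <- seq(0.15, 0.60, by = 0.001)
  F1 <- f(r)
  prof1 <- free_energy_profile(r, F1)
  ib <- which.max(F1[r < 0.35])
  F2 <- F1
  F2[ib] <- F2[ib] + 1        # well shape untouched
  prof2 <- free_energy_profile(r, F2)
  ratio <- tst_rate(prof2, 10.3) / tst_rate(prof1, 10.3)
  expect_equal(ratio, exp(-1), tolerance = 1e-4)
})

test_that("TST bounds the counting rate from above on recrossing-rich walks", {
  for (barrier in c(1.5, 2.5, 3.5)) {
    f <- double_well_fun(depth = 4, barrier = barrier)
    r <- seq(0.15, 0.60, by = 0.001)
    prof <- free_energy_profile(r, f(r))
    walk <- gen_langevin_radial(f, c(0.15, 0.60), D = 5e-4, dt = 0.05,
                                steps = 20000L, walkers = 8L,
                                r0 = 0.21, seed = round(barrier * 10))
    kc <- radial_exchange_rate(walk, shell_indicator(0.28, 0.40))
    if (barrier <= 2.5) expect_gt(kc$N, 0)
    expect_gte(tst_rate(prof, 10.3), kc$k)
  }
})
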