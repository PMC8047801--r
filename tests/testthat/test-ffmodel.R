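# Pair-potential algebra and combination rules.

test_that("12-6 energy has its zero at sigma and its minimum of -epsilon", {
  p <- pair_interaction(0.3, 1.0)
  expect_equal(lj_energy(p, 0.3), 0)
  expect_equal(lj_energy(p, 0.3 * 2^(1 / 6)), -1.0)
  # frozen value computed by direct arithmetic for the microMg ion-water pair
  pio <- pair_interaction(0.2085, 12.250)
  expect_equal(lj_energy(pio, 0.30), -4.89978817794, tolerance = 1e-10)
  # vectorized evaluation matches pointwise calls
  r <- seq(0.25, 1, by = 0.05)
  expect_equal(lj_energy(pio, r), vapply(r, function(x) lj_energy(pio, x),
                                         numeric(1)))
  expect_error(lj_energy(p, 0), "positive")
  expect_error(lj_energy(p, c(0.3, -1)), "positive")
})

test_that("12-6 energy decays to zero and the r^-4 term is strictly attractive", {
  p0 <- pair_interaction(0.3, 1.0)
  p4 <- pair_interaction(0.3, 1.0, c4 = 0.005)
  r <- seq(13 * 0.3, 20, length.out = 50)
  expect_true(all(abs(lj_energy(p0, r)) < 1e-6 * p0$epsilon_ij))
  expect_true(all(diff(abs(lj_energy(p0, seq(3, 20, by = 0.5)))) < 0))
  rr <- seq(0.2, 3, by = 0.01)
  expect_true(all(lj_energy(p4, rr) < lj_energy(p0, rr)))
})

test_that("coulomb energy follows k_e q_i q_j / r", {
  expect_equal(coulomb_energy(0, 5, 1), 0)
  # oracle: k_e from CODATA e, eps0, N_A computed independently
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; NAv <- 6.02214076e23
  ke <- NAv * e^2 / (4 * pi * eps0) * 1e9 / 1e3
  expect_equal(coulomb_energy(2, -1, 1.0), -2 * ke, tolerance = 1e-8)
  expect_equal(coulomb_energy(2, -1, 0.7), coulomb_energy(-1, 2, 0.7))
  expect_error(coulomb_energy(1, 1, 0), "positive")
})

test_that("Lorentz-Berthelot rule reproduces the printed ion-water parameters", {
  # microMg and nanoMg ion-water pairs against TIP3P oxygen, at the
  # precision the parameter table prints
  io <- combine_lb(lj_params(0.1019, 235.80), TIP3P_OXYGEN)
  expect_equal(round(io$sigma_ij, 4), 0.2085)
  expect_equal(round(io$epsilon_ij, 3), 12.250)
  io2 <- combine_lb(lj_params(0.1025, 389.80), TIP3P_OXYGEN)
  expect_equal(round(io2$sigma_ij, 4), 0.2088)
  expect_equal(round(io2$epsilon_ij, 3), 15.750)
  expect_identical(io$provenance, "standard-rule")
  # symmetry and idempotence
  a <- lj_params(0.2, 3); b <- lj_params(0.4, 5)
  ab <- combine_lb(a, b); ba <- combine_lb(b, a)
  expect_equal(ab$sigma_ij, ba$sigma_ij)
  expect_equal(ab$epsilon_ij, ba$epsilon_ij)
  aa <- combine_lb(a, a)
  expect_equal(aa$sigma_ij, a$sigma)
  expect_equal(aa$epsilon_ij, a$epsilon)
})

test_that("scaled combination rule reduces to the standard rule at lambda = 1", {
  a <- lj_params(0.1019, 235.80); b <- TIP3P_OXYGEN
  s1 <- scaling_factors(1, 1, "X")
  sc <- combine_scaled(a, b, s1); lb <- combine_lb(a, b)
  expect_identical(sc$sigma_ij, lb$sigma_ij)
  expect_identical(sc$epsilon_ij, lb$epsilon_ij)
  expect_identical(sc$provenance, "scaled-rule")
})

test_that("scaled rule reproduces the printed Mg-phosphate-oxygen strengths", {
  op <- lj_params(0.295992, 0.87864)  # AMBER nonbridging phosphate oxygen
  e1 <- combine_scaled(lj_params(0.1019, 235.80), op,
                       scaling_factors(1.1375, 0.32, "RNA"))$epsilon_ij
  e2 <- combine_scaled(lj_params(0.1025, 389.80), op,
                       scaling_factors(1.1435, 0.25, "RNA"))$epsilon_ij
  expect_equal(e1, 4.6061, tolerance = 2e-4 / 4.6061)
  expect_equal(e2, 4.6266, tolerance = 2e-4 / 4.6266)
})

test_that("Mg-Cl strengths are mutually consistent across the two parameter sets", {
  # invert the microMg row for the chloride well depth, then forward-compute
  # the nanoMg Mg-Cl strength
  lam_eps <- 0.1
  eps_cl <- (0.8181 / lam_eps)^2 / 235.80
  e_nano <- combine_scaled(lj_params(0.1025, 389.80),
                           lj_params(0.4401, eps_cl),
                           scaling_factors(1.8, lam_eps, "Cl"))$epsilon_ij
  expect_equal(e_nano, 1.0518, tolerance = 2e-4 / 1.0518)
})

test_that("builtin registry returns the printed records and rejects unknown names", {
  m <- builtin_params("microMg")
  expect_equal(m$ion$lj$sigma, 0.1019)
  expect_equal(m$ion$lj$epsilon, 235.80)
  expect_equal(m$ion$charge, 2)
  n <- builtin_params("nanoMg")
  expect_equal(n$scalings$RNA$lambda_sigma, 1.1435)
  expect_equal(n$scalings$RNA$lambda_epsilon, 0.2500)
  expect_equal(n$scalings$Cl$lambda_sigma, 1.8)
  expect_error(builtin_params("unknown"), "available")
})

test_that("potential curve is the vectorized energy on the grid", {
  p <- pair_interaction(0.3, 1.0)
  expect_equal(potential_curve(p, 0.3)$V, 0)
  g <- seq(0.25, 1.2, by = 0.001)
  cu <- potential_curve(p, g)
  expect_equal(cu$V, lj_energy(p, g))
  expect_equal(cu$r[which.min(cu$V)], 0.3 * 2^(1 / 6), tolerance = 0.002)
  expect_error(potential_curve(p, c(-0.1, 0.2)), "positive")
  expect_error(potential_curve(p, c(0.3, 0.2)), "increasing")
})

test_that("combination-rule inversion is the exact inverse on both builtin sets", {
  for (name in c("microMg", "nanoMg")) {
    ps <- builtin_params(name)
    back <- invert_lb(combine_lb(ps$ion$lj, TIP3P_OXYGEN))
    expect_equal(back$sigma, ps$ion$lj$sigma, tolerance = 1e-12)
    expect_equal(back$epsilon, ps$ion$lj$epsilon, tolerance = 1e-12)
  }
  expect_error(invert_lb(pair_interaction(0.1, 1)), "nonpositive")
})

test_that("constructors enforce the physical invariants", {
  expect_error(lj_params(-0.1, 1), "positive")
  expect_error(lj_params(0.1, -1), "nonnegative")
  expect_error(ion_model("", 2, lj_params(0.1, 1)), "nonempty")
  expect_error(pair_interaction(0.2, 1, c4 = -1), "nonnegative")
  expect_error(scaling_factors(0, 1, "X"), "positive")
})
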