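# Kirkwood-Buff integrals and the activity derivative of a 2:1 electrolyte.

test_that("KB integral closed forms: ideal, excluded volume, Gaussian bump", {
  grid <- seq(0.0005, 2, by = 0.0005)
  gi <- gen_rdf("ideal", list(rho = 1), grid = grid)
  expect_equal(kb_integral(gi, c(1, 1.8))$G, 0, tolerance = 1e-12)
  d <- 0.3
  gx <- gen_rdf("excluded-volume", list(rho = 1, d = d), grid = grid)
  expect_equal(kb_integral(gx, c(1, 1.8))$G, -(4 / 3) * pi * d^3,
               tolerance = 0.005)
  # Gaussian bump: oracle via adaptive quadrature on the analytic form
  A <- 0.4; mu <- 0.5; s <- 0.05
  gb <- rdf(grid, 1 + A * exp(-(grid - mu)^2 / (2 * s^2)), rho_bulk = 1)
  G_oracle <- integrate(function(r) 4 * pi * A * exp(-(r - mu)^2 / (2 * s^2)) * r^2,
                        0, 2, rel.tol = 1e-12)$value
  expect_equal(kb_integral(gb, c(1.2, 1.8))$G, G_oracle, tolerance = 0.005)
})

test_that("running KB integral is linear in g-1 and flat beyond the support", {
  grid <- seq(0.001, 2, by = 0.001)
  # linearity: scaling (g-1) scales G (Gaussian bump keeps g nonnegative)
  gb1 <- rdf(grid, 1 + 0.2 * exp(-(grid - 0.5)^2 / (2 * 0.05^2)), rho_bulk = 1)
  gb3 <- rdf(grid, 1 + 0.6 * exp(-(grid - 0.5)^2 / (2 * 0.05^2)), rho_bulk = 1)
  expect_equal(kb_integral(gb3, c(1, 1.5))$G, 3 * kb_integral(gb1, c(1, 1.5))$G,
               tolerance = 1e-10)
  d <- 0.25
  g1 <- gen_rdf("excluded-volume", list(rho = 1, d = d), grid = grid)
  run <- kb_integral(g1, c(1, 1.5))$running
  tail_vals <- run$G[run$r > d + 0.01]
  expect_lt(max(abs(tail_vals - tail_vals[1])), 1e-12)
})

test_that("activity derivative satisfies the ideal and cancellation limits", {
  rho <- molar_to_density(0.25)
  G0 <- list(cc = 0, ca = 0, aa = 0, cw = 0, aw = 0)
  expect_equal(activity_derivative(G0, rho)$a_cc, 1)
  # G_ss = G_sw != 0 cancels exactly
  Gc <- list(cc = 0.2, ca = 0.2, aa = 0.2, cw = 0.2, aw = 0.2)
  expect_equal(activity_derivative(Gc, rho)$a_cc, 1)
  expect_error(activity_derivative(list(cc = 0, ca = 0), rho), "missing")
  # strong salt-water excess trips the stability check
  expect_error(activity_derivative(list(cc = -9, ca = -9, aa = -9,
                                        cw = 9, aw = 9), 1),
               "instability")
})

test_that("activity derivative matches an independent scalar evaluation", {
  set.seed(21)
  rho <- molar_to_density(0.5)
  for (i in 1:20) {
    G <- as.list(stats::setNames(rnorm(5, 0, 0.1),
                                 c("cc", "ca", "aa", "cw", "aw")))
    # independent scalar arithmetic for the 2:1 stoichiometric combination
    nu_c <- 1; nu_a <- 2; nu <- 3
    Gss <- (nu_c^2 * G$cc + 2 * nu_c * nu_a * G$ca + nu_a^2 * G$aa) / nu^2
    Gsw <- (nu_c * G$cw + nu_a * G$aw) / nu
    expect_equal(activity_derivative(G, rho)$a_cc,
                 1 / (1 + rho * (Gss - Gsw)), tolerance = 1e-12)
  }
})

test_that("a_cc is monotone decreasing in the salt-salt excess", {
  rho <- molar_to_density(0.25)
  deltas <- seq(-0.5, 1.0, by = 0.1)
  accs <- vapply(deltas, function(dG) {
    activity_derivative(list(cc = dG, ca = dG, aa = dG, cw = 0, aw = 0),
                        rho)$a_cc
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("concentration series orders entries and propagates block errors", {
  grid <- seq(0.001, 2, by = 0.001)
  ideal_set <- function() {
    sets <- lapply(c("cc", "ca", "aa", "cw", "aw"),
                   function(t) gen_rdf("ideal", list(rho = 1), grid = grid))
    stats::setNames(sets, c("cc", "ca", "aa", "cw", "aw"))
  }
  out <- concentration_series(list(list(concentration = 0.25,
                                        rdfs = ideal_set())))
  expect_equal(out$a_cc, 1)
  # duplicates preserved, ascending order
  out2 <- concentration_series(list(
    list(concentration = 1.0, rdfs = ideal_set()),
    list(concentration = 0.25, rdfs = ideal_set()),
    list(concentration = 0.25, rdfs = ideal_set())))
  expect_equal(out2$concentration, c(0.25, 0.25, 1.0))
  # per-block noisy RDFs give a finite 3-block error
  set.seed(31)
  noisy_set <- function() {
    sets <- lapply(c("cc", "ca", "aa", "cw", "aw"), function(t) {
      g <- pmax(1 + rnorm(length(grid), 0, 0.01), 0)
      rdf(grid, g, rho_bulk = 1)
    })
    stats::setNames(sets, c("cc", "ca", "aa", "cw", "aw"))
  }
  out3 <- concentration_series(list(list(
    concentration = 0.5,
    blocks = list(noisy_set(), noisy_set(), noisy_set()))))
  expect_true(is.finite(out3$err))
  expect_gt(out3$err, 0)
  expect_equal(out3$a_cc, 1, tolerance = 0.05)
})
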