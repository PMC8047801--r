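# RDF estimation, first-shell analysis, and diffusion from the MSD.

test_that("two fixed atoms put all RDF mass in the bin containing their distance", {
  d <- 0.4321
  tr <- static_traj(list(A = matrix(c(0, 0, 0), 1),
                         B = matrix(c(d, 0, 0), 1)), n_frames = 5, box = 4)
  g <- compute_rdf(tr, c("A", "B"), bin_width = 0.01, r_max = 2)
  hit <- which(g$g > 0)
  expect_length(hit, 1L)
  expect_lt(abs(g$r[hit] - d), 0.005 + 1e-12)
  expect_identical(attr(g, "pair_count"), 5L)  # one pair, five frames
})

test_that("ideal-gas positions give g close to 1 in every bin", {
  set.seed(42)
  nf <- 150L; nb <- 250L; box <- 4
  B <- array(runif(nf * nb * 3, 0, box), c(nf, nb, 3))
  A <- array(box / 2, c(nf, 1, 3))
  tr <- trajectory(seq_len(nf) - 1, list(A = A, B = B), rep(box, 3))
  g <- compute_rdf(tr, c("A", "B"), bin_width = 0.05, r_max = 2)
  # Poisson counting: per-bin deviations consistent with sqrt(N) noise
  expect_gt(length(g$r), 30)
  ideal_counts <- nf * (4 / 3) * pi *
    diff(seq(0, 2, by = 0.05)^3) * nb / box^3
  sel <- seq_along(g$g) > 2 & ideal_counts > 30
  z <- abs(g$g[sel] - 1) * sqrt(ideal_counts[sel])
  expect_lt(mean(z > 4), 0.03)
  # count-weighted overall density matches the bulk to sub-percent level
  g_overall <- sum(g$g[sel] * ideal_counts[sel]) / sum(ideal_counts[sel])
  expect_lt(abs(g_overall - 1), 0.01)
})

test_that("RDF pair counts are conserved and r_max is validated", {
  set.seed(7)
  nf <- 10L; nb <- 20L; box <- 3
  B <- array(runif(nf * nb * 3, 0, box), c(nf, nb, 3))
  A <- array(runif(nf * 2 * 3, 0, box), c(nf, 2, 3))
  tr <- trajectory(seq_len(nf) - 1, list(A = A, B = B), rep(box, 3))
  g <- compute_rdf(tr, c("A", "B"), bin_width = 0.05, r_max = 1.5)
  d <- mgff:::pair_distances(tr, "A", "B")
  expect_identical(attr(g, "pair_count"), sum(d < 1.5))
  expect_error(compute_rdf(tr, c("A", "B"), r_max = 2), "half the smallest")
  expect_error(compute_rdf(tr, c("A", "missing")), "lacks role")
})

test_that("first-shell analysis recovers the closed forms of synthetic RDFs", {
  # gaussian shell carrying exactly A partners
  g <- gen_rdf("gaussian-shell", list(A = 6, mu = 0.21, s = 0.01, rho = 1e-4))
  tr <- attr(g, "truth")
  sh <- first_shell(g)
  expect_equal(sh$R1, tr$R1, tolerance = 1e-3)
  expect_equal(sh$n1, tr$n1, tolerance = 0.01)
  # uniform fluid with a forced shell boundary
  gi <- gen_rdf("ideal", list(rho = 2), grid = seq(0.001, 1, by = 0.001))
  shi <- first_shell(gi, r_min1 = 0.5)
  expect_equal(shi$n1, (4 / 3) * pi * 2 * 0.5^3, tolerance = 0.01)
  # a peak centered exactly on a bin interpolates to that bin center
  r <- seq(0.05, 1, by = 0.01)
  gsym <- 1 + 5 * exp(-(r - 0.25)^2 / (2 * 0.03^2))
  shs <- first_shell(rdf(r, gsym, rho_bulk = 1))
  expect_equal(shs$R1, 0.25, tolerance = 1e-9)
  # monotone or peakless input is rejected with a named condition
  expect_error(first_shell(rdf(r, seq(2, 1, length.out = length(r)),
                               rho_bulk = 1)), "no interior maximum")
})

test_that("n1 is monotone in the shell boundary", {
  g <- gen_rdf("gaussian-shell", list(A = 6, mu = 0.21, s = 0.01, rho = 0.5))
  cuts <- seq(0.24, 0.6, by = 0.04)
  n1s <- vapply(cuts, function(a) first_shell(g, r_min1 = a)$n1, numeric(1))
  expect_true(all(diff(n1s) >= -1e-12))
})

test_that("coordination number is stable under bin-width refinement", {
  spec <- hopping_spec(k_true = 5e8, N_Mg = 8, N_H2O = 240, t_sim = 5e-8,
                       dt = 1e-10, seed = 11)
  tr <- gen_hopping_traj(spec)
  n1_of <- function(bw) {
    g <- compute_rdf(tr, c("Mg", "Ow"), bin_width = bw, r_max = 0.9)
    first_shell(g, r_min1 = 0.3)$n1
  }
  expect_equal(n1_of(0.002), n1_of(0.004), tolerance = 0.02)
  expect_equal(n1_of(0.002), 6, tolerance = 0.1)
})

test_that("diffusion is zero for stationary particles and translation-invariant", {
  tr <- static_traj(list(Ow = matrix(runif(30, 0, 5), 10)), n_frames = 50,
                    box = 10)
  fit <- msd_diffusion(tr, "Ow", fit_window = c(1, 20))
  expect_equal(fit$D0, 0, tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-20)
  # rigid translation leaves D unchanged
  set.seed(3)
  tb <- gen_brownian(D = 0.7, n = 5, steps = 2000, dt = 1, box = 50, seed = 3)
  shifted <- tb
  for (k in 1:3) shifted$coords$Ow[, , k] <- (shifted$coords$Ow[, , k] + 1.3) %% 50
  f1 <- msd_diffusion(tb, "Ow", c(2, 50))
  f2 <- msd_diffusion(shifted, "Ow", c(2, 50))
  expect_equal(f1$D0, f2$D0, tolerance = 1e-10)
  expect_error(msd_diffusion(tb, "Ow", c(1, 2.5)), "fewer than 3")
})
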