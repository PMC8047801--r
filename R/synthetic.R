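# Synthetic-data generators with closed-form ground truths: shell-hopping
# trajectories with a known exchange rate, parametric RDFs with analytic
# Kirkwood-Buff integrals and coordination numbers, Brownian trajectories
# with known diffusion coefficient, analytic free-energy profiles with known
# binding observables, and overdamped Langevin walks on a radial PMF for
# recrossing-rich kinetics benchmarks.

#' Specification of a synthetic shell-hopping trajectory
#'
#' Parameters of the per-water two-state (bound/bulk) Markov process used by
#' [gen_hopping_traj]. The default composition mirrors a 1 us, 1 M MgCl2
#' simulation box; tests use scaled-down specs.
#'
#' @param k_true Target per-water exchange rate constant, s^-1 (the value
#'   the transition-counting estimator recovers in expectation).
#' @param N_Mg,N_H2O Ion and water counts.
#' @param t_sim Total simulated time, s.
#' @param dt Frame spacing, s; must satisfy `k_true * dt <= 0.1`.
#' @param R1 Bound-shell radius, nm (default 0.21, inside the default bound
#'   cutoff).
#' @param R2 Minimum bulk distance from any ion, nm (default 0.45, outside
#'   the default unbound cutoff).
#' @param jitter Radial jitter of bound waters, nm.
#' @param n1 Mean first-shell coordination number (default 6).
#' @param box Cubic box length, nm; default auto-sized from the ion count.
#' @param seed RNG seed.
#' @return A list of class `hopping_spec`.
#' @export
hopping_spec <- function(k_true = 8e5, N_Mg = 39, N_H2O = 2160,
                         t_sim = 1e-6, dt = 1e-9, R1 = 0.21, R2 = 0.45,
                         jitter = 0.02, n1 = 6, box = NULL, seed = 1L) {
  if (k_true < 0) stop("'k_true' must be nonnegative")
  if (k_true * dt > 0.1)
    stop("frame spacing too coarse: k_true * dt = ", signif(k_true * dt, 3),
         " > 0.1; reduce 'dt'")
  if (N_H2O <= n1 * N_Mg)
    stop("need N_H2O > n1 * N_Mg for a sub-unity bound fraction")
  if (R1 + jitter >= R2) stop("R1 + jitter must be below R2")
  ni_side <- ceiling(N_Mg^(1 / 3))
  spacing <- max(4 * R2, 2.0)
  if (is.null(box)) box <- ni_side * spacing
  structure(list(k_true = k_true, N_Mg = as.integer(N_Mg),
                 N_H2O = as.integer(N_H2O), t_sim = t_sim, dt = dt,
                 R1 = R1, R2 = R2, jitter = jitter, n1 = n1,
                 box = box, seed = as.integer(seed)),
            class = "hopping_spec")
}

# ions on a cubic sublattice, well separated
.ion_lattice <- function(N_Mg, box) {
  side <- ceiling(N_Mg^(1 / 3))
  idx <- seq_len(N_Mg) - 1L
  sp <- box / side
  cbind((idx %% side + 0.5) * sp,
        ((idx %/% side) %% side + 0.5) * sp,
        (idx %/% side^2 + 0.5) * sp)
}

#' Synthetic shell-hopping trajectory with known exchange rate
#'
#' Each water follows an independent two-state continuous-time Markov chain
#' between a bound shell (radius `R1` around an assigned ion, with radial
#' jitter) and bulk (uniform in the box at distance >= `R2` from every ion).
#' The off-rate is chosen so the transition-counting estimator recovers
#' `k_true` in expectation, and the stationary bound fraction equals
#' `n1 * N_Mg / N_H2O` (i.e. `n1` waters per ion on average). Exchange is
#' modelled as memoryless: only stationary counting statistics are emulated,
#' not the concerted exchange mechanism.
#'
#' @param spec A [hopping_spec].
#' @return A [trajectory] with roles `"Mg"` (static ions) and `"Ow"`.
#'   Attribute `"truth"` carries `k_true`, the per-water off/on rates and
#'   the stationary bound fraction.
#' @export
gen_hopping_traj <- function(spec) {
  stopifnot(inherits(spec, "hopping_spec"))
  set.seed(spec$seed)
  nf <- max(2L, round(spec$t_sim / spec$dt) + 1L)
  nw <- spec$N_H2O; ni <- spec$N_Mg
  p_b <- spec$n1 * ni / nw
  k_off <- spec$k_true * nw / (nw - spec$n1)
  k_on <- if (p_b < 1) k_off * p_b / (1 - p_b) else stop("bound fraction >= 1")
  p_off <- 1 - exp(-k_off * spec$dt)
  p_on <- 1 - exp(-k_on * spec$dt)
  ions <- .ion_lattice(ni, spec$box)
  # state: 0 = bulk, i>0 = bound to ion i
  state <- matrix(0L, nf, nw)
  bound0 <- stats::runif(nw) < p_b
  state[1, bound0] <- sample.int(ni, sum(bound0), replace = TRUE)
  if (nf >= 2L) for (t in 2:nf) {
    prev <- state[t - 1, ]
    u <- stats::runif(nw)
    cur <- prev
    go_off <- prev > 0L & u < p_off
    go_on <- prev == 0L & u < p_on
    cur[go_off] <- 0L
    if (any(go_on)) cur[go_on] <- sample.int(ni, sum(go_on), replace = TRUE)
    state[t, ] <- cur
  }
  # geometric embedding
  Ow <- array(NA_real_, c(nf, nw, 3))
  bulk_draw <- function(n) {
    out <- matrix(stats::runif(3 * n, 0, spec$box), n, 3)
    repeat {
      d2min <- rep(Inf, nrow(out))
      for (i in seq_len(ni)) {
        dd <- sweep(out, 2, ions[i, ])
        dd <- dd - spec$box * round(dd / spec$box)
        d2min <- pmin(d2min, rowSums(dd^2))
      }
      bad <- d2min < spec$R2^2
      if (!any(bad)) return(out)
      out[bad, ] <- matrix(stats::runif(3 * sum(bad), 0, spec$box), sum(bad), 3)
    }
  }
  for (t in seq_len(nf)) {
    st <- state[t, ]
    nb <- sum(st > 0L)
    if (nb > 0L) {
      u <- matrix(stats::rnorm(3 * nb), nb, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- stats::runif(nb, spec$R1 - spec$jitter, spec$R1 + spec$jitter)
      pos <- ions[st[st > 0L], , drop = FALSE] + u * rad
      Ow[t, st > 0L, ] <- pos %% spec$box
    }
    if (nb < nw) Ow[t, st == 0L, ] <- bulk_draw(nw - nb)
  }
  Mg <- array(rep(ions, each = nf), c(nf, ni, 3))
  times <- (seq_len(nf) - 1L) * spec$dt * 1e12   # ps
  traj <- trajectory(times, list(Mg = Mg, Ow = Ow), rep(spec$box, 3))
  attr(traj, "truth") <- list(k_true = spec$k_true, k_off = k_off,
                              k_on = k_on, p_bound = p_b, spec = spec)
  traj
}

#' Parametric RDF with closed-form observables
#'
#' Families:
#' \describe{
#'   \item{`ideal`}{g = 1 everywhere; G = 0, n1(a) = (4/3) pi rho a^3.}
#'   \item{`excluded-volume`}{g = 0 below `d`, 1 beyond; G = -(4/3) pi d^3.}
#'   \item{`gaussian-shell`}{g = 1 + A N(r; mu, s) / (4 pi rho r^2), a shell
#'     carrying exactly `A` partners; the first-peak position and shell
#'     integral have closed forms attached.}
#' }
#'
#' @param family One of `"ideal"`, `"excluded-volume"`, `"gaussian-shell"`.
#' @param params Named list: `rho` (all families), `d` (excluded-volume),
#'   `A`, `mu`, `s` (gaussian-shell).
#' @param grid Distance grid, nm (default 0.002-nm bins to 1.5 nm).
#' @return An [rdf] with attribute `"truth"`: list with `G` (nm^3) and,
#'   where defined, `R1`, `n1` and the cutoff `r_min1` they refer to.
#' @export
gen_rdf <- function(family = c("ideal", "excluded-volume", "gaussian-shell"),
                    params = list(), grid = seq(0.002, 1.5, by = 0.002)) {
  family <- match.arg(family)
  rho <- params$rho %||% 1.0
  if (rho <= 0) stop("'rho' must be positive")
  if (family == "ideal") {
    g <- rep(1, length(grid))
    truth <- list(G = 0, n1 = function(a) (4 / 3) * pi * rho * a^3)
  } else if (family == "excluded-volume") {
    d <- params$d %||% 0.3
    if (d <= 0 || d >= max(grid)) stop("'d' must lie inside the grid")
    g <- as.numeric(grid >= d)
    truth <- list(G = -(4 / 3) * pi * d^3,
                  n1 = function(a) (4 / 3) * pi * rho * pmax(a^3 - d^3, 0))
  } else {
    A <- params$A %||% 6; mu <- params$mu %||% 0.21; s <- params$s %||% 0.01
    if (A < 0 || mu <= 0 || s <= 0) stop("gaussian-shell needs A >= 0, mu > 0, s > 0")
    dens <- stats::dnorm(grid, mu, s)
    g <- 1 + A * dens / (4 * pi * rho * grid^2)
    if (any(g < 0)) stop("parameters imply negative g")
    r_min1 <- min(mu + 4 * s, max(grid))
    truth <- list(
      G = A / rho * (stats::pnorm(max(grid), mu, s) - stats::pnorm(0, mu, s)),
      R1 = (mu + sqrt(mu^2 - 8 * s^2)) / 2,   # peak of N(mu,s)/r^2
      r_min1 = r_min1,
      n1 = A * (stats::pnorm(r_min1, mu, s) - stats::pnorm(0, mu, s)) +
           (4 / 3) * pi * rho * r_min1^3)
  }
  out <- rdf(grid, g, rho_bulk = rho, pair_tag = paste0("synthetic-", family))
  attr(out, "truth") <- truth
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brownian trajectory with known diffusion coefficient
#'
#' Independent Gaussian displacement processes with per-step variance
#' `2 D dt` per dimension, wrapped into a cubic periodic box (unwrap with
#' the MSD machinery when analysing).
#'
#' @param D Diffusion coefficient in 1e-5 cm^2/s.
#' @param n Number of particles.
#' @param steps Number of frames.
#' @param dt Frame spacing, ps.
#' @param box Cubic box length, nm (default 10).
#' @param seed RNG seed.
#' @param role Role name for the particles (default `"Ow"`).
#' @return A [trajectory]; attribute `"truth"` holds `D`.
#' @export
gen_brownian <- function(D, n = 10L, steps = 1000L, dt = 1, box = 10,
                         seed = 1L, role = "Ow") {
  stopifnot(D >= 0, n >= 1L, steps >= 2L, dt > 0, box > 0)
  set.seed(seed)
  D_nmps <- D * 1e-3                       # 1e-5 cm^2/s -> nm^2/ps
  sdstep <- sqrt(2 * D_nmps * dt)
  X <- array(NA_real_, c(steps, n, 3))
  X[1, , ] <- matrix(stats::runif(3 * n, 0, box), n, 3)
  if (sdstep > 0) {
    for (k in 1:3) {
      disp <- matrix(stats::rnorm((steps - 1L) * n, sd = sdstep), steps - 1L, n)
      start <- matrix(X[1, , k], 1L, n)
      X[, , k] <- rbind(start,
                        matrix(apply(disp, 2, cumsum), steps - 1L, n) +
                          matrix(start, steps - 1L, n, byrow = TRUE))
    }
  } else {
    for (t in 2:steps) X[t, , ] <- X[1, , ]
  }
  X <- X %% box
  co <- list(); co[[role]] <- X
  traj <- trajectory((seq_len(steps) - 1L) * dt, co, rep(box, 3))
  attr(traj, "truth") <- list(D = D)
  traj
}

#' Analytic free-energy profile with known binding observables
#'
#' Gaussian-well plus Gaussian-barrier profile
#' \deqn{F(r) = -w\, e^{-(r - r_w)^2 / 2\sigma_w^2}
#'            + b\, e^{-(r - r_b)^2 / 2\sigma_b^2}}
#' in k_B T units, zero in bulk by construction. The attached ground truths
#' (binding distance, barrier position/height, standard-state binding
#' affinity) are computed from the analytic form by adaptive quadrature and
#' continuous optimization, independent of the grid used for the profile.
#'
#' @param well_depth Well depth `w`, k_B T (>= 0).
#' @param well_pos Well position, nm.
#' @param barrier Barrier Gaussian amplitude `b`, k_B T.
#' @param barrier_pos Barrier position, nm; must exceed `well_pos`.
#' @param grid Distance grid, nm.
#' @param well_width,barrier_width Gaussian widths, nm.
#' @param T Temperature, K.
#' @param standard_volume Standard-state volume for the attached affinity.
#' @return A [free_energy_profile]; attribute `"truth"` holds `R_b`,
#'   `r_barrier`, `barrier` (height above the well minimum) and `dG_b0`.
#' @export
gen_profile <- function(well_depth = 6, well_pos = 0.21, barrier = 4,
                        barrier_pos = 0.30,
                        grid = seq(0.12, 1.2, by = 0.002),
                        well_width = 0.015, barrier_width = 0.02, T = 300,
                        standard_volume = STANDARD_VOLUME) {
  if (barrier_pos <= well_pos)
    stop("'barrier_pos' must exceed 'well_pos'")
  if (well_depth < 0) stop("'well_depth' must be nonnegative")
  f <- function(r) -well_depth * exp(-(r - well_pos)^2 / (2 * well_width^2)) +
                    barrier * exp(-(r - barrier_pos)^2 / (2 * barrier_width^2))
  F <- f(grid)
  prof <- free_energy_profile(grid, F, T = T, tag = "synthetic")
  Rb <- stats::optimize(f, c(min(grid), barrier_pos))$minimum
  rbar <- stats::optimize(f, c(well_pos, min(barrier_pos + 6 * barrier_width,
                                             max(grid))),
                          maximum = TRUE)$maximum
  I <- stats::integrate(function(r) 4 * pi * r^2 * exp(-f(r)),
                        min(grid), rbar, rel.tol = 1e-10)$value
  attr(prof, "truth") <- list(R_b = Rb, r_barrier = rbar,
                              barrier = f(rbar) - f(Rb),
                              dG_b0 = -log(I / standard_volume))
  prof
}

#' Overdamped Langevin walk on a radial free-energy profile
#'
#' Integrates \eqn{dr = -D \beta F'(r)\, dt + \sqrt{2 D dt}\,\xi} for several
#' independent walkers with reflecting boundaries, producing recrossing-rich
#' one-dimensional trajectories for benchmarking the transition-counting
#' estimator against the TST upper bound on the same profile.
#'
#' @param profile_fun Function of `r` (nm) returning F in k_B T.
#' @param r_range Domain `c(lo, hi)`, nm (reflecting boundaries).
#' @param D Diffusion coefficient along the coordinate, nm^2/ps.
#' @param dt Time step, ps.
#' @param steps Number of recorded steps.
#' @param walkers Number of independent walkers.
#' @param r0 Initial position(s), nm (default mid-well: `r_range[1]`).
#' @param seed RNG seed.
#' @return List of class `radial_walk`: matrix `r` `[steps, walkers]`,
#'   `times` (ps), `dt`.
#' @export
gen_langevin_radial <- function(profile_fun, r_range, D = 1e-3, dt = 0.05,
                                steps = 20000L, walkers = 8L,
                                r0 = NULL, seed = 1L) {
  stopifnot(is.function(profile_fun), length(r_range) == 2L,
            r_range[1] < r_range[2])
  set.seed(seed)
  h <- 1e-5
  grad <- function(r) (profile_fun(r + h) - profile_fun(r - h)) / (2 * h)
  if (is.null(r0)) r0 <- r_range[1] + 0.1 * diff(r_range)
  r <- matrix(NA_real_, steps, walkers)
  cur <- rep_len(r0, walkers)
  sdstep <- sqrt(2 * D * dt)
  for (t in seq_len(steps)) {
    cur <- cur - D * grad(cur) * dt + stats::rnorm(walkers, sd = sdstep)
    # reflecting boundaries
    cur <- ifelse(cur < r_range[1], 2 * r_range[1] - cur, cur)
    cur <- ifelse(cur > r_range[2], 2 * r_range[2] - cur, cur)
    cur <- pmin(pmax(cur, r_range[1]), r_range[2])
    r[t, ] <- cur
  }
  structure(list(r = r, times = (seq_len(steps) - 1L) * dt, dt = dt),
            class = "radial_walk")
}

#' Transition-counting rate from one-dimensional radial walks
#'
#' Applies the dual-cutoff hysteresis labeling to each walker's distance
#' series and returns transitions per unit cumulative bound time,
#' \eqn{k = N / (2 T_{bound})}, the per-coordinate analogue of the
#' trajectory estimator.
#'
#' @param walk A `radial_walk` from [gen_langevin_radial].
#' @param ind A [shell_indicator].
#' @return List with `k` (s^-1), `N`, and `t_bound` (s).
#' @export
radial_exchange_rate <- function(walk, ind) {
  stopifnot(inherits(walk, "radial_walk"), inherits(ind, "shell_indicator"))
  mid <- (ind$r_bound + ind$r_unbound) / 2
  N <- 0L; bound_frames <- 0L
  for (w in seq_len(ncol(walk$r))) {
    d <- walk$r[, w]
    v <- ifelse(d < ind$r_bound, 1L, ifelse(d > ind$r_unbound, 0L, NA_integer_))
    first <- if (d[1] < mid) 1L else 0L
    s <- .locf(v, first)
    N <- N + sum(s[-1] != s[-length(s)])
    bound_frames <- bound_frames + sum(s == 1L)
  }
  t_bound <- bound_frames * walk$dt * 1e-12   # ps -> s
  list(k = if (t_bound > 0) N / (2 * t_bound) else 0, N = N, t_bound = t_bound)
}
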