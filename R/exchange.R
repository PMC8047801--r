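# Water-exchange kinetics: dual-cutoff state labeling with hysteresis,
# transition counting, the closed-form rate constant, block-averaged errors,
# and a transition-state-theory upper-bound comparator.

BOLTZMANN_KB <- 0.008314462618  # kJ/(mol K)

#' Dual-cutoff shell indicator
#'
#' Defines the bound and unbound state of a water molecule with respect to
#' the first hydration shell using two cutoff distances. A water is committed
#' bound below `r_bound`, committed unbound above `r_unbound`, and carries
#' its previous committed state in between (hysteresis suppresses
#' recrossing noise). Defaults correspond to the Mg-Ow first RDF minimum and
#' the second-shell onset.
#'
#' @param r_bound Bound cutoff, nm (default 0.28).
#' @param r_unbound Unbound cutoff, nm (default 0.40); must exceed `r_bound`.
#' @return An object of class `shell_indicator`.
#' @export
shell_indicator <- function(r_bound = 0.28, r_unbound = 0.40) {
  stopifnot(is.numeric(r_bound), is.numeric(r_unbound))
  if (r_bound <= 0) stop("'r_bound' must be positive")
  if (r_bound >= r_unbound)
    stop("'r_bound' (", r_bound, ") must be smaller than 'r_unbound' (",
         r_unbound, ")")
  structure(list(r_bound = r_bound, r_unbound = r_unbound),
            class = "shell_indicator")
}

# forward-fill NAs; leading NAs filled with `first`
.locf <- function(v, first) {
  if (is.na(v[1])) v[1] <- first
  idx <- cummax(seq_along(v) * (!is.na(v)))
  v[idx]
}

#' Label bound/unbound states of every water molecule
#'
#' Applies the dual-cutoff indicator to the minimum Mg-Ow distance of each
#' water in each frame. State encoding: positive integer i = bound to ion i,
#' 0 = unbound; frames between the cutoffs inherit the last committed state.
#' The initial state of a water starting between the cutoffs is resolved by
#' the nearer cutoff.
#'
#' @param traj A [trajectory] containing `"Mg"` and `"Ow"` roles.
#' @param ind A [shell_indicator].
#' @return An object of class `state_series`: integer state matrix
#'   `[frames, waters]` plus `times`.
#' @export
label_states <- function(traj, ind) {
  stopifnot(inherits(traj, "trajectory"), inherits(ind, "shell_indicator"))
  if (is.null(traj$coords[["Mg"]]) || is.null(traj$coords[["Ow"]]))
    stop("trajectory must contain 'Mg' and 'Ow' roles")
  d <- pair_distances(traj, "Ow", "Mg")       # [frames, waters, ions]
  nf <- dim(d)[1]; nw <- dim(d)[2]; ni <- dim(d)[3]
  dmin <- matrix(d[, , 1], nf, nw)
  imin <- matrix(1L, nf, nw)
  if (ni > 1L) for (j in 2:ni) {
    dj <- matrix(d[, , j], nf, nw)
    m <- dj < dmin
    imin[m] <- j
    dmin[m] <- dj[m]
  }
  states <- matrix(NA_integer_, nf, nw)
  mid <- (ind$r_bound + ind$r_unbound) / 2
  for (w in seq_len(nw)) {
    v <- ifelse(dmin[, w] < ind$r_bound, imin[, w],
                ifelse(dmin[, w] > ind$r_unbound, 0L, NA_integer_))
    first <- if (dmin[1, w] < mid) imin[1, w] else 0L
    states[, w] <- .locf(v, first)
  }
  structure(list(states = states, times = traj$times,
                 r_bound = ind$r_bound, r_unbound = ind$r_unbound),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("State series: %d frames x %d waters, %d transitions\n",
              nrow(x$states), ncol(x$states), count_transitions(x)))
  invisible(x)
}

#' Count committed-state transitions
#'
#' Total number of committed-state changes summed over all waters; the
#' first-to-second-shell exchange and the reverse transition each count as
#' individual events.
#'
#' @param s A [state_series] (or a plain state matrix `[frames, waters]`).
#' @return Integer transition count.
#' @export
count_transitions <- function(s) {
  m <- if (inherits(s, "state_series")) s$states else as.matrix(s)
  if (nrow(m) < 2L) return(0L)
  sum(m[-1, , drop = FALSE] != m[-nrow(m), , drop = FALSE])
}

#' Ideal 1 M MgCl2 box composition
#'
#' The default composition used when a simulation-box composition is not
#' supplied: water-to-magnesium ratio 55.5:1 (1 M), with a fractional
#' effective ion count so the ratio is exact.
#'
#' @param N_H2O Number of water molecules (default 2160).
#' @param ratio Water:Mg ratio (default 55.5, i.e. 1 mol/L).
#' @return List with `N_H2O` and `N_Mg`.
#' @export
ideal_composition <- function(N_H2O = 2160, ratio = 55.5) {
  list(N_H2O = N_H2O, N_Mg = N_H2O / ratio)
}

#' Water-exchange rate constant from transition counts
#'
#' Closed-form transition-counting estimator:
#' \deqn{p_B = n_1/(N_{H_2O} - n_1), \quad
#'       t_B = N_{Mg}\, p_B\, t_{sim}, \quad
#'       k = N / (2 N_{H_2O} t_B)}
#' where \eqn{t_B} is the cumulative time a water molecule spends in the
#' first hydration shell of any ion and the division by 2 converts
#' bidirectional transition counts into exchange events.
#'
#' @param N Total transition count (both directions).
#' @param N_H2O Number of water molecules; must exceed `n1`.
#' @param N_Mg Number of ions (fractional values allowed for idealized
#'   compositions).
#' @param t_sim Total simulation time, seconds.
#' @param n1 First-shell coordination number (default 6 for Mg2+).
#' @param N_err Optional uncertainty on `N`; propagated linearly to `k`.
#' @return An object of class `exchange_stats` with fields `N`, `N_H2O`,
#'   `N_Mg`, `t_sim`, `p_B`, `t_B`, `k` and `k_err` (s^-1).
#' @examples
#' comp <- ideal_composition()
#' exchange_rate(376, comp$N_H2O, comp$N_Mg, t_sim = 1e-6)  # ~8e5 s^-1
#' @export
exchange_rate <- function(N, N_H2O, N_Mg, t_sim, n1 = 6, N_err = NA_real_) {
  stopifnot(is.numeric(N), N >= 0, is.numeric(t_sim), t_sim > 0,
            is.numeric(N_Mg), N_Mg > 0)
  if (N_H2O <= n1)
    stop("N_H2O (", N_H2O, ") must exceed the coordination number n1 (", n1, ")")
  p_B <- n1 / (N_H2O - n1)
  t_B <- N_Mg * p_B * t_sim
  k <- N / (2 * N_H2O * t_B)
  k_err <- if (is.finite(N_err)) N_err / (2 * N_H2O * t_B) else NA_real_
  structure(list(N = N, N_H2O = N_H2O, N_Mg = N_Mg, t_sim = t_sim, n1 = n1,
                 p_B = p_B, t_B = t_B, k = k, k_err = k_err),
            class = "exchange_stats")
}

#' @export
print.exchange_stats <- function(x, ...) {
  cat("Water-exchange statistics\n")
  cat(sprintf("  composition : N_H2O = %g, N_Mg = %g (ratio %.4g)\n",
              x$N_H2O, x$N_Mg, x$N_H2O / x$N_Mg))
  cat(sprintf("  N           : %g transitions in %.4g s\n", x$N, x$t_sim))
  cat(sprintf("  p_B         : %.6g\n", x$p_B))
  cat(sprintf("  t_B         : %.6g s\n", x$t_B))
  cat(sprintf("  k           : %.4g", x$k))
  if (is.finite(x$k_err)) cat(sprintf(" +- %.2g", x$k_err))
  cat(" s^-1\n")
  invisible(x)
}

#' Expected transition count at a given rate constant
#'
#' Inverts the transition-counting closed form for `N`:
#' \eqn{N = 2 k N_{H_2O} t_B}.
#'
#' @inheritParams exchange_rate
#' @param k Exchange rate constant, s^-1.
#' @return Expected transition count (not rounded).
#' @export
expected_transitions <- function(k, N_H2O, N_Mg, t_sim, n1 = 6) {
  if (N_H2O <= n1)
    stop("N_H2O must exceed the coordination number n1")
  p_B <- n1 / (N_H2O - n1)
  t_B <- N_Mg * p_B * t_sim
  2 * k * N_H2O * t_B
}

#' Block-averaged error estimate
#'
#' Splits the input into contiguous blocks (truncating the remainder),
#' recomputes a statistic per block, and returns the standard deviation of
#' block values divided by the square root of the number of blocks. If the
#' input already has one value per block it is used directly.
#'
#' @param x Numeric vector: either a per-frame series or precomputed
#'   per-block statistics.
#' @param n_blocks Number of blocks (>= 2; default `length(x)` when `x` is
#'   already per-block).
#' @param stat Function applied to each block (default [mean]); ignored when
#'   `length(x) == n_blocks`.
#' @return List with `mean`, `error`, and the per-block `blocks` values.
#' @export
block_error <- function(x, n_blocks = 2L, stat = mean) {
  stopifnot(is.numeric(x), n_blocks >= 2L)
  if (length(x) < n_blocks)
    stop("input has fewer elements (", length(x), ") than blocks (", n_blocks, ")")
  if (length(x) == n_blocks) {
    vals <- x
  } else {
    blk <- floor(length(x) / n_blocks)
    vals <- vapply(seq_len(n_blocks),
                   function(b) stat(x[((b - 1) * blk + 1):(b * blk)]),
                   numeric(1))
  }
  list(mean = mean(vals), error = stats::sd(vals) / sqrt(n_blocks),
       blocks = vals)
}

#' Full water-exchange pipeline on a trajectory
#'
#' Labels states, counts transitions, and applies the closed-form estimator
#' with a block-averaged error on the transition count (default 2 blocks).
#'
#' @param traj A [trajectory] with `"Mg"` and `"Ow"` roles.
#' @param ind A [shell_indicator].
#' @param t_sim Total simulated time in seconds; defaults to the trajectory
#'   time span (ps) converted to seconds.
#' @param n1 Coordination number (default 6).
#' @param n_blocks Blocks for the error estimate (default 2).
#' @return An `exchange_stats` object.
#' @export
water_exchange <- function(traj, ind = shell_indicator(), t_sim = NULL,
                           n1 = 6, n_blocks = 2L) {
  s <- label_states(traj, ind)
  N <- count_transitions(s)
  nf <- nrow(s$states)
  if (is.null(t_sim)) t_sim <- diff(range(traj$times)) * 1e-12
  blk <- floor(nf / n_blocks)
  Nb <- vapply(seq_len(n_blocks), function(b) {
    as.numeric(count_transitions(s$states[((b - 1) * blk + 1):(b * blk), ,
                                          drop = FALSE]))
  }, numeric(1))
  be <- block_error(Nb * n_blocks, n_blocks = n_blocks)  # scale blocks to full length
  exchange_rate(N, N_H2O = ncol(s$states), N_Mg = dim(traj$coords[["Mg"]])[2],
                t_sim = t_sim, n1 = n1, N_err = be$error)
}

#' Transition-state-theory rate from a 1-D free-energy profile
#'
#' One-dimensional TST estimate
#' \deqn{k_{TST} = \sqrt{k_B T / (2\pi\mu)}\; e^{-\beta F(r^\ddagger)} /
#'       \int_{well} e^{-\beta F(r)}\,dr}
#' with \eqn{r^\ddagger} the barrier top (first interior maximum after the
#' well minimum) and the well integral running from the start of the grid to
#' \eqn{r^\ddagger}. Because recrossings of the dividing surface are
#' neglected, this is an upper bound on the transition-counting rate.
#'
#' @param profile A [free_energy_profile] (F in units of k_B T).
#' @param reduced_mass Reduced mass of the reactive pair, g/mol (amu).
#' @param T Temperature, K (default the profile's temperature).
#' @return Rate constant, s^-1.
#' @export
tst_rate <- function(profile, reduced_mass, T = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (is.null(T)) T <- profile$T
  r <- profile$r; F <- profile$F; n <- length(r)
  iwell <- which.min(F)
  ibar <- NA_integer_
  if (iwell < n - 1) for (i in (iwell + 1):(n - 1)) {
    if (F[i] > F[i - 1] && F[i] >= F[i + 1]) { ibar <- i; break }
  }
  if (is.na(ibar))
    stop("profile has no interior maximum after the well: cannot locate a barrier")
  sel <- seq_len(ibar)
  w <- exp(-(F[sel] - F[iwell]))
  Z_well <- sum(diff(r[sel]) * (w[-1] + w[-length(w)]) / 2)   # nm
  # sqrt(kJ/mol / (g/mol)) = 1 nm/ps exactly in these units
  v <- sqrt(BOLTZMANN_KB * T / (2 * pi * reduced_mass))       # nm/ps
  k_ps <- v * exp(-(F[ibar] - F[iwell])) / Z_well             # 1/ps
  k_ps * 1e12
}
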