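# Ion-binding thermodynamics from 1-D free-energy profiles: standard-state
# binding affinity dG_b0, binding distance R_b, and barrier heights.

#' Standard-state volume for a 1 M reference concentration
#'
#' 1/(1 mol/L x N_A) expressed in nm^3 per molecule.
#' @format Length-one numeric, 1.661 nm^3.
#' @export
STANDARD_VOLUME <- 1.661

#' One-dimensional free-energy profile
#'
#' A potential of mean force along a distance coordinate, stored in units of
#' \eqn{k_B T}.
#'
#' @param r Strictly increasing distance grid, nm.
#' @param F Free energy at `r`, in k_B T units (use `units = "kJ/mol"` to
#'   convert on input).
#' @param T Temperature in K (default 300); required for unit conversion
#'   and for [tst_rate].
#' @param tag Reaction-coordinate identifier, e.g. `"MgOw"` or `"MgOP"`.
#' @param units `"kBT"` (default) or `"kJ/mol"`.
#' @return An object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(r, F, T = 300, tag = "MgOw",
                                units = c("kBT", "kJ/mol")) {
  units <- match.arg(units)
  stopifnot(is.numeric(r), is.numeric(F), length(r) == length(F),
            length(r) >= 5L)
  if (any(diff(r) <= 0)) stop("'r' grid must be strictly increasing")
  if (any(!is.finite(F))) stop("'F' must be finite everywhere on the grid")
  if (units == "kJ/mol") F <- F / (BOLTZMANN_KB * T)
  structure(list(r = r, F = F, T = T, tag = tag),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile [%s]: %d points on %.3g-%.3g nm, T = %g K\n",
              x$tag, length(x$r), min(x$r), max(x$r), x$T))
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$r, x$F, type = "l", xlab = "r [nm]",
                 ylab = expression(F ~ "[" * k[B] * T * "]"), main = x$tag, ...)
  invisible(x)
}

# First interior maximum of F after the global minimum of the leading part.
.find_barrier <- function(r, F) {
  n <- length(r)
  iwell <- which.min(F)
  if (iwell >= n - 1) return(NA_integer_)
  for (i in (iwell + 1):(n - 1)) {
    if (F[i] > F[i - 1] && F[i] >= F[i + 1]) return(i)
  }
  NA_integer_
}

# Shift F so the bulk plateau (outermost fraction of the grid) is zero.
.anchor_bulk <- function(profile, bulk_fraction = 0.1, plateau_tol = 0.5) {
  n <- length(profile$r)
  tail_idx <- seq.int(ceiling(n * (1 - bulk_fraction)), n)
  tailF <- profile$F[tail_idx]
  if (stats::sd(tailF) > plateau_tol)
    stop("no bulk plateau detected over the outermost ",
         round(bulk_fraction * 100), "% of the grid (spread ",
         signif(stats::sd(tailF), 3), " k_BT); supply a longer-range profile")
  profile$F <- profile$F - mean(tailF)
  profile
}

#' Standard-state binding affinity from a free-energy profile
#'
#' Integrates the Boltzmann weight of the bound region,
#' \deqn{\Delta G_b^0 = -\ln\left(\frac{1}{V^0}\int_{r_{start}}^{r^\ddagger}
#'       4\pi r^2 e^{-F(r)}\, dr\right)}
#' with \eqn{F} shifted so the bulk plateau (outermost 10% of the grid) is
#' zero, \eqn{r^\ddagger} the barrier top separating the bound (inner-sphere)
#' state from the rest of the profile, and \eqn{V^0} the 1 M standard-state
#' volume. The result is gauge-invariant under vertical shifts of `F`.
#'
#' @param profile A [free_energy_profile].
#' @param standard_volume Standard-state volume, nm^3 (default
#'   [STANDARD_VOLUME]). A spherical-shell standard state is used.
#' @param r_boundary Optional explicit bound-region boundary (nm),
#'   overriding barrier detection (needed e.g. for barrierless model
#'   profiles).
#' @param apply_jacobian Multiply by the radial 4 pi r^2 weight (default
#'   `TRUE`). Disable for profiles already Jacobian-corrected; the integrand
#'   is then taken as a volume density per nm^2 of cross-section.
#' @param bulk_fraction Fraction of the outer grid used for plateau
#'   anchoring (default 0.1).
#' @param plateau_tol Maximum k_B T spread tolerated over the anchoring
#'   region before the profile is rejected as non-converged.
#' @return \eqn{\Delta G_b^0} in k_B T units (negative = bound).
#' @export
binding_affinity <- function(profile, standard_volume = STANDARD_VOLUME,
                             r_boundary = NULL, apply_jacobian = TRUE,
                             bulk_fraction = 0.1, plateau_tol = 0.5) {
  stopifnot(inherits(profile, "free_energy_profile"))
  profile <- .anchor_bulk(profile, bulk_fraction, plateau_tol)
  r <- profile$r; F <- profile$F
  if (is.null(r_boundary)) {
    ib <- .find_barrier(r, F)
    if (is.na(ib))
      stop("no barrier found after the inner minimum; pass 'r_boundary' explicitly")
    r_boundary <- r[ib]
  }
  sel <- r <= r_boundary
  if (sum(sel) < 3L) stop("bound region covers fewer than 3 grid points")
  w <- exp(-F[sel])
  integrand <- if (apply_jacobian) 4 * pi * r[sel]^2 * w else w
  I <- sum(diff(r[sel]) * (integrand[-1] + integrand[-sum(sel)]) / 2)
  -log(I / standard_volume)
}

#' Binding distance from a free-energy profile
#'
#' Location of the global minimum before the first barrier, refined by
#' parabolic interpolation through the three surrounding grid points.
#' Invariant under vertical shifts of `F`.
#'
#' @param profile A [free_energy_profile] with an inner minimum.
#' @return \eqn{R_b} in nm.
#' @export
binding_distance <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  r <- profile$r; F <- profile$F
  ib <- .find_barrier(r, F)
  upto <- if (is.na(ib)) length(r) else ib
  imin <- which.min(F[seq_len(upto)])
  if (imin == 1L || imin == length(r)) return(r[imin])
  .parabolic_vertex(r, F, imin)
}

#' Barrier height of a free-energy profile
#'
#' \eqn{F(r^\ddagger) - F(r_{min})} with the reference minimum either the
#' inner (bound) minimum before the barrier or the outer minimum after it.
#' Shift-invariant.
#'
#' @param profile A [free_energy_profile].
#' @param reference `"inner-minimum"` (default) or `"outer-minimum"`.
#' @return Barrier height in k_B T.
#' @export
barrier_height <- function(profile,
                           reference = c("inner-minimum", "outer-minimum")) {
  reference <- match.arg(reference)
  r <- profile$r; F <- profile$F; n <- length(r)
  ib <- .find_barrier(r, F)
  if (is.na(ib)) stop("profile has no interior barrier")
  if (reference == "inner-minimum") {
    iref <- which.min(F[seq_len(ib)])
  } else {
    if (ib >= n) stop("no outer region beyond the barrier")
    iref <- ib - 1L + which.min(F[ib:n])
  }
  F[ib] - F[iref]
}

#' Convert a log stability constant to a binding free energy
#'
#' \deqn{\Delta G_b^0 = -\ln(10) \log K}
#'
#' @param logK Decadic log of the stability constant.
#' @return Free energy in k_B T (e.g. log K = 0.45 gives -1.036).
#' @export
logK_to_dG <- function(logK) -log(10) * logK
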