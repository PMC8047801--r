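# Pair-potential algebra: 12-6 / 12-6-4 Lennard-Jones energies, Coulomb term,
# standard and scaled Lorentz-Berthelot combination rules, builtin parameter sets.
# Internal units throughout: nm, kJ/mol, elementary charge e, ps.

#' Coulomb constant in internal units
#'
#' \eqn{k_e = 1/(4\pi\epsilon_0)} expressed in kJ nm / (mol e^2), derived from
#' CODATA values of the vacuum permittivity, elementary charge and Avogadro
#' constant. This is the conversion constant used by major MD engines.
#'
#' @format A length-one numeric, 138.935458 kJ nm mol^-1 e^-2.
#' @export
COULOMB_KE <- 138.935458

#' TIP3P water oxygen Lennard-Jones parameters
#'
#' The oxygen site of the TIP3P water model (\eqn{\sigma_o} = 0.315061 nm,
#' \eqn{\epsilon_o} = 0.6364 kJ/mol); the hydrogen sites carry no LJ term.
#' All builtin Mg2+ parameter sets are defined in combination with this water
#' model and are not transferable to other water models.
#'
#' @format An [lj_params] object.
#' @export
TIP3P_OXYGEN <- NULL  # assigned in .onLoad-free fashion below

#' Lennard-Jones parameters for a single species
#'
#' @param sigma LJ diameter in nm; must be positive.
#' @param epsilon LJ well depth in kJ/mol; must be nonnegative.
#' @return An object of class `lj_params` with fields `sigma` and `epsilon`.
#' @examples
#' lj_params(0.315061, 0.6364)
#' @export
lj_params <- function(sigma, epsilon) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L,
            is.numeric(epsilon), length(epsilon) == 1L)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive length (nm), got ", sigma)
  if (!is.finite(epsilon) || epsilon < 0)
    stop("'epsilon' must be a nonnegative energy (kJ/mol), got ", epsilon)
  structure(list(sigma = sigma, epsilon = epsilon), class = "lj_params")
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("LJ parameters: sigma = %.6g nm, epsilon = %.6g kJ/mol\n",
              x$sigma, x$epsilon))
  invisible(x)
}

# evaluate TIP3P_OXYGEN now that the constructor exists
TIP3P_OXYGEN <- lj_params(0.315061, 0.6364)

#' An ion (or atom) species model
#'
#' A charged point particle with Lennard-Jones parameters, the basic species
#' record used by the combination rules and the topology emitter.
#'
#' @param name Nonempty species identifier, e.g. `"Mg"`.
#' @param charge Signed charge in units of the elementary charge.
#' @param lj An [lj_params] object.
#' @param mass Optional atomic mass in g/mol (used only when emitting
#'   topology files); default `NA`.
#' @return An object of class `ion_model`.
#' @export
ion_model <- function(name, charge, lj, mass = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("species 'name' must be nonempty")
  stopifnot(is.numeric(charge), length(charge) == 1L, is.finite(charge))
  if (!inherits(lj, "lj_params")) stop("'lj' must be an lj_params object")
  structure(list(name = name, charge = charge, lj = lj, mass = mass),
            class = "ion_model")
}

#' @export
print.ion_model <- function(x, ...) {
  cat(sprintf("Ion model '%s': q = %+g e, sigma = %.6g nm, epsilon = %.6g kJ/mol\n",
              x$name, x$charge, x$lj$sigma, x$lj$epsilon))
  invisible(x)
}

#' Effective pair interaction parameters
#'
#' Holds the pair-specific \eqn{\sigma_{ij}}, \eqn{\epsilon_{ij}} and optional
#' \eqn{C_4} coefficient of the 12-6-4 extension. `c4` is stored positive and
#' enters the energy as an attractive \eqn{-C_4/r^4} term mimicking
#' charge-induced dipole interactions.
#'
#' @param sigma_ij Pair LJ diameter, nm (> 0).
#' @param epsilon_ij Pair well depth, kJ/mol (>= 0).
#' @param c4 12-6-4 coefficient, kJ nm^4 / mol (>= 0, default 0 gives the
#'   pure 12-6 potential).
#' @param provenance One of `"standard-rule"`, `"scaled-rule"`, `"explicit"`.
#' @return An object of class `pair_interaction`.
#' @export
pair_interaction <- function(sigma_ij, epsilon_ij, c4 = 0,
                             provenance = c("explicit", "standard-rule",
                                            "scaled-rule")) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(sigma_ij), is.numeric(epsilon_ij), is.numeric(c4))
  if (!is.finite(sigma_ij) || sigma_ij <= 0)
    stop("'sigma_ij' must be positive, got ", sigma_ij)
  if (!is.finite(epsilon_ij) || epsilon_ij < 0)
    stop("'epsilon_ij' must be nonnegative, got ", epsilon_ij)
  if (!is.finite(c4) || c4 < 0)
    stop("'c4' must be nonnegative, got ", c4)
  structure(list(sigma_ij = sigma_ij, epsilon_ij = epsilon_ij, c4 = c4,
                 provenance = provenance),
            class = "pair_interaction")
}

#' @export
print.pair_interaction <- function(x, ...) {
  cat(sprintf("Pair interaction (%s): sigma_ij = %.6g nm, epsilon_ij = %.6g kJ/mol",
              x$provenance, x$sigma_ij, x$epsilon_ij))
  if (x$c4 > 0) cat(sprintf(", C4 = %.6g kJ nm^4/mol", x$c4))
  cat("\n")
  invisible(x)
}

#' Combination-rule scaling factors for a partner class
#'
#' Multiplicative modifications \eqn{\lambda_\sigma}, \eqn{\lambda_\epsilon}
#' applied to the Lorentz-Berthelot rules for one selected partner class
#' (e.g. chloride or the RNA atoms), leaving ion-water interactions untouched.
#'
#' @param lambda_sigma,lambda_epsilon Positive dimensionless scale factors.
#' @param species_tag Identifier of the partner class, e.g. `"Cl"` or `"RNA"`.
#' @return An object of class `scaling_factors`.
#' @export
scaling_factors <- function(lambda_sigma, lambda_epsilon, species_tag) {
  stopifnot(is.numeric(lambda_sigma), is.numeric(lambda_epsilon),
            is.character(species_tag), length(species_tag) == 1L)
  if (!is.finite(lambda_sigma) || lambda_sigma <= 0)
    stop("'lambda_sigma' must be positive")
  if (!is.finite(lambda_epsilon) || lambda_epsilon <= 0)
    stop("'lambda_epsilon' must be positive")
  structure(list(lambda_sigma = lambda_sigma, lambda_epsilon = lambda_epsilon,
                 species_tag = species_tag),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("Scaling factors [%s]: lambda_sigma = %.6g, lambda_epsilon = %.6g\n",
              x$species_tag, x$lambda_sigma, x$lambda_epsilon))
  invisible(x)
}

#' Lennard-Jones (12-6 or 12-6-4) pair energy
#'
#' Evaluates \deqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - C_4/r^4}
#' at one or more distances. With `c4 = 0` this is the pure 12-6 form,
#' vanishing at \eqn{r = \sigma} with minimum \eqn{-\epsilon} at
#' \eqn{r = 2^{1/6}\sigma}.
#'
#' @param pair A [pair_interaction] object.
#' @param r Distance(s) in nm, all strictly positive.
#' @return Energy in kJ/mol, same length as `r`.
#' @export
lj_energy <- function(pair, r) {
  stopifnot(inherits(pair, "pair_interaction"), is.numeric(r))
  if (length(r) == 0L) return(numeric(0))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all distances 'r' must be positive and finite")
  sr6 <- (pair$sigma_ij / r)^6
  4 * pair$epsilon_ij * (sr6^2 - sr6) - pair$c4 / r^4
}

#' Coulomb pair energy
#'
#' \eqn{V(r) = k_e q_i q_j / r} with [COULOMB_KE] in kJ nm/(mol e^2).
#'
#' @param q_i,q_j Charges in elementary-charge units.
#' @param r Distance(s) in nm, strictly positive.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(q_i, q_j, r) {
  stopifnot(is.numeric(q_i), is.numeric(q_j), is.numeric(r))
  if (length(r) == 0L) return(numeric(0))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all distances 'r' must be positive and finite")
  COULOMB_KE * q_i * q_j / r
}

.as_lj <- function(x) {
  if (inherits(x, "ion_model")) x$lj
  else if (inherits(x, "lj_params")) x
  else stop("expected an lj_params or ion_model object")
}

#' Lorentz-Berthelot combination rule
#'
#' Standard combination rules for unlike pairs:
#' \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}.
#'
#' @param a,b [lj_params] (or [ion_model]) objects.
#' @return A [pair_interaction] with provenance `"standard-rule"`.
#' @examples
#' mg <- lj_params(0.1019, 235.80)
#' combine_lb(mg, TIP3P_OXYGEN)   # sigma_io 0.2085 nm, epsilon_io 12.250 kJ/mol
#' @export
combine_lb <- function(a, b) {
  a <- .as_lj(a); b <- .as_lj(b)
  pair_interaction((a$sigma + b$sigma) / 2,
                   sqrt(a$epsilon * b$epsilon),
                   c4 = 0, provenance = "standard-rule")
}

#' Scaled Lorentz-Berthelot combination rule
#'
#' Combination rules with adjustable scaling factors for a selected partner
#' class: \eqn{\sigma_{ij} = \lambda_\sigma (\sigma_i + \sigma_j)/2},
#' \eqn{\epsilon_{ij} = \lambda_\epsilon \sqrt{\epsilon_i \epsilon_j}}.
#' With both factors equal to 1 this reduces exactly to [combine_lb] (up to
#' the provenance tag).
#'
#' @param a,b [lj_params] (or [ion_model]) objects.
#' @param s A [scaling_factors] object.
#' @return A [pair_interaction] with provenance `"scaled-rule"`.
#' @export
combine_scaled <- function(a, b, s) {
  if (!inherits(s, "scaling_factors"))
    stop("'s' must be a scaling_factors object")
  a <- .as_lj(a); b <- .as_lj(b)
  pair_interaction(s$lambda_sigma * (a$sigma + b$sigma) / 2,
                   s$lambda_epsilon * sqrt(a$epsilon * b$epsilon),
                   c4 = 0, provenance = "scaled-rule")
}

# Registry of the optimized builtin parameter sets (defined with TIP3P water).
.builtin_registry <- list(
  microMg = list(
    ion = list(name = "Mg", charge = 2, sigma = 0.1019, epsilon = 235.80,
               mass = 24.305),
    scalings = list(
      Cl  = c(lambda_sigma = 1.8000, lambda_epsilon = 0.1000),
      RNA = c(lambda_sigma = 1.1375, lambda_epsilon = 0.3200))
  ),
  nanoMg = list(
    ion = list(name = "Mg", charge = 2, sigma = 0.1025, epsilon = 389.80,
               mass = 24.305),
    scalings = list(
      Cl  = c(lambda_sigma = 1.8000, lambda_epsilon = 0.1000),
      RNA = c(lambda_sigma = 1.1435, lambda_epsilon = 0.2500))
  )
)

#' Builtin optimized Mg2+ parameter sets
#'
#' Returns one of the two optimized Mg2+ parameter sets defined for use with
#' TIP3P water: `"microMg"` (water exchange on the experimental microsecond
#' timescale) or `"nanoMg"` (accelerated, nanosecond-timescale exchange).
#' Each record carries the ion-ion LJ parameters and the combination-rule
#' scaling factors for the chloride and RNA partner classes. Literature
#' comparison sets are not hard-coded; supply them via parameter files
#' ([read_params]).
#'
#' @param name `"microMg"` or `"nanoMg"`.
#' @return A list with elements `name`, `ion` (an [ion_model]) and `scalings`
#'   (named list of [scaling_factors]).
#' @export
builtin_params <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.builtin_registry))
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(.builtin_registry), collapse = ", "))
  rec <- .builtin_registry[[name]]
  ion <- ion_model(rec$ion$name, rec$ion$charge,
                   lj_params(rec$ion$sigma, rec$ion$epsilon),
                   mass = rec$ion$mass)
  scal <- lapply(names(rec$scalings), function(tag) {
    v <- rec$scalings[[tag]]
    scaling_factors(v[["lambda_sigma"]], v[["lambda_epsilon"]], tag)
  })
  names(scal) <- names(rec$scalings)
  list(name = name, ion = ion, scalings = scal)
}

#' Invert the Lorentz-Berthelot rule for the ion parameters
#'
#' Given ion-water pair parameters and the water oxygen parameters, recover
#' the ion's own LJ parameters: \eqn{\sigma_i = 2\sigma_{io} - \sigma_o},
#' \eqn{\epsilon_i = \epsilon_{io}^2/\epsilon_o}. Used when a search
#' parameterized in ion-water space must be expressed as ion-ion constants.
#'
#' @param pair A [pair_interaction] holding the ion-water values.
#' @param water Water-oxygen [lj_params] (default [TIP3P_OXYGEN]).
#' @return An [lj_params] for the ion.
#' @export
invert_lb <- function(pair, water = TIP3P_OXYGEN) {
  stopifnot(inherits(pair, "pair_interaction"))
  water <- .as_lj(water)
  sig <- 2 * pair$sigma_ij - water$sigma
  if (sig <= 0) stop("inversion yields a nonpositive ion diameter")
  lj_params(sig, pair$epsilon_ij^2 / water$epsilon)
}

#' Potential-energy curve on a distance grid
#'
#' Vectorized [lj_energy] over a strictly increasing positive grid, returned
#' as a two-column data frame suitable for plotting or export with
#' [write_xy].
#'
#' @param pair A [pair_interaction].
#' @param r_grid Strictly increasing positive distances, nm.
#' @return A data frame with columns `r` (nm) and `V` (kJ/mol), classed
#'   `potential_curve`.
#' @export
potential_curve <- function(pair, r_grid) {
  stopifnot(is.numeric(r_grid), length(r_grid) >= 1L)
  if (any(!is.finite(r_grid)) || any(r_grid <= 0))
    stop("'r_grid' must contain positive finite distances only")
  if (length(r_grid) > 1L && any(diff(r_grid) <= 0))
    stop("'r_grid' must be strictly increasing")
  out <- data.frame(r = r_grid, V = lj_energy(pair, r_grid))
  class(out) <- c("potential_curve", "data.frame")
  out
}

#' @export
plot.potential_curve <- function(x, ..., ylim = NULL) {
  if (is.null(ylim)) {
    vmin <- min(x$V)
    ylim <- c(vmin * 1.2, abs(vmin) * 2 + 1e-9)
  }
  graphics::plot(x$r, x$V, type = "l", xlab = "r [nm]", ylab = "V [kJ/mol]",
                 ylim = ylim, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
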