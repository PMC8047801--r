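---
title: "Models and estimators behind mgff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind mgff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgff)
```

`mgff` implements the computational core of an Mg²⁺ force-field
parametrization workflow: pair-potential algebra with scaled combination
rules, hydration-shell structure analysis, a transition-counting estimator
of the water-exchange rate, Kirkwood–Buff activity derivatives,
profile-based binding thermodynamics, and a three-step selection procedure.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not demonstrate.

## Interaction model and unit system

All internal quantities use nm, kJ/mol, elementary charges, and ps;
converters exist only at the I/O boundary. The pair energy is

$$V(r) = \frac{k_e q_i q_j}{r}
       + 4\varepsilon_{ij}\left[\left(\frac{\sigma_{ij}}{r}\right)^{12}
       - \left(\frac{\sigma_{ij}}{r}\right)^{6}\right] - \frac{C_4}{r^4},$$

with $k_e = 138.935458$ kJ·nm/(mol·e²) derived from CODATA constants (the
value used by the major MD engines). The optional $C_4$ coefficient is
stored positive and subtracted, i.e. attractive, matching the sign
convention of the 12–6–4 literature where the term mimics charge-induced
dipole interactions. Only the Lennard-Jones parameters are ever adjusted;
the Coulomb term is left untouched, so no charge scaling is available by
design.

Unlike pairs combine via the Lorentz–Berthelot rules
$\sigma_{ij} = (\sigma_i+\sigma_j)/2$,
$\varepsilon_{ij}=\sqrt{\varepsilon_i\varepsilon_j}$, optionally scaled by
per-partner-class factors $\lambda_\sigma$, $\lambda_\varepsilon$. The
builtin *microMg* / *nanoMg* registry stores the ion–ion values and the
Cl⁻/RNA scaling factors; the ion–water values are always recomputed from
the rule rather than stored, which the test suite exploits as a consistency
check (they reproduce the tabulated 0.2085/12.250 and 0.2088/15.750 at the
printed precision). Recomputing σ_MgOP from the same inputs yields
0.2263/0.2278 nm against tabulated 0.2262/0.2277 — a last-digit rounding
difference in the published table; the ε values reproduce exactly, so the
registry stores the λ factors and recomputes pair values rather than
hard-coding them. TIP3P oxygen parameters (σ = 0.315061 nm, ε = 0.6364
kJ/mol) are hard-coded because the builtin sets are defined only with that
water model. Literature comparison sets are *not* hard-coded — their exact
constants vary across sources — and enter through `read_params()` config
files instead.

## Trajectories, RDFs, and the first shell

`trajectory` holds per-role coordinate arrays with per-frame orthorhombic
boxes; triclinic boxes are rejected because all distance code uses
orthorhombic minimum image. Supported formats are GRO and a documented
plain XYZ-with-box text format; compressed binary trajectory formats are
out of scope for this package's desk-scale analyses.

`compute_rdf()` histograms minimum-image distances and normalizes by
ideal-gas shell counts. The default bin width of 0.002 nm resolves the very
narrow Mg–O first peak (the structural targets are quoted to ±0.004 nm).
`first_shell()` finds the first peak by parabolic interpolation through the
three bins around the discrete maximum; the first minimum is detected on a
3-bin moving average — the raw curve's shot noise otherwise produces
spurious minima — but the coordination integral
$n_1 = 4\pi\rho\int_0^{r_{min,1}} g r^2 dr$ uses the unsmoothed values.
The reported precision is the binning half-width, kept separate
from any block spread.

`msd_diffusion()` implements the Einstein relation with strided time
origins and a least-squares fit over a user-chosen lag window; the
uncertainty is the spread of per-block slopes (3 blocks by default).
A finite-size (Yeh–Hummer-type) correction is *not* applied automatically:
it requires the solvent viscosity, so it is left to the caller as an
additive post-hoc term.

## Water-exchange rate

The estimator follows each water individually. A dual-cutoff indicator
commits a water as bound below `r_bound` and unbound above `r_unbound`;
between the cutoffs the previous committed state persists. This hysteresis
suppresses barrier-top recrossing noise, which is exactly why the counting
estimate is reliable where transition-state theory is not. Defaults
`r_bound = 0.28` nm and `r_unbound = 0.40` nm correspond to the first
Mg–Ow RDF minimum and the second-shell onset; both are mandatory,
documented configuration rather than hidden constants, and the suite
verifies that ±10% variations move the recovered rate by less than 5%.

With $N$ transitions (both directions counted) among $N_{H_2O}$ waters and
$N_{Mg}$ ions over $t_{sim}$:

$$p_B = \frac{n_1}{N_{H_2O}-n_1},\qquad
  t_B = N_{Mg}\,p_B\,t_{sim},\qquad
  k = \frac{N}{2\,N_{H_2O}\,t_B},$$

where $n_1 = 6$ is the first-shell coordination number, $t_B$ the
cumulative first-shell residence time per water, and the factor 2 converts
bidirectional transition counts into exchange events. This closed form was
fixed by dimensional analysis and validated against all three published
benchmark rows (376 → 8.0×10⁵ s⁻¹, 52 086 → 1.11×10⁸ s⁻¹,
6 720 → 1.43×10⁷ s⁻¹) before being frozen; inverted at the experimental
5.3×10⁵ s⁻¹ it returns 248 expected events. When no box composition is
supplied, `ideal_composition()` provides the ideal 1 M ratio
water:Mg = 55.5:1 with a fractional effective ion count (2160 waters,
38.92 ions); the exact ratio — rather than a rounded integer ion count —
is what reproduces the published expected-event count of 248. Errors use
block averaging with 2 blocks for exchange counts and 3 blocks for
Kirkwood–Buff quantities, matching the conventions of the source analyses.

`tst_rate()` provides the 1-D transition-state-theory estimate
$k_{TST} = \sqrt{k_BT/2\pi\mu}\; e^{-F(r^\ddagger)}/\int_{well} e^{-F} dr$.
It is documented and tested as an upper bound only: on overdamped Langevin
benchmarks with recrossings the counting estimator stays below it, which
mirrors the physical situation where distance-coordinate TST overestimates
the true exchange rate.

## Kirkwood–Buff activity derivative

`kb_integral()` accumulates the running integral
$G(r) = 4\pi\int_0^r (g-1)s^2 ds$ and averages it over a convergence
window, 1.0–1.5 nm by default — standard practice for converged
salt-solution RDFs. Tail corrections are deliberately off by default.

For a 2:1 salt the five pair integrals collapse to
$G_{ss} = (\nu_c^2 G_{cc} + 2\nu_c\nu_a G_{ca} + \nu_a^2 G_{aa})/\nu^2$ and
$G_{sw} = (\nu_c G_{cw} + \nu_a G_{aw})/\nu$, and the activity derivative
is $a_{cc} = 1/(1+\rho_s(G_{ss}-G_{sw}))$. This convention satisfies the
ideal-solution limit $a_{cc}=1$ and reproduces the qualitative signature
that over-attractive cation–anion interactions drive $a_{cc}$ below 1.
Because concentration-scale conventions differ across the literature
(molarity vs molality derivatives, indistinguishable-ion corrections), the
convention is an explicit tag recorded in every result, so an alternative
form can be added without touching calling code. Whether a water–water
integral should enter is precisely the kind of convention difference the
tag exists for.

## Binding thermodynamics from 1-D profiles

Profiles are stored in $k_BT$; a kJ/mol converter needs the temperature.
`binding_affinity()` anchors the profile by shifting the mean of the
outermost 10% of the grid to zero (rejecting profiles whose tail is not
flat to within 0.5 $k_BT$), takes the bound region as everything up to the
first interior barrier after the global minimum — i.e. the inner-sphere
state, matching the inner/outer-sphere split of Mg²⁺–phosphate profiles —
and evaluates

$$\Delta G_b^0 = -\ln \frac{1}{V^0}\int_{r_{start}}^{r^\ddagger}
  4\pi r^2 e^{-F(r)}\,dr, \qquad V^0 = 1.661\ \mathrm{nm^3},$$

a spherical-shell standard state (the result metadata notes this; an axial
convention would differ by a geometry factor). The 4πr² Jacobian can be
disabled for profiles supplied already radially weighted. The estimate is
gauge-invariant by construction, strictly decreasing in well depth, and
stable to grid refinement below 0.01 $k_BT$ on smooth profiles — all
verified properties. `binding_distance()` parabolic-interpolates the
global minimum before the barrier; `barrier_height()` measures the barrier
against the inner or outer minimum.

## Selection workflow

The optimizer consumes CSV observable tables rather than driving an MD
engine — that is what makes the workflow desk-scale and engine-agnostic.
Stage 1 keeps candidates within tolerance of ΔG_solv and R₁ and with the
coordination number matched exactly as an integer; default tolerances
(±5 kJ/mol, ±0.004 nm — the experimental R₁ uncertainty — and ±0.02 on
a_cc) apply where the caller states none. Stage 2 selects by smallest
|log₁₀(k/k_exp)| or by maximum rate. Stage 3 minimizes |a_cc − target| on
the Cl λ-grid and, on the RNA grid, restricts to rows within the R_b
tolerance before minimizing |ΔG_b⁰ − target|; declared grid ranges
(λ_σ^Cl ∈ [1, 2.6], λ_ε^Cl ∈ [0.01, 1], λ_σ^RNA ∈ [0.97, 1.23],
λ_ε^RNA ∈ [0.08, 1.04]) are validated with warnings. All selections are
deterministic, with ties broken by smallest σ then smallest ε so repeated
runs of the pipeline select identical rows. The published search was
parameterized in ion–water (σ_io, ε_io) space; where ion–ion values are
needed they are back-solved against TIP3P oxygen by inverting the
combination rule.

## Synthetic generators: what they emulate, and what they do not

`gen_hopping_traj()` models each water as an independent two-state
continuous-time Markov chain between a bound shell (radius 0.21 ± 0.02 nm
around an assigned ion) and bulk (≥ 0.45 nm from any ion), with the
off-rate chosen so the counting estimator recovers `k_true` in expectation
and the stationary bound fraction giving $n_1$ waters per ion. The default
spec mirrors the benchmark conditions (1 μs, 1 M composition, $n_1 = 6$).
The process is memoryless and the geometry teleports between shells: it
emulates stationary *counting statistics* only, not the concerted two-water
exchange mechanism, intermediate configurations, or force-field-dependent
dynamics. Passing tests therefore demonstrate the correctness of the
labeling/counting/rate pipeline, not the realism of any force field.
`gen_langevin_radial()` complements it with overdamped dynamics on an
actual barrier so that recrossing behaviour (and the TST bound) can be
exercised.

`gen_rdf()` attaches closed-form G, R₁ and n₁ per family (the
Gaussian-shell peak position is the root $r = (\mu+\sqrt{\mu^2-8s^2})/2$ of
the radially weighted density). `gen_brownian()` draws exact Gaussian
displacements with per-step variance $2D\,dt$. `gen_profile()` builds a
Gaussian-well/Gaussian-barrier profile and attaches ground truths computed
from the *analytic* form by adaptive quadrature and continuous
optimization, independent of the grid on which the profile is sampled.
All generators are deterministic under a fixed seed.

## Numerical choices and problem sizes

Integrals are trapezoidal on the stored grids; shell and KB integrals
extend to $r = 0$ with the leading bin treated as excluded-volume core
when $g$ starts at zero. Extremum locations use 3-point parabolic
interpolation. Degenerate inputs (monotone RDFs, barrierless or
plateau-less profiles, cutoff misordering, insufficient frames) raise
errors naming the condition rather than returning silent defaults.

The validation suite runs the full pipeline at reduced scale, chosen so
statistics remain decisive: hopping recovery uses 120 waters, 4 ions,
2 001 frames across six seeds (~1 000 transitions per seed, so the 3-SE
band is a few percent); diffusion recovery uses 10 particles over 10⁵
steps (5% band); Langevin benchmarks use 8 walkers over 20 000 steps.
Published observables that require actual MD (ΔG_solv, simulated R₁, a_cc
= 0.93 at 0.25 M, D₀, barrier heights) are validated structurally against
these synthetic ground truths, not reproduced numerically.

## Known limitations

- No Ewald/PME electrostatics, polarizable models, or force evaluation for
  dynamics: the potential algebra serves parametrization, not simulation.
- Only the GROMACS topology dialect is emitted; the 12–6–4/LJ-edit
  mechanism of other engines is structurally different. By default every
  partner type in a scaled class receives an override (hydrogens included);
  restrict the partner table to change that.
- KB integrals assume converged, well-sampled RDFs; no finite-size closure
  is applied by default.
- The binding analysis assumes a single inner barrier separates the bound
  state; multi-basin profiles need explicit `r_boundary` input.
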