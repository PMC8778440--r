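---
title: "Modelling protein SAXS in binary solvents: the saxsolv method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein SAXS in binary solvents: the saxsolv method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsolv)
```

# The problem

Small-angle X-ray scattering (SAXS) of a protein solution measures the
absolute macroscopic cross section $d\Sigma/d\Omega(q)$, which mixes three
kinds of information: the shapes of the protein species present (form
factors), how the protein molecules are distributed among oligomeric or
unfolded states (populations), and how the particles interact at long
range (structure factor). When a small cosolvent such as a modified sugar
is added, the populations shift because the cosolvent competes with water
for sites on the protein surface — preferential solvation — and the
scattering contrast of the hydration region changes as well.

`saxsolv` implements a forward model for this situation on an absolute
scale,
$$\frac{d\Sigma}{d\Omega}(q) = n\,P(q)\,S_M(q),$$
with $n = c N_A / M_1$ the nominal monomer number density, $P(q) =
\sum_j x_j \alpha_j P_j(q)$ the effective form factor of the state
mixture, and $S_M(q) = 1 + \beta(q)[S(q) - 1]$ the measured structure
factor under the decoupling approximation, and a regularized global fit
that extracts transition and exchange thermodynamics from a batch of
curves recorded at several concentrations, temperatures and cosolvent
levels.

# The thermodynamic core

## States and elementary processes

The protein occupies $N_s$ states $j$, each with an aggregation number
$\alpha_j$, first- and second-shell hydration site counts $m_j$ and
$m_{j,2}$, a radius $R_j$, a net charge $Z_j$ and a relative
hydration-water density $d_j \in [1, 1.15]$. Two families of elementary
processes act:

* **transition** of a monomer (state 1) into state $j$, releasing
  $m_1 - \alpha_j^{-1} m_j$ first-shell waters per monomer, with an
  elementary constant $K_{W1j}$ in water;
* **exchange** of one surface-bound cosolvent molecule for a bulk water
  molecule over state $j$ (the Schellman picture), with constant
  $K_{exj}$. The closed-form inversion of the exchange isotherm gives the
  water occupancy $\phi_j$ directly
  (`phiFromExchange()`).

Each elementary energy follows the classical law
$\Delta G(T) = \Delta G^\circ + (\Delta C_p - \Delta S^\circ)(T - T^\circ)
- \Delta C_p T \ln(T/T^\circ)$ with $T^\circ = 298.15$ K (natural
logarithm: the thermodynamic derivation requires it). The electrostatic
contribution to the transition energy is split off and treated with
Debye–Hückel theory for a spherical macroion, with the counterion ionic
strength recomputed self-consistently from the current populations; the
macroion charge enters the ionic strength as monovalent-equivalent ions
(electroneutral-pair bookkeeping) while its own $z^2$ self-term is
excluded — screening is by small ions.

## The coupled system and how it is solved

The unknowns $\{x_j, \phi_j\}$ satisfy the normalisation
$\sum_j x_j = 1$, one exchange isotherm per state, and one mass-action
relation per non-reference state built on the *effective* constant
$$K_{1j} = K_{W1j}\,\phi_1^{m_1}\,X_{Wb}^{\alpha_j^{-1} m_j - m_1}
  \big/ \phi_j^{\alpha_j^{-1} m_j},$$
with the bulk composition, the mean molar volume, and the monomer
molarity $C_P = X_P/\langle\nu\rangle$ recomputed from the current state.
`solveDistribution()` uses a damped fixed-point iteration (damping 0.5,
relative tolerance $10^{-10}$, at most 500 sweeps): the $\phi_j$ update
is closed-form, the $x_j$ update is a one-dimensional root solve in the
log monomer concentration, and all exponentials are evaluated in log
space because the site-count exponents are of order several hundred. The
initial state is the native monomer in pure water ($x_1 = 1$,
$\phi_j = 1$). States with $\alpha_j > 1$ whose population falls below
$10^{-15}$ are clamped to zero.

The iteration scheme was designed for the dilute regime this model
targets (protein at grams per litre, $X_P \sim 10^{-6}$), where it
converges in a few tens of sweeps. The solver's contract is the solved
system — mass balances to $10^{-10}$ and agreement with an independent
polynomial mass-action solver to $10^{-8}$ — not any particular
iteration path.

Units: energies are J/mol internally and kJ/mol at interfaces, lengths
Å, concentrations mol/L, scattering length densities cm$^{-2}$,
intensities cm$^{-1}$.

# Hydration shells and scattering length densities

Hydration sites are generated by burying the structure in an FCC lattice
whose per-site volume equals one bulk water molecule (29.9 Å$^3$, lattice
constant 4.93 Å); a site belongs to shell $s$ when its distance to the
nearest atom van der Waals surface lies in $((s-1)\cdot 2.8, s\cdot
2.8]$ Å, with two shells kept. Sites in sealed interior cavities are
removed by a flood fill over the lattice connectivity whose edges are
checked for midpoint clearance, so the walk cannot tunnel through walls
thinner than a lattice bond. Counts are averaged over a small set of
fixed lattice offsets to suppress registration artifacts. The lattice
spacing is our choice (the shell thickness is standard; published
site-count tables depend on unpublished lattice details), so exact
m-counts are configuration-overridable: thermodynamic bookkeeping can
use published counts while the scattering sites come from the built
lattice.

Preferential solvation changes the composition of the *local domain*
(first plus second shell): bound cosolvent, being larger than water,
displaces $k_j = m_j (1-\phi_j)(\nu_{Gs} - \nu_{Ws})/\nu_{Wb}$
second-shell sites, and the remaining second-shell sites fill with bulk
solvent. The resulting local molar volumes and composition give a single
local-domain SLD $\rho_{ld,j}$ assigned uniformly to all sites of the
state, against the bulk SLD $\rho_0$. First-shell water is denser than
bulk by the factor $d_j$ (default 1.07, the midpoint of the accepted
range); site cosolvent volume equals the bulk value.

# Form factors

State form factors use a Debye approach with three ingredients per
scatterer: a $q$-independent atomic scattering length $r_e N_e$, a
Gaussian excluded-volume term at the bulk SLD (Fraser–MacRae–Suzuki
volumes), and Gaussian dummy spheres of contrast $\rho_{ld} - \rho_0$ on
the shell sites. This is adequate for the working band
$q \in [0.01, 0.35]$ Å$^{-1}$; five-Gaussian atomic form factors and
explicit hydrogens are out of scope.

Because the SLDs change with the solvation state at every fit step, the
package precomputes, per structure, class-pair distance histograms (one
class per element plus one for shell sites, occupancy-weighted, per-bin
mean distances) and reduces them on the q grid once; any SLD pair is
then a cheap quadratic form (`formFactorBasis()` /
`evaluateFormFactor()`). With 0.25 Å bins and per-bin mean distances the
binning error is below $10^{-3}$ relative in the working band.

The orientationally averaged amplitude needed for the coupling function
is computed exactly: the spherical average of $e^{i\mathbf q\cdot\mathbf
r}$ is $j_0(qr)$, so $\langle\Delta A(q)\rangle$ is a single $j_0$ sum
about the electron-weighted centroid — no angular quadrature and no
quadrature-order parameter. The normalisation convention is per
monomer: $P_j = \langle|\Delta A_j|^2\rangle/\alpha_j^2$ and $P^{(1)}_j
= \langle\Delta A_j\rangle/\alpha_j^2$, which makes $n \sum_j x_j
\alpha_j P_j$ the physical mixture intensity (pinned in the tests by an
independent Debye computation). With this convention
$\beta = |P^{(1)}|^2/P$ equals 1 at $q \to 0$ for a single monomeric
state; for oligomeric mixtures it is strictly below 1 there
(Cauchy–Schwarz), which the structure-factor coupling inherits.
$\beta$ is clipped to $[0,1]$.

# Protein–protein interactions

A single effective particle represents the mixture, with
population-averaged radius and charge
($R = \langle\alpha^{-1}\rangle^{-1}\sum_j x_j \alpha_j^{-1} R_j$, same
for $Z$) and particle density $n\langle\alpha^{-1}\rangle$. The pair
potential is a hard core of diameter $2R$ plus two Yukawa tails: a DLVO
screened-Coulomb repulsion
$B_{1C} = Z^2 q_e^2 / (4\pi\epsilon_0\epsilon(1 + \kappa_D R)^2)$ with
decay $\kappa_D$, and a generic attraction with contact depth $J$
(carried in units of $k_BT$ so fit bounds are condition-independent) and
range $d$, $u_{YA}(2R) = -J$ exactly. $S_0(q)$ is the analytic
Wertheim–Thiele Percus–Yevick solution; the tails enter through the
random-phase approximation,
$1/S = 1/S_0 + n\,\tilde u(q)/(k_BT)$, with the closed-form transform of
each tail truncated at the contact distance (consistent with the hard
core). Non-positive $S(q)$ is reported as an RPA instability rather than
silently clipped.

# The global fit

A batch of curves, each labelled with (c°, T, cosolvent, C_G°), is
fitted by minimising $H = \chi^2 + \gamma L$: the average reduced
chi-square (curves averaged after their own points, so unequal point
counts are handled) plus a regularization $L$ that penalises ratio
differences of the per-curve interaction parameters $(J, d)$ between
curves differing in exactly one label. For a label with several values
the neighbour is the nearest one, ties towards the smaller value; curves
with no neighbour in a label contribute nothing. $\gamma = 10^{-7}$ by
default, chosen so that $\gamma L$ is a small fraction of $H$ near
$\chi^2 \approx 1$.

The optimiser is a seeded differential-evolution stage (rand/1/bin)
followed by Nelder–Mead and BFGS polish with parameter scaling taken
from the declared bounds; box constraints are enforced by a smooth
quadratic out-of-box penalty (a hard clamp would present simplex methods
with a flat plateau at the boundary). Polish runs from both the DE best
and the box midpoint and keeps the better result. The contract is the
minimised $H$; the path is not specified. Uncertainties are
covariance-based, from the numerical Hessian of the summed squared
standardized residuals at the optimum, and are labelled as such.

# The synthetic-data generator and what passing tests mean

Because the experimental curves this model was developed against are not
distributable, the package carries a first-class generator.
`defaultRecoveryScenario()` encodes the study conditions: a
monomer–dimer protein with myoglobin-like site counts (404/465 and
753/827), radii (17.0 and 26.7 Å), charges (+5/+10), one neutral
cosolvent of molar volume 0.2 L/mol, buffer ionic strength 10 mM, a
12-curve design crossing protein concentration (2 and 10 g/L),
temperature (25, 45, 60 °C) and cosolvent level (0 and 0.15 M), 2 %
relative Gaussian noise plus a 10$^{-5}$ cm$^{-1}$ floor — a
synchrotron-like error model ($\sigma = \text{floor} + f\,I + c\sqrt I$
is configurable). The true thermodynamics
($\Delta G^\circ = -11$ kJ/mol, $\Delta S^\circ = 300$ J/mol/K for the
transition; $+1.5$ and $-2$ kJ/mol for the exchanges) put the
monomer–dimer midpoint inside the temperature window and keep both
exchange constants moderate; exchange energies much below about
$-4$ kJ/mol would drive $\phi_j$ so close to 1 that the parameter loses
identifiability in any design of this size — a property of the model,
not of the optimiser.

Toy structures are deterministic grid-filled spheres and dumbbells (and
a seeded self-avoiding-walk coil). Their staircased, slightly porous
surfaces carry more lattice hydration sites than a smooth body of the
same size; this is self-consistent between generator and fit but means
absolute site counts for toys exceed smooth-surface estimates. What a
passing recovery shows is that the estimator is consistent and
well-calibrated *under the model's own assumptions* (Gaussian noise,
exact forward model, monodisperse interactions); it does not validate
the model against real detector artifacts, smearing, buffer-subtraction
errors, or polydisperse aggregates, which are all out of scope.

Problem sizes used throughout (12 curves of 100 points, toy structures
of a few hundred pseudo-atoms, DE population 16 with 25 generations)
were chosen so a full recovery runs in about two minutes on one CPU
while leaving the statistical checks comfortably powered.

# Numerical choices and degenerate inputs

* log-space equilibrium algebra; mass-action root bracketed downward in
  steps of 5 log units, `uniroot` tolerance $10^{-12}$;
* $\phi$ at $x_{Gb} = 1$ returns the 0 limit with a warning; zero shell
  occupancy is an error (a fully cosolvent-covered shell is outside the
  model);
* second-shell overflow ($k_j > m_{j,2}$) is clamped with a warning —
  it only occurs for extreme trial parameters during optimisation;
* the PY solution switches to its analytic $q \to 0$ limit below
  $q\sigma = 10^{-3}$;
* curve files round-trip at full double precision (`%.17g`);
* the dielectric constant of water uses a standard empirical Celsius
  polynomial; the cosolvent effect on it is neglected (second order at
  $\le 0.25$ M); the mean microion radius defaults to 2 Å; both are
  configurable.

# Known limitations

No activity corrections beyond Debye–Hückel, no pressure dependence, no
temperature-dependent $\Delta C_p$, no multi-component partial structure
factors, no Bayesian posteriors (point estimates with covariance-based
errors only), no raw-data reduction. Published per-protein hydration
site counts cannot be reproduced exactly because the original lattice
parameterisation is unpublished; the package's counts are
volume-consistent approximations, and site counts are injectable where
published values should be used.

# A worked example

```{r example, eval = FALSE}
scen <- defaultRecoveryScenario(seed = 1)
rec <- recoveryExperiment(scen, seed = 1,
                          control = list(popSize = 16, maxGen = 25))
cbind(truth = rec$truth, estimate = rec$estimate, bias = rec$bias)
rec$chi2AtTruth
```

The same numbers are recomputed from scratch by
`scripts/acceptance.R`; see the README for how to run it.
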