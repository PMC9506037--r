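---
title: "CPA modeling of CO2 mixtures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CPA modeling of CO2 mixtures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model `cpaeos` implements, the numerical
choices behind its solvers, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable option existed.

## The model

The cubic-plus-association (CPA) equation of state adds a Wertheim-type
association contribution to the Soave–Redlich–Kwong (SRK) cubic
equation.  In pressure-explicit form,

$$P = \frac{RT}{V_m-b} - \frac{a(T)}{V_m(V_m+b)}
  - \tfrac12\,\frac{RT}{V_m}\Bigl(1+\rho\frac{\partial\ln g}{\partial\rho}\Bigr)
    \sum_i x_i \sum_{A_i}(1-X_{A_i}),$$

with $a(T) = a_0\,[1+c_1(1-\sqrt{T/T_c})]^2$, the simplified radial
distribution function $g = 1/(1-1.9\eta)$ at reduced density
$\eta = b\rho/4$, and unbonded-site fractions solving

$$X_{A_i} = \Bigl(1+\rho\sum_j x_j\sum_{B_j}X_{B_j}\,\Delta^{A_iB_j}\Bigr)^{-1},
\qquad
\Delta^{A_iB_j} = g\,[e^{\varepsilon^{A_iB_j}/RT}-1]\,b_{ij}\,\beta^{A_iB_j}.$$

Mixing rules are van der Waals one-fluid with a single
temperature-independent binary correction $k_{ij}$ on the geometric-mean
cross energy; $b$ mixes linearly and $b_{ij}=(b_i+b_j)/2$.  A pure fluid
is described by five parameters ($a_0$ in L²·bar/mol², $b$ in L/mol,
$c_1$, and for self-associating fluids $\varepsilon$ in bar·L/mol and
$\beta$) plus a critical temperature; all are carried verbatim in the
bundled JSON registry, in exactly these units, with
$R = 0.083145$ bar·L/(mol·K) fixed package-wide.  No other unit system
is accepted internally; conversion belongs at the I/O boundary.

Residual Helmholtz energy and fugacity coefficients are not part of the
pressure-explicit statement above; the package adopts the standard
simplified-CPA form

$$\frac{A^{res}}{nRT} = -\ln(1-b\rho) - \frac{a}{bRT}\ln(1+b\rho)
 + \sum_i x_i \sum_{A_i}\Bigl(\ln X_{A_i}-\frac{X_{A_i}}{2}+\frac12\Bigr),$$

whose volume derivative reproduces the pressure equation, and computes
$\ln\varphi_i$ analytically using the stationarity of the site-fraction
equations (the association chemical potential reduces to
$\sum_{A_i}\ln X_{A_i}$ plus the $\partial\ln g/\partial n_i$ term).
Both identities are enforced as permanent tests: the pressure is checked
against a five-point numerical volume derivative of $A^{res}$, and the
analytic $\ln\varphi_i$ against numerical composition derivatives of
$n\,a^{res}$.

## Association schemes and site bookkeeping

Sites are grouped into classes with a polarity and a multiplicity:

* `2B` (alcohols): one positive + one negative site;
* `4C` (glycols, water): two + two;
* `3x2B` (glycerol, three hydroxyls): three + three;
* `1A` (carboxylic acids): one *bipolar* site that bonds with itself
  (acid dimerization) and, when a cross rule is declared, with either
  polarity of a partner's sites;
* solvation-only: one positive site with zero self-association energy.

A positive site bonds only with negative (or bipolar) sites and vice
versa.  Cross-association parameters follow CR-1 (arithmetic-mean
energy, geometric-mean volume; both partners must self-associate),
mCR-1 (arithmetic-mean energy with the non-self-associating partner
contributing zero; volume adjustable) or explicit values.

CO2 is inert by default.  It acquires its single positive solvation
site *per mixture*, only when a binary interaction declaring mCR-1 or
explicit cross parameters involves it.  Thus CO2 cross-associates with
glycerol (one-site parameter set) and with methanol/ethanol (explicit
spectroscopic-energy parameters) but remains inert toward polyethylene
glycols, triglycerides, esters and lauric acid, matching how each
binary was parameterized.  The CO2–glycerol pair ships in two named
variants ("inert", `kij = 0.1643`; "one-site", `kij = 0.3084`,
`beta_cross = 0.0979`); the one-site variant is the default because it
is the one used in multicomponent predictions.

Missing binary parameters are an error that lists every missing pair —
never an implicit zero.  Ester–ester pairs carry *explicit* zeros in
the registry, preserving the discipline that every interaction in a
multicomponent prediction is declared at the binary level.

## Polyethylene-glycol parameter correlations

Within the glycol family the co-volume is almost exactly linear in
molar mass and $a_0$ close to linear (mildly quadratic), provided the
association parameters are held constant across the family
($\varepsilon = 143.37$ bar·L/mol, $\beta = 0.0188$, 4C).  The package
fits ordinary least squares in the monomial basis to the four glycol
oligomers (molar masses 62.07, 106.12, 150.17, 194.23 g/mol — standard
values, which reproduce the tabulated PEG parameters to print
precision) *at run time*, so the reproduction of the tabulated PEG
columns is a genuine computation, not a stored constant.  The linear
$a_0$ correlation is the working default for phase-equilibrium
calculations; the quadratic one is reported alongside.

No functional form is recoverable for $c_1$ and $T_c$ versus molar mass
($c_1$ plateaus at high mass), so the five tabulated values (at 150,
200, 300, 400, 600 g/mol) are authoritative, piecewise-linear
interpolation covers intermediate masses, and values outside 150–600
clamp to the nearest anchor with a logged note.  The prediction domain
is 62–650 g/mol.

## Solver numerics

**Site fractions.** Damped successive substitution (damping 0.5) with a
bounded Newton fall-back when convergence stalls; tolerance $10^{-12}$
on the fixed-point defect ($10^{-14}$ in the compiled core), iterates
clamped to $(0,1]$.  The solver is validated against the closed-form
quadratic solution $X = (-1+\sqrt{1+4n\rho\Delta})/(2n\rho\Delta)$ for
the symmetric pure-fluid schemes ($n$ = 1, 2, 3) over $\rho\Delta \in
[0, 10^3]$.

**Volume roots.** Sign scan of $P(V)-P$ on a 120-point logarithmic grid
from $1.001\,b$ to $10^3\,RT/P$, with Illinois refinement of each
bracket to $|P(V)-P| \le 10^{-13}P$ or machine-precision interval
width.  Warm-started site fractions carry across the scan.  With
several roots, the liquid hint takes the smallest, the vapor hint the
largest, and the default takes the root of lower residual Gibbs energy
$a^{res}+Z-1-\ln Z$; ties (within $10^{-12}$) resolve to the vapor-like
root.

**Pure saturation.** The fugacity-equality residual is evaluated as the
difference of *full* fugacities $\ln(\varphi P)$ computed at each
branch's own refined volume; this cancels the volume-refinement error
that otherwise leaves a noise floor near $10^{-10}$ and lets a secant
iteration reach residuals at machine precision.  Cold starts scan
pressure logarithmically to find the two-root window (extending one
coarse step past its edges, which matters near the critical point);
warm starts go straight to the secant.

**Bubble and dew points.** $\varphi$–$\varphi$ successive substitution
on the K-values with Raoult-type initialization from pure saturation
pressures; components above their two-root limit (CO2 at most study
temperatures) get an extrapolated pressure, linear in $\ln P$ versus
$1/T$ from anchors at $0.8\,T_c$ and $0.9\,T_c$.  Pressure updates by
damped successive substitution ($P \leftarrow PS$, steps clamped to a
factor of 3), switching to a secant step near the solution
($|\ln S| < 0.05$).  Convergence demands $|S-1| < 10^{-11}$ and
K-value stagnation below $10^{-10}$; the reported residual is the
component-wise fugacity-equality defect, required $\le 10^{-9}$.  A
collapse onto the trivial solution ($\|x-y\|_\infty < 10^{-5}$ after
the first ten sweeps) is flagged, never returned as converged.
Near-critical states converge slowly (the dominant eigenvalue of the
substitution map approaches one), hence the generous default iteration
cap of 2000.

**Flash.** Two-phase Rachford–Rice nested in the same K-value
substitution; overall compositions whose Rachford–Rice function has no
root in $(0,1)$ are reported as single phase with vapor fraction 0
or 1.  The material balance holds by construction to $10^{-10}$.

**Binary coexistence at fixed (T, P).** For a binary, two-phase
compositions follow exactly from the K-values
($x_1 = (1-K_2)/(K_1-K_2)$), so a direct substitution converges in a
handful of sweeps; a bracket-safeguarded secant on bubble pressure
versus $x_1$ is the fall-back.  This is the workhorse behind the
liquid- and vapor-composition regression objectives and the
vapor-minimum locator.

**Warm-start hygiene.** Warm starts propagate along an isotherm within
one objective evaluation but never across parameter evaluations:
re-using K-values from a distant $k_{ij}$ can land the bubble solver on
a different solution branch in strongly asymmetric CO2–triglyceride
systems and silently corrupt the objective.  This was observed during
development and is the reason the regression code re-initializes from
Raoult starts at every parameter value.

## Regression

The source tables report deviations in bubble pressure, in the liquid
CO2 fraction, or in the heavy-compound vapor fraction, depending on
what was measured for each system, but no objective function.  The
package adopts relative least squares on the quantity each dataset
reports, exposed as an explicit `objective` flag (`pressure`,
`liquid_x`, `vapor_y`, `combined`), with uniform per-record weights.
One-parameter fits use golden-section/parabolic search on
$k_{ij} \in [-0.3, 0.5]$; two-parameter fits
($k_{ij}, \beta_{cross} \in (0, 0.5]$) run five bounded quasi-Newton
starts to avoid secondary minima.  Post-fit, percent average absolute
deviations ($100\cdot\text{mean}|X^{exp}-X^{calc}|/X^{exp}$) are
reported for every quantity the dataset carries, whether or not it
entered the objective.

Pure-fluid fits adjust $a_0$, $b$, $c_1$ to saturation pressures and
liquid molar volumes with equal relative weights, holding the
association parameters fixed as is done within a homologous family.
Initialization is data-driven: $b$ from the densest liquid volume,
$a_0$ from a Clausius–Clapeyron estimate of the critical pressure.

## The synthetic-data generator

The generator replaces the unprinted literature measurements with
model-consistent pseudo-data of the same *structure*: isothermal binary
T–P–x–y records over 303–393 K and up to ~350 bar; liquid-only and
vapor-only variants mimicking the triglyceride data patterns
(tributyrin-like sets report only liquid compositions, trimyristin-like
sets only vapor compositions); fixed-composition ternary bubble curves;
and a five-ester biodiesel surrogate.  Noise is multiplicative
(log-normal), matching the field's relative-deviation metrics; defaults
are 1 % on pressure and 10 % on heavy vapor fractions — engineering
choices, since the true experimental uncertainties are unknown — and a
heavy-tailed mode ($\sigma_{\ln} = \ln(10)/2$) emulates heavy-compound
vapor data whose sources disagree by one to two orders of magnitude.
Generation is bit-reproducible under a fixed seed.

Zero-noise datasets lie exactly on the model surface, so every
downstream fit must return the generating parameters; this end-to-end
identifiability is what the recovery tests certify.  What passing them
does *not* show: that the model fits *real* data to any particular
accuracy (synthetic data contain no model error, no systematic bias, no
sample-impurity effects, no inconsistent sources), nor that the
published deviations from experiment are reproduced — those compare
against measurements that are not available here.

The bundled biodiesel ester profile (C16:0 0.11, C18:0 0.04, C18:1
0.23, C18:2 0.54, C18:3 0.08) is a synthetic soy-type default for
testing, not a measured sample composition; real work should supply the
analyzed profile.

## Numerical limits of the consistency checks

The thermodynamic-consistency tests compare analytic derivatives with
five-point central differences.  For the pressure identity the
achievable agreement is bounded by
$\sim 10^{-12}\,RT/((V-b)P)$ in double precision — the check is
evaluated at 10–250 bar, where this floor sits safely below the
$10^{-9}$ assertion; at pressures of a few bar in dense liquids the
difference oracle, not the model, becomes the limiting factor.  The
differentiation step scales with $V-b$, the curvature scale of the
repulsive term.

## Computed behavior worth knowing

With the one-site parameter set, the glycerol mole fraction in the
CO2-rich phase passes through an interior minimum along each isotherm —
dilution of a nearly nonvolatile compound at low pressure, solvation by
dense CO2 at high pressure.  As computed by
`analysis/03_glycerol_vapor_minimum.R` and the acceptance script, the
minimum at 323 K lies near 27 bar (rising to ~47 bar at 373 K), i.e. at
lower pressures than a 50-bar-and-up window would reveal; the
vapor-minimum locator therefore searches from 5 bar and validates
against a dense scan.  Monotone (ideal-like) systems correctly return
the boundary with an `interior = FALSE` flag.

## Problem sizes

The test suite and acceptance script run binary recoveries on two
isotherms of five to six points each, the noise study on 20 replicates,
consistency checks on 50 random ternary states, and ternary predictions
on eleven fixed compositions at three temperatures; these sizes give
parameter recoveries at the $10^{-8}$ level and keep the full suite in
a few minutes on one core.  Scaling the grids up changes none of the
conclusions, only the runtime.

## Known limitations

* Two-phase VLE only: no three-phase flash, no liquid–liquid or
  vapor–liquid–liquid construction (the low-temperature CO2–glycerol
  region where such behavior is expected is out of scope), no critical-
  point or spinodal solvers.
* $k_{ij}$ is temperature independent by design; systems whose optimal
  correction drifts with temperature will show structured residuals.
* Predictions inherit the quality of the pure-fluid parameters;
  PEG parameters come from correlations, and triolein's were themselves
  predicted from family correlations, so heavy-compound vapor fractions
  for those systems carry large model uncertainty.
* Successive substitution slows near mixture critical points; the
  trivial-solution guard flags rather than resolves such states.
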