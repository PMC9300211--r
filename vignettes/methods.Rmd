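---
title: "Characterising a weak intramolecular halogen bond by NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising a weak intramolecular halogen bond by NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbnmr)
```

## The scientific problem

A halogen bond between a non-fluorinated aryl iodide and an ether oxygen
is worth well under 1 kJ/mol in solution — far too weak to be observed
directly through interaction-induced chemical shift changes. The
strategy implemented here sidesteps that limit by embedding the donor
and acceptor in a cooperatively folding β-hairpin peptide, so that the
weak interaction manifests as a measurable shift in the folding
equilibrium, and by reading the donor–acceptor geometry out of residual
dipolar couplings (RDCs) rather than chemical shifts. Three independent
measurements of the same folded population — thermal melting of
chemical shifts, NOE/J-based ensemble deconvolution, and RDC ensemble
fitting — are reconciled against each other, and the package reproduces
that entire workflow on synthetic data with known ground truth.

## Two-state melting of chemical shifts

Every reporter proton is assumed to exchange fast between one folded
and one unfolded environment, so its observed shift is the
population-weighted average

$$\delta(T) = \delta_U + \frac{\delta_F - \delta_U}
  {1 + \exp\!\left(-\frac{\Delta H_m}{R}\left(\frac{1}{T} -
  \frac{1}{T_m}\right)\right)},$$

with terminal shifts $\delta_U, \delta_F$, melting temperature $T_m$
(folded fraction 0.5) and the unfolding enthalpy $\Delta H_m$ at
$T_m$. `fit_two_state()` fits all four parameters by
Levenberg–Marquardt least squares; because sigmoid fits are sensitive
to starting values, it multi-starts with $T_m$ placed in the first,
middle and last third of the temperature range, terminals seeded from
the coldest/hottest 10% of points, and $\Delta H_m$ = 25 kJ/mol, and
keeps the lowest-SSE convergent fit. The model carries no heat-capacity
term and no pre/post-transition baseline drift: the assumption is a
genuinely two-state equilibrium observed far from solvent phase
transitions.

`global_melt_fit()` implements the pooled ("normalised") analysis:
each proton is first fitted individually, rescaled to folded fraction
with its own terminals, and the pooled points are refitted with the
terminals pinned at 0/1, yielding one global $(T_m, \Delta H_m)$.
Protons with no usable transition (shift change below 0.01 ppm by
default) are excluded with a warning rather than poisoning the pool.

Free energies come by two deliberately separate routes:
$\Delta G^\circ = -RT\ln k_F$ with
$k_F = (\delta_U-\delta)/(\delta-\delta_F)$, and
$\Delta G^\circ = \Delta H_m - T\,\Delta S_m$ from tabulated
enthalpy/entropy pairs. The entropy itself is reported both as
$\Delta H_m / T_m$ and as the intercept of the van 't Hoff line
(`van_t_hoff_entropy()`, computed from the observed shifts, not the
fitted curve); for exact two-state data the two coincide, and on real
data their disagreement is a useful model diagnostic, so neither is
silently preferred.

### Relative stability of two compounds

The halogen-bond contribution is isolated by comparing the compound of
interest against a reference identical in everything except the
acceptor oxygen. Rather than subtracting two noisy absolute free
energies, the ratio of folding constants $K = k_F^{(1)}/k_F^{(2)}$ is
estimated directly from matched-temperature shifts: the identity
$k_{F1} = K\,k_{F2}$ rearranges to the bilinear form
$(\delta_{U1}-\delta_1)(\delta_2-\delta_{F2}) =
K\,(\delta_1-\delta_{F1})(\delta_{U2}-\delta_2)$, which avoids dividing
by near-zero shift differences at the extremes of the transition.
`relative_folding()` fits $K$ as the slope of the zero-intercept
regression of those products (the identity forces the line through the
origin, so a free intercept would only absorb noise), and
$\Delta\Delta G = -R\,T_{m2}\ln K$. The pipeline pools the product
points of all common protons into one regression: each proton's points
share the same slope $K$ regardless of its shift amplitude, so pooling
is scale-consistent. Temperatures where an observed shift strays
outside its terminals (folded fraction outside [0, 1]) are dropped with
a warning.

Amide temperature coefficients (`temperature_coefficients()`) are
|slope| of shift vs temperature in ppb/K, classified by the
conventional bands: below 3 intramolecular hydrogen bond, 3–5
(inclusive at both ends) dynamic equilibrium, above 5 solvent exposed.

## NOE build-ups and restraints

Cross-relaxation rates come from the initial-rate approximation:
`fit_initial_rate()` performs a zero-intercept regression of cross-peak
intensity on mixing time (the NOE is zero at zero mixing time by
construction). When no window is given, the linear regime is chosen as
the largest prefix of mixing times whose fit keeps all relative
residuals under 10% — with visibly curved build-ups this still accepts
a mild downward bias in the slope, which is why the default seven
mixing times span only 0.1–0.7 s. The reported standard error assumes
noise proportional to intensity, which is how cross-peak volume errors
actually behave; the suite verifies two-sigma coverage of at least 90%
under that noise model, where a homoscedastic OLS error underestimates
badly.

Distances follow the isolated-spin-pair calibration
$r = r_\mathrm{ref}(\sigma_\mathrm{ref}/\sigma)^{1/6}$ against a
geminal methylene pair fixed at 1.78 Å (the glycine Hα pair in the
synthetic system); tolerances are max(10%, 0.2 Å). Couplings use the
Karplus relation $J = A\cos^2(\phi-60°) + B\cos(\phi-60°) + C$ with the
Vuister–Bax $^3J(H^N,H^\alpha)$ coefficients (6.51, −1.76, 1.60 Hz) by
default; both the calibrant and the coefficients are configuration, not
inference.

## NAMFIS-style deconvolution

Given a rigid conformer pool, `fit_populations()` finds populations
$p \ge 0, \sum p = 1$ minimising the tolerance-weighted SSE between
observed and back-calculated averages, with
$\langle r\rangle = (\sum_i p_i r_i^{-6})^{-1/6}$ (slow-tumbling
isolated spin pairs; the exponent is configurable to −3) and linear
averaging of Karplus-predicted couplings. Scaling each residual by its
restraint tolerance makes Å and Hz commensurable. The simplex
constraint is handled by the smooth reparametrisation
$p_i = z_i^2/\sum_j z_j^2$ with analytic gradients under BFGS, from a
uniform start plus 10 Dirichlet-random restarts under a fixed seed;
populations under 1% are pruned once and the survivors refitted. Ties
(equal SSE to 1e−10) resolve to the sparsest solution, then the lowest
conformer index, so output is deterministic. Tests verify the optimiser
against exhaustive simplex grid search on every 3-conformer sub-pool.
`jackknife_stability()` reports per-conformer population spread under
random restraint deletion, which is the honest way to attach error bars
to ensemble populations.

## RDC analysis

RDCs are extracted as $D = (T - J)/n_H$ from total and scalar
couplings; the multiplicity scaling reproduces the printed methyl
values of coupled-HSQC tables. Each unit internuclear vector
contributes a Losonczi design row
$(c_y^2-c_x^2,\; c_z^2-c_x^2,\; 2c_xc_y,\; 2c_xc_z,\; 2c_yc_z)$ so that
$D = D_{max}\,(\mathrm{row}\cdot s)$ for the Saupe 5-vector
$s = (S_{yy}, S_{zz}, S_{xy}, S_{xz}, S_{yz})$; $D_{max}$ is −22,700 Hz
for a 1.09 Å C–H, and since the tensor absorbs overall scale only the
interpretation of tensor magnitude depends on it. `svd_fit()` solves
the weighted linear system by SVD and reports the Cornilescu quality
factor $Q$, the design-matrix condition number, and $\chi^2$; rank
deficiency is reported as degenerate vector geometry rather than
silently regularised.

Ensemble fitting (`ensemble_rdc_fit()`) assumes one shared alignment
tensor across conformers — appropriate for a single weak-alignment
medium where all conformers experience the same orienting field — and
alternates two exact linear solves: tensor from the
population-averaged rows, then populations by simplex-constrained
least squares (solved exactly by support enumeration), iterated to a
$\chi^2$ change below 1e−8 with seeded multi-starts. A per-conformer
tensor would double-count alignment degrees of freedom for a
10-observation dataset.

Sub-ensemble selection (`model_select()`) scores the best m-conformer
ensemble by $\chi^2 + \lambda\,k$ with $k = 5 + (m-1)$ free parameters.
Because each size's $\chi^2$ is already a minimum over all
$\binom{n}{m}$ subsets, an AIC penalty ($\lambda = 2$) systematically
overfits, essentially always erring large. The default is therefore
the extended-BIC penalty for searched model spaces,
$\lambda = \ln n_{obs} + 2\ln n_{pool}$; the suite verifies at least
90% recovery of the true ensemble size at 1 Hz noise under this
default. Plain AIC and BIC remain available through the `lambda`
argument.

## Fold and halogen-bond classification

A conformer is called folded when (i) the turn residues' (φ, ψ) sit
within ±40° windows around the type II' ideals (60°, −120°) and
(−90°, 0°), (ii) the mean interstrand Cα–Cα distance over the paired
residues is at most 5.5 Å, and (iii) at least two cross-strand N···O
contacts are under 3.5 Å. It is halogen bonded when the I···O distance
is below the Bondi van der Waals sum 1.98 + 1.52 = 3.50 Å and the
C–I···O angle is at least 140°, a floor spanning both σ-hole approach
ranges observed in protein-like environments (~145–150° and ~160–170°).
All thresholds are configuration (`fold_criteria()`); none are fitted.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
truth without any external data. It emulates, at reduced scale, the
study conditions: a 10-residue hairpin with the halogen-bond donor on
residue 3 and the acceptor on residue 8, a central type II' turn, a
two-state melt with $T_m$ = 274 K and $\Delta H_m$ = 23.9 kJ/mol
sampled 218–348 K in 10 K steps (the reference compound: 267.6 K,
26.4 kJ/mol), NOE build-ups at seven mixing times 0.1–0.7 s, and RDCs
from a fixed Saupe tensor scaled so noise-free couplings span roughly
−70 to +60 Hz. Chains are built by natural-extension-of-reference-frame
placement with fixed ideal bond lengths and angles; the hairpin
template's dihedrals were tuned once against the fold criteria (with a
steric penalty) and frozen. Default pool: 10 folded conformers
(template + 8° Gaussian dihedral jitter, resampled until the built
geometry actually satisfies the fold criteria — the generator's labels
are a guarantee about emitted geometry, not build intent) and 10
random-coil conformers from a broad β/α basin mixture; 60% of folded
conformers are built halogen-bonded at 3.2 Å / 145°. The default true
populations put 30% on a halogen-bonded folded conformer, 20% on a
non-bonded folded one and 50% on two coils, so the ground truth is
50% folded / 30% halogen-bonded, and the comparison temperature
defaults to $T_m$ so the melt-derived folded fraction is consistent
with the ensemble populations.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: conformational strain relaxation
(jittered conformers keep ideal geometry), spin diffusion and
anisotropic tumbling in the NOE, side-chain rotamer ensembles beyond a
single coarse pseudo-atom per residue, chemical-shift prediction (the
melt terminals are synthetic constants), and alignment-medium physics
(the Saupe tensor is imposed, not predicted from shape).

## Numerical choices and problem sizes

R = 8.314 J/(K·mol); temperatures in kelvin, coordinates in Å, angles
in degrees at interfaces and radians internally. The recovery studies
run at sizes chosen to characterise the estimators well while keeping
the full suite quick: 50 replicates for the melt-recovery and
selection-consistency studies, a 20-conformer pool for deconvolution
closed loops, an 8-conformer pool for the brute-force grid
cross-checks (all 56 3-conformer sub-pools at 0.02 simplex
resolution), and 10-vector RDC datasets. Exhaustive sub-ensemble
search is used up to `choose(n, m)` = 3003 subsets per size, greedy
forward selection beyond.

## Known limitations

The two-state model ignores heat capacity and baseline drift; the
initial-rate window rule biases rates slightly low on curved build-ups;
the rigid-pool assumption means restraint misfit cannot be repaired by
geometry relaxation; the shared-tensor assumption is untestable from a
single alignment medium; and the coarse side-chain representation makes
the synthetic halogen-bond geometry a construction, not an energetic
prediction.
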