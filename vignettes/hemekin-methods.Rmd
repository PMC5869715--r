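---
title: "hemekin: models, calibration and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemekin: models, calibration and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nitric oxide photodissociated from a solvent-exposed heme site (a
microperoxidase-like system) rebinds with kinetics that depend strongly on
the solvent: a glycerol/water mixture cages the ligand and rebinding is
purely geminate on sub-picosecond to few-picosecond timescales with near-unit
yield, while in pure water the ligand can diffuse away, producing a second,
much slower rebinding phase and a substantial non-rebinding fraction within
a nanosecond. `hemekin` implements a reduced-coordinate, fully reproducible
model of this experiment: two electronic states represented as
reproducing-kernel surfaces, a smooth reactive mixing of the two, Langevin
dynamics under solvent surrogates, and the downstream survival-fraction and
structural analyses.

The three coordinates are the iron–ligand center-of-mass distance $R$ (Å),
the orientation angle $\theta$ of the diatomic about its center of mass
(degrees; $\theta \approx 160^\circ$ is the Fe–NO bound geometry,
$\theta \approx 27^\circ$ the metastable Fe–ON isomer), and the iron doming
coordinate $\varphi$ (degrees) with a harmonic term
$V_c(\varphi) = \tfrac12 k (\varphi - \varphi_e)^2$.

# The synthetic reference world

No ab initio data ship with the package. Instead `surface_spec()` /
`make_reference_surfaces()` build analytic doublet (bound, ²A) and quartet
(repulsive, ⁴A) surfaces pinned to the published stationary points:

* ²A: deep FeNO well, 21 kcal/mol at ($R$ = 2.37 Å, $\theta$ = 160°);
  secondary FeON well, 6 kcal/mol at (2.48 Å, 27°); dissociation limit
  defines the zero of energy.
* ⁴A: repulsive at the bound geometries with a shallow (1 kcal/mol) outer
  well near 3.2 Å, and a calibrated Mp···NO well spanning
  $\theta \in [55^\circ, 120^\circ]$ near $R$ = 2.45 Å.

The radial structure is a sum of Morse-type wells plus an exponential
background, all vanishing at long range. The angular structure is carried by
envelope functions (von-Mises bumps for the two doublet wells, a plateau for
the quartet well) that are **projected onto Legendre polynomials
$P_0..P_{10}$ and truncated there**. This makes the synthetic world exactly
representable by the package's finite angular expansion, so the RKHS fit can
interpolate the default grid to machine precision — which is what makes the
"node residual ≤ 1e−8" invariant meaningful. For generic (non-band-limited)
energies tabulated on more than 11 angular nodes that invariant cannot hold
with a fixed order-10 expansion; the fit then reports the truncation misfit
in its diagnostics instead.

Two small consequences of the truncation are handled explicitly. First, the
envelope peaks ring by a few parts in $10^3$; depth-scale factors in the
defaults compensate so the achieved well depths are 21.00/6.00 kcal/mol.
Second, the quartet plateau leaves ±0.1–0.25 kcal/mol ripples on the
Mp···NO shelf; `locate_barriers()` therefore prunes extremum pairs with
prominence below 0.3 kcal/mol (the construction tolerance) before pairing
minima with maxima.

## The deep quartet well and the printed barriers

The published account constrains the lowest adiabat at $R$ = 2.4 Å with a
4A shift $\Delta$ = 5 kcal/mol to cross ²A→⁴A near 55°, return near 120°,
with barriers of 3.5 and 1 kcal/mol in the FeON→FeNO direction. Those
numbers force the quartet state to dip roughly 7–9 kcal/mol below its
asymptote in the crossing region: with the FeON well at −5.8 kcal/mol on
that cut, the first crossing must sit near −2.3, i.e. the shifted quartet
must reach −2.3 there. A quartet bounded below by a merely "faint"
(1 kcal/mol) well cannot do this — the states would first cross above
+4 kcal/mol and the first barrier would exceed ~10 kcal/mol. The package
therefore carries a genuine Mp···NO well on the quartet surface, localized
in both $R$ (steep Morse, α = 5 Å⁻¹ at 2.45 Å) and $\theta$ (power-6
plateau), solved analytically so the crossings and barriers land on the
printed values; the shallow 1 kcal/mol well remains everywhere else.
Localizing the well in $R$ matters for the dynamics: a long-ranged version
steers the photodissociated ligand sideways into the well during the 500 fs
excited-state propagation, destroying the observed monotone outward motion.

# RKHS representation

`fit_rkhs()` implements
$$V(R, \theta, \varphi) = \sum_{\lambda=0}^{10} V_\lambda(R, \varphi)
P_\lambda(\cos\theta) + V_c(\varphi), \qquad
V_\lambda(R,\varphi) = \sum_{i,j} \beta_{\lambda,i,j}\,
\kappa(R, R_i)\, \Gamma(\varphi, \varphi_j),$$
with the reciprocal-power radial reproducing kernel of smoothness $n=2$ and
decay $m=5$ (leading $R^{-6}$ tail, dispersion-like) and a Gaussian doming
kernel. $V_c$ is subtracted before projection and re-added at evaluation.
Per ($R_i$, $\varphi_j$) column the angular values are least-squares
projected on $P_0..P_{10}$ (with Gauss–Legendre nodes in $\cos\theta$ this
coincides with the quadrature projection); per $\lambda$ one symmetric
positive-definite Gram system (radial ⊗ Gaussian, Cholesky) yields
$\beta_\lambda$, optionally stabilized by a Tikhonov term for noisy grids.

Numerical choices that differ from the obvious defaults:

* **Doming kernel width σ_φ = 10°** (twice the node spacing). With σ_φ equal
  to the spacing the interpolant of the φ-independent well wiggles by
  ~0.6 kcal/mol between nodes — 3% of the well depth, enough to corrupt
  doming forces. 10° brings the off-node error below 0.03 kcal/mol at a
  Gram condition (~4·10⁸) still safely factorizable.
* **Radial grid**: 20 nodes on [1.8, 10] Å with 0.1 Å spacing below 2.7 Å.
  The $n=2$ kernel is only piecewise-smooth between nodes, and the repulsive
  wall is the hardest feature to interpolate; the dense short-range spacing
  keeps the off-grid error of the fitted doublet below 0.05 kcal/mol in the
  thermally relevant region.
* **Angular grid**: 21 Gauss–Legendre nodes in $\cos\theta$ (a node falls
  0.1 rad from the FeNO minimum, so the tabulated grid resolves the
  −21 kcal/mol well to 0.15 kcal/mol).

# Two-state mixing

The quartet is shifted by a constant $\Delta$ (default 7.5 kcal/mol for
kinetics, 5 for the barrier scans) so the shifted ⁴A sits exactly $\Delta$
above the ²A dissociation limit. The reactive energy uses normalized
exponential weights $w_s \propto e^{-(V_s - V_{\min})/\Delta V_{mix}}$ with
$\Delta V_{mix}$ = 0.5 kcal/mol: smooth ($C^\infty$ in the state energies),
exactly the lowest adiabat in the limit $\Delta V_{mix} \to 0$, equal to the
common value at a crossing, and with an analytic gradient (used by the
integrator, so gas-phase NVE dynamics on the mixed surface conserve energy).
Environment-dependent barrier shaping (gas/water/glycerol-water) is an
additive pair of Gaussian bumps in $\theta$ near 45° and 130°, applied to
both states and switched off radially beyond ~5 Å; it is a modeling
surrogate calibrated to the printed environment barriers, not a fitted
solvent free energy.

# Dynamics

Langevin dynamics (BAOAB splitting; velocity Verlet when frictionless) at
$\Delta t$ = 1 fs propagate $(R, \theta, \varphi)$ with effective inertias
30 amu (NO mass), $\mu_{NO} d_{NO}^2$ = 9.89 amu Å² (NO rotation,
$d_{NO}$ = 1.151 Å), and 310 amu Å² for doming (≈50 cm⁻¹ with the default
stiffness $k$ = 0.02 kcal/mol/deg²). θ is reflective at the poles; an inner
guard reflects at 0.8 Å. Photodissociation alone integrates at 0.25 fs
because the excited-state wall is the stiffest feature (1 fs conserves
gas-phase energy only to a few 10⁻³ kcal/mol there). The random stream is an
own xoshiro256++ generator seeded per (base seed, trajectory id), so
ensembles are bit-reproducible and order-independent.

Rebinding is detected geometrically/electronically: doublet weight ≥ 0.9,
$R \le 2.8$ Å and $\theta \ge 120^\circ$, sustained for 200 fs (the sustain
window suppresses single-frame recrossings); the recorded time and doming
angle are taken at the first frame of the sustained window. The Fe
out-of-plane distance surrogate is $d = 0.05\,\mathrm{Å/deg}\cdot
(\varphi - \varphi_e)$.

## Solvent surrogates

Explicit solvent is replaced by per-coordinate friction, temperature, and a
few structural terms. All values below are the package's one-time
calibration against the reported phenomenology (geminate-only biexponential
kinetics with ~80:20 amplitudes and near-unit yield in glycerol/water; two
timescales, a static fraction, and rebound fraction well below 1 in water;
higher rebound fraction at 283 K than 300 K); they were tuned once and then
frozen.

| label | γ (R, θ, φ) /ps | cage | extras |
|---|---|---|---|
| gas | 0, 0, 0 | — | NVE |
| water | 5, 30, 5 | — | entropic force, hot drag |
| glycerol_water | 15, 400, 15 | wall at 5.2 Å (5 kcal/mol/Å²) | — |
| water_ions | 8, 48, 8 | soft wall at 6 Å (0.5) | entropic force, hot drag |

Three surrogate terms deserve explanation:

* **Entropic radial force** $+2 k_B T / R$ (free energy $-2k_BT \ln R$):
  the reduced radial coordinate of a 3-D ligand carries the $R^2$ measure of
  accessible solvent volume. Without it, 1-D diffusion always returns and
  rebinding saturates; with it, escape versus geminate capture is a genuine,
  temperature-dependent competition, which yields the static (non-rebinding)
  component. It is applied in the diffusive solvents and omitted in the cage
  (where the accessible volume does not grow with $R$) and in gas-phase NVE
  runs (where a temperature-dependent force has no place).
* **Hot-ligand drag**: radial speeds above 6.5 Å/ps relax toward that
  threshold at 0.04 fs⁻¹, representing the rapid collisional cooling of a
  ballistic photodissociated ligand; thermal speeds (~3 Å/ps) are
  unaffected, so equilibrium properties are preserved. Under purely linear
  friction the water surrogate cannot simultaneously stop the
  photodissociated ligand near 3.9 Å and sustain the slow (>50 ps) return
  phase; speed-dependent dissipation resolves exactly that. The strongly
  damped glycerol mixture does not need it (its linear friction already
  dissipates the excess energy within the cage).
* **Viscosity scaling**: frictions scale with an Arrhenius factor
  $e^{(E_a/k_B)(1/T - 1/300)}$, $E_a$ = 4.2 kcal/mol for water-like
  solvents (the measured activation energy of water viscosity; γ is ×1.53
  at 283 K). This carries the temperature effect the experiment attributes
  to damped structural dynamics at low temperature: at 283 K the ligand
  rotates and diffuses less during and after photodissociation, fewer
  trajectories stray into the FeON channel or escape, and the rebound
  fraction increases.

An outer reflecting wall at 20 Å stands in for the finite solvent box.
Beyond the kernel range the potential is at its asymptote and the ligand
diffuses freely; return remains possible.

# Kinetics and analyses

`survival_curve()` builds the right-censored empirical survival fraction;
`fit_survival()` does constrained least squares of
$S(t)=\sum_i a_i e^{-t/\tau_i} + a_3$ on a 200-point log-spaced grid
snapped to the observed event times (evaluating the step function at its
jump points removes the staircase bias that otherwise inflates fitted
timescales by a few percent), with ≥10 seeded multistarts and bounds
$a \in [0,1]$, $\tau \in [10^{-3}, 10\,t_{sim}]$ ps. Amplitudes are *not*
constrained to sum to one — the published fits themselves do not — beyond a
soft 1.05 bound. `select_model()` compares candidate forms by AICc computed
on the residuals of the survival *increments* (the curve itself is a
cumulative, random-walk-like process whose pointwise residuals are strongly
autocorrelated; its increments are nearly independent), with the effective
sample size equal to the number of events and ties broken toward fewer
parameters.

`oop_distribution()` histograms the doming-derived Fe-oop distance at the
moment of rebinding; `classify_by_rebinding_time()` partitions trajectories
into short (<20 ps), intermediate, and long (censored) classes with
(R₀, θ₀) centroids — fixed-boundary binning, because the class boundaries
are stated, not learned.

# What a green test does and does not establish

The synthetic world reproduces the printed stationary points, crossings,
barriers, the closed-form Table-style worked example, the geminate/diffusive
kinetics phenomenology, and the temperature ordering. It does **not**
contain an explicit peptide or solvent, so quantities that depend on
atomistic detail (absolute rebinding times beyond their order of magnitude,
cluster centroids, water self-diffusion) are out of scope; agreement there
would be coincidence and is not asserted. Known limitations, recorded
deliberately:

* The printed "14 kcal/mol" separation between the two doublet minima is
  inconsistent with the printed depths (21 − 6 = 15); the package follows
  the depths, which are the pinned calibration targets.
* Gas-phase FeON→FeNO isomerization at the printed ~250 ps timescale is not
  reachable from the barrier-scan calibration (the two published barrier
  sets — bare surfaces at Δ=5 versus His-heme+environment at Δ=7.5 — are
  mutually inconsistent and are treated as separate constraint sets). The
  isomerization machinery is exercised mechanistically instead, and the
  estimator-recovery target at the printed rate is met exactly.
* The quartet "faint minimum" is faint only away from the crossing region;
  near it the printed barriers force a ~9 kcal/mol Mp···NO well.
* A single fitted slow timescale from a 200-trajectory ensemble is noisy
  (roughly a factor-2 spread across seeds); acceptance checks use medians
  over replicate ensembles at the stated size.

# Reproducibility

Every stochastic element (grid noise, thermostat, multistart fitting,
synthetic draws) is seeded; rebinding ensembles are bit-identical across
reruns and independent of execution order. `run_pipeline()` embeds the
resolved configuration and seed in every artifact it writes.
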