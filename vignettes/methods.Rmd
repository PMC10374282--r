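---
title: "Models and methods behind fusedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fusedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedyn)
```

# Scope

fusedyn analyzes the conformational heterogeneity and exchange dynamics of
multi-domain proteins by fusing five complementary solution measurements:
time-resolved FRET (ensemble TCSPC), pulsed EPR (DEER), filtered
fluorescence correlation spectroscopy (fFCS), neutron spin echo (NSE) and
small-angle X-ray scattering (SAXS). Two candidate conformers — a major
state M1 and a minor state M2 — are discriminated jointly against all data
by a Fisher-method meta-analysis. A synthetic-data module generates toy
two-conformer systems and statistically faithful data for every modality,
so the entire pipeline is exercisable (and is tested) without any
experimental download.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do
not demonstrate about real data.

# Label models: accessible volume and contact volume

Dyes and spin labels are tethered to a residue by a flexible linker, so a
measured distance is a distribution over label positions, not a single
atom-pair distance. `accessible_volume()` simulates the allowed positions
on a cubic grid around the attachment bead: a cell belongs to the cloud
when it lies within the linker length of the anchor, clears every bead by
bead radius + label radius, and is reachable from the anchor through
clash-free neighbouring cells (26-connectivity flood fill).

Two implementation details matter on coarse bead chains:

* the attachment bead itself never obstructs, and
* the flood fill is seeded from every clash-free cell within a *seed
  radius* (default 6 Å) of the anchor, because the covalently bonded
  neighbour beads always overlap the anchor cell itself.

A fully buried site produces an explicit "inaccessible site" error rather
than an empty cloud. We use one effective label radius per site (the
largest of the usual three dye radii) — a documented coarsening relative
to three-radius AV variants. Spin labels use the same machinery with
MTSSL-like defaults (8 Å linker, 4.5 Å width, compact head group);
contact fractions for `accessible_contact_volume()` (the fraction of dyes
trapped at the protein surface) must be supplied by the user, typically
from time-resolved anisotropy.

Default grid spacing is 1.0 Å and is configurable; the discrimination
pipeline uses 1.5 Å, which changes predicted mean distances by well under
the restraint uncertainties. Coordinates are in Å throughout, with nm
used for DEER distance axes. The orientation factor is fixed at
$\kappa^2 = 2/3$ (mobile-dye regime); orientation uncertainty is carried
as part of the per-distance error budget, not recomputed.

# TCSPC: the FRET-induced donor decay

The donor decay with acceptor factorizes as
$f_{D|D(DA)}(t) = f_{D|D(D0)}(t)\,\epsilon_D(t)$ under the quasi-static
homogeneous assumption (all donor states are quenched by the same
FRET-rate distribution). The FRET-induced donor decay is

$$\epsilon_D(t) = (1 - x_{DOnly}) \int p(R_{DA})\,
  e^{-t k_0 (R_0/R_{DA})^6}\, dR_{DA} + x_{DOnly},$$

with Förster radius $R_0 = 52$ Å and $k_0 = 1/\tau_0$, $\tau_0 = 4$ ns by
default. The integral term is scaled by $1 - x_{DOnly}$ so that
$\epsilon_D(0) = 1$; without this normalization the donor-only offset
would double-count at $t = 0$. Distances are modeled as a superposition
of two normal components with common width $w$ parameterizing
$\exp(-2(R-\bar R)^2/w^2)$, i.e. a Gaussian SD of $w/2$; the default
$w = 12$ Å is fittable. Quadrature uses a 0.5 Å grid over 10–150 Å with
truncation below 1 Å and renormalization.

The measured histogram is modeled as
$g(t) = N_F\, f(t) \otimes IRF(t) + N_{BG}\, IRF(t) + bg$ with a unit-sum
IRF, an optional fitted sub-channel IRF shift (default 0) and an optional
multiplicative channel-linearization curve. The convolution is causal and
linear (no repetition-rate wrap); it matches the continuous convolution
closed form outside the IRF support and an $O(n^2)$ direct sum to
machine precision. FRET-sensitized acceptor decays are the channel-width
scaled convolution of the quenched donor decay with the acceptor
reference.

Fitting (`fit_decay()`) is a modified Levenberg–Marquardt minimization
with the classical Poisson weights $\sigma_k = \sqrt{\max(c_k, 1)}$, fit
range covering the full IRF and 99.9% of the cumulative fluorescence,
the fluorescence amplitude profiled analytically per dataset, and any
distance-model parameter shareable globally across datasets. Support
plane profiling with an F-test at 95% provides uncertainty intervals.
Two documented options matter for calibration studies: data-based
(Neyman) weights carry a small low-count bias that shifts recovered
fractions by below 0.01 at $10^6$–$10^7$-count scales; `weighting =
"model"` (Pearson) removes it, and `fit_range = "full"` disables the
data-driven range selection. Defaults keep the field's standard
behaviour.

`mem_reconstruct()` provides the model-free route: maximizing
$\alpha S - \chi^2/2$ over a distance grid with the extended Skilling
entropy against a flat prior, solved per regularization weight by
L-BFGS-B in log-density coordinates, with the corner of the (log misfit,
log entropy) L-curve selecting $\alpha$. FRET-lines (static and dynamic)
relate fluorescence-weighted lifetimes and efficiencies for
burst-histogram interpretation; the dynamic line uses species-weighted
photon averaging so that its endpoints sit on the static line and its
interior bows to longer lifetimes.

# DEER: dipolar kernel and Tikhonov inversion

The dipolar evolution signal of a spin pair at distance $R$ is
$K(t, R) = \int_0^1 \cos[(3x^2 - 1)\,\omega_{DD} t]\, dx$ with
$\omega_{DD} = 2\pi\,\nu_{dip}/R^3$. The constant
$\nu_{dip} = g^2 \mu_B^2 \mu_0 / (4\pi h)$ evaluates to 52.04 MHz·nm³
with the free-electron $g = 2.0023$ (the value 2.006 sometimes quoted
for nitroxides would give 52.24; we use the canonical kernel constant).
The kernel is evaluated in closed form via Fresnel integrals, with a
fixed-order trapezoid quadrature retained as an independent route; the
two agree to below $10^{-7}$.

Traces follow $V(t) = [1 - \Delta(1 - Kp)]\, e^{-kt}$: a homogeneous 3D
exponential background (excluded-volume backgrounds are out of scope)
with modulation depth $\Delta$. Background correction fits the log tail;
`deer_invert()` avoids committing to a plateau estimate by absorbing the
modulation depth into the non-negative solution through the shifted
kernel identity $F - 1 = (K - \mathbf{1})(\Delta p)$. Inversion is
non-negativity-constrained Tikhonov regularization with a free-boundary
second-difference penalty (an unconstrained mode is retained for
linear-algebra checks), on a default grid of 1.5–8 nm at 0.05 nm.
The regularization weight comes from the maximum-curvature (Menger)
corner of the L-curve after monotonicity repair; across seeded synthetic
traces the corner tracks the error-optimal weight to about one grid step
in the median. The synthetic DEER window is 8 µs so that distances up to
about 6 nm complete a dipolar period; shorter windows visibly bias the
background fit for long distances.

# Filtered FCS: species filters and shared relaxation times

Species filters are the weighted least-squares unmixers
$W = (M^\top S^{-1} M)^{-1} M^\top S^{-1}$ over detector × TAC channels,
unbiased by construction and minimal-variance under shot noise. Species
correlation functions are computed on binned weighted signals with a
multi-tau scheme (16 lags per cascade, factor-2 coarsening) —
a documented deviation from photon-by-photon correlation, adequate at
the microsecond lags of interest.

The model factorizes each curve into a 3D-Gaussian-focus diffusion term
and a kinetic term: three shared relaxation times with local amplitudes
constrained to the simplex (softmax parameterization, so $A_1 + A_2 +
A_3 = 1$ holds exactly), anti-correlation amplitudes on the two
cross-correlations (which share one effective number of molecules), and
an acceptor-bleach factor on curves involving the high-FRET species
(default bounds 1–20 ms). The global fit treats all curves of all
variants as one weighted least-squares problem with per-point SDs from
measurement splits. The per-variant scalar "average relaxation time" is
the amplitude-weighted arithmetic mean $\sum_i A_i t_{c,i}$.

Exchange kinetics connect to physics through the rate matrix: relaxation
times are the inverse non-zero eigenvalues, computed via the
detailed-balance symmetrization (a symmetric eigenproblem), and
`kinetic_correlation()` gives the exact multi-exponential amplitudes of
any species pair, validated against a matrix-exponential propagator and
a slow telegraph-process simulator.

# NSE: rigid-body diffusion and its corrections

The first-cumulant effective diffusion coefficient of a rigid body is an
orientational average of amplitude-weighted quadratic forms of
$(\hat q, \hat q \times r_j)$ with the 6×6 diffusion tensor, normalized
by $q^2 F(q)$. Coordinates are centred at the scattering-weighted
centroid, which must coincide with the tensor origin — then the
rotational contribution vanishes as $q \to 0$ and $D_0(q) \to D_t$. The
average uses a Gauss–Legendre × uniform-azimuth product grid (648
directions by default, well above the accuracy of a 590-point rule for
these integrands).

The full intermediate scattering function multiplies an internal-dynamics
channel $[(1 - A(q)) + A(q) e^{-\Gamma t}]$, the translational factor
$\exp(-q^2 D_t H_t t / S(q))$ — note the *division* by the structure
factor, the effective-diffusion convention $D_{t,eff} = D_t H_t /
S(q)$ — and the rotational spherical-harmonic expansion truncated at
$l_{max} = 15$ (configurable; terms above 15 contribute below 0.1% for
$qR_g \le 3$). Hydrodynamic corrections use $H_t = 1 - c[\eta]$ and the
spherical-particle relation $1 - H_r = (1 - H_t)/3$; for $H_t = 0.61$
this gives $H_r = 0.87$. The Debye–Waller bound on invisible internal
motion is $u = \sqrt{-3 \ln(1 - err)}/q$; at $err = 0.01$ and $q = 0.5$
nm⁻¹ the formula gives $u = 0.347$ nm (reported values of 0.25 nm in the
literature do not follow from these inputs through this formula; we
implement the formula as stated). Diffusion tensors are *inputs*
(produced by dedicated hydrodynamics software); the Kirkwood-type bead
helper, exact for a single sphere, exists to build synthetic tensors for
tests only.

# SAXS: forward model, reduction and two-state fits

Forward curves use the exact Debye double sum over beads. Guinier fits
iterate the window to $qR_g < 1.3$ (the sphere's $q^4$ curvature biases
the fitted $R_g$ by about 2% at this window — a property of the Guinier
approximation, not of the fit). Concentration series are reduced by
per-q linear extrapolation of $I/c$ to $c = 0$, with the
highest-concentration data merged in above a user-set $q$ where
interparticle interference is negligible. The Percus–Yevick hard-sphere
structure factor is analytic, with a series limit below $A = 2qR < 0.05$
(reproducing $S(0) = (1-\phi)^4/(1+2\phi)^2$ to $10^{-10}$) and the
decoupling correction $S'(q) = 1 + \beta(q)(S(q) - 1)$ for asymmetric
particles. No hydration layer is modeled: absolute $\chi^2$ values
against experimental curves are expected to be inflated relative to
tools that model the contrast layer.

Model-data comparison fits scale and offset analytically (affine
invariance) and divides by $N - 2$ or, when the particle diameter is
supplied, by a Shannon-channel count $N_s = \Delta q\, D_{max}/\pi$.
Two-state ensemble fits profile $\chi^2$ over the population fraction
grid and report the 68% interval from the profile.

# Discrimination: Fisher's method over conformer pairs

Every (M1, M2) candidate pair is scored by (i) the uncertainty-weighted
squared deviations between experimental FRET/DEER distances and AV-model
predictions — state-specific restraints on the assigned member, shared
restraints on both, with the label assignment swap evaluated and the
better orientation kept — and (ii) the best two-state SAXS mixture. Both
become upper-tail $\chi^2$ p-values: the label score with the effective
number of informative restraints from greedy backward elimination
(restraints are dropped while the Spearman correlation of the candidate
ranking stays above a threshold, default 0.9 — duplicated restraints are
discounted, orthogonal ones are all retained), and the SAXS score after
rescaling the per-point reduced $\chi^2$ to the Shannon-channel scale,
since neighbouring $q$ points are strongly correlated. Fisher's method
combines them, $X^2 = -2\sum \ln p_i \sim \chi^2_{2k}$, and pairs with
combined $p \ge 0.68$ are kept — a threshold at which decoy pairs
displaced by more than 15 Å RMSD are rejected at the 80%+ level in the
synthetic end-to-end test while the true pair survives.

Ensemble precision is summarized by the SD of all pairwise Cα–Cα
distances over the accepted ensemble, normalized by the same quantity
for a *reference* ensemble obtained by resampling the restraints within
their uncertainty around a best model and re-running the selection
(seeded); per-residue RMSF is computed after three rounds of iterative
mean-structure superposition.

# The synthetic-data generator and what the tests show

`make_toy_system()` builds a deterministic Cα bead chain (3.8 Å spacing,
four rigid bodies of 20 beads by default) whose distal bodies rotate by
a hinge angle (default 30°) to form the second conformer; label pairs
across the hinge are selected so distance changes span roughly 5–30 Å.
The ground-truth populations default to 0.61/0.39 (room-temperature
state fractions) for the label spectroscopies and 0.31/0.69 for the
structural mixture seen by SAXS/NSE (the low-temperature composition at
which those data are recorded). Exchange uses a reversible four-state
chain whose relaxation times span roughly 2–300 µs. TCSPC decays default
to paper-scale statistics (configurable photons, 14 ps channels, 254 ps
FWHM IRF); DEER traces get exponential backgrounds ($\Delta = 0.3$,
$k = 0.05$ µs⁻¹) and Gaussian noise; fFCS amplitudes derive from the
rate matrix through per-variant state efficiencies; SAXS and NSE curves
are two-state mixtures with Gaussian noise.

One deliberate convention: the *quoted* uncertainties in the synthetic
restraint table and SAXS curves are twice the stochastic scatter
actually applied. Real error budgets are conservative in exactly this
way — quoted distance errors include $\kappa^2$, AV-calibration and
reference systematics, and SAXS errors include buffer-subtraction
allowances. The consequence is that a correct model scores
$\chi^2 \ll$ dof and survives a $p \ge 0.68$ selection with high
probability; if quoted errors equalled the true scatter, the expected
$p$ of the true model would be 0.5 and no selection at 0.68 could retain
it reliably.

What passing tests show: the estimators are unbiased and calibrated
*under the generating models* — Gaussian distance components,
exponential backgrounds, reversible exchange, rigid bodies, Poisson or
Gaussian noise. They do not probe model misspecification found in real
data: dye photophysics beyond a donor-only fraction, orientation-factor
violations, excluded-volume DEER backgrounds, hydration-layer contrast,
flexible linkers between rigid bodies, or detector artifacts. Problem
sizes in the test suite (e.g. 10–20 replicates where the corresponding
study-scale property speaks of 100, 30–50 DEER traces, four-variant
global fits alongside the full 12-variant case) were chosen as the
smallest sizes at which the statistical assertions are stable.

# Numerical choices and degenerate inputs

* Convolutions are FFT-based, causal and non-circular; a discrete delta
  is the identity.
* Non-negative least squares uses an active-set solver; the
  unconstrained Tikhonov route solves the regularized normal equations
  and reports a condition-number diagnostic on singular systems.
* L-curve corners use discrete Menger curvature after enforcing the
  theoretical monotonicity of both axes.
* MEM optimization clamps log-densities to ±700 before exponentiation
  and guards non-finite objective/gradient values.
* Distance distributions renormalize to unit trapezoid integral;
  simulated DEER signals use trapezoid quadrature so $V(0) = 1$ exactly
  even for densities truncated at the grid boundary.
* Degenerate inputs error early and explicitly: empty label clouds,
  all-zero IRFs, collinear fFCS patterns, non-positive DEER tails,
  non-PSD diffusion tensors, zero-integral densities, concentrations
  with $c[\eta] \ge 1$.
* Ties and boundaries are flagged rather than silently accepted:
  two-state fractions at 0 or 1, flat mixture profiles, fit parameters
  at bounds.

# Known limitations

* AV uses a single effective label radius and Euclidean (not geodesic)
  linker reach; contact fractions are user inputs.
* fFCS correlates binned signals, not photon time tags; afterpulsing
  and triplet dynamics are not modeled.
* The SAXS forward model has no hydration layer; absolute comparisons
  with experimental curves are approximate.
* Hydrodynamic tensors are inputs; the built-in Kirkwood helper is for
  synthetic tensors only.
* The Neyman-weighted TCSPC fit (the field default) carries a small
  low-count bias; use `weighting = "model"` for calibration work.
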