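# fusedyn

Multi-domain proteins such as the dynamin-like GTPases rarely live in a
single conformation: solution measurements see mixtures of a major and a
minor conformer exchanging on microsecond timescales. No single technique
resolves this — time-resolved FRET and DEER report complementary distance
windows, filtered FCS reports exchange kinetics, SAXS reports overall
shape, and neutron spin echo reports rigid-body versus internal dynamics.
fusedyn implements the full multi-modal analysis as a tested, reusable R
package for structural biophysicists: forward models and inversions for
each modality, and a meta-analysis that discriminates candidate conformer
pairs against all data at once.

## What is implemented

**Label simulation.** Accessible-volume (AV) clouds of tethered dyes and
spin labels on coarse bead structures (grid flood fill with clash and
reachability rules, compiled), accessible-contact-volume reweighting for
surface-trapped dyes, inter-label distance distributions and FRET
observables with κ² = 2/3:
E̅ = Σ wᵢwⱼ [1 + (Rᵢⱼ/R₀)⁶]⁻¹, R̄ = R₀(1/E̅ − 1)^{1/6}.

**TCSPC / FRET.** The FRET-induced donor decay
ε_D(t) = (1 − x_DOnly)∫p(R) e^{−t k₀ (R₀/R)⁶} dR + x_DOnly over a
two-Gaussian distance model (R₀ = 52 Å, τ₀ = 4 ns defaults), iterative
reconvolution with the instrument model
g(t) = N_F f⊗IRF + N_BG IRF + bg, Levenberg–Marquardt global fits with
shared parameters and support-plane errors, maximum-entropy model-free
distance reconstruction with L-curve selection, lifetime moments and
static/dynamic FRET-lines.

**DEER.** Dipolar kernel K(t,R) = ∫₀¹ cos[(3x²−1)ω_DD t]dx with
ν_dip = 52.04 MHz·nm³ (Fresnel closed form + quadrature cross-check),
exponential background correction, and non-negative Tikhonov inversion
with a second-difference penalty and maximum-curvature L-curve corner.

**Filtered FCS.** Unbiased species filters
W = (MᵀS⁻¹M)⁻¹MᵀS⁻¹, multi-tau species auto/cross correlations, the
diffusion × kinetics model with three globally shared relaxation times
and simplex-constrained amplitudes, exchange spectra from rate matrices,
and a telegraph-process reference simulator.

**NSE.** Effective rigid-body diffusion D₀(q) from a 6×6 diffusion
tensor by orientational averaging, the full intermediate scattering
function with an l ≤ 15 spherical-harmonic rotational expansion and an
internal-dynamics channel, cumulant analysis (D_eff = −K₁/q²),
hydrodynamic corrections H_t = 1 − c[η], 1 − H_r = (1 − H_t)/3, and the
Debye–Waller bound u = √(−3 ln(1 − err))/q.

**SAXS.** Debye forward scattering, Guinier/Kratky analysis,
concentration-series extrapolation to the form factor, the analytic
Percus–Yevick hard-sphere structure factor with decoupling correction,
affine-invariant χ² scoring with optional Shannon-channel dof, and
two-state ensemble fits with profile confidence intervals.

**Discrimination.** χ² scoring of candidate (M1, M2) structure pairs
against FRET/DEER restraint tables (AV predictions, swap handling,
effective dof by greedy backward elimination) and SAXS, combined by
Fisher's method X² = −2 Σ ln pᵢ ~ χ²₂ₖ, selection at a combined
p ≥ 0.68, and ensemble precision metrics (pairwise Cα distance SDs,
reference-ensemble normalization, RMSF after iterative superposition).

**Synthetic data.** A first-class generator of toy two-conformer bead
systems (hinge rotation between rigid bodies, 0.61/0.39 state
populations, 2–300 µs exchange) and statistically faithful datasets for
every modality, used throughout the tests.

## Worked example

Simulate a DEER trace for a two-state spin-pair mixture and invert it,
then fit a matching TCSPC decay:

```r
library(fusedyn)

r  <- seq(1.5, 8, 0.05)                      # nm
tt <- seq(0, 6, length.out = 200)            # us
kern   <- dipolar_kernel(tt, r)
p_true <- distance_distribution(r, 0.61 * dnorm(r, 3.1, 0.25) +
                                   0.39 * dnorm(r, 4.2, 0.25),
                                kind = "spin", unit = "nm")
trace <- simulate_deer(p_true, kern, delta = 0.3, k = 0.05,
                       noise_sd = 0.005, seed = 42)
inv <- deer_invert(trace)
distribution_moments(inv$p)
#> recovered <R_SS> = 3.55 nm (truth 3.53), SD = 0.62 nm
#> background k = 0.050 /us, modulation depth = 0.30, alpha = 0.18

don   <- fluorophore_reference(1, 4, "donor")
t_ns  <- seq(0, by = 0.0141, length.out = 4096)
gm    <- gaussian_mixture_distance(45, 60, width = 12, x1 = 0.61)
decay <- simulate_tcspc(gm, don, t_ns, irf = gaussian_irf(t_ns),
                        n_photons = 2e7, seed = 42)
fit <- fit_decay(list(list(curve = decay, donor_ref = don)),
                 list(list(mean1 = 43, mean2 = 62, width = 12,
                           x1 = 0.5, x_donly = 0)),
                 fixed = list(width = 12, x_donly = 0))
fit
#> tcspc_fit: 1 dataset(s), chi2_r = 0.9506
#> distances 45.0 / 60.0 A, major-state fraction x1 = 0.612
```

The DEER inversion recovers the mixture's mean spin–spin distance to
0.02 nm and the fitted background and modulation depth match the
simulation settings; the reconvolution fit recovers both state distances
and the 0.61 major-state fraction with a reduced χ² near one, i.e. the
noise model is consistent.

See `vignettes/methods.Rmd` for the models, parameter conventions,
numerical choices and limitations.

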