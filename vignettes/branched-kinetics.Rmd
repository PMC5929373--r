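---
title: "Branched alkylenzyme kinetics: model, fitting pipeline and design notes"
author: "stehkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched alkylenzyme kinetics: model, fitting pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stehkin)
```

## The reaction scheme

Epoxide hydrolases of the alpha/beta-hydrolase fold open their
substrate in two chemical steps: nucleophilic attack of an active-site
aspartate on one epoxide carbon forms a covalent alkylenzyme ester,
and hydrolysis of that ester by an activated water releases the diol.
For 2-substituted aromatic epoxides the attack can occur at either the
benzylic (C1) or homobenzylic (C2) carbon, so two *different*
alkylenzymes compete; with S\_N2 inversion at the attacked carbon, the
winning branch fixes the stereochemistry of the product diol. On top
of this chemical branching, the free enzyme and the Michaelis complex
can each interconvert between two conformers.

`stehkin` encodes this as a nine-species network:

* E ⇌ E′ — free-enzyme conformers, rates `k0`, `k_m0` (s⁻¹);
* E + S ⇌ ES and E′ + S ⇌ E′S — binding, realized *explicitly* with an
  association rate `kon` (µM⁻¹s⁻¹) and `koff = kon·K_S`;
* ES ⇌ E′S — Michaelis-complex interconversion, `k5`, `k_m5`;
* ES ⇌ E-alkyl (`k2`, `k_m2`) and E′S ⇌ E′-alkyl (`k2_prime`,
  `k_m2_prime`) — reversible alkylation on each branch;
* E-alkyl → E + P1 (`k3`) and E′-alkyl → E′ + P2 (`k3_prime`) —
  hydrolysis, with product release lumped in: the tetrahedral
  intermediate decomposes much faster than it forms, so no separate
  release step is modelled.

Units are fixed package-wide: s, s⁻¹, µM, kcal mol⁻¹, K.

Two modelling decisions deserve emphasis. First, binding is *not*
hard-coded as a rapid equilibrium. The experimental analysis of
stopped-flow data treats binding as pre-equilibrated (only K_S is
measurable), but the ODE realizes it with a finite `kon`
(default 1000 µM⁻¹s⁻¹, near the diffusion limit), so the
rapid-equilibrium behaviour is an *emergent, testable* limit: the test
suite verifies that the slowest relaxation of the linearized system
matches the rapid-equilibrium law
$k_{obs}(S) = k_2 S/(K_S+S) + (k_{-2}+k_3)$ to better than 1% when
binding is ≥ 100-fold faster than chemistry. Second, the dissociation
constant of the E′S complex is experimentally inaccessible; the
default is `K_S_prime = K_S`, overridable.

## Simulation

`simulate_scheme()` integrates the network with `deSolve::lsoda`
(stiff-capable; the system spans rates from ~10⁻² s⁻¹ chemistry to
~10⁶ s⁻¹ binding) at relative tolerance 1e-8 and absolute tolerance
1e-10 µM. Every trajectory carries its enzyme and substrate
mass-balance residuals; the tests require both below 1e-6 relative on
every output point. Integration failures raise errors — never silent
NaNs.

`relaxation_rates()` is the package's internal oracle for transient
experiments: it linearizes the six enzyme species at clamped [S] and
returns the eigenvalue magnitudes, the rates an idealized
pseudo-first-order stopped-flow experiment observes.

## The fitting pipeline

`fit_exponential()` fits
$F(t) = F_\infty + \sum_i A_i e^{-k_{obs,i} t}$ (one or two phases,
floating endpoint). The optimization uses variable projection: for
any trial rate vector the amplitudes and endpoint are linear and are
solved exactly, so only the rates are searched — on a log-spaced
multistart grid (4 points per decade over 10⁻²–10⁴ s⁻¹, all pairs for
the biphasic model), with the best start refined by Brent (one phase)
or Nelder–Mead (two phases) on the profiled SSE. This is deterministic
given the data, immune to the convergence failures of generic
nonlinear least squares on degenerate traces, and cheap enough to run
thousands of fits in the calibration tests. Standard errors come from
the Gauss approximation at the optimum. Amplitudes are referenced to
the first fitted time point, which keeps the design matrix conditioned
when fast phases hide behind the instrument dead time; points before
`dead_time` (default 2 ms on generated fixtures) are excluded.

Degenerate inputs are flagged, not hidden: near-zero amplitudes
(`amplitude_near_zero`), rate standard errors exceeding the rate
(`rate_ill_determined`), and biphasic fits whose two rates collapse
within 5% of each other (`degenerate_phases`).

`select_order()` applies the extra-sum-of-squares F-test,
$F = \frac{(SSE_1-SSE_2)/\Delta df}{SSE_2/df_2}$, keeping the biphasic
model only at p < α. The significance level is not prescribed by the
experimental protocol this mirrors; the package default is α = 0.05,
configurable. The calibration test drives 500 single-phase noisy
traces through the full fit-and-select path and checks that the
empirical type-I error brackets the nominal level at both α = 0.05 and
α = 0.01.

`fit_kobs_hyperbolic()` and `fit_kobs_decreasing()` regress the
per-concentration observed rates (via `minpack.lm::nlsLM`,
inverse-variance weighted when standard errors are present) on

$$k_{obs}(S) = \frac{k_2 S}{K_S + S} + (k_{-2}+k_3)
\qquad\text{or}\qquad
k_{obs}(S) = k_{lim} + \frac{k_{rev}}{1 + S/K_{app}},$$

the second being the classic two-step law for a substrate-independent
isomerization observed through deepening saturation; its S → 0
intercept $k_{lim}+k_{rev}$ estimates the summed isomerization rates.
Whether that sum belongs to the free-enzyme step (k0 + k−0) or the
Michaelis-complex step (k5 + k−5) is not decidable from the fit alone —
the function returns the intercept and leaves the mechanistic label to
the caller. Each function rejects a series whose trend calls for the
other model, and flags extrapolated K_S (beyond the covered
concentration range) and weak identification (SE exceeding the
estimate).

`extract_micro_rates()` inverts the steady-state expression
$k_{cat} = k_2 k_3/(k_2+k_{-2}+k_3)$ to split the transient intercept:
$k_3 = k_{cat}(k_2 + (k_{-2}+k_3))/k_2$, $k_{-2}$ by difference. The
inversion is an exact left inverse (feeding the results back through
`steady_state_params()` reproduces the input kcat to machine
precision — a tested invariant). Standard errors propagate to first
order treating k2, the intercept and kcat as independent; an implied
negative k−2 is reported and flagged, never clipped. Bootstrap
resampling is deliberately not the default — the delta method matches
how such regression errors are conventionally reported — and the
k_obs-level weighting makes a bootstrap across traces ill-defined
without the raw replicate traces.

### A note on Km versus K_S

For the wild-type (S,S)-1a parameter set the Michaelis constant
implied by the scheme, $K_m = K_S(k_{-2}+k_3)/(k_2+k_{-2}+k_3)$
≈ 202 µM, disagrees with the independently measured 77 µM. The two
measurements are not reconciled by the published analysis, and the
package does not attempt to: no derived quantity in the tests or the
acceptance script depends on Km, and `run_report()` reports measured
and derived values side by side.

### Single-turnover hydrolysis rates

`single_turnover_k3()` fits the fluorescence recovery under
single-turnover conditions ([E], [S] ≫ K_S, enzyme in slight excess),
taking the window from the signal minimum and then restarting it one
relaxation time later so the residual fast (alkylation) component does
not bias the rate low. The conventional identification k_obs ≈ k3 is
itself approximate: with de-alkylation active the recovery relaxes at
the slow eigenvalue of the saturated ES ⇌ E-alkyl → E + P subsystem,
$\tfrac{1}{2}\big(\Sigma - \sqrt{\Sigma^2 - 4k_2k_3}\big)$ with
$\Sigma = k_2+k_{-2}+k_3$, which sits *below* k3 by roughly the
equilibrium partition factor. For the wild-type (S,S)-1b constants
(k2 = 23, k−2 = 4.5, k3 = 3.9 s⁻¹) that eigenvalue is 3.18 s⁻¹ — an
18% systematic gap that no fitting choice can close, because it is a
property of the scheme, not of the estimator. The tests therefore
validate the estimator against the eigenvalue (within 5%), verify the
monotone approach to the saturated plateau across an E = S sweep from
1× to 20× K_S, and document that the recovered rate underestimates a
k3 defined as the pure hydrolysis rate constant whenever k−2 is not
negligible.

## Flux prediction

`branch_fractions_from_barriers()` partitions flux between branches as
a Boltzmann ratio of first-order rates over the step designated as
flux-determining. For this enzyme the hydrolysis step is committed and
rate-determining, so it is the default; alkylation-step partitioning
is available for systems where selectivity is set at ring opening.
Fractions are invariant under a common barrier shift (tested), and
barrier standard errors propagate to an interval by seeded Gaussian
resampling (default 10⁴ draws) — the barrier inputs carry standard
errors of the mean but no published selectivity interval, so the
interval is the package's own construction.

`committed_flux_from_rates()` is the independent route: integrate the
full ODE to ≥ 99.9% conversion and take the product-pool ratio. The two
routes agree (within one percentage point, tested) exactly when the
network upstream of hydrolysis pre-equilibrates — de-alkylation fast
against hydrolysis on both branches and equal alkylation access. That
construction matters because the calculated reaction free energies of
alkylation for this system are strongly over-exothermic (a known
limitation of the underlying barrier calculations): taken literally
they would make alkylation committed and flip the prediction to the
wrong branch. The package therefore treats the *hydrolysis barriers
relative to each alkylenzyme* as the flux-relevant quantities, which
is also how the mechanistic argument for enantioconvergence is framed:
with equal access to both alkylenzymes and hydrolysis barriers of
16.5 vs 20.9 kcal/mol, the lower branch carries ≥ 99.9% of the flux,
reproducing the observed ~99% C1 regioselectivity; with near-equal
barriers the prediction degrades gracefully to a near-racemic split.

The mapping from branch label (C1/C2 attack) to product enantiomer is
supplied by the caller's labels, not inferred from chemistry — the
package predicts fractions per labelled branch and leaves the
stereochemical bookkeeping explicit.

## The synthetic-data generator

`gen_trace()` emulates the fluorescence experiment: the signal is
$F(t) = F_0 - \sum_i q_i[\text{species}_i](t)$ with, by default, only
the two alkylenzymes quenching (`q = 0.3` per µM occupancy,
`F0 = 1`) — whether the Michaelis complexes also quench is unknown, so
ES/E′S quenching is switchable but off by default. The quench
coefficients are arbitrary conventions (no published calibration
exists); they scale amplitudes only, never rates. Sampling follows
stopped-flow practice: 1000 log-spaced points from the 2 ms dead time
to 10 slowest-relaxation times. Noise is additive Gaussian, averaged
over `n_replicates` independent draws (default 6, the experimental
minimum), with the default sigma scaled for a single-trace SNR of
about 20. Reproducibility is bit-exact per seed (tested), and the
averaged-noise level follows the √n law (tested against 100 seeds).

`gen_kobs_series()` chains generation, biphasic fitting and F-test
selection per concentration. A second phase is reported only when it
is non-degenerate, carries at least 5% of the total amplitude, and
completes at least one e-fold within the record — on near-noiseless
data the F-test alone would otherwise accept cosmetic drift terms
(substrate depletion masquerading as an ultra-slow exponential). The
default enzyme concentration is 1/20 of the lowest substrate
concentration, comfortably inside the pseudo-first-order criterion of
at least tenfold excess.

What the generator does *not* emulate: photobleaching, mixing
artefacts, instrument-specific noise spectra, pH or temperature
dependence of the rate constants, or the distinct spectral properties
of tryptophan- versus tyrosine-based detection. Passing the recovery
tests therefore demonstrates estimator correctness under the stated
noise model, not robustness to every instrumental pathology of real
stopped-flow data.

## Fixtures

The published rate constants for the five-variant panel ship as YAML
under `inst/extdata/table1/`, one file per variant × substrate row,
with standard errors and per-row provenance notes. Only values
actually reported are present; rows carrying only bounds raise
explicit "not reported" errors. `as_rate_set()` builds a simulatable
scheme from a complete row; since only the *sum* k5 + k−5 is
experimentally determined, the default 50/50 split between k5 and
k−5 is a documented convention, overridable — as is dropping the
isomerization step entirely. The free-enzyme step k0/k−0 is never
reported for these variants and defaults to zero (single free
conformer).

## Problem sizes and numerical choices in the test suite

The validation experiments are sized for routine desk-scale runs: the
parameter-recovery pipeline uses 8 substrate concentrations
(30–1500 µM) × 6 averaged replicates at 1% noise with fixed seeds, and
recovers k2, K_S, k−2 and k3 within 15%; the F-test calibration uses
500 seeded traces of 120 points; the eigenvalue-oracle check runs one
noiseless trace per complete fixture row at deep enzyme dilution
(E = S/2000), where the clamped-substrate idealization behind the
eigenvalue comparison is accurate to well under the 5% tolerance. At
the pseudo-first-order *boundary* (E = S/10) the quasi-steady
depletion drift biases a fitted k_obs by up to ~9% against the
clamped-substrate eigenvalue — a real feature of the regime, which is
why validation traces use deeper dilution and why the recovery
pipeline windows each trace at 8 fast-relaxation times.

## Known limitations

* The tetrahedral-intermediate substeps of hydrolysis are lumped into
  k3; no pH or temperature dependence beyond the Eyring relation.
* Fitting is trace-by-trace followed by k_obs regression; no global
  multi-trace fitting.
* The committed-flux ODE route requires the caller to encode
  "hydrolysis is rate-determining" in the rate set; the package does
  not invent de-alkylation rates from thermodynamics it considers
  unreliable.
* Single-turnover rates estimate the slow saturated relaxation, which
  equals k3 only in the k−2 → 0 limit (see above).
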