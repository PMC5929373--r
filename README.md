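# stehkin

Kinetic analysis of the branched catalytic mechanism of potato epoxide
hydrolase (StEH1) and its engineered variants.

StEH1 hydrolyses epoxides through a covalent alkylenzyme intermediate:
the active-site aspartate attacks one of the two epoxide carbons
(benzylic C1 or homobenzylic C2 for aromatic substrates), and the ester
intermediate is then hydrolysed by an activated water. Because attack
can occur at either carbon — and the Michaelis complex itself can
interconvert between conformers — the mechanism is a *branched* scheme
in which two alkylenzymes compete for flux, and the branch that wins
determines the regiochemistry and hence the stereochemistry of the
diol product. This package implements that scheme end to end:

* **Simulation** — the full two-branch mechanism (E ⇌ E′ conformers,
  explicit substrate binding with dissociation constants K_S and K_S′,
  ES ⇌ E′S interconversion k5/k−5, reversible alkylation k2/k−2 on each
  branch, lumped hydrolysis + release k3) as a stiff ODE system.
* **Transient fitting** — the standard stopped-flow pipeline: single /
  double exponentials with floating endpoints, F-test order selection,
  regression of k_obs against [S] with the hyperbolic law
  k_obs(S) = k2·S/(K_S+S) + (k−2+k3) or the decreasing two-step law
  k_obs(S) = k_lim + k_rev/(1+S/K_app), and extraction of the
  microscopic constants: k3 = kcat·(k2 + (k−2+k3))/k2 and
  k−2 = (k−2+k3) − k3, with delta-method standard errors.
* **Transition-state analysis** — Eyring interconversion
  ΔG‡ = RT·ln(k_B·T/(h·k)) (transmission coefficient 1), exact in both
  directions.
* **Flux prediction** — Boltzmann partition of branch flux over the
  barriers of the committed (hydrolysis) step,
  f_i = exp(−ΔG_i‡/RT)/Σ_j exp(−ΔG_j‡/RT), an ODE committed-flux route
  for cross-checking, regioselectivity and enantiomeric excess.
* **Synthetic data** — noisy, replicate-averaged stopped-flow traces,
  k_obs sweeps and Michaelis–Menten initial-rate tables from known
  ground truth, plus fixtures of the published rate constants for the
  StEH1 variant panel (wild type, R-C1, R-C1B1, R-C1B1D33,
  R-C1B1D33E6 with the 1a/1b substrate enantiomers).

The intended users are enzymologists analysing pre-steady-state
fluorescence data for branched (or plain three-step) mechanisms, and
computational chemists who want to turn calculated barrier sets into
testable selectivity predictions.

## Worked example

```r
library(stehkin)

# published parameters for wild-type StEH1 with (S,S)-1a
fx <- table1_fixture("wild_type", "(S,S)-1a")
rs <- as_rate_set(fx)
rs
#> Branched-scheme rate set
#>   binding:     kon = 1000 uM^-1 s^-1, K_S = 470 uM, K_S' = 470 uM
#>   alkylation:  k2 = 370, k-2 = 170 | k2' = 0, k-2' = 0 s^-1
#>   hydrolysis:  k3 = 110 | k3' = 0 s^-1
#>   conformers:  k0 = 0, k-0 = 0; k5 = 16, k-5 = 16 s^-1

# a synthetic 6-trace-averaged stopped-flow experiment at 1500 uM
cond  <- reaction_conditions(E_total = 4, S_total = 1500)
trace <- gen_trace(rs, cond, noise_model(seed = 1))
fit1 <- fit_exponential(trace, 1)
fit2 <- fit_exponential(trace, 2)
select_order(fit1, fit2)$order   # F-test demands the biphasic model
#> [1] 2
fit2
#> Exponential fit (order 2, 1000 points, SSE 0.0133)
#>   k_obs1 = 576.42 +/- 4.77 s^-1, amplitude 0.1933 +/- 0.00072
#>   k_obs2 = 17.72 +/- 0.106 s^-1, amplitude -0.1941 +/- 0.000445
#>   endpoint = 0.60058 +/- 0.000268
```

The fast phase (576 s⁻¹) is alkylenzyme buildup and decay — it follows
the hyperbolic law above, reaching k2 + k−2 + k3 at saturation; the
slow phase reflects the ES ⇌ E′S interconversion. The steady-state
parameters implied by the microscopic rates, and the activation free
energy of alkylation:

```r
steady_state_params(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470)
#> kcat = 62.62 s^-1, Km = 202.5 uM, kcat/Km = 309.3 s^-1 mM^-1
eyring_barrier(370)        # 303.15 K default
#> [1] 14.19346            # 14.2 kcal/mol
```

(The printed turnover number for this variant is 63 ± 3 s⁻¹.) Finally,
why does a reaction that forms *two* alkylenzymes yield a *single*
diol? Partitioning the flux over the two hydrolysis barriers
(16.5 vs 20.9 kcal/mol, calculated EVB inputs):

```r
b <- branch_barriers(c("C1", "C2"), dG_alk = c(12.2, 13.3),
                     dG_hyd = c(16.5, 20.9))
branch_fractions_from_barriers(b)
#> Branch flux prediction
#>   C1: 0.9993
#>   C2: 0.0007
#>   regioselectivity: 99.9%; dominant: C1; ee = 99.9%
```

Hydrolysis only lets the pro-(1R,2S) intermediate through — matching
the observed ~99% C1 regioselectivity.

A thin command-line wrapper over these functions ships at
`system.file("cli", "stehkin.R", package = "stehkin")` with subcommands
`simulate`, `gen-trace`, `fit-trace`, `fit-kobs`, `extract-rates`,
`predict-flux` and `report`.

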