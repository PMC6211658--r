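# occudyn

Dynamic drug–target occupancy when the binding site itself builds and decays.

Classical occupancy pharmacology assumes a fixed pool of binding sites at
equilibrium, so that the bound fraction is just the Hill form
γ = L₀/(L₀ + K_d). In cells, binding sites are transient: the site-bearing
protein is synthesised and degraded or shuttled between compartments
(**scenario 1**), or a binding-competent conformational state opens and
closes (**scenario 2**, e.g. ion-channel gating). occudyn solves the
resulting non-equilibrium binding rate equation

```
dC/dt = kon · (B_total(t) − C) · L0 − koff′ · C,        C(0) = 0
```

where `B_total(t)` builds with rate constant `ki` and decays with `k₋ᵢ`
(exponential saw-tooth in scenario 1, bi-logistic in scenario 2), `L0` is the
fixed free ligand concentration, and `koff′ = max(koff, k₋ᵢ)` is the
dissociation rate "hijacked" by site decay — a complex cannot outlive its
site. In dimensionless time `τ = ki·t` the system is governed by the groups

```
alpha = kon·L0/ki     beta = koff′/k₋ᵢ     gamma = k₋ᵢ/ki
```

and is solved in closed form (three-exponential branch solution in
scenario 1; a Gauss ₂F₁ hypergeometric solution in scenario 2) with an
adaptive ODE integrator as fallback and cross-check. Three results organise
the pharmacology:

* **konSS rule** — constant *steady-state occupancy* (SSO, a constant bound
  fraction at every instant) requires `kon ≥ konSS = 10·ki/L0`. Below it the
  profile is *non-steady-state* (nSSO): occupancy lags the site, peaks below
  the equilibrium expectation, and cannot be rescued except by saturating
  dose (*quasi-steady-state*, qSSO).
* **koff hijacking** — once `koff ≤ k₋ᵢ`, residence time is irrelevant:
  `Kd′ = koff′/kon ≥ Kd` and further koff slowing adds no occupancy.
* **Kinetic tuning** — optimise `kon` up to konSS first, then `koff` down to
  `k₋ᵢ`, to reach maximal fractional occupancy at the lowest free drug
  concentration.

The package ships the reference tables behind the case studies (turnover-rate
grid, wt/D374Y PCSK9–LDL-receptor kinetics, hERG blocker back-calculations,
32 marketed-drug kinetic records) as plain CSV fixtures, a tidyverse-style
API (tibbles in/out, `tidy()`/`glance()`/`autoplot()` on results), and a thin
CLI (`inst/cli/occudyn`).

## Worked example

Gain-of-function D374Y PCSK9 binding the LDL receptor at lysosomal pH, at the
top of the reported plasma range (40.5 nM), with the ~5-min PCSK9 turnover
(`ki = k₋ᵢ = 10⁻² s⁻¹`):

```r
library(occudyn)
sim <- case_pcsk9("D374Y", 5.3, L0 = 40.5e-9)
sim
#> <occu_sim> scenario 1 (continuous, analytic)
#>   kon 6.74e+05 /M/s, koff 0.0023 /s (koff' 0.0023), ki 0.01, k-i 0.01 /s, L0 4.05e-08 M
#>   alpha 2.73, beta 0.23, gamma 1, c_inf 0.922
#>   profile qSSO; peak c = 0.854 at tau = 3.030; konSS 2.47e+06 (kon/konSS 0.273)

peak_occupancy(sim)
#> # A tibble: 1 x 2
#>   c_peak tau_peak
#> 1  0.854     3.03
```

Peak occupancy reaches 85% of the site maximum just after the site peak at
τ = 3 (the wild type gives 82%) — but the profile is only quasi-steady: kon
is ~4-fold below konSS, so occupancy is achieved by near-saturating
concentration, not kinetic tuning. The same advisor logic is available
directly:

```r
tuning_report(kon = 5e5, koff = 5e-1, ki = 1e-2, k_minus_i = 1e-2, L0 = 1e-9)
#>   kon_ss = 1e8, kon_ratio = 0.005, advisory = "speed_kon_first"
```

and the marketed-drug census:

```r
drugset_summary(load_fixture("table4"))
#>   n_records = 32, pct_kon_ge_1e5 = 72, pct_kd_sub_nM = 44,
#>   pct_kon_driven = 44, pct_koff_driven = 22
```

72% of the 32 drugs have `kon ≥ 10⁵ M⁻¹s⁻¹` (fast enough for SSO on targets
with half-lives from ~1 min to ~19 h), while sub-nanomolar affinity occurs in
only 44% — consistent with occupancy in vivo being association-rate-driven
rather than residence-time-driven.

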