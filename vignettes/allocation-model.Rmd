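---
title: "A coarse-grained allocation model of phytoplankton stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained allocation model of phytoplankton stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoalloc)
```

## The model

`phytoalloc` treats a phytoplankton cell as a budget of carbon, nitrogen,
and phosphorus distributed over a handful of measurable macromolecular
pools: three protein classes (photosynthetic, biosynthetic, and a fixed
"essential" remainder), chlorophyll, RNA, DNA, thylakoid phospholipid,
essential carbohydrate + lipid, and three storage pools (carbohydrate/
lipid carbon, cyanophycin nitrogen, polyphosphate phosphorus). All pools
are quotas — mol per mol cellular C — so the carbon pools sum to one.

Four relationships connect pools to rates:

1. **Photosynthesis saturates with light.** The chlorophyll-specific
   gross photosynthesis rate is
   $v_I(I) = v_I^{max}\,(1 - e^{-A_I I})$.
2. **The thylakoid has fixed composition.** Photosynthetic protein and
   thylakoid phospholipid are proportional to the chlorophyll quota
   ($Q_C^{Pro\text{-}Pho} = A_{Pho} Q_C^{Chl}$,
   $Q_P^{Thy} = A_{Pho}^{P:Chl} Q_C^{Chl}$). More light-harvesting
   machinery means proportionally more of everything in it.
3. **Biosynthetic protein is proportional to growth rate**:
   $Q_C^{Pro\text{-}Bio} = A_{Bio}\,\mu$.
4. **RNA scales with protein times growth rate**, with a floor:
   $Q_P^{RNA} = A_{RNA}^{P}\,\mu\,Q_C^{Pro} + Q_{P,min}^{RNA}$. This is
   the growth-rate hypothesis written at the quota level: faster
   division needs proportionally more ribosomes per unit protein.

At steady state the carbon balance
$v_I Q_C^{Chl} = (1 + E)\mu + m$ makes the chlorophyll quota **exactly
linear in growth rate**,
$Q_C^{Chl} = A_{Chl}(I)\,\mu + B_{Chl}(I)$ with
$A_{Chl} = (1+E)/v_I$ and $B_{Chl} = m/v_I$; both slope and intercept
rise as light falls. Substituting the four rules into the N and P pool
sums gives closed **quadratic** forms
$N{:}C = a_N \mu^2 + b_N \mu + c_N$ and
$P{:}C = a_P \mu^2 + b_P \mu + c_P$. The N:C quadratic term comes only
from RNA nitrogen and is small, so N:C looks linear; RNA dominates
cellular P, so the P:C curvature is visible. Setting the flexible carbon
storage to zero closes the carbon budget into a quadratic in $\mu$ whose
positive root is the nutrient-replete maximum growth rate
$\mu_{max}(I)$ — growth saturates with light *earlier* than
photosynthesis does, because cheap light-harvesting at high light frees
carbon for biosynthesis.

The culture layer adds the chemostat steady state: $\mu = D$, biomass
equals feed concentration of the limiting element divided by its
non-storage quota (the residual dissolved nutrient is neglected
relative to the feed, as in the source experiments), and the culture is
N-limited exactly when feed N:P is below the required (non-storage)
N:P. The non-limiting element is taken up in excess and stored:
polyphosphate carries no carbon and is capped through the *total* P
quota ($Q_P^{max}$), while cyanophycin is capped on the *storage
component only* ($Q_N^{Sto,max}$) and carries carbon at C:N = 2.

## Elemental conversion constants

Fixed mol:mol ratios convert between element bookkeepings: protein
N:C = 1/3.82 (cross-species average), chlorophyll a N:C = 4/55,
phospholipid C:P = 40 (taken as the conventional constant for
phosphatidylglycerol with C16 fatty acids, not re-derived from
structure — atom-count conventions for the head group are ambiguous).
Nucleic-acid ratios are derived from genomic GC content by averaging
the C and N atoms of the four nucleotide-monophosphate residues
(base + sugar, one P each), with G and C at `gc/2` each. At the default
GC = 0.563 this gives RNA C:N:P = 9.5:3.78:1 and DNA 9.72:3.78:1; RNA
C:P is exactly 9.5 at *any* GC because A+U and G+C residue pairs carry
equal carbon. All constants can be overridden for other organisms via
`stoich_ratios()` or a JSON/YAML parameter file.

## Parameters

Eleven parameters are calibrated from data; the rest are fixed
configuration.

| parameter | units | default | role |
|---|---|---|---|
| `m` | d⁻¹ | 0.1 | maintenance respiration |
| `v_I_max` | mol C (mol Chl C)⁻¹ d⁻¹ | 100 | max photosynthesis per chlorophyll |
| `A_I` | (µmol photons m⁻² s⁻¹)⁻¹ | 0.015 | light-saturation coefficient |
| `E` | — | 0.936 | respiratory cost per C synthesized |
| `A_Pho` | — | 4 | photo-protein C per chlorophyll C |
| `A_Bio` | d | 0.15 | biosynthetic protein C per unit µ |
| `Q_C_Pro_Other` | mol C/mol C | 0.2 | essential protein pool |
| `A_RNA_P` | mol P (mol C)⁻¹ d | 0.012 | RNA-P per (protein C × µ) |
| `Q_P_min_RNA` | mol P/mol C | 5e-4 | RNA floor at zero growth |
| `A_Pho_PChl` | mol P (mol Chl C)⁻¹ | 0.03 | thylakoid lipid P per chlorophyll C |
| `Q_P_Other0` | mol P/mol C | 5e-4 | fixed other-P pool |
| `Q_C_DNA` | mol C/mol C | 0.01 | DNA pool |
| `Q_C_Other0` | mol C/mol C | 0.25 | essential carbohydrate + lipid |
| `Q_N_Sto_max` | mol N/mol C | 0.03 | cyanophycin storage cap |
| `Q_P_max` | mol P/mol C | 0.015 | total-P cap |

The defaults are a *synthetic* "default organism": an
order-of-magnitude-plausible parameterization of a freshwater
cyanobacterium chosen so that the implied observables are realistic —
Chl:C of roughly 0.005–0.05 mol Chl C per mol C, µ_max ≈ 1.6 d⁻¹ at
saturating light, N:C between ~0.07 and ~0.2, and N:P spanning ~14–27
across growth rates. They are not a fit to any published data set; they
are the ground truth for the package's tests and examples.

`E` is not a fitted parameter. The default 0.936 is derived by
electron-equivalent bookkeeping for biomass of composition
C₅H₇O₂NP₁/₃₀ synthesized from photosynthate (CH₂O, 4 e⁻ per C) with
nitrate as nitrogen source (28 e⁻ equivalents per C₅ unit) at an energy
transfer efficiency of 0.6; the short derivation script ships in
`inst/scripts/derive_respiratory_cost.R`. Growth on ammonium would
lower `E`; it is a plain config field.

## Numerical choices and degenerate inputs

* The quadratic roots use the rationalized form
  $\mu = -2c/(b + \sqrt{b^2 - 4ac})$, which neither cancels when
  $|4ac| \ll b^2$ nor degenerates as $a \to 0$.
* Infeasibility ($c_M \ge 0$: fixed pools plus maintenance exceed the
  cell at that light) raises a typed condition rather than returning 0,
  so calibration can penalize such parameter sets; washout
  ($D > \mu_{max}$) is likewise a typed error carrying the attainable
  maximum.
* Feed N:P exactly equal to required N:P is classified N-limited
  (arbitrary but fixed tie-break).
* Under P limitation the cyanophycin carbon implied by the storage rule
  can exceed the carbon remaining after the functional pools as
  $D \to \mu_{max}$. N storage is therefore additionally capped by that
  remaining carbon; the cap tightens to zero at $\mu_{max}$, which
  keeps every pool nonnegative and preserves the identity that carbon
  storage vanishes exactly at the maximum growth rate.
* Carbon closure tolerates a negative residual of 1e-9 before declaring
  a state infeasible; pool identities in the test suite are checked at
  1e-12.

## Calibration

The error function is the per-dataset sigma-scaled sum of squares
$\mathrm{Err}_k = \sum_i (y_i - \hat y_i)^2 / 2\sigma_k^2$, combined as
$\sum_k \mathrm{Err}_k / n_k$ so that curves with many points do not
swamp sparse ones (e.g. the µ_max-vs-light curve). The search is a
Metropolis-Hastings chain used as an optimizer: every free parameter of
the active stage is perturbed jointly by independent multiplicative
factors uniform in ±20%, out-of-bounds proposals (negative values;
chlorophyll parameters above 5× their initial values) are rejected
whole, and a proposal is accepted when
$\exp(\mathrm{Err}_{cur} - \mathrm{Err}_{new})$ exceeds a uniform
random number. The best visited state, not the final one, is reported;
no posterior summaries are attempted.

Fitting is staged to mirror the model's one-way dependencies, in a
single pass:

1. (`m`, `v_I_max`, `A_I`) from Chl:C vs. µ across light levels —
   chlorophyll depends on nothing else;
2. (`A_Pho`, `A_Bio`, `Q_C_Pro_Other`, `Q_N_Sto_max`, `Q_C_Other0`)
   from N:C under both limitations, N-limited biomass, and µ_max vs.
   light, holding stage 1 fixed;
3. (`A_RNA_P`, `A_Pho_PChl`, `Q_P_Other0`) from P-limited biomass and
   P:C.

Two design points deserve note. First, feasibility is only enforced
where the µ_max root *is* the model (µ_max rows get the finite 10⁶
penalty when no positive root exists): the quota and biomass curves are
algebraic in µ, and penalizing a stage for the provisional values of
parameters that a *later* stage will fit distorts the search badly.
Second, during stages 2–3 the not-yet-fitted parameters sit at their
initial values; their influence there is second-order (RNA carbon in
the µ_max closure), which is the price of the single-pass design.

## The synthetic-data generator

`generate_dataset()` emulates a classic dilution-gradient chemostat
study: four acclimation light levels (15, 40, 120, 300 µmol photons
m⁻² s⁻¹) spanning strongly light-limited to near-saturating, dilution
rates 0.1–1.5 d⁻¹ in steps of 0.2 at every light level, one feed with
N:P = 10 (below the required ratio, hence N-limiting) and one with
N:P = 40 (P-limiting), and the per-light-level maximum growth rate
reported as its own dataset. Vessels diluted above µ_max(I) wash out
and are omitted, as published dilution series only report vessels where
the limiting nutrient was fully consumed. Observation noise is
multiplicative Gaussian on the relative scale (default sd 5% on every
observable), truncated at zero by redrawing since all observables are
positive. Each dataset carries the generator's true error scale
σ_k = noise_sd × mean(truth); for noiseless designs a vanishing
relative scale (10⁻⁶) stands in, under which the acceptance rule
reduces to strict descent — the intended limit when data carry no
noise.

What the generator does *not* emulate: replicate vessel-to-vessel
variability beyond i.i.d. noise, measurement drift, photo-inhibition at
high light, temperature effects, non-steady-state transients, and the
digitization error of reading points off published figures. Recovery
tests on these data therefore demonstrate that the calibration machinery
is correct and well-conditioned under the stated design — not that any
particular laboratory data set is fit well.

Problem sizes in the shipped tests were chosen to keep the full suite
fast while exercising every code path: 10³ randomized states for the
conservation/equivalence/limitation properties, 2×10⁴ MH steps for the
noiseless chlorophyll-stage recovery, and 10⁵ steps per stage across
five seeds for the noisy full recovery (production calibrations would
use the 10⁶-step configuration). With the default design the noiseless
chlorophyll stage recovers its three parameters to well under 2%, and
the per-parameter median of the noisy 11-parameter recovery across
seeds sits within 25% of truth; individual seeds can leave the weakest
parameter (`A_Pho_PChl`, a 5–15% contribution to P:C observed through
5% noise) ~30% off at the likelihood optimum, which is an
identifiability limit of the design, not an optimizer failure.

## Known limitations

* Single-species steady states only; no dynamics, no competition.
* One photosynthesis-light parameter set across acclimation lights; the
  model deliberately has no photo-inhibition term.
* The storage caps are empirical ceilings, not mechanisms; predictions
  of N:P under strong luxury uptake inherit their crudeness.
* Nutrient-uptake machinery is not resolved; at very low growth rates
  under severe nutrient limitation, transporter investment could matter.
* `Q_P_max` must exceed the functional P quota over the growth range of
  interest; parameter sets violating this are rejected as internally
  inconsistent rather than reinterpreted.

## A worked example

```{r example}
params <- model_params()
ratios <- default_ratios()
mu_max(c(15, 40, 120, 300), params, ratios)

sol <- solve_culture(chemostat_env(I = 120, N_in = 0.25, P_in = 0.025,
                                   D = 0.5), params, ratios)
sol$state
sol$biomass
```

```{r fit, eval = FALSE}
# calibrate against a synthetic data set (desk-scale step count)
obs <- generate_dataset(params, design_spec(seed = 1))
fit <- staged_fit(obs, params, ratios, fit_config(steps = 2e4, seed = 1))
fit
```
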