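---
title: "NTCP-guided plan assessment: models, assumptions and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NTCP-guided plan assessment: models, assumptions and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcplan)
```

## The problem

Whole-brain radiotherapy (WBRT) at 30 Gy in 10 fractions with open
opposed fields irradiates the bilateral parotid and lacrimal glands,
producing acute xerostomia and dry eye at clinically relevant rates.
Given per-structure dose-volume histograms (DVHs) under an original 3D
plan and candidate re-plans (a parotid-blocked 3D plan, an IMRT/VMAT
plan), `ntcplan` estimates each patient's complication risk per plan,
checks the plans against standard clinical goals, and tests whether the
re-plans reduce risk across a cohort in a paired design.

## DVH conventions

Internally everything is volume-fraction based: a differential DVH is a
set of bins `(D_i, Δv_i)` with `Σ Δv_i = 1`; a cumulative DVH gives the
fraction receiving at least each grid dose, starting at 1. Absolute
volumes (cc, or percent) are converted at the file boundary only.
Numerical choices, made once:

* **Bin dose = lower bin edge**; default rebinning width 0.1 Gy. This
  matches typical treatment-planning-system export granularity.
* **`V_xGy` is closed at x** ("equal to or greater than x Gy").
* **Flat segments in `dose_at_volume`** return the *highest* dose
  attaining the requested fraction — conservative for organ-at-risk
  reporting, where under-reporting dose is the worse error.
* **Round trips**: `to_differential(to_cumulative(d))` is the identity
  on the shared grid to 1e-9 (zero-volume bins are dropped); conversions
  conserve total volume exactly up to floating point.
* `make_differential` renormalizes raw volume sums within 1% of 1 (TPS
  rounding) and refuses anything further off, which almost always means
  absolute volumes arrived undeclared.
* **D_max** has two consistent readings: on differential input it is the
  largest occupied bin dose; in goal evaluation on a cumulative curve it
  is the dose at which the curve reaches zero volume. The two differ by
  one bin width under the lower-edge convention.

## The dose-response models

The relative-seriality (RS) model composes a Poisson sigmoid per bin,

$$P(D) = 2^{-\exp(e\,\gamma\,(1 - D/D_{50}))},$$

into the organ-level risk

$$\mathrm{NTCP} = \Big[1 - \prod_i \big(1 - P(D_i)^s\big)^{\Delta v_i}\Big]^{1/s}.$$

Parameters, with units and shipped defaults:

| parameter | meaning | parotid (xerostomia) | lacrimal (dry eye) |
|---|---|---|---|
| `D50` (Gy) | uniform dose giving 50% risk | 24.9 | 63.9 |
| `gamma` | max normalized slope of `P` | 0.26 | 0.34 |
| `s` | relative seriality | 1e-4 | 1e-4 |

`s = 1e-4` encodes an almost perfectly parallel organ: the risk tracks a
volume-weighted geometric mean of the per-bin log-responses rather than
the hottest bin.

**Numerical path.** At `s = 1e-4`, `P^s` is within ~1e-4 of 1 and the
product of `(1 - P^s)^{Δv}` factors underflows in direct form, so the
implementation accumulates `Σ Δv_i · log(1 − exp(s·ln P_i))` with
`log1p`/`expm1` branches (`log1mexp`) and exponentiates once. Limits are
handled by continuity: a bin with `P = 0` contributes factor 1; a bin
with `P = 1` forces NTCP = 1. A single-bin DVH reduces *exactly* to the
uniform response for any `s` (tested to 1e-9), `s = 1` matches the
serial closed form to 1e-12, and `s ≤ 1e-3` matches the parallel-limit
geometric-mean formula to 1e-3.

**Two properties worth knowing.** First, the maximum slope of `P` with
respect to `D/D50` equals `γ` analytically — the package recovers it
numerically (grid step 1e-4) and uses that as a self-check, along with
the fact that the response passes through `1/e` at its steepest point.
Second, these shallow published slopes put nonzero risk at zero dose:
`P(0) ≈ 24.5%` (parotid) and `17.4%` (lacrimal). That is a property of
the parameterization, not a bug — but it also means the model's risk for
*any* plan has a floor near those values, which matters below.

The LKB alternative (`NTCP = Φ((gEUD − TD50)/(m·TD50))`,
`gEUD = (Σ Δv_i D_i^{1/n})^n`) is provided with no shipped parameters:
fitted values for these endpoints were not available to ship, and
inventing them would be worse than requiring explicit input.

Fractionation: the shipped RS parameters were fitted and applied at the
same 3 Gy/fraction schedule, so the default pipeline uses physical dose.
`eqd2_dvh()` (per-bin linear-quadratic rescaling) is strictly opt-in for
users applying the models across schedules.

## Clinical goals

`default_goals()` encodes the ten hippocampal-avoidance WBRT objectives:
PTV `D_2% ≤ 37.5 Gy`, `D_98% ≥ 25 Gy`, `V_30Gy ≥ 90%` (secondary tier
`≥ 95%`); hippocampi `D_min ≤ 9 Gy`, `D_max ≤ 16 Gy`; lacrimal
`V_15Gy ≤ 80%` (secondary `D_max ≤ 15 Gy`); parotid `V_20Gy ≤ 50%`
(secondary `D_max ≤ 20 Gy`). `D_min` is implemented as `D_100%` — the
dose covering the whole volume — which is how minimum-dose goals are
stated for hippocampal sparing; the two names denote the same metric.
A plan is *clinically acceptable* iff PTV `V_30Gy ≥ 0.90`; with no PTV
DVH supplied, acceptability is indeterminate (`NA`), never silently
`FALSE`.

## Cohort statistics

Risks are compared in a paired design: each patient under their own
original plan is the control for their re-plans. `paired_t` implements
the textbook statistic on per-patient differences (sample SD, `n − 1`);
the family of inferential tests is the two original-vs-re-plan
comparisons per endpoint, Bonferroni-controlled at family α = 0.05
(per-test 0.025). The 3D-vs-IMRT contrast is reported alongside but
deliberately kept outside the family. Power uses the exact noncentral-t
formulation (`df = n − 1`, noncentrality `effect·√n`): at the
clinically meaningful standardized effect of 1.1 (a 7% risk reduction
against a 6.2% between-patient SD) and `n = 11`,
`paired_power(11, 1.1, 0.025)` gives 0.825 — the noncentral-t reading of
the usual "~82% power" statement, which is why that formulation was
adopted over a normal approximation.

## The synthetic cohort: what it emulates, and what it does not

No per-patient DVHs are published for this setting (only figure-level
curve families), so the generator is a *stated world*, not a fit. Each
gland DVH is a two-component truncated-normal mixture on
`[0, 1.25 × prescription]`: a high-dose component (fraction `f_high`
near `mu_high`) representing gland volume in or near the open fields,
and a scatter component near `mu_low`. This is the minimal shape family
with independently tunable `V_20`/`V_15` and the shoulder-plus-falloff
look of real WBRT gland DVHs. Plan technique moves `(f_high, mu_high)`:

| structure.plan | f_high | mu_high (Gy) |
|---|---|---|
| parotid.original | 0.55 | 27 |
| parotid.replan_3d | 0.35 | 27 |
| parotid.replan_imrt | 0.15 | 22 |
| lacrimal.original | 0.80 | 22 |
| lacrimal.replan_3d | 0.80 | 22 |
| lacrimal.replan_imrt | 0.45 | 14 |

with `sigma_high = 3 Gy`, `mu_low = 6/5 Gy` (parotid/lacrimal),
`sigma_low = 2 Gy`, patient-level SDs `f_sd = 0.10/0.06` and
`mu_sd = 1.5 Gy`, all chosen once as plausible for this anatomy. The
lacrimal 3D preset *equals* the original by design: extra 3D blocking of
the lacrimals is generally anatomically impossible, so only delivery
jitter separates those plans and their cohort difference correctly
hovers at zero without tuning.

**Correlation structure.** Patient anatomy effects on `(f_high,
mu_high)` are drawn once per patient×structure and shared across the
three plans; independent per-plan jitter (SD 0.02 on `f`, 0.5 Gy on
`mu`) sits on top. The shared component is what a paired design
exploits — between-patient spread cancels in per-patient differences —
and without it the generator could not reproduce a realistic
significance pattern at `n = 11`.

**What a green test establishes.** With the default seed the end-to-end
study reproduces the qualitative fingerprint of gland-sparing
re-planning — per-patient risk ordering IMRT < 3D < original for
xerostomia, both xerostomia re-plan tests significant at 0.025, dry eye
significant only under IMRT with the 3D delta within ±2 points of
zero — and original-plan cohort means inside broad plausibility bands
(parotid 25–45%, lacrimal 15–30%). It does *not* establish agreement
with any published per-patient values, and one known discrepancy is
structural: published re-plan cohort means of ~13% (xerostomia) and
~11% (dry eye) lie below the RS model's own zero-dose floors (24.5% and
17.4%) under the shipped parameters, so no DVH fed through this formula
can reach them. The synthetic study therefore shows compressed risk
reductions (e.g. −9.5 rather than −20.6 percentage points for IMRT
xerostomia) while preserving every ordering and significance relation.
Absolute deltas from this generator should not be quoted as clinical
estimates.

**Determinism.** All randomness flows from `cohort_config(seed=)`; the
generator saves and restores the caller's RNG state, and identical
configs produce bit-identical DVHs, NTCP tables and comparison tables.

## Known limitations

* Pooled bilateral DVHs per gland pair (as figure-level data are
  presented); no per-gland laterality.
* No NTCP parameter fitting or confidence intervals; parameters are
  inputs.
* No DICOM-RT import; the CSV dialect documented in `read_dvh_csv()` is
  the only file format.
* The generator makes no attempt at hippocampal/PTV realism beyond what
  goal-evaluation demos need, and none at 3-D dose realism.
* Config files are JSON (`jsonlite`), not YAML, because no YAML parser
  is available in the supported dependency set.
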