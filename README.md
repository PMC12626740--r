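# ntcplan

NTCP-guided assessment of whole-brain radiotherapy (WBRT) plans in R.

WBRT delivered with open opposed fields puts clinically significant dose
into the parotid and lacrimal glands, driving acute xerostomia and dry
eye. `ntcplan` is for medical physicists and outcome modelers who want to
quantify how much a gland-sparing re-plan (field blocking or IMRT/VMAT)
is expected to reduce those risks: it turns per-structure dose-volume
histograms (DVHs) into normal tissue complication probabilities (NTCP),
evaluates plans against standard hippocampal-avoidance clinical goals,
and runs the paired cohort statistics of a re-planning study — plus a
seeded synthetic-cohort generator so the whole pipeline is testable
without patient data.

## Models

**Relative seriality (RS).** Each DVH bin (dose `D_i`, volume fraction
`Δv_i`) responds via the Poisson sigmoid

    P(D) = 2^(−exp(e·γ·(1 − D/D50)))

and the organ-level risk is

    NTCP = [1 − Π_i (1 − P(D_i)^s)^(Δv_i)]^(1/s)

with `D50` the uniform dose giving 50% risk, `γ` the maximum normalized
slope, and `s` the relative seriality (`s = 1` serial, `s → 0` parallel).
Shipped presets (fitted for WBRT at 30 Gy / 10 fx):
parotid xerostomia `D50 = 24.9 Gy, γ = 0.26, s = 1e-4`; lacrimal dry eye
`D50 = 63.9 Gy, γ = 0.34, s = 1e-4`. The product is evaluated in log
space — at `s = 1e-4` the naive form underflows.

**LKB.** `NTCP = Φ((gEUD − TD50)/(m·TD50))` with
`gEUD = (Σ Δv_i D_i^(1/n))^n`. No parameter presets are shipped for
these endpoints; supply your own via `lkb_params()`.

**Cohort statistics.** Paired t-tests of per-patient NTCP between plans,
two-sided, with Bonferroni control over the two original-vs-re-plan
comparisons (family α = 0.05 → per-test 0.025), risk-difference
summaries, standardized effect sizes, and exact noncentral-t power
(`paired_power(11, 1.1, 0.025)` ≈ 0.825).

## Worked example

```r
library(ntcplan)

# a parotid DVH: 25% scatter, the rest near/above 20 Gy
parotid <- ntcp_presets("parotid_xerostomia_rs")
d <- make_differential(c(5, 18, 26, 31), c(0.25, 0.20, 0.35, 0.20), "parotid")
sprintf("V20 = %.1f%%, mean dose = %.1f Gy, NTCP = %.1f%%",
        100 * volume_at_dose(to_cumulative(d), 20),
        summary_metrics(d)$d_mean, 100 * rs_ntcp(d, parotid))
#> "V20 = 70.0%, mean dose = 20.1 Gy, NTCP = 45.2%"

# full synthetic re-planning study: 11 patients x 2 glands x 3 plans
print(run_study(cohort_config())$comparison)
#> Cohort NTCP comparison (per-test alpha = 0.025)
#>    endpoint        plan mean_pct sd_pct delta_mean_pct delta_sd_pct      t        p significant in_family
#>     dry_eye    original     26.0    0.9             NA           NA     NA       NA          NA     FALSE
#>     dry_eye   replan_3d     26.1    0.9            0.1          0.3   0.91 3.85e-01       FALSE      TRUE
#>     dry_eye replan_imrt     21.4    0.4           -4.7          0.5 -31.32 2.59e-11        TRUE      TRUE
#>     dry_eye  imrt_vs_3d       NA     NA           -4.7          0.6 -27.98 7.90e-11        TRUE     FALSE
#>  xerostomia    original     42.8    1.4             NA           NA     NA       NA          NA     FALSE
#>  xerostomia   replan_3d     38.7    1.2           -4.1          0.8 -17.11 9.83e-09        TRUE      TRUE
#>  xerostomia replan_imrt     33.4    1.0           -9.5          0.9 -35.15 8.25e-12        TRUE      TRUE
#>  xerostomia  imrt_vs_3d       NA     NA           -5.3          0.5 -32.92 1.58e-11        TRUE     FALSE
```

Reading the table: per endpoint, cohort mean ± SD of the modeled risk
under each plan, and the per-patient risk change of each re-plan against
the original (`Δ` mean ± SD, paired t, two-sided p). The pattern is the
signature of gland-sparing re-planning: xerostomia risk falls
significantly under both the parotid-blocked 3D re-plan and IMRT, while
dry-eye risk falls only under IMRT — the lacrimal glands sit too close
to the brain to block with 3D fields, so its 3D Δ hovers at zero.
`imrt_vs_3d` is a supplementary contrast outside the Bonferroni family.

## Command line

```sh
Rscript inst/cli/ntcplan simulate --seed 7 --out-dir out/        # synthetic study
Rscript inst/cli/ntcplan compute --dvh out/cohort_dvhs.csv \
        --model rs --preset parotid_xerostomia_rs                # NTCP per DVH
Rscript inst/cli/ntcplan goals   --dvh plan_dvhs.csv             # Table-style goal report
Rscript inst/cli/ntcplan cohort  --table out/cohort_ntcp.csv     # paired comparison
```

Exit code 0 on success, 2 on validation errors; every run logs version,
seed and a config hash.

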