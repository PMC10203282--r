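# metabolonr

Tested R implementations of the computational analyses used to characterise
a native oxoglutarate dehydrogenase complex (OGDHc) metabolon — the 24-mer
E2o core whose disordered arms swing a lipoyl domain (LD) between peripheral
E1o and E3 dimers. The package is aimed at structural bioinformaticians and
biochemists who need these desk-scale computations as reusable, seeded,
testable code rather than one-off scripts:

* **Unresolved-linker survey** — parse mmCIF `atom_site` +
  `_pdbx_unobs_or_zero_occ_residues` records, merge unobserved residues into
  maximal regions, measure the end-to-end Cα–Cα distance across each region,
  bin adaptively (unit bins to 50 aa, then 55…4000), and fit the empirical
  saturation model

  *y* = *A* (1 − e^(−*b x*)) + 3.5,

  with *y* the mean Cα–Cα distance (Å), *x* the linker length (aa) and the
  3.5 Å offset fixed.
* **Crosslink validation** — map residue–residue crosslink ledgers onto
  models (minimum Cα–Cα distance over homomer chain assignments), report
  distance satisfaction at 25/30/35 Å cutoffs, fit the expected log-normal
  distance distribution, and count unique intra/inter links.
* **Guiding-surface analysis** — per-residue contact frequencies of a
  receptor over an ensemble of docked LD poses (5 Å heavy-atom rule), with
  top-quartile hotspot extraction under both readings of the quartile rule.
* **Kinetics under substrate-excess inhibition** — Beer–Lambert conversion
  of WST-8 absorbance traces (ε = 3.07 × 10⁴ M⁻¹cm⁻¹), early-linear-window
  initial velocities, and the Michaelis constant from the abscissa intercept
  of the asymptotic Lineweaver–Burk regression,
  *K*<sub>M</sub> = slope/intercept, restricted to low [S] where
  *v* = *V*<sub>max</sub>[S]/(*K*<sub>M</sub> + [S](1 + [S]/*K*<sub>i</sub>))
  is unbent by inhibition.
* **Stoichiometry** — iBAQ-anchored copy numbers (anchor: E2o = 24) and the
  maximal-occupancy chain count of the metabolon
  (24 + 24 + 2·12 + 2·12 = 96).

Every stage has a seeded synthetic-data generator with exact ground truth
(`gen_*` functions), so the full pipeline runs offline and every computation
is tested against independent oracles. The numbered scripts under
`analysis/` are narrative drivers that exercise each stage end to end and
write tables, figures and JSON reports under `results/`.

## Worked example

```r
library(metabolonr)

# --- linker survey: recover the saturation constants from a noisy survey
survey <- gen_survey_points(A = 11, b = 0.2, max_length = 250,
                            noise_sd = 0.3, seed = 1)
fit <- fit_saturation(survey)
fit
#> <saturation_fit> y = 11.027 * (1 - exp(-0.2025 x)) + 3.5  (SS 3.86 over 59 bins)
evaluate_model(fit, 73)   # predicted reach of a 73-residue linker arm
#> [1] 14.53

# --- kinetics: KM of a CoA-like titration with substrate-excess inhibition
g <- gen_kinetics(km = 22.81, vmax = 1, ki = 500, noise = 0.05, seed = 1)
rates <- do.call(rbind, lapply(split(g$traces, g$traces$substrate_uM),
                               initial_velocity))
lineweaver_burk_km(rates)
#> <km_fit> KM = 21.75 uM, Vmax = 0.934 uM/min (asymptotic subset of 4 points)

# --- stoichiometry: copies anchored to the 24-mer core
relative_copies(gen_abundance(noise_cv = 0, seed = 1)$table)
#>  protein    ibaq oligomer_size copies assembly_units
#>      E2o 2.4e+08             1     24             24
#>      E1o 2.0e+08             2     20             10
#>       E3 8.0e+07             2      8              4
#>    E3BPo 4.0e+07             1      4              4
max_occupancy_chains(24, 24, c(12, 12))
#> [1] 96
```

The fitted amplitude and rate sit on the generating constants (11 Å,
0.2 aa⁻¹); the saturation value *A* + 3.5 ≈ 14.5 Å says a disordered linker's
mean end-to-end reach plateaus quickly with length. The Michaelis constant
is recovered from the low-concentration asymptote despite velocities
*falling* above ~100 µM, and the copy-number table reproduces the planted
24/20/8/4 composition exactly in the noise-free case.

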