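---
title: "Computational analyses of a native OGDHc metabolon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational analyses of a native OGDHc metabolon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolonr)
```

# Scope

The oxoglutarate dehydrogenase complex (OGDHc) is a megadalton metabolon: a
24-mer E2o cubic core whose long disordered N-terminal arms carry a lipoyl
domain (LD) that shuttles reaction intermediates between the peripheral E1o
and E3 dimers, with the monomeric E3BPo tethering E3 to the core.
Characterising such an assembly in a native cell extract leans on a chain of
bespoke desk-scale computations, each of which this package implements as
tested, seeded, reusable code:

1. a PDB-wide survey of *unobserved regions* — stretches present in a
   deposited sequence but missing from the coordinates — with the end-to-end
   Calpha distance between their observed flanks as a proxy for how far a
   disordered linker of given length reaches;
2. mapping of crosslinking mass-spectrometry residue pairs onto structural
   models, with distance-satisfaction statistics and a log-normal check of
   the mapped-distance distribution;
3. contact-frequency ("guiding surface") analysis of a receptor across an
   ensemble of docked LD poses;
4. Michaelis-constant determination from plate-reader absorbance traces in
   the presence of substrate-excess inhibition;
5. iBAQ-anchored copy-number estimation and the maximal-occupancy chain
   count of the assembly.

Each stage has a synthetic-data generator with known ground truth
(`gen_structure()`, `gen_survey_points()`, `gen_crosslinks()`,
`gen_pose_ensemble()`, `gen_kinetics()`, `gen_abundance()`), so the entire
pipeline runs and is tested without any downloads. The numbered scripts
under `analysis/` are thin narrative drivers over these functions.

# The linker survey and its saturation model

Unobserved regions are read from the mmCIF
`_pdbx_unobs_or_zero_occ_residues` category and merged into maximal runs of
consecutive residues per chain. Author numbering (`auth_seq_id`) is used to
match unobserved records to coordinates because that category is authored in
it. Zero-occupancy records are treated identically to fully unobserved ones
(the source category mixes them and nothing downstream distinguishes them);
among altloc duplicates the highest-occupancy conformer wins, ties broken
alphabetically. A region's distance is the Euclidean Calpha–Calpha distance
of its two flanking observed residues; terminal runs (one flank absent) are
kept as regions but are ineligible for distance statistics, since the
measurement requires both flanks.

Lengths are binned with unit width for 1–50 residues; beyond 50 the right
edge grows through 55, 60, 65, 70, 75, 100, 125, 150, 250 and 4000,
reflecting how quickly long gaps become rare. Within each bin we report the
mean distance and the 0.0–1.0 quantile envelope in steps of 0.2 (linear
interpolation between order statistics — the common monotone default). The
relation between mean distance $y$ and linker length $x$ is summarised by
the empirical saturation model

$$y = A\,(1 - e^{-b x}) + 3.5,$$

fit by nonlinear least squares (Levenberg–Marquardt via `minpack.lm`) over
$(A, b)$ with the 3.5 Å offset *fixed*: the offset is part of the model
definition (roughly one trans Calpha–Calpha step — the shortest distance a
single-residue gap can span), not a free parameter. Numerical choices:

* **Abscissa for merged bins**: the arithmetic bin midpoint. Unbiased for
  symmetric bins; the alternative (count-weighted mean length) would tie the
  fit to the survey's length distribution.
* **Weighting**: unweighted by default; `weight_by_n = TRUE` is available.
* **Initialisation**: $A_0 = \max(y) - 3.5$, $b_0 = 1/\mathrm{median}(x)$,
  with two deterministically scaled restarts on failure.
* **Degenerate input**: a survey whose means never exceed the offset returns
  $A = 0$ with $b$ flagged unidentifiable rather than an arbitrary number.

For context the survey is plotted against an extended-chain line (a
configurable slope, 7 Å per residue by default, with 3.5 Å per residue as a
contour reference) and literature power-law models of disordered-chain
dimensions ($\text{prefactor} \times N^{\text{exponent}}$). The shipped
power-law constants follow the hydrodynamic-radius parameterisations of
Marsh & Forman-Kay (2.49, 0.509) and Wilkins et al. (2.21, 0.57), plus an
approximate ideal-coil scaling (2.0, 0.5) for the George & Heringa loop
survey; all are arguments, not facts baked into code, and should be replaced
when a specific parameterisation is required.

```{r survey-example}
survey <- gen_survey_points(A = 11, b = 0.2, max_length = 250,
                            noise_sd = 0.3, seed = 1)
fit_saturation(survey)
```

# Crosslink mapping and satisfaction

Ledgers are delimited tables of residue pairs; links are canonicalised as
unordered (protein, residue) pairs and deduplicated across replicates with
provenance retained. Distances are measured between Calpha atoms, matching
the survey convention; for a protein mapped to several chains (E1o and E3
are homodimers) the *minimum* distance over allowed chain assignments is
used — the standard resolution of homomer ambiguity, since a crosslink
cannot distinguish copies. A link whose residues lack a Calpha in every
candidate chain is reported unmapped, which is data (it flags disordered or
unmodelled regions), not an error.

The satisfaction cutoff deserves emphasis: published satisfaction
percentages rarely state it. For a BS3-like reagent (11.4 Å spacer plus two
lysine side chains and backbone tolerance) 30 Å Calpha–Calpha is the
community convention, so 30 Å is the default — but every report here also
states fractions at 25/30/35 Å (`satisfaction_profile()`), making the
cutoff sensitivity visible instead of hiding it. The boundary is inclusive:
a link exactly at the cutoff is satisfied.

The mapped-distance distribution is summarised by the closed-form
log-normal maximum-likelihood fit (mean and standard deviation of log
distances, $n$-denominator) with a Kolmogorov–Smirnov statistic against the
fitted law.

# Guiding-surface contact frequencies

For each pose, a receptor residue is an interface residue if any of its
heavy atoms lies within 5 Å (inclusive) of any ligand heavy atom; hydrogens
are excluded because their presence varies across refined models. Counts
are accumulated over the ensemble and normalised by the pose count. A
bounding-box prefilter keeps the scan fast at the 400-pose, 500-residue
scale while remaining exactly equivalent to the all-pairs computation (the
tests assert identity against a brute-force oracle).

"Top quartile" admits two readings, and both ship:

* `rule = "percentile"` (default): residues whose frequency reaches the
  75th percentile of the *nonzero* frequencies, ties at the percentile
  included (so a flat profile returns every contacted residue rather than
  an arbitrary subset);
* `rule = "absolute"`: residues contacted in more than 25% of poses.

The default is the reading that adapts to the ensemble's frequency scale;
the absolute reading is preferable when ensembles of different sizes must be
compared on one scale.

# Kinetics under substrate-excess inhibition

Absorbance at 460 nm is converted to product concentration via
Beer–Lambert with the WST-8 formazan coefficient
$\varepsilon = 3.07 \times 10^4\ \mathrm{M^{-1}cm^{-1}}$. The optical path
of a plate well is geometry-dependent and often unreported; the default is
1 cm, it is configurable in `assay_constants()`, and every fit report echoes
the value used — treat absolute concentrations and $V_{max}$ with
corresponding caution (the Michaelis constant itself is path-independent,
since a global scale on velocities cancels in the abscissa intercept).

Initial velocities are slopes of ordinary least squares over the longest
leading window (at least 5 points) whose linear fit reaches
$R^2 \ge 0.99$, after first-timepoint blank subtraction. This screen is
deliberately permissive: on noisy traces a stricter threshold frequently
leaves no admissible window at all. The cost is that on a sharply
plateauing trace the window can admit a handful of post-plateau points and
bias the slope by a few percent; with a tighter `r2_min` (e.g. 0.999,
appropriate for low-noise data) the window pins to the linear phase and the
bias drops below 2%. Both behaviours are asserted in the test suite, and
`r2_min`/`min_points` are exposed as policy arguments.

Because velocity declines again at high substrate (excess inhibition,
$v = V_{max}[S]/(K_M + [S](1 + [S]/K_i))$), the double-reciprocal
(Lineweaver–Burk) regression is restricted to the asymptotic
low-concentration subset — the $k$ points of highest $1/[S]$, default
$k = \max(3, \lfloor n/2 \rfloor)$ — where the inhibition term is
negligible. $K_M = \mathrm{slope}/\mathrm{intercept}$ (the abscissa
intersection) and $V_{max} = 1/\mathrm{intercept}$. Data so dominated by
inhibition that the fitted intercept or slope is non-positive raise an
error naming the problem rather than returning a negative constant.

```{r kinetics-example}
g <- gen_kinetics(km = 22.81, vmax = 1, ki = 500, noise = 0, seed = 1)
lineweaver_burk_km(g$truth)
```

# Stoichiometry

iBAQ intensities are molar-abundance proxies, so copy numbers follow from
linear anchoring on a subunit of known copy number — here the E2o core,
fixed at 24 by its cubic architecture. Copies divide by oligomer size to
give assembly units (dimers for E1o/E3). No rounding is applied; the
estimates are qualitative bands by nature, and presentation (e.g. "fewer
than 10 dimers") is left to reports. `max_occupancy_chains()` performs the
maximal-occupancy arithmetic: core + tethers + twice each dimer count.

# What the generators emulate, and what they do not

* `gen_structure()` builds Calpha traces as 3.8 Å-step random walks with
  internally excised segments. The walks are not self-avoiding and carry no
  secondary structure; this is irrelevant to the bookkeeping being tested
  (region merging, flank resolution, distance measurement) but means the
  *distance statistics* of synthetic surveys do not reproduce the
  compactness of real folded chains. Coordinates are written at mmCIF's
  3-decimal precision and ledger truths are computed from the rounded
  coordinates, so round-trips are exact rather than approximately equal.
* `gen_crosslinks()` plants an exact satisfied fraction at a stated cutoff
  and adds decoys referencing absent residues to exercise the unmapped
  path. Real ledgers add identification noise and FDR structure that these
  tables do not model.
* `gen_pose_ensemble()` plants a spatially compact site and calibrates the
  ligand anchor with a 0.5 Å margin against the contact cutoff so that pose
  jitter cannot flip contact membership; off-site poses sit beyond 15 Å.
  Real docking ensembles have graded, overlapping interfaces — recovery
  there is a harder problem than these tests certify.
* `gen_kinetics()` integrates product linearly at the true initial rate
  until substrate exhaustion, then plateaus. Real traces curve smoothly
  into the plateau; the piecewise form is chosen so that "the true initial
  velocity" is well-defined to machine precision for recovery tests.
* `gen_abundance()` applies multiplicative log-normal noise to true copy
  numbers; it does not model peptide-level missingness.

Passing tests therefore certify the *computations* — parsing, merging,
measuring, binning, fitting, counting — under controlled truth, not the
field behaviour of the upstream experiments.

# Problem sizes and determinism

The test suite and the acceptance script use 20-seed replicate experiments
for the stochastic recoveries (saturation constants, Michaelis constant), a
400-pose ensemble over a 500-residue receptor for the interface scan, and
surveys of a few hundred regions for the structure path; the full suite
runs in well under a minute. All randomness is funnelled through explicit
`seed` arguments; a fixed seed reproduces generator output byte for byte.

# Known limitations

* The mmCIF reader covers the two categories this pipeline consumes
  (`atom_site`, `_pdbx_unobs_or_zero_occ_residues`) with quoted-token
  loops; it does not parse semicolon text blocks, assemblies or anisotropic
  records, and insertion codes are not ordered beyond integer residue
  numbering.
* Satisfaction percentages depend on the cutoff choice; always read them
  alongside the 25/30/35 Å profile.
* The asymptotic subset rule for the double-reciprocal fit is a policy, not
  an estimate of where inhibition becomes negligible; with very strong
  inhibition ($K_i \lesssim 10 K_M$) even the lowest concentrations are
  biased and the recovered $K_M$ drifts low.
* Linear iBAQ anchoring propagates any bias in the anchor's intensity to
  every copy number; the anchor ratio also doubles the noise variance
  relative to a single intensity.
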