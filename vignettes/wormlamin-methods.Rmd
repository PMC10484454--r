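---
title: "Phenotyping and scoring C. elegans lamin variant models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping and scoring C. elegans lamin variant models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormlamin)
```

## The problem

Missense variants of the human lamin gene *LMNA* cause striated-muscle
laminopathies whose severity ranges from cardiac-only disease to early-onset
disorders that also affect skeletal muscle, and hundreds of variants of
unknown clinical significance (VUS) await characterization. The single
*C. elegans* lamin gene *lmn-1* conserves many of the affected residues, so
homozygous worm strains carrying homologous missense edits can serve as fast
clinical avatars: measurable defects in worm fertility, motility and nuclear
biology track the severity of the corresponding human variant.

`wormlamin` implements the quantitative half of that programme as a tested
pipeline: per-animal assay measurements in, per-variant pathogenicity score
cards out, with a synthetic-data generator (including rendered swim videos
with ground truth) so that every stage can be validated end to end without
any external data.

## Assays and their statistics

Five assays feed the analysis. Each dataset is a tidy per-animal table
(`assay_dataset`), and every comparison is reported as a `stat_result` row
carrying the raw and multiplicity-adjusted p-value, the effect direction and
a degeneracy flag.

* **Viability.** Mothers are moved to a fresh plate daily for three days;
  the brood is the summed egg count (`brood_size()`) and embryonic
  lethality is `100 × unhatched / brood` (`percent_lethality()`). A mother
  that laid no eggs has no defined lethality; she is excluded from
  lethality means (flagged sterile) but retained for brood means and for
  the inviability call. Brood and lethality are each compared against the
  control by one-way ANOVA with single-step Dunnett (many-to-one)
  adjustment (`anova_dunnett()`), the standard guard on familywise error
  when a dozen variant strains share one wild-type control.
* **Swimming.** Thrashing animals are scored as body bends per second
  (BBPS) over a 30-s window. Besides a Dunnett comparison of mean BBPS,
  the headline statistic is the *defect fraction*: the proportion of
  animals at or below the 1.1 BBPS threshold, the corroborated mean
  swimming rate of the well-studied *lmn-1(Y59C)* strain. Ties at the
  threshold count as defective ("at or below"). Fractions are compared
  against the control by Pearson's chi-squared on the 2×2 table without
  continuity correction (`swim_defect_test()`); a table with an empty
  margin returns statistic 0 and p = 1, flagged degenerate, rather than
  erroring.
* **Nuclear migration.** Dorsal hyp7 precursor nuclei that fail their
  embryonic migration are stranded in the dorsal cord and counted per
  animal; counts are compared all-pairs by ANOVA with Tukey's studentized
  range adjustment (`anova_tukey()`).
* **Nuclear morphology.** Nuclear blebs on one lateral side of the hyp7
  syncytium are counted per animal and compared to control with a
  rank-based two-sample test, with the family of raw p-values adjusted by
  Benjamini–Hochberg at a 5% false discovery rate (`bleb_defect_tests()`).
  The rank test is used because bleb counts are small, skewed counts;
  the BH step-up itself (`bh_adjust()`) is checked against a brute-force
  implementation of its definition in the test suite.
* **Fluorescence.** Nuclear-envelope protein levels are quantified as
  corrected total nuclear fluorescence,
  `CTCF = integrated density − area × mean background` (`ctcf()`;
  negative values are preserved and flagged), and compared by a two-sided
  equal-variance Student's t test (`two_group_t()`).

The base significance level is `alpha = 0.05` throughout; report stars use
`p ≤ 0.05 / 0.01 / 0.001` with inclusive thresholds.

### Numerical choices

Dunnett adjusted p-values come from the multivariate-t quadrature in
`multcomp`; because that quadrature is stochastic, it is evaluated under a
fixed internal RNG state (saving and restoring the caller's state), making
results reproducible to well below the 1e-3 level that matters for the
rubric. An independent Monte-Carlo route (`dunnett_p_mc()`, 1e5–2e5 draws of
the many-to-one multivariate-t maximum) agrees with the quadrature within
0.005 in the test suite. Tukey p-values use the closed-form `ptukey` and are
cross-checked against base `TukeyHSD`. With a single comparison in the
family both procedures reduce to the two-sample pooled t test within 1e-6.
Degenerate inputs (zero within-group variance, empty 2×2 margins) return
flagged conventional values rather than errors, so that a calibration run
never aborts mid-family.

## The scoring rubric

Each non-control variant receives three component scores:

| component | values | rule |
|---|---|---|
| viability | 0 / 1 / 2 | 2 if homozygous inviable — every mother sterile, or eggs laid but none viable; 1 if brood *or* lethality is significantly worse than control (Dunnett-adjusted p ≤ 0.05 in the worse direction); else 0 |
| swimming | 0 / 2 | 2 if strictly more than 30% of animals are at or below 1.1 BBPS; else 0 |
| migration | 0 / 1 (or N/A) | 1 if the Tukey-adjusted comparison is significant with more mislocalized nuclei than control; N/A when no data exist (contributes 0, printed as "N/A") |

The total is the sum of non-missing components and the classification is
**severe (skeletal + cardiac pattern)** when the total is at least 2,
mild/cardiac-only otherwise. Two boundary conventions are deliberate and
fixed: the 30% cutoff is strict (a fraction of exactly 0.30 scores 0), and
the inviability rule covers both the fully sterile case and the
eggs-laid-but-dead case, so that a strain can reach viability score 2 by
either route. "Significantly worse" is directional: a variant with a
significantly *larger* brood than control is not penalized.

The rubric deliberately excludes bleb counts and fluorescence: they are
reported as supporting evidence but carry no score weight. Whether the
swimming component should additionally require chi-squared significance on
top of the >30% rule is undetermined; the fraction rule alone decides the
score, and the chi-squared result is attached to the evidence bundle.

## The synthetic-data generator

The generator exists so that the statistical pipeline can be calibrated
under known truth. A `genotype_profile` holds one strain's generative
parameters; four templates encode the study's archetypes:

* `wild_type` — brood mean 250 eggs (negative-binomial, size 25; a
  realistic lab-strain brood), 1% embryonic lethality, swimming mixture
  centred at 1.86 BBPS with 2% impaired animals, 0.5% per-nucleus
  migration failure, 0.3 blebs/side.
* `severe` — brood mean 88 (≈ 35% of wild type), 25% lethality, 60%
  impaired swimmers (impaired component at 0.4 BBPS), 25% per-nucleus
  migration failure (≈ 4 of 16 nuclei mislocalized), 3 blebs/side.
* `cardiac_only` and `benign_vus` — wild-type-like in all rubric assays.

Generative families: brood counts are zero-inflated negative binomial
(sterile mothers lay nothing; overdispersion reflects animal-to-animal
spread), unhatched eggs are binomial per egg, BBPS is a two-component
normal mixture truncated at zero (swimming rates are nonnegative and
defective strains are visibly bimodal), mislocalized nuclei are binomial
over `nuclei_per_animal` scorable nuclei, blebs are Poisson, and
fluorescence is Gaussian. The per-animal denominator for migration is not
a published constant; the default of 16 scorable dorsal nuclei is a
configurable convention of this package.

One global integer seed drives everything; each assay draws from a stream
derived by hashing the seed with an assay tag (`derive_seed()`), so adding
or reordering assays never perturbs another assay's draws, and identical
inputs are byte-for-byte reproducible.

What the generator does **not** emulate: correlated phenotypes within an
animal, day-to-day batch effects, heterozygous (balancer) genetics,
developmental timing, or realistic worm texture and self-occlusion in the
videos. Passing calibration therefore demonstrates that the statistics and
rubric behave correctly under the assumed generative families, not that
those families capture every feature of real assay data.

## The swim-video chain

`generate_swim_video()` renders each worm as a thickened constant-curvature
arc whose curvature oscillates sinusoidally. BBPS counts side-bends — two
per full left-right thrash cycle — so the curvature oscillates at half the
target bend frequency; the body then passes through a bent configuration
`bend_freq_hz` times per second, which is the ground-truth BBPS returned
per worm. Worms translate along a slow circular orbit (radius 7 px by
default): thrashing worms are not pixel-stationary, and the motion keeps
the temporal background estimate worm-free. Placement uses a jittered grid
with a conservative non-overlap separation and errors out beyond the
packing density.

The tracker mirrors a standard binarize-label-link design:

1. **Background subtraction** (`binarize_frames()`): per-pixel temporal
   quantile of an evenly spaced frame subsample (default quantile 0.2,
   robust even where a slowly orbiting worm covers a pixel in most
   frames — a plain median breaks exactly there), or per-frame
   morphological opening ("rolling", the right choice for a worm that
   never moves). Thresholding is global Otsu on the pooled histogram, or
   a fixed level; an all-constant stack makes Otsu's histogram degenerate
   and is an explicit error.
2. **Tracking** (`track_worms()`): 8-connected components per frame,
   area-filtered, linked greedily to the nearest open track head with a
   per-frame distance gate; gaps longer than `max_gap` frames close a
   track. Equidistant ties resolve to the lower component label, then the
   older track, making linking deterministic.
3. **Bend counting** (`count_body_bends()`): the per-frame bend signal is
   the component's normalized elongation (square root of the ratio of its
   principal second moments) — chosen over skeleton curvature because it
   is robust at low resolution and cheap. The signal is smoothed over
   ~0.1 s, mean-centred, and crossings of zero are counted with a
   hysteresis band of 0.25 signal SDs; BBPS = crossings / 2 / duration. A
   signal SD below 0.05 is called immobile (0 BBPS).

Closed-loop validation renders 20 worms per frequency at 0.5, 1.0, 1.5 and
2.0 Hz (30 fps, 30 s) and requires every recovered BBPS within 10% of
truth; observed errors are below 5%. These runs use 380×380 px frames with
36 px worms — the smallest geometry that holds 20 non-overlapping animals —
while the generator's default canvas is 512×512 px with 60 px worms.

## Calibration experiments

Two seeded Monte-Carlo experiments pin the rubric's operating
characteristics at the study's sample sizes (10 mothers, 40 swimmers, 20
migration animals per strain), with 200 replicates each:

* a wild-type-identical strain scored against the control totals 0 in at
  least 95% of replicates (observed ≈ 96–97%; the residual is the
  directional false-positive rate of the viability and migration
  components), and
* a severe-template strain classifies severe in at least 95% of
  replicates (observed ≈ 100%).

The chi-squared defect test's type-I error is measured over 1000 null
replicate pairs at n = 40. The null defect rate for this calibration is
0.2, chosen by the standard validity rule for Pearson's test (expected
cell counts ≥ 5, i.e. rate ≥ 0.125 at n = 40); within that regime the
uncorrected test sits near its nominal 5% level. At the wild-type defect
rate (≈ 0.035) the same test is *conservative* (exact type-I error ≈
0.026 by enumeration), which is the safe direction for the screening
question asked of it; the suite asserts that behaviour separately.

## The packaged workbook

The package ships a small sectioned workbook
(`inst/extdata/s1_synthetic_workbook.csv`, *synthetic*, built by
`scripts/make_fixture.R`) holding a full 13-genotype panel — wild type plus
the twelve modelled variants — in the raw-data layout the reader
(`read_s1_workbook()`) accepts: one `# section:` block per assay, one
column per genotype, one value per animal, ragged columns allowed. The
panel is generated from the template profiles and deterministically
rescaled so that the genotype sample means equal the published summary
values (wild-type mean 1.86 BBPS, Y59C 1.1 BBPS, L535P below 1 BBPS, the
E358K brood below 40% of wild type) and the full analysis reproduces the
published twelve-row score table, including the G528R strain's missing
migration data (printed "N/A"). It is a stand-in for the original raw-data
workbook, which is not redistributed here; `read_s1_workbook()` reads an
XLSX with the same layout directly, and a `section_map` config entry
renames nonstandard section headers.

## Known limitations

* The elongation-based bend signal cannot separate two worms that touch;
  the simulator avoids collisions by construction, and on real videos
  merged animals would need to be excluded upstream.
* Heterozygous balancer-carrying genotypes are not scored as part of the
  panel (homozygotes define the score table); they can be analysed as
  ordinary additional genotypes if supplied.
* The lethality ANOVA operates on per-mother percentages, which is the
  conventional design here but ignores differing brood sizes; a binomial
  GLM would weight mothers by brood and is out of scope.
* Dunnett families are formed from all genotypes present in a dataset;
  analysing subsets changes the adjustment, as it should.
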