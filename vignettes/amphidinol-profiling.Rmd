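---
title: "Methods: amphidinol screening, annotation and strain profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amphidinol screening, annotation and strain profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amprofiler)
```

## The problem

Amphidinols (AMs) are large polyketides (> 1000 Da) produced by benthic
dinoflagellates of the genus *Amphidinium*, with hemolytic, antifungal and
cytotoxic activities. Roughly fifty analogs are known under assorted trivial
names (luteophanols, lingshuiols, symbiopolyols, karatungiols, carteraols).
Full structure elucidation needs NMR on purified material; in practice most
discovery and profiling work is done by LC-MS/MS on crude extracts, where
electrospray ionization yields stable sodium adducts that fragment sparsely
under collision-induced dissociation (CID). The few fragments that do form
are highly diagnostic, which makes AMs well suited to rule-based spectrum
interpretation. `amprofiler` implements that interpretation, the screening
strategy around it, semi-quantification, a companion brine-shrimp toxicity
reduction, and multivariate profiling of strain chemotypes.

## The fragmentation grammar

All arithmetic operates directly on observed sodium-adduct m/z; no
neutral-mass conversion is ever applied, because all the diagnostic losses
are themselves defined on adduct masses. Four rules make up the grammar,
each anchored at the precursor `M` (or at the desulfated ion where noted):

1. **Sulfation** ([`detect_sulfation()`]): a fragment at `M - 120`
   (loss of NaHSO4) marks a sulfated variant; the matching fragment is the
   desulfated ion `D`.
2. **Lipophilic-arm loss** ([`assign_arm()`]): the cleavage between the two
   vicinal hydroxyls of the conserved central region (the C1/C1' bond, the
   weakest in the molecule) releases the lipophilic arm as a neutral of
   conserved mass — 392, 398 or 426 Da in the default library — leaving the
   charged hydrophilic fragment at `B - arm`, where `B = D` for sulfated
   compounds and `B = M` otherwise. A 392 Da arm is shared with
   lingshuiol-A, 398 Da with AM-B.
3. **Carbonyl pairs** ([`detect_carbonyl_pairs()`]): a
   di-γ-hydroxy-carbonyl group cleaves on either side of the carbonyl via
   six-membered transition states, so the two cleavage products always
   differ by 58 Da. Pairs are searched across the whole fragment list (both
   the high-mass series retaining the arm and the low-mass series after arm
   loss show them), excluding the precursor.
4. **Terminus loss** ([`detect_terminus_loss()`]): a 218 Da neutral loss
   from the pseudo-molecular ion marks a conserved hydrophilic-arm
   terminus; sulfated counterparts lose 200 Da from the desulfated ion
   instead (the AM-18/AM-19 relationship). 218 takes precedence if both
   match.

The verdict logic is deliberately conservative: a spectrum is `novel` only
with positive structural evidence — an assigned arm, or a carbonyl pair
*plus* a terminus loss. A precursor that merely falls in the AM mass range
stays `non-AM`, so full-scan noise is never auto-promoted.

```{r}
fx <- make_fixture_table1()
annotate_spectrum(fx$spectra[["ARC-8"]])
```

## Tolerances and tie-breaks

The reference instrument is a unit-resolution triple quadrupole and every
published mass is an integer, so all matching uses an absolute tolerance,
default **0.5 Da**, configurable throughout. Retention-time matching uses
**0.1 min**, wide enough to absorb the up-to-0.06 min differences between
the narrative and tabulated retention times of several variants. Arm
assignment breaks ties by smallest mass deviation, then largest fragment
intensity, then smallest arm mass; known-variant matching by closest Q1,
then closest RT (ambiguity is logged). All tie-breaking is total, so
annotation is deterministic.

Two source inconsistencies are resolved in favour of arithmetic: for the
m/z 1446 variant the desulfated ion is taken as 1446 − 120 = 1326 (one
narrative passage says 1278, which contradicts both the subtraction and the
figure caption), and the m/z 1608 fixture follows its figure caption
(desulfation to 1488, 426 Da arm, 58 Da pairs, 200 Da terminus) rather than
a fragment listing that mixes in values from the m/z 1506 variant.

## Screening

Three modes run in order of specificity:

* **SRM** (`srm_detect()`): a chromatographic peak matching a library
  transition in Q1, Q3 and RT. The shipped library contains the eight ARC
  variants recoverable from the published text; the historical ~50-variant
  library is not public, so the CSV is user-extendable.
* **Neutral loss** (`nl_screen()`): fourteen channels — seven non-sulfated
  arm masses and their sulfated (+120 Da) counterparts. Only 392/398/426
  are published; the other four ship as flagged placeholders and must be
  treated as user-supplied.
* **Full scan** (`fs_screen()`): any remaining precursor inside m/z
  1000–1800 and RT 2.0–4.2 min (inclusive). Precursors within 0.2 min
  beyond the RT window are excluded but reported with a warning rather than
  silently dropped, since genuine variants are known to elute marginally
  outside the nominal window (the fixture's m/z 1506 variant elutes at
  4.35 min).

All modes gate on S/N ≥ 3, the method's stated detection threshold. The
paper's S/N comes from vendor chromatogram software and is unspecified for
peak lists, so two estimators are provided. For traces,
`estimate_snr()` uses `(peak − median baseline) / (1.4826 × MAD)`, a
standard robust choice. For centroided peak lists, `fragment_snr()` defines
the noise floor as the median intensity of peaks below 10% of the base
peak; spectra with no such sub-threshold peaks are treated as noise-free
(infinite S/N). Both are configurable and documented as estimator choices,
not published constants.

## Semi-quantification

No per-variant standards exist, so all concentrations are luteophanol-D
(LPD) equivalents from a one-point external calibration:

* concentration: `conc = area_toxin × c(LPD) / area(LPD)`,
* cell quota: `quota = conc × volume(µL) × 10⁶ / n_cells` (fg cell⁻¹),
* limit of detection: `LoD = c(LPD) × 3 / (S/N)(LPD) × volume × 10⁶ /
  n_cells`.

The default standard concentration is **12.5 ng µL⁻¹** (10 µg dissolved in
800 µL; the commonly quoted rounded value "about 13" can be set via
config). Whether reported strain totals should include below-LoD trace
signals is not specified anywhere; the package excludes them by default
(the conservative choice) with an `include_below_lod` switch.

## Toxicity

The brine-shrimp (*Artemia salina*) assay uses three treatment and six
control wells of ~60 nauplii per strain. Treatment deaths are adjusted by
subtracting the initial (inoculation) mortality and the mean control death
count — DMSO and seawater controls are pooled by default since the protocol
does not distinguish them — floored at zero, and averaged across wells.
The mortality rate is `ln(dead_48h) / 48 h × 24 h`, i.e. `ln(count)/2` per
day. The log of a *count* (not a proportion) is intentional: it reproduces
the reported 0–2.25 d⁻¹ scale, and with ≤ 60 individuals per well bounds
rates by `ln(60)/2 ≈ 2.05`. Counts of 0 or 1 (and fractional adjusted means
below 1) map to rate 0; the 24 h counts are carried through the tables but,
as in the published rate definition, do not enter the rate.

## Multivariate profiling

Because quotas span orders of magnitude while rates live on `[0, 2]`, each
feature (per-variant quota, total quota, mortality rate) is min-max scaled
to `[0, 1]` (constant features map to 0) and then `ln(x + 1)` transformed.
Ordination is classical metric scaling (`stats::cmdscale`) of the pairwise
distance matrix — Euclidean by default, the conventional input for
classical scaling, under which PCoA scores coincide with centered PCA
scores; Bray–Curtis is available via vegan for users who prefer a
composition-oriented distance. Negative eigenvalues are truncated to zero
for percent-variability; clustering is complete-linkage `hclust` on the
positive-eigenvalue score matrix, cut at `k = 3` by default (the number of
main chemotype groups typically resolved; finer cuts are one config value
away). Cluster labels are renumbered by decreasing size so labelling is
deterministic.

## The synthetic-data generator

No raw data accompany the source study, so the package ships a generator
that is itself first-class, tested code. `make_spectrum()` emits exactly
the fragments the grammar implies for a variant spec, with the high-mass
carbonyl pair anchored at `(B − terminus, B − terminus − 58)` and the
low-mass pair one arm loss below — the layout that reproduces the observed
1506 → 1288/1230 and 862/804 series. When a spec has carbonyl pairs but no
terminus loss, the pair anchor offset is 230 Da, chosen to be inert under
every detector. Decoy peaks are placed uniformly but at least 2 Da from
every rule-consistent position (all diagnostic anchors, and ±58 Da of any
existing peak), which guarantees decoys can never satisfy a rule at the
0.5 Da tolerance — this is what makes the 100%-flag-recovery property a
theorem about the code rather than a statistical observation. Decoy
intensities sit below the 10% noise threshold so base-peak identity is
preserved.

`make_panel()` plants the study conditions: 54 strains in three equal
chemotype archetypes — a low-quota archetype (tens of fg cell⁻¹ of
AM20(S)/KAR-type markers) with deliberately broad toxicity, and two
high-quota archetypes with disjoint variant profiles and moderate and high
toxicity respectively, strain totals staying below the ~4700 fg cell⁻¹
observed maximum. Peak areas are obtained by inverting the calibration and
quota equations from the planted quotas and multiplying lognormal noise
(CV 0.25, a realistic triple-quadrupole area repeatability); assay deaths
are binomial in wells of 60 with archetype-specific death probabilities
(per-strain logit jitter, widest in archetype 1). The "known" variants in
the panel catalog use invented, grammar-valid precursor masses — their true
values are not public — and carry a `-syn` suffix to make that explicit.
With `area_cv = 0` the generator switches to expected counts and exact
areas, so zero-noise runs are fully deterministic and planted-structure
recovery (ARI = 1.0) is an exact check, not a lucky draw. All randomness
flows from the single config seed, recorded in the truth manifest.

What the generator does *not* emulate: chromatographic peak shapes and
integration, isotope envelopes, in-source fragmentation, matrix effects,
and retention-time drift. Passing tests therefore demonstrate correctness
of the interpretation, calibration and profiling logic under the stated
noise model — not robustness to raw-signal artifacts.

## Problem sizes used in the test-suite

Property suites use 500 random variant specs for grammar round-trips, 1000
random spectra for the screening oracle, 1000 simulated strains for the
assay Monte-Carlo, and 54-strain panels for clustering — sizes at which
each suite runs in seconds while leaving no realistic room for coincidental
passes.

## Known limitations

* The annotator assigns structural *evidence*, not structures; carbon
  positions and stereochemistry are out of scope (they require NMR).
* One-point calibration makes all quantities semi-quantitative LPD
  equivalents; per-variant response factors are unknown.
* The 11 unpublished NL channels and the historical transition library are
  placeholders until users supply laboratory values.
* `fs_screen()` consumes centroided peak lists, not raw traces; peak
  integration is upstream of this package.
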