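---
title: "Profiling IgG Fc/2 subunit proteoforms: models and methods"
author: "iggfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling IgG Fc/2 subunit proteoforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iggfc)
```

## The measurement this package models

IdeS proteolysis below the IgG hinge releases ~25 kDa single-chain Fc
fragments (Fc/2). Measured intact by reversed-phase LC coupled to a TOF
instrument, each Fc/2 species appears as a charge envelope (z ≈ 18–22 in
m/z 1000–1600) riding on a chromatographic peak. Because the analyte is the
intact subunit, one measurement simultaneously resolves:

* **allotypes** — inherited constant-region sequence variants (IMGT IGHG\*NN
  nomenclature; a diploid individual carries at most two per subclass, hence
  at most eight allotypes in total), separated both chromatographically and
  by backbone mass;
* **glycoforms** — the CH2 N-glycan (HxNyFzSw compositions), a ladder of
  ~130–360 Da mass steps on each backbone;
* **doubly glycosylated IgG3** — some IgG3 allotypes carry a second N-site in
  the CH3 domain (Asn392); occupied chains appear ~1.2–3.5 kDa above the
  singly glycosylated ladder;
* **additional PTMs** — incomplete C-terminal lysine clipping (+128.17 Da),
  C-terminal GK truncation (−185.22 Da), cysteinylation (+119.14 Da) and open
  CH2 disulfides (+2.016 Da, chromatographically shifted).

The pipeline quantifies these features in four IgG fractions per patient —
total and antigen-specific (ACPA) IgG, each from plasma and synovial fluid
(SF) — and compares fractions statistically. Everything runs equally on
simulated runs (the built-in generator) or on mzML files plus a run manifest.

## Mass bookkeeping

All assignment and deconvolution arithmetic uses **average masses**: at
resolving power 15000 the isotope envelope of a 25 kDa ion is unresolved, so
the observed peak centroid sits at the average mass. Monoisotopic residue
masses are kept only for bookkeeping. A species mass is strictly additive:

> backbone + CH2 glycan + CH3 glycan (if any) + PTM delta,

with glycan residue masses Hex 162.1406, HexNAc 203.1925, dHex 146.1412,
Neu5Ac 291.2546 Da (averages). Backbone masses come from a shipped reference
table; when a sequence is supplied instead, the backbone mass is computed
from standard average amino-acid masses with two closed disulfide bridges
(−2 × 2.016 Da). The shipped table
(`inst/extdata/allotype_reference_synthetic.tsv`) is **synthetic**: the
printed allotype set of the source field carries no public sequences at the
Fc/2 level, so the table's backbone masses were constructed to be realistic
(23.4–24.1 kDa, plausible within-subclass differences) while guaranteeing
that the glycoform ladders of allotypes absent from a sample stay ≥ 4 Da away
from every simulated species mass. Users with real allotype masses or
sequences substitute their own table.

Glycan classification follows the biantennary IgG Fc convention: the
Man3GlcNAc2 core accounts for H3N2, so a complex-type composition has
galactose count `min(2, H − 3)`; a fifth HexNAc is read as a bisecting
GlcNAc; any deoxyhexose as core fucose. Compositions with N = 2 and H ≥ 4 are
high-mannose; N ≤ 1 marks the chitobiose stub left by EndoS2 treatment
(supported by the classifier so EndoS2-treated data can be analysed, but not
simulated by default).

## The synthetic cohort

`cohort_config()` fixes the study conditions the generator emulates; these
defaults are the package's definition of a realistic cohort and are not
adjusted per analysis:

* subclass means IgG1/2/3/4 = 60/27/7/6 % with patient-level log-normal
  jitter; heterozygosity probability 0.6 per subclass; allotype ratios drawn
  from U(0.30, 0.70);
* a CH2 glycoform baseline centred on G0F/G1F/G2F with afucosylated,
  bisected, sialylated, high-mannose and non-glycosylated (0.5 %) species;
* fraction effects in the directions reported for RA cohorts: ACPA fractions
  multiply afucosylated species by 0.45, bisected by 0.55 and
  non-glycosylated by 0.40; SF fractions down-weight each galactose by 0.95
  (total) or 0.80 (ACPA) and each sialic acid by 0.92/0.75; ACPA allotype
  ratios shift by up to ±0.10;
* CH3 occupancy per IgG3 allotype and fraction drawn from U(0.07, 0.45), the
  range observed across patients; CH3 glycans dominated by high-mannose
  species, elevated ×1.4 in ACPA;
* C-terminal lysine only in SF (up to 1.6 % of the anchor pair in total IgG,
  up to 5.3 % in ACPA), GK truncation only in IgG4, open disulfides and
  cysteinylation at 0.5–2 %.

The renderer places each species as a Gaussian elution peak (σ = 3 s;
a sharp nano-RP protein peak) at its allotype's reference retention time,
with charge states 18–22 triangularly weighted around z = 20 and m/z peaks of
FWHM = m/z/15000 on a uniform 0.02 m/z grid (profile mode, 3 s scans).
Open-disulfide species elute +15 s after their parent, which at σ = 3 s
makes the +2 Da variant chromatographically separable — in m/z the shift
(+0.1 m/z at z = 20) is unresolvable. Noise is additive Gaussian (sd 20) on
a constant detector baseline (60): keeping the baseline above ~3 noise SD
means the detector's non-negativity almost never truncates the noise, so
weak species (0.3 % non-glycosylated IgG) remain unbiased; the Tophat stage
removes the baseline exactly as it would on a real instrument. A global
retention-time shift per run (U(−6, 6) s) exercises the alignment stage. One
master seed determines every draw; identical seeds give byte-identical runs.

What the generator deliberately does **not** emulate: isotope fine structure
(peaks are single Gaussians at the average mass), charge-state-dependent
adducts, electrospray ionisation efficiency differences between glycoforms,
tailing peak shapes, retention drift within a run, and correlated (chemical)
noise. Passing recovery tests therefore demonstrate correctness of the
quantification arithmetic under the stated signal model, not robustness to
every instrumental artefact of real data.

## Preprocessing and deconvolution

Two processing paths coexist, as in the original workflow where vendor
software deconvoluted the raw data while an OpenMS/Skyline chain handled
EIC quantification:

* **EIC path** — per-scan Gaussian smoothing, then Tophat baseline
  subtraction (morphological opening, structuring element 1.0 m/z), then
  extracted ion chromatograms. The generic `smooth_spectrum()` default width
  is m/z 1.0, appropriate for broad low-resolution profiles; the *pipeline*
  default is 0.2 m/z because at FWHM ≈ 0.085 m/z peaks a 1.0 m/z kernel
  merges the cysteinylation (+119.14 Da) and +K (+128.17 Da) signals, which
  are only 0.45 m/z apart at z = 20 (kernel σ of 0.42 m/z leaves ≈ 57 % of a
  neighbour's apex inside the window; at 0.2 m/z the cross-talk is nil).
* **Deconvolution path** — scans summed over a retention-time window, Tophat
  on the summed spectrum, then zero-charge transformation on a 1.0 Da mass
  grid: the intensity at candidate mass M combines the interpolated reads at
  (M + z·1.00728)/z across charges. The default combine is plain summation.
  The pipeline instead uses the **charge-consensus median**: each charge
  channel is first normalised by its expected peak height (envelope weight
  divided by m/z — at constant resolving power the m/z peak narrows, and the
  apex grows, with charge), making clean channels exchangeable; the median
  then ignores up to two contaminated channels. This suppresses
  charge-misassignment images (a z = 21 peak read as z = 22 appears at
  M·22/21 in exactly one channel) which the summation rule promotes to
  spurious peaks — one such image falls within 1 Da of the doubly
  glycosylated anchor glycoform and would otherwise bias occupancy by ≈ 10 %.
  Peaks are 3-point local maxima (plateau ties to the lower mass) above
  median + 5 MAD with a 0.1 %-of-maximum floor; reported peak intensity is
  the grid sum within ±2 Da ("sum-peak" style), which is insensitive to
  sub-grid apex position.

Retention-time alignment fits a piecewise-linear warp through the apexes of
anchor species (the G0F glycoforms of the first- and last-eluting called
allotypes) against their reference times, extended as a constant shift
outside the anchor range; runs whose anchors are undetected are flagged and
left unwarped.

## Quantification

Allotypes are identified by intact mass matching: an allotype is called when
at least two of its expected G0F/G1F/G2F glycoform masses match picked peaks
within 2.0 Da (a single matching mass is never enough — the glycoform ladder
is the evidence), with at most the two best-supported allotypes per subclass.
The pipeline deconvolves one retention-time segment per reference allotype
(±15 s around its reference apex, wide enough for ±6 s run-to-run shifts
while excluding neighbours ≥ 30 s away), so mass evidence can only come from
co-eluting signal.

Each quantified species gets an EIC summed over the three consecutive charge
states with maximal envelope weight inside the m/z window (fixed per
allotype so its glycoform profile is internally consistent), with m/z borders
± 2 × FWHM (FWHM = m/z/15000; the window multiplier is the `w` knob).
Areas are trapezoidal over ±9 s (3 elution σ) around the allotype apex, after
subtracting the median EIC level of flanking regions — the constant
background that survives spectrum-level baseline subtraction. Open-disulfide
species are integrated in [+9 s, +27 s] so that spill-over between the
parent (σ = 3 s) and the +15 s offset species is below 0.2 %.

Derived quantities:

* **glycoform profiles** per allotype: areas of the CH2 glycoforms and the
  non-glycosylated backbone normalised to 100 % (PTM species excluded from
  the denominator but included in allotype totals, so trait values remain
  comparable to glycan-only reports);
* **subclass profiles**: allotype profiles averaged with allotype total
  intensities as weights;
* **allotype ratios**: first/total of the summed intensities of all
  identified glycoforms;
* **CH3 occupancy**: the doubly glycosylated anchor glycoform
  (CH2 = H3N4F1, CH3 = H5N2; isolated by > 8 Da from every other CH2 × CH3
  combination) is quantified by EIC; its area divided by its relative
  abundance among all doubly glycosylated glycoforms (from the deconvolved
  doubly glycosylated region, b + 2300…3600 Da, integrated over the union of
  expected combination windows so that combinations below the picking
  threshold still count) gives the total doubly glycosylated area, which is
  compared with the combined singly glycosylated area. The intact-molecule
  view assumes independent heavy-chain pairing: a per-chain occupancy p
  implies 1 − (1 − p)² of intact IgG3 carry at least one CH3 glycan, so the
  observed per-chain range 13.7–24.1 % maps to 25.5–42.4 %;
* **PTM levels**: modified/(modified + unmodified) of the H3N4F1 anchor pair
  (bounded percentages; the plain modified/unmodified ratio is available via
  `bounded = FALSE`);
* **traits**: galactosylation and sialylation as weighted sums with
  doubly galactosylated (sialylated) species counted twice, divided by two;
  afucosylation, bisection and agalactosylation as complex-type shares.
  Complex-type traits use the complex-type repertoire as denominator;
  high-mannose and non-glycosylated levels are shares of the full species
  total, matching the separated reporting of these features.

## Statistics

The statistical layer mirrors the source workflow: PCA on fraction features
with missing values imputed by the minimum positive number (0.01), columns
standardised, and either per-patient centering (within-patient differences
between the four fractions) or per-patient concatenation of the four
fractions; two-sided paired t-tests on complete cases; Šídák adjustment
1 − (1 − p)^k for predefined comparison families; Spearman correlations with
clinical parameters using pairwise deletion, with cells based on fewer than
four complete pairs flagged unavailable. Mixed-effects models used in parts
of the source workflow are deliberately replaced by complete-case paired
tests plus Šídák: on complete data the estimand (within-patient contrasts)
is the same, and the simpler model is exactly reproducible. The ambiguity in
"differences within each patient used as input" for the fraction PCA is
resolved by offering both modes; per-patient centering is the pipeline
default, neither is asserted to be the original choice.

## Numerical choices and degenerate inputs

* Deconvolution grid 1.0 Da; allotype-call tolerance 2.0 Da and annotation
  tolerance 1.5 Da (grid step plus calibration slack — both config knobs);
  peak picking threshold median + 5 MAD (a declared stand-in, the original
  picking threshold is not public).
* Combinatorial annotation of doubly glycosylated masses reports *all*
  candidate pairs within tolerance ranked by |Δmass|, never collapsing
  isobars — the site swap of two compositions is always co-reported, and a
  miss reports the nearest enumerated pair.
* Empty profiles give all-NA traits; a zero anchor gives NA occupancy and NA
  PTM levels; zero-variance paired differences are flagged degenerate unless
  they are exactly zero (t = 0, p = 1); paired tests drop NA pairs;
  deconvolution of an empty retention-time range returns an empty peak list.
* Peak-picking plateau ties go to the lower mass, making picking
  deterministic.

## Problem sizes

The bundled validation (`scripts/acceptance.R`, mirrored by the acceptance
test) simulates 20 patients × 4 fractions at the full acquisition geometry
(30 001 m/z points × 241 scans per run), processes all 80 runs end to end,
and compares against the generator's ground truth, which is computed by the
same trait formulas from the sampled distributions — so the reported errors
isolate measurement and quantification error. Typical results: glycoform
proportions recovered to well under 1 percentage point median absolute
error, CH3 occupancy to ≈ 0.01 across the 0.07–0.45 range, allotype ratios
to < 0.01, and a clearly positive total-vs-ACPA silhouette in the fraction
PCA.

## Known limitations

* Average-mass arithmetic breaks down if a user supplies resolutions high
  enough to resolve isotopes; the deconvolver has no isotope model.
* The charge-consensus median assumes an approximately known envelope shape;
  envelopes far from the configured weights degrade its height
  normalisation (the summation combine is unaffected and remains available).
* Open-disulfide quantification relies on chromatographic separation; peak
  widths much above σ ≈ 4 s would re-merge the +2 Da species with its parent.
* The allotype caller requires the reference table to contain the sample's
  allotypes; it reports ambiguity for backbone masses within tolerance but
  cannot distinguish true isobars.
* No cross-run normalisation beyond relative abundances; no absolute
  quantification.
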