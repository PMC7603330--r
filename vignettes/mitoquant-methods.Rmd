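---
title: "Methods behind mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

`mitoquant` re-implements, as tested tidyverse-style functions, the
quantitative procedures used to characterise a 70-nt mitochondrial-DNA-encoded
non-coding RNA in alveolar epithelial type II (AETII) cells and the
physiological readouts that accompany it: airspace morphometry, per-cell in
situ hybridisation (ISH) scoring, linescan colocalization, ¹³C isotopomer
flux, extracellular-flux bioenergetics, small-RNA mapping to the circular
mitochondrial genome, and qPCR relative quantification. Every stage is paired
with a seeded synthetic-data generator whose ground truth makes parameter
recovery testable without any raw microscopy, spectrometry or sequencing
files.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical shape* of each laboratory readout,
not its physics:

* **Parenchyma masks** (`make_parenchyma_mask()`) are unions of discs and
  ellipses on a tissue background, optionally speckled with small debris and
  pinholes. Real Gill-stained sections have irregular, connected airspace
  networks; discs are used because parallel-line chord sampling of a disc has
  the closed form mean chord $= \pi r / 2$, giving an analytic oracle. Tests
  passing on discs validate the chord extraction algorithm, not the
  segmentation of real histology (which is upstream of this package).
* **Cell fields** (`make_cell_field()`) draw per-cell dot counts from a
  Poisson law at the type-specific rate. The source material reports only
  mean ± sd of dots per cell; Poisson is the natural first model for counts
  of discrete spots. Overdispersed (negative-binomial) fields are a possible
  extension; the scoring functions are agnostic to the generating law.
* **OCR traces** (`make_ocr_trace()`) add Gaussian instrument noise to four
  phase means in the canonical injection order (basal → oligomycin → FCCP →
  rotenone/antimycin A), three readings per phase by default, matching the
  mito stress test layout.
* **Isotopomer panels** (`make_isotopomer_panel()`) place each product's
  labeled fraction (true fractional flux × precursor enrichment) in its fully
  labeled mass bin and perturb intensities with mean-one multiplicative
  log-normal noise of configurable CV — the conventional model for
  multiplicative detector noise. Real spectra distribute label across many
  isotopomers; since the enrichment statistic only divides labeled by total
  signal, the single-bin simplification does not change what it tests.
* **Read sets** (`make_reads()`) draw mostly full-length (80% by default)
  copies of the light-strand transcript at coordinates 16,188–16,119 with
  per-base substitution errors, plus random off-target reads of 15–100 nt.
  The dominance of full-length reads mirrors a discrete small-RNA species;
  the default fraction is a modelling choice, and the modal tabulated length
  is insensitive to it until sub-reads dominate. The reference is *synthetic
  random DNA* of the mouse mitochondrial genome length (16,299 nt) — the real
  sequence is not bundled, so coordinate arithmetic is exercised without any
  download; files derived from it are labelled synthetic.
* **Ct tables** (`make_ct_table()`) encode a true fold change as a target-Ct
  shift of $-\log_2(\text{fold})$ in the treated group.

All generators draw their randomness from one explicit `seed` argument
(`withr::local_seed()`; no global state), and attach a `ground_truth()`
tibble. Same seed ⇒ bit-identical output.

## Morphometry

The mean alveolar chord length (CL) estimator overlays one-pixel-wide
horizontal and vertical sampling lines on the binarised mask and measures
every maximal run of airspace pixels as one chord (its pixel count is its
length); runs touching the image border are excluded because their true
length is censored by the field of view. Horizontal and vertical chords are
pooled into one distribution; per-image descriptive statistics and a pooled
batch mean are reported, the batch mean being the sample-level CL.

Choices the published description leaves open, decided here:

* **Grid pitch.** The source describes one-pixel-wide grids but not their
  spacing; the default samples every row and column (`spacing = 1`),
  maximising data use deterministically. The pitch is configurable.
* **Cleaning thresholds.** Debris/hole removal is connected-component based
  (8-connectivity, via EBImage): tissue objects smaller than `min_debris_px`
  become airspace, airspace objects smaller than `min_hole_px` become
  tissue. The published macro's thresholds are unstated; the defaults (64 px
  each) are this package's declaration, not an inference.
* **Vessels and airways** are an input responsibility: the functions accept
  an exclusion mask (treated as tissue) rather than editing pixels.

On a centred disc of radius 100 px the pooled mean chord agrees with
$\pi r/2$ within 3% (pixelisation tolerance); chord multisets are invariant
under interior translation, and enlarging airspace strictly increases mean
CL — the direction that distinguishes emphysematous from sham lungs.

## ISH scoring

For each field, the total nucleus count $T$ and the surfactant-B-positive
count $S$ partition cells into AETII ($S$) and non-AETII ($T-S$). Dots are
assigned to the nearest nucleus within `max_radius` (default 10 µm, the
order of an alveolar cell radius; ties go to the lower nucleus index). The
AETII mean is AETII dots / $S$; the non-AETII mean is the pooled remainder
(assigned dots − AETII dots) / $(T-S)$, exactly the printed formula. Dots
beyond the radius stay unassigned and enter no average — whether the manual
procedure counted such dots is unknowable, so the conservative choice is
declared rather than hidden.

The 4-tier score is: 0 = no spots; 3 = more than 10 spots/cell; 2 = moderate
(more than `few_cutoff`, at most 10); 1 = few (positive, at most
`few_cutoff`). Two boundary decisions are this package's: a mean of exactly
10 is *moderate* (tier 3 stays strictly ">10"), and the "few"/"moderate"
boundary — absent from the published rule — defaults to 3 dots/cell,
configurable; the published worked examples (10.7 → 3, 2.15 → 1) hold under
the default. Fractional means are never rounded before scoring.

## Linescan colocalization

`extract_linescan()` samples intensity at unit steps along a segment,
averaging over `width` pixels (default 4) perpendicular to it — averaging,
not summation, so the profile does not scale with the width — with bilinear
interpolation off-grid. The published classification of RNA/marker overlap is
visual; the quantitative rule here is declared in the output: supports are
full-width-at-half-maximum (FWHM) intervals of the background-subtracted
peaks (background = 10th percentile of the profile), and a pair is
*complete* if the peak offset is ≤ `epsilon` (0.25 µm) and mutual FWHM
overlap ≥ `theta` (0.8); *engulfed* if ≥ `theta` of the RNA FWHM lies in a
strictly wider marker FWHM; *partial* for any remaining positive overlap;
*none* otherwise. Dot diameter is the FWHM (2.355 σ for a Gaussian spot).
The call is invariant to joint translation and to positive intensity
scaling. No frequency target is asserted for the three relationships: the
source reports them only as "predominantly equal".

## Isotopomer flux

Enrichment is the labeled share of total isotopomer signal; for glucose
(monitored as M0–M5 on its derivative fragment) the labeled set is the M5
bin. Fractional flux is MPE(product)/MPE(precursor); absolute flux is
fractional flux × pool size, with pool size the metabolite-to-internal-
standard signal ratio. Which isotopomers count as labeled for multi-carbon
metabolites is not fixed by the phrase "in the same manner as for glucose";
`labeled_sets` is therefore an explicit per-metabolite parameter defaulting
to all M ≥ 1. Natural-abundance ¹³C correction (binomial deconvolution of
the carbon skeleton) is available but **off** by default — the printed
formulas operate on uncorrected intensities. Fractional flux above 1 warns
rather than errors, since noise can produce it. No numeric target is set on
the published absolute rates (40 vs 0.4 µmol/day): their pool-size
calibration is not reconstructible.

## Bioenergetics

With $\overline{x}_p$ the mean of the first $k$ (default 3) readings of
phase $p$ and $nm$ the mean of the *last* $k$ post-rotenone/antimycin
readings: basal $= \overline{x}_{basal} - nm$; proton leak
$= \overline{x}_{oligo} - nm$; ATP production $=$ basal $-$ leak; maximal
$= \overline{x}_{FCCP} - nm$; spare capacity $=$ maximal $-$ basal. "Last 3
readings" is read as the last $k$ post-rotenone/antimycin readings in every
formula — the only interpretation that makes all four formulas
self-consistent. Coupling efficiency is implemented exactly as the source
prints it, $100 \times$ ATP / non-mitochondrial respiration, although the
conventional definition divides by basal respiration; both are exposed via
`coupling_definition`, defaulting to the printed form, and the discrepancy
is intentional fidelity. Protein normalisation divides rates after
differencing (mathematically identical to dividing before, for constant
per-well protein). The identities ATP + leak = basal and spare = maximal −
basal hold to machine precision by construction, and are asserted as such.

## Small-RNA mapping

Reads are locally aligned against both strands of the doubled target region
(default 16,116–16,210) with BLASTN-like scoring (match +1, mismatch −2,
gap −2.5); doubling realises circular hits, and coordinates are folded back
onto the 16,299-nt circle. A score threshold (default 15, roughly a 15-nt
exact match) stands in for an e-value cutoff at region scale; the published
word size and exact scoring are unstated, so the defaults are declared as
defaults, and no result depends on score values. The alignment engine is
`Biostrings::pairwiseAlignment()`; the filter chain around it — duplicate
removal, highest-identity best hit with deterministic tie-breaks (longer
alignment, lower start, `+` before `−`), orientation onto the plus strand,
and alignment-length tabulation — is the package's own implementation and is
cross-checked in the tests against a brute-force Smith–Waterman circular
scan and an exhaustive enumeration of the best-hit rule.

`interval_length()` measures intervals in the light-strand (descending)
direction with origin wrap: (16,188, 16,119) → 70 nt. `uniqueness_scan()`
returns the *shortest* query prefix with no exact occurrence (either strand)
in a toy genome set — the quantity behind "the first 29 bp are unique" — and
0 when the whole query occurs; genome-scale homology screening is out of
scope.

## qPCR quantification

`ddct_fold()` follows the Livak procedure: per-sample ΔCt = target −
reference, group-averaged ΔCt before differencing, fold $= 2^{-\Delta\Delta
Ct}$. Folds below 1 are reported as fractions with a separate direction
annotation. `copy_number_ratio()` normalises the mitochondrial-to-nuclear
ratio to a control of 1. `fold_change_filter()` applies thresholds
symmetrically on $|\log_2$ fold$|$ (whether the published ≥1.7-fold filter
was applied on raw or log scale is unstated; the symmetric log-scale rule is
used so reciprocal folds filter identically).

## Problem sizes and numerical choices

The test suite exercises: disc masks up to 320² px; cell fields of ~1,200
cells; 1,000-seed flux and OCR recovery loops; 10,000-read mapping runs;
brute-force alignment oracles on ≤60-nt circles. These sizes were chosen so
each statistical check has adequate power (recovery is asserted within 3
standard errors) while the whole suite runs in about a minute. Ties are
broken deterministically everywhere (lowest index, lowest coordinate, `+`
strand first); degenerate inputs (all-tissue masks, S = 0 or T = S fields,
all-zero intensity vectors, unlabeled precursors, flat profiles, empty read
sets) raise typed errors or flagged `none` calls rather than propagating
NaN.

## Known limitations

* No segmentation: masks, nuclei, dot positions and profiles are assumed
  already extracted from images.
* The synthetic reference is random DNA; identity-based conclusions about
  the real mitochondrial genome (e.g. true nuclear homology) cannot be drawn
  from it.
* Chromatogram integration, adapter trimming, amplification-efficiency
  correction and 3D colocalization coefficients are out of scope.
* Passing recovery tests on Poisson/Gaussian/log-normal synthetic data shows
  the estimators are correct under those models, not that real data meet the
  models' assumptions.
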