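---
title: "An integrated PFAS suspect-screening, semi-quantification and risk-prioritization workflow"
author: "fluorscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated PFAS suspect-screening, semi-quantification and risk-prioritization workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorscreen)
```

## The problem

Routine monitoring of per- and polyfluoroalkyl substances (PFAS) in
surface waters is limited to the few dozen compounds for which authentic
analytical standards exist, while thousands of structurally related
fluorochemicals are in use. High-resolution mass spectrometry (HRMS)
suspect screening closes part of this gap: features extracted from
full-scan negative-electrospray data are matched against curated suspect
lists by accurate mass, supported by isotope patterns, diagnostic MS2
fragments and mass-defect analytics, and graded into identification
confidence levels. Compounds identified this way can then be
semi-quantified with surrogate response factors, screened against
toxicity-weighted environmental quality standards (EQS), and ranked by a
hazard-times-exposure risk index.

`fluorscreen` implements this complete chain as composable, tested R
functions, together with a synthetic-data generator that emulates a
paired river survey with known ground truth, so that every stage can be
validated end to end.

## Study design emulated by the generator

The generator encodes a 24-sample paired survey: 12 settlements over
five water bodies (six on a large river, three on a canal system, one
each on three further rivers), each sampled once upstream (odd site
numbers) and once downstream (even). The compound roster holds ten
targets quantified with authentic standards (C4--C9 perfluorocarboxylates
and perfluorosulfonates plus a fluorotelomer sulfonate) and ten
suspect-screening compounds: the ultra-short-chain acids TFA, PFPrA and
TFMS, the ether acid ADONA, two hydrogen-substituted acids and four
fluorinated pesticides. Key design choices:

* **Concentration noise** is lognormal with a 30% coefficient of
  variation around each compound mean. Environmental concentration data
  are positive and right-skewed; no distribution is prescribed by survey
  reports, so this is a generator parameter, not a claim about any real
  study. Inter-site variance is likewise a free parameter.
* **Detection** is Bernoulli per compound and sample, with detection
  probabilities spanning ~17% to 100%, mirroring the detection-frequency
  range seen in this kind of survey.
* **A dominant compound** (the TFA analogue) is configured with a mean
  concentration two orders of magnitude above the others — a
  `dominant` flag validated to sit at least 100x the median of the
  rest — because ultra-short-chain acids dominate real surface-water
  PFAS burdens.
* **Ions**: all planted PFAS appear exclusively as singly charged
  [M−H]⁻ ions (negative electrospray); the ion mass convention is
  neutral monoisotopic mass − 1.007276 Da (one proton). Fragment anions
  carry one extra electron over their atom sum. Fixing the charge-carrier
  convention is what makes ppm-level tests meaningful.
* **Peak response** follows the isotope-dilution model
  `area = conc/conc_IS × area_IS × RRF` with unit response factors, and
  S/N scales linearly with concentration anchored at S/N = 10 for
  0.1 ng/L. Linear S/N scaling is an explicit assumption, used again by
  the MQL estimator.
* **Interferents**: non-fluorinated decoys are drawn with positive mass
  defects and rejected unless their CF2 Kendrick mass defect stays at
  least 0.004 Da away from every previously planted feature, so they can
  neither match a suspect at 5 ppm nor link into a homologous series at
  the 0.002 Da KMD tolerance; blank-borne background compounds are
  planted in every sample and in the procedural blanks at one third of
  the sample intensity, i.e. below the ratio-of-5 blank-subtraction
  threshold.

What the generator does **not** emulate: chromatographic peak shapes,
retention-time drift between batches, matrix effects, ionization
suppression, isotopologue peaks in the feature tables, or correlated
noise between compounds. Passing tests therefore demonstrate the
correctness of the algorithms under the stated noise model, not
instrument-level robustness on real raw data.

## Mass-defect analytics

The standard mass defect is `m − round(m)` constrained to [−0.5, 0.5)
(half-up rounding). Kendrick masses rescale by nominal/exact base-unit
mass — 50/49.9968066 for CF2, 14/14.0156500 for CH2 — and the Kendrick
mass defect (KMD) is `round(KM) − KM`; the sign convention is arbitrary
in the literature, so it is fixed and documented here. CF2 homologues
share KMD exactly, which the test suite verifies to 1e-6 Da.

Homologous-series detection links features whose KMDs agree within
0.002 Da and whose mass differences are integer multiples (1--10 units;
the cap reflects the C4--C14 span of typical target lists) of the exact
repeat-unit mass within 5 ppm, then reports connected sets of two or
more. The implementation is union-find over pairwise links; the tests
compare it against an independent O(n³) matrix-closure oracle.

Formula enumeration searches element counts exhaustively (heaviest
element first, with mass-bound pruning) for candidates within a ppm
window of the deprotonated ion mass, then applies documented heuristic
filters: ring-double-bond equivalents ≥ 0, F ≤ 2C+1 and an acyclic
valence bound. These filters are declared approximations of the
PFAS-favouring heuristics used by commercial software, whose exact rules
are proprietary; they are configurable via the `rules` argument.

## Screening and confidence levels

Cross-sample grouping is transitive closure at 0.2 min and 5 ppm. The
full adaptive-curve chromatographic alignment of vendor software is
deliberately out of scope; with the generator's 0.02 min RT jitter the
simple tolerance grouping is exact, and this is a documented deviation
from what vendor pipelines do on real data. Blank subtraction removes a
group when its maximum sample area is at most 5 times the maximum
matched blank area ("at most": the boundary ratio of exactly 5 is
removed), using the same tolerances as grouping (the matching tolerance
for blanks is not separately prescribed anywhere, so reusing the
grouping tolerances is the least surprising choice).

Evidence per candidate annotation comprises: accurate-mass match
(±5 ppm), unequivocal formula (the suspect's formula recovered by
enumeration), curated-library MS2 membership, diagnostic-fragment or
neutral-loss hits (±10 ppm at MS2 — looser than the precursor tolerance
because fragment spectra are acquired at lower resolving power), and
retention-time agreement with an authentic standard (±0.1 min). The
decision table maps evidence to levels L1--L5; L1 additionally requires
MS2 evidence on top of the RT match, following the convention that a
confirmed identification needs mass, retention time *and* fragmentation.
Only levels 1--3 are retained for interpretation. When several suspects
match one group, all candidates are kept and ranked by absolute ppm
error.

The isotope-pattern score is a declared surrogate for the undisclosed
vendor similarity score: theoretical aggregated-isotopologue envelopes
are computed by convolving per-element isotope distributions, observed
peaks are matched at 10 ppm, intensity deviations within ±30% score
zero and the excess is rescaled, and `100 × (1 − mean deviation)` is
compared against the conventional 80% acceptance threshold. Missing
expected peaks above 5% relative abundance count as full deviation.

## Quantification

Relative response factors are the slope of the origin-constrained
least-squares fit of area ratio against concentration ratio. Calibration
weighting schemes are out of scope; a consequence, verified by
Monte-Carlo in the tests, is that with 5% multiplicative area noise and
a two-decade level design the fitted RRF is unbiased in the median but
individual fits carry a ~3% median relative error, dominated by the top
level. Propagated to concentrations with 5% sample-area noise the
median relative error stays well below 10%.

Surrogate assignment for compounds without standards minimizes RT
distance, breaking ties by subclass and then by neutral-mass distance,
and logs the distances of the choice. QC gating follows the stated
boundary conventions literally: S/N must be *greater than* 3, the
qualifier-to-quantifier ion-ratio uncertainty *below* 30%, and the RT
deviation *within* ±0.1 min (inclusive) — the RT gate applying only to
targets with authentic standards. MQLs extrapolate each accepted record
to the concentration producing S/N = 10 and take the per-compound
minimum.

## EQS compliance and risk prioritization

Per-sample PFAS sums use lower-bound aggregation (non-detects and
below-MQL records contribute zero). PFOA equivalents multiply each
concentration by a relative potency factor (RPF; PFOA ≡ 1) and are
compared — strictly, a value exactly at a standard does not exceed it —
against the proposed 4.4 ng/L group EQS, and PFOS against its 0.65 ng/L
annual-average and 36000 ng/L maximum-allowable EQS. The bundled RPF
table is an explicitly editable placeholder set modeled on published
equivalency proposals, not measured study values. Per-river summaries
average over samples (not settlements), report the sample standard
deviation, and round only at presentation (3 significant figures).
Including semi-quantified compounds such as TFA in an extended
PFOA-equivalent sum is an option (`includeSsa`), mirroring two-tier
reporting practice.

The hazard side uses 18 QSAR-derived attributes in four groups
(3 persistence, 2 bioaccumulation, 3 ecotoxicity, 10 human health; the
human-endpoint count of 10 is the only value under which the printed
group weights 1/9, 1/6, 1/18, 1/60 sum to one — an inference the test
suite checks in exact rational arithmetic). Attributes are min-max
normalized after direction alignment (biodegradation probabilities are
reflected; every other attribute is oriented so larger = more
hazardous, with the orientation held in an explicit, user-editable
schema); a constant attribute normalizes to zeros rather than NaN.
ToxPi is the plain weighted sum of the normalized attributes — not the
slice-rescaled variant of the original ToxPi software — because that is
how the weighting is stated in the prioritization frameworks this module
follows. Exposure is detection frequency (a fraction in [0, 1]; the
percent-vs-fraction choice is inert because the subsequent min-max
normalization removes the scale) times the normalized maximum
concentration, and the risk index RI = ToxPi × normalized exposure is
binned at 0.1/0.01/0.001 with boundaries belonging to the lower
category.

A structural property of this framework, reproduced as a regression
test: an abundant, always-detected, low-ToxPi compound (the TFA
analogue) outranks rarer compounds with much higher ToxPi, because the
exposure term is concentration-driven.

## Paired statistics

Downstream − upstream differences per settlement (non-detects as zero)
are tested per compound with the Wilcoxon signed-rank test, two-sided
(the direction of a settlement effect is not prespecified). Zero
differences are dropped by default (classical convention; Pratt
handling is available by flag). For n ≤ 25 the p-value is exact even
under ties: midranks are doubled to integers and the null distribution
of the rank sum over all 2^n sign assignments is built by
generating-function convolution, which the tests verify against explicit
2^n enumeration. Above that, the tie-corrected normal approximation is
used. Normality of the differences is reported via Shapiro--Wilk, and
p-values are adjusted with Benjamini--Hochberg step-up FDR (the standard
choice where only "an FDR procedure" is conventionally required).
Settlements are pooled across rivers rather than tested per river — the
paired design is per settlement, and per-river subgroups of one or three
pairs would be untestable.

Under the null generator (no planted settlement effect) the
FDR-significant fraction over repeated simulated studies stays within
0.05 plus three binomial standard errors; a single study can still flag
a compound by chance (twelve concordant signs occur at p = 2/4096), so
no assertion is made per draw.

## Worked example

```{r example}
design <- defaultStudyDesign(seed = 1)
study <- simulateStudy(design)
study$experiment

scr <- screenStudy(study$features, study$blanks, study$suspects,
                   study$spectra)
table(scr$annotations$confidence)

eqs <- eqsScreen(study$experiment)
sum(eqs$exceeds_group_eqs)

head(prioritizeRisk(study$experiment, study$hazard), 3)
```

## Numerical choices and problem sizes

Degenerate inputs never produce NaN: constant attributes and zero-range
magnitudes/exposures normalize to zero with a warning; all-zero
difference vectors report NA; empty blank tables retain everything. The
test suite runs the full 24-sample study for recovery checks, 200
Monte-Carlo seeds for calibration/quantification error, 500 simulated
studies for the null calibration of the statistics stage, and 1000
replicate draws for the detection-frequency convergence check — sizes
chosen to make the binomial control bands tight enough to be
informative.

## Known limitations

* Feature extraction from vendor raw data, peak deconvolution and
  adaptive chromatographic alignment are out of scope; the pipeline
  starts from feature tables.
* The isotope-pattern score and the formula-assignment heuristics are
  declared surrogates for proprietary vendor algorithms.
* Matrix-effect and recovery corrections, calibration weighting and
  isotope fine structure are not modeled.
* RPFs and hazard attributes are user-supplied inputs; the bundled
  tables are placeholders for demonstration and testing.
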