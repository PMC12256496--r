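---
title: "Methods: bioactivity-exposure risk evaluation for DART"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioactivity-exposure risk evaluation for DART}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartnam)
```

## Overview

`dartnam` implements the quantitative core of an exposure-led, tiered,
animal-free risk assessment for developmental and reproductive toxicity
(DART). The organizing quantity is the bioactivity:exposure ratio

$$\mathrm{BER} = \frac{\min \mathrm{PoD}}{C_{max}},$$

the lowest concentration at which any assay platform detects biological
perturbation (the minimum point of departure, in µM) divided by the
estimated maximum plasma concentration for a specific exposure scenario.
A BER at or below 1 flags the scenario as *uncertain risk* (bioactivity is
expected at the estimated exposure and a higher-tier evaluation is
triggered); a BER above 1 is called *low risk*. The boundary is inclusive
(`ber(1, 1)` is uncertain risk): where the narrative convention is
ambiguous between "below 1" and "1 or below", the package takes the more
protective reading, and the threshold is an argument.

Performance against a labelled benchmark suite is summarized by
*protectiveness* (percentage of high-risk scenarios called uncertain risk)
and *utility* (percentage of low-risk scenarios called low risk).
Scenarios with an uncertain benchmark label enter neither metric.

## In-silico evaluation

Binary hazard calls per chemical and model are tallied into TP/FN/TN/FP
against truth labels. Three conventions matter and are fixed here:

* chemicals with unknown truth are dropped before tallying (they are not
  part of the labelled benchmark);
* `not_predicted` is a first-class call: it stays in the labelled total
  (reducing coverage) but enters no confusion cell, and is never imputed
  to non-toxic;
* accuracy is computed over evaluable calls, coverage is the evaluable
  fraction of the labelled set, and balanced accuracy is the mean of the
  *unrounded* sensitivity and specificity. Metrics are stored unrounded
  and rounded only at presentation; this is what makes the second decimal
  of the balanced-accuracy column reproducible.

Undefined metrics (e.g. sensitivity with no positives) are `NA`, never 0.

## Pharmacokinetic harmonization and population variability

Literature PK records are heterogeneous. Each record is reduced to a
(mean, SD) pair with a fixed precedence: reported SD, then
$SEM\sqrt{N}$, then $\mathrm{range}/6$ (three SDs either side of the mean
cover 99.7% of a normal). A missing mean is taken as the range midpoint
$(\max+\min)/2$; a literal half-range mode
(`mean_from_range = "compat_half_range"`) is kept only for compatibility
with workflows that print that formula, since a mean cannot lie below the
range minimum. External doses are converted to mg/day assuming a 70 kg
body weight or 1.7 m² body surface area; concentrations are converted to
µM by the molecular weight of the desalted, undissociated species.

Each study then yields a concentration-dose ratio (CDR, µM per mg/day);
SDs scale linearly with the dose. Studies are pooled per chemical and
population with N-weighting:

$$\bar x_{tot} = \frac{\sum \bar x_i N_i}{N_{tot}}, \qquad
SD_{tot} = \sqrt{\frac{\sum (N_i-1)SD_i^2 +
\sum N_i(\bar x_i-\bar x_{tot})^2}{N_{tot}-1}}.$$

This is exactly the SD of the raw pooled sample reconstructed to have the
per-study means and SDs, and the tests verify it against that oracle at
1e-9. Studies lacking any SD information feed the mean but are excluded
from the SD sum; records without a defined external dose (typical of
biomonitoring) are excluded from CDR with a reason code.

The toxicokinetic variability factor is
$\mathrm{TKVF}_{95} = p_{95}/\bar x_{tot} = 1 + z\,CV$ with $z = 1.64$
exactly (configurable; the difference to 1.6449 is below the precision of
anything downstream). Population contrasts report the fold difference of
weighted means plus a Welch-style two-sample z-test built from the
weighted summaries. The benchmark analysis this emulates does not name
its test; the Welch z is a documented package choice, isolated in
`compare_populations()`, and p-values are suppressed (with a flag)
whenever either group has fewer than 10 subjects.

## Concentration-response points of departure

**Two-phase profiling screen.** A target is followed up only when the
single-concentration screen shows more than 50% (strictly) inhibition or
stimulation of the maximal reference response. Follow-up curves are fit
with a Bayesian Hill model: log-normal prior on the IC50 centred at the
median tested concentration (sdlog 1), normal prior on the slope centred
at 1 (sd 0.5), low/high responses held near 0% and 100% by tight normal
priors (sd 2), Gaussian likelihood with a weak normal prior on the log
residual SD and a floor on the residual SD at 0.2% of the observed
response range, which keeps the likelihood proper (and the sampler
mobile) on noise-free curves without affecting real data. The stated convention fixes only the prior centres; the
"0% and 100%" levels are treated as near-fixed rather than free, which
reproduces the centres while letting small assay offsets through. The
sampler is an in-package adaptive Metropolis (2 chains, componentwise
proposals adapted during burn-in), gated on split-chain
$\hat R < 1.05$; non-converged or flat fits report no IC50 rather than a
number. The IC50 is the posterior median and is scale-equivariant in the
concentration axis.

**Trend prefilter and benchmark dose.** Biomarker responses enter BMD
modelling only if a Williams-type trend test gives p < 0.05 *and* the
maximal absolute fold change vs vehicle is at least 1.5 (down-regulation
is folded as 1/FC). The Williams statistic is the isotonic
(pool-adjacent-violators, N-weighted) estimate of the top-dose mean
contrasted with the control mean, studentized by the pooled within-group
variance; its null distribution is obtained by label permutation (10,000
by default, seeded) instead of tabulated critical values, which gives
exact small-sample behaviour - the suite checks the permutation p against
full enumeration on a 3×2 design and the type-I error over 1,000 null
data sets. Six continuous models (poly-2, Hill, power, exponential
3/4/5) are fit by Gaussian maximum likelihood (`minpack.lm::nlsLM`; the
exponential-3 direction sign is fit both ways and chosen by AIC), the
lowest-AIC model wins, and the BMD solves
$|f(\mathrm{bmd})-f(0)| = \mathrm{BMR}\,|f(0)|$ with BMR 10%. BMDL/BMDU
are parametric-bootstrap percentile bounds (200 refits, seeded) rather
than re-derived profile-likelihood internals of the reference desktop
tool. Estimates are kept only when the BMD is below the highest tested
concentration and $1.1 \le \mathrm{BMDU/BMDL} \le 5000$ - the lower edge
removes under-extrapolated (noise-free-tight) intervals, so a noise-free
curve correctly fails the filter.

**hiPSC differentiation threshold.** The ornithine/cystine ratio curve is
fit with a four-parameter log-logistic model and an asymmetric
five-parameter variant; the comparison uses small-sample corrected AICc,
because the 5PL nests the 4PL and plain AIC would prefer the asymmetric
model on ~16% of symmetric data sets at these design sizes. The dTP is
the crossing of the 0.85 threshold, solved analytically for the 4PL and
numerically for the 5PL, and only reported inside the tested range. The
multiphasic variant of the reference workflow is out of scope.

**Hierarchical viability PoD.** Plate readings are modelled as a shared
declining curve scaled by per-row baselines (log-normal row effects),
sampled with the same Metropolis machinery. For each posterior draw the
PoD is the concentration of a 5% drop from that draw's baseline; the
concentration dependency score (CDS) is the posterior probability that
this PoD lies below the highest tested concentration, and CDS ≥ 0.5
(inclusive) is a confident hit. A single row falls back to a
non-hierarchical fit with a warning.

**LOEC and carry-over.** Pre-screen LOECs use Dunnett's many-to-one
comparison (via `multcomp`) at α = 0.05 - the underlying workflow does
not state its criterion, so this is a documented choice - and the LOEC is
the lowest significant tested concentration. For the steroidogenesis
assay, direct receptor activity in the pre-screen at or below the
carried-over concentration (steroid LOEC ÷ dilution factor) flags the
steroid LOEC as confounded without discarding it.

All PoD-type outputs are in µM and lie within the tested range or are
absent; nothing is extrapolated below the lowest tested concentration.
Ties in LOEC and minimum-PoD selection break toward the lower
concentration, then platform precedence in the enumerated source order,
then endpoint id.

## Chemical space

Descriptors are filtered in two passes: columns with diversity below 0.3
are dropped, where diversity is defined as one minus the modal-value
frequency over n (the underlying algorithm leaves "diversity" undefined;
this scale-free definition removes near-constant descriptors and is the
package's documented choice); remaining columns are visited in order of
descending diversity and kept only if their pairwise Pearson r² with
every retained column stays at or below 0.8. Filtering is idempotent and
the retained-r² bound is asserted by brute force in the tests. The
variance target of the PCA stage defaults to 0.95 (the source procedure
says only "a desired amount"), and the 2-D embedding is an exact
(non-Barnes-Hut) t-SNE implemented in the package - no t-SNE
implementation ships with the environment's R stack - with perplexity
calibration by bisection, early exaggeration, and a fixed seed so that
identical inputs give identical coordinates. Descriptor computation from
SMILES is an optional adapter (`ChemmineR`/`ChemmineOB`, largest-fragment
desalting); the pipeline itself is tested on synthetic matrices.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs, with ground truth
returned separately from the data:

* `gen_pk_studies()` draws between-subject CDRs from a lognormal
  (physiological concentrations are positive and right-skewed), composes
  studies of 10-200 subjects, and randomizes reporting units to keep the
  conversion paths exercised. The TKVF machinery downstream assumes a
  normal p95 (z = 1.64); this mismatch is intentional and is why TKVF
  recovery is asserted at 15% rather than exactly.
* `gen_concresp()` emits Hill, exponential-decline, 4PL or flat curves
  with replicate/row structure, Gaussian noise, and the analytic IC50 /
  BMD / threshold-crossing carried in the truth object.
* `gen_benchmark_suite()` builds PoD and scenario tables in which
  high-risk scenarios have Cmax at least the minimum PoD and low-risk
  scenarios at most minPoD/separation, so that with separation 10 a
  perfect 100/100 protectiveness/utility is a construction invariant,
  not an empirical finding.

What passing tests on these data do **not** show: real assay noise is not
Gaussian or row-exchangeable, real PK study means are not exactly normal
within studies, real descriptor matrices are far from independent
Gaussian, and real benchmark chemicals do not come with a separation
dial. The synthetic results validate the *machinery* (estimators recover
known truths at stated tolerances under controlled conditions), not the
biological performance of any assay battery.

## Fixtures and reproduction

The packaged benchmark tables (49 exposure scenarios over 37 chemicals
with 17 high / 27 low / 5 uncertain risk labels; four in-silico models'
confusion counts over 20 toxic and 13 non-toxic chemicals; per-population
CDR statistics with TKVF, fold differences and small-N flags) are
schema-validated and checksummed at load. The per-chemical calls table
reproduces the published counts exactly; cells not fixed by the published
record are filled consistently and the file is marked partially
synthetic, with the count table remaining authoritative. The profiling
target annotation (49 DART-relevant of 72 targets) is a synthetic
stand-in, labelled as such in its file name. Small-N (<10) entries are
excluded from the TKVF and fold-difference summaries; with them, the
headline mean would not reproduce.

The published headline BERs themselves (e.g. the warfarin
misclassification) require the original raw assay data and full Cmax
tables and are not recomputable from fixtures; the package instead
verifies the count arithmetic behind the published protectiveness and
utility percentages and the construction invariant on the synthetic
suite.

## Problem sizes and numerical settings

Default test and acceptance runs use: 2-chain Metropolis with 1,000-2,000
kept draws for the Bayesian fits; 199-10,000 permutations for the
Williams test (199 in the 1,000-data-set size study, which bounds
attainable p-values at 1/200 granularity - adequate for a size check at
α = 0.05); 200 bootstrap refits for BMDL/BMDU; 200 replicate fits in the
IC50 bias study; and 100 seeded simulations for 4PL model recovery.
These sizes were chosen so the whole suite completes in about a minute on
one core while keeping Monte-Carlo error well inside every asserted
tolerance.

## Known limitations

* PBK simulation, plasma-protein binding and tissue partitioning are out
  of scope; Cmax values are inputs.
* The Bayesian models use a single likelihood family (Gaussian) and
  simple row-offset hierarchy; heavier-tailed plate artefacts will
  inflate the residual SD rather than be captured.
* BER uncertainty is not quantified (deliberately, matching the
  proof-of-concept framing); calls flip at the boundary with no measure
  of confidence.
* The Welch z population test treats weighted summaries as if they were
  simple-random-sample moments; clustered study designs will understate
  the variance.
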