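---
title: "Methods: longitudinal methylation subtype dynamics in glioma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal methylation subtype dynamics in glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcimptrace)
```

## The problem

Diffuse gliomas carrying an *IDH1/2* mutation usually establish the glioma
CpG island methylator phenotype (G-CIMP), a globally hypermethylated state
with comparatively favorable outcomes. A small fraction of G-CIMP-high
tumors, however, lose methylation at specific CpG signatures on recurrence
and relapse as G-CIMP-low, a phenotype that behaves like an *IDH*-wild-type
glioblastoma. `gcimptrace` implements the analysis chain used to study this
shift on Illumina 450K beta-value profiles (methylated / total intensity,
in [0, 1]):

1. two-tier random-forest classification of each tumor fragment into the
   seven pan-glioma methylation subtypes, with per-class probability
   indices and an index-window rule for "G-CIMP-intermediate" profiles;
2. patient-level aggregation of fragments and tabulation of
   primary-to-recurrence subtype transitions;
3. a DNA-methylation stemness index (mDNAsi) per sample;
4. supervised per-probe differential methylation with delta-beta filters;
5. odds-ratio enrichment of probe sets for genomic features and motif
   hits; and
6. a 7-CpG risk panel with survival stratification.

Because the original cohorts cannot be redistributed, the package ships a
synthetic cohort generator whose planted truth exercises every stage
end to end; all tests and the acceptance script run on generated data
only.

## Classification model

Training uses reference profiles with known subtype and four signature
probe sets: 1,300 probes separating the *IDH*-mutant from the
*IDH*-wild-type macro group (tier 1), 1,308 + 163 probes resolving
codel / G-CIMP-high / G-CIMP-low within the mutant group, and 914 probes
resolving the four wild-type subtypes (tier 2). Each tier is a random
forest (`randomForest`, 500 trees by default, mtry = sqrt(p), mandatory
seed); the probability index of a class is the fraction of trees voting
for it, so indices within a tier sum to one. The macro group is the tier-1
argmax and the subtype the argmax of the matching tier-2 forest; argmax
ties break by the fixed, recorded class order (ties essentially never
occur with hundreds of trees, but the rule makes results reproducible). A
flat seven-class forest over the union of all signature probes can be
fitted alongside (`flat = TRUE`) for comparison; the two-tier route is the
default because macro-group separation and within-group subtyping are
distinct steps with their own signatures.

Samples whose tier-2 indices fall in the windows gcimp_low ∈ [0.2, 0.5)
and gcimp_high ∈ [0.5, 0.75) are relabeled G-CIMP-intermediate — an
annotation of a borderline index profile rather than an eighth training
class, which is why `classify()` reports both `subtype` and
`subtype_argmax`, and accuracy is assessed on the argmax label. The rule
is applied only to samples whose macro group is *IDH*-mutant and whose
argmax is gcimp_high or gcimp_low: the windows are defined on the G-CIMP
index pair and a codel argmax is left untouched. Lower bounds are
inclusive, upper bounds exclusive.

Query matrices must cover at least 90% of each tier's features; missing
probes (and residual missing cells) are imputed with training-set probe
means, below that coverage classification refuses with a report. This
policy is a package choice — reference workflows rarely state one — and is
deliberately conservative.

## Transition taxonomy

Fragments of one surgery are aggregated to a modal label, ties broken
toward the more progressed label (gcimp_high < gcimp_intermediate <
gcimp_low; ties outside this spectrum break alphabetically). The
aggregation rule is explicit because multi-fragment surgeries are averaged
only for stemness in the source workflow; subtype aggregation is not
specified there.

Each patient with both a primary and a first-recurrence surgery is
categorized as:

* `change` — gcimp_high at primary, gcimp_low at first recurrence;
* `intermediate_change` — either endpoint G-CIMP-intermediate, or
  gcimp_high at both but gcimp_low by a second recurrence;
* `no_change` — identical labels;
* `other` — any remaining pair.

The `intermediate_change` definition groups several published patterns;
it is implemented as above (and documented) rather than guessed further.

## Stemness index

`compute_mdnasi()` scores each sample as the weighted sum of its
stemness-signature beta values, then min-max scales across the scored
cohort so the index spans [0, 1] cohort-relatively, then averages
fragments per patient-surgery. Weight training (one-class logistic
regression on stem/progenitor reference epigenomes) is out of scope:
weights are an input, and the generator supplies synthetic standard-normal
weights. Applying weights linearly to raw beta values is an assumption
recorded here; min-max scaling makes the index invariant to positive
rescaling of the weight vector. Samples missing some weighted probes
(up to 10%) are scored on the retained probes with renormalization by the
retained count; a cohort with identical raw scores scales to all zeros
with a warning.

## Differential methylation

Per probe, a two-sided Wilcoxon rank-sum test compares two sample groups:
exact when the combined n is at most 20 and the probe has no ties,
otherwise the normal approximation with tie and continuity correction
(the switch point is a package choice). Fully tied probes get p = 1.
Benjamini–Hochberg adjustment is applied across probes. Matched
primary–recurrence pairs are *not* exploited as pairs: the unpaired
rank-sum test is used even for the transition-pair analyses, a deliberate
fidelity choice to the source procedure.

Delta convention: `delta = mean(groupA) − mean(groupB)` with **groupA the
reference (primary / retaining) group** and groupB the case (recurrent /
progressing) group in every named preset. A large positive delta therefore
marks a probe *demethylated in the case group* (direction `hypo`), a large
negative delta one that gained methylation (`hyper`). The presets carry
the published thresholds: FDR < 0.05 with |delta| > 0.2; FDR < 0.05 with
delta > 0.5 / < −0.4; raw p < 0.01 with the same asymmetric deltas; and
raw p < 0.05 with |delta| > 0.2 for biomarker discovery.

## Feature enrichment

Enrichment of a probe set for a genomic feature uses the 2×2 table of
selected vs background probes (background = the full annotated universe
minus the selected set, configurable). The odds ratio is (a·d)/(b·c) with
the Haldane–Anscombe 0.5 correction only when a cell is zero; the 95% CI
is Woolf's normal interval on the log OR — chosen because the published
intervals look log-symmetric and no method is named; an exact conditional
CI is available via `conf_method = "exact"`. Calls are `enriched` when
ci_low > 1 and `depleted` when ci_high < 1; the two-sided Fisher exact p
accompanies each row, with BH across features when several are tested
(the source's multiplicity handling here is unstated). Percentages print
half-up at two decimals throughout (base `round()` is banker's rounding,
which would turn 11.705 into 11.70 or 11.71 depending on parity).

Motif analysis consumes boolean per-probe hit flags (e.g. AP-1, SOX);
motif *discovery* is out of scope.

## Risk panel and survival

The 7-CpG panel carries the published per-probe beta cutoffs
(cg09732711 0.70, cg09326832 0.28, cg24665265 0.67, cg06220958 0.17,
cg10245915 0.12, cg11689625 0.31, cg11799650 0.49). A probe is concordant
when beta lies strictly below its cutoff — the panel probes are
hypomethylated in primaries that later progress, and the strict-below
reading is recorded as an assumption, configurable per probe via the
`direction` column. A sample is `risk` at ≥ 5 concordant probes,
`unevaluable` below 5 evaluable probes. The rule is monotone by
construction: adding a concordant probe can never revoke a risk call.

Survival stratification reports Kaplan–Meier curves, the two-group
log-rank test, and a hazard ratio from a single-covariate Cox
proportional-hazards fit (the published analysis names only "hazard
ratio"; an observed/expected log-rank HR is available via
`hr_method = "logrank"`).

## The synthetic cohort generator

Beta values are drawn from Beta(μ·c, (1−μ)·c), so the mean is the
archetype value μ and c (`noise_concentration`, default 50, giving a
within-group SD of about 0.06 at μ = 0.5) controls tightness while values
respect (0, 1) without clipping — the reason a Beta noise model was chosen
over a truncated Gaussian. Archetypes: signature probes of a subtype's
defining block sit at `baseline_beta + signature_effect` (defaults
0.3 + 0.4), all other signature probes at baseline, background probes at
0.5; the G-CIMP-low archetype equals G-CIMP-high with the 163
subtype-signature probes demethylated, so those probes are the planted
transition signature. A separate small probe block is hypermethylated in
the low archetype, giving planted truth for both filter directions. No
published noise model exists for these data; the defaults are calibration
choices of the generator, not claims about the study cohorts.

Longitudinal cohorts give every patient a primary and a first-recurrence
surgery with `fragments_per_surgery` fragments each. Configured fractions
of gcimp_high patients recur from the gcimp_low archetype (`change`) or
from a high/low archetype-mean mixture (`intermediate_change`). The
mixture weight defaults to 0.55 on the high side rather than the literal
midpoint: measured over the trained forests, a 50/50-mean sample's
gcimp_high index straddles the 0.5 window boundary (5–95% range roughly
0.48–0.59), so planted intermediates would be recovered only about 80% of
the time by construction; at 0.55 the index centers near 0.65, inside
[0.5, 0.75). The literal midpoint remains available
(`mixture_weight_high = 0.5`).

Annotation flags (CGI relation, enhancer, bivalent, AP-1/SOX motif hits)
are sampled with separate probabilities for the 163 transition probes vs
all others, planting enrichment truth. Each sample carries a latent
stemness factor in [0, 1] that shifts stemness-signature probe means in
the direction of each probe's weight sign; transitioning recurrences draw
their factor from [0.5, 1]. Survival is exponential with baseline hazard
0.1 per time unit, multiplied by `hazard_ratio_risk_group` (default 2.19)
for transitioning patients, with independent exponential censoring
(default rate 0.04, about 30% censoring at the baseline hazard). When
`plant_panel` is on, the primaries of transitioning patients sit 0.10
below each panel cutoff and all other samples 0.25 above (clamped),
so panel sensitivity is a recoverable property, not a certainty.

A single master seed drives everything; per-stage substreams are derived
deterministically from it, so identical seed + config reproduce cohorts
byte for byte.

## What the synthetic experiments do and do not show

Passing tests on generated cohorts demonstrate that the implementations
are correct against their planted truth and independent oracles
(brute-force BH, hypergeometric tail sums, closed-form Woolf intervals,
exact rank-sum tails, hand-worked log-rank arithmetic). They do not
reproduce cohort-level findings that depend on the real data — the
identities of the published 684/28/350/84/7 probe sets, the printed
stemness medians, or the validation-cohort numbers (79/271 risk calls,
HR = 2.19) — which would require the original profiles. Count-derived
percentages, thresholds and decision rules are reproduced exactly from
their printed inputs; performance bounds (classifier accuracy > 95%) are
reproduced on synthetic cohorts under the default study-like conditions.

Real 450K data additionally feature probe-specific mean/variance
relationships, spatial correlation along the genome, batch structure and
cell-type admixture, none of which the generator emulates; robustness to
those is outside what the tests can show.

## Problem sizes

The default experiments use a reference cohort of 20 patients per subtype
(140 samples, ~4,900 probes) for training, a longitudinal cohort of 77
patients (308 fragments at two fragments per surgery), and 10-fold
cross-validation at 500 trees for the headline accuracy; property suites
use 100–1,000 replicates per invariant. These sizes make every analysis
reproducible on a laptop in minutes while keeping group sizes at or above
those of the motivating study arms (9 transition pairs, 53 high-primary
patients).
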