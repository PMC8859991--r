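# gcimptrace

Longitudinal DNA-methylation subtype dynamics in diffuse glioma.

Most *IDH*-mutant gliomas establish the glioma CpG island methylator
phenotype (G-CIMP) and keep it through recurrence, but a small subset of
G-CIMP-high primary tumors relapses as G-CIMP-low — a demethylated,
*IDH*-wild-type-glioblastoma-like phenotype with poor outcomes. Detecting
that shift, and predicting it from the primary tumor, is the clinical
question this package addresses for analysts working with Illumina 450K
beta-value profiles (β = M/(M+U) ∈ [0,1]).

The package implements the full analysis chain as tested, reusable
functions:

* **Subtype classification** — a two-tier random-forest classifier over
  published-style signature probe sets (1,300 macro-group probes; 1,308 +
  163 *IDH*-mutant probes; 914 *IDH*-wild-type probes). Per-class
  probability indices are tree-vote fractions; samples with
  gcimp_low index ∈ [0.2, 0.5) and gcimp_high index ∈ [0.5, 0.75) are
  flagged **G-CIMP-intermediate**.
* **Transition tabulation** — fragment-to-patient aggregation and the
  change / intermediate_change / no_change taxonomy of primary→recurrence
  pairs.
* **Stemness (mDNAsi)** — weighted linear probe score, cohort min-max
  scaled to [0,1], averaged per surgery.
* **Differential methylation** — per-probe Wilcoxon rank-sum tests with
  Benjamini–Hochberg FDR and the named delta-beta filter presets
  (FDR < 0.05 & |Δβ| > 0.2; FDR < 0.05 & Δβ > 0.5 / < −0.4; p < 0.01
  asymmetric; p < 0.05 & |Δβ| > 0.2).
* **Feature enrichment** — odds ratios vs the array background with Woolf
  95% CIs, OR = (a·d)/(b·c), Fisher exact p, CGI-relation distributions
  and motif-hit overlap fractions.
* **Risk panel & survival** — the 7-CpG panel with per-probe beta cutoffs
  and the n ≥ 5 concordance rule, Fisher validation, Kaplan–Meier,
  log-rank and Cox hazard ratios.
* **Synthetic cohorts** — a generator with Beta-distributed noise around
  subtype archetypes, planted transitions, feature enrichment, stemness
  gradients, a planted risk panel and exponential survival with a group
  hazard ratio, so the whole pipeline is testable without external data.

## Worked example

The `analysis/` scripts run the whole study workflow on a generated
cohort of 77 patients (53 G-CIMP-high, of which 9 transition, 7 go
intermediate, 37 retain; two fragments per surgery):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_classify_subtypes.R
Rscript analysis/03_transitions_stemness.R
Rscript analysis/04_differential_methylation.R
Rscript analysis/05_feature_enrichment.R
Rscript analysis/06_risk_survival.R
```

Step 03 prints the patient-level transition table recovered purely from
the classifier output:

```
transitions among G-CIMP-high primaries:
            category  n percent of_total
           no_change 37      70       53
 intermediate_change  7      13       53
              change  9      17       53
               other  0       0       53
agreement with planted transition truth: 1.000

mDNAsi medians gcimp_high_primary=0.422 vs gcimp_low_recurrence=0.734, rank-sum p = 2.86e-03
```

i.e. 70% of G-CIMP-high patients keep their phenotype, 17% progress to
G-CIMP-low, 13% show intermediate changes, and the progressed recurrences
score markedly higher stemness. Step 04 compares the 9 transition pairs
(18 primary vs 18 recurrent fragments):

```
FDR < 0.05 with delta > 0.5 / < -0.4: 163 hypo, 28 hyper
planted recovery: hypo 1.000, hyper 1.000
```

recovering exactly the planted demethylated transition signature and the
hypermethylated block. Step 05 shows where those probes live:

```
               feature odds_ratio ci_low ci_high        p     call
 cgi_relation=open_sea      8.539 5.6907  12.812 7.87e-34 enriched
              enhancer      4.029 2.9403   5.521 3.66e-17 enriched
             motif_AP1      4.014 2.8332   5.686 1.13e-12 enriched
             motif_SOX      2.923 1.9760   4.325 1.12e-06 enriched
```

and step 06 applies the 7-CpG panel to the primaries, capturing all 9
transitioning patients (Fisher p = 6.2e-12) and stratifying survival.
Every table is also written under `results/`.

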