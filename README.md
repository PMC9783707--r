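# pipscore

Pharmacogenomic interaction probability (PIP) scoring in R.

Panel-based pharmacogenomic (PGx) testing finds, for some patients, at least
one *evidence-based actionable drug–gene interaction* (EADGI): a drug–gene
(DGI), drug–drug–gene (DDGI), or drug–gene–gene (DGGI) interaction of
moderate, major, or contraindicated severity with FDA-label or CPIC A/B
guidance behind it. `pipscore` predicts, from nothing but a medication list
and population phenotype prevalences, the probability that testing would
reveal such a finding — so clinicians and health systems can prioritise who
to test. It is written for biostatisticians and PGx informaticians who want
an open, testable implementation of this class of scoring algorithm.

## The model

For medication list $M$, the score is the probability of at least one
actionable interaction under independent per-gene phenotype draws
$\pi_g(\cdot)$:

$$\mathrm{PIP}(M) = 1 - \prod_{c} \bigl(1 - p_c\bigr), \qquad
p_c = \Pr\Bigl(\bigcup_{o \in c} \{\text{phenotypes match opportunity } o\}\Bigr),$$

where opportunities are knowledge-base rules reachable from $M$ (paired with
co-medication inhibitor/inducer effects) surviving three filters: evidence
must be FDA label or CPIC A/B, post-phenoconversion severity must be at
least moderate, and a DDGI must exceed the severity of the corresponding
gene-free drug–drug interaction. Clusters $c$ are genes coupled by two-gene
rules; each $p_c$ is computed by exact enumeration, so shared phenotype
draws across co-substrate drugs are handled without approximation. The
*adjusted* PIP restricts to the genes actually ordered on the patient's
panel. Phenoconversion is categorical: AUC-change bins combine by ordinal
escalation (same direction: one bin beyond the stronger input; opposite:
the stronger de-escalated one bin), and severities escalate one level per
extra bin, capped at `contraindicated`.

See the methods vignette (`vignettes/pip-methodology.Rmd`) for the full
model, assumptions, and design choices.

## Worked example

```r
library(pipscore)
demo <- demo_kb()          # open demo knowledge base + prevalence table

compute_pip(c("clopidogrel", "tramadol", "escitalopram"),
            demo$kb, demo$prevalence, tested_genes = pgx_panel(5))
#> PIP score: 38.1% (adjusted to tested panel: 38.1%)
#>   12 actionable interaction opportunities across 2 gene clusters
#>   CYP2C19: 32.0%
#>   CYP2D6: 9.0%
```

A 38.1% chance that a 5-gene panel yields at least one actionable finding:
the CYP2C19 cluster (clopidogrel and escitalopram share the gene, union
mass 32%) and the CYP2D6 cluster (tramadol, 9%) combine as
`1 − 0.68 × 0.91`. After testing, the detector classifies what was actually
found — here a CYP2C19 intermediate metabolizer on clopidogrel + tramadol,
where the co-medication deepens the genetic exposure reduction
(−31–50% combined with −31–50% gives −51–80%) and escalates severity:

```r
p <- patient_record("PT-001", c("clopidogrel", "tramadol"),
                    tested_genes = pgx_panel(3),
                    phenotypes = c(CYP2C19 = "intermediate",
                                   CYP2C9 = "normal", CYP2D6 = "normal"))
detect_interactions(p, demo$kb)
#>   kind        drug    drug2 ...    gene    phenotype        severity combined_auc eadgi
#> 1 DDGI clopidogrel tramadol ... CYP2C19 intermediate contraindicated      -51-80%  TRUE
#> 2  DGI clopidogrel     <NA> ... CYP2C19 intermediate           major      -31-50%  TRUE
#> 3  DDI clopidogrel tramadol ...    <NA>         <NA>         monitor         none FALSE
```

Simulated cohorts validate the calibration — mean adjusted score and
observed detection rate agree:

```r
coh <- simulate_cohort(cohort_config(2000, seed = 1), demo$kb, demo$prevalence)
scored <- score_cohort(coh, demo$kb, demo$prevalence)
panel_summary(scored, 3)
#> >=3 genes: n=2000, mean PIP 25.0%, mean adjusted PIP 22.2%,
#>            rate 21.8% (436), NNT 4.6, p=0.6329
```

A command-line wrapper ships in `exec/pipscore`
(`pipscore score --meds "clopidogrel,tramadol"`, `pipscore kb validate`,
`pipscore run-study ...`).

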