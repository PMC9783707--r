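---
title: "Pharmacogenomic interaction probability scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacogenomic interaction probability scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipscore)
```

## The problem

Pharmacogenomic (PGx) panel testing reveals, for a subset of patients, at
least one *evidence-based actionable drug–gene interaction*: a drug–gene
(DGI), drug–drug–gene (DDGI), or drug–gene–gene (DGGI) interaction of
moderate, major, or contraindicated severity, backed by FDA drug labeling or
CPIC category A/B guidance. Testing everyone pre-emptively is expensive;
testing nobody misses preventable adverse drug events. The PIP
(pharmacogenomic interaction probability) score prioritises patients: given
only a medication list and the population prevalence of interpreted
phenotypes, it predicts the probability that panel testing would find at
least one actionable interaction for that patient.

`pipscore` implements the scoring engine, the phenoconversion algebra that
lets co-medication amplify or attenuate a genetic phenotype's effect, a
detector for genotyped patients, a cohort simulator, and the validation
statistics that compare predicted scores with observed detection rates.

## The probability model

Let $G$ be the set of panel genes, and for each gene $g$ let $\pi_g(\cdot)$
be the population distribution over its interpreted phenotypes (for
drug-metabolising enzymes the ladder *poor < intermediate < normal < rapid <
ultrarapid*; carrier/non-carrier or function categories otherwise). A
knowledge base maps (drug, gene, phenotype) triples — optionally with a
second gene and phenotype — to a severity, an AUC-change category, and an
evidence source.

Given a medication list $M$, the engine collects every *opportunity*: a rule
whose drug is in $M$, paired with the co-medications that inhibit or induce
the rule's gene. Opportunities are filtered (below), leaving a set of
phenotype events on the genes. Phenotypes are drawn independently across
genes, so the probability that testing finds at least one actionable
interaction factorises over gene clusters:

$$\mathrm{PIP}(M) \;=\; 1 - \prod_{c \in \text{clusters}}
  \bigl(1 - p_c\bigr), \qquad
p_c = \Pr\Bigl(\bigcup_{o \in c}\{\text{phenotypes match } o\}\Bigr).$$

Genes are coupled into one cluster only by two-gene rules; each cluster's
union probability $p_c$ is computed by exact enumeration of the Cartesian
product of its genes' phenotype distributions, so within-gene correlation
across co-substrate drugs (two drugs reading the same phenotype draw) is
handled exactly, with no approximation anywhere. The *adjusted* PIP applies
the same computation restricted to the genes actually ordered on the
patient's panel; since restriction can only remove opportunities, adjusted
$\le$ full always holds.

Cross-gene independence is an assumption (no linkage between pharmacogenes);
it is also the only computable choice given gene-level prevalence inputs.

### Exclusion filters

Three classes of rule matches never count toward the score, because the
genetic information would not change clinical management:

1. matches whose evidence is not FDA labeling or CPIC A/B;
2. matches whose post-phenoconversion severity is below moderate
   (monitoring-only findings);
3. two-drug (DDGI) matches whose severity does not exceed the strongest
   gene-free drug–drug rule for the same pair — the interaction would be
   flagged anyway without testing.

The detector applies identical criteria when flagging actionable findings in
genotyped patients, which is what makes the score *calibrated by
construction*: the indicator "patient has at least one actionable finding"
is Bernoulli with success probability exactly equal to the PIP score when
phenotypes follow the prevalence table.

## Phenoconversion

Co-medication changes effective enzyme activity. The model is categorical
throughout: exposure (AUC) changes are binned per direction — decreases
`-0-30%`, `-31-50%`, `-51-80%`, `-81-100%`; increases `+0-25%`, `+26-75%`,
`+76-200%`, `>200%` — and two changes combine by ordinal escalation:

* same direction: one bin beyond the stronger input, capped at the extreme;
* opposite directions: the stronger input de-escalated one bin, floored at
  its mildest bin; at equal bins the result is the mildest decrease bin,
  keeping the operation commutative;
* `none` is the identity.

```{r}
combine_auc("-31-50%", "-31-50%")
combine_auc("-31-50%", "+26-75%")
```

This rule was chosen because it reproduces all ten published cumulative-AUC
phenoconversion pairs exactly, whereas midpoint interval arithmetic
(multiplying central retention fractions and re-binning) fails the
`-51-80% + -31-50% → -81-100%` row; the interval alternative is retained in
the test suite as a reference oracle documenting that comparison.

A modifier is stored as an action (`inhibitor`/`inducer`) plus an ordinal
strength bin 1–4. For a parent-drug substrate, inhibition maps to the
increase bin of that strength and induction to the decrease bin; for a
prodrug rule — stated for the active metabolite — the direction is mirrored
at the same bin index (inhibiting the activating enzyme lowers metabolite
exposure). One ladder step per modifier, regardless of bin, is the minimal
model consistent with the published pairs; no published strength ladder
exists, so weak/moderate/strong inhibitors are not distinguished
(`effective_phenotype()` shifts one step per modifier and saturates at the
ladder ends).

When the combined category is more extreme than the rule's own bin, severity
escalates one level per extra bin, at most two, capped at `contraindicated`,
and never drops below the rule's stated severity. Whether severity may skip
levels for extreme combinations is not externally specified; the
cap-and-step rule is this package's choice.

Modifiers pair only with single-gene rules: a modifier on a two-gene rule
would create a two-drug/two-gene interaction outside the DGI/DDGI/DGGI/DDI/
DDDI taxonomy. Cumulative escalation by two or more simultaneous modifiers
of one rule is likewise not modelled; each (rule, modifier) pair is assessed
on its own.

## The demo knowledge base

Production interaction knowledge bases are proprietary. The package ships an
open, schema-versioned (`pip-kb/1`) JSON format and a demo knowledge base
over the 25 commonly panelled pharmacogenes and eighteen medications,
calibrated so that the single-medication PIP scores equal the published
per-medication values:

```{r}
demo <- demo_kb()
vapply(c("metoprolol", "omeprazole", "escitalopram", "clopidogrel",
         "tramadol", "amitriptyline"),
       function(d) compute_pip(d, demo$kb, demo$prevalence)$pip, numeric(1))
```

Calibration conventions, chosen once and documented rather than estimated:

* each drug's actionable-phenotype set has prevalence mass equal to its
  published score (e.g. metoprolol: CYP2D6 intermediate + poor + ultrarapid
  = 0.39 + 0.06 + 0.03 = 0.48);
* co-substrates of a gene overlap maximally — the smaller actionable set is
  nested in the larger (clopidogrel's {intermediate, poor} inside
  (es)citalopram's {intermediate, poor, rapid});
* escitalopram and citalopram are separate entries sharing one rule set.

Because no published per-phenotype breakdown exists, the CYP2D6/CYP2C19
prevalences are fixture values forced by this calibration — the CYP2C19
rapid-metabolizer mass (3%) in particular is far below realistic North
American frequencies. They are conventions of the demo fixture, not
population estimates; prevalences for the other 23 genes are plausible
placeholder marginals used only by the simulator. One published worked
example (a three-drug combination scoring 62%) is *not* reproduced under
these conventions (the demo KB gives 38.1%): it depends on the proprietary
phenotype-overlap structure, and no parameter here was tuned toward it.

Two entries exercise structure the calibrated drugs do not reach:
simvastatin (SLCO1B1, a gene absent from the 3/5-gene panels, so full and
adjusted scores separate) and warfarin (a CYP2C9 metabolizer rule plus an
intrinsic CYP2C9+VKORC1 two-gene rule, exercising joint cluster
enumeration).

## The simulator

`simulate_cohort()` emulates the validation cohort's statistical structure:

* panel mix over the nested 3/5/14/25-gene panels with exclusive
  proportions 21.6% / 69.6% / 3.1% / 5.7%, derived from the published
  nested counts;
* medication count per patient: 1 plus a negative binomial (size 2, mean
  8.4), resampled into [1, 62] — mean 9.4, supplements included;
* each medication slot holds a knowledge-base drug with probability 0.17
  (so about 83% of patients take at least one pharmacogenomically active
  medication), sampled by clinical area with weights proportional to the
  published actionable-interaction distribution, then uniformly within
  area; remaining slots are inert fillers unknown to the knowledge base,
  which the engine ignores by default (strict mode errors instead);
* phenotypes drawn independently per panelled gene; age and sex sampled as
  annotations only.

All defaults were fixed from the published cohort description before any
calibration experiment and are not tuned. What the simulator does *not*
emulate: real co-prescription correlation beyond the two-stage area model,
race/ethnicity-stratified prevalences, age effects on prescribing, and the
production knowledge base's full drug list. A passing calibration check on
simulated cohorts therefore demonstrates internal consistency of engine and
detector under the stated probability model — not field performance on real
patients.

## Validation statistics

For a scored, genotyped cohort the package computes panel-subgroup summaries
(patients whose ordered genes cover at least the 3/5/14/25-gene panel):
mean full and adjusted PIP, observed actionable-finding rate, the number
needed to test `NNT = n / count`, and a one-proportion z-test of the
observed rate against the mean adjusted PIP as a fixed null proportion,

$$z = \frac{\hat p - p_0}{\sqrt{p_0 (1 - p_0) / n}},$$

two-sided, no continuity correction (none is specified for the reference
analysis). Using the mean adjusted score as $p_0$ overstates the null
variance when per-patient scores are heterogeneous, so the test is slightly
conservative — acceptable for its confirmatory role.

Score-threshold bins use the boundary convention low `[0, 0.25)`, moderate
`[0.25, 0.50]`, high `(0.50, 1]` (both written boundaries fall in the
moderate band); the convention is documented and tested since the reference
description is ambiguous between `<25%` and `>25%`. Per band, each patient
contributes their single most severe interaction; ties at equal severity
break by kind precedence DGGI > DDGI > DGI > DDDI > DDI (gene-involving
kinds first — the precedence is this package's choice; only the max-severity
rule is externally specified), then lexical drug order. The non-decreasing
any-interaction fraction across bands is reported and asserted by the test
suite rather than enforced inside the function, so a sampling fluctuation in
a small cohort cannot abort a report run.

### Numerical choices

* Probabilities are double precision, never rounded internally; percentages
  and NNT are rounded half-up to one decimal only in the report layer
  (base R `round()` rounds half to even, which printed clinical tables do
  not).
* An undefined NNT (zero findings) is a typed condition and printed as "—",
  never infinity.
* Duplicate medications are de-duplicated and drug names are
  case-insensitive (stored lower-case).
* A zero-prevalence phenotype simply contributes zero mass; degenerate
  one-phenotype distributions are valid.
* The brute-force oracle `pip_bruteforce()` recomputes a score by
  enumerating every joint phenotype assignment over the relevant genes and
  calling the *detector* on each — a deliberately independent code path
  used to cross-check the engine (agreement within 1e-9 on randomized
  knowledge bases).

### Problem sizes used by the tests

The shipped suite checks the engine–oracle agreement on 200 randomized small
knowledge bases (3 ladder genes, 4 drugs), Monte-Carlo calibration at
10,000 patients, and the replicate calibration study on 100 simulated
cohorts of 10,000 patients each (z-test p > 0.05 required in at least
95 of 100); these sizes give binomial standard errors of about 0.4
percentage points at each check while keeping the full suite inside a few
minutes on one CPU.

## Known limitations

* Race/ethnicity- and age-stratified prevalences are out of scope, as is
  any Beers-criteria weighting of severities.
* Star-allele/diplotype-to-phenotype translation is not performed; the
  package operates on interpreted phenotypes.
* The demo knowledge base reproduces published medication-level scores by
  construction; its per-phenotype structure is a convention and should not
  be read as clinical content.
* Modifier strength is one ladder step per co-medication; graded
  inhibitor-strength data would refine DDGI severity escalation.
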