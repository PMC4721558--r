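---
title: "Test-retest reliability of immunostain panels on duplicate tissue microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability of immunostain panels on duplicate tissue microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmaretest)
```

## The problem

Archival formalin-fixed paraffin-embedded (FFPE) breast tumor blocks can be
decades old. Whether modern immunostains give reliable results on such
material is an empirical question, and the natural design to answer it is a
test-retest one: build two tissue microarrays (TMAs) in duplicate from the
same specimens, stain and score them independently, and measure agreement.
`tmaretest` implements that analysis chain end to end:

1. **core → TMA aggregation** — each specimen contributes 3 cores of 0.6 mm
   per TMA; per-core stain results are reduced to one call per TMA replicate;
2. **surrogate molecular phenotyping** — the panel (ER, PR, HER2, CK 5/6,
   EGFR, Ki67) is mapped to Luminal A / Luminal B / HER2-enriched /
   basal-like;
3. **reliability** — percent concordance and Cohen's kappa with confidence
   intervals between the duplicate TMAs, under explicit missing-data
   policies;
4. **simulation** — a generator for the whole study process (stratified
   sampling, retrieval loss, latent marker states, core-level noise) for
   property-based validation.

The package ships a reference panel table (`tma_fixture_path()`): 30
invasive breast cancer cases, five per diagnosis stratum from 1947-1959
through 2000-2009, each with duplicate TMA results for a CK cocktail control
stain, ER, PR, HER2, CK 5/6, EGFR and Ki67, plus the phenotype label under
which each panel was originally reported.

## Data model and aggregation

A dataset couples case records (`case_id`, diagnosis year and its decade
stratum, histology, grade) with panel records, one per (case, TMA). Binary
stains are `pos`/`neg`/`NA`; HER2 keeps its ordinal immunohistochemistry
scale `neg < 1+ < 2+ < 3+`; Ki67 is a percent of positive cells. `NA` always
means *no evaluable tissue*, which happens per stain section: a panel can
have a missing HER2 with every other marker scored, and one fixture panel
(case 3-13, TMA1) is missing entirely. Both situations round-trip through
the CSV dialect.

Aggregation rules (`aggregate_binary_marker()`, `aggregate_her2()`,
`aggregate_ki67()`):

* a binary marker is **positive if any core is positive**, negative if at
  least one core bears tissue and none is positive, missing otherwise;
* HER2 takes the **maximum ordinal score** over tissue-bearing cores. The
  source design reports a single score per TMA without stating how
  discordant cores were reconciled; the maximum is the natural ordinal
  generalization of the any-positive rule and is our convention;
* Ki67 is the **mean percent over tissue-bearing cores** — a dropped core
  does not dilute the average.

All three rules are permutation-invariant in core order and monotone (adding
a positive core never demotes a panel), which the test suite checks by
property.

The CK cocktail is a broad-spectrum cytokeratin control for antigen
preservation: carcinoma tissue should stain. `antigen_integrity()` judges a
case degraded only when at least one CK call is definite and all definite
calls (across both TMAs) are negative; a case with one missing and one
positive CK call counts as preserved. On the fixture exactly 2 of 30 cases
fail (1-5 and 2-9).

## The phenotype classifier

`classify()` implements the standard immunostain surrogate for intrinsic
subtype, with two conventions that the fixture itself pins down:

* **HER2-positive for classification means 3+ only.** Two fixture panels
  carry HER2 2+ yet were reported basal-like, which requires HER2-negative;
  so equivocal 2+ stains (which in clinical practice would reflex to ISH)
  classify as negative. The reliability coding of HER2 is deliberately
  different (below); both sets are configurable via `phenotype_rules()`.
* **Ki67 ≥ 14% is "high".** The boundary value itself must land in the high
  bin: one fixture panel reads exactly 14.0%.

Missing markers are resolved by **completion enumeration** rather than
imputation: the classifier evaluates every completion of the missing values
and returns the unanimous call if there is one, otherwise an `Ambiguous`
call carrying the candidate set. A panel missing both hormone receptors (or
missing everything) is `Unknown`. This reproduces the fixture's reported
"Luminal A or Luminal B" call for an ER+/PR+ panel with missing HER2 without
inventing probabilities, and it is exhaustively cross-checked in the tests
against an independently written rule table over the full marker grid.

One genuine untidiness in the source data: two panels (4-19 TMA2 and 6-28
TMA2) have the *same* missing-HER2 structure with low Ki67, but one was
reported "Unknown" and the other "Luminal A or Luminal B". No rule
distinguishes them, so the classifier emits `Ambiguous{LuminalA, LuminalB}`
for both, and validation treats printed `Unknown` and printed ambiguous-set
labels as one indefinite family. Under that equivalence the classifier
reproduces all 59 reported per-panel phenotypes.

## Reliability conventions

```{r report}
ds <- read_dataset(tma_fixture_path())
reliability_report(ds)[, c("target", "n_complete", "concordance_pct",
                           "kappa", "ci_low", "ci_high")]
```

The conventions, each forced by the printed statistics and recorded in the
report's `convention` column:

* **Concordance denominator is all 30 cases**, and a case is discordant only
  when *both* calls are definite and differ; a missing member never makes a
  pair discordant. Display rounding is half-up to integer percent; the raw
  proportion is kept alongside.
* **Kappa uses complete pairs only** (29 pairs; 27 for HER2, which loses two
  no-tissue cells).
* **HER2 is coded two ways.** Concordance compares the reported stain
  categories (2+ vs negative differs). Kappa dichotomizes at
  `{2+, 3+} = positive` — the coding under which the fixture yields
  kappa 0.908 — while the *classifier* counts only 3+ as positive. Both
  conventions are explicit arguments of `build_pairs()`.
* **Phenotype pairs** treat `Unknown` as missing and an ambiguous-set call
  as a definite category of its own. The report carries two phenotype rows:
  one over the classifier's calls and one over the as-published labels. They
  differ only at the two indefinite panels above — the published table calls
  one of them `Unknown` (dropping the pair) and the other
  "Luminal A or Luminal B" (a discordant definite pair), which yields 90%
  concordance; the classifier, which cannot distinguish the two, yields 87%
  under the same policy (both pairs discordant), or 93% if ambiguous calls
  were instead dropped. We report both rows rather than pretend the
  distinction is derivable.

### Kappa, standard errors, and what the printed table supports

`cohen_kappa()` is the unweighted statistic
$\kappa = (p_o - p_e)/(1 - p_e)$ on the square table of complete pairs, with
$p_e$ from the marginals; when all mass sits in one cell ($p_e = 1$) kappa
is undefined and flagged rather than forced. The asymptotic CI uses the
large-sample (Fleiss-Cohen-Everitt) variance with normal quantiles, clipped
to $[-1, 1]$; a case-resampling percentile bootstrap is available
(`kappa_ci(..., method = "bootstrap")`) since clipped intervals are
asymmetric by construction.

Running the fixture through these definitions reproduces the published
statistics exactly: kappa 0.908 (HER2), 0.628 (CK 5/6), 0.782 (EGFR), 0.346
(Ki67), and every published interval — (0.731, 1.000), (0.155, 1.000),
(0.372, 1.000), (-0.225, 0.916) — coincides with the asymptotic interval to
three decimals, which settles the otherwise unstated CI method. Two printed
values resist reproduction and are reported as computed rather than forced:

* **PR kappa**: the printed PR columns give 0.858 (17/12 vs 17/12 marginals,
  two discordant pairs); the published value 0.926 is not obtainable from
  the printed table under any enumerated convention.
* **Phenotype kappa**: the published point value 0.724 is likewise not
  obtainable; our classifier-based kappa is 0.784 with asymptotic CI
  (0.591, 0.976) — *identical* to the published interval — which suggests
  the published point value is a misprint and that the original computation
  coded ambiguous calls as their own category, as we do.

### The kappa-prevalence paradox

Dichotomized Ki67 shows 90% concordance but kappa 0.346: only about one
case in ten exceeds the 14% cutoff, so the marginals are extreme, chance
agreement $p_e$ is already 0.84, and the paradox follows from the
definition. `kappa_prevalence_sweep()` demonstrates the mechanism on
simulated studies: at fixed core-level noise, kappa falls monotonically as
the positive class is made rare while raw concordance moves only a few
points.

## The synthetic study generator

`sim_config()` encodes the study conditions: 10 cases sampled per decade
stratum; pathology report and block retrieval as Bernoulli stages with
probabilities 55/60 and 50/55 (the realized retrieval rates of the archival
study); 5 cases per stratum analyzed among those retrieved, with an explicit
shortfall flag when a stratum cannot fill its quota; duplicate TMAs of 3
cores. Marker prevalences default to the reported cohort composition
(ER 0.80, PR 0.60, HER2 0.20, CK 5/6 0.13, EGFR 0.07, CK cocktail 28/30),
and the latent Ki67 case mean is log-normal with median 5.5% and log-sd
0.75, a right-skewed choice that puts ~11% of cases above the 14% cutoff,
matching the reported 10-14%.

The noise mechanism is this package's own construct — archival studies
report no error model to copy. Both TMAs of a case share one latent state;
each (core, stain) section drops out independently (default 0.05);
tissue-bearing cores misread the latent state with per-core sensitivity
0.95 and specificity 0.97; HER2 cores draw from a confusion distribution
over the four ordinal levels given the latent state; Ki67 cores scatter
normally (sd 2.5 points) around the case mean, truncated to [0, 100]. A
single root seed expands deterministically into per-stage child seeds, so
retrieval, truth and staining are individually reproducible.

What the generator deliberately does **not** emulate: fixation-age-dependent
antigen decay (the feasibility finding is precisely that decade did not
matter); intratumor spatial correlation between cores; and section-to-
section correlation of dropout. One behavior worth knowing: because the
panel-level HER2 score is the *maximum* over cores, rare per-core upward
misreads accumulate — a latent-negative panel scores 1+ or higher with
probability $1 - 0.85^3 \approx 0.39$ under the default confusion matrix —
so simulated HER2 ordinal concordance is pessimistic relative to the
archival data. Passing pipeline tests on simulated data therefore show
internal consistency of the machinery, not that the noise model is a
calibrated portrait of staining error.

## Numerical choices and problem sizes

* Percent display rounding is half-up (`floor(x + 0.5)`), so 26/30 prints
  as 87; raw proportions are always retained.
* CI bounds are clipped to $[-1, 1]$ after the normal interval is formed;
  bootstrap resamples whose table degenerates to one category are dropped
  from the percentile computation.
* Ki67 exactly at the cutoff is high; HER2 positive-level sets must be
  upward-closed on the ordinal scale.
* The test suite sizes its property loops for depth rather than bulk: 1,000
  random tables against a brute-force kappa oracle, 300 random panels
  against an independently written completion-enumeration oracle, the full
  $2^4 \times 4 \times 2$ marker grid for branch exhaustiveness, parameter
  recovery on a 900-case simulated study, bootstrap coverage on 120
  simulated pair sets, and a 4-prevalence × 15-replicate sweep.

## Limitations

* The fixture is a transcription of a printed table; two of its published
  summary statistics (PR kappa, phenotype kappa point value) disagree with
  the table they summarize, as discussed above, and are reported as
  computed.
* Kappa here is unweighted and two-rater; no weighted kappa, no more than
  two replicates per case, and no intraclass correlation for continuous
  Ki67 (which is analyzed dichotomized throughout).
* The classifier is the immunostain surrogate algorithm only — no
  expression-based intrinsic subtyping, no HER2 ISH reflex logic.
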