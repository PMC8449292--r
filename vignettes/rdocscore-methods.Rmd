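---
title: "Methods: lexicon-based RDoC scoring and length-of-stay modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-based RDoC scoring and length-of-stay modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The score

For a domain $d$ with term set $T_d$ and a note with token sequence $V$,
the package computes the presence-fraction score

$$ s_d \;=\; \frac{\lvert \{\, t \in T_d : t \text{ occurs in } V \,\} \rvert}{\lvert T_d \rvert} \in [0, 1]. $$

Three modelling commitments follow from the defining worked example (a
10-term list with 2 terms present scores 20%):

* **Presence, not frequency.** A term occurring fifty times counts once.
* **The lexicon is the denominator.** Adding terms to $T_d$ that a note
  does not contain strictly dilutes its score; scores are only comparable
  under a fixed lexicon.
* **Per-document scoring.** Each note is scored independently; no
  corpus-level vocabulary restriction is applied, which is the reading that
  reproduces the worked example exactly.

Multi-word terms match as contiguous token subsequences in order
("suicidal ideation" does not match "ideation … suicidal"). Terms of
different domains may overlap and match independently — with no stated
coupling between domain lists, independence is the only assumption-free
choice. Scores are carried as fractions everywhere; the $\times 100$
rescaling to percentage points happens only when scores enter regressions,
so odds ratios and slopes read "per percentage point of the domain score".
The scale factor is a single configurable argument (`scale = 100`).

## Text normalization and translation

Clinical notes arrive messy and, in the motivating setting, bilingual.
The pipeline fixes one normalization for both lexicon terms and documents
— NFKC Unicode normalization, casefolding, every character that is not a
letter/digit/internal apostrophe replaced by a space, whitespace collapsed
— applied once at lexicon load and once per document, so matching can be
exact string equality on tokens. The function is total and idempotent.
No stemming or lemmatization is applied: the score's denominator semantics
are defined on literal terms, and silent stemming would change them
invisibly.

Translation sits behind a provider contract (`translate(text)`,
deterministic within a run, `translate("") == ""`). The default provider is
the identity; a dictionary word-substitution stub supports testing
bilingual corpora. The pipeline always translates before matching, and
never calls a live machine-translation service — translation accuracy is a
property of the provider, not of this package.

## The analysis battery

All analyses run on an admission-level table (one row per admission); the
baseline characteristics table first collapses to one record per patient,
keeping the chronologically first admission (admission ids sort in
admission order; the collapse rule is configurable in the sense that any
pre-collapsed table is accepted).

* **Baseline table.** One-way ANOVA for continuous variables; Pearson
  chi-square homogeneity (no continuity correction) for binary ones. The
  test tradition in this literature names the "Cochran Q test" for the
  categorical rows, but Cochran's Q is defined for matched repeated-measures
  binary data; for independent groups the homogeneity chi-square is the
  defensible operational choice, and a literal `cochran_q()` is exported
  for genuinely matched layouts. Both give statistic 0 and $p = 1$ on
  identical groups.
* **Per-domain comparison.** One-way ANOVA per domain, then all three
  pairwise two-sample t tests, pooled-variance form, reported unadjusted
  (a Bonferroni option exists, off by default — raw post hoc p values are
  the convention being mirrored). Post hoc rows are emitted only when the
  omnibus ANOVA has $p < \alpha$; the gate can be disabled
  (`posthoc = "always"`), which is also what the type-I-error simulations
  use so that the t test is evaluated unconditionally.
* **Covariate OLS.** Per domain: $100\,s_d \sim \text{age} + \text{sex} +
  \text{CCI}$.
* **Logistic length-of-stay model.** Per diagnosis group: long stay
  ($>$ 3 days, strictly; a stay of exactly 3 days is short, matching the
  3-day involuntary-admission window the cutoff encodes) on the five scores
  in percentage points plus age, CCI and sex (female = 1, the majority
  class). Wald 95% CIs on the log-odds scale, exponentiated.
* **Secondary Cox model.** Per domain separately (not mutually adjusted):
  hazard of discharge on the domain score plus age, sex, CCI and diagnosis
  (depression reference), Efron ties. All stays end in discharge, so there
  is no censoring. HR $< 1$ means slower discharge, i.e. the domain is
  associated with longer stays — the sign convention is opposite to the
  logistic model's.

Standard fitting machinery is deliberately standard: `lm`, `glm`
(IRLS, relative log-likelihood tolerance $10^{-8}$, 100 iterations max) and
`survival::coxph`. The test suite cross-checks them against independent
brute-force oracles (closed-form normal equations; the 2×2 cross-product
ratio, which is the one-binary-predictor logistic MLE; a grid-searched
Efron partial likelihood).

Degenerate inputs are flagged, never silently dropped: zero-variance
continuous variables mark a baseline row degenerate; rank-deficient OLS
designs flag the affected model only; logistic fits report convergence and
a separation flag (fitted probabilities within $10^{-8}$ of 0/1); Cox fits
flag zero-variance scores. Repeat admissions are announced but regressions
are not cluster-adjusted — the design being mirrored did not adjust either,
and the warning makes the choice visible.

## The synthetic generator

The generator exists so that every stage has testable ground truth; its
defaults are the study conditions the package targets.

* **Structure.** 732 admissions over 571 patients in three groups
  (612/83/37 admissions; 465/73/33 patients). Surplus admissions are
  assigned to random patients of the same group, creating repeat
  admissions.
* **Scores.** Each of the $m$ terms of domain $d$ enters an admission's
  note independently with probability $p_{g,d}$, so
  $\mathbb{E}[s_d] = p_{g,d}$ exactly and
  $\mathrm{SD}(s_d) = \sqrt{p(1-p)/m}$ — the ground truth is analytic by
  construction. Default $p_{g,d}$ are the group score means reported for
  this kind of cohort (0.08–0.19); the default $m = 30$ terms per domain
  puts the score SDs in the observed 0.05–0.07 range. (In the source
  table the depression and schizophrenia columns of the cognitive row are
  inconsistent with their own post hoc directions; the defaults follow the
  post hoc directions: cognitive and social scores higher in schizophrenia
  and bipolar disorder, negative valence highest in depression.)
* **Coherence between cohort and notes.** The cohort generator realizes
  the per-term Bernoulli draws; the note generator plants exactly those
  realized terms, padded with filler words disjoint from the lexicon, in
  shuffled order with phrase tokens kept contiguous. Cohort scores and
  pipeline-recovered scores therefore agree exactly, which makes
  end-to-end tests deterministic rather than approximate. Marginally the
  notes still follow the stated independent-inclusion model.
* **Outcome.** A logistic model on the realized scores (percentage
  points) and covariates draws the binary long-stay outcome; default
  coefficients are the per-point odds ratios observed in the depression
  group of the motivating analysis (e.g. 1.058 for negative valence), with
  intercept 0.7 giving a ~70–75% long-stay fraction consistent with mean
  stays near 9 days. Durations are then drawn log-normally *within* outcome
  arm (short: $\text{LN}(\log 1.5, 0.45)$ rejection-sampled below 3 days;
  long: $3 + \text{LN}(1.69, 0.9)$), so the dichotomy carries the planted
  signal and the durations merely respect it. A short-stay distribution
  with almost no mass below the threshold is rejected as infeasible at
  spec-construction time.
* **Determinism.** One global seed; each stage (vocabulary, cohort, notes)
  derives a fixed substream seed from it, so stages regenerate
  independently and identical specs produce byte-identical output. The
  generator saves and restores the caller's RNG state.

What the generator does **not** emulate: real clinical language (notes are
bags of pseudo-words with planted terms), negation and uncertainty,
section structure, Korean morphology (the bilingual mode is an invertible
token-substitution stub), within-patient correlation of scores across
repeat admissions, and any coupling between demographics and scores.
Passing tests therefore demonstrate the pipeline's correctness and the
statistical machinery's calibration under the stated generating model —
not the clinical validity of lexicon scoring on real notes.

## Numerical and design choices

* Ties at the LOS threshold code short (strict `>`): the legal 3-day
  window the cutoff encodes is inclusive of day 3.
* Wald intervals throughout (z quantiles); at the sample sizes involved
  the difference from t/profile intervals is immaterial, and Wald is what
  odds-ratio tables in this literature report.
* Post hoc t tests assume equal variances (pooled); the Welch alternative
  is one flag away (`var_equal = FALSE`).
* Duplicate lexicon rows collapse silently with a warning (set
  semantics); an empty domain after normalization is an error.
* The five canonical domains are a constant, but arbitrary domain sets are
  accepted everywhere, so synthetic and future lexicons need no special
  casing.
* Simulation sizes in the test suite: 2,000 replicates at $n = 320$ for
  type-I error; 200 replicates at $n = 2{,}000$ (logistic), $n = 500$
  (OLS) and $n = 300$ (Cox) for coverage; 100 replicates for the
  logistic/Cox direction agreement; 5,000 notes for generator calibration.
  These sizes give Monte-Carlo standard errors comfortably inside the
  asserted bands (e.g. rejection-rate SE ≈ 0.005 at 2,000 replicates
  against a [0.03, 0.07] band).

## Limitations

Lexicon scoring is deliberately naive: no negation handling ("denies
suicidal ideation" scores), no weighting, no synonymy beyond what the term
list encodes. The package ships only synthetic demonstration lexicons; the
canonical term list must be supplied by the user in the documented CSV
format. Regression results on real cohorts inherit all the usual
observational caveats — the package reproduces the analysis, not causal
claims.
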