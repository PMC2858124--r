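---
title: "Scoring the additional therapeutic value of a new drug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the additional therapeutic value of a new drug}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evita)
```

## The problem

At market entry, a new drug rarely has the evidence base a full health
technology assessment needs, yet prescribers must decide whether it adds
anything to the established therapies for an indication. The EVITA rubric
answers that question early, from the handful of randomized controlled trials
(RCTs) available around approval, by pure table arithmetic: it attributes
positive points for demonstrated superiority and a cleaner adverse-event
profile, negative points for inferiority and a worse one, and declares the
question *not assessable* when no trial meets minimum standards — itself an
informative verdict about how the drug was developed. It is a horizon-scanning
screen, not a replacement for comprehensive assessment: there is no
meta-analytic pooling and no weighting of trials by methodological quality
beyond the eligibility cut-off.

An assessment is always of one drug in one indication, captured in an
*assessment dossier* (`read_dossier()`, `assessment_dossier()`): the
therapeutic context, the candidate trials, and one risk profile per arm.

## The pipeline

`evita()` runs four deterministic stages.

**1. Trial screening** (`filter_trials()`). A trial is eligible only if its
Jadad quality score (`compute_jadad()`; randomization, blinding, withdrawals;
0–5) is at least 3. Comparison against placebo alone is accepted only when no
established therapy exists; placebo *add-on* designs (both arms on top of the
established therapy) are always admissible. Trials that ran the identical
protocol are collapsed into one logical trial via a shared
`duplicate_protocol_key`. Finally, once patient-relevant evidence is present,
surrogate-outcome trials no longer count towards efficiency (they may still
have supplied the adverse-event data; that provenance is a dossier-level
matter). Every exclusion is recorded with a verbatim reason in the audit
trail and in all report formats.

**2. Trial setting** (`classify_trial_setting()`). The surviving evidence is
labelled **A** (patient-relevant outcomes: mortality, events, functionality,
symptoms, quality of life) or **B** (surrogate outcomes such as HbA1c or
depression scale scores), and **1** (head-to-head against established
therapy) or **2** (placebo comparison, direct or add-on). When both
head-to-head and placebo trials exist at the defining outcome level, the
head-to-head design dominates and the digit is 1, the stronger design. No
eligible trial means setting **NA** and the `not_assessable` band; nothing
numeric is produced.

**3. Efficiency** (`efficiency_score()`). Trials are counted by result
direction. With patient-relevant outcomes, superiority scores +5.0 (one
trial) or +7.5 (two or more) and inferiority the mirror negatives;
non-inferiority/equivalence trials attenuate whichever direction the other
trials establish (−1.67/−2.5 against superiority, +1.67/+2.5 against
inferiority, 0 with nothing to attenuate). Surrogate-level evidence halves
every magnitude. Internally the one-trial attenuation cells are the exact
fractions 5/3 and 5/6 so that the patient-relevant value is *exactly* twice
the surrogate value; the conventional printed forms 1.67 and 0.83 are their
roundings. A trial that merely *failed to show* superiority
(`no_significant_difference`) contributes zero — it is neither equivalence
nor inferiority. When superiority and inferiority evidence coexist (the
tables are silent on this), both contribute and the attenuation sign follows
the sign of their sum; with a zero sum the attenuation is zero.

The signed base sum is then multiplied by the strength-of-effect modifier
(`modifier_lookup()`) when the pivotal superiority evidence provides a number
needed to treat. The NNT is first annualized (`annualize_nnt()`), assuming
the absolute risk reduction accrues linearly, so an NNT of 2.6 observed over
1.5 years is 3.9 per year. Treatment aims use three bands (<3 → 2.0, 3–<10 →
1.5, ≥10 → 1.0); prevention aims use eight bands from 2.0 (<20/year) down to
0.25 (≥1000/year), so a weak preventive effect *shrinks* the score. Bands are
half-open with the printed lower bound included: an annualized NNT of exactly
10 under a treatment aim gives 1.0. When several superiority trials carry an
NNT we take the smallest annualized one as pivotal (the strongest
demonstrated effect; noted in the result). Without any NNT the sum is left
unmodified — the modifier also applies to negative sums, which is what makes
the −25 lower bound attainable. If only an ARR is recorded it is converted
as 1/ARR; when both are present they must agree within 5% (source rounding
tolerance).

**Rounding.** The published evaluations are inconsistent: one reports 3.75
rounded to +4.0, another reports −1.25 unrounded. Both behaviours are
therefore reproducible via the dossier option `rounding` ∈ {`none`,
`half_up_integer`}; the default is `none`, and half-up is implemented
symmetrically as round-half-away-from-zero.

**4. Risk** (`risk_score()`). Per arm, the *highest* single-adverse-event
frequency in each CTCAE severity group is banded into the product-label
frequency classes (`frequency_class()`: 0, <0.1%, 0.1–<1%, 1–<10%, ≥10%) and
penalized per `severity_points()` — down to −4.0 for very common grade-4/5
events, −2.5 for grade 3, −1.5 for grades 1–2 — plus an interaction-class
penalty (`interaction_points()`; absence of information costs −1.0, the same
as interactions requiring dose changes). The arm sum is bounded by −10. The
net score is `arm_sum(drug) − arm_sum(comparator)`, so a cleaner profile than
the comparator yields positive points. Resolution is deliberately the
frequency *class*, not the raw percentage: arms whose worst events fall in
the same class contribute nothing, which is the only reading consistent with
the published worked examples (a "slightly less frequent" same-class
difference did not score). Consequently a 9.9% vs 10.1% pair does straddle a
class edge and scores; no smoothing is applied, and assessors should be aware
of that knife edge.

**Combination.** `total = efficiency + net risk`, asserted to lie in
[−25, +25]. `score_bounds()` *derives* these bounds by exhaustively
enumerating every admissible table combination (all count categories at both
outcome levels × every modifier factor of both aims × all 625² ordered
risk-class pairs) rather than trusting a constant. The color band is
presentation only: published thresholds are qualitative ("values around
zero"), so the yellow band half-width is configurable with default 2.0
points, which keeps both of the ambiguous published cases (−1.0 and −1.25)
yellow; the band never alters the numeric score. Therapeutic aim and disease
severity category (I–IV) annotate every report but never enter the
arithmetic — aim selects the modifier table, category is documentation only.

## Worked example

```{r example}
res <- evita(read_dossier(evita_fixture("lenalidomide_mm")))
summary(res)
```

The four bundled dossiers (`evita_fixture()`) encode the published drug
evaluations — lenalidomide (+6.0, A2), pioglitazone on 2001 evidence (+3.0,
B2) and on 2005 evidence (−1.0, A2), bupropion (−1.25, B1), zoledronic acid
(N/A) — and serve as end-to-end regressions in the test suite.

## The synthetic-dossier generator

`synthetic_dossier(seed, n_trials)` produces structurally valid random
dossiers: every enum literal of every field is drawn with positive
probability, including trials destined for exclusion (low Jadad, pure
placebo despite established therapy, twin protocols) and exact-zero
adverse-event frequencies. It emulates the *shape* of real dossiers, not
their epidemiology: field values are drawn independently (e.g. result
direction is independent of comparator kind, and NNT is independent of the
result), so generated dossiers exercise every code path and the bounds
property (10,000 seeds in the test suite stay within [−25, +25]) but say
nothing about realistic score distributions. Real assessments also involve
judgement the generator cannot emulate — outcome-level adjudication, NNT
provenance from secondary outcomes, GCP exclusions — which enter the dossier
as assessor-recorded fields (`exclusion_note`, the chosen `nnt`).

## Numerical and design choices

- Twin-protocol collapse keeps the *first* record in list order (the dossier
  schema carries no sample-size field to prefer "larger" evidence by); the
  collapsed-away record is audited as `"duplicate protocol"`.
- Validation tolerance between a recorded NNT and ARR is 5% relative, to
  absorb rounding in source publications.
- Frequencies are canonically percentages; named classes in dossier files are
  converted on load to anchor percents strictly inside their class
  (0, 0.05, 0.5, 5, 30).
- Jadad scores are clamped at 0; the clamp is unreachable territory for the
  ≥3 eligibility cut-off.
- The score-bound assertion in `combine_scores()` uses a 1e-9 slack purely
  against floating-point drift; all table values are exact binary fractions
  except 5/3 and 5/6.
- Problem sizes in the test suite (exhaustive 625² risk pairs, 10,000
  generator seeds, 400-seed enum coverage) were chosen so the whole suite
  enumerates every discrete case of the tables while completing in well under
  a minute.

## Limitations

Everything upstream of the dossier is out of scope: literature retrieval,
critical appraisal of real publications, parsing product labels, and NNT
computation from raw event tables. The rubric itself inherits the published
method's limits — no pooling, no quality weighting above the cut-off, and a
class-resolution risk comparison that ignores within-class differences.
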