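# evita

Early evaluation of the additional therapeutic value of a new drug in one
approved indication, from randomized-controlled-trial (RCT) evidence. The
package is aimed at clinical pharmacologists, horizon-scanning / early-HTA
groups and drug-bulletin editors who need a fast, transparent, fully
auditable screen of whether a newly approved compound adds anything to the
established therapies for an indication — not a replacement for a full
health technology assessment.

## The scoring rubric

An assessment of a drug–indication pair proceeds in four deterministic
stages, all pure table arithmetic:

1. **Eligibility.** An RCT is scored only if its Jadad quality score
   (randomization, blinding, withdrawals; 0–5) is ≥ 3. Placebo as sole
   comparator is accepted only when no established therapy exists, or in an
   *add-on* design. Twin-protocol trials collapse into one logical trial.
   Every exclusion is logged with its reason.
2. **Trial setting.** The evidence is classified A1/A2/B1/B2 or N/A:
   **A** = patient-relevant outcomes, **B** = surrogate outcomes only;
   **1** = head-to-head vs established therapy, **2** = placebo comparison.
   Patient-relevant evidence supersedes surrogate trials. No eligible trial
   ⇒ **N/A**, an explicit verdict rendered as a yield sign.
3. **Efficiency score.** Base points by result direction and trial count
   (superiority +5.0 / +7.5 for 1 / ≥2 patient-relevant trials, inferiority
   the mirror negatives, non-inferiority/equivalence attenuating either
   direction; all magnitudes halved for surrogate outcomes), multiplied by a
   strength modifier from the annualized number needed to treat:

   | aim | NNT/year | modifier |
   |---|---|---|
   | treatment | <3 / 3–<10 / ≥10 | 2.0 / 1.5 / 1.0 |
   | prevention | <20 … ≥1000 (8 bands) | 2.0 … 0.25 |

4. **Risk score.** Per arm, the worst single adverse-event frequency in each
   CTCAE severity group (grades 4+5, grade 3, grades 1+2) is banded into
   label frequency classes (0, <0.1%, 0.1–<1%, 1–<10%, ≥10%) and penalized
   (down to −4.0 / −2.5 / −1.5), plus an interaction penalty (0 to −2.0);
   the net risk is `arm_sum(drug) − arm_sum(comparator)`, so a cleaner
   profile than the comparator scores positive.

`total = efficiency + net risk ∈ [−25, +25]` (bounds derived by exhaustive
enumeration, `score_bounds()`), presented as a green / yellow / red bar.
Therapeutic aim and disease category (I–IV) annotate the report; the category
never enters the arithmetic.

## Worked example

```r
library(evita)
res <- evita(read_dossier(evita_fixture("lenalidomide_mm")))
summary(res)
#> EVITA assessment: lenalidomide - Refractory or relapsing multiple myeloma (ICD-10: C90)
#>   aim treatment | disease category I | trial setting A2
#>   efficiency +7.5 | risk -1.5 | total +6 [green]
#> Excluded trials:
#>   - MM-010: duplicate protocol
#> Included trials: MM-009
#> Efficiency: 7.5 point(s) [patient_relevant outcomes; 1 sup / 0 non-inf / 0 inf; base 5, modifier 1.50]
#>   note: modifier 1.50 from annualized NNT 3.9 (treatment aim)
#> Risk: -1.5 point(s) [lenalidomide + dexamethasone -8.5 vs placebo + dexamethasone -7]
```

The two twin-protocol registration trials count as one logical
patient-relevant superiority trial (+5.0 base points); its NNT of 2.6 over
1.5 years annualizes to 3.9/year, modifier 1.5, efficiency +7.5. Both arms
share identical adverse-event frequency classes, so the net risk is exactly
the interaction difference (−1.5). Total +6.0: a likely innovation (green).

Four published drug evaluations ship as dossier fixtures —
`evita_fixture()` lists them — covering a positive score, a score revised
downward by later patient-relevant evidence, a negative score, and an N/A
verdict. `synthetic_dossier(seed, n_trials)` generates random valid dossiers
for property testing, and a command line is available:

```sh
Rscript inst/cli/evita.R score inst/extdata/bupropion_depression.yaml --format svg -o report.svg
Rscript inst/cli/evita.R synth --seed 7 --trials 3 -o dossier.yaml
Rscript inst/cli/evita.R bounds
```

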