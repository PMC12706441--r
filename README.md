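# surveyfraud

Screening incentivized web-based survey responses for fraud.

Web surveys recruited through a generic shareable link, especially with a
financial incentive, attract fraudulent responses from bots, duplicating
respondents, and humans misrepresenting their eligibility. When fraud is
discovered mid-recruitment, study teams need a defensible, reproducible
way to remove fraudulent records afterwards. `surveyfraud` implements
that tertiary-prevention stage for researchers and analysts cleaning
fraud-affected survey exports:

* a **criteria engine** awarding signed *fraud points* — negative for
  protective evidence (sensical free text, not requesting remuneration,
  submission before the fraud-onset date), positive for suspicious
  evidence (honeypot hits, low CAPTCHA scores, nonsensical answer
  combinations, pattern-based emails, sub-threshold completion times,
  duplicate and batch submissions, repeated screening attempts);
* **control-based calibration**: respondents with trusted institutional
  email domains act as negative controls and those with suspicious
  pattern emails as positive controls; per-criterion sensitivity and
  specificity are tabulated on them and include/exclude score cut points
  selected against targets (default min specificity 0.99, min
  sensitivity 0.90);
* **three-bucket classification** with rule-based resolution of the
  review bucket, a categorical low/medium/high risk profile with a
  sensitivity-analysis split, and stage-by-stage **dataset accounting**;
* a seeded **synthetic cohort generator** emulating the four respondent
  archetypes (genuine, duplicator, misrepresenter, bot) with batch
  waves, a fraud-onset date, identifier realism and latent free-text
  plausibility, so the whole pipeline is testable without any real
  survey data.

A record's total score is the sum of fired criterion weights,
`S_i = sum_c w_c 1[c fires on i]`; records with `S <= t_low` are
included, `S >= t_high` excluded, and the midrange reviewed. No single
criterion decides a record.

## Worked example

```r
library(surveyfraud)

ds <- generate_cohort(cohort_preset("case1_like_separable",
                                    n_records = 1000, seed = 42))
fit <- suppressWarnings(fraud_screen(ds))
fit
#> Survey fraud screen
#> started 1000 | cleaning -30 -> scored 970 | fraud -377 (38.9%) -> included 593 (59.3% of started)
#> score thresholds: include <= 5 < review < 5 <= exclude (degenerate)
#> buckets: INCLUDE=593 REVIEW=0 EXCLUDE=377
#> vs truth: sensitivity 0.967, specificity 0.998
```

Reading the output: of 1000 respondents, 30 duplicate entries were
removed during data cleaning, 970 were scored,
and 377 were removed by the fraud score, leaving 593 included. The cut
points collapsed to a single cut at 5 points — on well-separated
controls the review band is often empty — and, because this is a
labelled synthetic cohort, the final decisions can be compared with the
truth archetypes: 96.7% of fraudulent records were removed and 99.8% of
genuine records kept.

The calibration table shows each criterion's performance on the
email-rule controls (protective criteria are scored with inverted
polarity, so sensitivity always measures fraud detection):

```r
head(as.data.frame(summary(fit)$calibration), 6)
#>           criterion  direction points  TP  FP  TN  FN sensitivity specificity
#> 1 freetext_sensical protective     -3 377   0 199   0   1.0000000   1.0000000
#> 2   no_remuneration protective     -1 377 160  39   0   1.0000000   0.1959799
#> 3         pre_onset protective     -2 352 100  99  25   0.9336870   0.4974874
#> 4    nonsense_combo suspicious      3 377   0 199   0   1.0000000   1.0000000
#> 5        post_onset suspicious      1 352 100  99  25   0.9336870   0.4974874
#> 6          honeypot suspicious      4 271   0 199 106   0.7188329   1.0000000

coef(fit)   # the signed fraud-point weights
plot(fit)   # score histogram with the include/exclude cuts
predict(fit, new_dataset)  # score a new export with the fitted cuts
```

Everything is also drivable from a YAML config:

```r
run_pipeline(list(cohort = list(preset = "case1_like", n_records = 2000,
                                seed = 7),
                  criteria = "case1", out_dir = "screening-run"))
```

which writes `decisions.csv`, `calibration.csv`, `accounting.csv`, and a
`run.log` recording every removal with a machine-readable reason.

Accounting arithmetic is exposed directly:

```r
account(1050, 135, 415)
#> started 1050 | cleaning -135 -> scored 915 | fraud -415 (45.4%) -> included 500 (47.6% of started)
proportion_report(2547, 5598)
#> [1] 45.5
```

See `vignette("fraud-screening")` for the model, its assumptions, the
generator's design, and known limitations.

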