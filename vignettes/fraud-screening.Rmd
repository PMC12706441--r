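---
title: "Screening web-based survey responses for fraud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening web-based survey responses for fraud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyfraud)
```

## The problem

Incentivized web-based surveys recruited through a generic shareable link
are attractive targets for fraud. Fraudulent respondents fall into four
broad archetypes: **genuine** eligible respondents; eligible
**duplicators** who re-enter to collect the incentive again;
**misrepresenters**, humans who fake eligibility; and **bots**. After
fraud is detected mid-recruitment, study teams face a tertiary problem:
removing fraudulent records from an already-collected dataset while
keeping as many valid respondents as possible.

`surveyfraud` implements that tertiary stage as a reproducible pipeline:
a criteria engine awarding signed *fraud points*, control-based
calibration of per-criterion sensitivity and specificity, score cut-point
selection into include/exclude/review buckets, rule-based resolution of
the review bucket, and stage-by-stage accounting. A seeded synthetic
cohort generator supplies labelled data for validation, since real
fraud-affected survey exports cannot be shared.

## The scoring model

Each criterion $c$ has a direction and a signed weight $w_c$: protective
criteria (plausible free text, not requesting remuneration, submission
before the fraud-onset date) carry $w_c < 0$; suspicious criteria
(honeypot hits, low CAPTCHA scores, nonsensical answer combinations,
pattern-based email addresses, sub-threshold completion times, duplicate
and batch submissions, repeated screening attempts) carry $w_c > 0$.
Larger magnitudes encode stronger assumed predictive value. A record's
total score is

$$S_i = \sum_{c} w_c \, \mathbf{1}[\text{criterion } c \text{ fires on record } i],$$

and no single criterion decides inclusion. Records with
$S_i \le t_{\mathrm{low}}$ are included, $S_i \ge t_{\mathrm{high}}$
excluded, and the midrange marked for review. Review records are resolved
by the same rules a manual review applies: protective free text with no
nonsensical combination includes; any violation or duplicate flag
excludes; anything else falls to a configurable default (exclude, the
conservative choice, since a possibly-valid respondent is cheaper to lose
than a fraudulent one is to keep).

### Calibration on controls

Respondents with known institutional email domains are designated
*negative controls* (assumed genuine), and those with highly suspicious
pattern-based emails *positive controls* (assumed fraudulent). Each
criterion's sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$ are
tabulated on the controls; for protective criteria the polarity is
inverted (not firing is the positive test) so sensitivity always measures
fraud detection. The cut points are then chosen against targets:
$t_{\mathrm{high}}$ is the smallest observed score keeping the fraction
of negative controls at or above it within $1-\text{min specificity}$,
and $t_{\mathrm{low}}$ the largest observed score keeping the fraction of
positive controls at or below it within $1-\text{min sensitivity}$.
Default targets are min specificity 0.99 and min sensitivity 0.90,
consistent with per-criterion performance in the high-90s being
attainable on well-separated controls. Candidate cuts are restricted to
observed scores; when no observed score satisfies a constraint, or the
two cuts cross, the selection is *degenerate*: the cuts collapse (to
their midpoint when crossing) and a warning is emitted. On well-separated
data a collapsed single cut is common and harmless — the review band is
simply empty.

Boundary conventions, none of which are forced by the procedure itself,
are fixed as: the include band is closed at $t_{\mathrm{low}}$, the
exclude band closed at $t_{\mathrm{high}}$; a submission at exactly the
fraud-onset instant counts as on/after (suspicious); completion-time and
CAPTCHA flags are strict inequalities, so a record at exactly the
threshold does not fire.

## Operationalized criteria

Two criteria replace what study teams do by eye:

* **Suspicious email patterns.** Fraudster emails are described
  qualitatively as "mostly numbers" or having "no relationship with the
  respondent's name", often "switching between numbers and letters". The
  flag fires when the digit fraction of the local part exceeds 0.5, or
  when no case-insensitive substring of length ≥ 3 is shared between the
  local part and the name tokens/initials *and* the local part has at
  least 3 digit-run/letter-run alternations. All three constants are
  parameters.
* **Sensical free text.** Manual judgment of free-text plausibility is
  proxied by token count (≥ 5), dictionary-word ratio (≥ 0.6), and the
  absence of verbatim duplication of the same answer in another record.
  The proxy is validated against the generator's latent plausibility
  labels, where it recovers them with ≥ 95% agreement.

The Case-style categorical profile (`categorize_risk()`) formalizes a
qualitative team judgment over six screening signals, three of which
(repeated screening attempts, high gift-card interest, screening
inconsistency) are high-weight: any high-weight signal plus a second
signal (or two high-weight signals) is *high* likelihood; two or more
signals otherwise is *medium*; else *low*. High-likelihood records are
dropped; the medium band is carried as a sensitivity-analysis split
(`sensitivity_split()`), analyses being run with and without it.

## The synthetic cohort generator

No deposited fraud-affected survey dataset exists, so the generator is a
first-class module, not a test fixture. It emulates:

* archetype mixing with configurable prevalence (default 55% genuine /
  45% fraudulent, matching the removal fraction a heavily-hit anonymized
  survey can face; other presets use lighter fraud loads);
* a recruitment window with a fraud-onset instant part-way through
  (default 53% of a 183-day window), after which bots concentrate;
* completion times: log-normal for humans (genuine median 900 s,
  $\sigma = 0.5$ for a long survey; 720 s and 1100 s medians in the
  short-survey and patient-survey presets) and uniform 30–300 s for
  bots — chosen so that the 300 s and 800 s minimum-time screens used in
  practice discriminate well;
* duplicator identity groups of 2–4 entries sharing email, phone, and
  name;
* bot submission waves: batches of tightly spaced submissions (gaps
  bounded by a window parameter) sharing an IP address, plus
  `inject_fraud_wave()` for appending a same-account influx of arbitrary
  size;
* identifier realism: name-concordant emails (some on trusted
  institutional domains, which later become negative-control candidates)
  versus digit-heavy or letter/digit-alternating pattern emails (later
  positive-control candidates);
* free text as a latent plausibility label plus surface text — dictionary
  sentences when plausible, empty/repeated/garbage tokens when not — so
  the free-text evaluator can be scored against the latent label;
* platform signals: honeypot values, Beta-distributed CAPTCHA scores
  (occasionally missing), screening-attempt counts, a remuneration
  request flag, and an externally supplied registry-verification boolean
  (registry lookup itself is out of scope and modelled only as that
  flag).

Generation is a pure function of the config, including its seed: the same
config yields byte-identical datasets, and the caller's RNG stream is
left untouched.

The `case1_like_separable` preset keeps the 55/45 shape but pushes the
signal probabilities to their extremes (bots always trip the honeypot,
genuine respondents never; email concordance and free-text plausibility 1
for genuine and 0 for fraudulent archetypes; misrepresenters always carry
an inconsistent answer combination). It exists to validate *recovery*:
when the signals truly separate the archetypes, the end-to-end pipeline
should find them. On 2000-record separable cohorts the pipeline reaches
sensitivity ≈ 0.94–0.96 and specificity ≥ 0.99 against the truth labels;
the residual misses are dominated by the first entries of duplicator
groups, which are genuinely indistinguishable from valid respondents
(their later entries are removed as duplicates, which is the correct
action record-wise). What passing these tests does *not* show is
performance on real data, where signals are weaker, correlated, and
adversarial; the semi-realistic `case1_like` preset (probabilities
strictly inside (0, 1)) gives a more sobering picture and is the default.

## Numerical and design choices

* **Percentages** are rounded half-up to one decimal everywhere
  (`proportion_report()`, accounting); R's banker's rounding is not used.
  Accounting targets the count identities (started − cleaning = scored;
  scored − fraud-removed = included), and percentages always recompute
  from counts.
* **Duplicate matching** lowercases and strips whitespace, treats missing
  or empty identifiers as never matching, merges groups transitively
  across keys, and retains the earliest-started record of each group.
* **Ties** in cut-point selection resolve toward the stricter
  (higher-specificity) side, since the smallest satisfying score is
  taken for the exclude cut.
* **Cleaning versus fraud removal** are logged separately: structural
  invalidity and duplicate entries are cleaning removals; score-based
  exclusions are fraud removals. Every removed record appears exactly
  once in the run log with a machine-readable reason.
* **Degenerate inputs**: an unset fraud-onset date leaves the onset
  criteria inert (with a one-time message) rather than erroneous; a
  missing email cannot fire the pattern flag or enter the controls;
  undefined sensitivity/specificity ratios are reported as `NA`, not 0.
* Validation problem sizes (600–2000 records for end-to-end runs, ≤ 200
  for the quadratic-oracle comparisons, 1000 random instances for
  tabulation checks) are chosen so that the full suite runs in under a
  minute while keeping binomial checks at 3-standard-deviation
  resolution.

## Known limitations

The free-text proxy shares its dictionary with the generator, so its
validated agreement is an internal-consistency result, not evidence it
would grade real clinical prose. Control designation from email rules
mislabels genuine respondents with odd email habits; the calibration
tables inherit that noise, exactly as a real pilot would. The Case-style
six-signal categorization encodes one team's qualitative weighting and is
configurable rather than canonical. Registry verification, phone
verification, and IP geolocation are consumed as given booleans or
fields, never performed.

## A worked run

```{r example, eval = FALSE}
ds <- generate_cohort(cohort_preset("case1_like_separable",
                                    n_records = 1000, seed = 42))
fit <- suppressWarnings(fraud_screen(ds))
fit
summary(fit)
coef(fit)
plot(fit)

# apply the fitted thresholds to a new export
new_ds <- generate_cohort(cohort_preset("case1_like_separable",
                                        n_records = 200, seed = 43))
head(predict(fit, new_ds))
```

The same run, driven from a YAML config with artifacts on disk:

```{r pipeline, eval = FALSE}
cfg <- list(cohort = list(preset = "case1_like_separable",
                          n_records = 1000, seed = 42),
            criteria = "case1", out_dir = "screening-run")
fit <- run_pipeline(cfg)
list.files("screening-run")
#> decisions.csv  calibration.csv  accounting.csv  run.log
```
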