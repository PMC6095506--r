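---
title: "Validating an EPR-derived neonatal registry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an EPR-derived neonatal registry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neovalid)
```

This vignette is the package's account of its statistical methods and the
design decisions behind them: what is computed, under what assumptions,
which knobs matter, and what the synthetic cohort does and does not
emulate. It states no empirical results beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The audit model

Two databases describe the same infants. The *gold* database plays the
role of a trial's clinical-record-form data: complete infant
characteristics, one row per episode of care, and a daily grid of care
flags. The *registry* (EPR extract) is keyed by an opaque identifier and
holds the same three tables, but is subject to the error phenomena the
audit is designed to measure: values that were never entered, categorical
entry errors, day counts that drift when derived from daily data,
identifiers that cannot be supplied, and episodes absent from the extract.

The audit estimates, per compared item, the probability that the two
databases disagree beyond a preset tolerance (the *discordancy rate*), and
for binary items the standard diagnostic-accuracy operating
characteristics with the gold value as truth. Items are compared at the
level at which they are recorded: day counts within an episode of care at
episode level, everything else per infant over the whole hospitalisation.
Pairs with a missing value on either side are excluded from the
denominator — missingness is reported separately, never counted as
disagreement.

## Tolerance bands

`default_rules()` carries one rule per compared item (16 characteristics,
17 processes, 11 outcomes). Banded kinds grade the absolute difference;
categorical kinds make any difference major:

* care-day counts and length of stay: ≤2 days agree, 3–4 minor, ≥5 major;
* expected date of delivery (EDD) and gestational age (in days):
  ≤2 agree, 3–6 minor, ≥7 major;
* day of first milk: 0 agree, 1 minor, ≥2 major;
* antibiotic/antacid days in the first 14 days: 0 agree, 1–2 minor,
  >2 major;
* binary, categorical and set-valued items (including milk-type sets,
  month/year fields, ethnicity, area code): any difference major.

Two bands are not fixed by convention and were set once as package
defaults: birth weight (≤10 g agree, ≤100 g minor) and the 5-minute Apgar
(exact agree, ±1 minor). All bands are data — edit the tibble or
round-trip it through `write_rules()`/`read_rules()` to audit under a
different protocol.

## Interval methods

Discordancy rates switch interval method on the point estimate, per
interval computed: below 5% the *Poisson approximation to the binomial* —
the exact gamma-quantile interval for the discordant count $k$,
$[\,q_{\Gamma}(\alpha/2;\,k),\; q_{\Gamma}(1-\alpha/2;\,k+1)\,]/n$, with
lower bound 0 at $k=0$ — and at or above 5% the Agresti–Coull interval
($\tilde n = n + z^2$, $\tilde p = (k + z^2/2)/\tilde n$,
$\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}$), which has better
coverage for moderate proportions. Diagnostic-accuracy metrics and
prevalences use exact Clopper–Pearson intervals via beta quantiles. The
test suite pins all three to independent bisection oracles on the
binomial and Poisson tail probabilities over every $k \le n \le 200$, and
checks the Bayes identity
$\mathrm{PPV} = \mathrm{sens}\cdot\pi \,/\,
[\mathrm{sens}\cdot\pi + (1-\mathrm{spec})(1-\pi)]$ on random tables.

Whether a study's 5% switch keys on the any- or the major-discordancy
rate is ambiguous when only one is published; the package applies the
switch to whichever rate the interval is being computed for.

Report formatting rounds rates and bounds to one decimal place, except
bounds below 0.1%, which keep two decimals so a small but positive lower
bound is not flattened to zero. Undefined quantities (zero denominators)
are explicit markers, never 0 or 100.

## Derivation rules

* Postnatal day 1 is the date of birth; the feeding/medication window is
  days 1–14 inclusive.
* Gestational age is derived from the EDD where both dates are present:
  $\mathrm{GA} = 280 - (\mathrm{edd} - \mathrm{birth})$ days, reported as
  completed weeks plus days; otherwise the recorded weeks + days are used.
* The 36-week postmenstrual-age assessment day is `edd - 28` days —
  computed from the date, not from rounded completed weeks, to avoid
  truncation error. An infant discharged or dead before that day is not
  assessable; an infant in care whose daily record is absent or flagged
  missing gets the distinct status `missing_record`. How the published
  denominator for this item was determined is not derivable from a report
  alone, so both policies are exposed (`"in_care"`, the default, and
  `"any_record"`).
* First-feed fields are comparable only when no missing daily record
  precedes the first observed feed; infants with no observed feed in the
  window are excluded from the first-feed items. The 14-day milk summary
  is the union over non-missing days.
* The registry's care-level categorisation is produced by unpublished
  embedded logic in the source system; only day counts per category are
  compared, so what matters is that one explicit rule is applied
  identically to both databases. The default
  (`default_care_rule()`): mechanical support ⇒ intensive; otherwise
  oxygen or central line ⇒ high dependency; otherwise special. The rule is
  a plain function argument.
* Missing daily records are explicit flags and never silently imputed as
  "no care given": a missing day can mask a feed but can never contribute
  to a day count.
* Infant-level composites: any-true for binary items, sums for day
  counts, maximum for worst-grade ordinals, and survival from the final
  episode's discharge-alive flag (a death followed by a further episode
  is rejected as a data error).

## Linkage design

Infants link through the opaque registry identifier only — no fuzzy
matching on names or dates, mirroring how such registries are actually
keyed. Episode matching is an order-preserving maximum matching (a small
dynamic programme) under the compatibility relation "same canonical unit
code and admission dates within ±1 day" — units are matched on codes, not
free-text names, because free text is exactly where real linkage failed.
The default tolerance of ±1 day reflects that stored admission dates are
compared directly; raising the tolerance can only grow the matching.
An infant with any unmatched gold episode is wholly excluded (analyses
need the complete hospitalisation), with a reason code:
`inconsistent_dates` when a same-unit candidate fell outside the window
(or episodes overlap within one database), `inconsistent_hospital` when
only differently-coded units remain, `missing_episode` when the registry
has no candidate. Attribution between those codes is a documented
heuristic; whether a real study's post-identifier exclusions were
automatic or manual is typically unknowable, so here they are
deterministic rules.

## The synthetic cohort and its error model

`generate_cohort()` emulates a very preterm multi-centre cohort:

* defaults of 1310 infants across 24 units, gestational age 23+0–31+6
  completed weeks (weighted towards the upper weeks), recruited over a
  37-month window — the scale of a realistic multi-centre trial;
* episode pathways of 1 + Geometric(transfer) episodes truncated at 4,
  with return transfers (A→B→A) allowed; the default transfer probability
  0.47 yields about 1.8 episodes per infant;
* outcome prevalences defaulting to a realistic very-preterm profile
  (survival 92.1%, oxygen at 36 weeks 49% of assessable infants, medical
  PDA treatment 20.3%, rarer surgical/cranial outcomes 1.9–5.8%), drawn
  independently given a gestational-age stratum (relative risk 2 below 28
  weeks, marginal equal to the configured prevalence) — outcomes are
  analysed marginally, so no richer dependence is modelled. Survival
  gates everything discharge-based: non-survivors die early (exponential,
  mean 20 days) and their final episode ends in death;
* survivors go home around 37.0 ± 1.5 weeks postmenstrual age, so
  roughly 70% of infants are still in care on the 36-week assessment day;
* day-count variables are never sampled directly: antibiotics, lines,
  oxygen, ventilation and feeds are generated as runs of flag-days in the
  daily grid and *derived* back out, so the derivation code paths are
  always exercised, and the 36-week flags are pinned to the drawn outcome
  for infants still in care.

`make_epr_twin()` copies the gold cohort, re-keys it, and injects error
per an `error_model()`, logging every perturbed cell in a truth log:
blanked values (optionally per centre, so centre-level completeness
profiles have real variation), categorical swaps and binary flips, day
jitter, unlinkable infants, and dropped episodes. Day jitter on count
variables edits the underlying daily grid — flag-days are added or removed
at the boundary of the existing run, clamped to the episode or window —
so the *derived* count moves by the sampled offset and the comparison
still flows through the derivation code. Where the grid cannot absorb the
full offset the truth log records the achieved offset; recovery
experiments that need an exactly unbiased channel therefore use
unconstrained targets (date shifts, binary flips, blanking), and the
clamped channels are validated cell-by-cell against the truth log
instead.

What the simulator does **not** emulate: real entry-screen behaviour
(e.g. the asymmetry of "no negative entry required" designs, which turns
absence into apparent negatives rather than missing values), free-text
diagnoses, payment categories, seasonal or centre-level practice
variation in care itself, and correlated multi-variable error. Passing
tests on the twin therefore demonstrate that the pipeline measures what
was injected — not that any particular real registry has these error
rates.

## Calibration: recovery of injected error

The package's core self-check is that injected probabilities come back
out of the full pipeline. `recovery_experiment()` perturbs a fixed gold
cohort repeatedly, runs linkage → derivation → concordance each time, and
recovers: a misclassification probability as the item's major-discordancy
proportion; a jitter distribution's tail mass as the same (when the
offsets lie wholly beyond the major band); a missingness probability as
the fraction of linked pairs with the registry value blank. The
acceptance suite runs 100 replicates at 1258 infants with injected
probabilities 0.02 (blanked Apgar), 0.05 (flipped hydrocephalus) and 0.10
(EDD shifted ≥7 days) and requires each replicate-mean to sit within 3
Monte-Carlo standard errors (`sd/√R`) of the injected value. These sizes
are the package's chosen study conditions, matching the scale at which
such audits are actually conducted.

## Numerical choices

* Quartiles of per-centre missingness use linear interpolation between
  order statistics (`stats::quantile` type 7), stated because plotting
  conventions differ.
* Zero variance in limits-of-agreement collapses the limits onto the mean
  (identical data is agreement, not an error).
* The episode-matching DP breaks ties toward the diagonal (pairing), so
  equal-score traces prefer more matches earlier.
* Interval bounds are clipped to [0, 1] before scaling to percent.
* All randomness flows through a single seeded RNG stream; the seed is
  recorded in cohort metadata and the pipeline's `metadata.json`, next to
  a hash of the full configuration. Identical configuration and seed
  reproduce every output byte-for-byte.

## Limitations

Tolerance-band tables for a given real study are protocol documents; the
defaults here encode the widely used band structure but must be replaced
by the study's own supplement to reproduce its numbers exactly. The
reason-code attribution for unmatched episodes is heuristic. Population
coverage against national birth statistics requires external
denominators; only the ratio computation (`coverage_ratio()`) is
provided. And the simulator's independence assumptions (outcomes given
gestational-age stratum, error channels given variable) are conveniences:
real registry errors cluster by unit, clinician and screen design in ways
no marginal error model captures.
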