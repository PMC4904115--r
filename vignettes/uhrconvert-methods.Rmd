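---
title: "Comparing and converting UHR diagnostic interviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and converting UHR diagnostic interviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhrconvert)
```

## The problem

Services for people at ultra high risk (UHR) of psychosis use two partly
incompatible structured interviews. The CAARMS 12/2006 rates four positive
subscales (P1 Unusual Thought Content, P2 Non-Bizarre Ideas, P3 Perceptual
Abnormalities, P4 Disorganized Speech) on 0–6 severity and 0–6 frequency
scales; the SIPS 5.0 rates five (P1 Unusual Thought Content/Delusional
Ideas, P2 Suspiciousness, P3 Grandiose Ideas, P4 Perceptual Abnormalities,
P5 Disorganized Communication) on 0–6 severity and a coarser frequency
scale (printed anchors 1–3; this package adds 0 for "below the lowest
anchor", which must be representable). Both assign one of three outcomes —
UHR−, UHR+ (subgroups GRD, APS, BLIPS/BIPS) and Psychosis — but the
operational criteria differ in ways that matter for individual patients.
This package implements both rule engines, a pragmatic case-conversion
algorithm between them, the agreement statistics used to compare them, and
equipercentile linking of their score scales.

## The rule engines

Each classifier evaluates the printed criteria in a fixed precedence:
Psychosis, then BLIPS/BIPS, APS, GRD, else UHR−. Every subject receives
exactly one primary outcome; all subgroups whose criteria pass are reported
(`subgroups_met`), with the primary subgroup label taking precedence
BLIPS > APS > GRD, since a subject can meet several subgroups at once.
Key operational choices, each recorded in the per-subject `rule_trace`:

- **Pairing.** Severity and qualifying frequency must be met on the *same*
  subscale. The alternative reading (any severity plus any frequency
  anywhere) is clinically incoherent and would make the CAARMS
  subthreshold-frequency APS path (psychotic intensity with frequency
  exactly 3) redundant.
- **CAARMS psychosis.** Psychotic-intensity severity (6 on P1/P2/P4, 5–6 on
  P3) with paired frequency 4–6, lasting more than 7 days *or* not
  resolving without antipsychotics, or any previous psychotic episode. A
  psychotic-intensity episode within the 7-day cap that did not resolve
  spontaneously cannot be BLIPS (spontaneous resolution is a BLIPS
  inclusion) and no other category can hold it, so it is classified
  Psychosis.
- **SIPS psychosis (POPS).** Severity 6 with paired frequency 3, or
  severity 6 with the urgency criterion — seriously disorganizing or
  dangerous symptoms rule in psychosis no matter what the duration.
  Whether urgency alone should rule in psychosis below severity 6 is not
  decidable from the printed criteria; we require severity 6, as the
  urgency row is attached to the psychotic-intensity threshold.
- **Frequency minima.** The SIPS APS anchor "frequency score of 2" and BIPS
  "frequency score of 1" are read as minimum qualifying frequencies, with
  POPS (frequency 3) taking precedence; a literal equality reading would
  leave severity-6/frequency-2 cases unclassifiable.
- **Gates.** CAARMS: onset within 12 months, symptoms no older than 5
  years, the SOFAS criterion for *all three* subgroups, and the
  peak-intoxication substance exclusion. SIPS: no functioning requirement
  for APS/BIPS; APS needs recency (onset within a year or a one-point
  escalation) plus presence over the past month; the comorbidity exclusion
  applies to APS/BIPS only, never POPS or GRD; substance-intertwined flags
  are per subscale, disqualifying that subscale only. The BIPS duration cap
  of "up to 3 months" is operationalized as 91 days.
- **The 30% functioning drop** is inclusive: current ≤ 0.70 × reference on
  the raw 0–100 scale (SOFAS from premorbid level; GAF over the last month
  versus 12 months before). A reference score of 0 makes a proportional
  drop undefined; the criterion evaluates false with a warning.
- **Unknowns.** Missing flags parse to "unknown". Classifiers rule in only
  on positive evidence: unknown exclusion flags do not trigger exclusions,
  unknown inclusion requirements do not satisfy inclusions, and each such
  assumption is appended to the result's `notes`. Distress ratings and the
  CAARMS substance-relation codes are carried but never alter outcomes.

## The conversion algorithm

Conversion is "crosswalk, then classify": map the ratings onto the target
instrument's subscales and scales, carry the shared clinical facts (course,
trait risk, functioning), and apply the target rule engine.

- **Domains.** CAARMS P1→SIPS P1, P2→P2, P3→P4, P4→P5. Going back, CAARMS
  P2 receives the highest of SIPS P2/P3 (with that subscale's frequency).
  Forward, SIPS P3 (Grandiose Ideas) is set to 0 with an assumption note —
  grandiosity is rarely the higher of the two, and the backward collapse
  makes the round trip exact either way. Severities cross unchanged: both
  instruments anchor 0–6 severity comparably, and the diagnostic thresholds
  are defined on those raw anchors. Equipercentile adjustment is a separate
  score-level facility, deliberately not part of diagnostic conversion.
- **Frequencies.** CAARMS 0–6 → SIPS 0–3 as {0,1→0, 2→1, 3,4→2, 5,6→3}
  (CAARMS 5 "daily, >1 h per occasion" satisfies SIPS 3 "≥1 h/day ≥4
  days/week"); SIPS 0–3 → CAARMS {0→1, 1→2, 2→3, 3→5}. Ambiguous cells are
  resolved downward: under-calling frequency is preferred to over-calling a
  diagnosis.
- **Qualifying-frequency floor (SIPS→CAARMS).** A SIPS subscale at severity
  6 with BIPS-qualifying frequency (≥1) is established psychotic-intensity
  symptomatology under its own instrument. The SIPS frequency anchors are
  much coarser than the CAARMS bands, and mapping such an episode below the
  CAARMS qualifying band 4–6 would misplace cases that the CAARMS criteria
  demonstrably capture (a >7-day psychotic episode is over the CAARMS
  threshold; a ≤7-day, spontaneously resolving one is BLIPS). The engine
  therefore raises the crosswalked frequency to at least 4 on such
  subscales, with an assumption note. This is the one place conversion is
  more than a cell-by-cell score map, and it is what guarantees the
  documented discordance behaviours in the backward direction.
- **Functioning.** The SIPS GRD functioning window is a GAF drop; when GAF
  is absent the SOFAS scores proxy it, noted per subject.

Five discordance mechanisms between the instruments are asserted as
regression tests: urgency (CAARMS BLIPS with dangerous/disorganizing
symptoms is SIPS Psychosis), the duration window (SIPS BIPS lasting 7
days–3 months is CAARMS Psychosis), the perceptual band shift (CAARMS P3
severity 5 is psychotic under CAARMS, attenuated as SIPS P4), the
functioning gate (SIPS APS/BIPS without the SOFAS criterion is CAARMS
UHR−), and the comorbidity gate (CAARMS APS better explained by another
disorder is SIPS UHR−). Only this input–output behaviour is guaranteed;
the branch order of the original graphical algorithm is not reconstructed.

## Agreement statistics

For a k×k paired-outcome table with proportions p, marginals p_i·, p_·j:
P₀ = Σp_ii, Pₑ = Σp_i·p_·i, κ = (P₀−Pₑ)/(1−Pₑ). The z statistic uses the
fixed-marginal null standard error
SE₀ = √(Pₑ + Pₑ² − Σ p_i·p_·i(p_i· + p_·i)) / ((1−Pₑ)√N), and *by
convention the confidence interval also uses SE₀* (κ ± 1.96·SE₀), the
convention under which the published interval for the 212-subject table
reproduces exactly; the large-sample non-null standard error is exposed via
`se = "asymptotic"`. PABAK = (k·P₀−1)/(k−1). The Bowker statistic drops
degenerate pairs (n_ij + n_ji = 0) from both the statistic and the degrees
of freedom; an exact binomial McNemar variant is provided for 2×2 tables.
Weighted kappa takes either an explicit symmetric unit-diagonal weight
matrix or per-category scores expanded to linear absolute-difference
weights w_ij = 1 − |s_i − s_j|/range(s). No reference value is attached to
the weighted analysis: the published weighted figures are not reproducible
from the published table under linear or quadratic weights on the stated
scores (1, 0.84, 0), so the weight construction is left fully
user-specifiable. `accuracy_metrics()` reports sensitivity, specificity
and the single-threshold ROC area (sensitivity + specificity)/2 on the
binarized labels, with kappa/PABAK/agreement on the full table; a rate
with an empty denominator is `NA`, not 0. Proportions are kept at full
precision; rounding happens only in `print()` methods.

## Equipercentile linking

Discrete scores are continuized with the uniform-kernel convention (each
integer score spreads over ±0.5), giving a piecewise-linear strictly
increasing percentile-rank function wherever counts are positive;
`link_scores()` composes the source rank with the interpolated inverse of
the target rank and clamps to [min−0.5, max+0.5] rather than extrapolate,
because the scales are bounded. No presmoothing is applied — unsmoothed
observed-score equating is the canonical baseline — and published linking
decimals are not reproduced (that would require the unpublished raw score
distributions). For linking only, SIPS frequency is recoded onto the
analytic bands {0→0, 1→2, 2→3, 3→1}: this matches the printed band
anchors, whose ordering conflicts with the standard 0–3 ordering, so the
recode is never used for diagnosis. Inverse ranks falling in a flat CDF
stretch return the midpoint of the stretch (standard tie-break).

## The synthetic cohort generator

`generate_cohort()` emulates a help-seeking high-risk service sample: each
subject draws a latent state (`none`, `trait_risk`, `attenuated`,
`brief_psychotic`, `frank_psychotic`), CAARMS ratings are drawn uniformly
within that state's criterion bands (no score distributions are published;
uniform-within-band is the least-assumption choice and is irrelevant to
outcome-level behaviour), and SIPS ratings are derived through the
crosswalk, so that with all mechanisms off both engines recover the latent
outcome exactly. Defaults follow the documented sample: mixture
(0.241, 0.04, 0.365, 0.118, 0.236) matching the observed outcome
marginals, urgency in 56% of brief episodes (14/25), long durations in 16%
(4/25), the perceptual band shift in 8% of psychotic-intensity cases
(≈6/75), comorbidity exclusion in 4.5% of attenuated cases (≈5/111), and
no functioning failures (referral pathways to the originating services
pre-selected on functional decline). Brief episodes are generated at
frequency 4 — a brief episode cannot satisfy the month-long sustained POPS
frequency band. Reproducibility: one global seed orders the latent states;
each subject's record is drawn from a counter-keyed substream, so records
do not change when `n` does.

What the generator does *not* emulate: item-level psychopathology, rater
noise and drift, time courses and transition to psychosis, correlated
missingness, and real marginal score distributions. Passing tests on
synthetic cohorts therefore demonstrate the internal consistency of the
rule engines, the conversion logic and the statistics — not the field
accuracy of the instruments themselves.

## Problem sizes and numerical choices

The test suite runs the classifier truth-table sweeps exhaustively over
the per-subscale severity×frequency grids (7×7 and 7×4) under seven
course/functioning configurations plus several hundred random
multi-subscale draws; parameter recovery uses n = 1000, the agreement
envelope 20 seeds of n = 212, and conversion accuracy n = 300. The
acceptance script uses n = 212 cohorts, matching the published sample
size. Equipercentile identities are asserted to 1e-9 (exact interpolation
arithmetic); statistics checked against published figures are asserted at
the precision those figures are printed with. Kappa is undefined (error,
not NaN) when chance agreement is 1; zero marginals make adjusted
residuals an error naming the offending row/column.

## Known limitations

Only the positive-symptom subscales are modelled — negative, cognitive,
disorganization and general scales of both instruments are out of scope,
as is item-level interviewing, rater training and reliability, and
older instrument versions (the criteria changed substantially between
versions, so neither the engines nor the conversion apply to them).
Schizotypal personality disorder and first-degree family history are taken
as input booleans, not diagnosed. The conversion engine guarantees
documented input–output behaviour, not the undocumented internal branch
order of the original tool.
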