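---
title: "Screening for constitutive GPCR activity with CRE-luciferase reporter plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for constitutive GPCR activity with CRE-luciferase reporter plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescreen)
```

## The assay and the statistical problem

A receptor is *constitutively active* when it signals without a ligand. For
receptors coupled to the cAMP pathway, that activity can be read out by
transfecting cells with the receptor plus a luciferase reporter under the
control of the cAMP response element (CRE): a Gs-like receptor raises
baseline reporter expression, while a Gi-like receptor lowers it — most
visibly after the adenylate cyclase activator forskolin has pushed cAMP up.

The raw data are relative light units (RLU) per well of a 96-well plate.
Each plate carries 12 treatment groups of 4 replicate wells: an empty-vector
negative control and a forskolin-stimulated empty-vector positive control,
plus receptors measured with and without 3 µM forskolin. Plates differ
substantially in overall brightness (transfection efficiency, cell density,
reagent age), so plates are statistical *blocks* and every comparison must
be made within plate.

## Normalization

`crescreen` implements a two-stage normalization:

1. **Between plates** — every group mean on a plate is divided by that
   plate's positive-control mean (empty vector + forskolin). The positive
   control itself normalizes to exactly 1 on every plate
   (`normalize_plate()`).
2. **Within condition** — each receptor group is divided by its matched
   empty-vector control in the same condition (± forskolin), minus 1, giving
   the *fractional change*: 0 means no effect, −0.5 means 50% inhibition,
   +2.0 means 200% stimulation (`fractional_changes()`). Per-plate
   fractional changes are averaged across plates, matching the within-block
   philosophy of the design, rather than forming a pooled ratio of grand
   means.

Because both stages are ratios of same-plate quantities, any multiplicative
plate effect cancels: rescaling a whole plate leaves every fractional change
unchanged (exactly so for real arithmetic; bit-for-bit for power-of-two
factors, and to within one part in 10^12 otherwise, which is what the test
suite asserts). For the baseline condition the stage-1 division cancels
algebraically in the stage-2 ratio; stage 1 still matters for the ANOVA
response and for comparing absolute levels between plates.

Group means are arithmetic means of the replicate wells — the unmarked
reading of "the average" — and plates whose positive control is missing or
non-positive are excluded with a logged reason rather than guessed at.

## The randomized complete block ANOVA

Significance of a receptor's effect is assessed with a replicated
randomized complete block ANOVA (`rcbd_anova()`), written out from the
classical balanced decomposition

$$SS_T = rb\sum_t(\bar y_t - \bar y)^2,\quad
  SS_B = rt\sum_b(\bar y_b - \bar y)^2,\quad
  SS_{TB} = r\sum_{tb}(\bar y_{tb} - \bar y_t - \bar y_b + \bar y)^2,$$

with the residual taken as the pure within-cell error and F ratios formed
against the residual mean square. The treatment-by-block interaction is
estimable because each cell holds $r \ge 2$ replicate wells, and it is
reported as a diagnostic: a large interaction means a receptor behaved
differently on different plates. Treating blocks as fixed and testing the
treatment against pooled within-cell error is the default; an
`error_term = "interaction"` switch gives the random-blocks alternative in
which the treatment F uses the interaction mean square.

Each receptor is tested per condition in a two-level comparison (receptor
vs. empty vector), with plates as blocks and the *stage-1 normalized
per-well values* as the response. This choice keeps the full n = 4
replication within each cell (a per-plate fractional change would collapse
it) while letting the block term absorb residual plate differences. No
multiple-testing correction is applied across receptors by default — the
screening convention this package follows — though `classify_screen()`
exposes `p_adjust = "BH"` for users who want it.

Degenerate inputs are flagged rather than mangled: if all observations are
equal, every p-value is reported as 1 with a `no_variance` flag; if a source
has positive sum of squares but the residual is exactly zero (the noise-free
limit), its p-value is reported as 0 with a `zero_residual` flag.

## Calling constitutive activity

A receptor is called constitutively active when it is statistically
significant (treatment p < α = 0.05 in the relevant condition) **and** meets
at least one magnitude criterion:

1. baseline fractional change ≥ +2.0 (200% elevation over baseline),
2. baseline fractional change ≤ −0.40 (40% inhibition of baseline), or
3. forskolin-condition fractional change ≤ −0.40 (40% inhibition of the
   forskolin response).

The thresholds are deliberately large: their purpose is to keep
over-expression artifacts from being scored as hits. Comparisons are
"meets" (≥/≤), and significance is required *per condition per criterion*:
a 50% forskolin inhibition whose own p-value is 0.072 does not satisfy
criterion 3, however large the magnitude. "200% elevation" is read on the
percent-change axis (treated/control ≥ 3); the alternative fold-change
reading (ratio ≥ 2) is available via `stimulation_as_fold = TRUE`.

The criteria map onto five response groups:

| pattern | group | meaning |
|---|---|---|
| crit2 ∧ crit3 | A | inhibits baseline and forskolin response |
| crit1 ∧ crit3 | B | stimulates baseline, inhibits forskolin response |
| crit3 only | C | inhibits forskolin response only |
| crit1 ∧ ¬crit3 | D | stimulates baseline only |
| none | E | no constitutive activity |
| crit2 ∧ ¬crit3 | OTHER | baseline-only inhibition |

Criteria 1 and 2 are mutually exclusive (opposite signs of the baseline
change), so the table is total. The `OTHER` pattern has no counterpart in
the five empirical groups; it is kept distinct rather than silently coerced
into A, so that evaluation metrics stay honest.

## The synthetic-data generator

Real per-well data for the published 40-receptor screen were never
deposited, so the package carries a generator (`simulate_screen()`) that
emulates the design: 12 groups × 4 replicates per plate, 4 plates by
default (the design was repeated 3–8 times; 4 is the conservative low end),
an empty-vector control, and a forskolin positive control held at five times
the baseline control signal — the ratio the original plates maintained.

The generative model is multiplicative throughout. The expected RLU of a
well is

$$\mu = \text{baseline\_mean} \times \text{ratio}^{[\text{forskolin}]}
  \times m_{\text{construct,condition}} \times \pi_{\text{plate}} \times
  \varepsilon_{\text{well}},$$

with $\pi$ and $\varepsilon$ independent log-normal factors of expectation
exactly 1 (log-mean −σ²/2). Defaults: baseline mean 20 000 RLU, plate
effect σ = 0.3 on the log scale (plates routinely double or halve in
brightness), well noise CV = 0.15 (a typical luciferase replicate spread).
Multiplicative noise is the right shape for luminescence — positive values,
roughly constant CV — and makes the normalization's ratio structure exact
in expectation. The single per-plate scalar is precisely the structure that
blocking and positive-control normalization both presuppose. An optional
`effect_jitter_sd` adds per-plate wobble to a receptor's effect multiplier,
mimicking the unexplained plate-to-plate variability some receptors show;
it is off by default because no magnitude for it was ever reported.

Ground truth is an *effect profile* per receptor: multipliers on baseline
and forskolin-stimulated expression (multiplier m ↔ fractional change
m − 1). The five archetypes used in testing sit well past the thresholds —
A = (0.4, 0.4), B = (4.0, 0.5), C = (1.0, 0.5), D = (4.0, 1.0),
E = (1.0, 1.0) — so each is classified into its own group in the zero-noise
limit and with ≥95% probability at default noise.

What the generator does **not** model: transfection-efficiency variation as
a separate mechanism (subsumed into plate and well noise), forskolin
dose–response, additive background, edge effects, or any receptor whose
effect sits near a threshold. Passing tests on simulated screens therefore
demonstrate that the pipeline recovers the truth *of this model*; they
cannot certify behaviour on real plates with, say, heavy-tailed
contamination or spatial gradients.

## Operating characteristics

`run_evaluation()` simulates screens with known truth, classifies them, and
tallies a confusion matrix, per-group recall/precision, and the
false-positive rate (true-null receptors called active). `power_curve()`
sweeps an effect multiplier toward a threshold and records detection
probability; at multiplier 1 this is the false-positive rate, far past a
threshold it approaches 1, and exactly at a threshold it is intermediate
(recorded, not asserted — at-threshold power depends on noise in a way the
package measures rather than promises). Seeds are a deterministic function
of a base seed and the replicate index, so every grid point reproduces
independently.

Problem sizes used by the test suite and the reproduction script — 200
simulated screens for archetype recovery, 1000–2000 for null calibration —
were chosen so Monte-Carlo error is small against the margins being checked
(binomial SE ≈ 0.5% at n = 2000).

## The published screen

`published_fixture()` ships the 40-receptor roster with each receptor's
reported group, following the results-section rosters (Group A includes
GPR55, which the abstract's list omits; GPR3 sits in Group D with a note on
its non-significant forskolin inhibition, p = 0.072).
`summarize_screen()` recomputes the headline tallies from the roster alone:
30 of 40 receptors (75%) constitutively active, 26 inhibitory
(groups A + B + C) versus 6 stimulatory (B + D), i.e. 65% vs 15%. The
inhibitory/stimulatory tallies are derived from group membership — exactly
the derivation those published counts are consistent with — not from
re-measured magnitudes, since per-receptor numbers exist only as figure
bars, and digitized bar heights are not acceptable ground truth.

## Known limitations

- The ANOVA is strictly balanced; unbalanced plates must be repaired or
  excluded first (`validate_dataset()` locates the offending cells).
- Whether the original analysis fit one omnibus model or per-comparison
  models, and whether it normalized before or after the ANOVA, was never
  stated; the defaults here (per-comparison two-level models on stage-1
  normalized wells) are one defensible reading, and both knobs are exposed.
- Fractional changes assume a positive matched control; plates violating
  that are skipped with a reason, and a receptor needs ≥2 usable plates to
  be evaluated at all.
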