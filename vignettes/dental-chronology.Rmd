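---
title: "Dental chronology from von Ebner increments: models and methods"
author: "toothchron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental chronology from von Ebner increments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothchron)
```

## The measurement model

Dentine in amniote teeth mineralizes in a circadian rhythm, leaving
incremental lines of von Ebner: one line per day of deposition, with single
increments between 1 and 30 µm wide. A tooth's age since the start of
dentine mineralization therefore equals its total line count, and the
replacement rate at a tooth position — the age of the functional tooth when
its successor began depositing dentine — is the difference between the
functional tooth's line count and the replacement tooth's line count. These
two identities are the core of everything this package computes:

* **tooth age (days) = observed lines + lines extrapolated across
  unreadable stretches**, and
* **replacement rate (days) = functional age − replacement age**.

Tooth longevity is the functional tooth's age at the time of observation
(for a shed tooth, its final age), and the *functional period* — the days a
tooth actually spends attached and working — is the shed tooth's age minus
the mean age of teeth caught at the attachment (ankylosis) stage.

### Mean line width and gaps

Fossilization and grinding make lines invisible along parts of a section,
so a transect is a strictly increasing sequence of boundary positions (µm,
pulp cavity outward) plus a list of unreadable gap intervals. The mean
daily width (the daily dentine apposition rate, DDAR) is taken from the
longest continuously readable run: the span of the gap-free run with the
most increments, divided by that number. When two runs tie, the
pulp-cavity-proximal run wins — an arbitrary but deterministic choice.
Using the run with the most increments (rather than the largest span)
matches the counting practice the data model descends from, and it is the
statistically better-sampled estimate of the per-day width.

Each gap then contributes `round(gap length / mean width)` extrapolated
lines, rounded half up. Extrapolated lines are carried separately from
observed lines and flagged in every downstream report: the sources this
package models do not state how unreadable stretches entered their printed
totals, so extrapolation-by-mean-width is this package's reconstruction of
intent and is labelled as such. When a gap sits strictly inside an
inter-boundary interval, the readable remainder of that interval is not
counted as an observed width — its bounding lines do not delimit single
daily increments — which slightly undercounts in that (rare) geometry;
in practice gaps are delimited by the last readable line on each side.

Widths outside the 1–30 µm plausibility band are *flagged, never dropped*
(`out_of_range_fraction`); an out-of-band width is a data-quality signal,
not a reason to alter the record silently.

### Obliquity

A section cut at angle θ to the true transverse plane inflates every
apparent width by 1/cos θ. `deoblique_width()` inverts this. The
correction assumes a single known angle for the whole section; it is the
standard first-order geometric correction, and the simulator's
oblique-sectioning noise is its exact inverse, which is why the round-trip
test can demand agreement within 1%.

## Replacement-rate estimators

`replacement_rate_for_family()` dispatches on what a tooth family
preserves:

1. **direct** — an intact replacement tooth with a counted age: integer
   subtraction against the *oldest* replacement in the family. When a
   family carries two successive replacement teeth, the immediate
   successor (the older one) defines the rate; the younger tooth belongs
   to the following cycle.
2. **rp_height** — replacement lost, resorption pit present: the pit
   height is scaled by 2/3 to approximate the lost crown's height, that
   height is overlaid on the functional tooth's exterior edge from the
   apex, and the lines inside the overlay are counted (inclusive at an
   exact tie: the last line *within* the area counts). The count is the
   estimated replacement age; subtraction proceeds as in the direct case.
3. **dentine_extent** — replacement present but its lines not continuously
   readable: its radial dentine extent divided by the functional tooth's
   mean line width. The "extent over width" reading is the only one whose
   units balance (µm ÷ µm/day = days); a literal two-dimensional-area
   reading would not yield days and is rejected.
4. **minimum** — neither replacement nor pit: the replacement had not yet
   begun depositing dentine, so the functional age is a *lower bound* on
   the rate, carried with `is_minimum = TRUE` through every summary.
   Downstream, minima are excluded from means but included in ranges with
   a lower-bound annotation, and excluded from the rate reconstruction on
   the tree (with the exclusion logged).

All reported rates are integer days, rounded half up; fractional
intermediates are kept internally. `is_minimum` is also set whenever the
functional tooth's own count is a minimum (e.g. a missing crown apex).

## Comparative analysis

`group_summary()` aggregates longevity and rate by diet category
(hypercarnivore, carnivore, herbivore, insectivore, omnivore) with the
minimum-handling rule above.

`mass_rate_association()` tests the body-mass association as a Pearson
correlation of log10(mass in kg) against rate in days. Mass is logged
because the taxa span roughly four orders of magnitude; the p-value comes
from a two-sided permutation null because n ≈ 10 supports no normality
assumption. With n ≤ 7 the null is exhaustive over all n! pairings (the
p-value is then exact and matches brute-force enumeration); above that it
is Monte-Carlo with a required seed, with the observed ordering counted as
one realisation. Degenerate variance (all masses or all rates equal) is an
error, not a silent NA.

`bm_ancestral_states()` reconstructs ancestral states of a continuous
trait under Brownian motion by two-pass Gaussian message passing (a
pruning algorithm): a post-order pass collapses each clade into a
(mean, variance) message, and a pre-order pass propagates the
rest-of-tree message down, so each node's state is the precision-weighted
combination of all incident messages. These are the maximum-likelihood
states; they equal the generalized-least-squares solution on the BM
covariance matrix (the test suite asserts agreement to 1e-9 against an
explicit-matrix GLS oracle and against an independent reference
implementation), they are convex combinations of the tip values (hence
always inside the tip range), and they are equivariant under shifting and
scaling of the tips. The BM rate σ² cancels from the ML states and is
profiled out, not reported. `branch_gradient()` linearly interpolates
states along branches at evenly spaced interior points for
continuous-character-map style figures; plotting itself is out of scope.

### The packaged fixtures

`paper_fixture()` ships every published per-tooth line count, pit-estimated
count, and rate for the thirteen fossil taxa and two extant varanids the
package models, one provenance note per row. Two rows carry
`expected_discrepancy = TRUE`:

* the edaphosaurid row, where the published rate (381) disagrees with the
  published counts (506 − 131 = 375) — the fixture stores both, and tests
  assert the recomputed and printed values *separately* rather than
  forcing agreement;
* the small-caseid row, where the text attributes the 115-line estimate to
  one tooth family but only the other family's 506-line count reproduces
  the published 391 — the fixture follows the arithmetic and flags the
  ambiguity.

The published multi-family averages for the hypercarnivorous varanopid
(≈41-day rate, ≈75-day longevity) are not reproducible from the five
published per-family rates (39, 34, 46, 36, 35) and are not asserted
anywhere; presumably unpublished families contribute.

`trait_fixture()` and `tree_fixture()` carry the comparative inputs. Body
masses are *package-estimated* order-of-magnitude values (the source
prints none), chosen once from the taxa's skeletal size classes, and the
tree is a topology-faithful reconstruction with plausible branch lengths
in Ma — both labelled synthetic in their file names and never asserted
numerically. Consequently the body-mass result is asserted only
qualitatively (no significant association, p > 0.05 on this fixture), and
no figure-derived branch length is tested.

## The synthetic dentine generator

The generator is the package's substitute for destructive histological
sampling: it produces teeth with *known* age, interval, and width so every
estimator can be validated by parameter recovery.

Defaults (chosen once, on field plausibility):

| parameter | default | rationale |
|---|---|---|
| `mean_daily_width` | 12 µm/day | mid-band; 10–16 µm is called "thick" for these taxa, so the typical tooth sits below that |
| `width_cv` | 0.2 | modest day-to-day variation; lognormal keeps widths positive |
| `width_distribution` | lognormal | right-skewed, positive; truncated-normal available |
| `height_per_increment` | 10 µm/line, constant | no crown geometry is published; the simplest monotone model is the default, with a decelerating alternative (`decelerating_height()`) |
| `true_replacement_interval` | 105 days | a mid-range published rate |
| `rp_growth_per_day` | 15 µm/day | equals 1.5 × height-per-increment, which makes the 2/3-pit rule *exactly unbiased* under the default linear crown — the estimator's intended geometry, so its logic is testable; mis-specify it deliberately to study robustness |

The pit-height identity: after t days of replacement growth the pit is
15t µm high, two-thirds of that is 10t µm, and a linear 10 µm/line crown
converts 10t µm back into exactly t lines. No published quantitative pit
geometry exists; the linear model is a stand-in and all recovery
tolerances refer to it.

Noise (`noise_params()`): independent per-line dropout (merging adjacent
increments), 1/cos θ obliquity inflation, and Gaussian position jitter
clamped to inter-boundary midpoints so the strict ordering survives (the
clamp slightly shrinks extreme jitter; for the jitter magnitudes of
interest, well below one increment width, it is immaterial).
`simulate_replacement_wave()` reproduces the jaw-level pattern —
alternating odd/even positions offset by half an interval, so adjacent
positions are never simultaneously toothless; its gap duration defaults to
a tenth of the interval, bounded to preserve that invariant.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: ontogenetic rate variation (the modelled
sampling is restricted to subadults/adults), seasonal or metabolic line
disruptions, curvature of the counting trajectory, reader disagreement in
line identification, and any nonlinearity of real pit growth. Recovery
results transfer to real teeth only to the extent these are second-order.

All randomness flows through one integer seed per call; identical
parameters and seed give bit-identical output, and derived seeds (as in
`recovery_experiment()`) are simple integer offsets so whole tables are
reproducible.

## Numerical and design choices

* Integer-day reporting uses round-half-up everywhere (`floor(x + 0.5)`),
  never banker's rounding, so printed chronologies are
  platform-independent.
* Overlay counting is inclusive at exact height ties.
* The width plausibility band is fixed at [1, 30] µm; one source table
  prints the band in mm, treated as a typographical slip for µm.
* Errors are classed conditions (`measurement_insufficient`,
  `inconsistent_family`, `missing_profile`, `dangling_reference`, ...) so
  pipelines can dispatch on failure mode.
* Problem sizes in the shipped tests — 200 recovery families, 500 dropout
  replicates, random trees of 5–8 tips, Monte-Carlo nulls of 10^4
  permutations — were chosen as the smallest sizes at which the asserted
  tolerances are comfortably identifiable.

## Known limitations

* Extrapolated counts inherit any bias in the mean-width estimate; on
  transects whose readable runs are unrepresentative of the gap region the
  extrapolation can drift, which is why extrapolated lines are flagged.
* The minimum-rate convention (rate lower bound = functional age) is
  conservative by construction and should not be averaged with measured
  rates; the package enforces this but cannot prevent a user from doing so
  on exported CSVs.
* The comparative fixture's masses and branch lengths are synthetic;
  fixture-based comparative numbers are regression anchors for this
  package, not published results.
* The ASR assumes homogeneous-rate Brownian motion; no Ornstein-Uhlenbeck
  or rate-shift models, and no phylogenetic signal statistics, are
  provided.
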