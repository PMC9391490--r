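# toothchron

Dental chronology for polyphyodont amniotes from incremental lines of von
Ebner — the daily growth lines in dentine. `toothchron` is aimed at
palaeohistologists and comparative dental biologists who count growth lines
on thin sections of continuously replaced dentitions (early synapsids and
reptiles, extant varanids, and the like) and need tooth ages, tooth
longevities, and tooth replacement rates, with honest handling of
unreadable sections, lost replacement teeth, and lower-bound estimates.

## The model

One von Ebner line is one day of dentine deposition, so for a tooth family
(a functional tooth plus the replacement developing lingually at the same
position):

* **tooth age** `A` (days) = total line count, pulp cavity to exterior,
  with `round(gap / w̄)` lines extrapolated across unreadable gaps from the
  mean line width `w̄` (the daily dentine apposition rate, taken from the
  longest continuously readable run);
* **replacement rate** `R = A_functional − A_replacement` — the functional
  tooth's age when its successor started depositing dentine;
* when the replacement tooth is lost, its age is estimated by overlaying
  **⅔ of the resorption-pit height** on the functional crown's exterior
  edge and counting lines from the apex; when its lines are unreadable,
  by **radial dentine extent ÷ w̄**;
* with neither replacement nor pit, `R ≥ A_functional` is reported as an
  explicit minimum.

On top of this sit diet-group summaries, a permutation test of the
`log10(body mass)` – rate association, and maximum-likelihood
Brownian-motion ancestral state reconstruction (two-pass pruning,
equal to the GLS closed form) on a time-calibrated tree, plus a fully
seeded synthetic dentine simulator with known ground truth for validating
every estimator by parameter recovery.

## Worked example

```r
library(toothchron)

# a transect: boundaries every 12 um, plus a 36-um unreadable stretch
tr <- increment_transect("mx05", "TR", c(seq(0, 120, by = 12), 156),
                         gaps = c(120, 156))
st <- count_total_increments(tr)
st
#> <increment_stats> mx05: 10 observed + 3 extrapolated lines, mean width 12.00 um/day
tooth_age_days(st)
#> [1] 13

# a tooth family with both counts measured: direct subtraction
f <- tooth_record("Dimetrodon", "ROMVP 85510", age_days = 459)
r <- tooth_record("Dimetrodon", "ROMVP 85510", age_days = 354)
replacement_rate_for_family(tooth_family(f, list(r)))
#> <replacement_estimate> 105 days (method: direct, replacement age used: 354)

# a lost replacement tooth: pit height 54 um, 1-um-per-line apex profile
fun <- tooth_record("Seymouria", "ROMVP 85515", age_days = 171, rp_height = 54)
replacement_rate_for_family(tooth_family(fun), apex_profile(1:171))
#> <replacement_estimate> 135 days (method: rp_height, replacement age used: 36)

# recompute every published rate from the packaged count fixture
rates <- recompute_fixture_rates()
subset(rates, method == "direct", c(taxon, recomputed_rate, printed_rate))
#>                     taxon recomputed_rate printed_rate
#> 1 Dimetrodon cf. limbatus             105          105
#> 7        Delorhynchus sp.             104          104
#> 8        Colobomycter sp.              98           98
#> 9         Captorhinus sp.              77           77
```

The 105-day rate means the apex predator initiated a new tooth at each
position roughly every three and a half months while its functional teeth
lived 459 days; the pit-based 135-day estimate for the stem amniote is
carried with the method label so downstream summaries can weigh it
accordingly. Rows whose published arithmetic is internally inconsistent
are flagged `expected_discrepancy` and never forced to agree.

A thin command-line wrapper over the same functions ships in
`inst/cli/toothchron.R` (subcommands `analyze`, `estimate`, `simulate`,
`recover`, `compare`, `asr`), and `run_pipeline()` drives the whole
analysis from CSV inputs to `rates.csv`, `summary.csv`, and ancestral
state tables with a structured log.

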