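# clinotatr

Quantitative aggregation of ClinVar clinical assertions for
reclassification prioritization — an R implementation of the Clinotator
method.

ClinVar variation reports collect independent clinical assertions of a
variant's significance, but those assertions differ in age, in submitter
expertise and in whether the submitter published assertion criteria.
`clinotatr` condenses each variation report into four metrics that rate the
strength and consistency of its evidence:

* **CTRS** (raw score): the weighted sum over valid clinical assertions
  *i*,

  CTRS = Σᵢ xᵢ·dᵢ·sᵢ,

  where xᵢ is the significance weight (B = −6, LB = −3, US = −0.3,
  LP = +3, P = +6), dᵢ an age-decay factor (1 for the first two years,
  (11 − n)/10 for ages 2–6 years, 0.5 beyond) and sᵢ a submitter factor
  (practice guideline 1.25, expert panel 1.10, criteria provided 1.00,
  otherwise 0). Assertions without published criteria, without a Mendelian
  significance or without a last-evaluated date are omitted.
* **CTAA**: the mean age in whole years of the valid assertions.
* **CTPS**: a predicted significance on the seven-label scale (B, BLB, LB,
  US, LP, PLP, P), obtained by locating the CTRS within score ranges
  calibrated on two-star control distributions with non-parametric
  prediction intervals (order statistics at ranks c = trunc(α/2·(n+1)) and
  r = n − c + 1). The combined categories BLB and PLP are the overlaps of
  adjacent class intervals.
* **CTRR**: a 0–3 reclassification priority from the ordinal distance
  between the reported significance (CVCS) and the prediction, plus one
  point per zone boundary crossed (benign | uncertain | pathogenic),
  capped at 3.

CTPS is **not** a clinical classifier: it rates evidence strength and
reclassification impact, not primary evidence. Classification should
always follow the ACMG/AMP guidelines against the available evidence.

Intended users are ClinVar submitters, curators and researchers triaging
large variant sets for reclassification or discordance analysis.

## Worked example

Two record sets ship with the package; `"conflicting"` holds sixteen
conflicting-interpretation variants with exactly two criteria-driven
assertions each. With the evaluation date pinned (assertion ages depend on
it):

```r
library(clinotatr)
recs <- ct_example_records("conflicting")
m <- ct_annotate(recs, evaluation_date = as.Date("2018-06-01"))
m[1:5, c("VID","CVCS","CVSZ","CVNA","CTRS","CTAA","CTPS","CTRR")]
#> # A tibble: 5 × 8
#>   VID   CVCS   CVSZ  CVNA  CTRS  CTAA CTPS   CTRR
#>   <chr> <chr> <int> <int> <dbl> <dbl> <chr> <int>
#> 1 10768 CI        1     2  10.8   1.5 PLP       3
#> 2 12348 CI        1     2  11.4   1.5 PLP       3
#> 3 18011 CI        1     2  12     0.5 PLP       3
#> 4 54153 CI        1     2   8.4   1.5 PLP       3
#> 5 55564 CI        1     2  10.8   2   PLP       3
```

Reading the first row: VID 10768 is reported as CI (conflicting
interpretations, one star) but its two valid assertions — both Pathogenic,
aged 3 and 0 years — give a raw score of 10.8, inside the PLP range
[8.4, 14.7]. Moving from the uncertain position to PLP is two ordinal
steps plus a zone crossing: reclassification rank 3, the highest priority.

The calibrated score ranges and their boundaries:

```r
tidy(ct_default_ranges())
#> # A tibble: 7 × 5
#>   label  lower upper lower_closed upper_closed
#>   <chr>  <dbl> <dbl> <lgl>        <lgl>
#> 1 B     -Inf   -26.7 FALSE        FALSE
#> 2 BLB    -26.7  -8.4 TRUE         TRUE
#> 3 LB      -8.4  -4.2 FALSE        TRUE
#> 4 US      -4.2   4.2 FALSE        FALSE
#> 5 LP       4.2   8.4 TRUE         FALSE
#> 6 PLP      8.4  14.7 TRUE         TRUE
#> 7 P       14.7 Inf   FALSE        FALSE
```

`autoplot()` draws the ranges or a scored batch; `ct_annotate_vcf()`
annotates a VCF (matching sites by rsID and alternate allele, per-allele
values in 12 namespaced INFO keys); `ct_calibrate()` +
`ct_build_ranges()` recalibrate the ranges from any record set;
`ct_generate_records()` simulates record sets for calibration experiments.
A command-line front end lives at `inst/scripts/clinotator`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","clinotator",package="clinotatr"))')" \
  -t vid -r records.jsonl -o myrun --date 2018-06-01 vids.txt
```

which writes `myrun.tsv` (the 14 metric columns, `.` for missing values)
and, for VCF input, `myrun.anno.vcf`.

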