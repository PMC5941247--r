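---
title: "Scoring, calibration and ranking of ClinVar clinical assertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, calibration and ranking of ClinVar clinical assertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinotatr)
```

## The problem

A ClinVar variation report aggregates independent clinical assertions —
professional judgements made under the ACMG/AMP framework, each with a
significance label, a last-evaluated date and a submitter review tier.
Summarising them is not a simple averaging problem: assertions age (older
ones predate current standards and newer evidence), expert-panel reviews
carry more weight than unreviewed submissions, and literature-only entries
are evidence rather than assertions. A mean or median of assertion values
would fall prey to skew or omission; an aggregate score expresses the
total volume of assertions instead. `clinotatr` scores each report, maps
the score onto a predicted significance through calibrated ranges, and
ranks the disagreement between the prediction and the reported
significance.

## The raw score

The raw score of a record is

$$\mathrm{CTRS} = \sum_i x_i\, d_i\, s_i$$

over its *valid* assertions: those with published assertion criteria
(submitter category practice guideline, expert panel or criteria
provided), one of the five Mendelian labels, and a last-evaluated date.
The factors, all unitless, with their defaults in `ct_constants()`:

* **Significance weight** $x_i$: B $-6$, LB $-3$, US $-0.3$, LP $+3$,
  P $+6$. The full categories are twice their "likely" counterparts, so an
  assertion decayed to the 0.5 floor is effectively downgraded one tier
  (P behaves like LP); LB and LP can be halved in strength but never cross
  into uncertainty. US is slightly negative rather than zero so that
  uncertain evidence registers without moving a record across the scale.
* **Age decay** $d_i$: 1 for ages under 2 years (a grace period), then
  $(11-n)/10$ for whole-year ages $2 \le n \le 6$ (a 10% reduction per
  year), then a static 0.5. Old *data* keeps its value; old *assertions*
  do not, since any current assertion must already incorporate prior
  evidence.
* **Submitter factor** $s_i$: practice guideline 1.25, expert panel 1.10,
  criteria provided 1.00, anything else 0. This gives expert review a
  louder voice without letting it mask the rest of the conversation, and
  it is what removes criteria-less submissions from the sum.

Assertion age is the floored whole-year count
$\lfloor \text{days}/365.25 \rfloor$ measured at the evaluation date
(`evaluation_date`, defaulting to the run date; pin it for reproducible
output). Whole years are deliberate: continuous ages would produce
different scores than the reference worked examples, and the decay
schedule is defined on integer years. Assertions dated after the
evaluation date are clamped to age 0 with a warning. CTAA, the mean of
those whole-year ages over valid assertions, is reported whenever at least
one valid assertion exists — a mean of one value is still informative —
while the predicted significance and rank require two.

The raw score itself is reported for any number of valid assertions
(including 0 and 1); only the downstream prediction is withheld below two,
since the calibration material consists of records with at least two
valid assertions.

## Calibrating the predicted-significance ranges

The score-to-significance map is calibrated on control distributions of
two-star records: those with an unambiguous Mendelian overall significance
(the combined PLP and BLB categories cannot be placed in a single class;
conflicting-interpretation records are excluded too) and at least two
valid assertions (`ct_calibration_set()`).

Each class range has a **fixed bound nearer zero**:
$2\,[x \cdot 0.7 \cdot 1.0]$ — the minimum score of a variant that just
meets the two-star criterion, i.e. two concordant criteria-provided
assertions at the oldest age (five years) still above the decay floor.
That gives $\pm 8.4$ for P/B and $\pm 4.2$ for LP/LB. The far bound comes
from a **non-parametric prediction interval**: the order statistics at
ranks $c = \mathrm{trunc}(\alpha/2 \times (n+1))$ and $r = n - c + 1$.
Rank-based intervals are the right tool here because the control
distributions are non-normal and heavily skewed by outliers; and because
the lower bound is fixed by the two-star criterion, only the outward
bound is data-dependent, which makes the intervals robust to however far
outliers stretch.

For each class, `ct_select_confidence()` scans a descending confidence
grid — default $\{0.999, 0.998, 0.995, 0.99, 0.98, 0.96, 0.95, 0.90\}$ —
and keeps the highest confidence whose interval endpoint nearer zero does
not cross the fixed bound toward zero; that endpoint is then clamped onto
the fixed bound exactly. Clamp-after-selection is our reading of aligning
the interval to the bound: in the shipped calibration every zero-side
endpoint equals $2 \cdot x \cdot 0.7$ exactly, which is what the
clamping produces. The grid itself is configurable; the default covers
every confidence appearing in the shipped calibration (95.0, 96.0, 99.5)
plus the finer quantile levels (99.8, 99.9) relevant at large $n$. The
uncertain class has no fixed bound — its range is simply what lies
between the LB and LP bounds — so it takes the highest computable
confidence and plays no role in range construction.

`ct_build_ranges()` then partitions the real line into seven contiguous
ranges. The combined categories are the *overlaps* of adjacent class
intervals — BLB where the B and LB intervals intersect, PLP for LP and P —
quantifying the region where neither classification can be excluded at
the selected confidence, rather than acting as yet another class. With
the packaged calibration:

```{r ranges}
tidy(ct_default_ranges())
```

Boundary ownership needed a convention, and only the pathogenic side has
direct evidence: records scoring exactly 8.4 are predicted PLP, so the
overlap categories are closed intervals and LP keeps its fixed bound 4.2;
the benign side mirrors this by the antisymmetry of the weights (no
boundary case exists to test it against, which we note as a residual
ambiguity). The uncertain range is open on both sides. Scores beyond the
outermost interval endpoints still classify as B or P — however extreme a
score, the prediction saturates rather than falling off the scale.
`ct_build_ranges()` refuses interval sets that do not overlap in the
required order, since no contiguous partition exists then.

The packaged default calibration (`ct_default_calibration()`) ships as a
plain TSV resource carrying the per-class sample sizes, medians, interval
bounds and confidences of the two-star control groups; its data-dependent
columns (the $n$, medians and outward bounds) are constants of that
control snapshot, not reproducible offline, while the zero-side bounds
are the analytic values above. `ct_calibrate()` recomputes everything
from any record set and `ct_write_calibration()` round-trips the resource
format.

## The reclassification rank

`ct_reclassification()` measures disagreement on the seven-position scale
B, BLB, LB, US/CI, LP, PLP, P (conflicting interpretations score at the
uncertain position): one point per position stepped, plus one point per
zone boundary crossed, where the zones are all-benign, uncertain and
all-pathogenic; the total is capped at 3. We count the bonus per boundary
crossed (a benign-to-pathogenic transition crosses two); after the cap
this is indistinguishable from a single-bonus reading for every reachable
pair, but it makes the rule total. The rank is symmetric in its two
arguments, zero exactly on ordinal identity, and undefined (missing) when
the prediction is withheld or the reported significance is off the scale
(e.g. drug response) — batch runs never abort over such records.

## Record model and I/O

Records travel as a tibble (one row per variation report, list-columns
for rsIDs, alleles and the per-submitter assertion table); the canonical
on-disk form is line-delimited JSON, which round-trips losslessly.
A ClinVar variation-report XML subset parser maps the same semantics from
`VariationReport` elements; element paths target the variation-report
dialect as a compatibility choice, since the upstream schema evolves, and
the JSON-lines format — not live XML — anchors the test suite. Review
status maps to stars via a versioned lookup (practice guideline 4, expert
panel 3, multiple concordant criteria submitters 2, single submitter or
conflicting 1, else 0), and the submitter category is inferred from each
assertion's review-status text, since the upstream category curation is
not machine-readable. Blank last-evaluated dates — common in older
submissions — are retained but invalid for scoring, with a warning.

VCF annotation matches sites by rsID and alternate allele only, exactly
the documented behaviour: multi-allelic sites get per-allele values
(`Number=A`), haplotype records match by allele membership, and position
is never consulted — so un-normalised or lifted-over coordinates cannot
produce false matches, at the cost of ignoring sites without an rsID in
the ID column. Twelve INFO keys are added: every metric column except
`vcf_match` (meaningless inside a VCF) and the rsID (already the ID
column) — our resolution of the twelve-versus-thirteen field count, noted
here deliberately. Keys carry a `CTO_` prefix to avoid collisions
(re-annotation is refused as a collision); free-text values have the VCF
4.3 reserved characters replaced by underscores and multiple conditions
joined with `|`. Stripping the added keys restores the input body
byte-identically, which is the invariant the line-level VCF I/O in this
package is built around.

The batched-fetch adapter (`ct_fetch()`) implements only the batching and
retry contract (link batches ≤ 1000, fetch batches ≤ 4500 by default,
three attempts per batch) over an injected transport function; the
package contains no live network path and none is exercised in tests.

## The synthetic generator

`ct_generate_records()` emulates the statistical shape of multiply
asserted ClinVar variants: a per-record assertion count of about
3.3 ± 1.9 (clamped to ≥ 2, matching the census of records the method
applies to), gamma-distributed assertion ages around 1.5 ± 0.9 years, a
class mix following the relative sizes of the five two-star control
groups, submitters mostly in the criteria-provided tier, and a one-step
label-noise probability. Stars and overall significance are assigned the
way ClinVar would: assertion sets spanning zones become one-star CI;
concordant sets with two or more valid assertions become two-star with
the shared label (or PLP/BLB when full and "likely" calls mix). A fixed
seed fully determines the output.

What the generator does *not* emulate: submitter ecology (correlated
labs, shared evidence between assertions), condition ontologies,
somatic/germline structure, and the long outlier tails of real score
distributions. Passing calibration-recovery tests on synthetic data
therefore demonstrates internal consistency of the scoring-calibration
loop, not performance on real ClinVar material.

One property worth stating precisely: on noise-free, young, concordant
records, the reclassification rank is not identically zero — a two-star P
record with two young P assertions scores 12, inside the PLP overlap, and
correctly ranks 1. The overlap categories exist to flag exactly this
borderline plasticity, so the test suite asserts rank ≤ 1 with rank 0
outside the overlaps, not rank ≡ 0.

## Problem sizes and numerical choices

The calibration-recovery check trains on 25,000 class-balanced records
(about 5,000 per class) and evaluates 5,000 fresh ones, comparing
per-class recovery (own class or adjacent overlap) against the selected
interval confidence within four binomial standard errors; oracle
cross-checks run 1,000 randomised cases per operation. Scoring is exact
floating-point arithmetic — range boundaries are compared with ordinary
equality, which is safe because boundary values (multiples of 0.3 and
0.7) arise identically on both sides. Ties in the confidence grid cannot
occur (the grid is strictly descending); degenerate inputs (empty
assertion lists, empty files, unknown labels) produce empty metrics or
missing values rather than errors, and every warning names the record it
concerns so batch logs stay actionable.

## Limitations

* The predicted significance is an evidence-strength rating, not a
  clinical classification, and must not be used as one.
* The shipped calibration reflects a specific two-star control snapshot;
  ranges drift as the database grows, and periodic recalibration
  (`ct_calibrate()`) is expected.
* Assertions are not split by condition/phenotype: ambiguous condition
  naming makes grouping unreliable, and splitting would leave most
  records below the two-assertion threshold.
* Somatic assertions are not reconciled with germline ones; they enter
  the sum like any other assertion if valid.
* rsID-based VCF matching ignores sites whose ID column lacks an rsID;
  positional matching is deliberately out of scope.
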