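---
title: "Segmenting high-cost expenditures by within-person monthly spending order"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting high-cost expenditures by within-person monthly spending order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-insurance spending is famously concentrated: in aged fee-for-service
populations the top tenth of beneficiaries by yearly spend typically holds
more than half of all expenditures. Care-management programs built on that
observation target the yearly high-cost cohort as a block — yet a yearly
total says nothing about *when* within the year a person was expensive.
spendseg implements a finer, month-level segmentation: within each high-cost
beneficiary, the twelve calendar months are ranked from their highest- to
lowest-spend month, and monthly spend and headcounts are aggregated over
(calendar month, rank). The resulting M × M grid shows that each month's
top-ranked segment concentrates a large share of that month's spending, while
the *people* occupying it turn over from month to month — a dynamic
equilibrium with direct consequences for how care-coordination resources
should be tiered and timed.

## The method, step by step

Let `x_b(m)` be beneficiary `b`'s total paid amount in calendar month `m`
(claims are attributed to the month of their claim-through date; months with
no claims contribute zero, so every beneficiary has a defined value for all
`M` months).

1. **Population.** Keep beneficiaries who are age-eligible and continuously
   enrolled and who have at least one claim in the study year. Decedents stay
   in the denominator for the whole year; their post-death months are zero.
2. **High-cost cohort.** Rank yearly totals `Σ_m x_b(m)` descending and keep
   the top fraction `f` (default 0.10). Cohort size is `ceiling(f · N)` —
   the only rounding consistent with a 122,241-member cohort from a
   1,222,402-member population at 10%. Ties at the cutoff are broken by
   ascending beneficiary id (the inputs report no rule, so we fix a
   deterministic, configurable one).
3. **Spending-order index.** For each cohort member, assign each month a
   unique index `k ∈ 1..M`, with `k = 1` the member's highest-spend month.
   Indices are unique **even under ties** (e.g. several zero-spend months):
   the default `chronological` rule gives the earlier tied month the smaller
   index; `reverse` is available. Each member's month→index map is therefore
   a permutation of `1..M` with spend non-increasing in index order.
4. **Segment grids.** `spend(k, m) = Σ_{b: idx_b(m)=k} x_b(m)` and
   `count(k, m) = |{b : idx_b(m) = k}|`. Spend columns sum exactly (in
   cents) to the cohort's baseline monthly totals; count columns each sum to
   the cohort size. With `M = 12` these are the 144-cell grids.
5. **Anchor subgroups and migration.** The anchor subgroup of month `a` is
   everyone with index 1 in `a`. The M subgroups are pairwise disjoint and
   cover the cohort (each member has exactly one index-1 month). Recomputing
   both grids over one subgroup gives its *occupancy* layers; layers sum
   cell-wise to the full grids, which is the stacked-color decomposition of
   the migration figures. The summary reports each subgroup's share of the
   cohort (≈ 100/M % when index-1 counts are near uniform) and of its anchor
   month's spending.

## Numerical conventions

* **Integer cents.** All currency is held as integer cents so conservation
  identities (`grid column sums = baseline totals`) hold *exactly*, not to a
  float tolerance. Cents are stored in doubles — exact for magnitudes far
  beyond any national program total — because population-scale sums overflow
  32-bit integers. Dollars appear only at reporting, rounded half away from
  zero (currency to the nearest million, percentages to the precision of the
  quantity: integer for yearly concentration, one decimal for segment and
  subgroup shares).
* **SD convention.** Summaries over the M monthly totals default to the
  population SD (divide by M), configurable to sample SD. The convention
  behind published monthly-SD figures is rarely stated, so SD output should
  be read as order-of-magnitude only.
* **Ties.** The tie rule only redistributes a member's tied months among
  adjacent indices; aggregate grids are reproducible bit-exactly for a fixed
  rule, and the rule is recorded in output metadata.
* **Degenerate inputs.** All-zero spending vectors are legal (indices follow
  the tie rule alone); empty anchor subgroups are legal outputs; an all-zero
  cohort produces a well-defined report with an explicit empty-cohort notice
  rather than division errors.

## The synthetic generator

Real claim-level extracts of this kind are access-restricted, so the package
ships a seeded generator producing panels with the statistical features the
method relies on:

* **Heavy-tailed yearly totals** — a log-normal per-beneficiary chronic
  monthly level (`chronic_log_mean = 5.5`, `chronic_log_sd = 1.9`, dollar
  scale: median ≈ $245/month with a long right tail).
* **Within-person month-to-month variation** — log-normal month noise
  (`month_log_sd = 1.2`).
* **Zero-utilization months** — each month is zeroed outright with
  probability `zero_month_prob = 0.15` (a zeroed month has no claims at all,
  episodes included).
* **Episodic acute spikes** — with probability `spike_prob = 0.08` a month
  gains a log-normal episode (`spike_log_mean = 9.0`, `spike_log_sd = 1.0`;
  median ≈ $8,100). Spikes are what make a typical member's index-1 month,
  and hence what drives subgroup migration.
* **Decedent truncation** — `death_prob = 0.04` of beneficiaries die in a
  uniform random month; later months are zero but the row stays in the
  denominator, mirroring the constant subgroup headcounts of the migration
  analysis.
* **Claim-level granularity** — each positive month is split into
  `1 + Poisson(claims_per_positive_month − 1)` claim lines, cent-exactly, so
  rebuilding the matrix from generated claims reproduces it bit for bit.

The defaults were fixed once with `scripts/calibrate_generator.R` (n =
20,000, seeds 1–5) so that the generated top-decile yearly share and the
top-segment monthly share sit in the bands the method is meant to exhibit
(roughly 45–70% and "almost half" respectively); the harness ships with the
repository and prints the shape metrics for any candidate parameter set.

What the generator does **not** emulate: diagnosis/procedure structure,
serial correlation of episodes (spikes are independent across months, so
multi-month hospitalization tails are absent), seasonality, negative-payment
adjustments, and enrollment churn other than death. Passing tests on
synthetic panels therefore demonstrate the *arithmetic and invariants* of
the segmentation, and the qualitative concentration/migration shape — not
calibration to any particular program's magnitudes.

## Problem sizes in the test suite

The suite exercises exhaustive-enumeration oracles on all cohorts of ≤ 5
beneficiaries × ≤ 4 months over 100 random panels, invariant suites on a
1,000-beneficiary synthetic panel, and generator-shape checks at 20,000
beneficiaries over 5 seeds — sizes chosen to give tight statistical checks
while keeping the default test run fast on a single CPU. The acceptance
script runs the full pipeline at 20,000 beneficiaries.

## Design choices where the design was open

* **Paid amounts.** A single signed `paid_amount` column is assumed
  (net-of-adjustment payments, not allowed charges); negative adjustment
  lines net within their month.
* **Eligibility as booleans.** Enrollment logic arrives precomputed
  (`age_eligible`, `continuously_enrolled`, `death_month`) rather than as
  monthly flag strings — the criterion level is all the method needs, and
  source-specific layouts stay upstream.
* **Cutoff ties.** Whether a published cohort count resolved cutoff ties by
  inclusion or identifier order is unknowable from the count alone; we rank
  by (total desc, id asc) and take exactly `ceiling(f · N)`.
* **No proration.** A claim belongs wholly to its claim-through month, even
  if its service period spans months.

## Limitations

The spending-order index is intrinsically retrospective — it is undefined
until the full year has elapsed — so the method characterizes migration and
informs tiering, but cannot prospectively flag next month's top subgroup.
Results on small panels (e.g. a single provider's patients) will be noisier
than on population-scale data; the aggregate regularities reported here are
large-sample properties.

## A worked run

```{r, eval = FALSE}
library(spendseg)
cfg <- run_config(simulate = generator_config(n_beneficiaries = 20000, seed = 1),
                  out_dir = "spendseg-out")
run_segment(cfg)
run_report("spendseg-out")
```
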