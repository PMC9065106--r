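---
title: "Disproportionality signal detection on spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems collect individual case safety
reports (ICSRs): a patient, one or more drugs (with a role — suspected,
concomitant, interacting — and sometimes a daily dose), and one or more
adverse events coded as MedDRA Preferred Terms (PTs). There is no exposure
denominator, so absolute risks cannot be estimated. What can be estimated is
*disproportionality*: whether a drug–event pair is reported more often than
expected if drug and event occurred independently across the database. A
disproportionality signal is a hypothesis to be evaluated clinically, never
a confirmed causal association — reporting is biased by media attention,
time on market, indication and regional practices.

`pvsignal` packages this analysis for a drug class: the data model (a
MedDRA-like dictionary and an ICSR store), the statistics (Information
Component and reporting odds ratio), the staged scan over the hierarchy, the
descriptive outputs, and a synthetic-database generator used to validate the
whole chain against known ground truth.

## The Information Component

All counts are *report-level*: a report mentioning three PTs under one HLT
counts once for that HLT, and a drug mentioned twice counts once. From the
four counts `(n_obs, n_drug, n_effect, n_total)`,

$$\mathrm{IC} = \log_2 \frac{N_\mathrm{observed} + 0.5}
                            {N_\mathrm{expected} + 0.5},
  \qquad N_\mathrm{expected} = \frac{N_\mathrm{drug}\,N_\mathrm{effect}}
                                    {N_\mathrm{total}}.$$

The +0.5 terms act as a shrinkage prior: at tiny counts the IC is pulled
toward 0, which suppresses the flood of spurious large ratios that raw
observed/expected ratios produce in sparse tables.

**Credibility interval.** We model the posterior of the reporting rate
ratio as $\Gamma(\text{shape}=N_{obs}+0.5,\ \text{rate}=N_{exp}+0.5)$ and
take $\mathrm{IC}_{025}$ and $\mathrm{IC}_{975}$ as the log2 of its 2.5th
and 97.5th percentiles. This choice is consistent with the point estimate
above — the posterior mean of the rate ratio is exactly
$(N_{obs}+0.5)/(N_{exp}+0.5)$ — so the point estimate always lies inside the
interval, and the interval width shrinks like $1/\sqrt{N_{obs}}$ as
information accumulates. A Monte-Carlo posterior-sampling oracle in the test
suite confirms the quantiles to two decimals. A `normal_approx` variant
(lognormal moment-match of the same posterior via digamma/trigamma) is kept
for comparability with legacy implementations; both satisfy
$\mathrm{IC}_{025} \le \mathrm{IC} \le \mathrm{IC}_{975}$ on all valid
inputs.

**Signal rule.** A pair is flagged iff $\mathrm{IC}_{025} > 0$, strictly: a
lower bound of exactly zero is not a signal. With this rule, under no
association roughly 2.5% of informative pairs are flagged per test; the
suite verifies ≤ 5% pooled over seeds for pairs with $N_{exp} \ge 5$.

**Background choice.** By default the expected count is computed against the
full database, index-drug reports included (`background = "full"`), which is
the convention for IC screening against "all other reports" at scale;
`background = "other_drugs"` subtracts the drug's own reports from the
margins, which matters when the index class is a non-negligible share of the
database.

## The reporting odds ratio

For ranking drugs *within* a class on a given event, the IC against the
common background is confounded by the shared background; the head-to-head
reporting odds ratio is the natural contrast. Reports co-suspecting both
drugs are excluded (their count is reported), cells are
`a/b` (drug A with/without event) and `c/d` (drug B), and
$\mathrm{ROR} = ad/bc$ with the Woolf interval
$\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. Any zero cell
triggers the Haldane–Anscombe correction (+0.5 to all cells, flagged in the
output). On uncorrected tables $\mathrm{ROR}(A,B) = 1/\mathrm{ROR}(B,A)$
exactly.

## The hierarchy and multi-axiality

The dictionary model enforces: unique codes; parent links that climb exactly
one level; exactly one PT parent per LLT (so LLT-coded reactions are mapped
up losslessly on load); at least one parent for every non-SOC term (hence
every term reaches a SOC, and acyclicity is automatic). Links above PT may
be one-to-many. Real MedDRA assigns multi-axial PTs a *primary* SOC;
`soc_axis = "primary"` (the default) counts each PT under its primary SOC
only, so the SOC layer partitions events and a report is never
double-counted within one SOC row; `soc_axis = "all"` follows every axis.
Below SOC, drill-down gating uses all parent-link ancestors: the axis
distinction only exists at the SOC layer.

## The staged scan

`run_scan()` reproduces the screening cascade used in practice:

1. **SOC screen** — all SOCs, exposure = any class drug suspected.
2. **Drill-down** — HLGTs and HLTs (and PTs, only if requested) whose SOC
   ancestor had positive IC025 at *class* level, evaluated for the class and
   each drug separately. Gating on the class-level screen alone keeps the
   drug-level results reportable without making them gatekeepers.
3. **Comparisons** — pairwise RORs on the configured selected terms (the
   focused terms are configuration, not inference: which warnings to pursue
   is a regulatory choice).
4. **Dose stratification** — per drug with a dose rule, high = daily dose
   strictly over the threshold (so a report at exactly the threshold is low
   dose), reports without a dose excluded and counted; within-stratum IC
   plus the high-vs-low ROR with low dose as reference.

The scan is deterministic given dataset and configuration; every drill-down
row recomputed standalone through `contingency()` + `evaluate_signal()` is
identical (verified in the suite). PT-level results are restricted to
selected terms by default because an exhaustive PT drill-down is rarely read
row by row; `pt_scan()` provides the exhaustive PT table when needed (it
feeds the per-SOC positive-proportion summary).

## The synthetic generator

`generate_dataset()` emulates the features of a large ICSR database that
drive the statistics, with defaults chosen once to match published
descriptives of JAK-inhibitor spontaneous reports and held fixed:

- **Scale**: 200,000 background reports plus three index drugs × 5,000
  reports (a scaled-down database with the index class ≈ 7% of reports;
  the real ratio is nearer 0.5%, which only makes margins cleaner).
- **Dictionary**: balanced 27 SOC × 3 HLGT × 3 HLT × 3 PT tree (729 PTs)
  with one LLT per PT; optional multi-axial fraction.
- **Events per report**: K = 1 + Poisson(1.3), which has median 2 and IQR
  [1, 3] — the published median PT count per report.
- **Event frequencies**: PT weights ∝ rank^(−0.7), giving the top PT ≈ 4%
  of event mentions and a long tail, a realistic concentration.
- **Profiles**: per-drug age (medians 70/61/61), sex (>75% women for the two
  arthritis drugs), indication mixes, reporter mix, fatality and
  hospitalization probabilities, and dose menus ({2,4} and {5,10} mg/day for
  the drugs with dose thresholds).
- **Planting**: a signal multiplies the weights of all PTs under the target
  term by `rate_ratio` for that drug's reports (optionally only above a dose
  cut) and renormalizes. Renormalization keeps the per-report event-count
  distribution invariant, at the cost that the *realized* report-level
  observed/expected ratio is below the nominal event-level ratio: the
  planted excess also inflates the database margin `n_effect`, and
  multi-event reports dilute rates, so a nominal 4× plant realizes ≈ 3–3.5×
  at these sizes. The generator therefore records realized counts in its
  ground-truth output, and recovery tests condition on realized, not
  nominal, quantities; the realized ratio approaches the nominal one as the
  background grows (verified at three sizes).

What the generator does *not* emulate: duplicate reports, reporting latency
and secular trends, country effects, free-text drug names, correlated event
co-occurrence beyond the shared report mechanism, and missing-data patterns
other than absent doses. Passing tests on synthetic data therefore validate
the *statistical machinery* — counting, shrinkage, calibration, recovery,
ranking — not robustness to real-world reporting artefacts.

## Numerical choices and degenerate inputs

- `n_expected` is kept real-valued; no rounding anywhere in the chain.
- `IC` at `n_obs = n_expected = 0` is 0 by construction; `n_obs = 0` against
  a large expected count gives a strongly negative IC025, so an unreported
  pair can never signal.
- Gamma quantiles come from `qgamma`; no sampling is involved in the
  pipeline itself, so results are exactly reproducible without a seed. The
  configuration seed is echoed for downstream resampling extensions.
- Ties at the dose threshold go to the low stratum (strict ">").
- Reports with no reaction rows are rejected at load with a counted warning;
  dangling dictionary parents, duplicate report ids and unknown reaction
  codes are errors, not warnings.
- Empty drill-down gates, empty strata and zero-margin tables return empty
  results or raise argument errors rather than NaNs.

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use the study-scale
defaults above (215,000-report databases) with 10–20 seeds for the
calibration, recovery and ranking checks, and 20,000-report backgrounds for
the dose-stratification checks where only within-drug contrasts matter.
These sizes give every planted term an expected count well above the
regimes (≥ 20 for HLT recovery, ≥ 30 events per stratum for dose contrasts)
where the properties are claimed.

## Limitations

The package screens; it does not adjudicate. No multiplicity adjustment is
applied across the scan (the IC's shrinkage plus the IC025 threshold is the
traditional control, and the null-calibration check quantifies it); no
duplicate detection, no causality assessment, no latency analysis, and no
subgroup analyses beyond dose strata are provided. RORs compare reporting
odds, not risks, and inherit every reporting bias of the database.
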