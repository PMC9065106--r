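# pvsignal

Disproportionality-based signal detection for spontaneous adverse-event
reporting databases (pharmacovigilance).

Spontaneous-report databases (WHO VigiBase, FDA FAERS and their national
counterparts) collect individual case safety reports (ICSRs), each linking
one or more suspected drugs to one or more adverse events coded with the
MedDRA hierarchy (LLT → PT → HLT → HLGT → SOC). Because there is no
denominator of exposed patients, safety screening compares how often a
drug–event pair is *reported* against how often it would be reported if drug
and event were independent within the database. `pvsignal` implements this
workflow end to end for analysts evaluating a drug class: data model,
statistics, staged hierarchy scan, descriptive summaries, and a synthetic
database generator with planted signals of known strength so the whole
pipeline can be validated against ground truth.

## The statistics

For a drug–event pair counted at report level, with
`N_expected = N_drug × N_effect / N_total`, the **Information Component** is

    IC = log2 ( (N_observed + 0.5) / (N_expected + 0.5) )

The +0.5 terms shrink small-count ratios toward IC = 0. Uncertainty comes
from a gamma posterior on the reporting rate ratio,
`Gamma(shape = N_observed + 0.5, rate = N_expected + 0.5)`; `IC025` and
`IC975` are the log2 of its 2.5th and 97.5th percentiles. A pair is a
**signal** when `IC025 > 0` (strictly). Within a drug class, drugs are
compared head to head with the **reporting odds ratio**
`ROR = (a·d)/(b·c)` and its Woolf (log-normal) 95% CI, with the
Haldane–Anscombe 0.5 correction on zero cells.

The staged scan mirrors routine practice: screen all system organ classes
(SOCs) with class-level exposure; drill down through HLGT and HLT under the
positive SOCs, for the class and each drug; compare drugs pairwise on
selected terms; and re-estimate selected terms within high/low daily-dose
strata (high = strictly over the drug's threshold), with the ROR of high
versus low dose.

## Worked example

Generate a synthetic database (50,000 background reports, three index drugs
× 3,000 reports, 27-SOC dictionary) with a rate-ratio-4 signal planted on
one HLT for all three drugs, then run the staged scan:

```r
library(pvsignal)

drugs <- c("ruxolitinib", "tofacitinib", "baricitinib")
cfg <- generator_config(
  seed = 2026, n_background_reports = 50000,
  drug_profiles = default_drug_profiles(3000),
  planted_signals = lapply(drugs, function(d)
    list(drug = d, term_code = "SOC03.HG02.HT01", level = "HLT",
         rate_ratio = 4)))
g <- generate_dataset(cfg)

res <- run_scan(g$dataset, scan_config(
  class_drugs = drugs,
  selected_terms = data.frame(term_code = "SOC03.HG02.HT01", level = "HLT"),
  dose_rules = c(baricitinib = 2, tofacitinib = 5)))
summary(res)
```

```
Top SOC rows by IC025 (class exposure):
 term_code n_obs expected      ic   ic025 is_signal
     SOC03  1722     1348  0.3533  0.2843      TRUE
     SOC06   792      748  0.0826 -0.0197     FALSE
     ...

Drill-down: 10/48 rows flagged; top by IC025:
       term_code level  drug_scope n_obs expected  ic025
 SOC03.HG02.HT01   HLT       class   579    217.1 1.2934
 SOC03.HG02.HT01   HLT baricitinib   198     72.4 1.2380
 SOC03.HG02.HT01   HLT tofacitinib   194     72.4 1.2064
 SOC03.HG02.HT01   HLT ruxolitinib   187     72.4 1.1495
```

Only the SOC containing the planted HLT passes the screen (IC025 0.28 > 0),
and the drill-down localizes the signal to the planted HLT for the class and
each drug: 579 observed co-reports against 217 expected under independence,
IC ≈ 1.4 ≈ log2 of the realized report-level rate ratio. A single pair can
be inspected directly:

```r
ct <- contingency(g$dataset, "tofacitinib", "SOC03.HG02.HT01", "HLT")
evaluate_signal(ct)
#> IC 1.42 (1.21 to 1.61), n_obs=194, expected=72.36 -> SIGNAL (IC025 > 0)
```

Since all three drugs carry the same planted effect, the head-to-head RORs
sit near 1 (e.g. baricitinib vs ruxolitinib 1.06 [0.86–1.31]).
`soc_positive_proportions()` and `describe_reports()` produce the
per-SOC positive-PT proportions and the per-drug descriptive table;
`write_scan_report()` and `write_dataset()` serialize everything to flat
CSV/JSON.

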