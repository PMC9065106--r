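# Shared mid-size fixture: 20k background + 3 x 2k index reports, one
# class-wide planted HLT signal strong enough to open its SOC gate.
scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(
        seed = 502, n_background_reports = 20000,
        drug_profiles = default_drug_profiles(2000),
        planted_signals = lapply(
          c("ruxolitinib", "tofacitinib", "baricitinib"),
          function(d) list(drug = d, term_code = "SOC03.HG02.HT01",
                           level = "HLT", rate_ratio = 4)))
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})

base_config <- function(...) {
  scan_config(class_drugs = c("ruxolitinib", "tofacitinib", "baricitinib"),
              selected_terms = data.frame(term_code = "SOC03.HG02.HT01",
                                          level = "HLT"),
              dose_rules = c(baricitinib = 2, tofacitinib = 5), ...)
}

test_that("the SOC screen covers every SOC once and sorts by ic025", {
  g <- scan_fixture()
  soc <- soc_screen(g$dataset, base_config())
  expect_equal(sort(soc$term_code),
               terms_at_level(g$dataset$dictionary, "SOC")$code)
  expect_false(is.unsorted(rev(soc$ic025)))
  expect_true(all(soc$drug_scope == "class"))
  # the planted HLT lifts its SOC above the signal threshold
  expect_true("SOC03" %in% soc$term_code[soc$is_signal])
  expect_error(soc_screen(g$dataset, base_config()$nope), "scan_config")
})

test_that("a single-SOC dictionary yields a single screen row", {
  cfg <- generator_config(seed = 9, n_background_reports = 2000,
                          drug_profiles = default_drug_profiles(200),
                          dictionary_shape = c(1, 2, 2, 2))
  g <- generate_dataset(cfg)
  soc <- soc_screen(g$dataset, base_config())
  expect_equal(nrow(soc), 1)
})

test_that("drill-down is gated by positive SOCs and empty without them", {
  g <- scan_fixture()
  cfg <- base_config()
  expect_equal(nrow(drilldown(g$dataset, cfg, character(0))), 0)
  dd <- drilldown(g$dataset, cfg, "SOC03")
  expect_gt(nrow(dd), 0)
  # gating invariant: every row's SOC ancestor is a positive SOC
  for (i in seq_len(nrow(dd))) {
    expect_true("SOC03" %in% ancestors_at_level(
      g$dataset$dictionary, dd$term_code[i], "SOC"))
  }
  # scopes: class plus each drug
  expect_setequal(unique(dd$drug_scope),
                  c("class", "ruxolitinib", "tofacitinib", "baricitinib"))
  expect_error(drilldown(g$dataset, cfg, "SOC03.HG01"), "non-SOC")
})

test_that("a drug-specific planted HLT signal is flagged only for that drug", {
  cfg <- generator_config(
    seed = 77, n_background_reports = 20000,
    drug_profiles = default_drug_profiles(2000),
    planted_signals = list(list(drug = "baricitinib",
                                term_code = "SOC01.HG02.HT02",
                                level = "HLT", rate_ratio = 4)))
  g <- generate_dataset(cfg)
  dd <- drilldown(g$dataset, base_config(), "SOC01")
  row <- function(scope) dd[dd$term_code == "SOC01.HG02.HT02" &
                              dd$drug_scope == scope, ]
  expect_true(row("baricitinib")$is_signal)
  expect_false(row("ruxolitinib")$is_signal)
  expect_false(row("tofacitinib")$is_signal)
})

test_that("drug comparisons produce all ordered pairs with reciprocal RORs", {
  g <- scan_fixture()
  comp <- compare_drugs(g$dataset, base_config())
  expect_equal(nrow(comp), 6)  # 3 drugs, ordered pairs, 1 term
  for (i in seq_len(nrow(comp))) {
    j <- which(comp$drug_a == comp$drug_b[i] & comp$drug_b == comp$drug_a[i])
    if (!comp$continuity_corrected[i]) {
      expect_equal(comp$ror[i], 1 / comp$ror[j])
    }
  }
  cfg_null <- base_config()
  cfg_null$selected_terms <- data.frame(term_code = "SOC27.HG03.HT03",
                                        level = "HLT")
  expect_warning(compare_drugs(g$dataset, cfg_null), "no positive")
})

test_that("dose stratification splits strictly above the threshold", {
  dict <- toy_dictionary()
  reports <- data.frame(report_id = c("a", "b", "c", "d"))
  drugs <- data.frame(report_id = c("a", "b", "c", "d"),
                      drug_name = "baricitinib", role = "suspected",
                      daily_dose_mg = c(4, 2, 2.5, NA))
  rx <- data.frame(report_id = c("a", "b", "c", "d"),
                   pt_code = c("P1", "P1", "P3", "P1"))
  ds <- icsr_dataset(reports, drugs, rx, dict)
  cfg <- scan_config("baricitinib",
                     selected_terms = data.frame(term_code = "P1",
                                                 level = "PT"),
                     dose_rules = c(baricitinib = 2))
  out <- dose_stratified_scan(ds, cfg, "baricitinib")
  # dose 4 and 2.5 are high ("over 2"); dose exactly 2 is low; NA excluded
  high <- out$ic[out$ic$stratum == "high", ]
  low <- out$ic[out$ic$stratum == "low", ]
  expect_equal(high$n_drug, 2)
  expect_equal(low$n_drug, 1)
  expect_equal(attr(out, "n_dose_missing"), 1)
  expect_equal(out$ror$a, 1)  # high with P1: report a only
  expect_equal(out$ror$c, 1)  # low with P1: report b
  expect_error(dose_stratified_scan(ds, cfg, "ruxolitinib"), "dose rule")
})

test_that("the full scan composes all stages deterministically", {
  g <- scan_fixture()
  cfg <- base_config()
  rep1 <- run_scan(g$dataset, cfg)
  expect_s3_class(rep1, "scan_report")
  expect_gt(nrow(rep1$soc_results), 0)
  expect_gt(nrow(rep1$drilldown_results), 0)
  expect_gt(nrow(rep1$comparisons), 0)
  expect_length(rep1$dose_results, 2)
  rep2 <- run_scan(g$dataset, cfg)
  expect_identical(rep1, rep2)

  # stage consistency: a drill-down row recomputed standalone is identical
  dd <- rep1$drilldown_results
  row <- dd[dd$drug_scope == "tofacitinib", ][1, ]
  ct <- contingency(g$dataset, "tofacitinib", row$term_code, row$level,
                    soc_axis = cfg$soc_axis)
  s <- evaluate_signal(ct, ic_method = cfg$ic_method,
                       background = cfg$background)
  expect_equal(row$n_obs, ct$n_obs)
  expect_equal(row$expected, s$expected)
  expect_equal(row$ic025, s$ic025)

  out <- capture.output({print(rep1); summary(rep1)})
  expect_true(any(grepl("SOC screen", out)))
})

test_that("scan reports serialize to per-stage flat files", {
  g <- scan_fixture()
  rep1 <- run_scan(g$dataset, base_config())
  dir <- withr::local_tempdir()
  write_scan_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "soc_results.csv", "drilldown_results.csv", "comparisons.csv",
    "dose_ic.csv", "dose_ror.csv", "metadata.json")))))
  back <- read.csv(file.path(dir, "soc_results.csv"))
  expect_equal(back$ic025, rep1$soc_results$ic025)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$n_total, nrow(g$dataset$reports))
})
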