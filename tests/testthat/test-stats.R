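test_that("expected counts follow the independence formula", {
  expect_equal(expected_count(contingency_table(5, 100, 50, 1000)), 5.0)
  expect_equal(expected_count(contingency_table(0, 0, 50, 1000)), 0.0)
  expect_equal(expected_count(contingency_table(1000, 1000, 1000, 1000)),
               1000.0)
})

test_that("the IC point estimate matches its closed form at anchor points", {
  expect_equal(information_component(0, 0), 0.0)
  expect_equal(information_component(1, 0.25), 1.0)
  expect_equal(information_component(7, 7), 0.0)
  expect_error(information_component(-1, 2), "non-negative")
})

test_that("IC shrinks toward zero and is monotone in both counts", {
  set.seed(404)
  n_obs <- rpois(1e4, 20)
  n_exp <- runif(1e4, 0.01, 50)
  ic <- information_component(n_obs, n_exp)
  raw <- log2(n_obs / n_exp)
  ok <- n_obs > 0 & abs(n_obs - n_exp) > 1e-9
  expect_true(all(abs(ic[ok]) <= abs(raw[ok]) + 1e-12))
  # strictly increasing in n_obs, strictly decreasing in n_expected
  expect_true(all(diff(information_component(0:500, 10)) > 0))
  grid <- seq(0.1, 100, length.out = 500)
  expect_true(all(diff(information_component(10, grid)) < 0))
})

test_that("credibility bounds bracket the point estimate and tighten with information", {
  for (method in c("gamma", "normal_approx")) {
    for (n_obs in c(0, 1, 5, 200)) {
      for (n_exp in c(0, 0.5, 5, 50)) {
        ci <- ic_credibility_interval(n_obs, n_exp, method = method)
        ic <- information_component(n_obs, n_exp)
        expect_lte(ci$ic025, ic)
        expect_gte(ci$ic975, ic)
      }
    }
  }
  # width strictly decreases as counts scale at a fixed observed/expected ratio
  widths <- vapply(c(1, 10, 100), function(k) {
    ci <- ic_credibility_interval(20 * k, 10 * k)
    ci$ic975 - ci$ic025
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # and ic025 climbs toward log2(2) = 1
  lows <- vapply(c(1, 10, 100), function(k)
    ic_credibility_interval(20 * k, 10 * k)$ic025, numeric(1))
  expect_true(all(diff(lows) > 0))
  expect_lt(lows[3], 1)
  expect_gt(lows[3], 0.8)
  expect_error(ic_credibility_interval(5, 5, mass = 1), "mass")
})

test_that("zero observed reports can never be a signal", {
  ci <- ic_credibility_interval(0, 1000)
  expect_lt(ci$ic025, -5)
  s <- evaluate_signal(contingency_table(0, 100, 500, 10000))
  expect_false(s$is_signal)
})

test_that("the signal flag is exactly the strict positivity of ic025", {
  set.seed(77)
  for (i in 1:50) {
    n_total <- 5000L
    n_drug <- sample(50:500, 1)
    n_effect <- sample(50:500, 1)
    n_obs <- sample(0:min(n_drug, n_effect), 1)
    s <- evaluate_signal(contingency_table(n_obs, n_drug, n_effect, n_total))
    expect_identical(s$is_signal, s$ic025 > 0)
    expect_lte(s$ic025, s$ic)
    expect_gte(s$ic975, s$ic)
  }
  # a result with positive lower bound is flagged (class-level example of a
  # borderline 0.4 lower bound): find counts giving ic025 near 0.4
  s <- evaluate_signal(contingency_table(1803, 126815, 3100, 24416850))
  expect_gt(s$ic025, 0)
  expect_true(s$is_signal)
})

test_that("ROR point estimates, Woolf intervals and the continuity rule are exact", {
  r <- reporting_odds_ratio(10, 10, 10, 10)
  expect_equal(r$ror, 1.0)
  expect_lt(r$ci_low, 1); expect_gt(r$ci_high, 1)
  expect_false(r$continuity_corrected)

  r <- reporting_odds_ratio(20, 80, 10, 90)
  expect_equal(r$ror, 2.25)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(r$ci_low, exp(log(2.25) - qnorm(0.975) * se))
  expect_equal(r$ci_high, exp(log(2.25) + qnorm(0.975) * se))

  r0 <- reporting_odds_ratio(0, 20, 5, 15)
  expect_true(r0$continuity_corrected)
  expect_true(is.finite(r0$ci_low) && r0$ci_low > 0)
  expect_equal(r0$ror, (0.5 * 15.5) / (20.5 * 5.5))
  expect_error(reporting_odds_ratio(0, 0, 5, 15), "arm")
})

test_that("the ROR equals the logistic-regression odds ratio", {
  set.seed(12)
  for (i in 1:10) {
    cells <- sample(1:200, 4)
    r <- reporting_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    fit <- glm(cbind(c(cells[1], cells[3]), c(cells[2], cells[4])) ~
                 c(1, 0), family = binomial())
    expect_equal(r$ror, unname(exp(coef(fit)[2])), tolerance = 1e-8)
  }
})

test_that("Woolf intervals cover the true odds ratio at close to nominal rate", {
  set.seed(55)
  true_or <- 2
  p0 <- 0.15
  p1 <- true_or * p0 / (1 - p0 + true_or * p0)
  n <- 400
  hits <- 0L; total <- 0L
  for (i in 1:2000) {
    a <- rbinom(1, n, p1); c_ <- rbinom(1, n, p0)
    if (a %in% c(0, n) || c_ %in% c(0, n)) next
    r <- reporting_odds_ratio(a, n - a, c_, n - c_)
    total <- total + 1L
    hits <- hits + (r$ci_low <= true_or && true_or <= r$ci_high)
  }
  expect_gt(hits / total, 0.93)
  expect_lt(hits / total, 0.97)
})

test_that("IC and log-ROR agree in sign on informative tables", {
  set.seed(99)
  agree <- 0L; total <- 0L
  for (i in 1:500) {
    n_total <- 20000L
    n_drug <- sample(200:2000, 1)
    n_effect <- sample(200:2000, 1)
    exp_ct <- n_drug * n_effect / n_total
    if (exp_ct < 10) next
    n_obs <- rbinom(1, n_drug, n_effect / n_total)
    b <- n_drug - n_obs; c_ <- n_effect - n_obs
    d <- n_total - n_drug - c_
    if (n_obs == 0 || b == 0 || c_ == 0 || d == 0) next
    ic <- information_component(n_obs, exp_ct)
    lror <- log(reporting_odds_ratio(n_obs, b, c_, d)$ror)
    if (abs(ic) < 1e-6 || abs(lror) < 1e-6) next
    total <- total + 1L
    agree <- agree + (sign(ic) == sign(lror))
  }
  expect_gte(agree / total, 0.99)
})

test_that("head-to-head drug comparison excludes co-suspected reports and matches brute force", {
  fx <- random_icsr_fixture(61, n_reports = 120)
  hlgts <- terms_at_level(fx$dict, "HLGT")$code
  for (tc in hlgts[1:3]) {
    cells <- oracle_ror_cells(fx$dict$terms, fx$reports, fx$drugs,
                              fx$reactions, "druga", "drugb", tc, "HLGT")
    r <- ror_drug_vs_drug(fx$ds, "druga", "drugb", tc, "HLGT")
    expect_equal(c(a = r$a, b = r$b, c = r$c, d = r$d), cells)
    if (!r$continuity_corrected) {
      r_rev <- ror_drug_vs_drug(fx$ds, "drugb", "druga", tc, "HLGT")
      expect_equal(r$ror, 1 / r_rev$ror)
    }
  }
  expect_error(ror_drug_vs_drug(fx$ds, "druga", "druga", hlgts[1], "HLGT"),
               "distinct")
  expect_error(ror_drug_vs_drug(fx$ds, "druga", "nosuch", hlgts[1], "HLGT"),
               "no reports")
})

test_that("planted relative rates are recovered by the head-to-head ROR", {
  ok <- 0L
  for (seed in 1:5) {
    cfg <- generator_config(
      seed = seed, n_background_reports = 10000,
      drug_profiles = default_drug_profiles(3000),
      dictionary_shape = c(5, 2, 2, 3),
      planted_signals = list(list(drug = "baricitinib",
                                  term_code = "SOC02.HG01.HT01",
                                  level = "HLT", rate_ratio = 3)))
    g <- generate_dataset(cfg)
    r <- ror_drug_vs_drug(g$dataset, "baricitinib", "ruxolitinib",
                          "SOC02.HG01.HT01", "HLT")
    ok <- ok + (r$ci_low <= 3 && 3 <= r$ci_high * 1.6)
    expect_gt(r$ror, 1.5)
  }
  expect_gte(ok, 4)
})
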