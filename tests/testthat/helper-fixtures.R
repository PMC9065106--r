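# Hand-built fixtures shared across test files.

# Two-SOC dictionary with one multi-axial PT (P2 sits under H1/S1 and H3/S2,
# primary SOC S1) and one LLT.
toy_dictionary <- function() {
  meddra_dictionary(data.frame(
    code = c("S1", "S2", "G1", "G2", "H1", "H2", "H3",
             "P1", "P2", "P3", "P4", "L1"),
    name = paste("term", c("S1", "S2", "G1", "G2", "H1", "H2", "H3",
                           "P1", "P2", "P3", "P4", "L1")),
    level = c("SOC", "SOC", "HLGT", "HLGT", "HLT", "HLT", "HLT",
              "PT", "PT", "PT", "PT", "LLT"),
    parent_codes = c("", "", "S1", "S2", "G1", "G1", "G2",
                     "H1", "H1|H3", "H2", "H3", "P1"),
    primary_soc = c(NA, NA, NA, NA, NA, NA, NA,
                    "S1", "S1", "S1", "S2", NA),
    stringsAsFactors = FALSE
  ))
}

# 10 reports: 4 with drug A suspected, 5 with event P1, 2 with both,
# matching the worked 2x2 example (2, 4, 5, 10).
toy_dataset <- function() {
  dict <- toy_dictionary()
  reports <- data.frame(report_id = sprintf("r%02d", 1:10),
                        age_years = c(60, 70, 80, NA, 50, 55, 65, 75, 40, 45),
                        sex = rep(c("female", "male"), 5),
                        stringsAsFactors = FALSE)
  drugs <- data.frame(
    report_id = c("r01", "r02", "r03", "r04", "r05", "r05", "r06"),
    drug_name = c("druga", "druga", "druga", "druga", "drugb", "druga",
                  "drugb"),
    role = c("suspected", "suspected", "suspected", "suspected", "suspected",
             "concomitant", "suspected"),
    daily_dose_mg = c(4, 2, NA, 4, 5, 5, 10),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    report_id = c("r01", "r02", "r03", "r04", "r05", "r06", "r07", "r08",
                  "r09", "r10"),
    pt_code = c("P1", "P1", "P3", "P4", "P1", "P1", "P1", "P2", "P3", "P4"),
    serious = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                FALSE),
    fatal = c(TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE
  )
  icsr_dataset(reports, drugs, reactions, dict)
}

# Random small dictionary (multi-axial) for property tests.
random_dictionary <- function(seed, shape = c(3, 2, 2, 3)) {
  generate_dictionary(generator_config(
    seed = seed, dictionary_shape = shape, llt_per_pt = 1,
    multiaxial_fraction = 0.3))
}

# Random small ICSR fixture built directly (not via the generator) so that
# brute-force oracles exercise an independent construction path. Returns the
# raw tables alongside the validated dataset.
random_icsr_fixture <- function(seed, n_reports = 200) {
  set.seed(seed)
  dict <- random_dictionary(seed)
  pts <- terms_at_level(dict, "PT")$code
  ids <- sprintf("x%04d", seq_len(n_reports))
  drug_pool <- c("druga", "drugb", "drugc", "bg1", "bg2")
  drows <- lapply(ids, function(id) {
    k <- sample(1:2, 1)
    data.frame(report_id = id,
               drug_name = sample(drug_pool, k),
               role = sample(c("suspected", "concomitant", "interacting"),
                             k, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
               daily_dose_mg = ifelse(stats::runif(k) < 0.3, NA,
                                      sample(c(2, 4, 5, 10), k,
                                             replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  rrows <- lapply(ids, function(id) {
    k <- sample(1:3, 1)
    pt <- sample(pts, k, replace = TRUE)  # duplicates allowed on purpose
    data.frame(report_id = id, pt_code = pt, serious = FALSE, fatal = FALSE,
               stringsAsFactors = FALSE)
  })
  reports <- data.frame(report_id = ids, stringsAsFactors = FALSE)
  drugs <- do.call(rbind, drows)
  reactions <- do.call(rbind, rrows)
  list(dict = dict, reports = reports, drugs = drugs, reactions = reactions,
       ds = icsr_dataset(reports, drugs, reactions, dict))
}
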