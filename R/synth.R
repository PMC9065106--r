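# Synthetic spontaneous-reporting database generator: a balanced MedDRA-like
# dictionary, a large drug-unspecific background, index drugs with realistic
# demographic/indication/dose profiles, and planted drug-event associations
# of known rate ratio at any hierarchy level.

#' Default index-drug profiles
#'
#' Three JAK-inhibitor-like index drugs whose demographics mirror published
#' spontaneous-reporting descriptives: a myeloproliferative-neoplasm drug
#' (median age about 70, balanced sex, 14\% fatal reports) and two
#' rheumatoid-arthritis drugs (median age about 61, over 75\% women, low
#' fatality). Daily doses support high/low stratification at thresholds of
#' 5 mg/day and 2 mg/day for the second and third drug.
#'
#' @param n_reports Reports per index drug.
#' @return Named list of profile lists, one per drug.
#' @export
default_drug_profiles <- function(n_reports = 5000) {
  list(
    ruxolitinib = list(
      n_reports = n_reports,
      dose = list(values = c(10, 20, 30, 40), probs = rep(0.25, 4)),
      indication = c(myelofibrosis = 0.435, `polycythemia vera` = 0.193),
      age_mean = 70, age_sd = 15, p_female = 0.50, p_physician = 0.25,
      p_fatal = 0.140, p_hosp = 0.163
    ),
    tofacitinib = list(
      n_reports = n_reports,
      dose = list(values = c(5, 10), probs = c(0.5, 0.5)),
      indication = c(`rheumatoid arthritis` = 0.55),
      age_mean = 61, age_sd = 14, p_female = 0.76, p_physician = 0.20,
      p_fatal = 0.019, p_hosp = 0.096
    ),
    baricitinib = list(
      n_reports = n_reports,
      dose = list(values = c(2, 4), probs = c(0.5, 0.5)),
      indication = c(`rheumatoid arthritis` = 0.797),
      age_mean = 61, age_sd = 14, p_female = 0.76, p_physician = 0.20,
      p_fatal = 0.014, p_hosp = 0.129
    )
  )
}

#' Configuration of the synthetic-database generator
#'
#' @param seed Integer seed; identical configurations generate identical
#'   databases (and identical files through [write_dataset()]).
#' @param n_background_reports Background database size (reports carrying a
#'   dummy background drug).
#' @param drug_profiles Named list of index-drug profiles, see
#'   [default_drug_profiles()].
#' @param dictionary_shape Integer vector
#'   `(n_soc, hlgt_per_soc, hlt_per_hlgt, pt_per_hlt)`; the default
#'   `(27, 3, 3, 3)` gives the 27 SOCs of the real nosology with 729 PTs.
#' @param llt_per_pt LLT leaves per PT (each LLT maps to exactly one PT).
#' @param n_background_drugs Number of dummy background drugs.
#' @param event_weight_exponent Power-law exponent `alpha`: baseline PT
#'   weights are proportional to `rank^-alpha` in PT code order, emulating
#'   the heavy-tailed event frequencies of real databases.
#' @param events_per_report_lambda PT count per report is
#'   `1 + Poisson(lambda)`; the default 1.3 gives median 2 and IQR 1-3.
#' @param multiaxial_fraction Fraction of PTs given a second HLT parent under
#'   a different SOC (primary SOC stays the original one).
#' @param planted_signals List of planted associations, each a list with
#'   `drug`, `term_code`, `level`, `rate_ratio` (> 0) and optional
#'   `dose_over` (the signal then applies only to reports of the drug with a
#'   daily dose strictly over this value, i.e. a high-dose-only effect).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_background_reports = 200000,
                             drug_profiles = default_drug_profiles(),
                             dictionary_shape = c(27, 3, 3, 3),
                             llt_per_pt = 1,
                             n_background_drugs = 50,
                             event_weight_exponent = 0.7,
                             events_per_report_lambda = 1.3,
                             multiaxial_fraction = 0,
                             planted_signals = list()) {
  stopifnot(length(dictionary_shape) == 4, all(dictionary_shape >= 1),
            llt_per_pt >= 0, n_background_drugs >= 1,
            event_weight_exponent >= 0, events_per_report_lambda > 0,
            multiaxial_fraction >= 0, multiaxial_fraction <= 1)
  for (p in drug_profiles) stopifnot(p$n_reports >= 0)
  for (s in planted_signals) {
    stopifnot(!is.null(s$drug), !is.null(s$term_code), !is.null(s$level),
              is.numeric(s$rate_ratio), s$rate_ratio > 0)
  }
  structure(
    list(seed = as.integer(seed),
         n_background_reports = as.integer(n_background_reports),
         drug_profiles = drug_profiles,
         dictionary_shape = as.integer(dictionary_shape),
         llt_per_pt = as.integer(llt_per_pt),
         n_background_drugs = as.integer(n_background_drugs),
         event_weight_exponent = event_weight_exponent,
         events_per_report_lambda = events_per_report_lambda,
         multiaxial_fraction = multiaxial_fraction,
         planted_signals = planted_signals),
    class = "generator_config"
  )
}

#' Generate a balanced synthetic dictionary
#'
#' Builds a deterministic balanced tree with self-describing codes
#' (`SOC01`, `SOC01.HG01`, `SOC01.HG01.HT01`, `SOC01.HG01.HT01.PT01`, ...),
#' optionally adding a second, cross-SOC HLT parent to a random fraction of
#' PTs to emulate multi-axiality.
#'
#' @param cfg A `generator_config`.
#' @return A `meddra_dict`.
#' @export
generate_dictionary <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sh <- cfg$dictionary_shape
  soc <- sprintf("SOC%02d", seq_len(sh[1]))
  hg <- as.vector(outer(sprintf(".HG%02d", seq_len(sh[2])), soc,
                        function(s, p) paste0(p, s)))
  ht <- as.vector(outer(sprintf(".HT%02d", seq_len(sh[3])), hg,
                        function(s, p) paste0(p, s)))
  pt <- as.vector(outer(sprintf(".PT%02d", seq_len(sh[4])), ht,
                        function(s, p) paste0(p, s)))
  parent_of <- function(code) sub("\\.[A-Z]{2}[0-9]+$", "", code)
  soc_of <- function(code) sub("\\..*$", "", code)

  pt_parents <- parent_of(pt)
  if (cfg$multiaxial_fraction > 0 && sh[1] > 1) {
    n_multi <- floor(cfg$multiaxial_fraction * length(pt))
    if (n_multi > 0) {
      pick <- sort(sample.int(length(pt), n_multi))
      for (i in pick) {
        other <- ht[soc_of(ht) != soc_of(pt[i])]
        extra <- sample(other, 1)
        pt_parents[i] <- paste(pt_parents[i], extra, sep = "|")
      }
    }
  }
  rows <- list(
    data.frame(code = soc, level = "SOC", parent_codes = "",
               primary_soc = NA_character_, stringsAsFactors = FALSE),
    data.frame(code = hg, level = "HLGT", parent_codes = parent_of(hg),
               primary_soc = NA_character_, stringsAsFactors = FALSE),
    data.frame(code = ht, level = "HLT", parent_codes = parent_of(ht),
               primary_soc = NA_character_, stringsAsFactors = FALSE),
    data.frame(code = pt, level = "PT", parent_codes = pt_parents,
               primary_soc = soc_of(pt), stringsAsFactors = FALSE)
  )
  if (cfg$llt_per_pt > 0) {
    llt <- as.vector(outer(sprintf(".LT%02d", seq_len(cfg$llt_per_pt)), pt,
                           function(s, p) paste0(p, s)))
    rows[[5]] <- data.frame(code = llt, level = "LLT",
                            parent_codes = parent_of(llt),
                            primary_soc = NA_character_,
                            stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, rows)
  terms$name <- paste("Synthetic term", terms$code)
  meddra_dictionary(terms)
}

# Descendant PTs of a term (identity at PT level).
.descendant_pts <- function(dict, term_code, level) {
  map <- .ancestor_map(dict, "PT", level)
  sort(unique(map$code[map$ancestor == term_code]))
}

.sample_categorical <- function(n, probs) {
  # probs: named probabilities summing to <= 1; remainder goes to "other"
  rest <- 1 - sum(probs)
  p <- c(probs, other = max(rest, 0))
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic ICSR database with known ground truth
#'
#' Background reports carry one dummy background drug; index-drug reports
#' carry their drug with dose, indication and demographics drawn from the
#' profile. Every report draws `1 + Poisson(lambda)` PT events from the
#' power-law baseline weights; for index drugs, weights of PTs under each
#' planted term are multiplied by the signal's `rate_ratio` and renormalized
#' (so a planted signal slightly deflates the drug's other events, and the
#' realized ratio at small n is reported in the ground truth rather than
#' assumed equal to the nominal one).
#'
#' @param cfg A `generator_config`.
#' @return List with elements `dataset` (an `icsr_dataset`) and `truth`
#'   (data.frame echoing each planted signal with its realized report-level
#'   counts `n_obs`, `n_drug`, `n_effect`, `n_total` and `n_expected`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  dict <- generate_dictionary(cfg)
  set.seed(cfg$seed + 1L)

  pts <- terms_at_level(dict, "PT")$code
  w_base <- seq_along(pts)^(-cfg$event_weight_exponent)
  for (s in cfg$planted_signals) {
    if (!s$term_code %in% dict$terms$code) {
      stop("planted term not in dictionary: ", s$term_code, call. = FALSE)
    }
  }

  profiles <- c(list(.background = list(
    n_reports = cfg$n_background_reports,
    dose = NULL, indication = NULL,
    age_mean = 60, age_sd = 18, p_female = 0.50, p_physician = 0.20,
    p_fatal = 0.05, p_hosp = 0.10
  )), cfg$drug_profiles)

  bg_drugs <- sprintf("bgdrug%02d", seq_len(cfg$n_background_drugs))
  rep_rows <- list(); drug_rows <- list(); rx_rows <- list()
  fatal_ids <- character(0)
  next_id <- 0L
  for (dn in names(profiles)) {
    p <- profiles[[dn]]
    n <- p$n_reports
    if (n == 0) next
    ids <- sprintf("R%08d", next_id + seq_len(n))
    next_id <- next_id + n

    age <- round(pmin(pmax(stats::rnorm(n, p$age_mean, p$age_sd), 18), 100))
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(p$p_female, 1 - p$p_female))
    reporter <- sample(
      c("physician", "other_health_professional", "consumer", "other"), n,
      replace = TRUE,
      prob = c(p$p_physician, (1 - p$p_physician) * c(0.4, 0.4, 0.2)))
    fatal <- stats::runif(n) < p$p_fatal
    hosp <- stats::runif(n) < p$p_hosp
    fatal_ids <- c(fatal_ids, ids[fatal])
    rep_rows[[dn]] <- data.frame(
      report_id = ids, age_years = age, sex = sex, reporter = reporter,
      country = NA_character_, stringsAsFactors = FALSE)

    if (dn == ".background") {
      drug_name <- sample(bg_drugs, n, replace = TRUE)
      dose <- rep(NA_real_, n)
      indication <- rep(NA_character_, n)
    } else {
      drug_name <- rep(dn, n)
      dose <- if (is.null(p$dose)) rep(NA_real_, n) else
        sample(p$dose$values, n, replace = TRUE, prob = p$dose$probs)
      indication <- if (is.null(p$indication)) rep(NA_character_, n) else
        .sample_categorical(n, p$indication)
    }
    drug_rows[[dn]] <- data.frame(
      report_id = ids, drug_name = drug_name, role = "suspected",
      daily_dose_mg = dose, indication = indication,
      stringsAsFactors = FALSE)

    # event sampling: weight groups differ by which planted signals apply
    sigs <- Filter(function(s) identical(tolower(s$drug), dn),
                   cfg$planted_signals)
    applies <- matrix(TRUE, nrow = n, ncol = length(sigs))
    if (length(sigs)) {
      for (j in seq_along(sigs)) {
        if (!is.null(sigs[[j]]$dose_over)) {
          applies[, j] <- !is.na(dose) & dose > sigs[[j]]$dose_over
        }
      }
    }
    group <- if (length(sigs)) {
      apply(applies, 1, function(r) paste(as.integer(r), collapse = ""))
    } else rep("", n)
    k <- 1L + stats::rpois(n, cfg$events_per_report_lambda)
    for (g in unique(group)) {
      in_g <- group == g
      w <- w_base
      if (length(sigs)) {
        on <- as.logical(as.integer(strsplit(g, "")[[1]]))
        for (j in which(on)) {
          under <- .descendant_pts(dict, sigs[[j]]$term_code, sigs[[j]]$level)
          w[pts %in% under] <- w[pts %in% under] * sigs[[j]]$rate_ratio
        }
      }
      kk <- k[in_g]
      ev <- sample(pts, sum(kk), replace = TRUE, prob = w)
      rx_rows[[paste(dn, g)]] <- data.frame(
        report_id = rep(ids[in_g], kk), pt_code = ev,
        serious = rep(fatal[in_g] | hosp[in_g], kk),
        fatal = FALSE, stringsAsFactors = FALSE)
    }
  }
  reports <- do.call(rbind, rep_rows)
  drugs <- do.call(rbind, drug_rows)
  reactions <- do.call(rbind, rx_rows)
  reactions <- reactions[order(match(reactions$report_id,
                                     reports$report_id)), , drop = FALSE]
  # fatal reports carry the flag on their first reaction mention
  first <- !duplicated(reactions$report_id)
  reactions$fatal <- first & reactions$report_id %in% fatal_ids
  rownames(reports) <- rownames(drugs) <- rownames(reactions) <- NULL

  ds <- icsr_dataset(reports, drugs, reactions, dict)

  truth <- NULL
  if (length(cfg$planted_signals)) {
    truth <- do.call(rbind, lapply(cfg$planted_signals, function(s) {
      ct <- contingency(ds, s$drug, s$term_code, s$level)
      data.frame(
        drug = tolower(s$drug), term_code = s$term_code, level = s$level,
        rate_ratio = s$rate_ratio,
        dose_over = if (is.null(s$dose_over)) NA_real_ else s$dose_over,
        n_obs = ct$n_obs, n_drug = ct$n_drug, n_effect = ct$n_effect,
        n_total = ct$n_total, n_expected = expected_count(ct),
        stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
  }
  list(dataset = ds, truth = truth)
}

#' Write a dataset (and ground truth) to plain-text files
#'
#' Emits `reports.csv`, `drugs.csv`, `reactions.csv`, `dictionary.csv` and,
#' when ground truth is supplied, `ground_truth.json`. Reading the files back
#' with [read_meddra_dictionary()] and [read_icsr_dataset()] reproduces the
#' dataset exactly.
#'
#' @param ds An `icsr_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth data.frame from [generate_dataset()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, truth = NULL) {
  stopifnot(inherits(ds, "icsr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$reports, file.path(dir, "reports.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(ds$reactions, file.path(dir, "reactions.csv"),
                   row.names = FALSE)
  write_meddra_dictionary(ds$dictionary, file.path(dir, "dictionary.csv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         pretty = TRUE, na = "null")
  }
  invisible(dir)
}
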