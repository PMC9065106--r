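# Staged hierarchy scan: class-level SOC screen, drill-down through
# HLGT/HLT for the class and each drug, head-to-head drug comparisons on
# selected terms, and dose-stratified analyses.

#' Configuration of a staged scan
#'
#' @param class_drugs Character vector of index drug names forming the
#'   therapeutic class (non-empty).
#' @param soc_axis `"primary"` (default) counts each PT under its primary SOC
#'   only at SOC level; `"all"` follows every axis.
#' @param levels Hierarchy levels scanned, ordered general to specific.
#'   `"SOC"` drives the screen; `"HLGT"`/`"HLT"` drive the drill-down; adding
#'   `"PT"` forces an exhaustive PT-level drill-down (by default PT results
#'   are computed only for `selected_terms`).
#' @param selected_terms data.frame with columns `term_code`, `level` (or
#'   NULL): the focused terms for drug comparisons and dose stratification.
#' @param dose_rules Named numeric vector: daily-dose threshold in mg/day per
#'   drug; a report is high dose when its dose is strictly over the threshold.
#' @param background `"full"` (default) or `"other_drugs"`, see
#'   [evaluate_signal()].
#' @param roles Drug roles counting as exposure.
#' @param ic_method Credibility-interval method, see
#'   [ic_credibility_interval()].
#' @param seed Integer seed echoed into the report (the scan itself is
#'   deterministic; the seed keys any downstream resampling).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(class_drugs,
                        soc_axis = c("primary", "all"),
                        levels = c("SOC", "HLGT", "HLT"),
                        selected_terms = NULL,
                        dose_rules = NULL,
                        background = c("full", "other_drugs"),
                        roles = "suspected",
                        ic_method = c("gamma", "normal_approx"),
                        seed = 1L) {
  stopifnot(length(class_drugs) >= 1L)
  soc_axis <- match.arg(soc_axis)
  background <- match.arg(background)
  ic_method <- match.arg(ic_method)
  .level_rank(levels)
  if (is.unsorted(rev(.level_rank(levels)))) {
    stop("levels must be ordered from general to specific", call. = FALSE)
  }
  if (!is.null(selected_terms)) {
    selected_terms <- as.data.frame(selected_terms, stringsAsFactors = FALSE)
    stopifnot(all(c("term_code", "level") %in% names(selected_terms)))
    selected_terms$term_code <- as.character(selected_terms$term_code)
    selected_terms$level <- as.character(selected_terms$level)
    .level_rank(selected_terms$level)
  }
  if (!is.null(dose_rules)) {
    stopifnot(is.numeric(dose_rules), !is.null(names(dose_rules)),
              all(dose_rules > 0))
    names(dose_rules) <- tolower(names(dose_rules))
  }
  structure(
    list(class_drugs = tolower(class_drugs), soc_axis = soc_axis,
         levels = levels, selected_terms = selected_terms,
         dose_rules = dose_rules, background = background, roles = roles,
         ic_method = ic_method, seed = as.integer(seed)),
    class = "scan_config"
  )
}

# Exposure report-id sets for the class and each drug.
.scope_ids <- function(ds, cfg) {
  out <- list(class = reports_with_drug(ds, cfg$class_drugs, cfg$roles))
  for (d in cfg$class_drugs) out[[d]] <- reports_with_drug(ds, d, cfg$roles)
  out
}

# Signal rows for one exposure set over a set of terms at one level.
.scan_level <- function(ds, exposure_ids, scope_label, level, cfg,
                        terms = NULL) {
  tl <- terms_at_level(ds$dictionary, level)
  if (!is.null(terms)) tl <- tl[tl$code %in% terms, , drop = FALSE]
  if (nrow(tl) == 0) {
    return(.signal_frame(character(), character(), character(), character(),
                         integer(), integer(), integer(), integer(),
                         cfg$background, cfg$ic_method))
  }
  em <- .event_map(ds, level, cfg$soc_axis)
  n_effect <- table(factor(em$term, levels = tl$code))
  in_drug <- em$report_id %in% exposure_ids
  n_obs <- table(factor(em$term[in_drug], levels = tl$code))
  .signal_frame(
    term_code = tl$code, term_name = tl$name, level = level,
    drug_scope = scope_label,
    n_obs = as.integer(n_obs), n_drug = length(exposure_ids),
    n_effect = as.integer(n_effect), n_total = nrow(ds$reports),
    background = cfg$background, ic_method = cfg$ic_method
  )
}

#' Stage 1: class-level SOC screen
#'
#' One signal row per SOC with exposure defined as "any drug of the class
#' suspected" (a report co-suspecting several class drugs counts once).
#' Rows are sorted by `ic025` descending.
#'
#' @param ds An `icsr_dataset`.
#' @param cfg A `scan_config`.
#' @return data.frame of signal rows (one per SOC).
#' @export
soc_screen <- function(ds, cfg) {
  stopifnot(inherits(ds, "icsr_dataset"), inherits(cfg, "scan_config"))
  socs <- terms_at_level(ds$dictionary, "SOC")
  if (nrow(socs) == 0) stop("dictionary has no SOC terms", call. = FALSE)
  ids <- reports_with_drug(ds, cfg$class_drugs, cfg$roles)
  out <- .scan_level(ds, ids, "class", "SOC", cfg)
  out <- out[order(-out$ic025, out$term_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Terms at `level` whose SOC ancestors (parent links) intersect positive_socs.
.gated_terms <- function(dict, level, positive_socs) {
  if (level == "SOC") return(intersect(terms_at_level(dict, level)$code,
                                       positive_socs))
  amap <- .ancestor_map(dict, level, "SOC")
  sort(unique(amap$code[amap$ancestor %in% positive_socs]))
}

#' Stage 2: drill-down below positive SOCs
#'
#' For the class and for each drug separately, computes signal rows for every
#' HLGT and HLT (per `cfg$levels`) whose SOC ancestor is among
#' `positive_socs`, plus any `cfg$selected_terms` passing the same gate. With
#' `"PT"` in `cfg$levels` the PT layer is scanned exhaustively as well.
#'
#' @param ds An `icsr_dataset`.
#' @param cfg A `scan_config`.
#' @param positive_socs SOC codes that passed the class-level screen.
#' @return data.frame of signal rows.
#' @export
drilldown <- function(ds, cfg, positive_socs) {
  stopifnot(inherits(ds, "icsr_dataset"), inherits(cfg, "scan_config"))
  soc_codes <- terms_at_level(ds$dictionary, "SOC")$code
  if (!all(positive_socs %in% soc_codes)) {
    stop("positive_socs contains non-SOC code(s)", call. = FALSE)
  }
  scopes <- .scope_ids(ds, cfg)
  levels_below <- setdiff(cfg$levels, "SOC")
  want <- lapply(levels_below, function(lv)
    .gated_terms(ds$dictionary, lv, positive_socs))
  names(want) <- levels_below
  if (!is.null(cfg$selected_terms)) {
    for (i in seq_len(nrow(cfg$selected_terms))) {
      lv <- cfg$selected_terms$level[i]
      tc <- cfg$selected_terms$term_code[i]
      if (lv == "SOC") next
      if (length(intersect(ancestors_at_level(ds$dictionary, tc, "SOC"),
                           positive_socs))) {
        want[[lv]] <- union(want[[lv]], tc)
      }
    }
  }
  rows <- list()
  for (scope in names(scopes)) {
    for (lv in names(want)) {
      if (!length(want[[lv]])) next
      rows[[length(rows) + 1L]] <-
        .scan_level(ds, scopes[[scope]], scope, lv, cfg, terms = want[[lv]])
    }
  }
  if (!length(rows)) {
    return(.signal_frame(character(), character(), character(), character(),
                         integer(), integer(), integer(), integer(),
                         cfg$background, cfg$ic_method))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage 3: head-to-head drug comparisons on selected terms
#'
#' All ordered pairs of class drugs, for every selected term. On tables
#' needing no continuity correction, `ror(A, B) = 1 / ror(B, A)`, so the
#' ordered pairs carry the full ranking information. A warning is issued for
#' selected terms with no positive `ic025` for any single drug.
#'
#' @param ds An `icsr_dataset`.
#' @param cfg A `scan_config` with non-NULL `selected_terms`.
#' @return data.frame with one row per (drug_a, drug_b, term).
#' @export
compare_drugs <- function(ds, cfg) {
  stopifnot(inherits(ds, "icsr_dataset"), inherits(cfg, "scan_config"))
  st <- cfg$selected_terms
  if (is.null(st) || nrow(st) == 0) {
    stop("selected_terms is empty", call. = FALSE)
  }
  drugs <- cfg$class_drugs
  rows <- list()
  for (i in seq_len(nrow(st))) {
    tc <- st$term_code[i]; lv <- st$level[i]
    any_pos <- FALSE
    for (d in drugs) {
      t2 <- contingency(ds, d, tc, lv, cfg$roles, cfg$soc_axis)
      s <- evaluate_signal(t2, ic_method = cfg$ic_method,
                           background = cfg$background)
      if (s$is_signal) { any_pos <- TRUE; break }
    }
    if (!any_pos) {
      warning("selected term ", tc,
              " has no positive ic025 for any class drug")
    }
    for (da in drugs) for (db in drugs) {
      if (da == db) next
      r <- ror_drug_vs_drug(ds, da, db, tc, lv, cfg$roles, cfg$soc_axis)
      rows[[length(rows) + 1L]] <- data.frame(
        term_code = tc, level = lv, drug_a = da, drug_b = db,
        a = r$a, b = r$b, c = r$c, d = r$d,
        ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
        continuity_corrected = r$continuity_corrected,
        n_cosuspected = attr(r, "n_cosuspected"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Max daily dose per report for one drug (role-filtered); NA-dose reports
# are excluded from stratification.
.dose_by_report <- function(ds, drug, roles) {
  d <- ds$drugs
  hit <- d$drug_name == tolower(drug) & d$role %in% roles
  dd <- d[hit & !is.na(d$daily_dose_mg), , drop = FALSE]
  if (nrow(dd) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tapply(dd$daily_dose_mg, dd$report_id, max)
}

#' Stage 4: dose-stratified analysis for one drug
#'
#' Splits the drug's reports into high dose (daily dose strictly over the
#' drug's threshold in `cfg$dose_rules`) and low dose (at or under it;
#' reports without a recorded dose are excluded, their count is reported in
#' the result's `n_dose_missing` attribute). For each selected term it
#' computes the within-stratum IC against the configured background and the
#' ROR of high versus low dose (low dose as reference). Terms with an empty
#' stratum are skipped with a warning.
#'
#' @param ds An `icsr_dataset`.
#' @param cfg A `scan_config` with a dose rule for `drug`.
#' @param drug Drug name.
#' @return List with data.frames `ic` (per term x stratum signal rows) and
#'   `ror` (per term high-vs-low rows).
#' @export
dose_stratified_scan <- function(ds, cfg, drug) {
  stopifnot(inherits(ds, "icsr_dataset"), inherits(cfg, "scan_config"))
  drug <- tolower(drug)
  if (!drug %in% names(cfg$dose_rules)) {
    stop("no dose rule configured for ", drug, call. = FALSE)
  }
  thr <- unname(cfg$dose_rules[[drug]])
  st <- cfg$selected_terms
  if (is.null(st) || nrow(st) == 0) {
    stop("selected_terms is empty", call. = FALSE)
  }
  dose <- .dose_by_report(ds, drug, cfg$roles)
  all_drug <- reports_with_drug(ds, drug, cfg$roles)
  n_missing <- length(all_drug) - length(dose)
  strata <- list(high = names(dose)[dose > thr],
                 low = names(dose)[dose <= thr])
  ic_rows <- list(); ror_rows <- list()
  for (i in seq_len(nrow(st))) {
    tc <- st$term_code[i]; lv <- st$level[i]
    ev <- reports_with_event(ds, tc, lv, cfg$soc_axis)
    if (length(strata$high) == 0 || length(strata$low) == 0) {
      warning("empty dose stratum for ", drug, "; term ", tc, " skipped")
      next
    }
    for (s in c("high", "low")) {
      ids <- strata[[s]]
      ic_rows[[length(ic_rows) + 1L]] <- cbind(
        .signal_frame(tc, .dict_name(ds$dictionary, tc), lv,
                      paste(drug, s, sep = ":"),
                      n_obs = length(intersect(ids, ev)),
                      n_drug = length(ids),
                      n_effect = length(ev), n_total = nrow(ds$reports),
                      background = cfg$background,
                      ic_method = cfg$ic_method),
        data.frame(drug = drug, stratum = s, stringsAsFactors = FALSE)
      )
    }
    a <- length(intersect(strata$high, ev))
    c_ <- length(intersect(strata$low, ev))
    r <- reporting_odds_ratio(a, length(strata$high) - a,
                              c_, length(strata$low) - c_)
    ror_rows[[length(ror_rows) + 1L]] <- data.frame(
      term_code = tc, level = lv, drug = drug,
      a = r$a, b = r$b, c = r$c, d = r$d,
      ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
      continuity_corrected = r$continuity_corrected,
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    ic = if (length(ic_rows)) do.call(rbind, ic_rows) else NULL,
    ror = if (length(ror_rows)) do.call(rbind, ror_rows) else NULL
  )
  attr(out, "n_dose_missing") <- n_missing
  out
}

.dict_name <- function(dict, codes) {
  dict$terms$name[match(codes, dict$terms$code)]
}

#' Run the full staged scan
#'
#' Executes, in order: the class-level SOC screen; the drill-down through
#' HLGT/HLT (and selected terms) under SOCs with a positive `ic025`;
#' head-to-head drug comparisons on the selected terms; and dose-stratified
#' analyses for every drug with a dose rule. The result is deterministic
#' given the dataset and configuration.
#'
#' @param ds An `icsr_dataset`.
#' @param cfg A `scan_config`.
#' @return An object of class `scan_report` with elements `soc_results`,
#'   `drilldown_results`, `comparisons`, `dose_results` and `metadata`.
#' @export
run_scan <- function(ds, cfg) {
  stopifnot(inherits(ds, "icsr_dataset"), inherits(cfg, "scan_config"))
  soc <- soc_screen(ds, cfg)
  positive <- soc$term_code[soc$is_signal]
  drill <- drilldown(ds, cfg, positive)
  comp <- NULL
  if (!is.null(cfg$selected_terms) && nrow(cfg$selected_terms) > 0) {
    comp <- compare_drugs(ds, cfg)
  }
  dose <- list()
  for (drug in intersect(cfg$class_drugs, names(cfg$dose_rules))) {
    dose[[drug]] <- dose_stratified_scan(ds, cfg, drug)
  }
  per_drug <- vapply(cfg$class_drugs, function(d)
    length(reports_with_drug(ds, d, cfg$roles)), integer(1))
  class_ids <- reports_with_drug(ds, cfg$class_drugs, cfg$roles)
  # reports suspected of >1 class drug: counted once at class level,
  # once per drug in per-drug scopes
  n_co <- sum(per_drug) - length(class_ids)
  structure(
    list(soc_results = soc,
         drilldown_results = drill,
         comparisons = comp,
         dose_results = dose,
         metadata = list(
           n_total = nrow(ds$reports),
           n_class = length(class_ids),
           n_per_drug = as.list(per_drug),
           n_cosuspected_class = n_co,
           positive_socs = positive,
           config = unclass(cfg)
         )),
    class = "scan_report"
  )
}

#' @export
print.scan_report <- function(x, ...) {
  m <- x$metadata
  cat("Staged disproportionality scan\n")
  cat(sprintf("  database: %d reports; class exposure: %d reports (%s)\n",
              m$n_total, m$n_class,
              paste(m$config$class_drugs, collapse = ", ")))
  cat(sprintf("  SOC screen: %d/%d SOCs with positive IC025\n",
              length(m$positive_socs), nrow(x$soc_results)))
  cat(sprintf("  drill-down rows: %d; comparison rows: %d; dose rows: %d\n",
              nrow(x$drilldown_results),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
              sum(vapply(x$dose_results, function(d)
                if (is.null(d$ic)) 0L else nrow(d$ic), integer(1)))))
  invisible(x)
}

#' @export
summary.scan_report <- function(object, n = 10, ...) {
  cat("Top SOC rows by IC025 (class exposure):\n")
  print(utils::head(object$soc_results[
    , c("term_code", "n_obs", "expected", "ic", "ic025", "is_signal")], n),
    row.names = FALSE, digits = 3)
  dd <- object$drilldown_results
  if (!is.null(dd) && nrow(dd)) {
    sig <- dd[dd$is_signal, , drop = FALSE]
    cat(sprintf("\nDrill-down: %d/%d rows flagged; top by IC025:\n",
                nrow(sig), nrow(dd)))
    sig <- sig[order(-sig$ic025), , drop = FALSE]
    print(utils::head(sig[, c("term_code", "level", "drug_scope", "n_obs",
                              "expected", "ic025")], n),
          row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Serialize a scan report to flat files
#'
#' Writes one CSV per stage (`soc_results.csv`, `drilldown_results.csv`,
#' `comparisons.csv`, `dose_ic.csv`, `dose_ror.csv`) plus `metadata.json`.
#'
#' @param x A `scan_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_report <- function(x, dir) {
  stopifnot(inherits(x, "scan_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$soc_results, file.path(dir, "soc_results.csv"),
                   row.names = FALSE)
  utils::write.csv(x$drilldown_results,
                   file.path(dir, "drilldown_results.csv"), row.names = FALSE)
  if (!is.null(x$comparisons)) {
    utils::write.csv(x$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  ic <- do.call(rbind, lapply(x$dose_results, `[[`, "ic"))
  ror <- do.call(rbind, lapply(x$dose_results, `[[`, "ror"))
  if (!is.null(ic)) {
    utils::write.csv(ic, file.path(dir, "dose_ic.csv"), row.names = FALSE)
  }
  if (!is.null(ror)) {
    utils::write.csv(ror, file.path(dir, "dose_ror.csv"), row.names = FALSE)
  }
  jsonlite::write_json(x$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
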