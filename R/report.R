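# Paper-style summaries: exhaustive PT-level disproportionality per drug,
# per-SOC proportions of positive PTs, and descriptive report tables.

#' Exhaustive PT-level disproportionality scan for one exposure
#'
#' One signal row per PT reported at least once with the drug(s). PTs never
#' co-reported with the exposure are not tested hypotheses and are omitted
#' (the denominators of [soc_positive_proportions()] follow this rule).
#'
#' @param ds An `icsr_dataset`.
#' @param drug_names Drug name(s) defining the exposure.
#' @param scope_label Label written into the `drug_scope` column.
#' @param roles Drug roles that count as exposure.
#' @param background,ic_method See [evaluate_signal()].
#' @return data.frame of signal rows, sorted by PT code.
#' @export
pt_scan <- function(ds, drug_names, scope_label = paste(drug_names,
                                                        collapse = "+"),
                    roles = "suspected", background = "full",
                    ic_method = "gamma") {
  stopifnot(inherits(ds, "icsr_dataset"))
  ids <- reports_with_drug(ds, drug_names, roles)
  em <- .event_map(ds, "PT", "all")
  in_drug <- em$report_id %in% ids
  tested <- sort(unique(em$term[in_drug]))
  n_obs <- table(factor(em$term[in_drug], levels = tested))
  n_effect <- table(factor(em$term[em$term %in% tested], levels = tested))
  .signal_frame(
    term_code = tested, term_name = .dict_name(ds$dictionary, tested),
    level = "PT", drug_scope = scope_label,
    n_obs = as.integer(n_obs), n_drug = length(ids),
    n_effect = as.integer(n_effect), n_total = nrow(ds$reports),
    background = background, ic_method = ic_method
  )
}

#' Per-SOC proportion of PTs with a positive IC025
#'
#' For each drug, runs the exhaustive PT scan and aggregates by SOC: the
#' number of PTs tested (reported at least once with the drug), the number
#' with `ic025 > 0`, and their ratio. Every (SOC, drug) pair appears, with
#' proportion 0 when no tested PT is positive; displaying only non-zero SOCs
#' is a presentation choice left to the caller.
#'
#' @param ds An `icsr_dataset`.
#' @param drug_names Drugs to summarize (one row set per drug).
#' @param soc_axis `"primary"` (default) assigns each PT to its primary SOC,
#'   partitioning the tested PTs; `"all"` counts multi-axial PTs under every
#'   SOC ancestor.
#' @param roles,background,ic_method Passed to [pt_scan()].
#' @return data.frame with columns `soc_code`, `soc_name`, `drug_name`,
#'   `n_pt_tested`, `n_pt_positive`, `proportion`.
#' @export
soc_positive_proportions <- function(ds, drug_names,
                                     soc_axis = c("primary", "all"),
                                     roles = "suspected",
                                     background = "full",
                                     ic_method = "gamma") {
  stopifnot(inherits(ds, "icsr_dataset"))
  soc_axis <- match.arg(soc_axis)
  socs <- terms_at_level(ds$dictionary, "SOC")
  if (soc_axis == "primary") {
    ps <- .primary_soc_map(ds$dictionary)
    map <- data.frame(code = names(ps), ancestor = unname(ps),
                      stringsAsFactors = FALSE)
  } else {
    map <- .ancestor_map(ds$dictionary, "PT", "SOC")
  }
  rows <- list()
  for (d in drug_names) {
    sc <- pt_scan(ds, d, scope_label = tolower(d), roles = roles,
                  background = background, ic_method = ic_method)
    m <- merge(sc[, c("term_code", "is_signal")], map,
               by.x = "term_code", by.y = "code")
    soc_f <- factor(m$ancestor, levels = socs$code)
    tested <- table(soc_f)
    positive <- table(soc_f[m$is_signal])
    rows[[d]] <- data.frame(
      soc_code = socs$code, soc_name = socs$name, drug_name = tolower(d),
      n_pt_tested = as.integer(tested),
      n_pt_positive = as.integer(positive),
      proportion = ifelse(tested > 0, as.integer(positive) /
                            as.integer(tested), 0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grouped bar chart of per-SOC positive-PT proportions
#'
#' A plain grouped bar chart standing in for the radial layout often used for
#' this summary (layout is presentation, not method).
#'
#' @param props Output of [soc_positive_proportions()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_soc_proportions <- function(props, ...) {
  m <- stats::xtabs(proportion ~ drug_name + soc_code, data = props)
  graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.6,
                    ylab = "proportion of tested PTs with IC025 > 0",
                    legend.text = rownames(m), ...)
}

.pct <- function(x) 100 * mean(x, na.rm = TRUE)

#' Descriptive summary of reports per drug
#'
#' Per-drug report counts, median age with IQR, percentage of women, of
#' physician reporters, of reports with at least one fatal event, of reports
#' with at least one serious (e.g. hospitalization) event, and the median
#' number of distinct PTs per report with IQR. Missing ages/sexes are
#' excluded from their summaries; the number of reports with missing age is
#' returned in `n_age_missing`.
#'
#' @param ds An `icsr_dataset`.
#' @param drug_names Drugs to describe.
#' @param roles Drug roles that count as exposure.
#' @return data.frame with one row per drug.
#' @export
describe_reports <- function(ds, drug_names, roles = "suspected") {
  stopifnot(inherits(ds, "icsr_dataset"))
  known <- unique(ds$drugs$drug_name)
  missing <- setdiff(tolower(drug_names), known)
  if (length(missing)) {
    stop("drug(s) not present in dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(drug_names, function(d) {
    ids <- reports_with_drug(ds, d, roles)
    rep_ <- ds$reports[ds$reports$report_id %in% ids, , drop = FALSE]
    rx <- ds$reactions[ds$reactions$report_id %in% ids, , drop = FALSE]
    pts_per <- tapply(rx$pt_code, rx$report_id,
                      function(x) length(unique(x)))
    fatal_by <- tapply(rx$fatal, rx$report_id, function(x) any(x %in% TRUE))
    serious_by <- tapply(rx$serious, rx$report_id,
                         function(x) any(x %in% TRUE))
    aq <- stats::quantile(rep_$age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
    pq <- stats::quantile(pts_per, c(0.25, 0.5, 0.75), type = 1,
                          names = FALSE)
    data.frame(
      drug_name = tolower(d), n_reports = nrow(rep_),
      age_median = aq[2], age_q25 = aq[1], age_q75 = aq[3],
      n_age_missing = sum(is.na(rep_$age_years)),
      pct_female = .pct(rep_$sex == "female"),
      pct_physician = .pct(rep_$reporter == "physician"),
      pct_fatal = 100 * mean(fatal_by),
      pct_serious = 100 * mean(serious_by),
      pts_median = pq[2], pts_q25 = pq[1], pts_q75 = pq[3],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
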