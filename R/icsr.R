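# Individual case safety reports (ICSRs): one record per spontaneous report,
# with drug mentions (role, daily dose, indication) and reaction mentions
# coded at MedDRA PT level. All disproportionality counts are report-level.

#' Construct and validate an ICSR dataset
#'
#' Assembles the report store from three linked tables keyed by `report_id`.
#' Reaction codes are validated against the dictionary; LLT codes are mapped
#' up to their unique PT parent. Reports without any reaction row are dropped
#' with a warning (a case safety report must carry at least one adverse
#' event).
#'
#' @param reports data.frame with columns `report_id` and optionally
#'   `age_years`, `sex` (`female`/`male`/`unknown`), `reporter`, `country`.
#' @param drugs data.frame with columns `report_id`, `drug_name`, `role`
#'   (`suspected`/`concomitant`/`interacting`) and optionally `daily_dose_mg`,
#'   `indication`.
#' @param reactions data.frame with columns `report_id`, `pt_code` (or
#'   `llt_code`) and optionally logical `serious`, `fatal`.
#' @param dictionary A `meddra_dict` the reaction codes resolve against.
#' @return An object of class `icsr_dataset` with elements `reports`,
#'   `drugs`, `reactions`, `dictionary`.
#' @export
icsr_dataset <- function(reports, drugs, reactions, dictionary) {
  stopifnot(inherits(dictionary, "meddra_dict"))
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  if (is.null(reports$report_id)) stop("reports table needs report_id",
                                       call. = FALSE)
  reports$report_id <- as.character(reports$report_id)
  if (anyDuplicated(reports$report_id)) {
    stop("duplicated report_id(s): ",
         paste(unique(reports$report_id[duplicated(reports$report_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("age_years")) {
    if (is.null(reports[[col]])) reports[[col]] <- NA_real_
    reports[[col]] <- as.numeric(reports[[col]])
  }
  for (col in c("sex", "reporter", "country")) {
    if (is.null(reports[[col]])) reports[[col]] <- NA_character_
    reports[[col]] <- as.character(reports[[col]])
  }

  need_d <- setdiff(c("report_id", "drug_name", "role"), names(drugs))
  if (length(need_d)) {
    stop("drugs table missing column(s): ", paste(need_d, collapse = ", "),
         call. = FALSE)
  }
  drugs$report_id <- as.character(drugs$report_id)
  drugs$drug_name <- tolower(trimws(as.character(drugs$drug_name)))
  drugs$role <- as.character(drugs$role)
  bad_role <- setdiff(unique(drugs$role),
                      c("suspected", "concomitant", "interacting"))
  if (length(bad_role)) {
    stop("unknown drug role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(drugs$daily_dose_mg)) drugs$daily_dose_mg <- NA_real_
  drugs$daily_dose_mg <- as.numeric(drugs$daily_dose_mg)
  if (any(is.finite(drugs$daily_dose_mg) & drugs$daily_dose_mg < 0)) {
    stop("negative daily_dose_mg", call. = FALSE)
  }
  if (is.null(drugs$indication)) drugs$indication <- NA_character_
  drugs$indication <- as.character(drugs$indication)

  if (is.null(reactions$report_id)) stop("reactions table needs report_id",
                                         call. = FALSE)
  reactions$report_id <- as.character(reactions$report_id)
  if (is.null(reactions$pt_code) && is.null(reactions$llt_code)) {
    stop("reactions table needs a pt_code or llt_code column", call. = FALSE)
  }
  code <- if (!is.null(reactions$pt_code)) as.character(reactions$pt_code)
          else rep(NA_character_, nrow(reactions))
  if (!is.null(reactions$llt_code)) {
    llt <- as.character(reactions$llt_code)
    use <- (is.na(code) | !nzchar(code)) & !is.na(llt) & nzchar(llt)
    code[use] <- llt[use]
  }
  i <- match(code, dictionary$terms$code)
  if (anyNA(i)) {
    stop("reaction code(s) not in dictionary: ",
         paste(sort(unique(code[is.na(i)])), collapse = ", "), call. = FALSE)
  }
  lev <- dictionary$terms$level[i]
  if (any(!lev %in% c("PT", "LLT"))) {
    stop("reaction code(s) not at PT/LLT level: ",
         paste(sort(unique(code[!lev %in% c("PT", "LLT")])), collapse = ", "),
         call. = FALSE)
  }
  if (any(lev == "LLT")) {
    # each LLT has exactly one PT parent, so mapping up loses nothing
    e <- dictionary$edges
    up <- stats::setNames(e$parent, e$code)
    code[lev == "LLT"] <- unname(up[code[lev == "LLT"]])
  }
  reactions$pt_code <- code
  reactions$llt_code <- NULL
  for (col in c("serious", "fatal")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- NA
    reactions[[col]] <- as.logical(reactions[[col]])
  }

  orphan_d <- setdiff(drugs$report_id, reports$report_id)
  orphan_r <- setdiff(reactions$report_id, reports$report_id)
  if (length(orphan_d) || length(orphan_r)) {
    stop("drug/reaction rows reference unknown report_id(s): ",
         paste(sort(unique(c(orphan_d, orphan_r))), collapse = ", "),
         call. = FALSE)
  }

  no_reaction <- !(reports$report_id %in% reactions$report_id)
  if (any(no_reaction)) {
    warning(sum(no_reaction),
            " report(s) without reactions dropped from dataset")
    keep <- reports$report_id[!no_reaction]
    reports <- reports[!no_reaction, , drop = FALSE]
    drugs <- drugs[drugs$report_id %in% keep, , drop = FALSE]
  }

  rownames(reports) <- rownames(drugs) <- rownames(reactions) <- NULL
  structure(
    list(reports = reports[, c("report_id", "age_years", "sex", "reporter",
                               "country")],
         drugs = drugs[, c("report_id", "drug_name", "role", "daily_dose_mg",
                           "indication")],
         reactions = reactions[, c("report_id", "pt_code", "serious",
                                   "fatal")],
         dictionary = dictionary),
    class = "icsr_dataset"
  )
}

#' Read an ICSR dataset from its three-file CSV serialization
#'
#' @param reports_path,drugs_path,reactions_path Paths to `reports.csv`,
#'   `drugs.csv`, `reactions.csv` (columns as in [icsr_dataset()]).
#' @param dictionary A loaded `meddra_dict`.
#' @return A validated `icsr_dataset`.
#' @seealso [write_dataset()] for the inverse.
#' @export
read_icsr_dataset <- function(reports_path, drugs_path, reactions_path,
                              dictionary) {
  for (p in c(reports_path, drugs_path, reactions_path)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  icsr_dataset(
    utils::read.csv(reports_path, stringsAsFactors = FALSE),
    utils::read.csv(drugs_path, stringsAsFactors = FALSE),
    utils::read.csv(reactions_path, stringsAsFactors = FALSE),
    dictionary
  )
}

#' Reports mentioning any of a set of drugs
#'
#' Matching is case-insensitive on the normalized drug name. By default only
#' mentions with role `suspected` count (spontaneous-report disproportionality
#' convention); widen `roles` for sensitivity analyses.
#'
#' @param ds An `icsr_dataset`.
#' @param drug_names Character vector of drug names (non-empty).
#' @param roles Drug roles that count as exposure.
#' @return Character vector of unique report ids.
#' @export
reports_with_drug <- function(ds, drug_names, roles = "suspected") {
  stopifnot(inherits(ds, "icsr_dataset"), length(drug_names) >= 1L)
  hit <- ds$drugs$drug_name %in% tolower(trimws(drug_names)) &
    ds$drugs$role %in% roles
  unique(ds$drugs$report_id[hit])
}

# Report-level event map at a hierarchy level: data.frame(report_id, term),
# deduplicated so a report counts once per term no matter how many of its
# reaction PTs roll up to it. soc_axis applies only when level == "SOC".
.event_map <- function(ds, level, soc_axis = c("primary", "all")) {
  soc_axis <- match.arg(soc_axis)
  rx <- ds$reactions
  if (level == "PT") {
    map <- data.frame(code = unique(rx$pt_code), stringsAsFactors = FALSE)
    map$ancestor <- map$code
  } else if (level == "SOC" && soc_axis == "primary") {
    ps <- .primary_soc_map(ds$dictionary)
    map <- data.frame(code = names(ps), ancestor = unname(ps),
                      stringsAsFactors = FALSE)
  } else {
    map <- .ancestor_map(ds$dictionary, "PT", level)
  }
  if (!anyDuplicated(map$code)) {
    term <- map$ancestor[match(rx$pt_code, map$code)]
    out <- data.frame(report_id = rx$report_id, term = term,
                      stringsAsFactors = FALSE)
  } else {
    i <- split(seq_len(nrow(map)), map$code)
    idx <- i[rx$pt_code]
    n <- lengths(idx)
    out <- data.frame(report_id = rep(rx$report_id, n),
                      term = map$ancestor[unlist(idx, use.names = FALSE)],
                      stringsAsFactors = FALSE)
  }
  out <- out[!is.na(out$term), , drop = FALSE]
  out[!duplicated(paste0(out$report_id, "\r", out$term)), , drop = FALSE]
}

#' Reports mentioning an event term at any hierarchy level
#'
#' A report counts once for a term if at least one of its reaction PTs has
#' that term among its ancestors at the stated level (report-level
#' deduplication: three sibling PTs under one HLT count the report once).
#'
#' @param ds An `icsr_dataset`.
#' @param term_code Code of a term at `level`.
#' @param level Hierarchy level of `term_code`.
#' @param soc_axis For SOC-level queries: `"primary"` counts each PT under its
#'   primary SOC only; `"all"` follows every axis.
#' @return Character vector of unique report ids.
#' @export
reports_with_event <- function(ds, term_code, level,
                               soc_axis = c("primary", "all")) {
  stopifnot(inherits(ds, "icsr_dataset"), length(term_code) == 1L)
  soc_axis <- match.arg(soc_axis)
  if (.dict_level(ds$dictionary, term_code) != level) {
    stop("term ", term_code, " is not at level ", level, call. = FALSE)
  }
  em <- .event_map(ds, level, soc_axis)
  em$report_id[em$term == term_code]
}

#' The 2x2 contingency counts behind an IC or ROR
#'
#' @param n_obs Reports with both the drug and the event.
#' @param n_drug Reports with the drug.
#' @param n_effect Reports with the event.
#' @param n_total All reports in the database.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(n_obs, n_drug, n_effect, n_total) {
  v <- c(n_obs = n_obs, n_drug = n_drug, n_effect = n_effect,
         n_total = n_total)
  if (any(v < 0) || any(v != round(v))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (n_obs > min(n_drug, n_effect) || max(n_drug, n_effect) > n_total ||
      n_total - n_drug - n_effect + n_obs < 0) {
    stop("inconsistent contingency counts", call. = FALSE)
  }
  structure(as.list(v), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(
    "2x2 report counts: n_obs=%d n_drug=%d n_effect=%d n_total=%d\n",
    x$n_obs, x$n_drug, x$n_effect, x$n_total))
  invisible(x)
}

#' Build the 2x2 contingency table for a (drug set, event term) pair
#'
#' Counts are report-level over the whole dataset: `n_obs` reports mention
#' both a listed drug (in an accepted role) and the event term at the given
#' level; margins as documented in [contingency_table()].
#'
#' @inheritParams reports_with_drug
#' @inheritParams reports_with_event
#' @return A `contingency_table`.
#' @export
contingency <- function(ds, drug_names, term_code, level,
                        roles = "suspected",
                        soc_axis = c("primary", "all")) {
  soc_axis <- match.arg(soc_axis)
  d <- reports_with_drug(ds, drug_names, roles)
  e <- reports_with_event(ds, term_code, level, soc_axis)
  contingency_table(
    n_obs = length(intersect(d, e)),
    n_drug = length(d),
    n_effect = length(e),
    n_total = nrow(ds$reports)
  )
}

#' @export
print.icsr_dataset <- function(x, ...) {
  cat("ICSR dataset:", nrow(x$reports), "reports,",
      nrow(x$drugs), "drug mentions,",
      nrow(x$reactions), "reaction mentions\n")
  cat("Dictionary:", nrow(x$dictionary$terms), "terms\n")
  invisible(x)
}
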