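# Brute-force reference implementations, kept independent of the package
# internals they check: they operate on raw term/report tables only.

# Exhaustive breadth-first search over parent links in the raw term table.
oracle_ancestors <- function(terms, code, target) {
  lv <- c("LLT", "PT", "HLT", "HLGT", "SOC")
  rank <- function(cd) match(terms$level[terms$code == cd], lv)
  parents <- function(cd) {
    p <- strsplit(terms$parent_codes[terms$code == cd], "|",
                  fixed = TRUE)[[1]]
    p[nzchar(p)]
  }
  frontier <- code
  while (rank(frontier[1]) < match(target, lv)) {
    frontier <- unique(unlist(lapply(frontier, parents)))
  }
  sort(frontier)
}

# Report-by-report double loop over the raw tables (all-axes event counting).
oracle_contingency <- function(terms, reports, drugs, reactions,
                               drug_names, term_code, level,
                               roles = "suspected") {
  n_obs <- n_drug <- n_effect <- 0L
  for (id in reports$report_id) {
    drow <- drugs[drugs$report_id == id, , drop = FALSE]
    has_drug <- any(tolower(drow$drug_name) %in% tolower(drug_names) &
                      drow$role %in% roles)
    pts <- unique(reactions$pt_code[reactions$report_id == id])
    has_event <- any(vapply(pts, function(p)
      term_code %in% oracle_ancestors(terms, p, level), logical(1)))
    n_drug <- n_drug + has_drug
    n_effect <- n_effect + has_event
    n_obs <- n_obs + (has_drug && has_event)
  }
  c(n_obs = n_obs, n_drug = n_drug, n_effect = n_effect,
    n_total = nrow(reports))
}

# Brute-force 2x2 cells for a head-to-head drug comparison (suspected role,
# co-suspected reports excluded).
oracle_ror_cells <- function(terms, reports, drugs, reactions,
                             drug_a, drug_b, term_code, level) {
  cells <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  for (id in reports$report_id) {
    drow <- drugs[drugs$report_id == id & drugs$role == "suspected", ,
                  drop = FALSE]
    in_a <- drug_a %in% tolower(drow$drug_name)
    in_b <- drug_b %in% tolower(drow$drug_name)
    if (in_a == in_b) next  # neither, or co-suspected
    pts <- unique(reactions$pt_code[reactions$report_id == id])
    ev <- any(vapply(pts, function(p)
      term_code %in% oracle_ancestors(terms, p, level), logical(1)))
    if (in_a && ev) cells["a"] <- cells["a"] + 1L
    if (in_a && !ev) cells["b"] <- cells["b"] + 1L
    if (in_b && ev) cells["c"] <- cells["c"] + 1L
    if (in_b && !ev) cells["d"] <- cells["d"] + 1L
  }
  cells
}

# Monte-Carlo posterior-sampling oracle for the IC credibility bounds.
oracle_ic_quantiles <- function(n_obs, n_expected, n_draws = 1e6) {
  draws <- stats::rgamma(n_draws, shape = n_obs + 0.5,
                         rate = n_expected + 0.5)
  log2(stats::quantile(draws, c(0.025, 0.975), names = FALSE))
}
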