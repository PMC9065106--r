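# Disproportionality statistics: the Information Component (IC), a shrinkage
# log2 observed-to-expected reporting ratio with a Bayesian credibility
# interval, and the reporting odds ratio (ROR) with Woolf confidence limits.

#' Expected report count under independence
#'
#' `n_expected = n_drug * n_effect / n_total`: the number of drug-and-event
#' reports expected if drug and event were mentioned independently across the
#' database.
#'
#' @param t A `contingency_table`.
#' @return Non-negative real (not rounded).
#' @export
expected_count <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n_total == 0) stop("n_total must be positive", call. = FALSE)
  t$n_drug * t$n_effect / t$n_total
}

#' Information Component point estimate
#'
#' `IC = log2((n_obs + 0.5) / (n_expected + 0.5))`. The +0.5 terms shrink the
#' ratio toward 1 (IC toward 0), so the statistic is defined and stable even
#' at `n_obs = 0`.
#'
#' @param n_obs Observed drug-and-event report count (vectorized).
#' @param n_expected Expected count under independence (vectorized).
#' @return IC in log2 units.
#' @export
information_component <- function(n_obs, n_expected) {
  if (any(n_obs < 0) || any(n_expected < 0)) {
    stop("n_obs and n_expected must be non-negative", call. = FALSE)
  }
  log2((n_obs + 0.5) / (n_expected + 0.5))
}

#' Credibility interval of the Information Component
#'
#' The posterior of the reporting rate ratio is taken as
#' `Gamma(shape = n_obs + 0.5, rate = n_expected + 0.5)`; the bounds are the
#' log2 of its central-`mass` quantiles. The posterior mean is
#' `(n_obs+0.5)/(n_expected+0.5)`, so the point estimate of
#' [information_component()] always lies inside the interval. The
#' `normal_approx` method is the lognormal moment-match of the same posterior
#' (mean `digamma(shape) - log(rate)`, sd `sqrt(trigamma(shape))` on the
#' natural-log scale), kept for comparability with legacy implementations.
#'
#' @inheritParams information_component
#' @param mass Posterior mass of the central interval (default 0.95).
#' @param method `"gamma"` (exact quantiles, default) or `"normal_approx"`.
#' @return List with numeric vectors `ic025` and `ic975` (named for the
#'   default 95\% mass), in log2 units.
#' @export
ic_credibility_interval <- function(n_obs, n_expected, mass = 0.95,
                                    method = c("gamma", "normal_approx")) {
  method <- match.arg(method)
  if (any(n_obs < 0) || any(n_expected < 0)) {
    stop("n_obs and n_expected must be non-negative", call. = FALSE)
  }
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  alpha <- (1 - mass) / 2
  shape <- n_obs + 0.5
  rate <- n_expected + 0.5
  if (method == "gamma") {
    lo <- log2(stats::qgamma(alpha, shape = shape, rate = rate))
    hi <- log2(stats::qgamma(1 - alpha, shape = shape, rate = rate))
  } else {
    z <- stats::qnorm(1 - alpha)
    mu <- digamma(shape) - log(rate)
    sd <- sqrt(trigamma(shape))
    lo <- (mu - z * sd) / log(2)
    hi <- (mu + z * sd) / log(2)
  }
  list(ic025 = lo, ic975 = hi)
}

#' Evaluate the signal decision for one contingency table
#'
#' Composes [expected_count()], [information_component()] and
#' [ic_credibility_interval()]. The pair is a signal when the lower
#' credibility bound is strictly positive (`ic025 > 0`; a bound of exactly
#' zero is not a signal).
#'
#' @param t A `contingency_table`.
#' @param mass Credibility mass (default 0.95).
#' @param ic_method Interval method, see [ic_credibility_interval()].
#' @param background `"full"` compares against the whole database (the
#'   default; the index drug's own reports stay in the background);
#'   `"other_drugs"` computes the expected count from reports not mentioning
#'   the drug.
#' @return An object of class `ic_signal` with fields `table`, `expected`,
#'   `ic`, `ic025`, `ic975`, `is_signal`.
#' @export
evaluate_signal <- function(t, mass = 0.95,
                            ic_method = c("gamma", "normal_approx"),
                            background = c("full", "other_drugs")) {
  stopifnot(inherits(t, "contingency_table"))
  ic_method <- match.arg(ic_method)
  background <- match.arg(background)
  if (background == "full") {
    expected <- expected_count(t)
  } else {
    n_bg <- t$n_total - t$n_drug
    if (n_bg == 0) stop("no background reports", call. = FALSE)
    expected <- t$n_drug * (t$n_effect - t$n_obs) / n_bg
  }
  ci <- ic_credibility_interval(t$n_obs, expected, mass, ic_method)
  structure(
    list(table = t,
         expected = expected,
         ic = information_component(t$n_obs, expected),
         ic025 = ci$ic025,
         ic975 = ci$ic975,
         is_signal = ci$ic025 > 0),
    class = "ic_signal"
  )
}

#' @export
print.ic_signal <- function(x, digits = 2, ...) {
  cat(sprintf(
    "IC %.*f (%.*f to %.*f), n_obs=%d, expected=%.2f -> %s\n",
    digits, x$ic, digits, x$ic025, digits, x$ic975,
    x$table$n_obs, x$expected,
    if (x$is_signal) "SIGNAL (IC025 > 0)" else "no signal"))
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a*d)/(b*c)` from the 2x2 table (a = exposed with event,
#' b = exposed without, c = reference with event, d = reference without).
#' The 95\% CI is the log-normal (Woolf) interval
#' `exp(log(ror) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero,
#' the Haldane-Anscombe correction adds 0.5 to all four cells and flags the
#' result.
#'
#' @param a,b,c,d Non-negative integer cell counts; both margins `a+b` and
#'   `c+d` must be positive.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `pv_ror` with fields `a,b,c,d`, `ror`,
#'   `ci_low`, `ci_high`, `continuity_corrected`.
#' @export
reporting_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("no reports in one exposure arm (a+b or c+d is zero)", call. = FALSE)
  }
  corrected <- any(v == 0)
  if (corrected) v <- v + 0.5
  ror <- (v["a"] * v["d"]) / (v["b"] * v["c"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / v))
  structure(
    list(a = a, b = b, c = c, d = d,
         ror = unname(ror),
         ci_low = unname(exp(log(ror) - z * se)),
         ci_high = unname(exp(log(ror) + z * se)),
         continuity_corrected = corrected),
    class = "pv_ror"
  )
}

#' @export
print.pv_ror <- function(x, digits = 2, ...) {
  cat(sprintf("ROR %.*f [%.*f-%.*f]%s (a=%d b=%d c=%d d=%d)\n",
              digits, x$ror, digits, x$ci_low, digits, x$ci_high,
              if (x$continuity_corrected) " (0.5 continuity correction)"
              else "",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Head-to-head ROR between two drugs for one event term
#'
#' Restricts the database to reports suspected of exactly one of the two
#' drugs (reports co-suspecting both are excluded; their count is attached as
#' attribute `n_cosuspected`) and computes the ROR of the event with `drug_a`
#' relative to `drug_b`.
#'
#' @param ds An `icsr_dataset`.
#' @param drug_a,drug_b Distinct drug names; `drug_b` is the reference.
#' @param term_code,level Event term and its hierarchy level.
#' @param roles Drug roles that count as exposure.
#' @param soc_axis SOC counting axis for SOC-level terms.
#' @return A `pv_ror`.
#' @export
ror_drug_vs_drug <- function(ds, drug_a, drug_b, term_code, level,
                             roles = "suspected",
                             soc_axis = c("primary", "all")) {
  soc_axis <- match.arg(soc_axis)
  if (tolower(drug_a) == tolower(drug_b)) {
    stop("drug_a and drug_b must be distinct", call. = FALSE)
  }
  ra <- reports_with_drug(ds, drug_a, roles)
  rb <- reports_with_drug(ds, drug_b, roles)
  co <- intersect(ra, rb)
  ra <- setdiff(ra, co)
  rb <- setdiff(rb, co)
  if (length(ra) == 0 || length(rb) == 0) {
    stop("no reports for ", if (length(ra) == 0) drug_a else drug_b,
         " after excluding co-suspected reports", call. = FALSE)
  }
  ev <- reports_with_event(ds, term_code, level, soc_axis)
  a <- length(intersect(ra, ev))
  c_ <- length(intersect(rb, ev))
  out <- reporting_odds_ratio(a, length(ra) - a, c_, length(rb) - c_)
  attr(out, "n_cosuspected") <- length(co)
  out
}

# Vectorized signal computation over parallel count vectors; the workhorse
# behind the scan and report modules. Returns one row per term.
.signal_frame <- function(term_code, term_name, level, drug_scope,
                          n_obs, n_drug, n_effect, n_total,
                          background = "full", ic_method = "gamma",
                          mass = 0.95) {
  if (background == "other_drugs") {
    expected <- n_drug * (n_effect - n_obs) / (n_total - n_drug)
  } else {
    expected <- n_drug * n_effect / n_total
  }
  ci <- ic_credibility_interval(n_obs, expected, mass, ic_method)
  data.frame(
    term_code = term_code, term_name = term_name, level = level,
    drug_scope = drug_scope,
    n_obs = as.integer(n_obs), n_drug = as.integer(n_drug),
    n_effect = as.integer(n_effect), n_total = as.integer(n_total),
    expected = expected,
    ic = information_component(n_obs, expected),
    ic025 = ci$ic025, ic975 = ci$ic975,
    is_signal = ci$ic025 > 0,
    stringsAsFactors = FALSE
  )
}
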