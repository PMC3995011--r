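#' 2x2 carrier-by-status contingency table for one stratum
#'
#' @param a Case carriers.
#' @param b Case non-carriers.
#' @param c Control carriers.
#' @param d Control non-carriers.
#' @param label Stratum name.
#' @return A `contingency_2x2` list.
#' @export
contingency_2x2 <- function(a, b, c, d, label = "stratum") {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(is.finite(counts)), all(counts >= 0),
            all(counts == round(counts)))
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 label = label),
            class = "contingency_2x2")
}

#' Build the deletion-carrier 2x2 table from calls and phenotypes
#'
#' Carrier status is deletion-only: samples called `DELETION_B` are carriers
#' and everything else (including duplications) counts as non-carrier,
#' matching the replication analyses which considered only the putative
#' etiological deletion variant. Phenotyped samples without a call are
#' dropped with a message.
#'
#' @param calls Calls tibble with `sample` and `category`.
#' @param phenotypes Tibble with `sample`, `status` ("case"/"control") and
#'   optionally `stratum`.
#' @param stratum Stratum label; when `phenotypes` has a `stratum` column,
#'   only that stratum's samples are used.
#' @return A [contingency_2x2()].
#' @export
build_table <- function(calls, phenotypes, stratum = "stratum") {
  if ("stratum" %in% names(phenotypes))
    phenotypes <- phenotypes[phenotypes$stratum == stratum, , drop = FALSE]
  if (!all(phenotypes$status %in% c("case", "control")))
    stop("phenotype status must be 'case' or 'control'")
  m <- dplyr::left_join(phenotypes, calls[, c("sample", "category")],
                        by = "sample")
  miss <- is.na(m$category)
  if (any(miss)) {
    message(sum(miss), " phenotyped sample(s) without a call dropped")
    m <- m[!miss, , drop = FALSE]
  }
  carrier <- m$category == "DELETION_B"
  contingency_2x2(a = sum(carrier & m$status == "case"),
                  b = sum(!carrier & m$status == "case"),
                  c = sum(carrier & m$status == "control"),
                  d = sum(!carrier & m$status == "control"),
                  label = stratum)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc`; the log-scale standard error is the Woolf estimate
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% CI is
#' `exp(log OR +/- 1.96 SE)`. With `a = 0` the OR is 0 and the CI flagged
#' one-sided; with both carrier cells zero the OR is undefined.
#'
#' @param t A [contingency_2x2()].
#' @return List `or`, `log_or_se`, `ci95` (length-2), `one_sided` flag.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$a == 0 && t$c == 0)
    stop("no carriers in either arm; odds ratio undefined")
  if (t$b == 0 || t$c == 0 || t$d == 0)
    stop("zero cell in b, c or d; odds ratio unbounded")
  if (t$a == 0) {
    se <- NA_real_
    upper <- exp(stats::qnorm(0.975) *
                   sqrt(1 / 1 + 1 / t$b + 1 / t$c + 1 / t$d))
    return(list(or = 0, log_or_se = se, ci95 = c(0, upper),
                one_sided = TRUE))
  }
  or <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(or = or, log_or_se = se,
       ci95 = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se),
       one_sided = FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uses the closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one
#' degree of freedom and no continuity correction; the two-sided p-value is
#' the upper chi-square tail.
#'
#' @param t A [contingency_2x2()].
#' @return List `chi2`, `df = 1`, `p`.
#' @export
pearson_chi2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  margins <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(margins == 0)) stop("zero margin; chi-squared undefined")
  chi2 <- t$n * (t$a * t$d - t$b * t$c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-stratum association summary
#'
#' @param t A [contingency_2x2()].
#' @return Tibble row: `label`, `a`, `b`, `c`, `d`, `or`, `ci_low`,
#'   `ci_high`, `chi2`, `p`.
#' @export
stratum_association <- function(t) {
  o <- odds_ratio(t)
  ch <- pearson_chi2(t)
  tibble::tibble(label = t$label, a = t$a, b = t$b, c = t$c, d = t$d,
                 or = o$or, ci_low = o$ci95[1], ci_high = o$ci95[2],
                 chi2 = ch$chi2, p = ch$p)
}

#' Mantel-Haenszel stratified odds-ratio meta-analysis
#'
#' Pools K 2x2 tables: `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`.
#' The 95% CI uses the Robins-Breslow-Greenland variance estimator of
#' `log OR_MH`. The association test is the Mantel-Haenszel chi-squared
#' statistic `(sum a_i - sum E_i)^2 / sum V_i` with
#' `E_i = (a_i+b_i)(a_i+c_i)/n_i` and hypergeometric variance
#' `V_i = (a_i+b_i)(c_i+d_i)(a_i+c_i)(b_i+d_i) / (n_i^2 (n_i - 1))`,
#' one degree of freedom, no continuity correction.
#'
#' @param tables List of [contingency_2x2()] (>= 1).
#' @return List `or_mh`, `ci95_rbg`, `chi2_mh`, `p_mh`, `k`. A single
#'   stratum pools to its crude odds ratio exactly.
#' @export
mantel_haenszel <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "contingency_2x2")))
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  c_ <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + c_ + d
  R <- a * d / n
  S <- b * c_ / n
  if (sum(S) == 0) stop("sum of b*c/n is zero; pooled OR undefined")
  or_mh <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n
  Q <- (b + c_) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  ci <- exp(log(or_mh) + c(-1, 1) * stats::qnorm(0.975) * sqrt(v))
  E <- (a + b) * (a + c_) / n
  V <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  chi2 <- (sum(a) - sum(E))^2 / sum(V)
  list(or_mh = or_mh, ci95_rbg = ci, var_log_or = v,
       chi2_mh = chi2,
       p_mh = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       k = length(tables))
}

#' Woolf test for heterogeneity of stratum odds ratios
#'
#' Weights each stratum log odds ratio by the inverse Woolf variance
#' `w_i = 1 / (1/a + 1/b + 1/c + 1/d)` and compares against their weighted
#' mean: `Q = sum w_i (log OR_i - log OR_w)^2` on `k - 1` degrees of
#' freedom. Strata with a zero cell have no finite Woolf variance and are
#' excluded with a message.
#'
#' @param tables List of [contingency_2x2()] (>= 2 usable).
#' @return List `q`, `df`, `p`, `k_used`.
#' @export
woolf_heterogeneity <- function(tables) {
  usable <- vapply(tables, function(t)
    all(c(t$a, t$b, t$c, t$d) > 0), logical(1))
  if (any(!usable))
    message(sum(!usable), " stratum(s) with zero cells excluded from ",
            "heterogeneity test")
  tables <- tables[usable]
  if (length(tables) < 2)
    stop("heterogeneity test requires at least two usable strata")
  lo <- vapply(tables, function(t) log((t$a * t$d) / (t$b * t$c)),
               numeric(1))
  w <- vapply(tables, function(t)
    1 / (1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d), numeric(1))
  lw <- sum(w * lo) / sum(w)
  q <- sum(w * (lo - lw)^2)
  df <- length(tables) - 1L
  list(q = q, df = df,
       p = stats::pchisq(q, df = df, lower.tail = FALSE),
       k_used = length(tables))
}

#' Forest-plot data table for stratified association
#'
#' One row per stratum (crude OR and Woolf CI) plus a summary row for the
#' Mantel-Haenszel pooled estimate. Stratum weights are shares of the pooled
#' Mantel-Haenszel mass `a_i d_i / n_i + b_i c_i / n_i`.
#'
#' @param tables List of [contingency_2x2()].
#' @param meta Result of [mantel_haenszel()] on the same tables.
#' @return Tibble `label`, `or`, `ci_low`, `ci_high`, `weight_share`.
#' @export
forest_table <- function(tables, meta = mantel_haenszel(tables)) {
  if (length(tables) == 0L) stop("no strata to tabulate")
  mass <- vapply(tables, function(t)
    (t$a * t$d + t$b * t$c) / t$n, numeric(1))
  rows <- lapply(tables, function(t) {
    o <- odds_ratio(t)
    tibble::tibble(label = t$label, or = o$or, ci_low = o$ci95[1],
                   ci_high = o$ci95[2])
  })
  out <- dplyr::bind_rows(rows)
  out$weight_share <- mass / sum(mass)
  dplyr::bind_rows(out,
                   tibble::tibble(label = "MH summary", or = meta$or_mh,
                                  ci_low = meta$ci95_rbg[1],
                                  ci_high = meta$ci95_rbg[2],
                                  weight_share = 1))
}
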