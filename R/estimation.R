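# Weighted incidence ------------------------------------------------------

#' Survey-weighted incidence of a binary indicator
#'
#' Point estimate p = sum(w f) / sum(w) x 100. The standard error uses the
#' weighted-proportion (Kish-style) form
#' SE = 100 sqrt(p(1-p) sum(w^2) / (sum w)^2) with p on the 0-1 scale, which
#' reduces to the simple binomial SE under equal weights; no strata/PSU
#' design effect is applied. The 95% CI is p +/- 1.96 SE truncated to
#' [0, 100].
#'
#' @param flags logical or 0/1 vector.
#' @param weights positive survey weights, same length.
#' @return `data.frame` (class `incidence_estimate`) with columns `estimate`,
#'   `std_error`, `ci_low`, `ci_high` (all in percent), `n` (unweighted
#'   count), `weighted_n`.
#' @export
weighted_incidence <- function(flags, weights = rep(1, length(flags))) {
  if (length(flags) == 0L) stop("no observations", call. = FALSE)
  if (length(flags) != length(weights))
    stop("flags and weights differ in length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  f <- as.numeric(flags)
  stopifnot(all(f %in% c(0, 1)))
  sw <- sum(weights)
  p <- sum(weights * f) / sw
  se <- sqrt(p * (1 - p) * sum(weights^2) / sw^2)
  out <- data.frame(estimate = 100 * p, std_error = 100 * se,
                    ci_low = max(0, 100 * (p - 1.96 * se)),
                    ci_high = min(100, 100 * (p + 1.96 * se)),
                    n = length(f), weighted_n = sw)
  class(out) <- c("incidence_estimate", "data.frame")
  out
}

# Income quartiles ---------------------------------------------------------

#' Assign income quartiles by household income per capita
#'
#' Cut-points are the lower weighted quantiles (25/50/75%) of per-capita
#' household income, using survey weights — consistent with every other
#' weighted estimate. A household falls in Qk when its value lies in
#' (c_{k-1}, c_k]; the lowest group is closed below and ties share the lower
#' group, so degenerate cut-points (all incomes identical) put everyone
#' in Q1.
#'
#' @param records validated household table.
#' @return Factor with levels Q1..Q4, one per household.
#' @export
assign_income_quartiles <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("nonempty household table required", call. = FALSE)
  pc <- records$income_total / records$family_size
  cuts <- weighted_quantile(pc, records$weight, c(0.25, 0.5, 0.75))
  q <- 1L + (pc > cuts[1]) + (pc > cuts[2]) + (pc > cuts[3])
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

# Subgroup gaps ------------------------------------------------------------

#' Subgroup incidence contrast with chi-square test
#'
#' Computes the weighted incidence of an indicator per level of a grouping
#' column, the percentage-point gap for a stated contrast (e.g. rural minus
#' urban, Q1 minus Q4), and a Pearson chi-square test of independence on the
#' G x 2 table of weight-normalized counts. Weights are rescaled so they sum
#' to the unweighted sample size (a first-order scale correction only; no
#' second-order Rao-Scott adjustment), which makes the statistic reduce to
#' the textbook Pearson test under equal weights.
#'
#' @param flag_table output of [build_flag_table()] (or any data.frame with
#'   the indicator, grouping and `weight` columns).
#' @param indicator name of a logical flag column.
#' @param grouping name of the grouping column.
#' @param contrast length-2 vector of group labels; the gap is
#'   `contrast[1] - contrast[2]` in percentage points.
#' @return list (class `gap_estimate`): `group_estimates` (named list of
#'   incidence estimates), `contrast`, `gap_pp`, `chi2_stat`, `df`,
#'   `p_value`, `stars`.
#' @export
subgroup_gap <- function(flag_table, indicator, grouping, contrast) {
  stopifnot(indicator %in% names(flag_table),
            grouping %in% names(flag_table), length(contrast) == 2L)
  g <- as.character(flag_table[[grouping]])
  levels_present <- unique(g)
  missing_groups <- setdiff(as.character(contrast), levels_present)
  if (length(missing_groups))
    stop("contrast group(s) empty: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  f <- as.numeric(flag_table[[indicator]])
  w <- flag_table$weight
  groups <- sort(levels_present)
  est <- lapply(groups, function(gr)
    weighted_incidence(f[g == gr], w[g == gr]))
  names(est) <- groups
  gap <- est[[as.character(contrast[1])]]$estimate -
         est[[as.character(contrast[2])]]$estimate
  # Pearson chi-square on weight-normalized counts
  wn <- w * length(w) / sum(w)
  obs <- rbind(vapply(groups, function(gr) sum(wn[g == gr] * f[g == gr]), 0),
               vapply(groups, function(gr) sum(wn[g == gr] * (1 - f[g == gr])),
                      0))
  chi2 <- .pearson_chi2(obs)
  df <- (length(groups) - 1L) * 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(group_estimates = est, indicator = indicator,
                 grouping = grouping, contrast = as.character(contrast),
                 gap_pp = gap, chi2_stat = chi2, df = df, p_value = p,
                 stars = significance_stars(p)),
            class = "gap_estimate")
}

.pearson_chi2 <- function(obs) {
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd == 0)) return(0)
  sum((obs - expd)^2 / expd)
}

#' Significance stars at the 1% / 5% / 10% levels
#'
#' @param p p-value in [0, 1].
#' @return `"***"` (p < 0.01), `"**"` (p < 0.05), `"*"` (p < 0.10), else "".
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi)
    if (pi < 0.01) "***" else if (pi < 0.05) "**"
    else if (pi < 0.10) "*" else "", "")
}

# Trends -------------------------------------------------------------------

#' Incidence trend across survey waves
#'
#' @param tables named list of flag tables; names (or a `wave_year` column)
#'   give the wave years. Duplicate years are an error.
#' @param indicator flag column to summarize.
#' @return `data.frame` with one row per wave, ordered by year: `wave_year`,
#'   `estimate`, `std_error`, `ci_low`, `ci_high`, `n`, `weighted_n`.
#' @export
trend_series <- function(tables, indicator) {
  stopifnot(length(tables) >= 1L)
  yrs <- if (!is.null(names(tables)) && all(nzchar(names(tables))))
    as.integer(names(tables))
  else vapply(tables, function(t) as.integer(t$wave_year[1]), 1L)
  if (anyDuplicated(yrs))
    stop("duplicate wave_year in trend input: ",
         paste(yrs[duplicated(yrs)], collapse = ", "), call. = FALSE)
  o <- order(yrs)
  rows <- lapply(o, function(i) {
    e <- weighted_incidence(tables[[i]][[indicator]], tables[[i]]$weight)
    cbind(data.frame(wave_year = yrs[i]), as.data.frame(e))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Formatting ---------------------------------------------------------------

#' Format "estimate (ci_low-ci_high)" at 2 decimal places
#' @param e an incidence estimate row.
#' @return character scalar.
#' @export
format_incidence <- function(e) {
  sprintf("%.2f (%.2f-%.2f)", e$estimate, e$ci_low, e$ci_high)
}
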