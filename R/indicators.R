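# CHE definitions --------------------------------------------------------

#' Define a catastrophic health expenditure (CHE) threshold
#'
#' A household is flagged CHE when its out-of-pocket (OOP) health spending is
#' at least `threshold` times a denominator: either the nonfood
#' capacity-to-pay (total consumption minus food) or total consumption.
#' The comparator is ">=" ("at least"). When the denominator is nonpositive
#' (food reported above consumption), any positive OOP is catastrophic and
#' zero OOP never is.
#'
#' @param denominator `"nonfood_capacity"` or `"total_consumption"`.
#' @param threshold fraction in (0, 1). The canonical set uses 0.40 with the
#'   nonfood denominator and 0.10 / 0.25 with total consumption; any value is
#'   accepted for sensitivity analysis.
#' @param label short name used for flag columns; derived if missing.
#' @return Object of class `che_definition`.
#' @export
che_definition <- function(denominator = c("nonfood_capacity",
                                           "total_consumption"),
                           threshold, label = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  if (is.null(label))
    label <- sprintf("che_%s%d",
                     if (denominator == "nonfood_capacity") "nonfood"
                     else "total", round(100 * threshold))
  structure(list(denominator = denominator, threshold = threshold,
                 label = label), class = "che_definition")
}

#' The three canonical CHE definitions
#'
#' 40% of nonfood capacity-to-pay, 10% of total consumption, 25% of total
#' consumption — the WHO-style threshold set used throughout.
#'
#' @return Named list of [che_definition()]s.
#' @export
canonical_che_definitions <- function() {
  defs <- list(che_definition("nonfood_capacity", 0.40),
               che_definition("total_consumption", 0.10),
               che_definition("total_consumption", 0.25))
  stats::setNames(defs, vapply(defs, `[[`, "", "label"))
}

# Poverty lines -----------------------------------------------------------

#' Construct an absolute poverty line from a USD-per-day base
#'
#' Converts a base poverty line in USD per person-day (e.g. the 1.9 or 3.1
#' USD international lines in 2011 prices) into local currency in a target
#' year: per-day value = base x PPP factor x CPI factor; annual value =
#' per-day x `days_per_year`. With PPP 3.52 and CPI 1.13 the 1.9 USD line
#' converts to 7.56 RMB per person-day.
#'
#' @param base_usd_per_day base line, USD per person per day (> 0).
#' @param ppp_factor purchasing-power-parity conversion USD -> local currency.
#' @param cpi_factor price-index inflation factor between base and target year.
#' @param days_per_year days used to annualize (default 365).
#' @param label short name for flag columns.
#' @return Object of class `poverty_line` with fields `kind = "absolute"`,
#'   `value` (currency per person-YEAR), `per_day`, and `provenance`.
#' @export
absolute_poverty_line <- function(base_usd_per_day, ppp_factor, cpi_factor,
                                  days_per_year = 365L, label = NULL) {
  vals <- c(base_usd_per_day, ppp_factor, cpi_factor, days_per_year)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all poverty-line inputs must be positive", call. = FALSE)
  per_day <- base_usd_per_day * ppp_factor * cpi_factor
  if (is.null(label))
    label <- sprintf("usd%s", gsub("\\.", "_", format(base_usd_per_day)))
  structure(list(kind = "absolute", value = per_day * days_per_year,
                 per_day = per_day, label = label,
                 provenance = list(base_usd_per_day = base_usd_per_day,
                                   ppp_factor = ppp_factor,
                                   cpi_factor = cpi_factor,
                                   days_per_year = as.integer(days_per_year))),
            class = "poverty_line")
}

#' Construct a relative poverty line from the sample
#'
#' `median_share` (conventionally 60%) of the weighted median per-capita
#' total consumption expenditure. The median is taken over households using
#' the survey weights, with the lower-weighted-median convention at ties
#' (smallest value whose cumulative weight reaches half the total).
#'
#' @param records validated household table.
#' @param median_share fraction of the median (default 0.6).
#' @param label short name for flag columns.
#' @return Object of class `poverty_line` with `kind = "relative"`.
#' @export
relative_poverty_line <- function(records, median_share = 0.6,
                                  label = "relative") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("relative poverty line requires a nonempty household table",
         call. = FALSE)
  stopifnot(median_share > 0)
  pc <- records$consumption_total / records$family_size
  med <- weighted_median(pc, records$weight)
  structure(list(kind = "relative", value = median_share * med,
                 label = label,
                 provenance = list(median_share = median_share,
                                   weighted_median_pc = med)),
            class = "poverty_line")
}

#' The canonical poverty-line set
#'
#' The 1.9 and 3.1 USD/person-day absolute lines (2011 USD) converted with
#' PPP 3.52 and CPI 1.13 to target-year currency, plus the 60%-of-median
#' relative line computed from `records`.
#'
#' @param records validated household table (for the relative line).
#' @return Named list of [poverty_line()] objects.
#' @export
canonical_poverty_lines <- function(records) {
  lines <- list(absolute_poverty_line(1.9, 3.52, 1.13),
                absolute_poverty_line(3.1, 3.52, 1.13),
                relative_poverty_line(records))
  stats::setNames(lines, vapply(lines, `[[`, "", "label"))
}

#' Read a definition set from a YAML/JSON config file
#'
#' Parses the shipped `canonical_definitions.yaml` format: a
#' `che_definitions` list of (denominator, threshold) entries and a
#' `poverty_lines` list of absolute (base_usd_per_day, ppp_factor,
#' cpi_factor, days_per_year) or relative (median_share) entries.
#'
#' @param path config file; the canonical set ships at
#'   `system.file("extdata", "canonical_definitions.yaml",
#'   package = "finprotect")`.
#' @param records household table, required when the config contains a
#'   relative line (its value depends on the sample).
#' @return list with named elements `che_definitions` and `poverty_lines`.
#' @export
read_definitions <- function(path, records = NULL) {
  cfg <- .read_config(path)
  defs <- lapply(cfg$che_definitions, function(d)
    che_definition(d$denominator, d$threshold, label = d$label))
  lines <- lapply(cfg$poverty_lines, function(l) {
    if (identical(l$kind, "relative")) {
      if (is.null(records))
        stop("relative poverty line in config requires records", call. = FALSE)
      relative_poverty_line(records, l$median_share)
    } else {
      absolute_poverty_line(l$base_usd_per_day, l$ppp_factor, l$cpi_factor,
                            days_per_year = l$days_per_year %||% 365,
                            label = l$label)
    }
  })
  list(che_definitions = stats::setNames(defs, vapply(defs, `[[`, "", "label")),
       poverty_lines = stats::setNames(lines, vapply(lines, `[[`, "", "label")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted quantiles ------------------------------------------------------

#' Lower weighted quantile
#'
#' Smallest data value whose cumulative weight reaches `p` of the total
#' weight (the lower-quantile convention; at `p = 0.5` this is the lower
#' weighted median used for the relative poverty line).
#'
#' @param x numeric values.
#' @param w positive weights, same length.
#' @param p probabilities in [0, 1].
#' @return Numeric vector of quantiles, one per `p`.
#' @export
weighted_quantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), length(x) >= 1L, all(w > 0),
            all(p >= 0), all(p <= 1))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  total <- cw[length(cw)]
  vapply(p, function(pi) x[which(cw >= pi * total)[1L]], numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

# Classification ----------------------------------------------------------

#' Nonfood capacity to pay
#'
#' Total consumption minus food expenditure; may be nonpositive when food
#' is reported above consumption (such records are kept and handled by the
#' nonpositive-denominator rule in [classify_che()]).
#'
#' @param records validated household table.
#' @return Numeric vector, currency units per year.
#' @export
capacity_to_pay <- function(records) {
  records$consumption_total - records$food_expenditure
}

#' Classify catastrophic health expenditure
#'
#' @param records validated household table.
#' @param definition a [che_definition()].
#' @return Logical vector: OOP >= threshold x denominator; when the
#'   denominator is <= 0, `TRUE` iff OOP > 0; OOP of zero is never CHE.
#' @export
classify_che <- function(records, definition) {
  stopifnot(inherits(definition, "che_definition"))
  denom <- switch(definition$denominator,
                  nonfood_capacity = capacity_to_pay(records),
                  total_consumption = records$consumption_total)
  oop <- records$oop_health_expenditure
  ifelse(denom <= 0, oop > 0, oop >= definition$threshold * denom & oop > 0)
}

#' Classify consumption poverty
#'
#' A household is poor when its per-capita consumption falls strictly below
#' the line (gross), or when per-capita consumption net of OOP health
#' spending does (net). Negative net consumption is poor.
#'
#' @param records validated household table.
#' @param line a [poverty_line()].
#' @param net_of_oop subtract OOP health spending before comparing?
#' @return Logical vector.
#' @export
classify_poor <- function(records, line, net_of_oop = FALSE) {
  stopifnot(inherits(line, "poverty_line"))
  cons <- records$consumption_total
  if (net_of_oop) cons <- cons - records$oop_health_expenditure
  (cons / records$family_size) < line$value
}

#' Classify medical impoverishment
#'
#' The household-level event "not poor on gross consumption but poor once
#' OOP health spending is deducted". Because OOP >= 0 implies gross-poor =>
#' net-poor, the weighted share of this event equals the difference between
#' the net and gross poverty headcounts.
#'
#' @inheritParams classify_poor
#' @return Logical vector.
#' @export
classify_mi <- function(records, line) {
  !classify_poor(records, line, net_of_oop = FALSE) &
    classify_poor(records, line, net_of_oop = TRUE)
}

# Flag table ---------------------------------------------------------------

#' Build the per-household indicator flag table
#'
#' Vectorized application of [classify_che()], [classify_poor()] and
#' [classify_mi()] under every supplied definition and line, joined to the
#' grouping variables carried through to estimation.
#'
#' @param records validated household table.
#' @param che_definitions list of [che_definition()]s (possibly empty).
#' @param poverty_lines list of [poverty_line()]s (possibly empty).
#' @return `data.frame` with `household_id`, grouping columns (`survey_id`,
#'   `wave_year`, `urban`, `province`, `weight`, and `quartile` if present in
#'   `records`), one logical column per CHE definition (its label), and per
#'   poverty line `poor_gross_<label>`, `poor_net_<label>`, `mi_<label>`.
#' @export
build_flag_table <- function(records, che_definitions = list(),
                             poverty_lines = list()) {
  keep <- intersect(c("household_id", "survey_id", "wave_year", "urban",
                      "province", "weight", "quartile"), names(records))
  out <- records[, keep, drop = FALSE]
  for (d in che_definitions) out[[d$label]] <- classify_che(records, d)
  for (l in poverty_lines) {
    out[[paste0("poor_gross_", l$label)]] <- classify_poor(records, l, FALSE)
    out[[paste0("poor_net_", l$label)]]   <- classify_poor(records, l, TRUE)
    out[[paste0("mi_", l$label)]]         <- classify_mi(records, l)
  }
  rownames(out) <- NULL
  out
}
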