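# Fixtures are built in code; no files on disk beyond tempdir scratch.

# Small random household table exercising the awkward corners: zero OOP,
# food above consumption, heavy-tailed amounts, non-uniform weights.
random_households <- function(n, seed) {
  set.seed(seed)
  cons <- rlnorm(n, 9.5, 1)
  food_share <- runif(n, 0.05, 1.2)   # > 1 => food exceeds consumption
  oop <- ifelse(runif(n) < 0.3, 0, rlnorm(n, 7, 1.5))
  data.frame(household_id = sprintf("R%04d", seq_len(n)),
             survey_id = "fixture", wave_year = 2016L,
             urban = rbinom(n, 1, 0.5),
             province = sample(c("P1", "P2", "P3"), n, replace = TRUE),
             family_size = 1L + rpois(n, 2),
             income_total = rlnorm(n, 10, 1),
             consumption_total = cons,
             food_expenditure = food_share * cons,
             oop_health_expenditure = oop,
             weight = rlnorm(n, 0, 0.6),
             stringsAsFactors = FALSE)
}

# Brute-force oracle: per-household loop over scalar classifications.
naive_flag_table <- function(records, defs, lines) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    out <- list(household_id = r$household_id)
    for (d in defs) out[[d$label]] <- classify_che(r, d)
    for (l in lines) {
      out[[paste0("poor_gross_", l$label)]] <- classify_poor(r, l, FALSE)
      out[[paste0("poor_net_", l$label)]] <- classify_poor(r, l, TRUE)
      out[[paste0("mi_", l$label)]] <- classify_mi(r, l)
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

# A fixed poverty line at an exact annual value (days_per_year = 1 keeps the
# boundary free of division round-off).
fixed_line <- function(annual_value, label = "fixed") {
  absolute_poverty_line(annual_value, 1, 1, days_per_year = 1, label = label)
}

write_fixture_csv <- function(df, path, sep = ",") {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
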