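test_that("weighted_incidence: point estimates, SE limits, and error contracts", {
  e <- weighted_incidence(c(1, 0, 0, 1), rep(1, 4))
  expect_equal(e$estimate, 50)
  expect_equal(weighted_incidence(c(1, 0), c(3, 1))$estimate, 75)
  z <- weighted_incidence(rep(0, 10), rep(1, 10))
  expect_equal(c(z$estimate, z$ci_low, z$ci_high), c(0, 0, 0))
  # equal weights reduce to the simple binomial SE
  f <- rbinom(200, 1, 0.3)
  e2 <- weighted_incidence(f, rep(2.5, 200))
  p <- mean(f)
  expect_equal(e2$std_error, 100 * sqrt(p * (1 - p) / 200))
  expect_equal(e2$estimate, 100 * p)
  expect_error(weighted_incidence(numeric(0), numeric(0)), "observations")
  expect_error(weighted_incidence(c(1, 0), c(1, -1)), "positive")
  expect_error(weighted_incidence(c(1, 0), c(1)), "length")
})

test_that("incidence CI bracket and bounds hold on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:200, 1)
    e <- weighted_incidence(rbinom(n, 1, runif(1)), rlnorm(n, 0, 1))
    expect_true(e$ci_low <= e$estimate && e$estimate <= e$ci_high)
    expect_true(e$ci_low >= 0 && e$ci_high <= 100)
  }
})

test_that("income quartiles: equal split, degenerate ties, weighted cut walk", {
  base <- random_households(8, seed = 50)
  base$family_size <- 1L
  base$weight <- 1
  base$income_total <- c(10, 20, 30, 40, 50, 60, 70, 80)
  q <- assign_income_quartiles(base)
  expect_equal(as.integer(table(q)), c(2L, 2L, 2L, 2L))
  base$income_total <- rep(42, 8)
  expect_true(all(assign_income_quartiles(base) == "Q1"))
  # hand cumulative-weight walk: cuts at (2, 4, 4); ties share the lower group
  w4 <- base[1:4, ]
  w4$income_total <- 1:4
  w4$weight <- c(1, 1, 1, 5)
  expect_equal(as.character(assign_income_quartiles(w4)),
               c("Q1", "Q1", "Q2", "Q2"))
})

test_that("quartile weight shares are 25% up to the largest single weight", {
  for (seed in 61:63) {
    r <- random_households(300, seed)
    q <- assign_income_quartiles(r)
    shares <- tapply(r$weight, q, sum) / sum(r$weight)
    shares[is.na(shares)] <- 0
    tol <- max(r$weight) / sum(r$weight)
    expect_true(all(abs(shares - 0.25) <= tol + 1e-12), info = seed)
  }
})

test_that("subgroup_gap: zero gap at equal proportions, hand 2x2 chi-square, df", {
  mk <- function(flags, groups) data.frame(flag = flags, grp = groups,
                                           weight = 1)
  # identical proportions, equal weights -> gap 0, chi2 0
  t0 <- mk(rep(c(1, 0, 0, 0), 2), rep(c("a", "b"), each = 4))
  g0 <- subgroup_gap(t0, "flag", "grp", c("a", "b"))
  expect_equal(g0$gap_pp, 0)
  expect_equal(g0$chi2_stat, 0)
  # hand-computed Pearson on {{30,70},{10,90}}: 12.5 exactly
  t1 <- mk(c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
           rep(c("a", "b"), each = 100))
  g1 <- subgroup_gap(t1, "flag", "grp", c("a", "b"))
  expect_equal(round(g1$chi2_stat, 3), 12.5)
  expect_equal(g1$df, 1)
  expect_equal(g1$gap_pp, 30 - 10)
  # equal weights reduce to the textbook Pearson test
  oracle <- suppressWarnings(
    chisq.test(table(t1$grp, t1$flag), correct = FALSE))
  expect_equal(g1$chi2_stat, unname(oracle$statistic))
  expect_equal(g1$p_value, unname(oracle$p.value))
  # three groups -> df 2
  t2 <- mk(rbinom(60, 1, 0.4), rep(c("a", "b", "c"), each = 20))
  expect_equal(subgroup_gap(t2, "flag", "grp", c("a", "c"))$df, 2)
  expect_error(subgroup_gap(t1, "flag", "grp", c("a", "zzz")), "empty")
})

test_that("weight rescaling keeps the chi-square on the sample-size scale", {
  set.seed(77)
  t1 <- data.frame(flag = rbinom(400, 1, 0.3),
                   grp = rep(c("a", "b"), each = 200),
                   weight = rlnorm(400, 0, 0.5))
  g <- subgroup_gap(t1, "flag", "grp", c("a", "b"))
  t2 <- t1; t2$weight <- t1$weight * 1000   # scale-free in the weights
  g2 <- subgroup_gap(t2, "flag", "grp", c("a", "b"))
  expect_equal(g$chi2_stat, g2$chi2_stat)
  expect_equal(g$gap_pp, g2$gap_pp)
})

test_that("overall flagged mass decomposes over groups", {
  for (seed in 81:83) {
    r <- random_households(150, seed)
    r$flag <- rbinom(150, 1, 0.3)
    r$grp <- sample(c("g1", "g2", "g3"), 150, replace = TRUE)
    overall <- weighted_incidence(r$flag, r$weight)$estimate
    parts <- vapply(unique(r$grp), function(g) {
      i <- r$grp == g
      weighted_incidence(r$flag[i], r$weight[i])$estimate *
        sum(r$weight[i]) / sum(r$weight)
    }, 0)
    expect_equal(sum(parts), overall)
  }
})

test_that("trend_series orders waves, rejects duplicates, tracks declining truth", {
  f1 <- data.frame(flag = c(1, 1, 0, 0), weight = 1)
  single <- trend_series(stats::setNames(list(f1), "2016"), "flag")
  expect_equal(nrow(single), 1)
  expect_equal(single$estimate, weighted_incidence(f1$flag, f1$weight)$estimate)

  # waves supplied out of order come back sorted by year
  f2 <- data.frame(flag = c(1, 0, 0, 0), weight = 1)
  tr <- trend_series(list("2018" = f2, "2016" = f1), "flag")
  expect_equal(tr$wave_year, c(2016, 2018))
  expect_equal(tr$estimate, c(50, 25))
  expect_error(trend_series(list("2016" = f1, "2016" = f2), "flag"),
               "duplicate")

  # synthetic waves with declining shock rate -> declining estimates
  shock <- c(0.20, 0.10, 0.03)
  defs <- list(che_definition("nonfood_capacity", 0.40))
  tabs <- lapply(seq_along(shock), function(i) {
    cfg <- synthetic_config(n_households = 4000, p_shock = shock[i])
    build_flag_table(generate_households(cfg, seed = 900,
                                         wave_year = 2010 + 2 * i),
                     defs, list())
  })
  names(tabs) <- 2010 + 2 * seq_along(shock)
  tr2 <- trend_series(tabs, "che_nonfood40")
  expect_true(all(diff(tr2$estimate) < 0))
})

test_that("significance stars and incidence formatting", {
  expect_equal(significance_stars(c(0.005, 0.03, 0.08, 0.5)),
               c("***", "**", "*", ""))
  e <- weighted_incidence(c(1, 0, 0, 1), rep(1, 4))
  expect_match(format_incidence(e), "^50\\.00 \\(")
})
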