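one_household <- function(consumption, food, oop, size = 1, weight = 1) {
  data.frame(household_id = "H1", survey_id = "t", wave_year = 2017L,
             urban = 1, province = "P1", family_size = size,
             income_total = consumption, consumption_total = consumption,
             food_expenditure = food, oop_health_expenditure = oop,
             weight = weight)
}

test_that("capacity_to_pay is consumption minus food, nonpositive passes through", {
  expect_equal(capacity_to_pay(one_household(10000, 4000, 0)), 6000)
  expect_equal(capacity_to_pay(one_household(6000, 8000, 0)), -2000)
  expect_equal(capacity_to_pay(one_household(5000, 0, 0)), 5000)
})

test_that("classify_che honors the >= comparator and the nonpositive-capacity rule", {
  d40 <- che_definition("nonfood_capacity", 0.40)
  d10 <- che_definition("total_consumption", 0.10)
  # exact boundary: "at least" => >=
  expect_true(classify_che(one_household(10000, 4000, 2400), d40))
  expect_false(classify_che(one_household(20000, 0, 1999.99), d10))
  expect_true(classify_che(one_household(20000, 0, 2000), d10))
  # zero OOP is never catastrophic under any definition
  for (d in canonical_che_definitions())
    expect_false(classify_che(one_household(10000, 4000, 0), d))
  expect_false(classify_che(one_household(6000, 8000, 0), d40))
  # positive OOP with nonpositive capacity is always catastrophic
  expect_true(classify_che(one_household(6000, 8000, 50), d40))
})

test_that("absolute poverty line reproduces the PPP/CPI conversion", {
  l19 <- absolute_poverty_line(1.9, 3.52, 1.13)
  l31 <- absolute_poverty_line(3.1, 3.52, 1.13)
  expect_equal(round(l19$per_day, 2), 7.56)
  expect_equal(round(l31$per_day, 2), 12.33)
  expect_equal(l19$value, 1.9 * 3.52 * 1.13 * 365)
  expect_equal(round(l19$value, 2), 2758.47)
  expect_equal(absolute_poverty_line(1.9, 1, 1, 365)$value, 693.5)
  expect_error(absolute_poverty_line(-1, 3.52, 1.13), "positive")
  expect_error(absolute_poverty_line(1.9, 0, 1.13), "positive")
})

test_that("relative poverty line uses the lower weighted median of pc consumption", {
  r1 <- one_household(10000, 2000, 0)
  expect_equal(relative_poverty_line(r1)$value, 6000)
  r3 <- do.call(rbind, list(one_household(10000, 0, 0),
                            one_household(20000, 0, 0),
                            one_household(40000, 0, 0)))
  expect_equal(relative_poverty_line(r3)$value, 12000)  # median 20000 x 0.6
  r2 <- rbind(one_household(10000, 0, 0, weight = 3),
              one_household(30000, 0, 0, weight = 1))
  expect_equal(relative_poverty_line(r2)$value, 6000)   # lower weighted median
  expect_error(relative_poverty_line(r2[0, ]), "nonempty")
})

test_that("weighted quantiles follow the lower convention", {
  expect_equal(weighted_median(c(10, 30), c(3, 1)), 10)
  expect_equal(weighted_median(c(10, 20, 40), c(1, 1, 1)), 20)
  expect_equal(weighted_quantile(1:8, rep(1, 8), c(0.25, 0.75)), c(2, 6))
})

test_that("classify_poor uses strict <, net side handles negative consumption", {
  line <- fixed_line(3000)
  # exactly at the line is NOT poor (strict inequality)
  expect_false(classify_poor(one_household(3000, 0, 0), line))
  expect_true(classify_poor(one_household(2999.99, 0, 0), line))
  # negative net consumption is poor under any positive line
  expect_true(classify_poor(one_household(4000, 0, 5000), line, net_of_oop = TRUE))
  # zero OOP: gross equals net
  r <- random_households(50, seed = 3)
  r$oop_health_expenditure <- 0
  expect_equal(classify_poor(r, line, TRUE), classify_poor(r, line, FALSE))
})

test_that("classify_mi is the gross-nonpoor-net-poor event", {
  line <- fixed_line(2757.46)
  expect_true(classify_mi(one_household(3000, 0, 500), line))    # 3000 >= line, 2500 < line
  expect_false(classify_mi(one_household(2000, 0, 500), line))   # already gross-poor
  expect_false(classify_mi(one_household(3000, 0, 0), line))     # no OOP
})

test_that("flag table equals the naive per-household loop and keeps its invariants", {
  defs <- canonical_che_definitions()
  for (seed in c(21, 22)) {
    r <- random_households(25, seed)
    lines <- list(fixed_line(6000, "l6k"), relative_poverty_line(r))
    got <- build_flag_table(r, defs, lines)
    want <- naive_flag_table(r, defs, lines)
    for (cn in setdiff(names(want), "household_id"))
      expect_equal(got[[cn]], want[[cn]], info = paste(seed, cn))
    for (l in lines) {
      pg <- got[[paste0("poor_gross_", l$label)]]
      pn <- got[[paste0("poor_net_", l$label)]]
      mi <- got[[paste0("mi_", l$label)]]
      expect_true(all(pn[pg]))            # gross-poor => net-poor
      expect_equal(mi, !pg & pn)
    }
  }
  # empty definition lists: grouping columns only
  r <- random_households(5, seed = 23)
  empty <- build_flag_table(r, list(), list())
  expect_true(all(names(empty) %in%
    c("household_id", "survey_id", "wave_year", "urban", "province", "weight")))
})

test_that("CHE flags are invariant to uniform currency rescaling; MI to joint rescaling", {
  r <- random_households(60, seed = 31)
  defs <- canonical_che_definitions()
  r2 <- r
  for (f in c("income_total", "consumption_total", "food_expenditure",
              "oop_health_expenditure"))
    r2[[f]] <- r2[[f]] * 2
  for (d in defs)
    expect_equal(classify_che(r2, d), classify_che(r, d))
  line <- fixed_line(5000)
  line2 <- fixed_line(10000)
  expect_equal(classify_mi(r2, line2), classify_mi(r, line))
})

test_that("the shipped canonical definition config parses to the built-in set", {
  p <- system.file("extdata", "canonical_definitions.yaml",
                   package = "finprotect")
  r <- random_households(30, seed = 91)
  got <- read_definitions(p, records = r)
  want_d <- canonical_che_definitions()
  expect_equal(names(got$che_definitions), names(want_d))
  for (nm in names(want_d))
    expect_equal(got$che_definitions[[nm]]$threshold, want_d[[nm]]$threshold)
  want_l <- canonical_poverty_lines(r)
  expect_equal(names(got$poverty_lines), names(want_l))
  for (nm in names(want_l))
    expect_equal(got$poverty_lines[[nm]]$value, want_l[[nm]]$value)
})

test_that("threshold monotonicity holds on random tables", {
  for (seed in 41:45) {
    r <- random_households(80, seed)
    grid <- seq(0.05, 0.6, by = 0.05)
    for (den in c("nonfood_capacity", "total_consumption")) {
      inc <- vapply(grid, function(t)
        weighted_incidence(classify_che(r, che_definition(den, t)),
                           r$weight)$estimate, 0)
      expect_true(all(diff(inc) <= 1e-12), info = paste(seed, den))
    }
  }
})
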