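test_that("Fisher exact matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1.0)
  tab <- rbind(c(0, 10), c(10, 0))
  expect_equal(fisher_exact_2x2(tab), 2 / choose(20, 10), tolerance = 1e-10)
  # rectal-location style table
  t2 <- rbind(c(16, 23), c(3, 33))
  expect_equal(fisher_exact_2x2(t2), fisher_enum_oracle(t2), tolerance = 1e-10)
  # property: random tables with n <= 100
  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:100, 1)
    cells <- as.vector(rmultinom(1, n, prob = runif(4, 0.05, 1)))
    tb <- matrix(cells, 2, 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact_2x2(tb), fisher_enum_oracle(tb),
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("chi-squared test with and without Yates behaves as documented", {
  # independence: table proportional to the outer product of its margins
  ind <- outer(c(10, 20), c(30, 15)) / 15
  res <- chi_squared_test(ind, yates = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # synchronous-adenoma style 2x2: Yates-corrected p near 0.013
  tab <- rbind(c(3, 36), c(12, 24))
  yat <- chi_squared_test(tab, yates = TRUE)
  expect_equal(yat$statistic, 6.17, tolerance = 0.01)
  expect_equal(round(yat$p, 3), 0.013)
  raw <- chi_squared_test(tab, yates = FALSE)
  expect_gt(raw$statistic, yat$statistic)   # continuity-correction monotonicity
  expect_lt(raw$p, yat$p)

  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("test selection follows Cochran's rule with strict < 5", {
  expect_equal(choose_test(matrix(50, 2, 2)), "chisq")
  # expected counts exactly 5: stays chi-squared under the strict rule
  expect_equal(choose_test(rbind(c(1, 9), c(9, 1))), "chisq")
  expect_equal(choose_test(rbind(c(1, 8), c(9, 1))), "fisher")
  expect_equal(choose_test(rbind(c(0, 2), c(3, 1))), "fisher")
  ct <- contingency_test(rbind(c(0, 2), c(3, 1)))
  expect_identical(ct$test, "fisher")
})

test_that("Kaplan-Meier estimates equal the hand product-limit formula", {
  cv <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_surv_at(cv, c(1, 2, 2.5, 10)), c(2/3, 1/3, 1/3, 1/3))

  # censored-only data: survival stays at 1
  cv0 <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_equal(km_surv_at(cv0, c(0, 10)), c(1, 1))

  # all events at t = 1
  cv1 <- km_estimate(rep(1, 5), rep(1, 5))
  expect_equal(km_surv_at(cv1, 1), 0)

  # random fixture against the oracle, with monotonicity
  set.seed(17)
  tm <- round(rexp(40, 0.1), 1); ev <- rbinom(40, 1, 0.7)
  cv2 <- km_estimate(tm, ev)
  orc <- km_oracle(tm, ev)
  expect_equal(cv2$time, orc$time)
  expect_equal(cv2$surv, orc$surv, tolerance = 1e-12)
  expect_true(all(diff(cv2$surv) <= 1e-12))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches the hand O-E computation", {
  # identical groups: statistic 0, p 1
  tm <- c(1, 3, 5, 7, 9); ev <- c(1, 1, 0, 1, 0)
  lr0 <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  set.seed(23)
  t1 <- rexp(30, 0.05); t2 <- rexp(30, 0.15)
  cens <- runif(60, 0, 30)
  tm2 <- pmin(c(t1, t2), cens); ev2 <- as.integer(c(t1, t2) <= cens)
  grp <- rep(c("a", "b"), each = 30)
  lr <- logrank_test(tm2, ev2, grp)
  orc <- logrank_oracle(tm2, ev2, grp)
  expect_equal(lr$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(lr$p, orc$p, tolerance = 1e-10)

  # power at hazard ratio 3
  det <- vapply(1:5, function(s) {
    set.seed(100 + s)
    ta <- rexp(200, 0.02); tb <- rexp(200, 0.06)
    cc <- runif(400, 0, 80)
    logrank_test(pmin(c(ta, tb), cc), as.integer(c(ta, tb) <= cc),
                 rep(c("a", "b"), each = 200))$p
  }, numeric(1))
  expect_true(all(det < 0.001))
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "zero events")
})

test_that("CIMP calls follow the 3-of-5 / fewer-than-2 rules", {
  expect_equal(cimp_call(c(1, 1, 1, 0, 0)), "CIMP_positive")
  expect_equal(cimp_call(c(1, 1, 1, 1, 1)), "CIMP_positive")
  expect_equal(cimp_call(c(1, 0, 0, 0, 0)), "CIMP_negative")
  expect_equal(cimp_call(rep(0, 5)), "CIMP_negative")
  expect_equal(cimp_call(c(1, 1, 0, 0, 0)), "indeterminate")  # gap case
  # missing markers: call only when every completion agrees
  expect_equal(cimp_call(c(1, 1, 1, NA, NA)), "CIMP_positive")
  expect_equal(cimp_call(c(0, 0, 0, 0, NA)), "CIMP_negative")
  expect_equal(cimp_call(c(1, 1, 0, NA, 0)), "indeterminate")
  expect_equal(cimp_call(c(1, 0, 0, NA, NA)), "indeterminate")
  expect_error(cimp_call(rep(1, 6)), "more than 5")
  expect_error(cimp_call(c(1, 2, 0, 0, 0)), "0, 1 or missing")
})

test_that("beta-catenin activation uses the strict > 50% rule", {
  expect_true(beta_catenin_call(60))
  expect_false(beta_catenin_call(50))
  expect_false(beta_catenin_call(0))
  expect_true(is.na(beta_catenin_call(NA)))
  expect_error(beta_catenin_call(120), "\\[0, 100\\]")
})

test_that("group summaries use assessable denominators and print rounding", {
  st <- validate_sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:14),
    group = rep("MSI-O", 14),
    KRAS = c(rep("mutated", 4), rep("wild-type", 9), NA)))
  gsum <- group_summary(st, "KRAS", groups = "MSI-O")
  # 13 assessable of 14; percentages out of 13
  expect_equal(gsum$n_assessable[1], 13)
  expect_equal(gsum$pct[gsum$level == "mutated"], round(100 * 4 / 13))

  # location percentages: 16/39 rectum = 41%, 3/36 = 8.3%
  loc <- validate_sample_table(data.frame(
    sample_id = sprintf("t%02d", 1:75),
    group = rep(c("MSS-Y", "MSS-O"), c(39, 36)),
    tumor_location = c(rep(c("right", "left", "rectum", "multiple"),
                           c(6, 16, 16, 1)),
                       rep(c("right", "left", "rectum"), c(17, 16, 3)))))
  s0 <- group_summary(loc, "tumor_location", digits = 0)
  expect_equal(s0$pct[s0$group == "MSS-Y" & s0$level == "rectum"], 41)
  s1 <- group_summary(loc, "tumor_location", digits = 1)
  expect_equal(s1$pct[s1$group == "MSS-O" & s1$level == "rectum"], 8.3)
  # empty level shows zero count and zero percent
  expect_equal(s0$n[s0$group == "MSS-O" & s0$level == "multiple"], 0)
  expect_error(group_summary(loc, "tumor_location", groups = "nope"),
               "unknown group")
})

test_that("clinical_table couples summaries with rule-selected tests", {
  co <- generate_cohort(cohort_config(seed = 8L))
  ct <- clinical_table(co$samples, c("tumor_location", "BRAF"))
  expect_setequal(unique(ct$tests$variable), c("tumor_location", "BRAF"))
  expect_true(all(ct$tests$test %in% c("fisher", "chisq")))
  expect_true(all(ct$tests$p >= 0 & ct$tests$p <= 1))
  calls <- cimp_status(co$samples)
  expect_length(calls, nrow(co$samples))
  expect_true(all(calls %in% c("CIMP_positive", "CIMP_negative",
                               "indeterminate")))
})
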