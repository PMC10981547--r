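# covariate association (Pearson r, eta squared) and reference-value flags

test_that("pearson_r matches the textbook formula on random data", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_r(x, y)
    # independent brute-force formula
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$value, r_oracle, tolerance = 1e-12)
    t_stat <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    expect_equal(got$p_value, 2 * pt(-abs(t_stat), n - 2), tolerance = 1e-10)
    expect_equal(got$n_used, n)
  }
})

test_that("pearson_r handles perfect linearity, deletion and degenerate input", {
  x <- 1:10
  got <- pearson_r(x, 2 * x + 1)
  expect_equal(got$value, 1, tolerance = 1e-12)
  expect_lt(got$p_value, 1e-12)

  # pairwise deletion
  xm <- c(1, 2, NA, 4, 5, 6); ym <- c(2, 4, 6, NA, 10, 12)
  expect_equal(pearson_r(xm, ym)$n_used, 4)

  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("pearson_r is affine-invariant and sign-flips under negation", {
  set.seed(52)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- pearson_r(x, y)$value
  expect_equal(pearson_r(3 * x + 7, y)$value, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y)$value, -r0, tolerance = 1e-12)
})

test_that("eta_squared matches brute-force sums of squares and identities", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    v <- rnorm(n)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    got <- eta_squared(v, g)
    grand <- mean(v)
    ss_b <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
    ss_t <- sum((v - grand)^2)
    expect_equal(got$value, ss_b / ss_t, tolerance = 1e-12)
    # for binary groups eta^2 equals the squared point-biserial correlation
    expect_equal(got$value, cor(v, as.numeric(factor(g)))^2, tolerance = 1e-12)
  }
})

test_that("eta_squared hits its boundary cases and errors", {
  # identical group means -> 0
  expect_equal(eta_squared(c(1, 2, 1, 2), c("a", "a", "b", "b"))$value, 0)
  # zero within-group variance, distinct means -> 1
  expect_equal(eta_squared(c(1, 1, 5, 5), c("a", "a", "b", "b"))$value, 1)
  expect_error(eta_squared(rnorm(5), rep("a", 5)), "2 non-empty groups")
  expect_error(eta_squared(rep(2, 6), rep(c("a", "b"), 3)), "zero total variance")
})

test_that("eta_squared is invariant to relabeling and affine value transforms", {
  set.seed(54)
  v <- rnorm(24); g <- sample(c("x", "y", "z"), 24, replace = TRUE)
  e0 <- eta_squared(v, g)$value
  relab <- c(x = "3", y = "1", z = "2")[g]
  expect_equal(eta_squared(v, relab)$value, e0, tolerance = 1e-12)
  expect_equal(eta_squared(5 * v - 2, g)$value, e0, tolerance = 1e-12)
  expect_gte(e0, 0); expect_lte(e0, 1)
})

test_that("flag_above_reference reproduces known patient flag sets", {
  bio <- tongue_cohort_biometrics()
  crit <- reference_criteria()
  # patient 4: grade II blood pressure, HbA1c and FPG all above cutoff
  f4 <- flag_above_reference(bio[bio$patient_id == "4", ], crit)
  expect_setequal(f4, c("blood_pressure", "hba1c", "fpg"))
  # patient 11: nothing flagged
  expect_length(flag_above_reference(bio[bio$patient_id == "11", ], crit), 0)
  # patient 6: LDL-C and HbA1c
  expect_setequal(flag_above_reference(bio[bio$patient_id == "6", ], crit),
                  c("ldl_c", "hba1c"))
  # blood pressure counts once even when both SBP and DBP exceed
  both <- list(sbp = 170, dbp = 110)
  expect_identical(flag_above_reference(both, crit), "blood_pressure")
  # missing fields cannot satisfy their items
  expect_length(flag_above_reference(list(age = 50), crit), 0)
  # the optional HDL item picks up patient 17
  expect_setequal(flag_above_reference(bio[bio$patient_id == "17", ],
                                       reference_criteria(include_hdl = TRUE)),
                  "hdl_c")
})

test_that("flag counts are monotone in the cutoffs", {
  bio <- tongue_cohort_biometrics()
  loose <- flag_table(bio, reference_criteria())
  strict_crit <- reference_criteria()
  strict_crit$fpg <- function(rec) !is.na(rec[["fpg"]]) && rec[["fpg"]] >= 200
  strict <- flag_table(bio, strict_crit)
  expect_true(all(strict$n_items <= loose$n_items))
})

test_that("count_flags_by_group reproduces the cohort's acceptability split", {
  tab <- compare_lab_table(table2_pairs())
  flags <- flag_table(tongue_cohort_biometrics())
  split <- count_flags_by_group(tab, flags)
  acc <- split[split$group == "acceptable", ]
  unacc <- split[split$group == "unacceptable", ]
  expect_equal(acc$n, 14)
  expect_equal(acc$n_le1, 13)
  expect_equal(acc$pct_le1, 100 * 13 / 14, tolerance = 1e-9)
  expect_equal(unacc$n, 4)
  expect_equal(unacc$n_ge2, 3)

  # all-zero flags: every group is 100% at <= 1 item
  zero <- flags; zero$n_items <- 0L
  allz <- count_flags_by_group(tab, zero)
  expect_true(all(allz$pct_le1[allz$n > 0] == 100))
})

test_that("associate_covariates mirrors the cohort association table", {
  lab <- table2_pairs(); bio <- tongue_cohort_biometrics()
  assoc <- associate_covariates(lab$dE00, bio)
  expect_setequal(assoc$statistic[assoc$item %in% c("sex", "smoking", "cvd_drug")],
                  "eta_squared")
  expect_lt(assoc$value[assoc$item == "sex"], 0.1)
  expect_equal(abs(assoc$value[assoc$item == "fpg"]), 0.55, tolerance = 0.01)
  expect_true(all(assoc$n_used == 18))
})
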