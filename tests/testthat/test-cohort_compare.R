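test_that("overlap reports intersection size and fraction of the smaller cohort", {
  same <- cohort_overlap(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(same$count, 3)
  expect_equal(same$fraction, 1)
  expect_equal(same$jaccard, 1)

  none <- cohort_overlap(c("a", "b"), c("c", "d"))
  expect_equal(none$count, 0)
  expect_equal(none$fraction, 0)

  # 41 shared patients between cohorts of 218 and 286
  a <- paste0("m", 1:218)
  b <- c(paste0("m", 1:41), paste0("x", 1:245))
  ov <- cohort_overlap(a, b)
  expect_equal(ov$count, 41)
  expect_equal(ov$fraction, 41 / 218, tolerance = 1e-12)
  expect_equal(round(100 * ov$fraction), 19)

  expect_warning(empty <- cohort_overlap(character(0), c("a")), "empty cohort")
  expect_true(is.na(empty$fraction))
})

test_that("welch_t has the expected symmetries and identities", {
  a <- c(1, 2, 3, 4, 5)
  ident <- welch_t(a, a)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  b <- c(2, 3, 4, 5, 6)
  fwd <- welch_t(a, b)
  rev <- welch_t(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$statistic, -rev$statistic)

  expect_error(welch_t(c(1), c(1, 2)), "n >= 2")
  expect_error(welch_t(c(2, 2, 2), c(2, 2, 2), metric = "flatline"), "flatline")
})

test_that("welch_t agrees with a permutation oracle", {
  # small granular sample: exact permutation null (252 splits)
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  p_perm <- oracle_perm_p(a, b)
  p_t <- welch_t(a, b)$p_value
  expect_lt(abs(p_t - p_perm), 0.15)  # permutation p is granular at n = 5
  expect_equal(p_perm >= 0.05, p_t >= 0.05)

  # larger samples: the t-test approximates the permutation test closely
  a2 <- withr::with_seed(11, stats::rnorm(40))
  b2 <- withr::with_seed(12, stats::rnorm(40, mean = 0.3))
  p_perm2 <- oracle_perm_p(a2, b2, n_resample = 2e4)
  p_t2 <- welch_t(a2, b2)$p_value
  expect_lt(abs(p_t2 - p_perm2), 0.03)
})

test_that("welch_t reduces to the pooled t for equal sizes and variances", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- a + 2  # identical variance, equal n
  w <- welch_t(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-9)
  expect_equal(w$p_value, pooled$p.value, tolerance = 1e-9)
})

test_that("two-proportion z-test matches its contracts and the exact oracle", {
  eq <- prop_test(30, 100, 15, 50)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$statistic, 0)

  zero <- prop_test(0, 10, 0, 10)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)

  big <- prop_test(50, 100, 10, 100)
  fish <- stats::fisher.test(matrix(c(50, 50, 10, 90), nrow = 2))
  # same significance call and same order of magnitude
  expect_true(big$p_value < 0.05 && fish$p.value < 0.05)
  expect_lt(abs(log10(big$p_value) - log10(fish$p.value)), 1)

  # z^2 equals the continuity-uncorrected chi-square statistic
  pt <- stats::prop.test(c(30, 10), c(60, 50), correct = FALSE)
  mine <- prop_test(30, 60, 10, 50)
  expect_equal(mine$statistic^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(mine$p_value, pt$p.value, tolerance = 1e-9)

  expect_error(prop_test(5, 4, 1, 10))
})

make_cohort_tbl <- function(ids, seed) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = ids,
    n_unique_meds = sample(1:12, length(ids), replace = TRUE),
    ddi_moderate_plus = stats::rpois(length(ids), 1),
    pip_percent = sample(0:80, length(ids), replace = TRUE),
    er_visits = stats::rbinom(length(ids), 1, 0.2),
    er_cost = stats::rbinom(length(ids), 1, 0.2) * 300,
    inpatient_visits = stats::rbinom(length(ids), 1, 0.1),
    inpatient_cost = stats::rbinom(length(ids), 1, 0.1) * 4000,
    age_years = sample(18:80, length(ids), replace = TRUE),
    sex = sample(c("male", "female"), length(ids), replace = TRUE)
  ))
}

test_that("a cohort compared with itself gives p = 1 on every row", {
  tbl <- make_cohort_tbl(paste0("p", 1:40), seed = 21)
  rep <- compare_cohorts(tbl, tbl, "self", "self")
  expect_true(all(rep$metrics$p_value == 1))
  expect_equal(rep$overlap$fraction, 1)
  expect_equal(rep$sizes, c(40, 40))
})

test_that("the comparison panel has the full fixed set of rows with valid p-values", {
  a <- make_cohort_tbl(paste0("a", 1:60), seed = 22)
  b <- make_cohort_tbl(paste0("b", 1:45), seed = 23)
  rep <- compare_cohorts(a, b, "manual", "automated")
  expect_equal(nrow(rep$metrics), 10)
  expect_true(all(rep$metrics$p_value >= 0 & rep$metrics$p_value <= 1))
  expect_equal(rep$overlap$count, 0)
  md <- comparison_markdown(rep)
  expect_length(md, 12)  # header + rule + 10 rows
  expect_match(md[1], "manual \\(n = 60\\)")
})

test_that("comparison matches a hand-computed two-cohort panel", {
  a <- tibble::tibble(
    patient_id = paste0("a", 1:5),
    n_unique_meds = c(10L, 8L, 12L, 9L, 11L),
    ddi_moderate_plus = c(2L, 3L, 4L, 2L, 5L),
    pip_percent = c(20L, 35L, 10L, 25L, 30L),
    er_visits = c(1L, 0L, 1L, 0L, 1L),
    er_cost = c(500, 0, 700, 0, 300),
    inpatient_visits = c(0L, 1L, 0L, 0L, 0L),
    inpatient_cost = c(0, 4000, 0, 0, 0),
    age_years = c(30L, 40L, 35L, 28L, 50L),
    sex = c("female", "female", "male", "female", "male")
  )
  b <- tibble::tibble(
    patient_id = c("a1", paste0("b", 2:5)),
    n_unique_meds = c(7L, 6L, 8L, 7L, 9L),
    ddi_moderate_plus = c(1L, 0L, 1L, 2L, 0L),
    pip_percent = c(55L, 60L, 52L, 70L, 65L),
    er_visits = c(0L, 0L, 1L, 0L, 0L),
    er_cost = c(0, 0, 250, 0, 0),
    inpatient_visits = c(0L, 0L, 0L, 1L, 0L),
    inpatient_cost = c(0, 0, 0, 3500, 0),
    age_years = c(33L, 45L, 29L, 38L, 41L),
    sex = c("female", "male", "male", "female", "female")
  )
  rep <- compare_cohorts(a, b, "A", "B")
  m <- rep$metrics

  expect_equal(rep$overlap$count, 1)
  expect_equal(rep$overlap$fraction, 1 / 5)

  med_row <- m[m$metric == "average unique medication count", ]
  expect_equal(med_row$mean1, 10)
  expect_equal(med_row$mean2, 7.4)
  tt <- stats::t.test(a$n_unique_meds, b$n_unique_meds)
  expect_equal(med_row$p_value, tt$p.value)

  er_row <- m[m$metric == "at least one ER visit, % patients", ]
  expect_equal(er_row$prop1, 3 / 5)
  expect_equal(er_row$prop2, 1 / 5)
  # hand-computed pooled z: p1=.6, p2=.2, pool=.4 -> z = .4/sqrt(.24*.4)
  z <- 0.4 / sqrt(0.4 * 0.6 * (2 / 5))
  expect_equal(er_row$statistic, z, tolerance = 1e-12)
  expect_equal(er_row$p_value, 2 * stats::pnorm(-z), tolerance = 1e-12)

  cost_row <- m[m$metric == "ER visit claim cost, overall", ]
  expect_equal(cost_row$mean1, mean(c(500, 0, 700, 0, 300)))  # zeros included
  expect_equal(cost_row$mean2, 50)
})

test_that("compare_cohorts validates its inputs", {
  tbl <- make_cohort_tbl(paste0("p", 1:10), seed = 30)
  expect_error(compare_cohorts(tbl[, -3], tbl), "ddi_moderate_plus")
  expect_error(compare_cohorts(tbl[0, ], tbl), "non-empty")
})
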