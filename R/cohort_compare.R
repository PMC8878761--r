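# Two-cohort comparison: overlap, mean +/- SD panels with Welch t-tests,
# and proportion panels with two-proportion z-tests.

#' Cohort overlap
#'
#' @param cohort_a,cohort_b Character vectors of patient ids.
#' @return List with `count` (size of the intersection), `fraction` (of the
#'   smaller cohort; `NA` with a warning when a cohort is empty), and
#'   `jaccard`.
#' @export
cohort_overlap <- function(cohort_a, cohort_b) {
  a <- unique(cohort_a); b <- unique(cohort_b)
  n <- length(intersect(a, b))
  if (length(a) == 0 || length(b) == 0) {
    warning("empty cohort: overlap fraction undefined")
    frac <- NA_real_
    jac <- NA_real_
  } else {
    frac <- n / min(length(a), length(b))
    jac <- n / length(union(a, b))
  }
  list(count = n, fraction = frac, jaccard = jac)
}

#' Welch two-sample t-test on a metric
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, via [stats::t.test()].
#'
#' @param sample_a,sample_b Numeric vectors, each of length at least 2; at
#'   least one must have nonzero variance.
#' @param metric Metric name used in error messages and the result row.
#' @return One-row tibble: `metric`, `mean1`, `sd1`, `mean2`, `sd2`,
#'   `statistic`, `df`, `p_value`, `test`.
#' @export
welch_t <- function(sample_a, sample_b, metric = "metric") {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("metric '", metric, "': each sample needs n >= 2")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    stop("metric '", metric, "': both samples are constant; t-test undefined")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble::tibble(
    metric = metric,
    mean1 = mean(sample_a), sd1 = stats::sd(sample_a),
    mean2 = mean(sample_b), sd2 = stats::sd(sample_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, test = "Welch t"
  )
}

#' Two-proportion z-test
#'
#' Pooled-variance two-proportion z-test without continuity correction,
#' two-sided. When the pooled proportion is degenerate (0 or 1) the
#' proportions are necessarily equal and the test returns `z = 0, p = 1`.
#'
#' @param k1,n1,k2,n2 Successes and totals per group (`0 <= k <= n`,
#'   `n >= 1`).
#' @param metric Metric name for the result row.
#' @return One-row tibble: `metric`, `prop1`, `prop2`, `k1`, `n1`, `k2`,
#'   `n2`, `statistic`, `df` (`NA`), `p_value`, `test`.
#' @export
prop_test <- function(k1, n1, k2, n2, metric = "metric") {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2)
  z <- if (v == 0) 0 else (p1 - p2) / sqrt(v)
  tibble::tibble(
    metric = metric,
    prop1 = p1, prop2 = p2, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
    statistic = z, df = NA_real_,
    p_value = 2 * stats::pnorm(-abs(z)), test = "two-proportion z"
  )
}

# Welch row that degrades gracefully when a panel metric is constant in
# both cohorts (e.g. zero inpatient costs everywhere): equal constants give
# t = 0, p = 1; unequal constants are a genuine separation reported with
# p = 0.
panel_welch <- function(a, b, metric) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(tibble::tibble(
      metric = metric, mean1 = mean(a), sd1 = 0, mean2 = mean(b), sd2 = 0,
      statistic = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf,
      df = NA_real_, p_value = if (mean(a) == mean(b)) 1 else 0,
      test = "Welch t (degenerate)"
    ))
  }
  welch_t(a, b, metric)
}

#' Compare two selected cohorts on the standard metric panel
#'
#' Computes the cohort-characteristics panel: average unique medication
#' count, moderate-or-higher DDI count and the proportion of patients with
#' at least one, mean PIP, proportion with at least one ER visit and mean
#' ER cost, proportion with at least one inpatient visit and mean inpatient
#' cost, age, and sex split. Continuous rows use Welch t-tests; proportion
#' rows use two-proportion z-tests. Cost means are over all cohort members,
#' including zero-cost patients.
#'
#' @param table_a,table_b Per-patient tibbles (one per cohort) carrying
#'   `patient_id`, `n_unique_meds`, `ddi_moderate_plus`, `pip_percent`,
#'   `er_visits`, `er_cost`, `inpatient_visits`, `inpatient_cost`,
#'   `age_years`, `sex`. Build them with [cohort_table()].
#' @param label_a,label_b Cohort labels.
#' @return Object of class `pgx_comparison`: list with `labels`, `sizes`,
#'   `overlap` (see [cohort_overlap()]) and `metrics` (tibble of panel
#'   rows).
#' @export
compare_cohorts <- function(table_a, table_b, label_a = "A", label_b = "B") {
  need <- c("patient_id", "n_unique_meds", "ddi_moderate_plus", "pip_percent",
            "er_visits", "er_cost", "inpatient_visits", "inpatient_cost",
            "age_years", "sex")
  miss_a <- setdiff(need, names(table_a))
  miss_b <- setdiff(need, names(table_b))
  if (length(miss_a) || length(miss_b)) {
    stop("missing column(s): ", toString(unique(c(miss_a, miss_b))))
  }
  if (nrow(table_a) == 0 || nrow(table_b) == 0) stop("both cohorts must be non-empty")
  na <- nrow(table_a); nb <- nrow(table_b)

  cont <- function(col, metric) panel_welch(table_a[[col]], table_b[[col]], metric)
  prop <- function(flag_a, flag_b, metric) {
    prop_test(sum(flag_a), na, sum(flag_b), nb, metric)
  }

  metrics <- dplyr::bind_rows(
    cont("n_unique_meds", "average unique medication count"),
    cont("ddi_moderate_plus", "drug interactions (moderate-or-higher), mean"),
    prop(table_a$ddi_moderate_plus >= 1, table_b$ddi_moderate_plus >= 1,
         "drug interactions (moderate-or-higher), % patients"),
    cont("pip_percent", "average PIP score (%)"),
    prop(table_a$er_visits >= 1, table_b$er_visits >= 1,
         "at least one ER visit, % patients"),
    cont("er_cost", "ER visit claim cost, overall"),
    prop(table_a$inpatient_visits >= 1, table_b$inpatient_visits >= 1,
         "at least one inpatient visit, % patients"),
    cont("inpatient_cost", "inpatient claim cost, overall"),
    cont("age_years", "age, years"),
    prop(table_a$sex == "female", table_b$sex == "female", "female, % patients")
  )

  structure(
    list(
      labels = c(label_a, label_b),
      sizes = c(na, nb),
      overlap = cohort_overlap(table_a$patient_id, table_b$patient_id),
      metrics = metrics
    ),
    class = "pgx_comparison"
  )
}

#' Assemble the per-patient comparison table for a cohort
#'
#' Joins profiles with automated-method scores so a cohort can be fed to
#' [compare_cohorts()].
#'
#' @param profiles Profile tibble from [build_profiles()] (any superset of
#'   the cohort).
#' @param scores Tibble from [pip_scores()] over the same profiles.
#' @param ids Patient ids of the cohort.
#' @return Tibble with the columns required by [compare_cohorts()].
#' @export
cohort_table <- function(profiles, scores, ids) {
  miss <- setdiff(ids, profiles$patient_id)
  if (length(miss)) stop("ids missing from profiles: ", toString(utils::head(miss, 5)))
  p <- profiles[match(ids, profiles$patient_id), ]
  s <- scores[match(ids, scores$patient_id), ]
  tibble::tibble(
    patient_id = p$patient_id,
    n_unique_meds = p$n_unique_meds,
    ddi_moderate_plus = s$ddi_moderate_plus,
    pip_percent = s$pip_percent,
    er_visits = p$er_visits,
    er_cost = p$er_cost,
    inpatient_visits = p$inpatient_visits,
    inpatient_cost = p$inpatient_cost,
    age_years = p$age_years,
    sex = p$sex
  )
}

#' @export
print.pgx_comparison <- function(x, ...) {
  cat("<pgx_comparison> ", x$labels[1], " (n=", x$sizes[1], ") vs ",
      x$labels[2], " (n=", x$sizes[2], "); overlap ", x$overlap$count,
      " (", if (is.na(x$overlap$fraction)) "NA" else
        sprintf("%.0f%%", 100 * x$overlap$fraction),
      " of smaller cohort)\n", sep = "")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$test[i] == "two-proportion z") {
      cat(sprintf("  %-55s %6.1f%% vs %6.1f%%  p=%.4g\n", m$metric[i],
                  100 * m$prop1[i], 100 * m$prop2[i], m$p_value[i]))
    } else {
      cat(sprintf("  %-55s %8.2f +/- %.2f vs %8.2f +/- %.2f  p=%.4g\n",
                  m$metric[i], m$mean1[i], m$sd1[i], m$mean2[i], m$sd2[i],
                  m$p_value[i]))
    }
  }
  invisible(x)
}

#' Render a comparison report as a Markdown table
#'
#' @param x A `pgx_comparison` object.
#' @return Character vector of Markdown lines.
#' @export
comparison_markdown <- function(x) {
  stopifnot(inherits(x, "pgx_comparison"))
  m <- x$metrics
  fmt <- function(i, which) {
    if (m$test[i] == "two-proportion z") {
      sprintf("%.1f%%", 100 * m[[paste0("prop", which)]][i])
    } else {
      sprintf("%.1f ± %.1f", m[[paste0("mean", which)]][i], m[[paste0("sd", which)]][i])
    }
  }
  c(
    sprintf("| Metric | %s (n = %d) | %s (n = %d) | p value |",
            x$labels[1], x$sizes[1], x$labels[2], x$sizes[2]),
    "|---|---|---|---|",
    vapply(seq_len(nrow(m)), function(i) {
      sprintf("| %s | %s | %s | %.4g |", m$metric[i], fmt(i, 1), fmt(i, 2), m$p_value[i])
    }, "")
  )
}
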