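# Seeded synthetic claims generator. Emulates the statistical shape of a
# commercial-plan claims extract: young-adult age structure, majority-female
# enrolment, a heavily skewed medication popularity curve, sparse
# PGx-included medication burden matching published usage marginals, and
# ER/inpatient events with log-normal costs. It is calibration-faithful at
# the margins it targets, not a model of real longitudinal claims.

# Common prescription ingredients outside the PGx knowledge base; these form
# the background medication burden and are never counted by either method.
background_medications <- c(
  "lisinopril", "amlodipine", "atorvastatin", "levothyroxine", "metformin",
  "albuterol", "gabapentin", "hydrochlorothiazide", "losartan", "fluticasone",
  "montelukast", "prednisone", "amoxicillin", "azithromycin", "cephalexin",
  "doxycycline", "ibuprofen", "naproxen", "acetaminophen", "aspirin",
  "trazodone", "zolpidem", "alprazolam", "lorazepam", "clonazepam",
  "cyclobenzaprine", "tizanidine", "meloxicam", "cetirizine", "loratadine",
  "famotidine", "omega-3 acid ethyl esters", "glipizide", "rosuvastatin",
  "pravastatin", "valsartan", "carvedilol", "spironolactone", "furosemide",
  "insulin glargine"
)

#' Default synthetic-population configuration
#'
#' Encodes the study conditions the generator emulates: age 35 +/- 17.4
#' years truncated at 18, 62% female, and an included-medication count
#' distribution of 57% with exactly one, 13.1% with two, 2.5% with three and
#' 0.7% with four or more (the 26.7% mass at zero is back-derived so that
#' 73.3% of patients have at least one included medication). Medication
#' popularity is skewed with metoprolol, ondansetron and sertraline ranked
#' highest. ER/inpatient probabilities and log-normal cost parameters are
#' illustrative order-of-magnitude defaults.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the whole dataset is a pure function of
#'   (config, seed).
#' @param kb Knowledge base whose union medication list seeds the
#'   popularity weights.
#' @return Object of class `pgx_sim_config` (a named list; see fields in
#'   the source).
#' @export
default_sim_config <- function(n_patients = 20000L, seed = 1L, kb = load_kb()) {
  union_meds <- union(method_medications(kb, "manual"),
                      method_medications(kb, "automated"))
  top <- c("metoprolol", "ondansetron", "sertraline")
  rest <- sort(setdiff(union_meds, top))
  popularity <- c(stats::setNames(c(100, 90, 80), top),
                  stats::setNames(60 / seq_along(rest)^0.8, rest))
  structure(
    list(
      n_patients = as.integer(n_patients),
      seed = as.integer(seed),
      age_mean = 35, age_sd = 17.4, age_min = 18,
      prop_female = 0.62,
      included_med_count_pmf = c("0" = 0.267, "1" = 0.57, "2" = 0.131,
                                 "3" = 0.025, "4+" = 0.007),
      extra_included_pmf = c(0.7, 0.2, 0.1),  # 4+, how many beyond 4
      background_med_rate = 3.5,
      popularity_weights = popularity,
      er_prob = 0.08, inpatient_prob = 0.04,
      er_cost_meanlog = log(400), er_cost_sdlog = 1.0,
      inpatient_cost_meanlog = log(3500), inpatient_cost_sdlog = 1.2,
      unmappable_frac = 0.015,
      window = as.Date(c("2018-10-01", "2019-01-01"))
    ),
    class = "pgx_sim_config"
  )
}

validate_sim_config <- function(config) {
  pmf <- config$included_med_count_pmf
  if (abs(sum(pmf) - 1) > 1e-9 || any(pmf < 0)) {
    stop("included_med_count_pmf must be a probability vector summing to 1")
  }
  probs <- c(config$prop_female, config$er_prob, config$inpatient_prob,
             config$unmappable_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  invisible(config)
}

# truncated-normal sampler via inverse CDF, exact above the truncation point
rtnorm_min <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic claims dataset
#'
#' Draws a full population — demographics, pharmacy claims, medical claims
#' and the local NDC-to-ingredient mapping table — reproducibly from the
#' configuration's seed. Each patient receives a number of PGx-included
#' medications drawn from `included_med_count_pmf` (sampled without
#' replacement by popularity weight), a Poisson number of background
#' medications (at least one medication overall), and 1-3 uniformly dated
#' fills per medication inside the window. A small fraction of extra
#' pharmacy claims carry NDCs absent from the mapping table, emulating
#' non-drug items that the ingestion step must drop. ER and inpatient
#' events are Bernoulli with log-normal costs.
#'
#' @param config A `pgx_sim_config`, e.g. [default_sim_config()].
#' @return Object of class `pgx_sim`: list with tibbles `demographics`,
#'   `pharmacy`, `medical`, `mapping`, and a `manifest` list recording the
#'   configuration.
#' @export
simulate_claims <- function(config = default_sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_claims_impl(config))
}

simulate_claims_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  window <- config$window
  ndays <- as.integer(window[2] - window[1])

  demographics <- tibble::tibble(
    patient_id = ids,
    age_years = as.integer(floor(rtnorm_min(n, config$age_mean, config$age_sd,
                                            config$age_min))),
    sex = ifelse(stats::runif(n) < config$prop_female, "female", "male")
  )

  # per-patient included-medication count
  pmf <- config$included_med_count_pmf
  kcat <- sample(names(pmf), n, replace = TRUE, prob = pmf)
  extra <- sample(seq_along(config$extra_included_pmf) - 1L, n,
                  replace = TRUE, prob = config$extra_included_pmf)
  k <- as.integer(ifelse(kcat == "4+", "4", kcat)) +
    ifelse(kcat == "4+", extra, 0L)

  pop <- config$popularity_weights
  pool <- names(pop)
  included <- lapply(k, function(ki) {
    if (ki == 0) character(0) else sample(pool, ki, prob = pop)
  })

  n_bg <- stats::rpois(n, config$background_med_rate)
  n_bg[k == 0 & n_bg == 0] <- 1L  # every patient has at least one medication
  background <- lapply(n_bg, function(b) {
    if (b == 0) character(0) else sample(background_medications, min(b, length(background_medications)))
  })

  meds <- mapply(c, included, background, SIMPLIFY = FALSE)
  nfills <- lapply(meds, function(m) sample(1:3, length(m), replace = TRUE))
  pat_idx <- rep(seq_len(n), vapply(nfills, sum, 0))
  ing <- unlist(mapply(rep, meds, nfills, SIMPLIFY = FALSE), use.names = FALSE)

  all_ings <- c(pool, background_medications)
  mapping <- tibble::tibble(
    ndc = paste0("6000000", sprintf("%04d", seq_along(all_ings))),
    rxcui = sprintf("SYN%05d", seq_along(all_ings)),
    ingredient = all_ings
  )

  pharmacy <- tibble::tibble(
    patient_id = ids[pat_idx],
    fill_date = window[1] + sample(0:(ndays - 1), length(pat_idx), replace = TRUE),
    ndc = mapping$ndc[match(ing, mapping$ingredient)]
  )

  # unmappable non-drug items (lancets, test strips, ...) on top
  n_junk <- round(config$unmappable_frac * nrow(pharmacy))
  if (n_junk > 0) {
    junk <- tibble::tibble(
      patient_id = sample(ids, n_junk, replace = TRUE),
      fill_date = window[1] + sample(0:(ndays - 1), n_junk, replace = TRUE),
      ndc = paste0("9999999", sprintf("%04d", seq_len(n_junk) %% 10000))
    )
    pharmacy <- dplyr::bind_rows(pharmacy, junk)
  }
  pharmacy <- dplyr::arrange(pharmacy, .data$patient_id, .data$fill_date, .data$ndc)

  events <- function(prob, meanlog, sdlog, type) {
    has <- stats::runif(n) < prob
    m <- sum(has)
    tibble::tibble(
      patient_id = ids[has],
      visit_type = rep(type, m),
      date = window[1] + sample(0:(ndays - 1), m, replace = TRUE),
      cost = round(stats::rlnorm(m, meanlog, sdlog), 2)
    )
  }
  medical <- dplyr::bind_rows(
    events(config$er_prob, config$er_cost_meanlog, config$er_cost_sdlog, "ER"),
    events(config$inpatient_prob, config$inpatient_cost_meanlog,
           config$inpatient_cost_sdlog, "inpatient")
  )
  medical <- dplyr::arrange(medical, .data$patient_id, .data$date, .data$visit_type)

  structure(
    list(
      demographics = demographics,
      pharmacy = pharmacy,
      medical = medical,
      mapping = mapping,
      manifest = list(
        config = unclass(config)[setdiff(names(config), "popularity_weights")],
        n_unmappable = n_junk
      )
    ),
    class = "pgx_sim"
  )
}

#' Write a synthetic dataset to CSV files
#'
#' Emits `pharmacy.csv`, `medical.csv`, `demographics.csv`, `mapping.csv`
#' and `manifest.json` into a directory, in the formats the `read_*`
#' ingestion helpers expect.
#'
#' @param sim A `pgx_sim` object from [simulate_claims()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pgx_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$pharmacy, file.path(dir, "pharmacy.csv"))
  readr::write_csv(sim$medical, file.path(dir, "medical.csv"))
  readr::write_csv(sim$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(sim$mapping, file.path(dir, "mapping.csv"))
  manifest <- sim$manifest
  manifest$config$window <- as.character(manifest$config$window)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pgx_sim <- function(x, ...) {
  cat("<pgx_sim> ", nrow(x$demographics), " patients, ",
      nrow(x$pharmacy), " pharmacy claims, ", nrow(x$medical),
      " medical claims\n", sep = "")
  invisible(x)
}
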