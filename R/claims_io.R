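# Claims ingestion: CSV readers, NDC -> ingredient mapping, eligibility
# filtering, and per-patient medication profiles for an analysis window.
#
# Window convention throughout: half-open [start, end). A fill dated on the
# end date is outside the window.

#' Read claims and reference tables
#'
#' Thin readers over `readr::read_csv()` with typed columns.
#' `read_pharmacy()` expects `patient_id, fill_date, ndc`;
#' `read_medical()` expects `patient_id, visit_type, date, cost`;
#' `read_demographics()` expects `patient_id, age_years, sex`;
#' `read_ndc_mapping()` expects `ndc, rxcui, ingredient`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @name claims_readers
NULL

#' @rdname claims_readers
#' @export
read_pharmacy <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    fill_date = readr::col_date(),
    ndc = readr::col_character()
  ))
}

#' @rdname claims_readers
#' @export
read_medical <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    visit_type = readr::col_character(),
    date = readr::col_date(),
    cost = readr::col_double()
  ))
}

#' @rdname claims_readers
#' @export
read_demographics <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    age_years = readr::col_integer(),
    sex = readr::col_character()
  ))
}

#' @rdname claims_readers
#' @export
read_ndc_mapping <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    ndc = readr::col_character(),
    rxcui = readr::col_character(),
    ingredient = readr::col_character()
  ))
}

#' Map NDCs to ingredients
#'
#' Joins pharmacy claims against a local NDC-to-ingredient mapping table
#' (standing in for the RxNorm API). Claims whose NDC is malformed (not
#' exactly 11 digits) or absent from the mapping — typically non-drug items
#' such as lancets and test strips — are dropped and returned separately.
#'
#' @param claims Tibble of pharmacy claims (`patient_id`, `fill_date`, `ndc`).
#' @param mapping Tibble with columns `ndc`, `rxcui`, `ingredient`.
#' @return List with elements `mapped` (claims plus `rxcui` and `ingredient`
#'   columns) and `dropped` (the excluded claims with a `drop_reason`
#'   column, `"malformed_ndc"` or `"unmapped_ndc"`).
#' @export
map_ndc <- function(claims, mapping) {
  claims <- tibble::as_tibble(claims)
  if (nrow(claims) == 0) {
    empty <- dplyr::mutate(claims, rxcui = character(0), ingredient = character(0))
    return(list(mapped = empty,
                dropped = dplyr::mutate(claims, drop_reason = character(0))))
  }
  malformed <- is.na(claims$ndc) | !grepl("^[0-9]{11}$", claims$ndc)
  if (any(malformed)) {
    warning(sum(malformed), " pharmacy claim(s) with malformed NDC dropped")
  }
  ok <- claims[!malformed, ]
  joined <- dplyr::left_join(ok, mapping[, c("ndc", "rxcui", "ingredient")], by = "ndc")
  unmapped <- is.na(joined$ingredient)
  dropped <- dplyr::bind_rows(
    dplyr::mutate(claims[malformed, ], drop_reason = "malformed_ndc"),
    dplyr::mutate(ok[unmapped, ], drop_reason = "unmapped_ndc")
  )
  list(mapped = joined[!unmapped, ], dropped = dropped)
}

in_window <- function(dates, window) {
  !is.na(dates) & dates >= window[1] & dates < window[2]
}

#' Parse an analysis window
#'
#' @param window Either a length-2 Date vector or a string
#'   `"YYYY-MM-DD:YYYY-MM-DD"`. Interpreted as half-open `[start, end)`.
#' @return Length-2 Date vector.
#' @export
parse_window <- function(window) {
  if (is.character(window) && length(window) == 1) {
    window <- as.Date(strsplit(window, ":", fixed = TRUE)[[1]])
  }
  window <- as.Date(window)
  if (length(window) != 2 || anyNA(window) || window[1] >= window[2]) {
    stop("window must be a non-empty half-open date interval [start, end)")
  }
  window
}

#' Filter the claims population to the eligible cohort
#'
#' Applies the eligibility filters sequentially, logging the count removed
#' at each step: (1) adults (age >= 18; patients whose age is missing pass
#' here and are removed at the completeness step), (2) at least one pharmacy
#' claim filled in the window, (3) at least one in-window claim for a
#' medication on the union of the manual and automated lists, (4) complete
#' demographics (age and sex both present).
#'
#' Because the study's "predefined list" of PGx-recommended medications may
#' be broader than the knowledge base's union list, step 3 can be disabled
#' with `require_included = FALSE`; the log reports the union-list count
#' either way (column `n_with_included_med`).
#'
#' @param demographics Tibble (`patient_id`, `age_years`, `sex`).
#' @param claims Mapped pharmacy claims (from [map_ndc()]; must carry an
#'   `ingredient` column).
#' @param window Analysis window, see [parse_window()].
#' @param kb A `pgx_kb` object.
#' @param require_included Apply filter 3? Default `TRUE`.
#' @return List with `eligible_ids` (character vector) and `log` (tibble
#'   with columns `step`, `description`, `n_excluded`, `n_remaining`).
#' @export
filter_eligible <- function(demographics, claims, window, kb,
                            require_included = TRUE) {
  window <- parse_window(window)
  if (!"ingredient" %in% names(claims)) {
    stop("claims must be NDC-mapped (missing 'ingredient' column); run map_ndc() first")
  }
  ids <- demographics$patient_id
  steps <- list()
  note <- function(step, desc, keep) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = step, description = desc,
      n_excluded = length(ids) - sum(keep), n_remaining = sum(keep))
    ids <<- ids[keep]
  }

  age <- demographics$age_years[match(ids, demographics$patient_id)]
  note(1L, "adults (age >= 18, unknown age retained)", is.na(age) | age >= 18)

  cw <- claims[in_window(claims$fill_date, window), ]
  note(2L, "at least one pharmacy claim filled in window", ids %in% cw$patient_id)

  union_meds <- union(method_medications(kb, "manual"),
                      method_medications(kb, "automated"))
  has_included <- ids %in% cw$patient_id[cw$ingredient %in% union_meds]
  n_with_included <- sum(has_included)
  if (require_included) {
    note(3L, "at least one in-window claim on the included-medication list", has_included)
  } else {
    note(3L, "included-medication filter disabled (logged only)", rep(TRUE, length(ids)))
  }

  dem <- demographics[match(ids, demographics$patient_id), ]
  complete <- !is.na(dem$age_years) & !is.na(dem$sex) & dem$sex %in% c("male", "female")
  note(4L, "complete demographic data (age and sex)", complete)

  log <- dplyr::bind_rows(steps)
  log$n_with_included_med <- n_with_included
  list(eligible_ids = ids, log = log)
}

#' Build per-patient medication profiles
#'
#' For each eligible patient, collects the set of unique ingredients with at
#' least one in-window fill, and the in-window ER and inpatient visit counts
#' and summed costs. Costs for patients without visits are zero, not
#' missing.
#'
#' @param ids Character vector of eligible patient ids; every id must have a
#'   demographics row.
#' @param demographics,claims,medical Tibbles as read by the
#'   `read_*` helpers; `claims` must be NDC-mapped.
#' @param window Analysis window, see [parse_window()].
#' @return Tibble with one row per id: `patient_id`, `age_years`, `sex`,
#'   `medications` (list column of ingredient names), `n_unique_meds`,
#'   `er_visits`, `er_cost`, `inpatient_visits`, `inpatient_cost`.
#' @export
build_profiles <- function(ids, demographics, claims, medical, window) {
  window <- parse_window(window)
  miss <- setdiff(ids, demographics$patient_id)
  if (length(miss)) {
    stop("no demographics row for patient id(s): ",
         toString(utils::head(miss, 5)))
  }
  if (!"ingredient" %in% names(claims)) {
    stop("claims must be NDC-mapped (missing 'ingredient' column)")
  }

  cw <- claims[in_window(claims$fill_date, window) & claims$patient_id %in% ids, ]
  med_sets <- split(cw$ingredient, factor(cw$patient_id, levels = ids))
  med_sets <- lapply(med_sets, function(x) sort(unique(x)))

  mw <- medical[in_window(medical$date, window) & medical$patient_id %in% ids, ]
  util <- function(type) {
    m <- mw[mw$visit_type == type, ]
    visits <- table(factor(m$patient_id, levels = ids))
    cost <- vapply(split(m$cost, factor(m$patient_id, levels = ids)), sum, 0)
    list(visits = as.integer(visits), cost = unname(cost))
  }
  er <- util("ER")
  ip <- util("inpatient")

  dem <- demographics[match(ids, demographics$patient_id), ]
  tibble::tibble(
    patient_id = ids,
    age_years = dem$age_years,
    sex = dem$sex,
    medications = unname(med_sets),
    n_unique_meds = unname(lengths(med_sets)),
    er_visits = er$visits,
    er_cost = er$cost,
    inpatient_visits = ip$visits,
    inpatient_cost = ip$cost
  )
}

#' Included-medication count distribution
#'
#' Tabulates, over a set of profiles, how many knowledge-base-included
#' medications (union of both methods' lists) each patient has, and the
#' percentage of patients at each count. This is the medication-usage
#' marginal used to calibrate the synthetic generator.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param kb A `pgx_kb` object.
#' @return Tibble with columns `n_included` (0, 1, 2, 3, `"4+"` as
#'   character), `n_patients`, `pct` (percentage of all profiles).
#' @export
included_med_marginals <- function(profiles, kb) {
  union_meds <- union(method_medications(kb, "manual"),
                      method_medications(kb, "automated"))
  k <- vapply(profiles$medications, function(m) sum(m %in% union_meds), 0L)
  kcat <- ifelse(k >= 4, "4+", as.character(k))
  kcat <- factor(kcat, levels = c("0", "1", "2", "3", "4+"))
  tab <- table(kcat)
  tibble::tibble(
    n_included = names(tab),
    n_patients = as.integer(tab),
    pct = 100 * as.integer(tab) / nrow(profiles)
  )
}
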