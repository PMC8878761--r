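# Automated selection method: the pharmacogenetic interaction probability
# (PIP). For each gene, the probability that genotyping reveals at least one
# actionable drug-gene interaction given the patient's current medications,
# with phenoconversion by co-medicated inhibitors/inducers; gene-level
# probabilities combine under cross-gene independence into a whole-number
# percentage.

#' Effective phenotype under co-medication
#'
#' Applies phenoconversion: an inhibitor among the co-medications shifts the
#' genotype-predicted phenotype toward the poor end of the gene's activity
#' ladder, an inducer toward the ultrarapid end. A strong inhibitor converts
#' the normal phenotype and everything between it and poor into poor (e.g.
#' NM or IM -> PM); a moderate inhibitor shifts one ladder step toward poor.
#' A strong inducer converts to the top of the ladder, a moderate inducer
#' shifts one step up. The strongest modifier of each kind applies; if both
#' an inhibitor and an inducer are present they cancel (no net shift). Genes
#' that are not phenoconvertible always map identically.
#'
#' @param gene Gene symbol.
#' @param phenotype Genotype-predicted phenotype label (must be on the
#'   gene's ladder).
#' @param comeds Character vector of co-medications, excluding the victim
#'   drug itself.
#' @param kb A `pgx_kb` object.
#' @return A phenotype label on the same ladder.
#' @export
#' @examples
#' kb <- load_kb()
#' effective_phenotype("CYP2D6", "NM", "paroxetine", kb)  # strong inhibitor -> "PM"
effective_phenotype <- function(gene, phenotype, comeds, kb) {
  gi <- match(gene, kb$genes$symbol)
  if (is.na(gi)) stop("unknown gene: ", gene)
  ladder <- kb$genes$phenotypes[[gi]]
  pos <- match(phenotype, ladder)
  if (is.na(pos)) stop("phenotype '", phenotype, "' not on the ", gene, " ladder")
  if (!kb$genes$phenoconvertible[gi]) return(phenotype)

  mods <- kb$modifiers[kb$modifiers$gene == gene &
                         kb$modifiers$medication %in% comeds, ]
  if (nrow(mods) == 0) return(phenotype)
  has_inh <- any(mods$kind == "inhibitor")
  has_ind <- any(mods$kind == "inducer")
  if (has_inh && has_ind) return(phenotype)  # opposing modifiers cancel

  n <- length(ladder)
  if (has_inh) {
    strong <- any(mods$strength[mods$kind == "inhibitor"] == "strong")
    if (strong) {
      # normal or anything between normal and poor collapses to poor;
      # ladders without an "NM" label collapse entirely
      norm_pos <- match("NM", ladder)
      if (is.na(norm_pos) || pos >= norm_pos) pos <- n
    } else {
      pos <- min(pos + 1L, n)
    }
  } else {
    strong <- any(mods$strength[mods$kind == "inducer"] == "strong")
    pos <- if (strong) 1L else max(pos - 1L, 1L)
  }
  ladder[pos]
}

#' Per-gene actionable interaction probability
#'
#' The probability, over the gene's phenotype prevalence distribution, that
#' the patient's genotype-predicted phenotype is actionable for at least one
#' of their current medications — each medication evaluated at the effective
#' phenotype produced by its co-medications (see [effective_phenotype()]).
#'
#' @param gene Gene symbol.
#' @param medications Character vector of the patient's unique medications.
#' @param kb A `pgx_kb` object.
#' @return Probability in `[0, 1]`; 0 when no medication has a rule for the
#'   gene.
#' @export
gene_actionable_prob <- function(gene, medications, kb) {
  # only automated-method medications contribute candidate interactions
  # (e.g. warfarin, manual-only, never feeds the PIP); phenoconversion
  # perpetrators are unrestricted since inhibition is pharmacology, not
  # method membership
  automated <- method_medications(kb, "automated")
  rules <- kb$drug_gene_rules[kb$drug_gene_rules$gene == gene &
                                kb$drug_gene_rules$medication %in% medications &
                                kb$drug_gene_rules$medication %in% automated, ]
  if (nrow(rules) == 0) return(0)
  freq <- kb$frequencies[kb$frequencies$gene == gene, ]
  ladder <- kb$genes$phenotypes[[match(gene, kb$genes$symbol)]]

  # effective phenotype of each genotypic phenotype, per victim drug
  p <- 0
  for (phi in ladder) {
    hit <- FALSE
    for (i in seq_len(nrow(rules))) {
      eff <- effective_phenotype(gene, phi,
                                 setdiff(medications, rules$medication[i]), kb)
      if (eff %in% rules$actionable_phenotypes[[i]]) { hit <- TRUE; break }
    }
    if (hit) p <- p + freq$frequency[match(phi, freq$phenotype)]
  }
  min(p, 1)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' PIP score for one medication list
#'
#' Combines the per-gene actionable probabilities across all knowledge-base
#' genes under independence: `PIP = 100 * (1 - prod(1 - p_g))`, rounded half
#' away from zero to a whole-number percentage. Also reports the risk band
#' (see [pip_band()]) and the number needed to test, `NNT = 100 / PIP`.
#'
#' @param medications Character vector of the patient's unique medications.
#' @param kb A `pgx_kb` object.
#' @return List with `per_gene_prob` (named numeric over the KB genes),
#'   `pip_raw` (unrounded probability in `[0, 1]`), `pip_percent` (integer),
#'   `band`, `nnt` (`NA` when the PIP is 0).
#' @export
#' @examples
#' kb <- load_kb()
#' pip_score(c("clopidogrel", "omeprazole"), kb)$pip_percent
pip_score <- function(medications, kb) {
  genes <- kb$genes$symbol
  p <- vapply(genes, gene_actionable_prob, 0, medications = medications, kb = kb)
  raw <- 1 - prod(1 - p)
  pct <- round_half_up(100 * raw)
  list(
    per_gene_prob = p,
    pip_raw = raw,
    pip_percent = pct,
    band = pip_band(pct),
    nnt = if (pct > 0) 100 / pct else NA_real_
  )
}

#' PIP risk band
#'
#' Bands a whole-number PIP percentage: 0 is `"none"`; 1-25 `"low"` and
#' 26-50 `"moderate"` split patients into needing more or fewer than 1 in 4
#' tested to find something actionable; above 50 is `"high"`, where an
#' actionable interaction is more likely to be found than not.
#'
#' @param pip_percent Integer vector of PIP percentages in `[0, 100]`.
#' @return Character vector of bands.
#' @export
pip_band <- function(pip_percent) {
  if (any(is.na(pip_percent)) || any(pip_percent < 0 | pip_percent > 100)) {
    stop("pip_percent must be in [0, 100]")
  }
  ifelse(pip_percent == 0, "none",
         ifelse(pip_percent <= 25, "low",
                ifelse(pip_percent <= 50, "moderate", "high")))
}

#' Count drug-drug interactions on a medication list
#'
#' A DDI rule fires when its entire drug set (two or more medications) is
#' present on the list. Counts are binned by severity. Gene-related
#' interactions are not part of the DDI table, so these counts are
#' independent of genotype.
#'
#' @param medications Character vector of unique medications.
#' @param kb A `pgx_kb` object.
#' @return Named integer vector over [pgx_severity_levels], plus an
#'   attribute-free helper sum is available via [ddi_moderate_plus()].
#' @export
count_ddis <- function(medications, kb) {
  counts <- stats::setNames(integer(length(pgx_severity_levels)), pgx_severity_levels)
  for (i in seq_len(nrow(kb$ddi_rules))) {
    if (all(kb$ddi_rules$drugs[[i]] %in% medications)) {
      sev <- kb$ddi_rules$severity[i]
      counts[sev] <- counts[sev] + 1L
    }
  }
  counts
}

#' Moderate-or-higher DDI count
#'
#' @param ddi_counts Named vector from [count_ddis()] (or a matrix of such
#'   rows).
#' @return Total count of interactions at moderate severity or above.
#' @export
ddi_moderate_plus <- function(ddi_counts) {
  keep <- pgx_severity_levels[severity_rank(pgx_severity_levels) >= severity_rank("moderate")]
  if (is.matrix(ddi_counts)) rowSums(ddi_counts[, keep, drop = FALSE]) else sum(ddi_counts[keep])
}

#' PIP scores for a set of profiles
#'
#' Vectorized driver for the automated method: scores every profile with
#' [pip_score()] and [count_ddis()].
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param kb A `pgx_kb` object.
#' @return Tibble: `patient_id`, `pip_percent`, `pip_raw`, `band`, `nnt`,
#'   one `p_<gene>` column per knowledge-base gene, one `ddi_<severity>`
#'   column per severity level, `ddi_moderate_plus`, `total_med_count`.
#' @export
pip_scores <- function(profiles, kb) {
  res <- lapply(profiles$medications, pip_score, kb = kb)
  ddi <- t(vapply(profiles$medications, count_ddis,
                  stats::setNames(integer(length(pgx_severity_levels)), pgx_severity_levels),
                  kb = kb))
  mod_plus <- as.integer(ddi_moderate_plus(ddi))
  pg <- t(vapply(res, function(r) r$per_gene_prob, numeric(nrow(kb$genes))))
  colnames(pg) <- paste0("p_", kb$genes$symbol)
  colnames(ddi) <- paste0("ddi_", pgx_severity_levels)
  out <- tibble::tibble(
    patient_id = profiles$patient_id,
    pip_percent = vapply(res, function(r) r$pip_percent, 0L),
    pip_raw = vapply(res, function(r) r$pip_raw, 0),
    band = vapply(res, function(r) r$band, ""),
    nnt = vapply(res, function(r) r$nnt, 0)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(pg), tibble::as_tibble(ddi))
  out$ddi_moderate_plus <- mod_plus
  out$total_med_count <- profiles$n_unique_meds
  out
}

#' Rank patients for the automated method
#'
#' Orders by descending PIP, breaking ties by the drug-drug interaction
#' profile compared most-severe-first (contraindicated, then severe,
#' moderate, minor, minimal counts, each descending), then by descending
#' overall unique medication count, then randomly under a seeded stream.
#'
#' @param results Tibble from [pip_scores()].
#' @param seed Integer seed for the random tie-break.
#' @return `results` sorted into rank order with `random_key` and `rank`
#'   columns added.
#' @export
rank_automated <- function(results, seed = 1L) {
  if (nrow(results) == 0) stop("no results to rank")
  key <- withr::with_seed(seed, stats::runif(nrow(results)))
  sev_desc <- rev(pgx_severity_levels)  # contraindicated first
  args <- c(
    list(-results$pip_percent),
    lapply(sev_desc, function(s) -results[[paste0("ddi_", s)]]),
    list(-results$total_med_count, key)
  )
  ord <- do.call(order, args)
  out <- results[ord, ]
  out$random_key <- key[ord]
  out$rank <- seq_len(nrow(out))
  out
}
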