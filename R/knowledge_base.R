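# Drug-gene knowledge base: Table-style panel content driving both selection
# methods. Everything the scoring code knows about pharmacology lives here;
# the algorithms themselves are KB-driven and contain no per-drug logic.

#' Interaction severity ladder
#'
#' Ordinal severity levels used for both drug-gene and drug-drug interaction
#' rules, from least to most severe. Drug-gene rules must be at least
#' `"moderate"`, the lowest level with clinically actionable recommendations.
#'
#' @format Character vector of length 5.
#' @export
pgx_severity_levels <- c("minimal", "minor", "moderate", "severe", "contraindicated")

severity_rank <- function(x) match(x, pgx_severity_levels)

#' Construct a knowledge base from component tables
#'
#' Assembles and validates a `pgx_kb` object. Most users will call
#' [load_kb()] on a JSON file instead; this constructor is the programmatic
#' route used by tests and by the synthetic-data tooling.
#'
#' @param genes Tibble with columns `symbol`, `phenotypes` (list column of
#'   phenotype labels ordered from the ultrarapid end of the activity ladder
#'   to the poor end), and `phenoconvertible` (logical).
#' @param frequencies Tibble with columns `gene`, `phenotype`, `frequency`;
#'   population prevalence of each phenotype, summing to 1 within each gene.
#' @param medications Tibble with columns `name`, `rxcui`, `drug_class`,
#'   `in_manual`, `in_automated`.
#' @param drug_gene_rules Tibble with columns `medication`, `gene`,
#'   `actionable_phenotypes` (list column), `severity`.
#' @param modifiers Tibble with columns `medication`, `gene`, `kind`
#'   (`"inhibitor"` or `"inducer"`), `strength` (`"strong"` or `"moderate"`).
#'   May have zero rows.
#' @param ddi_rules Tibble with columns `drugs` (list column, each a set of
#'   two or more medication names) and `severity`. May have zero rows.
#'
#' @return A validated object of class `pgx_kb`.
#' @export
new_kb <- function(genes, frequencies, medications, drug_gene_rules,
                   modifiers = NULL, ddi_rules = NULL) {
  if (is.null(modifiers)) {
    modifiers <- tibble::tibble(medication = character(), gene = character(),
                                kind = character(), strength = character())
  }
  if (is.null(ddi_rules)) {
    ddi_rules <- tibble::tibble(drugs = list(), severity = character())
  }
  kb <- structure(
    list(
      genes = tibble::as_tibble(genes),
      frequencies = tibble::as_tibble(frequencies),
      medications = tibble::as_tibble(medications),
      drug_gene_rules = tibble::as_tibble(drug_gene_rules),
      modifiers = tibble::as_tibble(modifiers),
      ddi_rules = tibble::as_tibble(ddi_rules)
    ),
    class = "pgx_kb"
  )
  validate_kb(kb)
}

#' Validate a knowledge base
#'
#' Enforces the structural invariants of a `pgx_kb`: unique phenotype labels
#' per gene, per-gene frequencies that sum to 1 (within 1e-9) and are
#' non-negative, every medication belonging to at least one method, every
#' rule referencing a declared gene and medication with actionable phenotypes
#' drawn from that gene's ladder, a severity floor of `"moderate"` for
#' drug-gene rules, modifiers restricted to phenoconvertible genes, and
#' duplicate-free drug sets of size two or more in DDI rules.
#'
#' @param kb A `pgx_kb` object.
#' @return `kb`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending record.
#' @export
validate_kb <- function(kb) {
  g <- kb$genes
  if (anyDuplicated(g$symbol)) stop("duplicate gene symbols in knowledge base")
  for (i in seq_len(nrow(g))) {
    ph <- g$phenotypes[[i]]
    if (length(ph) < 1 || anyDuplicated(ph)) {
      stop("gene ", g$symbol[i], ": phenotype labels must be non-empty and unique")
    }
  }

  fr <- kb$frequencies
  bad <- setdiff(fr$gene, g$symbol)
  if (length(bad)) stop("frequencies reference unknown gene(s): ", toString(bad))
  for (sym in unique(fr$gene)) {
    f <- fr[fr$gene == sym, ]
    ladder <- g$phenotypes[[match(sym, g$symbol)]]
    if (!setequal(f$phenotype, ladder)) {
      stop("gene ", sym, ": frequency table phenotypes do not match the gene's ladder")
    }
    if (any(f$frequency < 0)) stop("gene ", sym, ": negative phenotype frequency")
    if (abs(sum(f$frequency) - 1) > 1e-9) {
      stop("gene ", sym, ": phenotype frequencies sum to ",
           format(sum(f$frequency)), ", not 1")
    }
  }
  missing_freq <- setdiff(g$symbol, fr$gene)
  if (length(missing_freq)) {
    stop("no phenotype frequencies for gene(s): ", toString(missing_freq))
  }

  med <- kb$medications
  if (anyDuplicated(med$name)) stop("duplicate medication names in knowledge base")
  if (any(med$name != tolower(med$name))) {
    stop("medication names must be lowercase: ",
         toString(med$name[med$name != tolower(med$name)]))
  }
  orphan <- !(med$in_manual | med$in_automated)
  if (any(orphan)) {
    stop("medication(s) in neither method: ", toString(med$name[orphan]))
  }

  dgr <- kb$drug_gene_rules
  bad <- setdiff(dgr$medication, med$name)
  if (length(bad)) stop("drug-gene rule references undeclared medication(s): ", toString(bad))
  bad <- setdiff(dgr$gene, g$symbol)
  if (length(bad)) stop("drug-gene rule references unknown gene(s): ", toString(bad))
  if (!all(dgr$severity %in% pgx_severity_levels)) {
    stop("drug-gene rule with unknown severity label")
  }
  low <- severity_rank(dgr$severity) < severity_rank("moderate")
  if (any(low)) {
    stop("drug-gene rule below the moderate severity floor: ",
         toString(paste(dgr$medication[low], dgr$gene[low], sep = "-")))
  }
  for (i in seq_len(nrow(dgr))) {
    ladder <- g$phenotypes[[match(dgr$gene[i], g$symbol)]]
    act <- dgr$actionable_phenotypes[[i]]
    if (length(act) == 0 || !all(act %in% ladder)) {
      stop("rule ", dgr$medication[i], "-", dgr$gene[i],
           ": actionable phenotypes must be a non-empty subset of the gene's ladder")
    }
  }

  mod <- kb$modifiers
  if (nrow(mod)) {
    bad <- setdiff(mod$medication, med$name)
    if (length(bad)) stop("modifier references undeclared medication(s): ", toString(bad))
    bad <- setdiff(mod$gene, g$symbol)
    if (length(bad)) stop("modifier references unknown gene(s): ", toString(bad))
    conv <- g$phenoconvertible[match(mod$gene, g$symbol)]
    if (any(!conv)) {
      stop("modifier on non-phenoconvertible gene(s): ", toString(unique(mod$gene[!conv])))
    }
    if (!all(mod$kind %in% c("inhibitor", "inducer"))) stop("modifier kind must be inhibitor or inducer")
    if (!all(mod$strength %in% c("strong", "moderate"))) stop("modifier strength must be strong or moderate")
  }

  ddi <- kb$ddi_rules
  for (i in seq_len(nrow(ddi))) {
    drugs <- ddi$drugs[[i]]
    if (length(drugs) < 2 || anyDuplicated(drugs)) {
      stop("DDI rule ", i, ": drug set must have >= 2 distinct medications")
    }
    bad <- setdiff(drugs, med$name)
    if (length(bad)) stop("DDI rule ", i, " references undeclared medication(s): ", toString(bad))
  }
  if (nrow(ddi) && !all(ddi$severity %in% pgx_severity_levels)) {
    stop("DDI rule with unknown severity label")
  }

  invisible(kb)
}

#' Load a knowledge base from JSON
#'
#' Reads a knowledge-base file with sections `genes`, `frequencies`,
#' `medications`, `drug_gene_rules`, `modifiers`, and `ddi_rules`, and
#' validates all invariants (see [validate_kb()]).
#'
#' @param path Path to a knowledge-base JSON document. Defaults to the
#'   packaged 8-gene fixture.
#' @return A `pgx_kb` object.
#' @seealso [write_kb()], [method_medications()], [membership_counts()]
#' @export
#' @examples
#' kb <- load_kb()
#' kb
load_kb <- function(path = default_kb_path()) {
  if (!file.exists(path)) stop("knowledge base file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("genes", "frequencies", "medications", "drug_gene_rules")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("knowledge base file missing section(s): ", toString(miss))

  chr1 <- function(x, what, rec) {
    if (is.null(x) || length(x) != 1 || is.na(x)) {
      stop("knowledge base record invalid (", what, "): ", rec)
    }
    as.character(x)
  }

  genes <- tibble::tibble(
    symbol = vapply(raw$genes, function(x) chr1(x$symbol, "gene symbol", "genes"), ""),
    phenotypes = lapply(raw$genes, function(x) as.character(unlist(x$phenotypes))),
    phenoconvertible = vapply(raw$genes, function(x) isTRUE(x$phenoconvertible), NA)
  )
  frequencies <- dplyr::bind_rows(lapply(raw$frequencies, function(x) {
    tibble::tibble(
      gene = chr1(x$gene, "frequency gene", "frequencies"),
      phenotype = as.character(unlist(x$phenotypes)),
      frequency = as.numeric(unlist(x$frequency))
    )
  }))
  medications <- dplyr::bind_rows(lapply(raw$medications, function(x) {
    tibble::tibble(
      name = chr1(x$name, "medication name", "medications"),
      rxcui = chr1(x$rxcui, "rxcui", x$name),
      drug_class = chr1(x$drug_class, "drug_class", x$name),
      in_manual = isTRUE(x$in_manual),
      in_automated = isTRUE(x$in_automated)
    )
  }))
  drug_gene_rules <- tibble::tibble(
    medication = vapply(raw$drug_gene_rules, function(x) chr1(x$medication, "rule medication", "drug_gene_rules"), ""),
    gene = vapply(raw$drug_gene_rules, function(x) chr1(x$gene, "rule gene", "drug_gene_rules"), ""),
    actionable_phenotypes = lapply(raw$drug_gene_rules, function(x) as.character(unlist(x$actionable_phenotypes))),
    severity = vapply(raw$drug_gene_rules, function(x) chr1(x$severity, "rule severity", "drug_gene_rules"), "")
  )
  modifiers <- if (length(raw$modifiers)) {
    tibble::tibble(
      medication = vapply(raw$modifiers, function(x) chr1(x$medication, "modifier medication", "modifiers"), ""),
      gene = vapply(raw$modifiers, function(x) chr1(x$gene, "modifier gene", "modifiers"), ""),
      kind = vapply(raw$modifiers, function(x) chr1(x$kind, "modifier kind", "modifiers"), ""),
      strength = vapply(raw$modifiers, function(x) chr1(x$strength, "modifier strength", "modifiers"), "")
    )
  } else NULL
  ddi_rules <- if (length(raw$ddi_rules)) {
    tibble::tibble(
      drugs = lapply(raw$ddi_rules, function(x) as.character(unlist(x$drugs))),
      severity = vapply(raw$ddi_rules, function(x) chr1(x$severity, "DDI severity", "ddi_rules"), "")
    )
  } else NULL

  new_kb(genes, frequencies, medications, drug_gene_rules, modifiers, ddi_rules)
}

#' Path to the packaged default knowledge base
#'
#' @return File path of the 8-gene default fixture shipped with the package.
#' @export
default_kb_path <- function() {
  system.file("extdata", "kb_default.json", package = "pgxselect", mustWork = TRUE)
}

#' Write a knowledge base to JSON
#'
#' Serializes a `pgx_kb` so that `load_kb(write_kb(kb, f))` round-trips
#' field-by-field.
#'
#' @param kb A `pgx_kb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "pgx_kb"))
  out <- list(
    genes = lapply(seq_len(nrow(kb$genes)), function(i) {
      list(symbol = kb$genes$symbol[i],
           phenotypes = kb$genes$phenotypes[[i]],
           phenoconvertible = kb$genes$phenoconvertible[i])
    }),
    frequencies = lapply(unique(kb$frequencies$gene), function(g) {
      f <- kb$frequencies[kb$frequencies$gene == g, ]
      list(gene = g, phenotypes = f$phenotype, frequency = f$frequency)
    }),
    medications = lapply(seq_len(nrow(kb$medications)), function(i) {
      as.list(kb$medications[i, ])
    }),
    drug_gene_rules = lapply(seq_len(nrow(kb$drug_gene_rules)), function(i) {
      list(medication = kb$drug_gene_rules$medication[i],
           gene = kb$drug_gene_rules$gene[i],
           actionable_phenotypes = kb$drug_gene_rules$actionable_phenotypes[[i]],
           severity = kb$drug_gene_rules$severity[i])
    }),
    modifiers = lapply(seq_len(nrow(kb$modifiers)), function(i) as.list(kb$modifiers[i, ])),
    ddi_rules = lapply(seq_len(nrow(kb$ddi_rules)), function(i) {
      list(drugs = kb$ddi_rules$drugs[[i]], severity = kb$ddi_rules$severity[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Medications used by a selection method
#'
#' The manual method uses the medications flagged `in_manual` (the shared
#' list plus the manual-only additions, e.g. warfarin); the automated method
#' uses those flagged `in_automated` (the shared list plus the
#' automated-only additions, e.g. metoprolol).
#'
#' @param kb A `pgx_kb` object.
#' @param method `"manual"` or `"automated"`.
#' @return Character vector of medication names.
#' @export
#' @examples
#' kb <- load_kb()
#' "warfarin" %in% method_medications(kb, "manual")
#' "metoprolol" %in% method_medications(kb, "automated")
method_medications <- function(kb, method = c("manual", "automated")) {
  method <- match.arg(method)
  flag <- if (method == "manual") kb$medications$in_manual else kb$medications$in_automated
  kb$medications$name[flag]
}

#' Method-membership counts of drug-gene entries
#'
#' Counts the knowledge base's drug-gene entries (table rows, so a drug
#' paired with three genes counts three times) by method membership.
#'
#' @param kb A `pgx_kb` object.
#' @return Named integer vector with elements `n_both`, `n_manual_only`,
#'   `n_automated_only`.
#' @export
#' @examples
#' membership_counts(load_kb())
membership_counts <- function(kb) {
  med <- kb$medications
  i <- match(kb$drug_gene_rules$medication, med$name)
  man <- med$in_manual[i]
  aut <- med$in_automated[i]
  c(n_both = sum(man & aut),
    n_manual_only = sum(man & !aut),
    n_automated_only = sum(!man & aut))
}

#' @export
print.pgx_kb <- function(x, ...) {
  cnt <- membership_counts(x)
  cat("<pgx_kb> ", nrow(x$genes), " genes, ", nrow(x$medications),
      " medications, ", nrow(x$drug_gene_rules), " drug-gene rules (",
      cnt["n_both"], " both / ", cnt["n_manual_only"], " manual-only / ",
      cnt["n_automated_only"], " automated-only), ",
      nrow(x$modifiers), " modifiers, ", nrow(x$ddi_rules), " DDI rules\n",
      sep = "")
  invisible(x)
}
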