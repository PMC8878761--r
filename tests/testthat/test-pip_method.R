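test_that("phenoconversion shifts phenotypes along the activity ladder", {
  kb <- phenoconv_kb()
  # strong inhibitor collapses NM, IM (and PM) to PM; UM and RM untouched
  expect_equal(effective_phenotype("GENE1", "NM", "inhibitorstrong", kb), "PM")
  expect_equal(effective_phenotype("GENE1", "IM", "inhibitorstrong", kb), "PM")
  expect_equal(effective_phenotype("GENE1", "PM", "inhibitorstrong", kb), "PM")
  expect_equal(effective_phenotype("GENE1", "RM", "inhibitorstrong", kb), "RM")
  expect_equal(effective_phenotype("GENE1", "UM", "inhibitorstrong", kb), "UM")
  # moderate inhibitor: one step toward poor, clamped at the bottom
  expect_equal(effective_phenotype("GENE1", "NM", "inhibitormod", kb), "IM")
  expect_equal(effective_phenotype("GENE1", "UM", "inhibitormod", kb), "RM")
  expect_equal(effective_phenotype("GENE1", "PM", "inhibitormod", kb), "PM")
  # inducers: one step up (moderate) or to the top (strong)
  expect_equal(effective_phenotype("GENE1", "IM", "inducermod", kb), "NM")
  expect_equal(effective_phenotype("GENE1", "UM", "inducermod", kb), "UM")
  expect_equal(effective_phenotype("GENE1", "PM", "inducerstrong", kb), "UM")
  # identity without modifiers, and opposing modifiers cancel
  expect_equal(effective_phenotype("GENE1", "IM", character(0), kb), "IM")
  expect_equal(effective_phenotype("GENE1", "NM",
                                   c("inhibitorstrong", "inducerstrong"), kb), "NM")
  # strongest modifier of a kind wins
  expect_equal(effective_phenotype("GENE1", "NM",
                                   c("inhibitormod", "inhibitorstrong"), kb), "PM")
  expect_error(effective_phenotype("GENE1", "XX", character(0), kb), "ladder")
  expect_error(effective_phenotype("NOGENE", "NM", character(0), kb), "unknown gene")
})

test_that("default fixture converts NM and IM to PM under a strong CYP2D6 inhibitor", {
  kb <- load_kb()  # paroxetine is the fixture's strong CYP2D6 inhibitor
  expect_equal(effective_phenotype("CYP2D6", "NM", "paroxetine", kb), "PM")
  expect_equal(effective_phenotype("CYP2D6", "IM", "paroxetine", kb), "PM")
})

test_that("gene probability equals hand enumeration under each modifier", {
  f <- phenoconv_freq
  # no modifier: actionable {PM} -> freq(PM)
  kb <- phenoconv_kb("PM")
  expect_equal(gene_actionable_prob("GENE1", "victimdrug", kb), f[["PM"]])
  # strong inhibitor: NM/IM/PM all present as PM
  expect_equal(gene_actionable_prob("GENE1", c("victimdrug", "inhibitorstrong"), kb),
               f[["NM"]] + f[["IM"]] + f[["PM"]])
  # actionable {NM} loses the NM mass under a strong inhibitor
  kb_nm <- phenoconv_kb("NM")
  expect_equal(gene_actionable_prob("GENE1", "victimdrug", kb_nm), f[["NM"]])
  expect_equal(gene_actionable_prob("GENE1", c("victimdrug", "inhibitorstrong"), kb_nm), 0)
  # moderate inhibitor: effective IM comes from genotypic NM only
  kb_im <- phenoconv_kb("IM")
  expect_equal(gene_actionable_prob("GENE1", c("victimdrug", "inhibitormod"), kb_im),
               f[["NM"]])
  # moderate inducer: effective NM comes from genotypic IM only
  expect_equal(gene_actionable_prob("GENE1", c("victimdrug", "inducermod"), kb_nm),
               f[["IM"]])
  # strong inducer makes everyone effectively UM
  kb_um <- phenoconv_kb("UM")
  expect_equal(gene_actionable_prob("GENE1", c("victimdrug", "inducerstrong"), kb_um), 1)
  # opposing modifiers cancel back to the genotypic distribution
  expect_equal(gene_actionable_prob(
    "GENE1", c("victimdrug", "inhibitorstrong", "inducerstrong"), kb_nm), f[["NM"]])
  # the victim drug's own modifier status never phenoconverts itself
  kb_self <- phenoconv_kb("NM")
  kb_self$modifiers <- rbind(kb_self$modifiers,
                             tibble::tibble(medication = "victimdrug", gene = "GENE1",
                                            kind = "inhibitor", strength = "strong"))
  expect_equal(gene_actionable_prob("GENE1", "victimdrug", kb_self), f[["NM"]])
  # no rules touching the gene
  expect_equal(gene_actionable_prob("GENE1", "inhibitorstrong", kb), 0)
})

test_that("PIP combines gene probabilities as one minus the product of misses", {
  kb <- toy_kb()
  # alphadrug: GA actionable {PM} -> 0.07; betadrug: GB {PM} -> 0.07
  res <- pip_score(c("alphadrug", "betadrug"), kb)
  expect_equal(res$pip_raw, 1 - (1 - 0.07) * (1 - 0.07))
  expect_equal(res$pip_percent, 14L)  # 13.51 rounds to 14
  expect_equal(res$band, "low")
  expect_equal(res$nnt, 100 / 14)

  empty <- pip_score(character(0), kb)
  expect_equal(empty$pip_percent, 0L)
  expect_equal(empty$band, "none")
  expect_true(is.na(empty$nnt))
})

test_that("manual-only medications never feed the PIP", {
  kb <- load_kb()
  expect_equal(pip_score("warfarin", kb)$pip_percent, 0L)
  kb_toy <- toy_kb()  # gammadrug is manual-only with a GA rule
  expect_equal(pip_score("gammadrug", kb_toy)$pip_percent, 0L)
})

test_that("whole-percent rounding is half away from zero", {
  # single gene, actionable mass 0.125 -> 12.5% -> 13
  genes <- tibble::tibble(symbol = "G1", phenotypes = list(c("A", "B")),
                          phenoconvertible = FALSE)
  freq <- tibble::tibble(gene = "G1", phenotype = c("A", "B"),
                         frequency = c(0.875, 0.125))
  meds <- tibble::tibble(name = "drugx", rxcui = "R1", drug_class = "t",
                         in_manual = TRUE, in_automated = TRUE)
  rules <- tibble::tibble(medication = "drugx", gene = "G1",
                          actionable_phenotypes = list("B"), severity = "moderate")
  kb <- new_kb(genes, freq, meds, rules)
  expect_equal(pip_score("drugx", kb)$pip_percent, 13L)
})

test_that("risk bands split at 0, 25, 50", {
  expect_equal(pip_band(c(0L, 1L, 25L, 26L, 50L, 51L, 100L)),
               c("none", "low", "low", "moderate", "moderate", "high", "high"))
  expect_error(pip_band(101L))
  expect_error(pip_band(-1L))
})

test_that("product-form PIP equals exhaustive joint-genotype enumeration", {
  for (seed in 1:40) {
    case <- random_small_kb(seed)
    expect_equal(pip_score(case$profile, case$kb)$pip_raw,
                 oracle_pip_enum(case$profile, case$kb),
                 tolerance = 1e-12)
  }
})

test_that("adding a medication never decreases the PIP without modifiers", {
  for (seed in 41:60) {
    case <- random_small_kb(seed)
    meds <- case$kb$medications$name
    base <- withr::with_seed(seed + 1000, sample(meds, max(1, length(meds) - 2)))
    p0 <- pip_score(base, case$kb)$pip_raw
    for (m in setdiff(meds, base)) {
      expect_gte(pip_score(c(base, m), case$kb)$pip_raw, p0 - 1e-12)
    }
  }
})

test_that("DDI counting requires the full drug set and bins by severity", {
  kb <- toy_kb()
  c1 <- count_ddis(c("alphadrug", "betadrug"), kb)
  expect_equal(unname(c1["severe"]), 1L)
  expect_equal(sum(c1), 1L)
  # 3-drug rule with only 2 of its drugs present does not fire
  c2 <- count_ddis(c("alphadrug", "deltadrug"), kb)
  expect_equal(sum(c2), 0L)
  c3 <- count_ddis(c("alphadrug", "deltadrug", "inhibdrug"), kb)
  expect_equal(unname(c3["moderate"]), 1L)
  # moderate-or-higher excludes the minor rule
  c4 <- count_ddis(c("betadrug", "gammadrug"), kb)
  expect_equal(unname(c4["minor"]), 1L)
  expect_equal(unname(ddi_moderate_plus(c4)), 0L)

  # brute-force subset enumeration over all rules on a 5-drug profile
  profile <- c("alphadrug", "betadrug", "gammadrug", "deltadrug", "inhibdrug")
  got <- count_ddis(profile, kb)
  expected <- stats::setNames(integer(5), pgx_severity_levels)
  for (i in seq_len(nrow(kb$ddi_rules))) {
    if (all(kb$ddi_rules$drugs[[i]] %in% profile)) {
      s <- kb$ddi_rules$severity[i]
      expected[s] <- expected[s] + 1L
    }
  }
  expect_equal(got, expected)
})

test_that("automated ranking orders by PIP, severity-major DDIs, then med count", {
  base <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    pip_percent = c(60L, 55L, 55L, 55L),
    ddi_contraindicated = 0L,
    ddi_severe = c(0L, 1L, 0L, 0L),
    ddi_moderate = c(0L, 0L, 3L, 3L),
    ddi_minor = 0L,
    ddi_minimal = 0L,
    total_med_count = c(2L, 2L, 2L, 9L)
  )
  r <- rank_automated(base, seed = 1)
  # A: highest PIP; B: one severe beats three moderates; D beats C on meds
  expect_equal(r$patient_id, c("A", "B", "D", "C"))

  tied <- tibble::tibble(
    patient_id = c("X", "Y"), pip_percent = 10L,
    ddi_contraindicated = 0L, ddi_severe = 0L, ddi_moderate = 0L,
    ddi_minor = 0L, ddi_minimal = 0L, total_med_count = 3L
  )
  expect_identical(rank_automated(tied, seed = 7)$patient_id,
                   rank_automated(tied, seed = 7)$patient_id)
  orders <- vapply(1:25, function(s) {
    paste(rank_automated(tied, seed = s)$patient_id, collapse = "")
  }, "")
  expect_setequal(unique(orders), c("XY", "YX"))
})

test_that("pip_scores drives the full automated pipeline over profiles", {
  kb <- toy_kb()
  profiles <- tibble::tibble(
    patient_id = c("p1", "p2"),
    medications = list(c("alphadrug", "betadrug", "plaindrug"), character(0)),
    n_unique_meds = c(3L, 0L)
  )
  res <- pip_scores(profiles, kb)
  expect_equal(res$pip_percent, c(14L, 0L))
  expect_equal(res$band, c("low", "none"))
  expect_equal(res$ddi_severe, c(1L, 0L))
  expect_equal(res$ddi_moderate_plus, c(1L, 0L))
  expect_equal(res$total_med_count, c(3L, 0L))
  expect_equal(res$p_GA, c(0.07, 0))
  expect_true(all(res$pip_raw >= 0 & res$pip_raw <= 1))
})
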