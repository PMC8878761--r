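# Shared fixture builders and independent oracles.
#
# The oracles deliberately avoid the package's own computational path:
# the PIP oracle enumerates every joint genotype assignment explicitly
# instead of using the per-gene product; the permutation oracle resamples
# group labels; DDI counting is cross-checked by plain subset enumeration
# in the tests themselves.

library(tibble)
library(dplyr)

# Exhaustive joint-genotype PIP oracle for modifier-free knowledge bases:
# walk every phenotype assignment across all genes, weight by the product
# of phenotype frequencies, and accumulate the mass of assignments where at
# least one (automated-method drug, gene) rule is actionable.
oracle_pip_enum <- function(medications, kb) {
  genes <- kb$genes$symbol
  stopifnot(nrow(kb$modifiers) == 0)
  automated <- kb$medications$name[kb$medications$in_automated]
  meds <- intersect(medications, automated)
  ladders <- kb$genes$phenotypes
  grid <- expand.grid(ladders, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- genes
  rules <- kb$drug_gene_rules
  total <- 0
  for (r in seq_len(nrow(grid))) {
    w <- 1
    hit <- FALSE
    for (j in seq_along(genes)) {
      g <- genes[j]
      ph <- grid[r, j]
      f <- kb$frequencies
      w <- w * f$frequency[f$gene == g & f$phenotype == ph]
      if (!hit) {
        sel <- which(rules$gene == g & rules$medication %in% meds)
        for (i in sel) {
          if (ph %in% rules$actionable_phenotypes[[i]]) {
            hit <- TRUE
            break
          }
        }
      }
    }
    if (hit) total <- total + w
  }
  total
}

# Exact permutation test for a difference in means (all label permutations
# when feasible, otherwise seeded resampling).
oracle_perm_p <- function(a, b, n_resample = 1e5, seed = 42) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  if (choose(length(pool), na) <= 5e4) {
    idx <- utils::combn(length(pool), na)
    d <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  } else {
    d <- withr::with_seed(seed, replicate(n_resample, {
      i <- sample(length(pool), na)
      mean(pool[i]) - mean(pool[-i])
    }))
  }
  mean(abs(d) >= obs - 1e-12)
}

# Random small knowledge base: <= 4 genes x <= 5 phenotypes, no modifiers,
# every medication in both methods, random frequencies and actionable sets.
random_small_kb <- function(seed) {
  withr::with_seed(seed, {
    ng <- sample(1:4, 1)
    ladders <- lapply(seq_len(ng), function(i) paste0("ph", seq_len(sample(2:5, 1))))
    genes <- tibble::tibble(
      symbol = paste0("G", seq_len(ng)),
      phenotypes = ladders,
      phenoconvertible = FALSE
    )
    frequencies <- dplyr::bind_rows(lapply(seq_len(ng), function(i) {
      w <- stats::rexp(length(ladders[[i]]))
      tibble::tibble(gene = genes$symbol[i], phenotype = ladders[[i]], frequency = w / sum(w))
    }))
    nm <- sample(2:6, 1)
    meds <- tibble::tibble(
      name = paste0("drug", seq_len(nm)),
      rxcui = paste0("R", seq_len(nm)),
      drug_class = "test",
      in_manual = TRUE,
      in_automated = TRUE
    )
    pairs <- expand.grid(medication = meds$name, gene = genes$symbol,
                         stringsAsFactors = FALSE)
    keep <- which(stats::runif(nrow(pairs)) < 0.5)
    if (length(keep) == 0) keep <- sample(nrow(pairs), 1)
    rules <- tibble::tibble(
      medication = pairs$medication[keep],
      gene = pairs$gene[keep],
      actionable_phenotypes = lapply(pairs$gene[keep], function(g) {
        ladder <- ladders[[match(g, genes$symbol)]]
        sample(ladder, sample(seq_along(ladder), 1))
      }),
      severity = "moderate"
    )
    profile <- c(sample(meds$name, sample(nm, 1)), "nonkb_drug")
    list(kb = new_kb(genes, frequencies, meds, rules), profile = profile)
  })
}

# Hand-built 5-phenotype single-gene KB for phenoconversion tests. Victim
# drug "victimdrug" has a configurable actionable set; "inhibitorstrong",
# "inhibitormod", "inducerstrong", "inducermod" are pure perpetrators.
phenoconv_kb <- function(actionable = "PM") {
  ladder <- c("UM", "RM", "NM", "IM", "PM")
  genes <- tibble::tibble(symbol = "GENE1", phenotypes = list(ladder),
                  phenoconvertible = TRUE)
  freq <- c(UM = 0.05, RM = 0.20, NM = 0.45, IM = 0.20, PM = 0.10)
  frequencies <- tibble::tibble(gene = "GENE1", phenotype = names(freq),
                        frequency = unname(freq))
  medn <- c("victimdrug", "inhibitorstrong", "inhibitormod",
            "inducerstrong", "inducermod")
  meds <- tibble::tibble(name = medn, rxcui = paste0("R", seq_along(medn)),
                 drug_class = "test", in_manual = TRUE, in_automated = TRUE)
  rules <- tibble::tibble(medication = "victimdrug", gene = "GENE1",
                  actionable_phenotypes = list(actionable),
                  severity = "moderate")
  modifiers <- tibble::tibble(
    medication = c("inhibitorstrong", "inhibitormod", "inducerstrong", "inducermod"),
    gene = "GENE1",
    kind = c("inhibitor", "inhibitor", "inducer", "inducer"),
    strength = c("strong", "moderate", "strong", "moderate")
  )
  new_kb(genes, frequencies, meds, rules, modifiers)
}

phenoconv_freq <- c(UM = 0.05, RM = 0.20, NM = 0.45, IM = 0.20, PM = 0.10)

# Small two-gene claims-world KB with manual/automated splits, one
# modifier, and DDI rules; used by the ingestion and method tests.
toy_kb <- function() {
  genes <- tibble::tibble(
    symbol = c("GA", "GB"),
    phenotypes = list(c("UM", "NM", "IM", "PM"), c("NM", "PM")),
    phenoconvertible = c(TRUE, FALSE)
  )
  frequencies <- dplyr::bind_rows(
    tibble::tibble(gene = "GA", phenotype = c("UM", "NM", "IM", "PM"),
           frequency = c(0.05, 0.70, 0.18, 0.07)),
    tibble::tibble(gene = "GB", phenotype = c("NM", "PM"), frequency = c(0.93, 0.07))
  )
  meds <- tibble::tribble(
    ~name,        ~rxcui, ~drug_class, ~in_manual, ~in_automated,
    "alphadrug",  "R1",   "classA",    TRUE,       TRUE,
    "betadrug",   "R2",   "classA",    TRUE,       TRUE,
    "gammadrug",  "R3",   "classB",    TRUE,       FALSE,   # manual only
    "deltadrug",  "R4",   "classB",    FALSE,      TRUE,    # automated only
    "inhibdrug",  "R5",   "classC",    FALSE,      TRUE
  )
  rules <- tibble::tibble(
    medication = c("alphadrug", "betadrug", "gammadrug", "deltadrug"),
    gene = c("GA", "GB", "GA", "GA"),
    actionable_phenotypes = list("PM", "PM", c("UM", "PM"), "PM"),
    severity = c("moderate", "severe", "moderate", "moderate")
  )
  modifiers <- tibble::tibble(medication = "inhibdrug", gene = "GA",
                      kind = "inhibitor", strength = "strong")
  ddi <- tibble::tibble(
    drugs = list(c("alphadrug", "betadrug"),
                 c("alphadrug", "deltadrug", "inhibdrug"),
                 c("betadrug", "gammadrug")),
    severity = c("severe", "moderate", "minor")
  )
  new_kb(genes, frequencies, meds, rules, modifiers, ddi)
}

# Deterministic toy claims world matched to toy_kb(): 6 patients covering
# each eligibility filter and the window boundary.
toy_claims <- function() {
  window <- as.Date(c("2018-10-01", "2019-01-01"))
  demographics <- tibble::tribble(
    ~patient_id, ~age_years, ~sex,
    "A", 40L, "female",   # eligible, 2 included meds + background
    "B", 30L, "male",     # eligible, 1 included med
    "C", 17L, "female",   # minor -> filter 1
    "D", 50L, "male",     # claims outside window -> filter 2
    "E", 45L, "female",   # only non-KB med in window -> filter 3
    "F", 35L, NA          # missing sex -> filter 4
  )
  mapping <- tibble::tribble(
    ~ndc, ~rxcui, ~ingredient,
    "00000000001", "R1", "alphadrug",
    "00000000002", "R2", "betadrug",
    "00000000003", "R3", "gammadrug",
    "00000000004", "R4", "deltadrug",
    "00000000005", "R9", "plaindrug"   # not in the KB
  )
  pharmacy <- tibble::tribble(
    ~patient_id, ~fill_date, ~ndc,
    "A", as.Date("2018-10-15"), "00000000001",
    "A", as.Date("2018-11-02"), "00000000001",  # repeat fill, same ingredient
    "A", as.Date("2018-12-20"), "00000000002",
    "A", as.Date("2018-11-11"), "00000000005",
    "B", as.Date("2018-10-01"), "00000000003",  # start date is in-window
    "B", as.Date("2019-01-01"), "00000000004",  # end date is out-of-window
    "C", as.Date("2018-11-05"), "00000000001",
    "D", as.Date("2017-01-15"), "00000000001",
    "E", as.Date("2018-11-20"), "00000000005",
    "F", as.Date("2018-10-30"), "00000000002",
    "A", as.Date("2018-11-03"), "99999999999",  # unmapped (non-drug item)
    "B", as.Date("2018-11-04"), "BADNDC"        # malformed
  )
  medical <- tibble::tribble(
    ~patient_id, ~visit_type, ~date, ~cost,
    "A", "ER", as.Date("2018-10-20"), 100,
    "A", "ER", as.Date("2018-12-01"), 200,
    "A", "inpatient", as.Date("2018-11-15"), 5000,
    "B", "ER", as.Date("2019-02-01"), 300    # outside window
  )
  list(window = window, demographics = demographics, mapping = mapping,
       pharmacy = pharmacy, medical = medical)
}
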