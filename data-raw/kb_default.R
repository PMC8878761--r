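# Builds inst/extdata/kb_default.json, the default drug-gene knowledge base.
#
# The gene/medication/method-membership structure transcribes the 8-gene
# clinical panel and its medication lists. Actionable-phenotype sets,
# phenotype prevalences, inhibitor/inducer modifiers and the drug-drug
# interaction table are plausible CPIC-style placeholders: they are
# configurable inputs, not authoritative clinical content.
#
# Run from the package root: Rscript data-raw/kb_default.R

suppressPackageStartupMessages(library(tibble))

genes <- list(
  list(symbol = "CYP2C19", phenotypes = c("UM", "RM", "NM", "IM", "PM"), phenoconvertible = TRUE),
  list(symbol = "CYP2D6",  phenotypes = c("UM", "NM", "IM", "PM"),       phenoconvertible = TRUE),
  list(symbol = "CYP2C9",  phenotypes = c("NM", "IM", "PM"),             phenoconvertible = TRUE),
  list(symbol = "CYP3A5",  phenotypes = c("NM", "IM", "PM"),             phenoconvertible = FALSE),
  list(symbol = "CYP4F2",  phenotypes = c("NF", "DF"),                   phenoconvertible = FALSE),
  list(symbol = "SLCO1B1", phenotypes = c("NF", "DF", "PF"),             phenoconvertible = FALSE),
  list(symbol = "TPMT",    phenotypes = c("NM", "IM", "PM"),             phenoconvertible = FALSE),
  list(symbol = "VKORC1",  phenotypes = c("NS", "IS"),                   phenoconvertible = FALSE)
)

# North-American-style prevalence placeholders; each gene sums to 1.
frequencies <- list(
  CYP2C19 = c(UM = 0.04, RM = 0.27, NM = 0.39, IM = 0.26, PM = 0.04),
  CYP2D6  = c(UM = 0.03, NM = 0.77, IM = 0.13, PM = 0.07),
  CYP2C9  = c(NM = 0.63, IM = 0.32, PM = 0.05),
  CYP3A5  = c(NM = 0.10, IM = 0.15, PM = 0.75),
  CYP4F2  = c(NF = 0.55, DF = 0.45),
  SLCO1B1 = c(NF = 0.73, DF = 0.25, PF = 0.02),
  TPMT    = c(NM = 0.900, IM = 0.095, PM = 0.005),
  VKORC1  = c(NS = 0.63, IS = 0.37)
)

# One row per drug-gene entry. membership: both / manual / automated method
# columns of the panel table.
rules <- tribble(
  ~gene, ~drug_class, ~medication, ~membership, ~actionable, ~severity,
  "CYP2C19", "antifungal",               "voriconazole",    "both",      "UM|RM|PM", "severe",
  "CYP2C19", "antiplatelet",             "cilostazol",      "automated", "PM",       "moderate",
  "CYP2C19", "antiplatelet",             "clopidogrel",     "both",      "IM|PM",    "severe",
  "CYP2C19", "benzodiazepine",           "clobazam",        "automated", "PM",       "moderate",
  "CYP2C19", "proton pump inhibitor",    "esomeprazole",    "both",      "UM|RM",    "moderate",
  "CYP2C19", "proton pump inhibitor",    "dexlansoprazole", "manual",    "UM|RM",    "moderate",
  "CYP2C19", "proton pump inhibitor",    "lansoprazole",    "both",      "UM|RM",    "moderate",
  "CYP2C19", "proton pump inhibitor",    "omeprazole",      "both",      "UM|RM",    "moderate",
  "CYP2C19", "proton pump inhibitor",    "pantoprazole",    "both",      "UM|RM",    "moderate",
  "CYP2C19", "proton pump inhibitor",    "rabeprazole",     "manual",    "UM|RM",    "moderate",
  "CYP2C19", "SSRI",                     "citalopram",      "both",      "UM|PM",    "moderate",
  "CYP2C19", "SSRI",                     "escitalopram",    "both",      "UM|PM",    "moderate",
  "CYP2C19", "SSRI",                     "sertraline",      "both",      "UM|PM",    "moderate",
  "CYP2C19", "tricyclic antidepressant", "amitriptyline",   "both",      "UM|PM",    "moderate",
  "CYP2C19", "tricyclic antidepressant", "clomipramine",    "both",      "UM|PM",    "moderate",
  "CYP2C19", "tricyclic antidepressant", "doxepin",         "both",      "UM|PM",    "moderate",
  "CYP2C19", "tricyclic antidepressant", "imipramine",      "both",      "UM|PM",    "moderate",
  "CYP2C19", "tricyclic antidepressant", "trimipramine",    "manual",    "UM|PM",    "moderate",
  "CYP2D6",  "5-HT3 antagonist",         "ondansetron",     "both",      "UM",       "moderate",
  "CYP2D6",  "alpha adrenergic blocker", "tamsulosin",      "automated", "PM",       "moderate",
  "CYP2D6",  "alpha agonist",            "clonidine",       "automated", "PM",       "moderate",
  "CYP2D6",  "antiarrhythmic",           "flecainide",      "automated", "UM|PM",    "severe",
  "CYP2D6",  "antiarrhythmic",           "mexiletine",      "automated", "PM",       "moderate",
  "CYP2D6",  "antiarrhythmic",           "risperidone",     "automated", "PM",       "moderate",
  "CYP2D6",  "anticholinergic",          "benztropine",     "automated", "PM",       "moderate",
  "CYP2D6",  "antiestrogen",             "tamoxifen",       "both",      "IM|PM",    "severe",
  "CYP2D6",  "antihistamine",            "meclizine",       "automated", "PM",       "moderate",
  "CYP2D6",  "antipsychotic",            "haloperidol",     "automated", "PM",       "moderate",
  "CYP2D6",  "antipsychotic",            "pimozide",        "automated", "UM|PM",    "contraindicated",
  "CYP2D6",  "antipsychotic",            "propafenone",     "automated", "PM",       "severe",
  "CYP2D6",  "anxiolytic",               "buspirone",       "automated", "PM",       "moderate",
  "CYP2D6",  "atypical antipsychotic",   "aripiprazole",    "both",      "PM",       "moderate",
  "CYP2D6",  "atypical antipsychotic",   "brexpiprazole",   "automated", "PM",       "moderate",
  "CYP2D6",  "beta blocker",             "metoprolol",      "automated", "UM|PM",    "moderate",
  "CYP2D6",  "beta blocker",             "nebivolol",       "automated", "PM",       "moderate",
  "CYP2D6",  "beta blocker",             "timolol",         "automated", "PM",       "moderate",
  "CYP2D6",  "CNS stimulant",            "lisdexamfetamine","automated", "PM",       "moderate",
  "CYP2D6",  "CNS stimulant",            "methamphetamine", "automated", "PM",       "moderate",
  "CYP2D6",  "pain",                     "codeine",         "both",      "UM|PM",    "contraindicated",
  "CYP2D6",  "pain",                     "hydrocodone",     "manual",    "UM|PM",    "moderate",
  "CYP2D6",  "pain",                     "oxycodone",       "manual",    "UM|PM",    "moderate",
  "CYP2D6",  "pain",                     "tramadol",        "both",      "UM|PM",    "severe",
  "CYP2D6",  "phenothiazine",            "promethazine",    "automated", "PM",       "moderate",
  "CYP2D6",  "serotonin modulator",      "vortioxetine",    "automated", "UM|PM",    "moderate",
  "CYP2D6",  "SNRI",                     "atomoxetine",     "both",      "UM|PM",    "moderate",
  "CYP2D6",  "SNRI",                     "venlafaxine",     "both",      "UM|PM",    "moderate",
  "CYP2D6",  "SSRI",                     "fluvoxamine",     "both",      "PM",       "moderate",
  "CYP2D6",  "SSRI",                     "paroxetine",      "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "amitriptyline",   "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "clomipramine",    "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "desipramine",     "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "doxepin",         "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "imipramine",      "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "nortriptyline",   "both",      "UM|PM",    "moderate",
  "CYP2D6",  "tricyclic antidepressant", "trimipramine",    "manual",    "UM|PM",    "moderate",
  "CYP2C9",  "angiotensin receptor blocker", "azilsartan",  "automated", "PM",       "moderate",
  "CYP2C9",  "anticoagulant",            "warfarin",        "manual",    "IM|PM",    "severe",
  "CYP2C9",  "antiepileptic",            "phenytoin",       "both",      "IM|PM",    "severe",
  "CYP2C9",  "nonsteroidal anti-inflammatory", "celecoxib", "automated", "IM|PM",    "moderate",
  "CYP2C9",  "nonsteroidal anti-inflammatory", "mefenamic acid", "automated", "IM|PM", "moderate",
  "CYP2C9",  "sulfonylurea",             "glimepiride",     "automated", "PM",       "moderate",
  "CYP3A5",  "immunosuppressant",        "tacrolimus",      "both",      "NM|IM",    "severe",
  "CYP4F2",  "anticoagulant",            "warfarin",        "manual",    "DF",       "moderate",
  "SLCO1B1", "statin",                   "simvastatin",     "both",      "DF|PF",    "moderate",
  "TPMT",    "immunosuppressant",        "azathioprine",    "both",      "IM|PM",    "severe",
  "TPMT",    "purine antagonist",        "mercaptopurine",  "both",      "IM|PM",    "severe",
  "TPMT",    "purine analog",            "thioguanine",     "both",      "IM|PM",    "severe",
  "VKORC1",  "anticoagulant",            "warfarin",        "manual",    "IS",       "moderate"
)

stopifnot(
  sum(rules$membership == "both") == 34,
  sum(rules$membership == "manual") == 9,
  sum(rules$membership == "automated") == 25
)

meds <- unique(rules$medication)
med_tbl <- lapply(seq_along(meds), function(i) {
  m <- meds[i]
  rows <- rules[rules$medication == m, ]
  list(
    name = m,
    rxcui = sprintf("SYN%05d", i),  # synthetic ingredient-level identifiers
    drug_class = rows$drug_class[1],
    in_manual = any(rows$membership %in% c("both", "manual")),
    in_automated = any(rows$membership %in% c("both", "automated"))
  )
})

rule_list <- lapply(seq_len(nrow(rules)), function(i) {
  list(
    medication = rules$medication[i],
    gene = rules$gene[i],
    actionable_phenotypes = strsplit(rules$actionable[i], "|", fixed = TRUE)[[1]],
    severity = rules$severity[i]
  )
})

modifiers <- list(
  list(medication = "paroxetine",   gene = "CYP2D6",  kind = "inhibitor", strength = "strong"),
  list(medication = "fluvoxamine",  gene = "CYP2C19", kind = "inhibitor", strength = "strong"),
  list(medication = "omeprazole",   gene = "CYP2C19", kind = "inhibitor", strength = "moderate"),
  list(medication = "esomeprazole", gene = "CYP2C19", kind = "inhibitor", strength = "moderate"),
  list(medication = "haloperidol",  gene = "CYP2D6",  kind = "inhibitor", strength = "moderate"),
  list(medication = "phenytoin",    gene = "CYP2C19", kind = "inducer",   strength = "strong")
)

# Curated drug-drug interaction placeholders (gene-independent rules only).
ddi_rules <- list(
  list(drugs = c("tramadol", "sertraline"),                 severity = "severe"),
  list(drugs = c("tramadol", "paroxetine"),                 severity = "severe"),
  list(drugs = c("codeine", "tramadol"),                    severity = "moderate"),
  list(drugs = c("fluvoxamine", "amitriptyline"),           severity = "moderate"),
  list(drugs = c("citalopram", "ondansetron"),              severity = "moderate"),
  list(drugs = c("haloperidol", "ondansetron"),             severity = "severe"),
  list(drugs = c("metoprolol", "clonidine"),                severity = "severe"),
  list(drugs = c("warfarin", "phenytoin"),                  severity = "severe"),
  list(drugs = c("simvastatin", "tacrolimus"),              severity = "moderate"),
  list(drugs = c("codeine", "promethazine"),                severity = "moderate"),
  list(drugs = c("esomeprazole", "escitalopram"),           severity = "minor"),
  list(drugs = c("pantoprazole", "sertraline"),             severity = "minimal"),
  list(drugs = c("tramadol", "sertraline", "ondansetron"),  severity = "contraindicated")
)

kb <- list(
  genes = genes,
  frequencies = lapply(names(frequencies), function(g) {
    f <- frequencies[[g]]
    list(gene = g, phenotypes = names(f), frequency = unname(f))
  }),
  medications = med_tbl,
  drug_gene_rules = rule_list,
  modifiers = modifiers,
  ddi_rules = ddi_rules
)

json <- jsonlite::toJSON(kb, auto_unbox = TRUE, pretty = TRUE, digits = NA)
writeLines(json, file.path("inst", "extdata", "kb_default.json"))
cat("wrote inst/extdata/kb_default.json:", nrow(rules), "drug-gene rules,",
    length(meds), "medications\n")
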