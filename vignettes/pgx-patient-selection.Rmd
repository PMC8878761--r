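---
title: "Selecting patients for pharmacogenomic testing from pharmacy claims"
author: "pgxselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting patients for pharmacogenomic testing from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxselect)
```

## The problem

Preemptive pharmacogenomic (PGx) testing can flag patients whose current
medications are likely to behave atypically given their genotype, but
testing budgets are finite: a health plan that can fund a few hundred tests
must decide *which* members to offer them to. `pgxselect` implements and
compares two selection strategies that operate on ordinary pharmacy and
medical claims:

* the **manual method** — rank patients by how many medications from a
  locally curated PGx list appear on their recent claims, break ties by
  overall medication count, then randomly;
* the **automated method** — rank by the **pharmacogenetic interaction
  probability (PIP)**, the probability that genotyping the patient would
  reveal at least one clinically actionable drug–gene or drug–drug–gene
  interaction given their current medications.

Both operate over the same 8-gene panel (CYP2C19, CYP2D6, CYP2C9, CYP3A5,
CYP4F2, SLCO1B1, TPMT, VKORC1) but use different medication lists: a shared
core (34 drug–gene entries), a manual-only set chosen on local evidence and
utilization (9 entries, including warfarin across three genes), and an
automated-only set chosen on CPIC level A/B evidence or actionable FDA
labeling (25 entries, including metoprolol).

## The PIP model

For a patient with medication set $D$ and a gene $g$ with phenotype ladder
$\Phi_g$ (ordered from ultrarapid to poor activity) and population
phenotype prevalences $f_g(\phi)$, the per-gene actionable probability is

$$
p_g \;=\; \sum_{\phi \in \Phi_g} f_g(\phi)\,
  \mathbf{1}\!\left[\exists\, d \in D:\;
  \mathrm{eff}_g\!\left(\phi,\, D \setminus \{d\}\right) \in A_{d,g}\right],
$$

where $A_{d,g}$ is the actionable-phenotype set of the drug–gene rule for
$(d, g)$ (only rules at moderate or higher interaction severity are in the
knowledge base, the lowest level with actionable recommendations), and
$\mathrm{eff}_g$ applies **phenoconversion**: a co-medicated inhibitor or
inducer shifts the genotype-predicted phenotype along the activity ladder.
Genes are then combined under independence:

$$
\mathrm{PIP} = \mathrm{round}\!\left(100 \times \Big(1 - \prod_g (1 - p_g)\Big)\right),
$$

rounded half away from zero to a whole-number percentage. The number needed
to test is $\mathrm{NNT} = 100/\mathrm{PIP}$ (continuous, undefined at
PIP 0). Patients are banded **none** (0), **low** (1–25), **moderate**
(26–50) and **high** (>50): the low/moderate edge splits patients into
needing more or fewer than 1 in 4 tested to find something actionable, and
in the high band an actionable finding is more likely than not.

The commercial algorithm this reconstructs is proprietary; the product form
above is the unique probability of "at least one actionable interaction"
under cross-gene independence and is declared, not reverse-engineered. The
test suite verifies it against exhaustive joint-genotype enumeration (all
phenotype assignments weighted by prevalence products) to 1e-12 on hundreds
of randomized small knowledge bases.

### Phenoconversion rules

Only phenoconvertible genes (the CYP enzymes in the default fixture) shift.
The perpetrator set for a victim drug is the patient's other medications;
a drug never phenoconverts itself.

| Modifier | Effect on the genotypic phenotype |
|---|---|
| strong inhibitor | normal, and everything between normal and poor, becomes poor (UM/RM untouched) |
| moderate inhibitor | one ladder step toward poor |
| strong inducer | top of the ladder (ultrarapid end) |
| moderate inducer | one ladder step toward ultrarapid |

The strongest modifier of each kind wins; when both an inhibitor and an
inducer are present they cancel (no net shift) — the simplest symmetric
rule. On a ladder without a label for the normal phenotype a strong
inhibitor collapses every phenotype to the bottom. These rules are exact
contracts, tested by hand-tabulated enumeration on a five-step ladder.

Method membership matters asymmetrically: manual-only medications (e.g.
warfarin) contribute **no** candidate interactions to the PIP — a
warfarin-only profile scores 0 — but any medication can act as a
phenoconversion perpetrator, since enzyme inhibition is pharmacology, not
list membership.

### Tie-breaking and selection

The automated ranking orders by PIP, then by drug–drug interaction counts
compared most-severe-first (contraindicated, severe, moderate, minor,
minimal), then by overall unique medication count, then by a seeded random
key. DDI rules fire only when their entire drug set is present and never
include gene-related interactions (those are unknown until testing).

Both methods select a cohort at the **natural cut**: among the distinct
score values, the threshold whose "score ≥ t" cohort size is closest to the
testing-budget target. When two thresholds are equidistant the smaller
cohort wins, conserving the budget (selecting 218 patients at "3 or more
medications" over 1128 at "2 or more" against a 250-patient goal is the
canonical example).

## Claims ingestion

Analysis windows are half-open date intervals `[start, end)` — unambiguous
at the boundary, tested there. NDCs (11-digit package-level codes) map to
ingredient names through a local mapping table standing in for the RxNorm
API; claims that do not map (non-drug items such as lancets and test
strips) are dropped and logged. "Unique medications" are unique ingredient
names, matching the ingredient-level panel.

Eligibility is filtered sequentially with per-step logging: adults (18+),
at least one in-window fill, at least one in-window fill for a medication
on the union of the two method lists, and complete demographics. The
union-list filter can be disabled (`require_included = FALSE`) while still
being logged, because locally curated "predefined lists" used for
eligibility screening are typically broader than a strict panel union — in
the study population this package emulates, only 73.3% of *eligible*
patients had a claim for an included medication, so usage marginals are
computed over the broader cohort. Patients with missing age cannot be
assessed at the adult filter and fall out at the completeness step,
keeping the filter counts monotone.

## Cohort comparison

`compare_cohorts()` reports overlap (count, fraction of the smaller cohort,
Jaccard) and a fixed ten-row panel: mean unique medication count, mean
moderate-or-higher DDI count and the share of patients with at least one,
mean PIP, ER and inpatient utilization (share with ≥1 visit, mean cost
over *all* cohort members including zero-cost patients), age, and sex
split. Continuous rows use Welch's unequal-variance t-test (a robust
default for unequal cohort sizes); proportion rows use the pooled
two-proportion z-test without continuity correction, with the degenerate
all-zero/all-one case defined as $z = 0, p = 1$. All tests are two-sided
and unadjusted for multiplicity. Cross-checks: an exact/resampled
permutation oracle for the t-test and Fisher's exact test for proportions.
Per-patient-with-visit cost summaries can be derived from the profile
table; the all-member mean is the primary definition.

## The synthetic generator

Real insurer claims cannot be redistributed, so `simulate_claims()`
generates a population with the statistical features the pipeline assumes,
calibrated once to published margins and never tuned afterwards:

* **age** 35 ± 17.4 years, normal truncated at 18 (exact inverse-CDF
  truncation, floored to integer years); **sex** 62% female;
* **included-medication burden**: exactly one for 57% of patients, two for
  13.1%, three for 2.5%, four or more for 0.7%; the 26.7% mass at zero is
  back-derived so that 73.3% have at least one;
* **popularity skew**: included medications are sampled without
  replacement with metoprolol, ondansetron and sertraline weighted
  highest and a long power-law tail;
* **background burden**: a Poisson number (mean 3.5) of common non-panel
  ingredients, at least one medication per patient overall;
* **fills**: 1–3 uniformly dated fills per medication in the window
  (Q4 2018 by default); ~1.5% extra claims carry unmappable NDCs to
  exercise the ingestion drop path;
* **utilization**: independent Bernoulli ER (8%) and inpatient (4%) events
  with log-normal costs (medians $400 and $3,500). These are illustrative
  order-of-magnitude choices; the source population's utilization is only
  published for *selected* cohorts, not the eligible population.

Everything is a pure function of the configuration and seed (tested by
byte-identical regeneration). What the generator does **not** model —
refill adherence dynamics, diagnosis codes, correlation between medication
burden and utilization (a correlation knob was considered and left out;
draws are independent), seasonal effects — bounds what passing tests show:
they demonstrate the pipeline's correctness and calibration recovery, not
that the two methods would select the same cohorts on real claims. The
published headline cohort contrasts (218 vs 286 selected, 41 overlapping,
mean PIP 62% vs 29%) derive from a specific proprietary population and are
intentionally not targets.

## Problem sizes and numerical choices

Calibration recovery is checked at n = 20,000 simulated patients, where
the binomial standard error of the 57% margin is about 0.35 percentage
points; the end-to-end pipeline test runs at n = 5,000 with a 250-patient
target, comfortably exercising both selection paths. PIP equivalence
against enumeration uses knowledge bases of up to 4 genes × 5 phenotypes,
where exhaustive enumeration (≤625 joint genotypes) is exact. Frequencies
must sum to 1 within 1e-9 at load; PIP comparisons are asserted at 1e-12;
rounding to whole percents is half-away-from-zero via `floor(x + 0.5)` on
the non-negative scale.

## Worked example

```{r example}
kb <- load_kb()
kb

cfg <- default_sim_config(n_patients = 5000, seed = 314)
sim <- simulate_claims(cfg)
mapped <- map_ndc(sim$pharmacy, sim$mapping)$mapped
elig <- filter_eligible(sim$demographics, mapped, cfg$window, kb)
elig$log

profiles <- build_profiles(elig$eligible_ids, sim$demographics, mapped,
                           sim$medical, cfg$window)
manual <- rank_manual(manual_scores(profiles, kb), seed = 314)
auto <- rank_automated(pip_scores(profiles, kb), seed = 314)

sel_m <- select_natural_cut(manual, target = 250,
                            score_col = "manual_med_count", method = "manual")
sel_a <- select_natural_cut(auto, target = 250,
                            score_col = "pip_percent", method = "automated")
sel_m
sel_a

compare_cohorts(cohort_table(profiles, auto, sel_m$selected_ids),
                cohort_table(profiles, auto, sel_a$selected_ids),
                "manual", "automated")
```

## Known limitations

* The default knowledge base's actionable-phenotype sets, prevalences,
  modifiers and DDI table are plausible CPIC-style placeholders, fully
  configurable but not clinically authoritative; algorithms are entirely
  KB-driven, so a site can substitute curated content without code
  changes.
* Cross-gene independence is an assumption of the product form; real
  linkage between loci is not modelled.
* The generator draws utilization independently of medication burden, so
  cost contrasts between selected cohorts are attenuated relative to real
  populations.
* Severity is recorded per drug–gene rule but the PIP weighs all
  actionable interactions equally once they clear the moderate floor.
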