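---
title: "The repurposing funnel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The repurposing funnel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`drugfunnel` implements a prioritization scheme for genome-based drug
repurposing: it narrows a full drug catalog to the set of target-action
pairs for which (i) an approved, selective small molecule exists and (ii)
the target gene carries well-genotyped common variation on an exome array,
so that a phenome-wide association scan of those variants is adequately
powered. This vignette explains the procedure, its assumptions, the
parameters that matter, what the synthetic data do and do not emulate, and
the design choices made where the design was genuinely open.

## The attrition model

The pipeline treats repurposability as a conjunction of pragmatic
predicates evaluated per drug, in a fixed order chosen so that each stage's
survivor count is interpretable on its own:

1. **Drug type.** Only small molecules proceed. The assumption is economic,
   not biological: trial-scale quantities of biologics are orders of
   magnitude more expensive and frequently proprietary.
2. **Approval status.** A drug must carry an allowlisted status label and
   no veto label. The veto dominates: a drug labelled both `approved` and
   `withdrawn` is excluded, because a withdrawal supersedes the historical
   approval for repurposing purposes.
3. **Mechanism selectivity.** Exactly one target with known action. The
   filter deliberately keys on the *known-action* count rather than the
   total target count: a drug whose extra targets have unknown action is
   still analyzable at its one characterized gene. The
   `one_target_total_rate()` statistic quantifies how close the two
   definitions are on a given catalog.
4. **Exclusions.** Three reason-coded removals: nonhuman known-action
   target (human genomic data cannot speak to a bacterial gyrase),
   blocklisted name (severe-toxicity and DNA-damaging agents; supplied as
   configuration because toxicity is not systematically mineable), and
   missing required fields (name, action, gene symbol, status).

Survivors are consolidated into **target-action pairs** — the key is
`(uppercased gene symbol, lowercased action)`. Distinct action words are
never merged: `inhibitor` and `antagonist` stay separate pairs because no
reliable synonym map exists, and over-merging would silently conflate
opposite pharmacology. The consolidation is a partition; tests assert that
the union of member sets equals the input and that pairs are disjoint.

## Variant eligibility

A variant survives QC iff all of:

* rsID present (a `NULL` rsID cannot be verified against dbSNP);
* genotyping missingness ≤ `missingness_max` (default 0.05, a conventional
  call-rate bound; higher missingness risks confounding phenotype
  associations when missingness is nonrandom);
* minor allele frequency ≥ `maf_min` in the configured population
  (default 0.001 = 0.1%; below that a variant is "rare" rather than
  "minor" and PheWAS is underpowered).

Both numeric screens are **strict**: a variant at exactly the threshold is
retained, since the removal conditions are `missingness > 0.05` and
`MAF < 0.001`. A variant failing several screens is counted once in the QC
report, under the first failing rule in the order rsID → missingness →
MAF; the order is a reporting convention (the eligible set is order-
independent) fixed for deterministic reports. MAF is stored per population
(`MAF_<population>` columns) so the cohort choice is a configuration key,
defaulting to `white`, the dominant demographic of the exome-chip cohorts
this screen was calibrated on; a record lacking the configured population's
MAF is removed with its own reason code. MAF is taken as given on the
minor allele (bounded by 0.5 at load); genotype-level recomputation is out
of scope.

## Integration and coverage

The join is purely gene-level: every eligible variant whose gene symbol
equals the pair's gene symbol counts toward that pair, so two pairs sharing
a gene see identical variant lists. "Unique targets covered" counts
distinct normalized gene symbols among covered pairs — gene symbol is the
join key, so it is the only consistent definition of "target" at this
stage. Uncovered pairs are retained in the mapping (flagged, not dropped)
so reports can enumerate them.

The coverage percentage is rounded **half-up** to an integer (so 227/237 =
95.78…% reports as 96%), and the exact fraction is carried alongside.
`one_target_total_rate()` uses the same half-up rule at two decimals.
Half-up is used instead of R's round-half-even because these are reporting
statistics, not further inputs.

The shortlist ranks covered pairs by descending eligible-variant count
(more variants, more association opportunities), tie-broken by gene symbol
then action for determinism, and joins each member drug's earliest
marketing date and countries (case-insensitive name match after trimming;
the earliest date is the minimum over a drug's dated products per country,
a proxy for intellectual-property headroom). Dates are ISO-8601 only;
unparseable dates are treated as absent with a warning rather than guessed.

## The synthetic data

Real DrugBank exports are license-gated and biobank genotype summaries are
private, so the package generates both inputs. The generators are **pure
functions of (composition, seed)** — byte-identical output for identical
arguments — and the composition is *structural*: every record is
constructed to pass all stages before its designated failure point and to
fail exactly there. Consequently the per-stage survivor counts are known
by construction and hold for every seed; the seed only varies record-level
noise (record order, marketing dates, frequencies, alleles, mutation
labels).

The default catalog composition realizes a full-scale study: 10,505 drugs
of which 1,213 are biologics, 7,073 small molecules fail approval status
(split investigational / experimental / approved-but-withdrawn), 1,396
approved drugs have zero or two known-action targets, 202 single-mechanism
drugs are excluded (150 nonhuman-target, 30 blocklisted, 22
missing-field — the split within the 202 is a fixture convention, chosen
once), and 621 survive, 518 of them with a single total target. The
survivors are laid out over 237 pairs on 157 genes: 80 genes carry two
actions and 67 one action (227 pairs on 147 genes intended for variant
coverage) plus 10 uncovered single-action pairs — the minimal layout
consistent with 237/227/147. Drugs are allocated one per pair and then
round-robin, so pairs 1–147 hold three members and 148–237 two.

The default variant composition has 239,796 variants, 58,945 eligible, and
the 180,851 removals split 20,000 null-rsID / 60,851 high-missingness /
100,000 low-MAF (again a documented convention). Every covered gene
receives at least one eligible variant, with the remainder spread over 600
filler genes by seeded weights (largest-remainder rounding keeps totals
exact); uncovered genes appear only in ineligible strata.

What the generator does **not** emulate: realistic MAF spectra or linkage
structure, genotypes or phenotypes, real gene symbols, DrugBank's full
schema (>200 fields), or correlated missingness. Passing the calibrated
end-to-end tests therefore demonstrates that the filter predicates,
consolidation, QC screens and join are correct against planted ground
truth — not that the package would reproduce any particular real catalog's
counts, which depend on the catalog version and the blocklist used.

## Degenerate inputs and numerical conventions

* An empty catalog flows through the funnel as an all-zero report; an
  empty drug set makes `one_target_total_rate()` an error (undefined), as
  does coverage of an empty pair mapping.
* `"NULL"` and empty-string field values are normalized to absent at parse
  time, so downstream null-removal rules act on one representation.
* Status labels are lowercased and comma-split (a single `<group>` may
  carry `approved, investigational`).
* Record-level defects (a drug without a name, a variant row with MAF
  above 0.5 or identical alleles) are quarantined in reject tables with
  reasons; they never abort a run.
* The status allowlist is exact-match against configured labels (default
  `approved`): substring matching would wrongly admit `vet-approved`,
  which does not certify human approval.
* Enzyme and transporter listings are carried per target and de-duplicated.

## Problem sizes and runtime

The test suite exercises the full-scale default composition once (a shared
cached run: ~10,500-drug XML parse plus ~240,000-row QC in roughly ten
seconds) and otherwise uses small randomized fixtures (20–1,000 records)
checked against independent brute-force oracles: a per-record predicate
scan for the funnel, a row-wise predicate for QC, a quadratic nested-loop
join for coverage, and a raw-XML scan for marketing dates.

## Known limitations

* Association testing itself is out of scope: the pipeline stops at a
  PheWAS-ready shortlist.
* Toxicity handling is a name blocklist, not a systematic toxicology
  screen; there is no mineable absolute toxicity measure to automate it.
* Drugs with multiple known-action targets are excluded outright rather
  than analyzed per target.
* The gene-symbol join assumes both sides use the same symbol vocabulary;
  no alias resolution (e.g. HGNC history) is attempted.
* Approval-status semantics are label-based; the package does not consult
  regulatory registries.
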