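# drugfunnel

Genome-based drug repurposing asks a pragmatic question: of all drugs ever
catalogued, which ones could realistically be redeployed against a new
indication on the strength of human genetic evidence at their target?
`drugfunnel` answers it by intersecting two resources a repurposing program
typically has in hand — a DrugBank-style drug catalog and an exome-array
variant annotation table from a genotyped biobank — and reducing them to the
**repurposable drugged genome**: the set of target-action pairs backed by an
approved, selective small molecule *and* by well-genotyped common variants
on the target gene, ready for phenome-wide association (PheWAS) follow-up.

The package is aimed at translational informaticians and repurposing teams
who need a reproducible, auditable attrition pipeline rather than a manual
spreadsheet triage.

## The method

**Pharmacodynamic attrition.** Each drug card carries a name, a type
(small molecule / biotech), approval-status labels, products and targets.
Four staged filters are applied in a fixed order, each recording its
exclusions:

1. **Type** — biologics are removed (cost and access make them impractical
   trial candidates).
2. **Approval status** — only drugs with an allowlisted status (default
   `approved`) and no veto label (`withdrawn`, `illicit`) survive.
3. **Mechanism selectivity** — only drugs with exactly one target of known
   mechanism of action (`known-action = yes`) survive; extra targets of
   *unknown* action are tolerated.
4. **Exclusions** — drugs whose known-action target is nonhuman (antibiotics,
   antivirals, …), drugs on a configurable toxicity/DNA-damaging blocklist,
   and drugs with missing required fields are removed, each with a reason
   code.

**Consolidation.** Survivors are grouped into *target-action pairs*
(gene symbol, action), the unit at which same-class drugs (e.g. all ACE
inhibitors) are redundant. Every drug belongs to exactly one pair.

**Variant QC.** Exome-chip variants are screened with strict rules: a
variant is removed iff its rsID is absent (unverifiable against dbSNP), its
genotyping missingness exceeds 0.05, or its minor allele frequency in the
configured population falls below 0.001 — the conventional PheWAS power
threshold. Boundary values are retained.

**Integration.** Pairs are joined to eligible variants by gene symbol.
The coverage summary reports how many pairs have at least one eligible
variant, how many distinct target genes that represents, and the coverage
percentage; covered pairs are ranked by eligible-variant count into a
shortlist annotated with each member drug's earliest marketing date and
countries.

Because real DrugBank exports are license-gated and biobank genotype
summaries are private, the package ships deterministic synthetic-data
generators whose default composition realizes a full-scale study: 10,505
drugs and 239,796 variants with a planted, known attrition structure.

## Worked example

```r
library(drugfunnel)

xml <- tempfile(fileext = ".xml"); tsv <- tempfile(fileext = ".tsv")
comp <- catalog_composition()                    # default full-scale composition
generate_drug_catalog(comp, seed = 1, path = xml)
generate_variant_table(variant_composition(), seed = 1, path = tsv)

catalog <- parse_drugbank_xml(xml)
#> <drug_catalog> 10505 drugs | 11167 targets | 13700 products

cfg <- attrition_config(excluded_drug_names = composition_blocklist(comp))
funnel <- run_funnel(catalog, cfg)
#> <funnel_report>
#>               stage  n_in n_out n_excluded
#>                type 10505  9292       1213
#>              status  9292  2219       7073
#>  known_action_count  2219   823       1396
#>          exclusions   823   621        202
#> 237 target-action pairs from 621 drugs

one_target_total_rate(funnel$cards)
#> [1] 83.41

qc <- qc_filter(load_variant_table(tsv))
#> <qc_result> 239796 variants in, 58945 eligible

coverage_summary(map_pairs_to_variants(funnel$pairs, qc))
#> <coverage_summary> 227/237 pairs covered (96%), 147 unique targets
```

Reading the numbers: of 10,505 catalogued drugs, 9,292 are small molecules,
2,219 of those are cleanly approved, 823 act through a single known
mechanism, and 621 survive the human-target/toxicity/completeness
exclusions, collapsing into 237 target-action pairs. 83.41% of the 621 have
only one total target, so the selectivity filter nearly coincides with
"one total target". On the genomic side, 58,945 of 239,796 exome-chip
variants pass QC; 227 of the 237 pairs (96%, half-up from 227/237) have at
least one eligible variant on their target gene, spanning 147 unique
targets — the repurposable drugged genome of this catalog, ranked in the
shortlist for PheWAS follow-up.

## Command line

```sh
Rscript inst/cli/drugfunnel.R simulate --config config.yaml   # write fixtures
Rscript inst/cli/drugfunnel.R run      --config config.yaml   # full pipeline
```

Subcommands `parse`, `funnel`, `qc`, `integrate` run each stage in
isolation. The YAML config names the catalog XML, variant TSV, output
directory, seed, and optional `attrition:` / `qc:` blocks. Reports land in
the output directory as TSV/JSON (`funnel.tsv`, `exclusions.tsv`,
`qc_report.tsv`, `coverage.json`, `shortlist.tsv`, …).

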