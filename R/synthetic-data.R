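# Deterministic generators for DrugBank-style catalogs and exome-array
# variant annotation tables. The default compositions plant a known attrition
# structure (per-stage survivor counts, pair layout, variant eligibility
# split) so the whole pipeline can be verified end-to-end against ground
# truth. Record-level noise (names, dates, frequencies) is seeded; the
# planted counts are structural and hold for every seed.

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Composition of a synthetic drug catalog
#'
#' Defines the stratum sizes of a synthetic DrugBank-style catalog: how many
#' records fail at each attrition stage (and for which reason), how many
#' survive, and how the survivors are laid out over target-action pairs.
#' Records in each stratum are constructed to pass every stage before their
#' designated one and fail exactly there, so the funnel's stage counts are
#' known by construction.
#'
#' The defaults reproduce a realistic full-scale catalog: 10,505 drugs
#' funnelling to 9,292 small molecules, 2,219 approved, 823 with a single
#' known-action target and 621 after exclusions (150 nonhuman-target, 30
#' blocklisted, 22 missing-field), grouped into 237 target-action pairs over
#' 157 genes — 80 genes carrying two actions and 67 one action (227 pairs on
#' 147 genes intended for variant coverage) plus 10 uncovered single-action
#' pairs. 518 of the 621 survivors carry exactly one total target.
#'
#' @param n_biotech biologics (fail the type stage).
#' @param n_not_approved small molecules failing the approval stage.
#' @param n_wrong_known_action approved drugs with a known-action target
#'   count other than one.
#' @param n_excluded_nonhuman,n_excluded_blocklist,n_excluded_missing_field
#'   single-known-action drugs removed at the exclusions stage, by reason.
#' @param n_final drugs surviving all stages.
#' @param n_final_single_target how many of the survivors have exactly one
#'   total target (the rest get extra unknown-action targets).
#' @param n_two_action_genes,n_one_action_genes covered-gene pair layout.
#' @param n_uncovered_pairs pairs on genes that will receive no eligible
#'   variants.
#' @return object of class `catalog_composition`.
#' @export
catalog_composition <- function(n_biotech = 1213,
                                n_not_approved = 7073,
                                n_wrong_known_action = 1396,
                                n_excluded_nonhuman = 150,
                                n_excluded_blocklist = 30,
                                n_excluded_missing_field = 22,
                                n_final = 621,
                                n_final_single_target = 518,
                                n_two_action_genes = 80,
                                n_one_action_genes = 67,
                                n_uncovered_pairs = 10) {
  comp <- structure(
    list(
      n_biotech = as.integer(n_biotech),
      n_not_approved = as.integer(n_not_approved),
      n_wrong_known_action = as.integer(n_wrong_known_action),
      n_excluded_nonhuman = as.integer(n_excluded_nonhuman),
      n_excluded_blocklist = as.integer(n_excluded_blocklist),
      n_excluded_missing_field = as.integer(n_excluded_missing_field),
      n_final = as.integer(n_final),
      n_final_single_target = as.integer(n_final_single_target),
      n_two_action_genes = as.integer(n_two_action_genes),
      n_one_action_genes = as.integer(n_one_action_genes),
      n_uncovered_pairs = as.integer(n_uncovered_pairs)
    ),
    class = "catalog_composition"
  )
  validate_catalog_composition(comp)
  comp
}

validate_catalog_composition <- function(comp) {
  counts <- unlist(comp[c("n_biotech", "n_not_approved",
                          "n_wrong_known_action", "n_excluded_nonhuman",
                          "n_excluded_blocklist", "n_excluded_missing_field",
                          "n_final")])
  if (any(counts < 0)) {
    stop("catalog composition counts must be non-negative", call. = FALSE)
  }
  if (comp$n_final_single_target > comp$n_final ||
      comp$n_final_single_target < 0) {
    stop("n_final_single_target must lie in [0, n_final]", call. = FALSE)
  }
  n_pairs <- n_pairs_total(comp)
  if (comp$n_final > 0 && n_pairs == 0) {
    stop("pair layout is empty but n_final > 0", call. = FALSE)
  }
  if (comp$n_final < n_pairs) {
    stop("n_final (", comp$n_final, ") must be at least the number of ",
         "pairs (", n_pairs, ") so every pair has a member drug",
         call. = FALSE)
  }
  invisible(comp)
}

n_pairs_total <- function(comp) {
  2L * comp$n_two_action_genes + comp$n_one_action_genes +
    comp$n_uncovered_pairs
}

catalog_total <- function(comp) {
  comp$n_biotech + comp$n_not_approved + comp$n_wrong_known_action +
    comp$n_excluded_nonhuman + comp$n_excluded_blocklist +
    comp$n_excluded_missing_field + comp$n_final
}

#' @export
print.catalog_composition <- function(x, ...) {
  cat("<catalog_composition>", catalog_total(x), "drugs ->", x$n_final,
      "final over", n_pairs_total(x), "pairs\n")
  invisible(x)
}

#' Gene vocabularies of a catalog composition
#'
#' Covered genes (`TGTnnn`) are those laid out to receive eligible variants
#' in the paired variant composition; uncovered genes (`UNCnnn`) are planted
#' to receive none.
#'
#' @param comp a [catalog_composition()].
#' @return character vector of gene symbols.
#' @export
covered_gene_symbols <- function(comp) {
  n <- comp$n_two_action_genes + comp$n_one_action_genes
  if (n == 0) return(character(0))
  sprintf("TGT%03d", seq_len(n))
}

#' @rdname covered_gene_symbols
#' @export
uncovered_gene_symbols <- function(comp) {
  if (comp$n_uncovered_pairs == 0) return(character(0))
  sprintf("UNC%03d", seq_len(comp$n_uncovered_pairs))
}

#' Toxicity blocklist planted by a catalog composition
#'
#' The synthetic catalog plants `n_excluded_blocklist` drugs whose names are
#' on this list; pass it to [attrition_config()] as `excluded_drug_names`
#' when running the funnel on the generated catalog.
#'
#' @param comp a [catalog_composition()].
#' @return character vector of blocklisted drug names.
#' @export
composition_blocklist <- function(comp) {
  if (comp$n_excluded_blocklist == 0) return(character(0))
  sprintf("Cytotoxin-%03d", seq_len(comp$n_excluded_blocklist))
}

# The fixed pair layout implied by a composition: covered genes first (two
# actions for the first n_two_action_genes, one for the rest), then
# uncovered single-action pairs. Order is part of the layout contract.
composition_pairs <- function(comp) {
  cov <- covered_gene_symbols(comp)
  two <- cov[seq_len(comp$n_two_action_genes)]
  one <- cov[setdiff(seq_along(cov), seq_len(comp$n_two_action_genes))]
  unc <- uncovered_gene_symbols(comp)
  tibble::tibble(
    gene_symbol = c(rep(two, each = 2), one, unc),
    action = c(rep(c("inhibitor", "agonist"), length(two)),
               rep("inhibitor", length(one)),
               rep("antagonist", length(unc)))
  )
}

nonhuman_organisms <- c("Staphylococcus aureus", "Influenza A virus",
                        "Candida albicans", "Plasmodium falciparum",
                        "Escherichia coli", "Hepatitis C virus")

#' Generate a synthetic DrugBank-style XML catalog
#'
#' Writes a deterministic XML catalog realizing a [catalog_composition()]:
#' each stratum's records pass every attrition stage before their designated
#' failure point, survivors are distributed over the composition's pair
#' layout (one drug per pair, then round-robin), and the configured number
#' of survivors carry exactly one total target. The same `(composition,
#' seed)` always yields byte-identical output.
#'
#' @param composition a [catalog_composition()].
#' @param seed integer seed for record-level noise (names, dates).
#' @param path file path to write the XML document to.
#' @return `path`, invisibly.
#' @export
generate_drug_catalog <- function(composition = catalog_composition(),
                                  seed = 1L, path) {
  validate_catalog_composition(composition)
  with_seed(seed, generate_drug_catalog_impl(composition, path))
}

generate_drug_catalog_impl <- function(comp, path) {
  target_xml <- function(name, known_action, action, organism, gene_symbol) {
    act <- ifelse(is.na(action), "",
                  sprintf("<actions><action>%s</action></actions>", action))
    org <- ifelse(is.na(organism), "",
                  sprintf("<organism>%s</organism>", organism))
    gene <- ifelse(is.na(gene_symbol), "",
                   sprintf("<polypeptide><gene-name>%s</gene-name></polypeptide>",
                           gene_symbol))
    sprintf("<target><name>%s</name><known-action>%s</known-action>%s%s%s</target>",
            xml_escape(name), known_action, act, org, gene)
  }
  product_xml <- function(country, date) {
    sprintf("<product><country>%s</country><started-marketing-on>%s</started-marketing-on></product>",
            country, date)
  }
  rand_dates <- function(n) {
    format(as.Date("1962-01-01") +
             sample.int(as.integer(as.Date("2018-12-31") -
                                     as.Date("1962-01-01")), n,
                        replace = TRUE),
           "%Y-%m-%d")
  }
  rand_products <- function(n) {
    two <- stats::runif(n) < 0.3
    p1 <- product_xml(sample(c("United States", "Canada"), n, replace = TRUE),
                      rand_dates(n))
    p2 <- product_xml(sample(c("United States", "Canada"), n, replace = TRUE),
                      rand_dates(n))
    ifelse(two, paste0(p1, p2), p1)
  }

  type <- character(0); name <- character(0); groups <- character(0)
  products <- character(0); targets <- character(0)
  add_stratum <- function(type_, name_, groups_, products_, targets_) {
    type <<- c(type, type_); name <<- c(name, name_)
    groups <<- c(groups, groups_); products <<- c(products, products_)
    targets <<- c(targets, targets_)
  }
  grp <- function(...) {
    paste0(sprintf("<group>%s</group>", c(...)), collapse = "")
  }

  # biologics: pass nothing to pass, fail the type stage
  nb <- comp$n_biotech
  if (nb > 0) {
    add_stratum(
      rep("biotech", nb),
      sprintf("Biological %04d", seq_len(nb)),
      rep(grp("approved"), nb),
      rand_products(nb),
      target_xml(sprintf("Receptor B%04d", seq_len(nb)), "yes", "antagonist",
                 "Humans", sprintf("BGN%04d", seq_len(nb)))
    )
  }

  # small molecules failing approval status: investigational / experimental /
  # approved-but-withdrawn (the veto case)
  nn <- comp$n_not_approved
  if (nn > 0) {
    n_inv <- floor(0.7 * nn)
    n_exp <- floor(0.2 * nn)
    n_wdn <- nn - n_inv - n_exp
    add_stratum(
      rep("small molecule", nn),
      sprintf("Investigational %04d", seq_len(nn)),
      c(rep(grp("investigational"), n_inv),
        rep(grp("experimental"), n_exp),
        rep(grp("approved", "withdrawn"), n_wdn)),
      rand_products(nn),
      target_xml(sprintf("Protein I%04d", seq_len(nn)), "yes", "inhibitor",
                 "Humans", sprintf("IGN%04d", seq_len(nn)))
    )
  }

  # approved small molecules with zero or two known-action targets
  nw <- comp$n_wrong_known_action
  if (nw > 0) {
    n_zero <- floor(0.6 * nw)
    n_two <- nw - n_zero
    t_zero <- target_xml(sprintf("Protein Z%04d", seq_len(n_zero)), "no",
                         NA, "Humans", sprintf("ZGN%04d", seq_len(n_zero)))
    t_two <- paste0(
      target_xml(sprintf("Protein Ma%04d", seq_len(n_two)), "yes",
                 "inhibitor", "Humans", sprintf("MGA%04d", seq_len(n_two))),
      target_xml(sprintf("Protein Mb%04d", seq_len(n_two)), "yes",
                 "activator", "Humans", sprintf("MGB%04d", seq_len(n_two)))
    )
    add_stratum(
      rep("small molecule", nw),
      sprintf("Multitarget %04d", seq_len(nw)),
      rep(grp("approved"), nw),
      rand_products(nw),
      c(t_zero, t_two)
    )
  }

  # exclusions stratum: nonhuman target / blocklisted name / missing gene
  ne <- comp$n_excluded_nonhuman
  if (ne > 0) {
    add_stratum(
      rep("small molecule", ne),
      sprintf("Antimicrobial %03d", seq_len(ne)),
      rep(grp("approved"), ne),
      rand_products(ne),
      target_xml(sprintf("Gyrase-like N%03d", seq_len(ne)), "yes",
                 "inhibitor",
                 rep_len(nonhuman_organisms, ne),
                 sprintf("NHG%03d", seq_len(ne)))
    )
  }
  nk <- comp$n_excluded_blocklist
  if (nk > 0) {
    add_stratum(
      rep("small molecule", nk),
      composition_blocklist(comp),
      rep(grp("approved"), nk),
      rand_products(nk),
      target_xml(sprintf("Polymerase K%03d", seq_len(nk)), "yes",
                 "inhibitor", "Humans", sprintf("KGN%03d", seq_len(nk)))
    )
  }
  nm <- comp$n_excluded_missing_field
  if (nm > 0) {
    add_stratum(
      rep("small molecule", nm),
      sprintf("Orphanol %03d", seq_len(nm)),
      rep(grp("approved"), nm),
      rand_products(nm),
      target_xml(sprintf("Uncharacterized protein %03d", seq_len(nm)), "yes",
                 "inhibitor", "Humans", NA)
    )
  }

  # survivors: laid out over the pair structure, one per pair then
  # round-robin; the first n_final_single_target carry one total target
  nf <- comp$n_final
  if (nf > 0) {
    pairs <- composition_pairs(comp)
    np <- nrow(pairs)
    extra <- nf - np
    counts <- rep(1L, np)
    if (extra > 0) {
      idx <- (seq_len(extra) - 1L) %% np + 1L
      counts <- counts + tabulate(idx, nbins = np)
    }
    pair_of_drug <- rep(seq_len(np), counts)
    multi <- seq_len(nf) > comp$n_final_single_target
    extra_t <- target_xml(sprintf("Accessory protein %03d", seq_len(sum(multi))),
                          "unknown", NA, "Humans",
                          sprintf("XTR%03d", seq_len(sum(multi))))
    t_main <- target_xml(
      sprintf("%s protein", pairs$gene_symbol[pair_of_drug]),
      "yes", pairs$action[pair_of_drug], "Humans",
      pairs$gene_symbol[pair_of_drug]
    )
    t_final <- t_main
    t_final[multi] <- paste0(t_main[multi], extra_t)
    add_stratum(
      rep("small molecule", nf),
      sprintf("Compound %05d", seq_len(nf)),
      rep(grp("approved"), nf),
      rand_products(nf),
      t_final
    )
  }

  n <- length(name)
  ord <- sample.int(n)
  rec <- sprintf(
    "  <drug type=\"%s\"><drugbank-id>SYN%05d</drugbank-id><name>%s</name><groups>%s</groups><products>%s</products><targets>%s</targets></drug>",
    type[ord], seq_len(n), xml_escape(name[ord]), groups[ord],
    products[ord], targets[ord]
  )
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<drugbank>", rec, "</drugbank>"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Composition of a synthetic variant annotation table
#'
#' Defines the eligibility split of a synthetic exome-array annotation
#' table: how many variants pass all QC screens and how many are planted to
#' fail each screen (null rsID, high missingness, low MAF). Every covered
#' gene is guaranteed at least one eligible variant; uncovered genes receive
#' only ineligible variants; remaining eligible variants are spread over
#' filler genes that correspond to no drug target.
#'
#' The defaults produce a full-scale table of 239,796 variants with 58,945
#' eligible, the 180,851 removals split as 20,000 null-rsID, 60,851
#' high-missingness and 100,000 low-MAF.
#'
#' @param n_eligible variants passing all screens.
#' @param n_null_rsid variants planted with a literal `NULL` rsID.
#' @param n_high_missingness variants with missingness above 0.05.
#' @param n_low_maf variants with MAF below 0.001.
#' @param covered_genes genes that must receive at least one eligible
#'   variant (default: the covered genes of the default
#'   [catalog_composition()]).
#' @param uncovered_genes genes that must receive no eligible variant.
#' @param n_filler_genes number of non-target genes absorbing the remaining
#'   eligible variants.
#' @return object of class `variant_composition`.
#' @export
variant_composition <- function(n_eligible = 58945,
                                n_null_rsid = 20000,
                                n_high_missingness = 60851,
                                n_low_maf = 100000,
                                covered_genes =
                                  covered_gene_symbols(catalog_composition()),
                                uncovered_genes =
                                  uncovered_gene_symbols(catalog_composition()),
                                n_filler_genes = 600) {
  comp <- structure(
    list(
      n_eligible = as.integer(n_eligible),
      n_null_rsid = as.integer(n_null_rsid),
      n_high_missingness = as.integer(n_high_missingness),
      n_low_maf = as.integer(n_low_maf),
      covered_genes = norm_gene(covered_genes),
      uncovered_genes = norm_gene(uncovered_genes),
      n_filler_genes = as.integer(n_filler_genes)
    ),
    class = "variant_composition"
  )
  validate_variant_composition(comp)
  comp
}

validate_variant_composition <- function(comp) {
  counts <- unlist(comp[c("n_eligible", "n_null_rsid", "n_high_missingness",
                          "n_low_maf")])
  if (any(counts < 0)) {
    stop("variant composition counts must be non-negative", call. = FALSE)
  }
  if (length(intersect(comp$covered_genes, comp$uncovered_genes)) > 0) {
    stop("covered and uncovered gene sets must be disjoint", call. = FALSE)
  }
  if (comp$n_eligible < length(comp$covered_genes)) {
    stop("n_eligible (", comp$n_eligible, ") cannot cover ",
         length(comp$covered_genes), " genes with one variant each",
         call. = FALSE)
  }
  invisible(comp)
}

variant_total <- function(comp) {
  comp$n_eligible + comp$n_null_rsid + comp$n_high_missingness +
    comp$n_low_maf
}

#' @export
print.variant_composition <- function(x, ...) {
  cat("<variant_composition>", variant_total(x), "variants,", x$n_eligible,
      "eligible,", length(x$covered_genes), "covered genes\n")
  invisible(x)
}

#' Generate a synthetic exome-array variant annotation table
#'
#' Writes a deterministic TSV realizing a [variant_composition()]: eligible
#' variants (rsID present, MAF in `[0.001, 0.5]`, missingness in
#' `[0, 0.05]`) allocated over covered and filler genes with every covered
#' gene receiving at least one, plus the three planted ineligible strata.
#' Columns: `exmID`, `rsID`, `Gene`, `MAF_white`, `Missingness`, `Mutation`,
#' `AlleleA`, `AlleleB`. Byte-identical for the same `(composition, seed)`.
#'
#' @param composition a [variant_composition()].
#' @param seed integer seed.
#' @param path TSV path to write.
#' @return `path`, invisibly.
#' @export
generate_variant_table <- function(composition = variant_composition(),
                                   seed = 1L, path) {
  validate_variant_composition(composition)
  with_seed(seed, generate_variant_table_impl(composition, path))
}

generate_variant_table_impl <- function(comp, path) {
  bases <- c("A", "C", "G", "T")
  filler <- if (comp$n_filler_genes > 0) {
    sprintf("FIL%03d", seq_len(comp$n_filler_genes))
  } else {
    character(0)
  }
  rand_alleles <- function(n) {
    a <- sample(bases, n, replace = TRUE)
    shift <- sample.int(3, n, replace = TRUE)
    b <- bases[(match(a, bases) - 1L + shift) %% 4L + 1L]
    list(a = a, b = b)
  }
  mutations <- c("missense", "synonymous", "stop-gain", "splice-site")

  # eligible counts per gene: one guaranteed per covered gene, remainder
  # allocated over covered + filler genes by seeded weights (largest
  # remainder rounding keeps the total exact)
  g_all <- c(comp$covered_genes, filler)
  base <- integer(length(g_all))
  base[seq_along(comp$covered_genes)] <- 1L
  remainder <- comp$n_eligible - sum(base)
  cnt <- integer(length(g_all))
  if (remainder > 0 && length(g_all) > 0) {
    w <- stats::runif(length(g_all), 0.2, 1.8)
    raw <- w / sum(w) * remainder
    cnt <- as.integer(floor(raw))
    short <- remainder - sum(cnt)
    if (short > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1L
    }
  }
  elig_counts <- base + cnt

  stratum <- function(n, gene, maf, miss, rsid_present) {
    tibble::tibble(gene = gene, maf = maf, miss = miss,
                   rsid_present = rep(rsid_present, n))
  }
  strata <- list()
  if (comp$n_eligible > 0) {
    strata$eligible <- stratum(
      comp$n_eligible,
      rep(g_all, elig_counts),
      stats::runif(comp$n_eligible, 0.001, 0.5),
      stats::runif(comp$n_eligible, 0, 0.0499),
      TRUE
    )
  }
  ineligible_pool <- c(filler, comp$covered_genes, comp$uncovered_genes)
  if (comp$n_null_rsid > 0) {
    strata$null_rsid <- stratum(
      comp$n_null_rsid,
      sample(ineligible_pool, comp$n_null_rsid, replace = TRUE),
      stats::runif(comp$n_null_rsid, 0.001, 0.5),
      stats::runif(comp$n_null_rsid, 0, 0.0499),
      FALSE
    )
  }
  if (comp$n_high_missingness > 0) {
    # uncovered genes live only in ineligible strata; seed each with a few
    # high-missingness probes so the gene appears on the chip at all
    n_unc <- length(comp$uncovered_genes)
    n_seeded <- min(comp$n_high_missingness, 20L * n_unc)
    g_seeded <- rep_len(comp$uncovered_genes, n_seeded)
    n_rest <- comp$n_high_missingness - n_seeded
    strata$high_miss <- stratum(
      comp$n_high_missingness,
      c(g_seeded, sample(ineligible_pool, n_rest, replace = TRUE)),
      stats::runif(comp$n_high_missingness, 0.001, 0.5),
      stats::runif(comp$n_high_missingness, 0.0501, 0.6),
      TRUE
    )
  }
  if (comp$n_low_maf > 0) {
    strata$low_maf <- stratum(
      comp$n_low_maf,
      sample(ineligible_pool, comp$n_low_maf, replace = TRUE),
      stats::runif(comp$n_low_maf, 0, 0.00099),
      stats::runif(comp$n_low_maf, 0, 0.0499),
      TRUE
    )
  }
  all <- dplyr::bind_rows(strata)
  n <- nrow(all)
  ord <- sample.int(n)
  all <- all[ord, ]
  al <- rand_alleles(n)
  tab <- tibble::tibble(
    exmID = sprintf("exm%06d", seq_len(n)),
    rsID = ifelse(all$rsid_present,
                  sprintf("rs%08d", 10000000L + seq_len(n)), "NULL"),
    Gene = all$gene,
    MAF_white = formatC(all$maf, format = "f", digits = 6),
    Missingness = formatC(all$miss, format = "f", digits = 4),
    Mutation = sample(mutations, n, replace = TRUE,
                      prob = c(0.55, 0.3, 0.1, 0.05)),
    AlleleA = al$a,
    AlleleB = al$b
  )
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}
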