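#' Join target-action pairs to eligible variants by gene symbol
#'
#' The gene-level join underlying the "repurposable drugged genome": each
#' target-action pair is mapped to every eligible variant whose gene symbol
#' equals the pair's gene symbol (both sides carry the same uppercase
#' normalization). Pairs with no matching variant are kept and flagged
#' uncovered, so reports can enumerate them. Two pairs sharing a gene but
#' differing in action map to identical variant sets — the join is purely
#' gene-level.
#'
#' @param pairs a `target_action_pairs` tibble from [consolidate_pairs()].
#' @param eligible_variants tibble of QC-eligible variants (the `eligible`
#'   component of a [qc_filter()] result, or a `qc_result`).
#' @return object of class `pair_variant_map`: list with
#'   \describe{
#'     \item{pairs}{the pair tibble plus `n_eligible_variants` and `covered`
#'       columns;}
#'     \item{variants_by_gene}{named list mapping each pair gene symbol to
#'       the tibble of its eligible variants (possibly zero-row).}
#'   }
#' @export
map_pairs_to_variants <- function(pairs, eligible_variants) {
  stopifnot(inherits(pairs, "target_action_pairs"))
  if (inherits(eligible_variants, "qc_result")) {
    eligible_variants <- eligible_variants$eligible
  }
  genes <- unique(pairs$gene_symbol)
  vsub <- eligible_variants[eligible_variants$Gene %in% genes, ]
  by_gene <- split(seq_len(nrow(vsub)), factor(vsub$Gene, levels = genes))
  variants_by_gene <- lapply(by_gene, function(i) vsub[i, ])
  names(variants_by_gene) <- genes

  counts <- vapply(variants_by_gene, nrow, integer(1))
  out <- pairs
  out$n_eligible_variants <- unname(counts[out$gene_symbol])
  out$covered <- out$n_eligible_variants > 0L
  structure(
    list(pairs = out, variants_by_gene = variants_by_gene),
    class = "pair_variant_map"
  )
}

#' @export
print.pair_variant_map <- function(x, ...) {
  cat("<pair_variant_map>", nrow(x$pairs), "pairs,",
      sum(x$pairs$covered), "covered\n")
  invisible(x)
}

#' Coverage of target-action pairs by eligible variants
#'
#' Summarizes a pair-to-variant mapping: how many pairs have at least one
#' eligible variant on their target gene, how many distinct target genes
#' those covered pairs represent, and the coverage percentage (half-up
#' rounded to an integer; the exact fraction is also reported).
#'
#' @param mapping a `pair_variant_map` from [map_pairs_to_variants()].
#' @return object of class `coverage_summary`: list with `n_pairs`,
#'   `n_pairs_covered`, `n_unique_targets_covered`, `coverage_percent`
#'   (integer, half-up), `coverage_fraction` (exact ratio).
#' @export
coverage_summary <- function(mapping) {
  stopifnot(inherits(mapping, "pair_variant_map"))
  p <- mapping$pairs
  if (nrow(p) == 0) {
    stop("coverage is undefined for an empty pair mapping", call. = FALSE)
  }
  n_pairs <- nrow(p)
  n_cov <- sum(p$covered)
  structure(
    list(
      n_pairs = n_pairs,
      n_pairs_covered = n_cov,
      n_unique_targets_covered = length(unique(p$gene_symbol[p$covered])),
      coverage_percent = as.integer(round_half_up(100 * n_cov / n_pairs)),
      coverage_fraction = n_cov / n_pairs
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> %d/%d pairs covered (%d%%), %d unique targets\n",
    x$n_pairs_covered, x$n_pairs, x$coverage_percent,
    x$n_unique_targets_covered))
  invisible(x)
}

#' Build the prioritized repurposing shortlist
#'
#' One entry per covered target-action pair, sorted by descending number of
#' eligible variants on the target gene (more variants, more phenome-wide
#' association opportunity) and then by gene symbol. Uncovered pairs are
#' excluded. When a marketing table from [extract_marketing_details()] is
#' supplied, each entry is annotated with its member drugs' countries and
#' earliest marketing dates; drugs without marketing information get absent
#' fields.
#'
#' @param mapping a `pair_variant_map`.
#' @param marketing_table optional tibble from
#'   [extract_marketing_details()].
#' @return tibble of class `repurposing_shortlist` with columns
#'   `gene_symbol`, `action`, `n_eligible_variants`, `drugs` (list of member
#'   drug names), `earliest_marketing_date` (earliest over member drugs,
#'   `NA` if unknown), `countries` (list), `marketing` (list of per-drug
#'   marketing tibbles).
#' @export
build_shortlist <- function(mapping, marketing_table = NULL) {
  stopifnot(inherits(mapping, "pair_variant_map"))
  p <- mapping$pairs[mapping$pairs$covered, ]
  p <- p[order(-p$n_eligible_variants, p$gene_symbol, p$action), ]

  lookup <- function(drug_names) {
    if (is.null(marketing_table)) {
      return(tibble::tibble(name = drug_names, country = NA_character_,
                            earliest_marketing_date = as.Date(NA)))
    }
    hit <- marketing_table[norm_lower(marketing_table$name) %in%
                             norm_lower(drug_names), ]
    miss <- drug_names[!norm_lower(drug_names) %in% norm_lower(hit$name)]
    dplyr::bind_rows(
      hit,
      tibble::tibble(name = miss, country = NA_character_,
                     earliest_marketing_date = as.Date(NA))
    )
  }
  marketing <- lapply(p$member_names, lookup)
  earliest <- as.Date(vapply(marketing, function(m) {
    d <- m$earliest_marketing_date[!is.na(m$earliest_marketing_date)]
    if (length(d) == 0) NA_real_ else as.numeric(min(d))
  }, numeric(1)))
  countries <- lapply(marketing, function(m) {
    sort(unique(m$country[!is.na(m$country)]))
  })

  out <- tibble::tibble(
    gene_symbol = p$gene_symbol,
    action = p$action,
    n_eligible_variants = p$n_eligible_variants,
    drugs = p$member_names,
    earliest_marketing_date = earliest,
    countries = countries,
    marketing = marketing
  )
  class(out) <- c("repurposing_shortlist", class(out))
  out
}

#' Write a shortlist to a tab-separated file
#'
#' List fields (drugs, countries) are collapsed with a `|` delimiter;
#' absent dates become empty cells.
#'
#' @param shortlist a `repurposing_shortlist` from [build_shortlist()].
#' @param path TSV path to write.
#' @return the path, invisibly.
#' @export
write_shortlist <- function(shortlist, path) {
  stopifnot(inherits(shortlist, "repurposing_shortlist"))
  collapse <- function(col) {
    vapply(col, function(x) paste(x, collapse = "|"), character(1))
  }
  tab <- tibble::tibble(
    gene_symbol = shortlist$gene_symbol,
    action = shortlist$action,
    drugs = collapse(shortlist$drugs),
    n_eligible_variants = shortlist$n_eligible_variants,
    earliest_marketing_date = shortlist$earliest_marketing_date,
    countries = collapse(shortlist$countries)
  )
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Write a coverage summary as TSV and JSON
#'
#' @param summary a `coverage_summary`.
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
write_coverage_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "coverage_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "coverage.tsv")
  f2 <- file.path(dir, "coverage.json")
  tab <- tibble::tibble(
    n_pairs = summary$n_pairs,
    n_pairs_covered = summary$n_pairs_covered,
    n_unique_targets_covered = summary$n_unique_targets_covered,
    coverage_percent = summary$coverage_percent
  )
  data.table::fwrite(tab, f1, sep = "\t", quote = FALSE)
  jsonlite::write_json(unclass(summary), f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}
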