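# Hand-rolled XML fixture builders, deliberately independent of the
# package's synthetic-data generator so parser tests do not lean on the
# code they check.

target_frag <- function(name = "Target X", known = "yes",
                        action = "inhibitor", organism = "Humans",
                        gene = "GENE1", enzymes = character(),
                        transporters = character()) {
  paste0(
    "<target><name>", name, "</name>",
    "<known-action>", known, "</known-action>",
    if (!is.na(action) && nzchar(action)) {
      paste0("<actions><action>", action, "</action></actions>")
    },
    if (!is.na(organism) && nzchar(organism)) {
      paste0("<organism>", organism, "</organism>")
    },
    if (!is.na(gene) && nzchar(gene)) {
      paste0("<polypeptide><gene-name>", gene, "</gene-name></polypeptide>")
    },
    if (length(enzymes)) {
      paste0("<enzymes>",
             paste0("<enzyme>", enzymes, "</enzyme>", collapse = ""),
             "</enzymes>")
    },
    if (length(transporters)) {
      paste0("<transporters>",
             paste0("<transporter>", transporters, "</transporter>",
                    collapse = ""),
             "</transporters>")
    },
    "</target>"
  )
}

product_frag <- function(country = "United States", date = "2000-01-01") {
  paste0("<product><country>", country, "</country>",
         "<started-marketing-on>", date, "</started-marketing-on></product>")
}

drug_frag <- function(name = "Drugol", type = "small molecule",
                      groups = "approved", targets = character(),
                      products = character(), id = NULL) {
  paste0(
    "<drug", if (!is.na(type)) paste0(" type=\"", type, "\""), ">",
    if (!is.null(id)) paste0("<drugbank-id>", id, "</drugbank-id>"),
    if (!is.na(name)) paste0("<name>", name, "</name>"),
    "<groups>", paste0("<group>", groups, "</group>", collapse = ""),
    "</groups>",
    if (length(products)) paste0("<products>", paste0(products, collapse = ""),
                                 "</products>"),
    if (length(targets)) paste0("<targets>", paste0(targets, collapse = ""),
                                "</targets>"),
    "</drug>"
  )
}

catalog_frag <- function(...) {
  paste0("<drugbank>", paste0(c(...), collapse = ""), "</drugbank>")
}

# A randomized catalog exercising every attrition predicate, built directly
# as XML strings (not via the package generator).
random_catalog_xml <- function(n, seed) {
  set.seed(seed)
  drugs <- vapply(seq_len(n), function(i) {
    type <- sample(c("small molecule", "biotech"), 1, prob = c(0.8, 0.2))
    groups <- sample(list("approved", "investigational",
                          c("approved", "withdrawn"),
                          c("approved", "investigational"), "illicit"), 1,
                     prob = c(0.4, 0.2, 0.15, 0.15, 0.1))[[1]]
    n_known <- sample(0:2, 1, prob = c(0.25, 0.5, 0.25))
    n_unknown <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
    organism <- sample(c("Humans", "Escherichia coli"), 1,
                       prob = c(0.8, 0.2))
    gene <- sample(c(sprintf("G%02d", 1:12), NA), 1)
    tg <- c(
      if (n_known > 0) {
        vapply(seq_len(n_known), function(k) {
          target_frag(name = sprintf("T%d-%d", i, k),
                      action = sample(c("inhibitor", "agonist"), 1),
                      organism = organism, gene = gene)
        }, character(1))
      },
      if (n_unknown > 0) {
        vapply(seq_len(n_unknown), function(k) {
          target_frag(name = sprintf("U%d-%d", i, k), known = "unknown",
                      action = NA, gene = sprintf("UG%02d", k))
        }, character(1))
      }
    )
    drug_frag(name = sprintf("Randomol %03d", i), type = type,
              groups = groups, targets = tg,
              products = product_frag(date = sprintf("19%02d-0%d-1%d",
                                                     sample(60:99, 1),
                                                     sample(1:9, 1),
                                                     sample(0:9, 1))))
  }, character(1))
  catalog_frag(drugs)
}

# Independent per-record funnel oracle: reads the raw XML with per-node
# loops and applies the stage predicates one record at a time.
oracle_funnel_counts <- function(xml_string, config) {
  doc <- xml2::read_xml(xml_string)
  drugs <- xml2::xml_find_all(doc, "/drugbank/drug")
  txt1 <- function(node, xp) {
    r <- xml2::xml_find_first(node, xp)
    if (inherits(r, "xml_missing")) return(NA_character_)
    v <- trimws(xml2::xml_text(r))
    if (v == "" || v == "NULL") NA_character_ else v
  }
  survive <- function(node) {
    if (!identical(xml2::xml_attr(node, "type"), "small molecule")) {
      return(1L)
    }
    labs <- tolower(trimws(unlist(strsplit(
      xml2::xml_text(xml2::xml_find_all(node, "./groups/group")), ","))))
    if (!any(labs %in% config$status_allowlist) ||
        any(labs %in% config$status_veto)) {
      return(2L)
    }
    tnodes <- xml2::xml_find_all(node, "./targets/target")
    known <- vapply(tnodes, function(t) {
      identical(tolower(txt1(t, "./known-action")), "yes")
    }, logical(1))
    if (sum(known) != 1L) return(3L)
    kt <- tnodes[known][[1]]
    org <- txt1(kt, "./organism")
    if (is.na(org) ||
        !tolower(org) %in% config$human_organism_labels) {
      return(4L)
    }
    nm <- txt1(node, "./name")
    if (tolower(nm) %in% config$excluded_drug_names) return(4L)
    if (is.na(txt1(kt, "./actions/action")) ||
        is.na(txt1(kt, "./polypeptide/gene-name")) ||
        length(labs) == 0) {
      return(4L)
    }
    5L
  }
  fate <- vapply(drugs, survive, integer(1))
  c(type = sum(fate >= 2), status = sum(fate >= 3),
    known_action = sum(fate >= 4), exclusions = sum(fate >= 5))
}

# Tiny random variant table as a tibble, for QC predicate tests.
random_variant_tibble <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    exmID = sprintf("exm%05d", seq_len(n)),
    rsID = ifelse(runif(n) < 0.1, NA_character_,
                  sprintf("rs%07d", seq_len(n))),
    Gene = sample(sprintf("G%02d", 1:15), n, replace = TRUE),
    MAF_white = round(runif(n, 0, 0.5) *
                        sample(c(1, 0.001), n, replace = TRUE), 6),
    Missingness = round(runif(n, 0, 0.12), 4),
    Mutation = "missense",
    AlleleA = "A", AlleleB = "G"
  )
}

write_variant_tsv <- function(tab, path = tempfile(fileext = ".tsv")) {
  tab$rsID[is.na(tab$rsID)] <- "NULL"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small calibrated composition used by CLI / generator tests: same planted
# structure as the default, scaled down.
tiny_catalog_composition <- function() {
  catalog_composition(
    n_biotech = 3, n_not_approved = 5, n_wrong_known_action = 3,
    n_excluded_nonhuman = 2, n_excluded_blocklist = 1,
    n_excluded_missing_field = 1, n_final = 10, n_final_single_target = 8,
    n_two_action_genes = 2, n_one_action_genes = 3, n_uncovered_pairs = 1
  )
}

tiny_variant_composition <- function(cc = tiny_catalog_composition()) {
  variant_composition(
    n_eligible = 40, n_null_rsid = 10, n_high_missingness = 12,
    n_low_maf = 15, covered_genes = covered_gene_symbols(cc),
    uncovered_genes = uncovered_gene_symbols(cc), n_filler_genes = 5
  )
}

# One shared full-scale calibrated pipeline run, computed lazily and cached
# for the acceptance tests (the generation + parse dominates test runtime).
.calibrated <- new.env(parent = emptyenv())

calibrated_pipeline <- function() {
  if (!is.null(.calibrated$res)) {
    return(.calibrated$res)
  }
  xml <- tempfile(fileext = ".xml")
  tsv <- tempfile(fileext = ".tsv")
  cc <- catalog_composition()
  generate_drug_catalog(cc, seed = 1L, path = xml)
  generate_variant_table(variant_composition(), seed = 1L, path = tsv)
  catalog <- parse_drugbank_xml(xml)
  cfg <- attrition_config(excluded_drug_names = composition_blocklist(cc))
  funnel <- run_funnel(catalog, cfg)
  qc <- qc_filter(load_variant_table(tsv))
  mapping <- map_pairs_to_variants(funnel$pairs, qc)
  .calibrated$res <- list(
    catalog = catalog, funnel = funnel, qc = qc, mapping = mapping,
    coverage = coverage_summary(mapping)
  )
  unlink(c(xml, tsv))
  .calibrated$res
}
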