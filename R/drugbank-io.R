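#' Parse a DrugBank-style XML catalog into a drug catalog object
#'
#' Reads an XML drug catalog (root `<drugbank>`, repeated `<drug>` elements)
#' and returns a relational catalog: one row per drug plus long-format target
#' and product tables keyed by drug id. Only the fields relevant to
#' repurposing prioritization are extracted — name, type, status labels,
#' products (country and marketing start date), and targets (name, action,
#' known-action flag, gene symbol, organism, enzymes, transporters). Unknown
#' elements are ignored, so richer exports in the same dialect remain
#' parseable.
#'
#' Derived per-drug counts (`n_targets`, `n_known_action_targets`) are always
#' recomputed from the `<target>` children, never trusted from attributes.
#' Empty-string and literal `"NULL"` field values are normalized to `NA` at
#' parse time. A `<drug>` missing its name or carrying an unrecognized type
#' is collected in the `rejects` table (with a reason) and parsing continues.
#'
#' @param source path to an XML file, a URL, or a raw XML string.
#' @return An object of class `drug_catalog`: a list with
#'   \describe{
#'     \item{cards}{tibble, one row per accepted drug: `drug_id`, `name`,
#'       `drug_type` (`"small molecule"` or `"biotech"`), `status_labels`
#'       (list of lowercase labels), `countries_approved` (list),
#'       `n_targets`, `n_known_action_targets`.}
#'     \item{targets}{tibble, one row per target: `drug_id`, `target_name`,
#'       `action`, `known_action`, `gene_symbol`, `organism`, `enzymes`,
#'       `transporters` (the last two are list columns of unique strings).}
#'     \item{products}{tibble, one row per product: `drug_id`, `country`,
#'       `marketing_start_date` (`Date`, `NA` when absent or unparseable).}
#'     \item{rejects}{tibble of rejected drug elements with reasons.}
#'   }
#' @export
#' @examples
#' xml <- paste0(
#'   "<drugbank><drug type='small molecule'><name>Examplol</name>",
#'   "<groups><group>approved</group></groups>",
#'   "<targets><target><name>ACE</name><known-action>yes</known-action>",
#'   "<actions><action>inhibitor</action></actions>",
#'   "<organism>Humans</organism>",
#'   "<polypeptide><gene-name>ACE</gene-name></polypeptide>",
#'   "</target></targets></drug></drugbank>")
#' cat1 <- parse_drugbank_xml(xml)
#' cat1$cards
parse_drugbank_xml <- function(source) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) {
      stop("malformed XML catalog: ", conditionMessage(e), call. = FALSE)
    }
  )
  drugs <- xml2::xml_find_all(doc, "/drugbank/drug")
  n <- length(drugs)
  if (n == 0L) {
    return(empty_drug_catalog())
  }

  first_text <- function(nodes, xpath) {
    res <- xml2::xml_find_first(nodes, xpath)
    na_if_null(xml2::xml_text(res))
  }
  # One-to-many children are pulled in a single document-order XPath sweep
  # and mapped back to their parent via per-parent counts; this keeps the
  # parse vectorized (no per-drug node queries) for large catalogs.
  child_index <- function(nodes, count_xpath) {
    cnt <- as.integer(xml2::xml_find_num(nodes, count_xpath))
    list(count = cnt, parent = rep(seq_along(nodes), cnt))
  }

  id_raw <- first_text(drugs, "./drugbank-id")
  name <- trimws_na(first_text(drugs, "./name"))
  type <- norm_lower(xml2::xml_attr(drugs, "type"))

  # status labels: lowercase, multi-valued; a single <group> may itself carry
  # a comma-separated multi-label such as "approved, investigational"
  grp <- child_index(drugs, "count(./groups/group)")
  grp_txt <- xml2::xml_text(xml2::xml_find_all(doc, "/drugbank/drug/groups/group"))
  grp_split <- strsplit(grp_txt, ",", fixed = TRUE)
  grp_parent <- rep(grp$parent, lengths(grp_split))
  grp_lab <- norm_lower(unlist(grp_split, use.names = FALSE))
  keep <- !is.na(na_if_null(grp_lab))
  status_labels <- unname(split(grp_lab[keep],
                                factor(grp_parent[keep], levels = seq_len(n))))
  status_labels <- lapply(status_labels, unique)

  # products
  prod <- child_index(drugs, "count(./products/product)")
  pnodes <- xml2::xml_find_all(doc, "/drugbank/drug/products/product")
  p_country <- trimws_na(first_text(pnodes, "./country"))
  p_date_raw <- first_text(pnodes, "./started-marketing-on")
  p_date <- parse_iso_date(p_date_raw)
  n_bad_dates <- sum(!is.na(p_date_raw) & is.na(p_date))
  if (n_bad_dates > 0L) {
    warning(n_bad_dates, " product marketing date(s) were not valid ISO-8601 ",
            "dates and were treated as absent", call. = FALSE)
  }

  # targets, with nested actions / enzymes / transporters
  tgt <- child_index(drugs, "count(./targets/target)")
  tnodes <- xml2::xml_find_all(doc, "/drugbank/drug/targets/target")
  t_name <- trimws_na(first_text(tnodes, "./name"))
  t_known <- norm_lower(first_text(tnodes, "./known-action"))
  t_org <- trimws_na(first_text(tnodes, "./organism"))
  t_gene <- trimws_na(first_text(tnodes, "./polypeptide/gene-name"))
  t_action <- trimws_na(first_text(tnodes, "./actions/action"))

  nested_list <- function(count_xpath, all_xpath) {
    cnt <- if (length(tnodes)) {
      as.integer(xml2::xml_find_num(tnodes, count_xpath))
    } else {
      integer(0)
    }
    txt <- xml2::xml_text(xml2::xml_find_all(doc, all_xpath))
    out <- unname(split(txt, factor(rep(seq_along(tnodes), cnt),
                                    levels = seq_along(tnodes))))
    lapply(out, unique)  # duplicate enzyme/transporter listings collapse
  }
  t_enzymes <- nested_list("count(./enzymes/enzyme)",
                           "/drugbank/drug/targets/target/enzymes/enzyme")
  t_transporters <- nested_list("count(./transporters/transporter)",
                                "/drugbank/drug/targets/target/transporters/transporter")

  known_action <- !is.na(t_known) & t_known == "yes"

  # record-level validation: missing name or unrecognized type rejects the
  # drug element but never aborts the parse
  reject_reason <- rep(NA_character_, n)
  reject_reason[is.na(name)] <- "missing-name"
  bad_type <- !is.na(name) & (is.na(type) | !type %in% c("small molecule", "biotech"))
  reject_reason[bad_type] <- "missing-or-invalid-type"
  rejected <- !is.na(reject_reason)

  drug_id <- ifelse(is.na(id_raw), sprintf("drug-%05d", seq_len(n)), id_raw)

  n_targets <- tabulate(tgt$parent, nbins = n)
  n_known <- tabulate(tgt$parent[known_action], nbins = n)

  countries <- unname(split(p_country[!is.na(p_country)],
                            factor(prod$parent[!is.na(p_country)],
                                   levels = seq_len(n))))
  countries <- lapply(countries, unique)

  cards <- tibble::tibble(
    drug_id = drug_id,
    name = name,
    drug_type = type,
    status_labels = status_labels,
    countries_approved = countries,
    n_targets = n_targets,
    n_known_action_targets = n_known
  )[!rejected, ]

  keep_t <- !rejected[tgt$parent]
  targets <- tibble::tibble(
    drug_id = drug_id[tgt$parent],
    target_name = t_name,
    action = t_action,
    known_action = known_action,
    gene_symbol = t_gene,
    organism = t_org,
    enzymes = t_enzymes,
    transporters = t_transporters
  )[keep_t, ]

  keep_p <- !rejected[prod$parent]
  products <- tibble::tibble(
    drug_id = drug_id[prod$parent],
    country = p_country,
    marketing_start_date = p_date
  )[keep_p, ]

  rejects <- tibble::tibble(
    position = which(rejected),
    name = name[rejected],
    reason = reject_reason[rejected]
  )

  new_drug_catalog(cards, targets, products, rejects)
}

trimws_na <- function(x) {
  x <- trimws(x)
  na_if_null(x)
}

new_drug_catalog <- function(cards, targets, products, rejects) {
  structure(
    list(cards = cards, targets = targets, products = products,
         rejects = rejects),
    class = "drug_catalog"
  )
}

empty_drug_catalog <- function() {
  new_drug_catalog(
    cards = tibble::tibble(
      drug_id = character(), name = character(), drug_type = character(),
      status_labels = list(), countries_approved = list(),
      n_targets = integer(), n_known_action_targets = integer()
    ),
    targets = tibble::tibble(
      drug_id = character(), target_name = character(), action = character(),
      known_action = logical(), gene_symbol = character(),
      organism = character(), enzymes = list(), transporters = list()
    ),
    products = tibble::tibble(
      drug_id = character(), country = character(),
      marketing_start_date = as.Date(character())
    ),
    rejects = tibble::tibble(position = integer(), name = character(),
                             reason = character())
  )
}

# Restrict a catalog to a set of drug ids, preserving card order.
subset_catalog <- function(catalog, drug_ids) {
  new_drug_catalog(
    cards = catalog$cards[catalog$cards$drug_id %in% drug_ids, ],
    targets = catalog$targets[catalog$targets$drug_id %in% drug_ids, ],
    products = catalog$products[catalog$products$drug_id %in% drug_ids, ],
    rejects = catalog$rejects
  )
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("<drug_catalog>", nrow(x$cards), "drugs |",
      nrow(x$targets), "targets |",
      nrow(x$products), "products")
  if (nrow(x$rejects) > 0) cat(" |", nrow(x$rejects), "rejected elements")
  cat("\n")
  invisible(x)
}

#' Extract earliest marketing date and country per drug
#'
#' For each requested drug name, reports one row per country in which the
#' drug has at least one dated product, with the earliest marketing start
#' date over that drug's products in that country. Marketing dates proxy for
#' patent-expiry/intellectual-property opportunity when prioritizing
#' repurposing candidates.
#'
#' Matching is case-insensitive exact match after whitespace trimming. Names
#' with no matching drug, or a matching drug with no dated products, yield a
#' single row with `NA` country and date; unmatched names additionally raise
#' a warning.
#'
#' @param catalog a `drug_catalog` from [parse_drugbank_xml()].
#' @param names character vector of drug names to look up (non-empty).
#' @return tibble with columns `name` (the name as requested), `country`,
#'   `earliest_marketing_date`.
#' @export
extract_marketing_details <- function(catalog, names) {
  stopifnot(inherits(catalog, "drug_catalog"))
  if (length(names) == 0) {
    stop("`names` must contain at least one drug name", call. = FALSE)
  }
  cards <- catalog$cards
  key <- norm_lower(cards$name)
  out <- vector("list", length(names))
  unmatched <- character(0)
  for (i in seq_along(names)) {
    qi <- names[[i]]
    hit <- which(key == norm_lower(qi))
    if (length(hit) == 0) {
      unmatched <- c(unmatched, qi)
      out[[i]] <- tibble::tibble(
        name = qi, country = NA_character_,
        earliest_marketing_date = as.Date(NA)
      )
      next
    }
    ids <- cards$drug_id[hit]
    prods <- catalog$products[catalog$products$drug_id %in% ids &
                                !is.na(catalog$products$country) &
                                !is.na(catalog$products$marketing_start_date), ]
    if (nrow(prods) == 0) {
      out[[i]] <- tibble::tibble(
        name = qi, country = NA_character_,
        earliest_marketing_date = as.Date(NA)
      )
      next
    }
    agg <- prods |>
      dplyr::group_by(.data$country) |>
      dplyr::summarise(
        earliest_marketing_date = min(.data$marketing_start_date),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$country)
    out[[i]] <- tibble::tibble(
      name = qi, country = agg$country,
      earliest_marketing_date = agg$earliest_marketing_date
    )
  }
  if (length(unmatched) > 0) {
    warning("no catalog match for drug name(s): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Write a drug catalog to a tab-separated table
#'
#' One row per drug card, in the extraction field order: name, type, status,
#' countries, target counts, then the per-target fields. Multi-valued fields
#' are serialized with a `|` delimiter; absent values are written as empty
#' cells. Scalar fields round-trip losslessly through
#' [utils::read.delim()].
#'
#' @param catalog a `drug_catalog`.
#' @param destination path of the TSV file to write.
#' @return the destination path, invisibly.
#' @export
write_cards_table <- function(catalog, destination) {
  stopifnot(inherits(catalog, "drug_catalog"))
  tg <- catalog$targets
  collapse <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_character_ else paste(x, collapse = "|")
  }
  by_drug <- split(seq_len(nrow(tg)), factor(tg$drug_id,
                                             levels = catalog$cards$drug_id))
  tab <- tibble::tibble(
    drug_id = catalog$cards$drug_id,
    name = catalog$cards$name,
    type = catalog$cards$drug_type,
    status = vapply(catalog$cards$status_labels, collapse, character(1)),
    countries_approved = vapply(catalog$cards$countries_approved, collapse,
                                character(1)),
    n_targets = catalog$cards$n_targets,
    n_known_action_targets = catalog$cards$n_known_action_targets,
    target_names = vapply(by_drug, function(i) collapse(tg$target_name[i]),
                          character(1)),
    actions = vapply(by_drug, function(i) collapse(tg$action[i]),
                     character(1)),
    gene_symbols = vapply(by_drug, function(i) collapse(tg$gene_symbol[i]),
                          character(1))
  )
  ok <- tryCatch({
    data.table::fwrite(tab, destination, sep = "\t", quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write cards table to '", destination, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(destination)
}
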