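#' Configuration for the pharmacodynamic attrition stages
#'
#' Holds the label sets and blocklists that drive the four attrition stages.
#' All label sets are stored lowercase.
#'
#' @param status_allowlist status labels that qualify a drug as approved for
#'   clinical use. A drug is retained at the approval stage when at least one
#'   of its status labels is in this set. Default `"approved"`; labels that
#'   merely contain the word (e.g. `"vet-approved"`) do not qualify, since
#'   they do not certify human approval.
#' @param status_veto labels that disqualify a drug outright even when an
#'   allowlisted label is also present (default withdrawn / illicit).
#' @param human_organism_labels organism strings accepted as human targets.
#' @param excluded_drug_names blocklist of drug names excluded for severe
#'   toxicity or DNA-damaging mechanisms (e.g. alkylating antineoplastics);
#'   this stands in for the manual pharmacologist review of candidates and is
#'   empty by default.
#' @param required_fields card fields that must be present after the
#'   known-action filter; cards missing any are excluded with reason
#'   `"missing-field"`.
#' @return an object of class `attrition_config`.
#' @export
attrition_config <- function(status_allowlist = "approved",
                             status_veto = c("withdrawn", "illicit"),
                             human_organism_labels = c("humans", "human"),
                             excluded_drug_names = character(),
                             required_fields = c("name", "action",
                                                 "gene_symbol", "status")) {
  status_allowlist <- unique(norm_lower(status_allowlist))
  if (length(status_allowlist) == 0) {
    stop("`status_allowlist` must be non-empty", call. = FALSE)
  }
  structure(
    list(
      status_allowlist = status_allowlist,
      status_veto = unique(norm_lower(status_veto)),
      human_organism_labels = unique(norm_lower(human_organism_labels)),
      excluded_drug_names = unique(norm_lower(excluded_drug_names)),
      required_fields = required_fields
    ),
    class = "attrition_config"
  )
}

new_stage_record <- function(stage_name, catalog, keep, reason) {
  ids <- catalog$cards$drug_id
  exclusions <- tibble::tibble(
    drug_id = ids[!keep],
    reason = as.character(if (length(reason) == 1) {
      rep(reason, sum(!keep))
    } else {
      reason[!keep]
    })
  )
  structure(
    list(stage_name = stage_name, n_in = length(ids), n_out = sum(keep),
         exclusions = exclusions),
    class = "stage_record"
  )
}

#' @export
print.stage_record <- function(x, ...) {
  cat(sprintf("<stage %s> in=%d out=%d excluded=%d\n",
              x$stage_name, x$n_in, x$n_out, nrow(x$exclusions)))
  invisible(x)
}

stage_result <- function(catalog, keep, stage_name, reason) {
  list(
    retained = subset_catalog(catalog, catalog$cards$drug_id[keep]),
    stage = new_stage_record(stage_name, catalog, keep, reason)
  )
}

#' Attrition stage 1: retain small molecules only
#'
#' Biologics are excluded first: compared with small molecules they are
#' costly to obtain in trial quantities and frequently proprietary, which
#' makes them impractical repurposing candidates for an academic program.
#'
#' @param catalog a `drug_catalog`.
#' @return list with `retained` (the filtered catalog, order preserved) and
#'   `stage` (a `stage_record` with per-drug exclusions).
#' @export
filter_small_molecules <- function(catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  keep <- catalog$cards$drug_type == "small molecule"
  stage_result(catalog, keep, "type", "biotech")
}

#' Attrition stage 2: retain approved drugs
#'
#' A drug survives when its status labels intersect the configured allowlist
#' and contain no veto label; veto labels (withdrawn, illicit) dominate, so
#' a drug labelled both approved and withdrawn is excluded.
#'
#' @param catalog a `drug_catalog` (normally the output of
#'   [filter_small_molecules()]).
#' @param config an [attrition_config()].
#' @return list with `retained` and `stage`, as for
#'   [filter_small_molecules()].
#' @export
filter_approved <- function(catalog, config = attrition_config()) {
  stopifnot(inherits(catalog, "drug_catalog"),
            inherits(config, "attrition_config"))
  has_allow <- vapply(catalog$cards$status_labels, function(s) {
    any(s %in% config$status_allowlist)
  }, logical(1))
  has_veto <- vapply(catalog$cards$status_labels, function(s) {
    any(s %in% config$status_veto)
  }, logical(1))
  keep <- has_allow & !has_veto
  reason <- ifelse(has_veto, "vetoed-status", "not-approved")
  stage_result(catalog, keep, "status", reason)
}

#' Attrition stage 3: retain drugs with exactly one known-action target
#'
#' Keys on the number of targets with a known mechanism of action, not the
#' total target count: a drug with one known-action target plus additional
#' targets of unknown action is retained. This privileges selective agents
#' whose pharmacology maps to a single gene for the genomic join.
#'
#' @inheritParams filter_small_molecules
#' @return list with `retained` and `stage`.
#' @export
filter_single_known_action <- function(catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  keep <- catalog$cards$n_known_action_targets == 1L
  stage_result(catalog, keep, "known_action_count", "not-single-known-action")
}

#' Attrition stage 4: human-target, toxicity and completeness exclusions
#'
#' Applied to cards that each carry exactly one known-action target. A card
#' is excluded, with a distinct reason, when (in precedence order):
#' \describe{
#'   \item{`nonhuman-target`}{the known-action target's organism is not a
#'     configured human label (antibacterials, antivirals, antifungals,
#'     anthelmintics target nonhuman genomes and cannot be joined to human
#'     variant data);}
#'   \item{`blocklisted`}{the drug name is on the configured toxicity /
#'     DNA-damaging blocklist;}
#'   \item{`missing-field`}{any required field (name, action, gene symbol,
#'     status) is absent.}
#' }
#'
#' @inheritParams filter_approved
#' @return list with `retained` and `stage`.
#' @export
apply_exclusions <- function(catalog, config = attrition_config()) {
  stopifnot(inherits(catalog, "drug_catalog"),
            inherits(config, "attrition_config"))
  cards <- catalog$cards
  if (any(cards$n_known_action_targets != 1L)) {
    stop("apply_exclusions() expects cards with exactly one known-action ",
         "target; run filter_single_known_action() first", call. = FALSE)
  }
  ka <- catalog$targets[catalog$targets$known_action, ]
  ka <- ka[match(cards$drug_id, ka$drug_id), ]

  human <- !is.na(ka$organism) &
    norm_lower(ka$organism) %in% config$human_organism_labels
  blocked <- !is.na(cards$name) &
    norm_lower(cards$name) %in% config$excluded_drug_names
  missing_field <- rep(FALSE, nrow(cards))
  fieldmap <- list(
    name = cards$name,
    action = ka$action,
    gene_symbol = ka$gene_symbol,
    status = ifelse(lengths(cards$status_labels) > 0, "present", NA)
  )
  for (f in config$required_fields) {
    if (!f %in% names(fieldmap)) {
      stop("unknown required field: ", f, call. = FALSE)
    }
    missing_field <- missing_field | is.na(fieldmap[[f]])
  }

  reason <- rep(NA_character_, nrow(cards))
  reason[missing_field] <- "missing-field"
  reason[blocked] <- "blocklisted"
  reason[!human] <- "nonhuman-target"
  keep <- is.na(reason)
  reason[keep] <- "retained"  # placeholder, dropped by new_stage_record
  stage_result(catalog, keep, "exclusions", reason)
}

#' Consolidate drugs into target-action pairs
#'
#' Drugs of the same class (e.g. ACE inhibitors) are redundant for
#' target-level genomics: they perturb the same gene in the same direction.
#' Consolidation therefore groups each post-exclusion drug by the
#' (gene symbol, action) of its single known-action target, producing one
#' "target-action pair" per distinct combination. Gene symbols are
#' normalized uppercase, actions lowercase; distinct action words (e.g.
#' inhibitor vs antagonist) are never merged.
#'
#' The result is a partition: every input drug belongs to exactly one pair.
#'
#' @param catalog a `drug_catalog` whose cards all survived
#'   [apply_exclusions()].
#' @return tibble of class `target_action_pairs`, sorted by gene symbol then
#'   action, with columns `gene_symbol`, `action`, `n_members`,
#'   `member_drug_ids` (list), `member_names` (list), `target_names` (list).
#' @export
consolidate_pairs <- function(catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  cards <- catalog$cards
  if (nrow(cards) == 0) {
    out <- tibble::tibble(
      gene_symbol = character(), action = character(), n_members = integer(),
      member_drug_ids = list(), member_names = list(), target_names = list()
    )
    class(out) <- c("target_action_pairs", class(out))
    return(out)
  }
  ka <- catalog$targets[catalog$targets$known_action, ]
  ka <- ka[match(cards$drug_id, ka$drug_id), ]
  if (anyNA(ka$gene_symbol) || anyNA(ka$action)) {
    stop("cards with absent gene symbol or action reached consolidation; ",
         "they must be excluded by apply_exclusions()", call. = FALSE)
  }
  df <- tibble::tibble(
    gene_symbol = norm_gene(ka$gene_symbol),
    action = norm_lower(ka$action),
    drug_id = cards$drug_id,
    name = cards$name,
    target_name = ka$target_name
  )
  out <- df |>
    dplyr::group_by(.data$gene_symbol, .data$action) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      member_drug_ids = list(.data$drug_id),
      member_names = list(.data$name),
      target_names = list(unique(.data$target_name)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_symbol, .data$action)
  class(out) <- c("target_action_pairs", class(out))
  out
}

#' One-target-total rate of a post-exclusion drug set
#'
#' Percentage of drugs whose total target count is exactly one, among drugs
#' already restricted to a single known-action target. A high rate indicates
#' the known-action filter is nearly equivalent to requiring one total
#' target.
#'
#' @param catalog a `drug_catalog` (normally the post-exclusion set).
#' @return percentage in `[0, 100]`, rounded half-up to 2 decimals.
#' @export
one_target_total_rate <- function(catalog) {
  stopifnot(inherits(catalog, "drug_catalog"))
  n <- nrow(catalog$cards)
  if (n == 0) {
    stop("one-target-total rate is undefined for an empty drug set",
         call. = FALSE)
  }
  round_half_up(100 * sum(catalog$cards$n_targets == 1L) / n, 2)
}

#' Run the full pharmacodynamic attrition funnel
#'
#' Applies the four stages in order — drug type, approval status, known-action
#' target count, exclusions — then consolidates the survivors into
#' target-action pairs. Each stage's input is the previous stage's output, so
#' the per-stage survivor counts form an attrition funnel.
#'
#' @param catalog a parsed `drug_catalog`.
#' @param config an [attrition_config()].
#' @return object of class `funnel_result`: a list with
#'   \describe{
#'     \item{pairs}{`target_action_pairs` tibble from [consolidate_pairs()].}
#'     \item{report}{a `funnel_report`: `stages` tibble
#'       (`stage`, `n_in`, `n_out`, `n_excluded`) and `exclusions` tibble
#'       (`drug_id`, `stage`, `reason`).}
#'     \item{cards}{the post-exclusion `drug_catalog`.}
#'   }
#' @export
run_funnel <- function(catalog, config = attrition_config()) {
  stopifnot(inherits(catalog, "drug_catalog"))
  stages <- list()
  s1 <- filter_small_molecules(catalog)
  s2 <- filter_approved(s1$retained, config)
  s3 <- filter_single_known_action(s2$retained)
  s4 <- apply_exclusions(s3$retained, config)
  stages <- list(s1$stage, s2$stage, s3$stage, s4$stage)
  pairs <- consolidate_pairs(s4$retained)

  report <- structure(
    list(
      stages = tibble::tibble(
        stage = vapply(stages, `[[`, character(1), "stage_name"),
        n_in = vapply(stages, `[[`, integer(1), "n_in"),
        n_out = vapply(stages, `[[`, integer(1), "n_out"),
        n_excluded = vapply(stages, function(s) nrow(s$exclusions), integer(1))
      ),
      exclusions = dplyr::bind_rows(lapply(stages, function(s) {
        tibble::tibble(drug_id = s$exclusions$drug_id,
                       stage = s$stage_name,
                       reason = s$exclusions$reason)
      }))
    ),
    class = "funnel_report"
  )
  structure(
    list(pairs = pairs, report = report, cards = s4$retained),
    class = "funnel_result"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' @export
print.funnel_result <- function(x, ...) {
  print(x$report)
  cat(nrow(x$pairs), "target-action pairs from", nrow(x$cards$cards),
      "drugs\n")
  invisible(x)
}

#' Write a funnel report to tab-separated files
#'
#' Writes `funnel.tsv` (stage, n_in, n_out, n_excluded) and
#' `exclusions.tsv` (drug_id, stage, reason) into `dir`.
#'
#' @param report a `funnel_report` (from [run_funnel()]'s `$report`).
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  stopifnot(inherits(report, "funnel_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "funnel.tsv")
  f2 <- file.path(dir, "exclusions.tsv")
  data.table::fwrite(report$stages, f1, sep = "\t", quote = FALSE)
  data.table::fwrite(report$exclusions, f2, sep = "\t", quote = FALSE)
  invisible(c(f1, f2))
}
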