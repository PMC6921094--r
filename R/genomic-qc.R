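#' Configuration for exome-array variant quality control
#'
#' @param population population key selecting which `MAF_<population>` column
#'   of the annotation table supplies the minor allele frequency; defaults to
#'   `"white"`, the dominant demographic in typical exome-chip biobank
#'   cohorts, where the PheWAS power calibration behind the default MAF
#'   cutoff was established.
#' @param maf_min minimum minor allele frequency for a variant to remain
#'   eligible (default 0.001 = 0.1\%; below this, variants are "rare" rather
#'   than "minor" and phenome-wide association scans are underpowered).
#'   Strict: a variant with MAF exactly `maf_min` is retained.
#' @param missingness_max maximum genotyping missingness (default 0.05;
#'   higher missingness risks confounded phenotype associations under
#'   nonrandom missingness). Strict: exactly `missingness_max` is retained.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(population = "white", maf_min = 0.001,
                      missingness_max = 0.05) {
  if (!(is.numeric(maf_min) && maf_min > 0 && maf_min < 0.5)) {
    stop("`maf_min` must be in (0, 0.5)", call. = FALSE)
  }
  if (!(is.numeric(missingness_max) && missingness_max > 0 &&
        missingness_max < 1)) {
    stop("`missingness_max` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(population = population, maf_min = maf_min,
         missingness_max = missingness_max),
    class = "qc_config"
  )
}

variant_required_cols <- c("exmID", "rsID", "Gene", "Missingness",
                           "Mutation", "AlleleA", "AlleleB")

#' Load an exome-array variant annotation table
#'
#' Reads a tab-separated annotation table with columns `exmID`, `rsID`,
#' `Gene`, one or more `MAF_<population>` columns, `Missingness`, `Mutation`,
#' `AlleleA`, `AlleleB`. Literal `"NULL"` (or empty) rsID cells are
#' normalized to `NA`; gene symbols are normalized uppercase. Rows violating
#' the record invariants — any MAF outside `[0, 0.5]`, missingness outside
#' `[0, 1]`, alleles not two distinct bases from A/C/G/T — are collected as
#' rejects with reasons rather than aborting the load.
#'
#' @param path path to the TSV file.
#' @return object of class `variant_table`: list with `variants` (tibble of
#'   accepted rows), `rejects` (tibble with a `reason` column), and
#'   `populations` (the population keys found).
#' @export
load_variant_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = NULL, showProgress = FALSE)
  missing_cols <- setdiff(variant_required_cols, names(dt))
  if (length(missing_cols) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  maf_cols <- grep("^MAF_", names(dt), value = TRUE)
  if (length(maf_cols) == 0) {
    stop("variant table must contain at least one MAF_<population> column",
         call. = FALSE)
  }

  v <- tibble::as_tibble(dt)
  v$rsID <- na_if_null(as.character(v$rsID))
  v$Gene <- norm_gene(v$Gene)
  v$AlleleA <- toupper(trimws(v$AlleleA))
  v$AlleleB <- toupper(trimws(v$AlleleB))

  bad_maf <- rep(FALSE, nrow(v))
  for (mc in maf_cols) {
    m <- v[[mc]]
    bad_maf <- bad_maf | (!is.na(m) & (m < 0 | m > 0.5))
  }
  bad_miss <- is.na(v$Missingness) | v$Missingness < 0 | v$Missingness > 1
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(v$AlleleA %in% bases) | !(v$AlleleB %in% bases) |
    v$AlleleA == v$AlleleB

  reason <- rep(NA_character_, nrow(v))
  reason[bad_allele] <- "invalid-alleles"
  reason[bad_miss] <- "missingness-out-of-range"
  reason[bad_maf] <- "maf-out-of-range"
  ok <- is.na(reason)

  structure(
    list(
      variants = v[ok, ],
      rejects = tibble::tibble(exmID = v$exmID[!ok], reason = reason[!ok]),
      populations = sub("^MAF_", "", maf_cols)
    ),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table>", nrow(x$variants), "variants |",
      nrow(x$rejects), "rejected rows | populations:",
      paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' Apply eligibility screens to exome-array variants
#'
#' A variant is removed iff its rsID is absent (it cannot be verified against
#' dbSNP), or its genotyping missingness exceeds `missingness_max`, or its
#' MAF in the configured population falls below `maf_min`. Both numeric
#' screens are strict inequalities: boundary values (missingness exactly
#' 0.05, MAF exactly 0.001 at the defaults) are retained. A variant failing
#' several screens is counted once, under the first failing rule in the
#' order rsID, missingness, MAF. A record whose MAF is absent for the
#' configured population is removed with reason `missing-population`.
#'
#' @param variants a `variant_table` from [load_variant_table()], or a
#'   tibble shaped like its `variants` component.
#' @param config a [qc_config()].
#' @return object of class `qc_result`: list with `eligible` (tibble of
#'   surviving variants), `report` (tibble `reason`, `n_removed`), `n_in`,
#'   `n_out`.
#' @export
qc_filter <- function(variants, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  if (inherits(variants, "variant_table")) variants <- variants$variants
  if (inherits(variants, "qc_result")) variants <- variants$eligible
  maf_col <- paste0("MAF_", config$population)
  if (!maf_col %in% names(variants)) {
    stop("variant table has no column '", maf_col,
         "' for the configured population", call. = FALSE)
  }
  maf <- variants[[maf_col]]
  reason <- rep(NA_character_, nrow(variants))
  reason[is.na(variants$rsID)] <- "null-rsid"
  sel <- is.na(reason) & variants$Missingness > config$missingness_max
  reason[sel] <- "high-missingness"
  sel <- is.na(reason) & !is.na(maf) & maf < config$maf_min
  reason[sel] <- "low-maf"
  reason[is.na(reason) & is.na(maf)] <- "missing-population"

  keep <- is.na(reason)
  reasons_all <- c("null-rsid", "high-missingness", "low-maf",
                   "missing-population")
  counts <- table(factor(reason, levels = reasons_all))
  structure(
    list(
      eligible = variants[keep, ],
      report = tibble::tibble(reason = reasons_all,
                              n_removed = as.integer(counts)),
      n_in = nrow(variants),
      n_out = sum(keep)
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>", x$n_in, "variants in,", x$n_out, "eligible\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Write QC outputs to tab-separated files
#'
#' Writes `eligible_variants.tsv` and `qc_report.tsv` (reason, n_removed)
#' into `dir`.
#'
#' @param qc a `qc_result` from [qc_filter()].
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  stopifnot(inherits(qc, "qc_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "eligible_variants.tsv")
  f2 <- file.path(dir, "qc_report.tsv")
  data.table::fwrite(qc$eligible, f1, sep = "\t", quote = FALSE, na = "")
  data.table::fwrite(qc$report, f2, sep = "\t", quote = FALSE)
  invisible(c(f1, f2))
}
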