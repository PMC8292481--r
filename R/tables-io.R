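#' Read a candidate-variant frequency table
#'
#' Expects a TSV with one row per variant and columns `rsid`, `gene`,
#' `carrier_maf` (frequency in the c.1100delC-carrier cohort), `fbc_maf`
#' (familial breast-cancer cohort), `crc_maf` (healthy controls), and
#' optionally `chrom`, any number of reference-database frequency columns
#' prefixed `ref_`, per-group call-rate columns prefixed `call_rate_`, and a
#' logical `driver_flag` (manual gene-function curation, pass-through).
#' Additional columns are retained untouched. Missing cells are `NA`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `variant_table`.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  need <- c("rsid", "gene", "carrier_maf", "fbc_maf", "crc_maf")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(dt)
  fcols <- c("carrier_maf", "fbc_maf", "crc_maf",
             grep("^ref_", names(df), value = TRUE),
             grep("^call_rate_", names(df), value = TRUE))
  for (cc in fcols) {
    v <- df[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("column %s holds values outside [0, 1]", cc), call. = FALSE)
    }
  }
  if (!"driver_flag" %in% names(df)) df$driver_flag <- rep(NA, nrow(df))
  df$driver_flag <- as.logical(df$driver_flag)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Column helpers for a variant table
#'
#' `reference_maf_columns()` and `call_rate_columns()` name the columns of a
#' [read_variant_table()] data frame holding reference-database frequencies
#' and per-group call rates.
#'
#' @param v A `variant_table`.
#' @return Character vector of column names.
#' @export
reference_maf_columns <- function(v) grep("^ref_", names(v), value = TRUE)

#' @rdname reference_maf_columns
#' @export
call_rate_columns <- function(v) grep("^call_rate_", names(v), value = TRUE)

#' Read a case-only strata table
#'
#' Expects a TSV with columns `stratum`, `noncarrier_counts` and
#' `carrier_counts`, the two count columns holding genotype triplets in the
#' published dash notation (see [parse_genotype_triplet()]). Extra columns
#' (e.g. transcribed printed statistics) are retained.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the raw columns.
#' @seealso [as_stratum_pairs()]
#' @export
read_strata_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  need <- c("stratum", "noncarrier_counts", "carrier_counts")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("strata table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Convert a strata table to a list of stratum pairs
#'
#' @param df A data frame as returned by [read_strata_table()].
#' @return A named list of [stratum_pair()] objects.
#' @export
as_stratum_pairs <- function(df) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    stratum_pair(df$stratum[i],
                 exposed = parse_genotype_triplet(df$carrier_counts[i]),
                 unexposed = parse_genotype_triplet(df$noncarrier_counts[i]))
  })
  stats::setNames(out, df$stratum)
}

.fixture <- function(name) {
  path <- system.file("extdata", name, package = "chek2mod", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("packaged fixture %s not found", name), call. = FALSE)
  }
  path
}

#' Packaged fixture: discovery-phase candidate variants
#'
#' The 14 non-synonymous candidate variants selected in the discovery phase
#' of the published c.1100delC modifier search, transcribed with their
#' per-cohort minor-allele frequencies (carrier cohort, familial
#' breast-cancer cohort, healthy-control cohort), four reference-database
#' frequencies, and the printed frequency-ratio columns
#' (`printed_ratio_crc`, `printed_ratio_fbc`) for replication checks.
#' One printed cell is corrected from an evident misprint; see the package
#' vignette and the `note` column.
#'
#' @return A `variant_table` with 14 rows.
#' @export
chek2_candidate_table <- function() {
  read_variant_table(.fixture("candidate_variants.tsv"))
}

#' Packaged fixture: case-only strata for the recessive candidate
#'
#' Per-study genotype counts of the recessive modifier candidate
#' (rs16897117) among breast-cancer cases, split by c.1100delC carrier
#' status, as published for two Swedish and four Finnish strata, together
#' with the printed case-only odds ratios, confidence intervals and
#' p-values. The `note` column marks cells with known transcription or
#' printing inconsistencies (documented in the vignette).
#'
#' @return A `data.frame` with one row per stratum plus a `Combined` row
#'   holding only the printed pooled statistics.
#' @export
chek2_caseonly_strata <- function() {
  read_strata_table(.fixture("caseonly_strata.tsv"))
}

#' Packaged fixture: validation-phase genotype counts
#'
#' Genotype counts (wild type / heterozygous / homozygous) for the 11
#' validated candidate variants in four cohorts (c.1100delC carriers,
#' familial breast cancer, sporadic breast cancer, healthy controls),
#' transcribed with the printed allele frequency, allelic odds ratio, 95%
#' confidence interval and p-value of each cohort-vs-controls comparison.
#' The `note` column marks known printing inconsistencies.
#'
#' @return A `data.frame` of class `validation_counts`, 44 rows
#'   (11 variants x 4 cohorts).
#' @export
chek2_validation_counts <- function() {
  df <- as.data.frame(data.table::fread(.fixture("validation_counts.tsv"),
                                        sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  class(df) <- c("validation_counts", "data.frame")
  df
}
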