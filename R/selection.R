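#' Discovery-phase selection criteria
#'
#' Thresholds for the candidate-variant filters. Defaults follow the
#' published discovery design: a carrier-vs-healthy-controls frequency ratio
#' of at least 2.0 and/or a carrier-vs-familial-cases ratio of at least 1.5;
#' a carrier allele frequency more than 30% above every available reference
#' database (strict inequality); a genotype call rate of at least 65% in
#' every study group (inclusive); and an optional manual gene-function flag
#' which is pass-through literature curation, disabled by default.
#'
#' All ratio comparisons are made on unrounded values.
#'
#' @param ratio_vs_controls Carrier/controls frequency-ratio threshold
#'   (`>=`, default 2.0).
#' @param ratio_vs_familial Carrier/familial frequency-ratio threshold
#'   (`>=`, default 1.5).
#' @param reference_enrichment Multiplicative reference-enrichment factor
#'   (strict `>`, default 1.3, i.e. "more than 30% higher").
#' @param min_call_rate Minimum per-group call rate (inclusive, default 0.65).
#' @param require_driver_flag Require the curated driver flag? Default FALSE.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(ratio_vs_controls = 2.0,
                               ratio_vs_familial = 1.5,
                               reference_enrichment = 1.3,
                               min_call_rate = 0.65,
                               require_driver_flag = FALSE) {
  stopifnot(ratio_vs_controls > 0, ratio_vs_familial > 0,
            reference_enrichment > 0,
            min_call_rate >= 0, min_call_rate <= 1,
            is.logical(require_driver_flag))
  structure(list(ratio_vs_controls = ratio_vs_controls,
                 ratio_vs_familial = ratio_vs_familial,
                 reference_enrichment = reference_enrichment,
                 min_call_rate = min_call_rate,
                 require_driver_flag = require_driver_flag),
            class = "selection_criteria")
}

#' Allele-frequency ratio
#'
#' Vectorized ratio of two frequencies with the degenerate cases encoded in
#' the return value: a positive numerator over a zero denominator is `Inf`
#' (passes any threshold), `0/0` is `NaN` (fails all thresholds).
#'
#' @param num,den Non-negative frequencies.
#' @return `num / den` with the conventions above.
#' @export
maf_ratio <- function(num, den) {
  stopifnot(all(num >= 0, na.rm = TRUE), all(den >= 0, na.rm = TRUE))
  ifelse(den == 0 & num == 0, NaN, num / den)
}

#' Frequency-ratio criterion
#'
#' A variant passes if its carrier/controls frequency ratio reaches
#' `ratio_vs_controls` *or* its carrier/familial ratio reaches
#' `ratio_vs_familial`. Missing frequencies make the criterion fail with the
#' reason recorded.
#'
#' @param v A `variant_table` (or any data frame with `carrier_maf`,
#'   `fbc_maf`, `crc_maf` columns).
#' @param criteria A [selection_criteria()] object.
#' @return A data frame with columns `ratio_crc`, `ratio_fbc`, `pass`,
#'   `reason` (NA when evaluable), one row per variant.
#' @export
passes_frequency_criteria <- function(v, criteria = selection_criteria()) {
  ratio_crc <- maf_ratio(v$carrier_maf, v$crc_maf)
  ratio_fbc <- maf_ratio(v$carrier_maf, v$fbc_maf)
  missing <- is.na(v$carrier_maf) | is.na(v$fbc_maf) | is.na(v$crc_maf)
  pass <- !missing &
    ((!is.nan(ratio_crc) & ratio_crc >= criteria$ratio_vs_controls) |
     (!is.nan(ratio_fbc) & ratio_fbc >= criteria$ratio_vs_familial))
  data.frame(ratio_crc = ratio_crc, ratio_fbc = ratio_fbc,
             pass = pass,
             reason = ifelse(missing, "missing frequency", NA_character_))
}

#' Reference-database enrichment criterion
#'
#' A variant passes if the carrier allele frequency strictly exceeds
#' `reference_enrichment` times *every* reference frequency present in the
#' table; absent reference cells are skipped. A variant with no reference
#' value at all is not evaluable and handled per `on_missing`.
#'
#' @inheritParams passes_frequency_criteria
#' @param on_missing Verdict when no reference frequency is present
#'   (default `FALSE`).
#' @return Logical vector, one verdict per variant.
#' @export
passes_reference_enrichment <- function(v, criteria = selection_criteria(),
                                        on_missing = FALSE) {
  cols <- reference_maf_columns(v)
  vapply(seq_len(nrow(v)), function(i) {
    refs <- unlist(v[i, cols, drop = TRUE], use.names = FALSE)
    refs <- refs[!is.na(refs)]
    if (!length(refs)) return(on_missing)
    carrier <- v$carrier_maf[i]
    if (is.na(carrier)) return(FALSE)
    all(carrier > criteria$reference_enrichment * refs)
  }, logical(1L))
}

#' Call-rate criterion
#'
#' Passes if every per-group call rate present reaches `min_call_rate`
#' (inclusive: "65%, or more"). A variant with no call-rate value at all is
#' not evaluable and handled per `on_missing`.
#'
#' @inheritParams passes_reference_enrichment
#' @return Logical vector, one verdict per variant.
#' @export
passes_call_rate <- function(v, criteria = selection_criteria(),
                             on_missing = FALSE) {
  cols <- call_rate_columns(v)
  vapply(seq_len(nrow(v)), function(i) {
    cr <- unlist(v[i, cols, drop = TRUE], use.names = FALSE)
    cr <- cr[!is.na(cr)]
    if (!length(cr)) return(on_missing)
    all(cr >= criteria$min_call_rate)
  }, logical(1L))
}

#' Run the discovery-phase candidate filters
#'
#' Evaluates, per variant: the frequency-ratio criterion (always), the
#' reference-enrichment criterion (when the table has `ref_` columns), the
#' call-rate criterion (when the table has `call_rate_` columns) and the
#' curated driver flag (when `require_driver_flag` is set). The overall
#' verdict is the conjunction of the evaluated criteria; input ordering is
#' preserved.
#'
#' @inheritParams passes_frequency_criteria
#' @return An object of class `selection_report`: the input table plus
#'   columns `ratio_crc`, `ratio_fbc`, `pass_frequency`, and (when
#'   evaluated) `pass_reference`, `pass_call_rate`, `pass_driver`, plus the
#'   conjunction `selected`; attribute `n_selected` carries the summary
#'   count.
#' @export
select_candidates <- function(v, criteria = selection_criteria()) {
  out <- as.data.frame(v)
  if (nrow(out) == 0L) {
    out$ratio_crc <- numeric(0); out$ratio_fbc <- numeric(0)
    out$pass_frequency <- logical(0); out$selected <- logical(0)
    return(structure(out, n_selected = 0L,
                     class = c("selection_report", "data.frame")))
  }
  freq <- passes_frequency_criteria(v, criteria)
  out$ratio_crc <- freq$ratio_crc
  out$ratio_fbc <- freq$ratio_fbc
  out$pass_frequency <- freq$pass
  selected <- freq$pass
  if (length(reference_maf_columns(v))) {
    out$pass_reference <- passes_reference_enrichment(v, criteria)
    selected <- selected & out$pass_reference
  }
  if (length(call_rate_columns(v))) {
    out$pass_call_rate <- passes_call_rate(v, criteria)
    selected <- selected & out$pass_call_rate
  }
  if (isTRUE(criteria$require_driver_flag)) {
    out$pass_driver <- !is.na(v$driver_flag) & v$driver_flag
    selected <- selected & out$pass_driver
  }
  out$selected <- selected
  structure(out, n_selected = sum(selected),
            class = c("selection_report", "data.frame"))
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> ", attr(x, "n_selected"), " of ", nrow(x),
      " variants selected\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Recessive homozygote screen
#'
#' Flags variants with at least `min_hom_carriers` alternate homozygotes in
#' the carrier group and *zero* alternate homozygotes in every comparison
#' group. Missing calls are ignored. This is the discovery screen that
#' surfaced a single recessive candidate (3 homozygous carriers of 28, none
#' among 98 comparison samples) in the published search.
#'
#' The default `min_hom_carriers = 2` keeps the screen meaningful at the
#' discovery scale (about 28 carriers) while remaining configurable down
#' to 1.
#'
#' @param m A [genotype_matrix()].
#' @param carrier_group Label of the carrier group.
#' @param comparison_groups Labels of the comparison groups.
#' @param min_hom_carriers Minimum carrier homozygote count (default 2).
#' @return A data frame with one row per flagged variant: `variant`,
#'   `hom_carriers`, and the per-comparison-group homozygote counts (all 0
#'   by construction).
#' @export
recessive_screen <- function(m, carrier_group, comparison_groups,
                             min_hom_carriers = 2L) {
  stopifnot(inherits(m, "genotype_matrix"), min_hom_carriers >= 1L)
  groups <- c(carrier_group, comparison_groups)
  missing <- setdiff(groups, unique(m$group_of))
  if (length(missing)) {
    stop(sprintf("unknown group(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  hom_in <- function(group) {
    idx <- m$group_of == group
    colSums(m$calls[idx, , drop = FALSE] == 2L, na.rm = TRUE)
  }
  hom_car <- hom_in(carrier_group)
  hom_cmp <- vapply(comparison_groups, hom_in,
                    numeric(length(m$variant_ids)))
  if (is.null(dim(hom_cmp))) hom_cmp <- matrix(hom_cmp, nrow = 1L)
  flagged <- hom_car >= min_hom_carriers & rowSums(hom_cmp > 0) == 0
  data.frame(variant = m$variant_ids[flagged],
             hom_carriers = unname(hom_car[flagged]),
             row.names = NULL)
}
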