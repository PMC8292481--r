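#' Genotype counts for one biallelic variant in one group
#'
#' The basic container of the package: the number of reference homozygotes,
#' heterozygotes and alternate homozygotes observed for a single biallelic
#' variant in a single group of individuals.
#'
#' @param hom_ref,het,hom_alt Non-negative integer counts of reference
#'   homozygotes, heterozygotes and alternate homozygotes.
#' @return An object of class `genotype_counts`.
#' @examples
#' g <- genotype_counts(549, 138, 16)
#' gt_total(g)
#' allele_frequency(g)
#' @export
genotype_counts <- function(hom_ref, het, hom_alt) {
  x <- c(hom_ref = hom_ref, het = het, hom_alt = hom_alt)
  if (length(x) != 3L || anyNA(x)) {
    stop("genotype_counts() needs three non-missing counts", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(hom_ref = as.integer(hom_ref), het = as.integer(het),
         hom_alt = as.integer(hom_alt)),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("<genotype_counts> ", format_genotype_triplet(x),
      "  (n = ", gt_total(x), ", alt freq = ",
      if (gt_total(x) > 0) signif(allele_frequency(x), 4) else NA, ")\n",
      sep = "")
  invisible(x)
}

#' Total number of genotyped individuals
#' @param g A [genotype_counts()] object.
#' @return Integer total.
#' @export
gt_total <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  g$hom_ref + g$het + g$hom_alt
}

#' Alternate / reference allele counts
#'
#' `alt_alleles()` is `het + 2 * hom_alt`; `ref_alleles()` is
#' `2 * hom_ref + het`. Their sum is always twice the genotyped total.
#'
#' @inheritParams gt_total
#' @return Integer allele count.
#' @export
alt_alleles <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  g$het + 2L * g$hom_alt
}

#' @rdname alt_alleles
#' @export
ref_alleles <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  2L * g$hom_ref + g$het
}

#' Alternate-allele frequency
#'
#' @inheritParams gt_total
#' @return The alternate-allele frequency `(het + 2 hom_alt) / (2 n)`,
#'   a value in \[0, 1\]. Stored at full precision; round only for display.
#' @export
allele_frequency <- function(g) {
  n <- gt_total(g)
  if (n == 0L) {
    stop("allele frequency undefined for an empty group", call. = FALSE)
  }
  alt_alleles(g) / (2 * n)
}

# dash dialect: published count triplets use U+2013; plain hyphen accepted too
.triplet_dashes <- "[–—-]"

#' Parse a genotype-count triplet string
#'
#' Count triplets such as `"549–138–16"` (hom ref - het - hom alt)
#' are the notation used in published per-cohort genotype tables. Both the
#' en dash (as printed) and the ASCII hyphen are accepted as separators;
#' [format_genotype_triplet()] emits the en dash.
#'
#' @param text A single triplet string.
#' @return A [genotype_counts()] object.
#' @examples
#' parse_genotype_triplet("549-138-16")
#' @export
parse_genotype_triplet <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("expected a single triplet string", call. = FALSE)
  }
  parts <- trimws(strsplit(text, .triplet_dashes, perl = TRUE)[[1L]])
  if (length(parts) != 3L) {
    stop(sprintf("malformed genotype triplet %s: expected 3 dash-separated fields, got %d",
                 dQuote(text), length(parts)), call. = FALSE)
  }
  bad <- !grepl("^[0-9]+$", parts)
  if (any(bad)) {
    stop(sprintf("non-integer token %s in genotype triplet %s",
                 dQuote(parts[bad][1L]), dQuote(text)), call. = FALSE)
  }
  n <- as.numeric(parts)
  genotype_counts(n[1L], n[2L], n[3L])
}

#' @rdname parse_genotype_triplet
#' @param g A [genotype_counts()] object.
#' @param dash Separator used when re-serializing (en dash by default).
#' @export
format_genotype_triplet <- function(g, dash = "–") {
  stopifnot(inherits(g, "genotype_counts"))
  paste(g$hom_ref, g$het, g$hom_alt, sep = dash)
}

#' One cohort stratum: genotype counts in carriers and non-carriers
#'
#' A labelled pair of [genotype_counts()] for a modifier variant, split by
#' carrier status for the primary risk allele (e.g. c.1100delC carriers vs
#' non-carriers among breast-cancer cases of one study).
#'
#' @param label Stratum label, e.g. `"SWEA1"`.
#' @param exposed Counts in the carrier (exposed) group.
#' @param unexposed Counts in the non-carrier group.
#' @return An object of class `stratum_pair`.
#' @export
stratum_pair <- function(label, exposed, unexposed) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(exposed, "genotype_counts"),
            inherits(unexposed, "genotype_counts"))
  structure(list(stratum_label = label, exposed = exposed,
                 unexposed = unexposed),
            class = "stratum_pair")
}

#' @export
print.stratum_pair <- function(x, ...) {
  cat("<stratum_pair> ", x$stratum_label,
      "\n  carriers:     ", format_genotype_triplet(x$exposed),
      "\n  non-carriers: ", format_genotype_triplet(x$unexposed), "\n", sep = "")
  invisible(x)
}
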