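#' Per-individual genotype matrix with group labels
#'
#' Stands in for the exome-sequenced discovery cohorts: an integer matrix of
#' genotype codes (0 = hom ref, 1 = het, 2 = hom alt, `NA` = missing call),
#' samples in rows, variants in columns, plus a group label per sample.
#' Dosage coding is derived on the fly, never stored.
#'
#' @param calls Integer matrix (samples x variants) with values in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids,variant_ids Character vectors naming rows/columns;
#'   default to the dimnames of `calls`.
#' @param group_of Character vector of group labels, one per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            variant_ids = colnames(calls), group_of) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids) || is.null(variant_ids)) {
    stop("sample and variant identifiers are required", call. = FALSE)
  }
  if (length(sample_ids) != nrow(calls) || length(variant_ids) != ncol(calls)) {
    stop("dimension mismatch between calls and identifiers", call. = FALSE)
  }
  if (length(group_of) != nrow(calls)) {
    stop("group_of must have one label per sample", call. = FALSE)
  }
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("genotype codes must be 0, 1, 2 or missing", call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(sample_ids, variant_ids)
  structure(list(calls = calls, sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids),
                 group_of = stats::setNames(as.character(group_of), sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      length(x$variant_ids), " variants; groups: ",
      paste(sprintf("%s (%d)", names(table(x$group_of)), table(x$group_of)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tally genotype counts for one variant in one group
#'
#' Missing calls are excluded from the counts; the call rate is the fraction
#' of the group's samples with a non-missing call.
#'
#' @param m A [genotype_matrix()].
#' @param variant Variant identifier.
#' @param group Group label.
#' @return A list with elements `counts` ([genotype_counts()]) and
#'   `call_rate`.
#' @export
counts_from_matrix <- function(m, variant, group) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (!variant %in% m$variant_ids) {
    stop(sprintf("unknown variant %s", dQuote(variant)), call. = FALSE)
  }
  if (!group %in% m$group_of) {
    stop(sprintf("unknown group %s", dQuote(group)), call. = FALSE)
  }
  idx <- which(m$group_of == group)
  calls <- m$calls[idx, variant]
  called <- calls[!is.na(calls)]
  list(
    counts = genotype_counts(sum(called == 0L), sum(called == 1L),
                             sum(called == 2L)),
    call_rate = if (length(idx)) length(called) / length(idx) else NaN
  )
}

#' Read a per-individual genotype matrix
#'
#' Two formats are supported. `"tsv"`: first column `sample_id`, second
#' column `group`, remaining columns one variant each with codes 0/1/2 and
#' `NA` for missing. `"vcf"`: a standard VCF with GT calls; only biallelic
#' SNV records are ingested, multiallelic records are skipped with a warning
#' reporting how many were dropped (requires the VariantAnnotation package).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @param group_of For VCF input (which carries no group labels): named
#'   character vector mapping sample id to group; defaults to a single
#'   group `"all"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), group_of = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1:2))
    need <- c("sample_id", "group")
    if (!all(need %in% names(dt))) {
      stop("genotype TSV must start with columns sample_id and group",
           call. = FALSE)
    }
    vcols <- setdiff(names(dt), need)
    calls <- as.matrix(dt[, vcols, with = FALSE])
    if (!all(is.na(calls) | calls %in% c(0, 1, 2))) {
      stop("genotype TSV contains codes outside {0, 1, 2, NA}", call. = FALSE)
    }
    genotype_matrix(calls, sample_ids = dt$sample_id, variant_ids = vcols,
                    group_of = dt$group)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("VCF input requires the VariantAnnotation package", call. = FALSE)
    }
    vcf <- VariantAnnotation::readVcf(path)
    nalt <- lengths(VariantAnnotation::alt(vcf))
    multi <- nalt != 1L
    if (any(multi)) {
      warning(sprintf("skipped %d multiallelic record(s)", sum(multi)),
              call. = FALSE)
      vcf <- vcf[!multi]
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    code <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      out <- rep(NA_integer_, length(x))
      out[x %in% c("0/0")] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x %in% c("1/1")] <- 2L
      out
    }
    coded <- matrix(code(as.vector(gt)), nrow = nrow(gt),
                    dimnames = dimnames(gt))
    calls <- t(coded)                       # samples x variants
    samples <- colnames(gt)
    if (is.null(group_of)) {
      group_of <- stats::setNames(rep("all", length(samples)), samples)
    }
    genotype_matrix(calls, sample_ids = samples, variant_ids = rownames(gt),
                    group_of = unname(group_of[samples]))
  }
}

#' Write a genotype matrix to TSV
#'
#' Inverse of `read_genotypes(format = "tsv")`.
#'
#' @param m A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(m, path) {
  stopifnot(inherits(m, "genotype_matrix"))
  dt <- data.table::data.table(sample_id = m$sample_ids,
                               group = unname(m$group_of[m$sample_ids]))
  dt <- cbind(dt, data.table::as.data.table(m$calls))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
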