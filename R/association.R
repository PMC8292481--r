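#' A 2x2 contingency table
#'
#' Rows are groups (exposed first), columns are allele-or-carriage
#' categories with the alternate/exposed category first: `a` and `b` are the
#' first group's alt and ref cells, `c` and `d` the reference group's.
#'
#' @param a,b,c,d Non-negative integer cells.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("two_by_two() cells must be non-negative integers", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(group = c("exposed", "reference"),
                              category = c("alt", "ref")))
  cat("<two_by_two>\n"); print(m)
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2,
         dimnames = list(c("exposed", "reference"), c("alt", "ref")))
}

.tbt_cells <- function(t) c(t$a, t$b, t$c, t$d)

.check_nonempty <- function(g, what) {
  if (gt_total(g) == 0L) {
    stop(sprintf("empty %s group: cannot build table", what), call. = FALSE)
  }
}

#' Allelic 2x2 table from two genotype-count groups
#'
#' Counts alleles, treating the two alleles of one person as independent
#' (the convention of allele-frequency association testing; see the
#' vignette for the assumption this entails).
#'
#' @param g1,g2 [genotype_counts()] for the exposed and reference group.
#' @return A [two_by_two()] with `a` = g1 alt alleles, `b` = g1 ref
#'   alleles, `c`/`d` the same for g2.
#' @export
allelic_table <- function(g1, g2) {
  .check_nonempty(g1, "exposed"); .check_nonempty(g2, "reference")
  two_by_two(alt_alleles(g1), ref_alleles(g1),
             alt_alleles(g2), ref_alleles(g2))
}

#' Dominant (carriage) 2x2 table from two genotype-count groups
#'
#' Exposure to the variant is carriage of at least one alternate allele.
#'
#' @inheritParams allelic_table
#' @return A [two_by_two()] with `a` = g1 carriers (het + hom alt),
#'   `b` = g1 hom ref, `c`/`d` the same for g2.
#' @export
dominant_table <- function(g1, g2) {
  .check_nonempty(g1, "exposed"); .check_nonempty(g2, "reference")
  two_by_two(g1$het + g1$hom_alt, g1$hom_ref,
             g2$het + g2$hom_alt, g2$hom_ref)
}

#' Recessive 2x2 table from two genotype-count groups
#'
#' Exposure is homozygous carriage of the alternate allele.
#'
#' @inheritParams allelic_table
#' @return A [two_by_two()].
#' @export
recessive_table <- function(g1, g2) {
  .check_nonempty(g1, "exposed"); .check_nonempty(g2, "reference")
  two_by_two(g1$hom_alt, g1$hom_ref + g1$het,
             g2$hom_alt, g2$hom_ref + g2$het)
}

# Haldane-Anscombe: +0.5 to every cell when any cell is zero.
.ha_correct <- function(t) {
  cells <- .tbt_cells(t)
  if (any(cells == 0)) {
    list(cells = cells + 0.5, applied = TRUE)
  } else {
    list(cells = cells, applied = FALSE)
  }
}

.check_defined_or <- function(t) {
  # two zeros in one row or one column leave the OR undefined even after
  # correction in any meaningful sense
  if ((t$a == 0 && t$b == 0) || (t$c == 0 && t$d == 0) ||
      (t$a == 0 && t$c == 0) || (t$b == 0 && t$d == 0)) {
    stop("odds ratio undefined: a full row or column of the table is zero",
         call. = FALSE)
  }
}

#' Sample odds ratio
#'
#' `(a d) / (b c)`, with the Haldane-Anscombe +0.5 correction applied to all
#' four cells first whenever the table contains a zero (flagged in the
#' `"correction_applied"` attribute).
#'
#' @param t A [two_by_two()].
#' @return The odds-ratio estimate with attribute `correction_applied`.
#' @export
sample_or <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  .check_defined_or(t)
  h <- .ha_correct(t)
  x <- h$cells
  structure(x[1] * x[4] / (x[2] * x[3]), correction_applied = h$applied)
}

#' Woolf confidence interval for an odds ratio
#'
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile at `(1 + level) / 2`. The Haldane-Anscombe
#' correction is applied first when the table contains a zero cell.
#'
#' @param t A [two_by_two()].
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` with attribute `correction_applied`.
#' @export
woolf_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"), level > 0, level < 1)
  .check_defined_or(t)
  h <- .ha_correct(t)
  x <- h$cells
  or <- x[1] * x[4] / (x[2] * x[3])
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(sum(1 / x))
  structure(exp(log(or) + c(-1, 1) * z * se),
            names = c("low", "high"), correction_applied = h$applied)
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` referred to chi-square with one
#' degree of freedom, without continuity correction (required to reproduce
#' the published DeFinetti-style p-values).
#'
#' @param t A [two_by_two()].
#' @return The p-value.
#' @export
pearson_chi2_p <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square test undefined: zero margin", call. = FALSE)
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# hypergeometric support and log-probabilities of the conditional
# distribution of cell a given all margins, at log odds ratio lpsi
.cond_support <- function(t) {
  m1 <- t$a + t$b; k <- t$a + t$c; m2 <- t$c + t$d
  seq.int(max(0, k - m2), min(k, m1))
}

.cond_logw <- function(t, lpsi) {
  m1 <- t$a + t$b; m2 <- t$c + t$d; k <- t$a + t$c
  supp <- .cond_support(t)
  stats::dhyper(supp, m1, m2, k, log = TRUE) + supp * lpsi
}

.cond_probs <- function(t, lpsi) {
  lw <- .cond_logw(t, lpsi)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Two-sided Fisher exact p-value
#'
#' The probability-mass rule: with all margins fixed, the p-value is the sum
#' of hypergeometric probabilities of every table as likely as or less
#' likely than the observed one (the convention of the standard R
#' machinery for 2x2 tables).
#'
#' @param t A [two_by_two()].
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  supp <- .cond_support(t)
  probs <- stats::dhyper(supp, t$a + t$b, t$c + t$d, t$a + t$c)
  pobs <- probs[match(t$a, supp)]
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= pobs * (1 + 1e-07)]))
}

#' Conditional maximum-likelihood odds ratio with exact CI
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of
#' cell `a` conditional on all margins, with the exact confidence interval
#' obtained by inverting the conditional tail probabilities at
#' `(1 - level) / 2` each side. This is the sparse-table machinery used by
#' the exact 2x2 ecosystem in R; when `a` sits on the boundary of its
#' support the estimate is 0 or `Inf` with a one-sided interval.
#'
#' @param t A [two_by_two()].
#' @param level Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`.
#' @export
conditional_mle_or <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"), level > 0, level < 1)
  supp <- .cond_support(t)
  if (length(supp) < 2L) {
    stop("conditional odds ratio undefined: degenerate margins", call. = FALSE)
  }
  a <- t$a
  alpha <- (1 - level) / 2
  bound <- 45                      # |log psi| search bound, exp(45) ~ 3.5e19
  cond_mean <- function(lpsi) sum(supp * .cond_probs(t, lpsi))
  tail_ge <- function(lpsi) sum(.cond_probs(t, lpsi)[supp >= a])
  tail_le <- function(lpsi) sum(.cond_probs(t, lpsi)[supp <= a])

  estimate <- if (a == min(supp)) {
    0
  } else if (a == max(supp)) {
    Inf
  } else {
    exp(stats::uniroot(function(l) cond_mean(l) - a, c(-bound, bound),
                       tol = 1e-10)$root)
  }
  ci_low <- if (a == min(supp)) {
    0
  } else {
    # P(A >= a | psi) increases with psi; lower limit where it equals alpha
    exp(stats::uniroot(function(l) tail_ge(l) - alpha, c(-bound, bound),
                       tol = 1e-10)$root)
  }
  ci_high <- if (a == max(supp)) {
    Inf
  } else {
    exp(stats::uniroot(function(l) tail_le(l) - alpha, c(-bound, bound),
                       tol = 1e-10)$root)
  }
  list(estimate = estimate, ci_low = ci_low, ci_high = ci_high)
}

#' Full association test on two genotype-count groups
#'
#' Convenience wrapper assembling the 2x2 table under the requested genetic
#' coding and computing the odds ratio, confidence interval and p-value
#' with the requested estimator, CI method and test.
#'
#' @param g1,g2 [genotype_counts()] for the exposed and reference group.
#' @param coding `"allelic"`, `"dominant"` or `"recessive"`.
#' @param estimator `"sample"` or `"conditional_mle"`.
#' @param ci_method `"woolf"` or `"exact"` (exact implies the conditional
#'   estimator's interval).
#' @param test `"pearson_chi2"` or `"fisher_exact"`.
#' @param level Confidence level.
#' @return An object of class `association_result` with fields
#'   `or_estimate`, `ci_low`, `ci_high`, `p_value`, the method tags, and
#'   `correction_applied`.
#' @export
assoc_test <- function(g1, g2,
                       coding = c("allelic", "dominant", "recessive"),
                       estimator = c("sample", "conditional_mle"),
                       ci_method = c("woolf", "exact"),
                       test = c("pearson_chi2", "fisher_exact"),
                       level = 0.95) {
  coding <- match.arg(coding)
  estimator <- match.arg(estimator)
  ci_method <- match.arg(ci_method)
  test <- match.arg(test)
  t <- switch(coding,
              allelic = allelic_table(g1, g2),
              dominant = dominant_table(g1, g2),
              recessive = recessive_table(g1, g2))
  correction <- FALSE
  if (estimator == "sample") {
    or <- sample_or(t)
    correction <- attr(or, "correction_applied")
    or <- as.numeric(or)
  } else {
    or <- conditional_mle_or(t, level)$estimate
  }
  ci <- if (ci_method == "woolf") {
    w <- woolf_ci(t, level)
    correction <- correction || attr(w, "correction_applied")
    as.numeric(w)
  } else {
    cm <- conditional_mle_or(t, level)
    c(cm$ci_low, cm$ci_high)
  }
  p <- switch(test,
              pearson_chi2 = pearson_chi2_p(t),
              fisher_exact = fisher_exact_p(t))
  structure(list(or_estimate = or, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, coding = coding, estimator = estimator,
                 ci_method = ci_method, test = test,
                 correction_applied = correction, table = t),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> OR %.3f [%.3f-%.3f], p %.4g (%s, %s, %s CI, %s%s)\n",
              x$or_estimate, x$ci_low, x$ci_high, x$p_value, x$coding,
              x$estimator, x$ci_method, x$test,
              if (x$correction_applied) ", +0.5 correction" else ""))
  invisible(x)
}
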