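#' Case-only 2x2 table for one stratum
#'
#' For a stratum of breast-cancer cases split by c.1100delC carrier status,
#' cross-tabulates carrier status against the modifier variant. Under the
#' dominant (default) coding the columns are modifier carriage vs none;
#' under the allelic coding they are allele counts. Rows are carriers
#' (exposed) first, so the odds ratio estimates the carrier-modifier
#' association among cases, which is the interaction OR under population
#' independence of the two loci and a rare disease.
#'
#' @param s A [stratum_pair()].
#' @param coding `"dominant"` or `"allelic"`.
#' @return A [two_by_two()].
#' @export
case_only_table <- function(s, coding = c("dominant", "allelic")) {
  stopifnot(inherits(s, "stratum_pair"))
  coding <- match.arg(coding)
  .check_nonempty(s$exposed, "carrier")
  switch(coding,
         dominant = dominant_table(s$exposed, s$unexposed),
         allelic = allelic_table(s$exposed, s$unexposed))
}

#' Mantel-Haenszel stratified odds ratio
#'
#' Fixed-effect pooled odds ratio over strata,
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with the
#' Robins-Breslow-Greenland variance for the confidence interval and the
#' Mantel-Haenszel chi-square (no continuity correction) for the p-value.
#' Strata contributing zero to *both* sums are dropped with a warning;
#' strata with one zero product are retained (they still inform one sum).
#'
#' @param strata A list of [two_by_two()] tables (or a single one).
#' @param level Confidence level (default 0.95).
#' @return An object of class `mh_result`: `pooled_or`, `ci_low`,
#'   `ci_high`, `chi2`, `p_value`, `n_strata` (used), and per-stratum
#'   `weights` (`b_i c_i / n_i`, the denominator weights).
#' @export
mantel_haenszel <- function(strata, level = 0.95) {
  if (inherits(strata, "two_by_two")) strata <- list(strata)
  stopifnot(length(strata) >= 1L,
            all(vapply(strata, inherits, logical(1), "two_by_two")))
  cells <- t(vapply(strata, .tbt_cells, numeric(4)))
  colnames(cells) <- c("a", "b", "c", "d")
  n <- rowSums(cells)
  if (any(n == 0)) stop("stratum with zero total", call. = FALSE)
  r <- cells[, "a"] * cells[, "d"] / n
  s <- cells[, "b"] * cells[, "c"] / n
  degenerate <- r == 0 & s == 0
  if (all(degenerate)) {
    stop("all strata degenerate: no information for pooling", call. = FALSE)
  }
  if (any(degenerate)) {
    warning(sprintf("dropping %d stratum/strata contributing zero to both sums",
                    sum(degenerate)), call. = FALSE)
    cells <- cells[!degenerate, , drop = FALSE]
    n <- n[!degenerate]; r <- r[!degenerate]; s <- s[!degenerate]
  }
  R <- sum(r); S <- sum(s)
  pooled <- R / S
  # Robins-Breslow-Greenland variance of log pooled OR
  P <- (cells[, "a"] + cells[, "d"]) / n
  Q <- (cells[, "b"] + cells[, "c"]) / n
  v <- sum(P * r) / (2 * R^2) + sum(P * s + Q * r) / (2 * R * S) +
    sum(Q * s) / (2 * S^2)
  z <- stats::qnorm((1 + level) / 2)
  ci <- exp(log(pooled) + c(-1, 1) * z * sqrt(v))
  # Mantel-Haenszel chi-square, no continuity correction
  E <- (cells[, "a"] + cells[, "b"]) * (cells[, "a"] + cells[, "c"]) / n
  V <- (cells[, "a"] + cells[, "b"]) * (cells[, "c"] + cells[, "d"]) *
    (cells[, "a"] + cells[, "c"]) * (cells[, "b"] + cells[, "d"]) /
    (n^2 * (n - 1))
  chi2 <- (sum(cells[, "a"]) - sum(E))^2 / sum(V)
  structure(list(pooled_or = pooled, ci_low = ci[1], ci_high = ci[2],
                 chi2 = chi2,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 n_strata = nrow(cells), weights = s),
            class = "mh_result")
}

#' @export
print.mh_result <- function(x, ...) {
  cat(sprintf("<mh_result> pooled OR %.3f [%.3f-%.3f], MH chi2 %.3f, p %.4g (%d strata)\n",
              x$pooled_or, x$ci_low, x$ci_high, x$chi2, x$p_value,
              x$n_strata))
  invisible(x)
}

#' Case-only Mantel-Haenszel analysis over stratum pairs
#'
#' Builds one [case_only_table()] per stratum and pools with
#' [mantel_haenszel()].
#'
#' @param strata A list of [stratum_pair()] objects.
#' @param coding Passed to [case_only_table()].
#' @param level Confidence level.
#' @return An `mh_result`.
#' @export
case_only_mh <- function(strata, coding = c("dominant", "allelic"),
                         level = 0.95) {
  coding <- match.arg(coding)
  mantel_haenszel(lapply(strata, case_only_table, coding = coding), level)
}

.model_matrix_cols <- function(data, covariates) {
  need <- c("case", "carrier", "dosage", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("interaction data is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(need)
}

#' Fit plain and interaction logistic risk models
#'
#' Maximum-likelihood logistic regressions of disease status on carrier
#' status and modifier dosage: the *plain* model
#' `logit P(case) = b0 + b1 carrier + b2 dosage + covariates` and the
#' *interaction* model adding `b3 carrier x dosage`. The modifier enters as
#' additive allele dosage 0/1/2 (per-allele effect); covariates are
#' arbitrary numeric columns (e.g. study indicators, principal components).
#' Fitting is iteratively reweighted least squares with convergence by
#' log-likelihood change below 1e-8 within 100 iterations; exponentiated
#' coefficients are reported, and the two fits are compared by a 1-df
#' likelihood-ratio test.
#'
#' @param data A data frame with columns `case` (0/1), `carrier` (0/1),
#'   `dosage` (0/1/2) and any covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param level Confidence level for coefficient intervals.
#' @return An object of class `interaction_model_result`: coefficient
#'   tables (`plain`, `interaction`, each with estimate, SE, OR and CI),
#'   log-likelihoods `ll_plain` and `ll_interaction`, `lrt_statistic`,
#'   `lrt_p`, and `n`.
#' @export
fit_interaction_model <- function(data, covariates = character(), level = 0.95) {
  .model_matrix_cols(data, covariates)
  if (length(unique(data$case)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  rhs <- paste(c("carrier", "dosage", covariates), collapse = " + ")
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit_one <- function(formula) {
    fit <- withCallingHandlers(
      stats::glm(formula, family = stats::binomial(), data = data, control = ctl),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged) {
      stop(sprintf("logistic fit did not converge within %d iterations (%s)",
                   ctl$maxit, deparse(formula)), call. = FALSE)
    }
    co <- stats::coef(fit)
    big <- abs(co) > 15 & names(co) != "(Intercept)"
    if (any(big)) {
      stop(sprintf("possible complete separation in term(s): %s",
                   paste(names(co)[big], collapse = ", ")), call. = FALSE)
    }
    fit
  }
  plain <- fit_one(stats::as.formula(paste("case ~", rhs)))
  inter <- fit_one(stats::as.formula(paste("case ~", rhs, "+ carrier:dosage")))
  lrt <- likelihood_ratio_test(plain, inter)
  z <- stats::qnorm((1 + level) / 2)
  coef_table <- function(fit) {
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               or = exp(sm[, 1]),
               or_low = exp(sm[, 1] - z * sm[, 2]),
               or_high = exp(sm[, 1] + z * sm[, 2]),
               row.names = NULL)
  }
  structure(list(plain = coef_table(plain),
                 interaction = coef_table(inter),
                 ll_plain = as.numeric(stats::logLik(plain)),
                 ll_interaction = as.numeric(stats::logLik(inter)),
                 lrt_statistic = lrt$statistic, lrt_p = lrt$p_value,
                 n = nrow(data),
                 fits = list(plain = plain, interaction = inter)),
            class = "interaction_model_result")
}

#' @export
print.interaction_model_result <- function(x, ...) {
  fmt <- function(tab, term) {
    i <- match(term, tab$term)
    sprintf("%.2f [%.2f-%.2f]", tab$or[i], tab$or_low[i], tab$or_high[i])
  }
  cat("<interaction_model_result> n =", x$n, "\n")
  cat(sprintf("  %-16s plain %-20s interaction %s\n", "dosage",
              fmt(x$plain, "dosage"), fmt(x$interaction, "dosage")))
  cat(sprintf("  %-16s plain %-20s interaction %s\n", "carrier",
              fmt(x$plain, "carrier"), fmt(x$interaction, "carrier")))
  cat(sprintf("  %-16s %-26s %s\n", "carrier:dosage", "",
              fmt(x$interaction, "carrier:dosage")))
  cat(sprintf("  LRT statistic %.4f, p %.4g\n", x$lrt_statistic, x$lrt_p))
  invisible(x)
}

#' Likelihood-ratio test of two nested fits
#'
#' Twice the log-likelihood gain of the larger model, referred to
#' chi-square with degrees of freedom equal to the difference in model
#' dimension (1 for the carrier-by-dosage interaction term). Both fits must
#' be on identical records. Gains that are negative by less than numerical
#' tolerance are clamped to zero.
#'
#' @param plain,interaction Fitted model objects (`glm` fits, or the
#'   result of [fit_interaction_model()], whose two internal fits are then
#'   compared).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(plain, interaction = NULL) {
  if (inherits(plain, "interaction_model_result") && is.null(interaction)) {
    interaction <- plain$fits$interaction
    plain <- plain$fits$plain
  }
  stopifnot(inherits(plain, "glm"), inherits(interaction, "glm"))
  if (stats::nobs(plain) != stats::nobs(interaction)) {
    stop("models fitted on differing record counts", call. = FALSE)
  }
  ll0 <- stats::logLik(plain); ll1 <- stats::logLik(interaction)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("models supplied in the wrong order", call. = FALSE)
  stat <- 2 * (as.numeric(ll1) - as.numeric(ll0))
  if (stat < 0) {
    if (stat < -1e-6) {
      stop("interaction model log-likelihood below plain model: not nested fits",
           call. = FALSE)
    }
    stat <- 0
  }
  df <- max(df, 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
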