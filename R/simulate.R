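#' Configuration of the cohort simulator
#'
#' The stated world of the simulator (see the vignette for the rationale of
#' each default): a rare risk variant carried as a dominant indicator at
#' carrier frequency 0.02 (the 1-3% range of c.1100delC in northern-European
#' populations), a common modifier in Hardy-Weinberg equilibrium at
#' minor-allele frequency 0.15, a baseline disease log-odds of
#' `qlogis(0.1)` (about a 10% lifetime-scale risk), a carrier effect of
#' `log(2.5)` (the 2-3-fold risk of the truncating allele), and null
#' modifier and interaction effects. Disease follows a logistic
#' (odds-multiplicative) model
#' `logit P(case) = beta0 + beta_carrier C + beta_modifier G +
#' beta_interaction C G` with `G` the allele dosage 0/1/2.
#'
#' @param n_individuals Population size.
#' @param carrier_freq Frequency of the rare risk-variant carrier state.
#' @param modifier_maf Alternate-allele frequency of the modifier.
#' @param beta0 Baseline log-odds of disease.
#' @param beta_carrier,beta_modifier,beta_interaction Log-odds effects.
#' @param n_strata Number of study strata; individuals are assigned to
#'   strata with probabilities `strata_weights`.
#' @param strata_weights Per-stratum size multipliers (normalized).
#' @param seed Root RNG seed. The same config and seed give bit-identical
#'   cohorts; each simulation component (carrier draw, genotype draw,
#'   disease draw, stratum assignment) uses its own child seed derived from
#'   the root.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 5000,
                              carrier_freq = 0.02,
                              modifier_maf = 0.15,
                              beta0 = stats::qlogis(0.1),
                              beta_carrier = log(2.5),
                              beta_modifier = 0,
                              beta_interaction = 0,
                              n_strata = 1L,
                              strata_weights = rep(1, n_strata),
                              seed = 1L) {
  stopifnot(n_individuals > 0,
            carrier_freq >= 0, carrier_freq <= 1,
            modifier_maf >= 0, modifier_maf <= 1,
            n_strata >= 1L, length(strata_weights) == n_strata,
            all(strata_weights > 0))
  structure(list(n_individuals = as.integer(n_individuals),
                 carrier_freq = carrier_freq, modifier_maf = modifier_maf,
                 beta0 = beta0, beta_carrier = beta_carrier,
                 beta_modifier = beta_modifier,
                 beta_interaction = beta_interaction,
                 n_strata = as.integer(n_strata),
                 strata_weights = strata_weights / sum(strata_weights),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# child seeds derived from one root seed; keeps components reproducible
# independently of how many draws each consumes
.child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

.expit <- function(x) stats::plogis(pmin(pmax(x, -700), 700))

#' Simulate a population cohort
#'
#' Carrier status is Bernoulli at `carrier_freq`, independent of the
#' modifier genotype which is drawn in Hardy-Weinberg equilibrium
#' (`Binomial(2, modifier_maf)` dosage); disease is Bernoulli with logistic
#' probability per the configured effects. Output is bit-identical for a
#' fixed config and seed.
#'
#' @param cfg A [simulation_config()].
#' @return A data frame of class `simulated_cohort` with columns `carrier`
#'   (0/1), `dosage` (0/1/2), `case` (0/1) and `stratum`; the config is
#'   attached as attribute `config`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_individuals
  seeds <- .child_seeds(cfg$seed, 4L)
  carrier <- .with_seed(seeds[1], stats::rbinom(n, 1L, cfg$carrier_freq))
  dosage <- .with_seed(seeds[2], stats::rbinom(n, 2L, cfg$modifier_maf))
  lp <- cfg$beta0 + cfg$beta_carrier * carrier + cfg$beta_modifier * dosage +
    cfg$beta_interaction * carrier * dosage
  case <- .with_seed(seeds[3], stats::rbinom(n, 1L, .expit(lp)))
  stratum <- .with_seed(seeds[4],
                        sample(paste0("stratum", seq_len(cfg$n_strata)), n,
                               replace = TRUE, prob = cfg$strata_weights))
  structure(data.frame(carrier = carrier, dosage = dosage, case = case,
                       stratum = stratum, stringsAsFactors = FALSE),
            config = cfg, class = c("simulated_cohort", "data.frame"))
}

#' Sample a case series / a case-control set from a cohort
#'
#' `sample_case_series()` returns diseased individuals (all of them, or a
#' seeded subsample without replacement); `sample_case_control()` returns a
#' labelled case-control set. Requests beyond the available individuals
#' raise an error stating the shortfall.
#'
#' @param cohort A `simulated_cohort`.
#' @param n_cases,n_controls Requested counts (`NULL` = all available
#'   cases for the case series).
#' @param seed Seed for the subsampling draw.
#' @return A data frame of the sampled rows (`sample_case_control()` adds
#'   no columns: `case` already labels the two arms).
#' @export
sample_case_series <- function(cohort, n_cases = NULL, seed = 1L) {
  cases <- cohort[cohort$case == 1L, , drop = FALSE]
  if (is.null(n_cases)) return(cases)
  if (n_cases > nrow(cases)) {
    stop(sprintf("requested %d cases but only %d available (shortfall %d)",
                 n_cases, nrow(cases), n_cases - nrow(cases)), call. = FALSE)
  }
  idx <- .with_seed(seed, sample.int(nrow(cases), n_cases))
  cases[idx, , drop = FALSE]
}

#' @rdname sample_case_series
#' @export
sample_case_control <- function(cohort, n_cases, n_controls, seed = 1L) {
  cases <- cohort[cohort$case == 1L, , drop = FALSE]
  controls <- cohort[cohort$case == 0L, , drop = FALSE]
  if (n_cases > nrow(cases)) {
    stop(sprintf("requested %d cases but only %d available (shortfall %d)",
                 n_cases, nrow(cases), n_cases - nrow(cases)), call. = FALSE)
  }
  if (n_controls > nrow(controls)) {
    stop(sprintf("requested %d controls but only %d available (shortfall %d)",
                 n_controls, nrow(controls), n_controls - nrow(controls)),
         call. = FALSE)
  }
  seeds <- .child_seeds(seed, 2L)
  i <- .with_seed(seeds[1], sample.int(nrow(cases), n_cases))
  j <- .with_seed(seeds[2], sample.int(nrow(controls), n_controls))
  rbind(cases[i, , drop = FALSE], controls[j, , drop = FALSE])
}

#' Case-only interaction test on a case series
#'
#' Cross-tabulates carrier status against modifier carriage (dominant
#' coding) or alleles (allelic coding) among cases and returns the Pearson
#' chi-square p-value (no continuity correction) together with the table
#' and sample OR. Degenerate tables (a zero margin) yield `p_value = NA`.
#'
#' @param cases A data frame with `carrier` and `dosage` columns
#'   (typically from [sample_case_series()]).
#' @param coding `"dominant"` or `"allelic"`.
#' @return A list with `table`, `or` and `p_value`.
#' @export
case_only_test <- function(cases, coding = c("dominant", "allelic")) {
  coding <- match.arg(coding)
  count3 <- function(d) genotype_counts(sum(d == 0L), sum(d == 1L),
                                        sum(d == 2L))
  g1 <- count3(cases$dosage[cases$carrier == 1L])
  g0 <- count3(cases$dosage[cases$carrier == 0L])
  if (gt_total(g1) == 0L || gt_total(g0) == 0L) {
    return(list(table = NULL, or = NA_real_, p_value = NA_real_))
  }
  t <- switch(coding, dominant = dominant_table(g1, g0),
              allelic = allelic_table(g1, g0))
  p <- tryCatch(pearson_chi2_p(t), error = function(e) NA_real_)
  or <- tryCatch(as.numeric(sample_or(t)), error = function(e) NA_real_)
  list(table = t, or = or, p_value = p)
}

.wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = centre - half, high = centre + half)
}

#' Estimate type-I error or power of the interaction tests
#'
#' Replicates the configured world `n_replicates` times (each replicate
#' with a child seed of the config's root seed) and reports the fraction of
#' replicates whose test p-value falls below `alpha`, with a Wilson score
#' interval. Under `beta_interaction = 0` this is the type-I error rate,
#' otherwise power. Replicates whose test is degenerate (p `NA`) count as
#' non-rejections and are tallied separately.
#'
#' @param cfg A [simulation_config()].
#' @param n_replicates Number of replicates (>= 100).
#' @param alpha Significance level (default 0.05).
#' @param test `"case_only"` (Pearson chi-square on the case-only table) or
#'   `"lrt"` (likelihood-ratio test of the interaction term in the
#'   case-control logistic model).
#' @return A list with `rate`, `ci` (Wilson), `n_replicates`, `alpha`,
#'   `test`, `n_rejected` and `n_degenerate`.
#' @export
estimate_error_rates <- function(cfg, n_replicates, alpha = 0.05,
                                 test = c("case_only", "lrt")) {
  stopifnot(inherits(cfg, "simulation_config"), n_replicates >= 100)
  test <- match.arg(test)
  seeds <- .child_seeds(cfg$seed, n_replicates)
  pvals <- vapply(seq_len(n_replicates), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    pop <- simulate_population(cfg_i)
    if (test == "case_only") {
      case_only_test(sample_case_series(pop))$p_value
    } else {
      res <- tryCatch(fit_interaction_model(pop),
                      error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$lrt_p
    }
  }, numeric(1L))
  rej <- sum(!is.na(pvals) & pvals < alpha)
  list(rate = rej / n_replicates,
       ci = .wilson_ci(rej, n_replicates),
       n_replicates = n_replicates, alpha = alpha, test = test,
       n_rejected = rej, n_degenerate = sum(is.na(pvals)))
}

#' Generate a discovery-and-validation-shaped fixture
#'
#' Writes files emulating the published study layout so that the whole
#' pipeline can be exercised against a known planted truth:
#'
#' * `discovery_genotypes.tsv` - a genotype matrix of 28 carrier, 28
#'   familial and 70 control samples, holding one planted recessive
#'   modifier (3 homozygous carriers, none elsewhere, emulating the
#'   discovery observation) among rare background variants (MAF 0.01-0.04,
#'   the search space of a rare-recessive screen), with sporadic missing
#'   calls;
#' * `candidate_table.tsv` - a candidate-variant frequency table with 14
#'   planted frequency-enriched variants (carrier/controls ratio 2.2-6)
#'   among null background rows whose frequencies carry only bounded
#'   database-scale jitter (|log ratio| <= 0.15), so the planted truth is
#'   decisively recoverable (see the vignette for what this does and does
#'   not establish);
#' * `validation_counts.tsv` - validation-shaped genotype-count tables for
#'   the planted variants in four cohorts.
#'
#' @param seed Root seed.
#' @param dir Output directory (created if needed).
#' @param n_background_matrix Background variants in the genotype matrix.
#' @param n_background_table Null rows in the candidate table.
#' @return A list with the file `paths`, the planted `truth`
#'   (`recessive`, `enriched`), and the in-memory `matrix` and
#'   `variant_table`.
#' @export
simulate_study_fixture <- function(seed = 1L, dir = tempfile("fixture"),
                                   n_background_matrix = 25L,
                                   n_background_table = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .child_seeds(seed, 3L)
  groups <- c(rep("carrier", 28), rep("fbc", 28), rep("crc", 70))
  n <- length(groups)

  ## discovery genotype matrix
  m <- .with_seed(seeds[1], {
    q_rec <- 0.2                       # planted recessive modifier MAF
    rec <- integer(n)
    car <- which(groups == "carrier")
    hom <- sample(car, 3L)             # the 3 homozygous carriers
    rec[hom] <- 2L
    rest <- setdiff(seq_len(n), hom)
    # comparison groups and remaining carriers: carriage without homozygosity
    rec[rest] <- stats::rbinom(length(rest), 1L, 2 * q_rec * (1 - q_rec))
    bg_maf <- stats::runif(n_background_matrix, 0.01, 0.04)
    bg <- vapply(bg_maf, function(q) stats::rbinom(n, 2L, q),
                 integer(n))
    calls <- cbind(planted_recessive = rec, bg)
    colnames(calls) <- c("planted_recessive",
                         sprintf("bg%02d", seq_len(n_background_matrix)))
    miss <- matrix(stats::runif(length(calls)) < 0.02, nrow = n)
    calls[miss] <- NA_integer_
    genotype_matrix(calls, sample_ids = sprintf("S%03d", seq_len(n)),
                    variant_ids = colnames(calls), group_of = groups)
  })

  ## candidate-variant frequency table
  vt <- .with_seed(seeds[2], {
    n_planted <- 14L
    jitter <- function(k, b = 0.15) exp(pmin(pmax(stats::rnorm(k, 0, 0.05),
                                                  -b), b))
    crc_p <- stats::runif(n_planted, 0.02, 0.04)
    car_p <- crc_p * stats::runif(n_planted, 2.2, 6)
    fbc_p <- car_p / stats::runif(n_planted, 1.0, 1.9)
    crc_b <- stats::runif(n_background_table, 0.03, 0.25)
    car_b <- crc_b * jitter(n_background_table)
    fbc_b <- crc_b * jitter(n_background_table)
    mk_ref <- function(base) base * jitter(length(base))
    df <- data.frame(
      rsid = sprintf("rsS%04d", seq_len(n_planted + n_background_table)),
      gene = c(sprintf("PLANT%02d", seq_len(n_planted)),
               sprintf("BG%02d", seq_len(n_background_table))),
      chrom = sample(1:22, n_planted + n_background_table, replace = TRUE),
      carrier_maf = c(car_p, car_b),
      fbc_maf = c(fbc_p, fbc_b),
      crc_maf = c(crc_p, crc_b),
      ref_panel_a = mk_ref(c(crc_p, crc_b)),
      ref_panel_b = mk_ref(c(crc_p, crc_b)),
      call_rate_carrier = stats::runif(n_planted + n_background_table, 0.85, 1),
      call_rate_fbc = stats::runif(n_planted + n_background_table, 0.85, 1),
      call_rate_crc = stats::runif(n_planted + n_background_table, 0.85, 1),
      driver_flag = rep(c(TRUE, FALSE), c(n_planted, n_background_table))
    )
    class(df) <- c("variant_table", "data.frame")
    df
  })

  ## validation-shaped count tables for the planted variants
  counts <- .with_seed(seeds[3], {
    planted <- vt[seq_len(14L), ]
    cohorts <- c(CHEK2 = 70L, Familial = 400L, Sporadic = 330L,
                 Controls = 280L)
    freqs <- function(row) c(CHEK2 = row$carrier_maf, Familial = row$fbc_maf,
                             Sporadic = row$crc_maf, Controls = row$crc_maf)
    do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
      f <- freqs(planted[i, ])
      do.call(rbind, lapply(names(cohorts), function(coh) {
        q <- f[[coh]]
        g <- stats::rmultinom(1, cohorts[[coh]],
                              c((1 - q)^2, 2 * q * (1 - q), q^2))[, 1]
        data.frame(gene = planted$gene[i], rsid = planted$rsid[i],
                   cohort = coh, hom_ref = g[1], het = g[2], hom_alt = g[3])
      }))
    }))
  })

  paths <- list(
    genotypes = file.path(dir, "discovery_genotypes.tsv"),
    candidate_table = file.path(dir, "candidate_table.tsv"),
    validation_counts = file.path(dir, "validation_counts.tsv"),
    metadata = file.path(dir, "metadata.json")
  )
  write_genotypes(m, paths$genotypes)
  data.table::fwrite(as.data.frame(vt), paths$candidate_table, sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(counts, paths$validation_counts, sep = "\t",
                     na = "NA", quote = FALSE)
  jsonlite::write_json(
    list(tool = "chek2mod",
         version = as.character(utils::packageVersion("chek2mod")),
         seed = seed),
    paths$metadata, auto_unbox = TRUE)
  list(paths = paths,
       truth = list(recessive = "planted_recessive",
                    enriched = sprintf("PLANT%02d", 1:14)),
       matrix = m, variant_table = vt)
}
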