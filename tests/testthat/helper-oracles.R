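# Independent oracles, deliberately naive: factorial enumeration and grid
# search only, no shared code with the package internals.

# two-sided Fisher p by direct enumeration over all tables with the observed
# margins (probability-mass rule)
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  supp <- max(0, k - m2):min(k, m1)
  prob <- vapply(supp, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  pobs <- prob[match(a, supp)]
  min(1, sum(prob[prob <= pobs * (1 + 1e-07)]))
}

# conditional MLE by grid search over the noncentral hypergeometric
# log-likelihood
grid_cmle <- function(a, b, c, d, lo = -7, hi = 7, n = 14001) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  supp <- max(0, k - m2):min(k, m1)
  lch <- lchoose(m1, supp) + lchoose(m2, k - supp)
  lpsi <- seq(lo, hi, length.out = n)
  ll <- vapply(lpsi, function(l) {
    lw <- lch + supp * l
    m <- max(lw)
    lw[match(a, supp)] - (m + log(sum(exp(lw - m))))
  }, numeric(1))
  exp(lpsi[which.max(ll)])
}

random_two_by_two <- function(max_cell = 40, min_cell = 1) {
  cells <- sample(min_cell:max_cell, 4, replace = TRUE)
  two_by_two(cells[1], cells[2], cells[3], cells[4])
}

random_genotype_counts <- function(max_count = 300) {
  genotype_counts(sample(1:max_count, 1), sample(0:max_count, 1),
                  sample(0:20, 1))
}

# the six published case-only strata (carrier group first), dominant coding
published_strata_tables <- function() {
  lapply(as_stratum_pairs(local({
    df <- chek2_caseonly_strata()
    df[df$stratum != "Combined", ]
  })), case_only_table)
}

# tiny discovery-shaped matrix builder
toy_matrix <- function(calls, groups) {
  genotype_matrix(calls,
                  sample_ids = sprintf("S%02d", seq_len(nrow(calls))),
                  variant_ids = colnames(calls), group_of = groups)
}
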