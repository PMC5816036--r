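# Independent oracles and small fixture builders shared across tests.

# Exact hypergeometric pmf by direct combinatorial enumeration
# (population N, K successes, n draws). Support 0..min(n, K).
hyper_pmf_enum <- function(N, K, n) {
  k <- 0:min(n, K)
  p <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
  stats::setNames(p, k)
}

hyper_mean <- function(N, K, n) n * K / N

# Exact pmf of (hits(A) - hits(B)) for two independent uniform n-subsets
# of 1..N with the pathway fixed as {1..K}: brute-force enumeration of
# all subset pairs.
null_diff_pmf_enum <- function(N, K, n) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  diffs <- outer(hits, hits, `-`)
  tab <- table(diffs) / length(diffs)
  stats::setNames(as.numeric(tab), names(tab))
}

# Median of a pmf given as named probabilities (midpoint convention).
pmf_median <- function(pmf) {
  v <- as.numeric(names(pmf))
  cdf <- cumsum(pmf)
  i <- min(which(cdf >= 0.5 - 1e-12))
  if (abs(cdf[i] - 0.5) < 1e-12) (v[i] + v[i + 1]) / 2 else v[i]
}

# Kolmogorov distance between an empirical sample and an exact pmf.
ks_distance <- function(sample, pmf) {
  v <- as.numeric(names(pmf))
  exact_cdf <- cumsum(pmf)
  emp_cdf <- vapply(v, function(x) mean(sample <= x), numeric(1))
  max(abs(emp_cdf - exact_cdf))
}

# Chi-square goodness-of-fit p-value against an exact pmf, pooling
# support points with expected count < 5 into the tails.
gof_pvalue <- function(sample, pmf) {
  v <- as.numeric(names(pmf))
  obs <- vapply(v, function(x) sum(sample == x), numeric(1))
  expd <- pmf * length(sample)
  keep <- expd >= 5
  obs <- c(sum(obs[!keep & v < stats::median(v)]), obs[keep],
           sum(obs[!keep & v >= stats::median(v)]))
  expd <- c(sum(expd[!keep & v < stats::median(v)]), expd[keep],
            sum(expd[!keep & v >= stats::median(v)]))
  nz <- expd > 0
  stat <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  stats::pchisq(stat, df = sum(nz) - 1, lower.tail = FALSE)
}

# Two-cell design (bulk.0 baseline vs rhizosphere.0) for single-contrast
# simulations.
two_cell_design <- function(replicates) {
  study_design(replicates = replicates,
               compartments = c("bulk", "rhizosphere"), cd_doses = 0)
}

# A calls data.frame in the shape call_pathways() returns, for feeding
# classify_calls() directly.
fake_calls <- function(enriched_treatment = character(0),
                       enriched_baseline = character(0),
                       not_significant = character(0)) {
  ids <- c(enriched_treatment, enriched_baseline, not_significant)
  data.frame(
    pathway_id = c(ids, ids),
    direction = rep(c("treatment", "baseline"), each = length(ids)),
    call = c(ifelse(ids %in% enriched_treatment, "enriched", "not_significant"),
             ifelse(ids %in% enriched_baseline, "enriched", "not_significant")),
    stringsAsFactors = FALSE
  )
}
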