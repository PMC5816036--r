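#' Pairwise comparison of a treatment cell against the baseline cell
#'
#' The pipeline's contrasts are always pairwise: one treatment cell of the
#' factorial design against the uncontaminated bulk-soil baseline.
#'
#' @param design a [study_design()].
#' @param treatment_cell cell label of the treatment group.
#' @param baseline_cell cell label of the baseline group (default the
#'   uncontaminated bulk soil, `"bulk.0"`).
#' @return An object of class `pairwise_comparison` with elements `id`,
#'   `treatment_cell`, `baseline_cell`, `treatment_samples`,
#'   `baseline_samples`.
#' @export
pairwise_comparison <- function(design, treatment_cell,
                                baseline_cell = design_cell("bulk", 0)) {
  stopifnot(inherits(design, "study_design"))
  ts <- cell_samples(design, treatment_cell)
  bs <- cell_samples(design, baseline_cell)
  if (length(ts) < 2 || length(bs) < 2) {
    stop(sprintf("comparison %s vs %s: both cells need >= 2 samples (found %d, %d)",
                 treatment_cell, baseline_cell, length(ts), length(bs)),
         call. = FALSE)
  }
  if (length(intersect(ts, bs))) {
    stop("treatment and baseline cells share samples", call. = FALSE)
  }
  structure(list(id = paste(treatment_cell, "vs", baseline_cell),
                 treatment_cell = treatment_cell, baseline_cell = baseline_cell,
                 treatment_samples = ts, baseline_samples = bs),
            class = "pairwise_comparison")
}

#' Directional sets of significantly enriched KOs for one comparison
#'
#' @param comparison a [pairwise_comparison()] (or a list with at least an
#'   `id` element).
#' @param enriched_in_treatment KO ids over-represented in the treatment
#'   group.
#' @param enriched_in_baseline KO ids over-represented in the baseline
#'   group. The two sets must be disjoint; their sizes are the resampling
#'   draw sizes (the per-direction `n`).
#' @return An object of class `enriched_ko_sets`.
#' @export
enriched_ko_sets <- function(comparison, enriched_in_treatment,
                             enriched_in_baseline) {
  et <- unique(as.character(enriched_in_treatment))
  eb <- unique(as.character(enriched_in_baseline))
  if (length(intersect(et, eb))) {
    stop("directional enriched sets must be disjoint", call. = FALSE)
  }
  structure(list(comparison = comparison,
                 enriched_in_treatment = et, enriched_in_baseline = eb,
                 n_treatment = length(et), n_baseline = length(eb)),
            class = "enriched_ko_sets")
}

#' @export
print.enriched_ko_sets <- function(x, ...) {
  cat(sprintf("enriched_ko_sets [%s]: n_treatment = %d, n_baseline = %d\n",
              x$comparison$id, x$n_treatment, x$n_baseline))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The model-fitting normalization used by count-based differential
#' abundance tools: per KO, the geometric mean across samples (KOs with
#' any zero count are excluded from the reference); per sample, the median
#' of count/geometric-mean ratios. Factors are returned as the raw medians
#' (unscaled); all downstream statistics are invariant to a common
#' rescaling of the factors.
#'
#' @param x a [ko_count_table()] or a counts matrix (rows = KOs).
#' @param pseudo_count if `TRUE`, add 1 to every count for factor
#'   estimation only — the fallback for sparse tables where no KO is
#'   observed in every sample.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(2, 4, 4, 8), 2, dimnames = list(c("K1", "K2"), c("a", "b")))
#' estimate_size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(x, pseudo_count = FALSE) {
  counts <- if (inherits(x, "ko_count_table")) x$counts else as.matrix(x)
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (pseudo_count) counts <- counts + 1
  all_pos <- rowSums(counts == 0) == 0L
  if (!any(all_pos)) {
    stop("no KO has nonzero counts in every sample; rerun with ",
         "pseudo_count = TRUE to estimate factors on counts + 1",
         call. = FALSE)
  }
  ref <- counts[all_pos, , drop = FALSE]
  log_geomean <- rowMeans(log(ref))
  factors <- apply(ref, 2, function(col) {
    stats::median(exp(log(col) - log_geomean))
  })
  stats::setNames(factors, colnames(counts))
}

#' Negative-binomial Wald test for KO differential enrichment
#'
#' A self-contained test in the spirit of NB-based differential abundance
#' tools, without empirical-Bayes dispersion shrinkage: per KO, group means
#' of normalized counts (count / size factor); dispersion by a pooled
#' within-group method-of-moments estimate floored at `dispersion_floor`;
#' `log2FC = log2(treatment mean / baseline mean)` with a pseudo-count of
#' 1/2 added to both group means only when one of them is zero; standard
#' error by the delta method under `Var = mu + alpha mu^2`; two-sided
#' p-value from the normal reference.
#'
#' KOs with all-zero counts in both groups cannot be tested; they are
#' dropped and reported in the `dropped` attribute.
#'
#' @param x a [ko_count_table()].
#' @param comparison a [pairwise_comparison()].
#' @param size_factors named positive per-sample factors from
#'   [estimate_size_factors()]; computed on `x` when omitted.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return A data.frame (`ko_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `pvalue`, `padj`) with BH-adjusted p-values, plus attribute `dropped`
#'   (untestable KO ids).
#' @export
nb_wald_test <- function(x, comparison, size_factors = NULL,
                         dispersion_floor = 1e-8) {
  stopifnot(inherits(x, "ko_count_table"), inherits(comparison, "pairwise_comparison"))
  size_factors <- size_factors %||% estimate_size_factors(x)
  if (any(size_factors <= 0)) stop("size factors must be positive", call. = FALSE)
  miss <- setdiff(c(comparison$treatment_samples, comparison$baseline_samples),
                  colnames(x$counts))
  if (length(miss)) {
    stop("comparison samples absent from counts: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  group_stats <- function(samples) {
    k <- x$counts[, samples, drop = FALSE]
    s <- size_factors[samples]
    y <- sweep(k, 2, s, `/`)
    list(n = length(samples),
         mean = rowMeans(y),
         var = apply(y, 1, stats::var),
         inv_s = mean(1 / s))
  }
  tr <- group_stats(comparison$treatment_samples)
  bl <- group_stats(comparison$baseline_samples)

  testable <- tr$mean > 0 | bl$mean > 0
  dropped <- rownames(x$counts)[!testable]

  m_t <- tr$mean[testable]; m_b <- bl$mean[testable]
  v_t <- tr$var[testable];  v_b <- bl$var[testable]

  # pooled within-group method-of-moments dispersion:
  # E[var_g] ~ mu_g * mean(1/s_g) + alpha * mu_g^2
  df_t <- tr$n - 1L; df_b <- bl$n - 1L
  excess <- (df_t * (v_t - m_t * tr$inv_s) + df_b * (v_b - m_b * bl$inv_s)) /
    (df_t + df_b)
  denom <- (df_t * m_t^2 + df_b * m_b^2) / (df_t + df_b)
  alpha <- pmax(ifelse(denom > 0, excess / denom, 0), dispersion_floor)

  zero <- m_t == 0 | m_b == 0
  m_t_adj <- ifelse(zero, m_t + 0.5, m_t)
  m_b_adj <- ifelse(zero, m_b + 0.5, m_b)
  log2fc <- log2(m_t_adj / m_b_adj)

  # delta method: Var(log2 mu_hat_g) = (mean(1/s_g)/mu_g + alpha) / (n_g ln(2)^2)
  var_log2 <- function(mu, inv_s, n) (inv_s / mu + alpha) / (n * log(2)^2)
  se <- sqrt(var_log2(m_t_adj, tr$inv_s, tr$n) +
             var_log2(m_b_adj, bl$inv_s, bl$n))
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))

  res <- data.frame(
    ko_id = rownames(x$counts)[testable],
    base_mean = (m_t * tr$n + m_b * bl$n) / (tr$n + bl$n),
    log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
    padj = bh_adjust(pvalue),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  attr(res, "comparison") <- comparison
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`sorted p * m / rank` with the
#' running minimum enforced from the largest rank, capped at 1), computed
#' through [stats::p.adjust()] after input validation.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order, elementwise `>=` input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Extract directional enriched-KO sets from test results
#'
#' KOs with BH-adjusted p below `alpha` are split by fold-change sign:
#' positive log2FC means enriched in the treatment group, negative means
#' enriched in the baseline group (the "decreased" direction of the
#' treatment).
#'
#' @param results data.frame from [nb_wald_test()].
#' @param alpha adjusted-p significance threshold in (0, 1).
#' @return An [enriched_ko_sets()].
#' @export
extract_enriched_sets <- function(results, alpha = 0.05) {
  assert_probability(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  sig <- !is.na(results$padj) & results$padj < alpha
  enriched_ko_sets(
    comparison = attr(results, "comparison") %||% list(id = "comparison"),
    enriched_in_treatment = results$ko_id[sig & results$log2fc > 0],
    enriched_in_baseline = results$ko_id[sig & results$log2fc < 0]
  )
}
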