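#' Generate a synthetic KO count table with planted pathway effects
#'
#' Draws every count from a negative-binomial model matching the analysis
#' model's assumptions: `count ~ NB(mean = mu, dispersion = alpha)` with
#' `Var = mu + alpha * mu^2`, where
#' `mu = base_mean * library-factor * 2^(log2FC)` and the fold-change term
#' applies only to KOs affected by a planted effect in samples of that
#' effect's target cell. Library-size factors are log-normal with
#' coefficient of variation `libsize_cv`, renormalized to geometric mean 1.
#'
#' Randomness is consumed in a fixed, documented order from one stream
#' seeded by `seed`: (1) library factors in design row order, (2) the
#' affected-KO subset of each effect in list order, (3) the count matrix
#' in column-major order (all KOs of sample 1, then sample 2, ...). Tables
#' are therefore bit-identical across calls with equal arguments.
#'
#' @param map a [pathway_map()]; the table has one row per universe KO.
#' @param design a [study_design()].
#' @param effects list of [planted_effect()] ground-truth descriptors.
#' @param base_mean baseline NB mean per KO (> 0).
#' @param dispersion NB dispersion alpha (> 0).
#' @param libsize_cv coefficient of variation of library-size factors
#'   (>= 0; 0 gives equal libraries).
#' @param seed integer seed.
#' @return A [ko_count_table()] with attribute `ground_truth`: a data.frame
#'   (`pathway_id`, `ko_id`, `cell`, `log2_fc`, `direction`) listing every
#'   affected KO, and attribute `library_factors`.
#' @examples
#' pm <- generate_pathway_map(5, 100, c(5, 10), 0.1, seed = 1)
#' des <- study_design(replicates = 3)
#' eff <- list(planted_effect("path001", "rhizosphere.100", log2_fc = 2))
#' tab <- generate_counts(pm, des, eff, seed = 1)
#' attr(tab, "ground_truth")[1:2, ]
#' @export
generate_counts <- function(map, design, effects = list(), base_mean = 500,
                            dispersion = 0.1, libsize_cv = 0.3, seed = 1L) {
  stopifnot(inherits(map, "pathway_map"), inherits(design, "study_design"),
            base_mean > 0, dispersion > 0)
  if (libsize_cv < 0) stop("libsize_cv must be non-negative", call. = FALSE)
  unknown <- setdiff(vapply(effects, `[[`, "", "pathway_id"),
                     names(map$pathways))
  if (length(unknown)) {
    stop("effects target unknown pathway id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  kos <- map$universe
  n_samp <- nrow(design)
  with_seed(seed, {
    lf <- if (libsize_cv > 0) {
      raw <- stats::rlnorm(n_samp, 0, sqrt(log(1 + libsize_cv^2)))
      raw / exp(mean(log(raw)))
    } else {
      rep(1, n_samp)
    }
    truth <- lapply(effects, function(e) {
      pk <- map$pathways[[e$pathway_id]]
      n_aff <- round(e$affected_fraction * length(pk))
      aff <- if (n_aff > 0) pk[sample.int(length(pk), n_aff)] else character(0)
      if (length(aff) == 0) return(NULL)
      data.frame(pathway_id = e$pathway_id, ko_id = aff, cell = e$cell,
                 log2_fc = if (e$direction == "up") e$log2_fc else -e$log2_fc,
                 direction = e$direction, stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    mu <- matrix(base_mean, nrow = length(kos), ncol = n_samp,
                 dimnames = list(kos, design$sample_id))
    mu <- sweep(mu, 2, lf, `*`)
    if (!is.null(truth) && nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        cols <- design$cell == truth$cell[i]
        mu[truth$ko_id[i], cols] <- mu[truth$ko_id[i], cols] * 2^truth$log2_fc[i]
      }
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    tab <- ko_count_table(counts, design)
    attr(tab, "ground_truth") <- truth %||%
      data.frame(pathway_id = character(0), ko_id = character(0),
                 cell = character(0), log2_fc = numeric(0),
                 direction = character(0))
    attr(tab, "library_factors") <- stats::setNames(lf, design$sample_id)
    tab
  })
}

#' Generate a synthetic enriched-KO set with a planted pathway signal
#'
#' Builds a directional enriched-KO set directly (bypassing the count and
#' testing stages) so the pathway-resampling machinery can be exercised
#' with exactly known overlap: the set contains `planted_count` KOs from
#' the planted pathway, and the remainder is drawn uniformly without
#' replacement from the rest of the universe.
#'
#' @param map a [pathway_map()].
#' @param n_enriched total size of the enriched set.
#' @param planted_pathway pathway id to plant, or `NULL` for a fully
#'   uniform set.
#' @param planted_count number of KOs taken from the planted pathway
#'   (`<= min(n_enriched, pathway size)`).
#' @param seed integer seed.
#' @return An [enriched_ko_sets()] whose treatment direction holds the
#'   generated set (baseline direction empty), comparison id `"synthetic"`.
#' @export
generate_enriched_sets <- function(map, n_enriched, planted_pathway = NULL,
                                   planted_count = 0L, seed = 1L) {
  stopifnot(inherits(map, "pathway_map"))
  if (n_enriched > length(map$universe)) {
    stop("n_enriched exceeds universe size", call. = FALSE)
  }
  pk <- character(0)
  if (!is.null(planted_pathway)) {
    if (!planted_pathway %in% names(map$pathways)) {
      stop("unknown planted pathway: ", planted_pathway, call. = FALSE)
    }
    pk <- map$pathways[[planted_pathway]]
    if (planted_count > min(n_enriched, length(pk))) {
      stop("planted_count exceeds n_enriched or pathway size", call. = FALSE)
    }
  }
  with_seed(seed, {
    inside <- if (planted_count > 0) pk[sample.int(length(pk), planted_count)]
              else character(0)
    pool <- setdiff(map$universe, pk)
    n_out <- n_enriched - length(inside)
    outside <- if (n_out > 0) pool[sample.int(length(pool), n_out)]
               else character(0)
    enriched_ko_sets(
      comparison = list(id = "synthetic", treatment_cell = "synthetic",
                        baseline_cell = "none"),
      enriched_in_treatment = c(inside, outside),
      enriched_in_baseline = character(0)
    )
  })
}
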