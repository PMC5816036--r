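#' Configuration of the pathway resampling null
#'
#' The pathway-enrichment statistic is calibrated against an ordered list
#' of resampled differences: with the default 1,000 replicates, the 5%
#' limit is the 50th and the 95% limit the 950th value of the sorted list.
#' For other replicate counts the ranks generalize to `ceiling(0.05 * R)`
#' and `floor(0.95 * R)`.
#'
#' @param n_reps number of resampling replicates (>= 100).
#' @param lower_index,upper_index 1-based ranks into the sorted null
#'   differences giving the lower and upper limits.
#' @param seed master seed; per-comparison/per-direction substreams are
#'   derived from it with [derive_seed()].
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_reps = 1000L,
                             lower_index = ceiling(0.05 * n_reps),
                             upper_index = floor(0.95 * n_reps),
                             seed = 1L) {
  n_reps <- as.integer(n_reps)
  lower_index <- as.integer(lower_index)
  upper_index <- as.integer(upper_index)
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  if (!(1L <= lower_index && lower_index < upper_index && upper_index <= n_reps)) {
    stop("need 1 <= lower_index < upper_index <= n_reps", call. = FALSE)
  }
  structure(list(n_reps = n_reps, lower_index = lower_index,
                 upper_index = upper_index, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Observed KO hits of a pathway
#'
#' The number of enriched KOs falling inside a pathway's KO set.
#'
#' @param enriched character vector of enriched KO ids.
#' @param pathway_kos character vector of the pathway's KO ids.
#' @return Non-negative integer count.
#' @export
observed_hits <- function(enriched, pathway_kos) {
  length(intersect(enriched, pathway_kos))
}

#' Resampled expected KO hits of a pathway
#'
#' Draws `n` KOs at random, without replacement, from the universe (the
#' collective predicted functional genome) and counts how many land in the
#' pathway; repeated `n_reps` times. Each draw is marginally
#' hypergeometric with population `|universe|`, successes
#' `|pathway_kos|`, draws `n`.
#'
#' @param n draw size (size of the enriched-KO list); `<= |universe|`.
#' @param universe character vector of all candidate KO ids.
#' @param pathway_kos the pathway's KO ids (must lie in `universe`).
#' @param n_reps number of replicates.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Integer vector of `n_reps` hit counts.
#' @export
expected_hit_draws <- function(n, universe, pathway_kos, n_reps = 1000L,
                               seed = NULL) {
  N <- length(universe)
  if (n > N) stop("draw size n exceeds universe size", call. = FALSE)
  member <- universe %in% pathway_kos
  draw <- function() {
    vapply(seq_len(n_reps),
           function(i) sum(member[sample.int(N, n)]), integer(1))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Difference of medians
#'
#' The pathway enrichment statistic: the median over replicates of
#' (observed hits - resampled expected hits). Because `observed` is
#' constant this equals `observed - median(draws)`; even-length medians
#' use the midpoint convention.
#'
#' @param observed observed hit count.
#' @param expected_draws integer vector from [expected_hit_draws()].
#' @return A single number.
#' @export
median_difference <- function(observed, expected_draws) {
  if (length(expected_draws) == 0) {
    stop("expected_draws must be non-empty", call. = FALSE)
  }
  stats::median(observed - expected_draws)
}

#' Randomized null distribution of hit-count differences
#'
#' Repeats the observed-vs-expected computation with the observed list
#' also drawn at random: each replicate is the difference between the hit
#' counts of two independent random `n`-subsets of the universe. The
#' sorted differences provide the percentile limits at the configured
#' ranks.
#'
#' @param n draw size; `<= |universe|`.
#' @param universe candidate KO ids.
#' @param pathway_kos the pathway's KO ids.
#' @param config a [bootstrap_config()]; its seed is used directly.
#' @return A list with `differences` (sorted ascending, length `n_reps`),
#'   `lower_limit`, `upper_limit`.
#' @export
null_distribution <- function(n, universe, pathway_kos, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  diffs <- with_seed(config$seed, {
    obs <- expected_hit_draws(n, universe, pathway_kos, config$n_reps)
    exp <- expected_hit_draws(n, universe, pathway_kos, config$n_reps)
    obs - exp
  })
  diffs <- sort(diffs)
  list(differences = diffs,
       lower_limit = diffs[config$lower_index],
       upper_limit = diffs[config$upper_index])
}

# Sparse pathway-by-universe incidence matrix (restricted to the universe).
pathway_incidence <- function(pathway_sets, universe) {
  idx <- lapply(pathway_sets, function(k) which(universe %in% k))
  Matrix::sparseMatrix(
    i = rep(seq_along(idx), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(idx), length(universe)),
    dimnames = list(names(pathway_sets), NULL)
  )
}

# n_reps hit counts for every pathway at once. Each replicate's random
# n-subset is shared across pathways (the per-pathway marginal law is the
# same as independent per-pathway draws: hypergeometric).
pathway_hit_draws <- function(incidence, N, n, n_reps) {
  idx <- vapply(seq_len(n_reps), function(i) sample.int(N, n), integer(n))
  U <- Matrix::sparseMatrix(i = as.vector(idx),
                            j = rep(seq_len(n_reps), each = n),
                            x = 1, dims = c(N, n_reps))
  as.matrix(incidence %*% U)
}

# Core percentile-null computation shared by enrichment calls and the
# under-representation screen.
resample_pathway_table <- function(pathway_sets, universe, observed, n, config) {
  N <- length(universe)
  if (n > N) stop("draw size n exceeds universe size", call. = FALSE)
  M <- pathway_incidence(pathway_sets, universe)
  exp_hits <- pathway_hit_draws(M, N, n, config$n_reps)
  null_diff <- pathway_hit_draws(M, N, n, config$n_reps) -
    pathway_hit_draws(M, N, n, config$n_reps)
  limits <- t(apply(null_diff, 1, function(d) {
    sort(d)[c(config$lower_index, config$upper_index)]
  }))
  med_diff <- vapply(seq_along(pathway_sets),
                     function(i) stats::median(observed[i] - exp_hits[i, ]),
                     numeric(1))
  data.frame(
    pathway_id = names(pathway_sets),
    pathway_size = as.integer(Matrix::rowSums(M)),
    n = n,
    observed_hits = as.integer(observed),
    median_difference = med_diff,
    lower_limit = limits[, 1],
    upper_limit = limits[, 2],
    stringsAsFactors = FALSE
  )
}

#' Call enriched and depleted pathways against the resampling null
#'
#' For each direction of a pairwise comparison (KOs enriched in the
#' treatment; KOs enriched in the baseline) and each pathway: the observed
#' KO hits, the median of `n_reps` observed-minus-resampled differences,
#' and the percentile limits of the randomized null in which both lists
#' are drawn at random. A pathway is called `enriched` when its median
#' difference lies strictly above the upper limit, `depleted` when
#' strictly below the lower limit, otherwise `not_significant`.
#'
#' Pathway KO sets and the enriched sets are intersected with `universe`
#' (by default the KOs present in the collective predicted functional
#' genome of the comparison). Each direction consumes an RNG substream
#' derived from `(config$seed, comparison id, direction)`.
#'
#' @param enriched_sets an [enriched_ko_sets()].
#' @param map a [pathway_map()] of the pathways to screen.
#' @param universe candidate KO universe; defaults to `map$universe`.
#' @param config a [bootstrap_config()].
#' @return A data.frame with one row per pathway and direction:
#'   `pathway_id`, `direction` (`"treatment"`/`"baseline"`),
#'   `pathway_size`, `n`, `observed_hits`, `median_difference`,
#'   `lower_limit`, `upper_limit`, `call`, `size_one`.
#' @export
call_pathways <- function(enriched_sets, map, universe = NULL,
                          config = bootstrap_config()) {
  stopifnot(inherits(enriched_sets, "enriched_ko_sets"),
            inherits(map, "pathway_map"), inherits(config, "bootstrap_config"))
  universe <- universe %||% map$universe
  comparison_id <- enriched_sets$comparison$id %||% "comparison"
  directions <- list(treatment = enriched_sets$enriched_in_treatment,
                     baseline = enriched_sets$enriched_in_baseline)
  out <- lapply(names(directions), function(dir) {
    enriched <- intersect(directions[[dir]], universe)
    n <- length(enriched)
    if (n == 0L) {
      warning(sprintf("empty enriched set for direction '%s' of %s; all calls not_significant",
                      dir, comparison_id), call. = FALSE)
      tab <- data.frame(
        pathway_id = names(map$pathways),
        pathway_size = lengths(lapply(map$pathways, intersect, universe)),
        n = 0L, observed_hits = 0L, median_difference = 0,
        lower_limit = 0, upper_limit = 0, stringsAsFactors = FALSE
      )
    } else {
      observed <- vapply(map$pathways, function(pk)
        observed_hits(enriched, intersect(pk, universe)), integer(1))
      tab <- with_seed(derive_seed(config$seed, comparison_id, dir),
                       resample_pathway_table(map$pathways, universe,
                                              observed, n, config))
    }
    tab$direction <- dir
    tab
  })
  out <- do.call(rbind, out)
  out$call <- ifelse(out$n == 0L, "not_significant",
              ifelse(out$median_difference > out$upper_limit, "enriched",
              ifelse(out$median_difference < out$lower_limit, "depleted",
                     "not_significant")))
  out$size_one <- out$pathway_size == 1L
  rownames(out) <- NULL
  out[, c("pathway_id", "direction", "pathway_size", "n", "observed_hits",
          "median_difference", "lower_limit", "upper_limit", "call",
          "size_one")]
}

#' Screen out pathways under-represented in the predicted metagenome
#'
#' Guards against KO-redundancy artifacts: the same resampling procedure
#' is run with the predicted metagenome's KO list as the observed data and
#' the full reference map universe as the source of expected draws.
#' Pathways whose difference of medians falls strictly below the lower
#' (5%) limit are significantly under-represented and excluded from the
#' final analysis.
#'
#' @param metagenome_kos KO ids present in the predicted metagenome
#'   (subset of the reference universe).
#' @param full_map the full reference [pathway_map()].
#' @param config a [bootstrap_config()]; the screen consumes the RNG
#'   substream `(seed, "screen")`.
#' @return A list of class `screen_result`: `excluded` and `retained`
#'   pathway-id vectors (disjoint; union = all pathways) and the per-
#'   pathway statistic `table`.
#' @export
underrepresentation_screen <- function(metagenome_kos, full_map,
                                       config = bootstrap_config()) {
  stopifnot(inherits(full_map, "pathway_map"), inherits(config, "bootstrap_config"))
  metagenome_kos <- unique(as.character(metagenome_kos))
  outside <- setdiff(metagenome_kos, full_map$universe)
  if (length(outside)) {
    stop("metagenome KOs absent from the reference universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  observed <- vapply(full_map$pathways,
                     function(pk) observed_hits(metagenome_kos, pk), integer(1))
  tab <- with_seed(derive_seed(config$seed, "screen"),
                   resample_pathway_table(full_map$pathways, full_map$universe,
                                          observed, length(metagenome_kos),
                                          config))
  excluded <- tab$pathway_id[tab$median_difference < tab$lower_limit]
  structure(list(excluded = excluded,
                 retained = setdiff(tab$pathway_id, excluded),
                 table = tab),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d retained, %d excluded pathway(s)\n",
              length(x$retained), length(x$excluded)))
  invisible(x)
}
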