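#' Pipeline configuration
#'
#' Bundles and validates everything one full run needs: input paths, the
#' KO-level significance threshold, the resampling-null settings, the
#' comparisons to run, and how the conditional registry entry and the
#' score denominator are resolved.
#'
#' @param counts path to the KO count TSV (rows = KOs, columns = samples).
#' @param metadata path to the sample metadata TSV.
#' @param pathway_map_path path to the two-column pathway-map TSV.
#' @param out_dir output directory (created if missing).
#' @param registry_path trait-registry TSV; defaults to the packaged
#'   registry.
#' @param comparisons character vector of treatment cell labels to compare
#'   against `baseline_cell`; `NULL` means every non-baseline cell in the
#'   metadata.
#' @param baseline_cell the reference cell (uncontaminated bulk soil).
#' @param alpha BH-adjusted significance threshold for KO enrichment.
#' @param n_reps,lower_index,upper_index,seed resampling-null settings,
#'   see [bootstrap_config()].
#' @param conditional `"S"` or `"C"`: class the conditional ABC-transporters
#'   registry entry counts toward.
#' @param denominator `"per_class"` or `"global"` score scaling.
#' @param biom_layout `TRUE` if the count TSV rows are KOs (default).
#' @param pseudo_count passed to [estimate_size_factors()].
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, pathway_map_path, out_dir,
                            registry_path = system.file("extdata",
                                                        "csr_trait_registry.tsv",
                                                        package = "catraits"),
                            comparisons = NULL,
                            baseline_cell = design_cell("bulk", 0),
                            alpha = 0.05, n_reps = 1000L,
                            lower_index = ceiling(0.05 * n_reps),
                            upper_index = floor(0.95 * n_reps),
                            seed = 1L,
                            conditional = c("S", "C"),
                            denominator = c("per_class", "global"),
                            biom_layout = TRUE, pseudo_count = FALSE) {
  conditional <- match.arg(conditional)
  denominator <- match.arg(denominator)
  for (p in c(counts, metadata, pathway_map_path, registry_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  assert_probability(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(counts = counts, metadata = metadata,
                 pathway_map_path = pathway_map_path, out_dir = out_dir,
                 registry_path = registry_path, comparisons = comparisons,
                 baseline_cell = baseline_cell, alpha = alpha,
                 bootstrap = bootstrap_config(n_reps, lower_index,
                                              upper_index, seed),
                 conditional = conditional, denominator = denominator,
                 biom_layout = biom_layout, pseudo_count = pseudo_count),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full community-aggregated-trait pipeline
#'
#' Executes, for every configured pairwise comparison against the
#' baseline cell: KO-level NB Wald tests with median-of-ratios
#' normalization and BH correction; the under-representation screen of
#' the pathway map against the predicted metagenome; pathway
#' enrichment/depletion calls against the resampling null; CSR trait
#' classification; and CSR net-change scores. All stage tables are
#' written as TSV into `config$out_dir` together with a JSON manifest
#' (input checksums, seed, package version, output checksums). The run is
#' a pure function of (input files, config, seed): repeated runs are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_result`: `manifest` (path),
#'   `calls`, `coordinates`, `screen`, `results` (per-comparison KO
#'   tests), `profiles`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- stage("read_inputs", read_ko_table(config$counts, config$metadata,
                                            biom_layout = config$biom_layout))
  map <- stage("read_inputs", read_pathway_map(config$pathway_map_path))
  registry <- stage("read_inputs", load_trait_registry(config$registry_path))

  comparisons <- config$comparisons %||%
    setdiff(sort(unique(tab$design$cell)), config$baseline_cell)
  cmp <- stage("validate", lapply(comparisons, function(cell) {
    pairwise_comparison(tab$design, cell, config$baseline_cell)
  }))

  sf <- stage("normalization",
              estimate_size_factors(tab, pseudo_count = config$pseudo_count))

  metagenome_kos <- rownames(tab$counts)[rowSums(tab$counts) > 0]
  screen <- stage("screen", underrepresentation_screen(
    intersect(metagenome_kos, map$universe), map, config$bootstrap))
  say("screen: %d pathway(s) excluded of %d", length(screen$excluded),
      length(map$pathways))
  retained_map <- if (length(screen$excluded)) {
    pathway_map(map$pathways[screen$retained], map$universe)
  } else {
    map
  }

  all_calls <- list()
  scores <- list()
  profiles <- list()
  results <- list()
  for (comparison in cmp) {
    id <- comparison$id
    res <- stage("ko_enrichment", nb_wald_test(tab, comparison, sf))
    sets <- stage("ko_enrichment", extract_enriched_sets(res, config$alpha))
    say("%s: n_treatment = %d, n_baseline = %d (KO tests: %d, dropped %d)",
        id, sets$n_treatment, sets$n_baseline, nrow(res),
        length(attr(res, "dropped")))
    comp_samples <- c(comparison$treatment_samples, comparison$baseline_samples)
    comp_universe <- rownames(tab$counts)[
      rowSums(tab$counts[, comp_samples, drop = FALSE]) > 0]
    calls <- stage("pathway_bootstrap", suppressWarnings(
      call_pathways(sets, retained_map, comp_universe, config$bootstrap)))
    if (length(screen$excluded)) {
      extra <- expand.grid(pathway_id = screen$excluded,
                           direction = c("treatment", "baseline"),
                           stringsAsFactors = FALSE)
      extra <- data.frame(extra, pathway_size = NA_integer_, n = NA_integer_,
                          observed_hits = NA_integer_,
                          median_difference = NA_real_, lower_limit = NA_real_,
                          upper_limit = NA_real_, call = NA_character_,
                          size_one = NA)
      calls <- rbind(calls, extra[, names(calls)])
    }
    calls$excluded_by_screen <- calls$pathway_id %in% screen$excluded
    calls$comparison <- id
    profile <- stage("csr_traits", classify_calls(
      calls[!calls$excluded_by_screen, ], registry,
      treatment = comparison$treatment_cell, conditional = config$conditional))
    if (length(unlist(profile$unclassified))) {
      say("%s: %d called pathway(s) not in registry (kept as unclassified)",
          id, length(unlist(profile$unclassified)))
    }
    score <- stage("csr_traits", csr_score(profile, registry,
                                           denominator = config$denominator))
    slug <- gsub("[^A-Za-z0-9._-]+", "_", id)
    write_tsv_strict(res, file.path(config$out_dir,
                                    paste0("ko_tests_", slug, ".tsv")))
    write_tsv_strict(
      data.frame(ko_id = c(sets$enriched_in_treatment,
                           sets$enriched_in_baseline),
                 direction = rep(c("treatment", "baseline"),
                                 c(sets$n_treatment, sets$n_baseline)),
                 stringsAsFactors = FALSE),
      file.path(config$out_dir, paste0("enriched_kos_", slug, ".tsv")))
    all_calls[[id]] <- calls
    results[[id]] <- res
    profiles[[id]] <- profile
    scores[[id]] <- score
  }

  calls_df <- do.call(rbind, all_calls)
  rownames(calls_df) <- NULL
  write_tsv_strict(calls_df, file.path(config$out_dir, "pathway_calls.tsv"))
  write_tsv_strict(screen$table, file.path(config$out_dir, "screen.tsv"))

  coords <- csr_coordinates(c(
    list(structure(list(treatment = config$baseline_cell, delta_C = 0,
                        delta_S = 0, delta_R = 0), class = "csr_score")),
    unname(scores)))
  write_tsv_strict(coords, file.path(config$out_dir, "csr_coordinates.tsv"))

  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "catraits",
    version = as.character(utils::packageVersion("catraits")),
    seed = config$bootstrap$seed,
    alpha = config$alpha,
    n_reps = config$bootstrap$n_reps,
    baseline_cell = config$baseline_cell,
    comparisons = comparisons,
    inputs = as.list(stats::setNames(
      as.vector(tools::md5sum(c(config$counts, config$metadata,
                                config$pathway_map_path,
                                config$registry_path))),
      c("counts", "metadata", "pathway_map", "registry"))),
    outputs = as.list(stats::setNames(
      as.vector(tools::md5sum(file.path(config$out_dir, outputs))),
      outputs))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  structure(list(manifest = manifest_path, calls = calls_df,
                 coordinates = coords, screen = screen, results = results,
                 profiles = profiles, scores = scores),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$coordinates)
  invisible(x)
}
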