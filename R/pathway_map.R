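#' Pathway map: many-to-many KO to pathway membership
#'
#' A `pathway_map` relates KEGG pathways to the KEGG orthologs (KOs) they
#' contain. A KO may belong to several pathways (KEGG redundancy) and the
#' KO universe may contain pathway-free KOs.
#'
#' @param pathways named list; each element a character vector of KO ids.
#' @param universe character vector of all KO ids; must contain every KO
#'   referenced by a pathway. Defaults to the union of pathway members.
#' @return An object of class `pathway_map` with elements `pathways`
#'   (named list of unique KO-id character vectors) and `universe`.
#' @examples
#' pm <- pathway_map(list(p1 = c("K1", "K2"), p2 = c("K2", "K3")))
#' ko_multiplicity(pm)
#' @export
pathway_map <- function(pathways, universe = NULL) {
  if (!is.list(pathways) || is.null(names(pathways)) ||
      anyDuplicated(names(pathways)) || any(!nzchar(names(pathways)))) {
    stop("`pathways` must be a list uniquely named by pathway id", call. = FALSE)
  }
  pathways <- lapply(pathways, function(k) unique(as.character(k)))
  if (any(lengths(pathways) == 0L)) {
    stop("pathway KO sets must be non-empty", call. = FALSE)
  }
  members <- unique(unlist(pathways, use.names = FALSE))
  universe <- unique(as.character(universe %||% members))
  missing <- setdiff(members, universe)
  if (length(missing)) {
    stop("KOs referenced by pathways but absent from universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("pathway_map: %d pathways, %d KOs in universe (%d pathway-free)\n",
              length(x$pathways), length(x$universe),
              length(x$universe) - length(unique(unlist(x$pathways)))))
  invisible(x)
}

#' Per-KO pathway multiplicity
#'
#' Counts, for every KO in the universe, how many pathways contain it.
#' Pathway-free KOs have multiplicity 0.
#'
#' @param map a [pathway_map()].
#' @return A named integer vector over the universe.
#' @export
ko_multiplicity <- function(map) {
  stopifnot(inherits(map, "pathway_map"))
  tab <- table(factor(unlist(map$pathways, use.names = FALSE),
                      levels = map$universe))
  stats::setNames(as.integer(tab), map$universe)
}

#' Generate a synthetic KO-to-pathway map
#'
#' Builds a random map emulating the structure of KEGG ontology links:
#' pathway sizes drawn uniformly from `size_range`, and with probability
#' `overlap_prob` each pathway slot reuses an already-assigned KO (creating
#' the multi-pathway redundancy real KEGG maps have) instead of consuming a
#' fresh one. With `overlap_prob = 0` pathways are pairwise disjoint.
#'
#' @param n_pathways number of pathways (>= 1).
#' @param n_kos size of the KO universe; must be able to satisfy all
#'   pathway sizes at `overlap_prob = 0`.
#' @param size_range integer pair, inclusive bounds on pathway size
#'   (lower bound >= 1; KEGG pathways can be as small as one KO).
#' @param overlap_prob probability in `[0, 1]` of reusing an assigned KO.
#' @param seed integer seed; the map is deterministic given the seed.
#' @return A [pathway_map()] whose universe has exactly `n_kos` KOs
#'   (`K0001`, `K0002`, ...); KOs never assigned remain pathway-free.
#' @export
generate_pathway_map <- function(n_pathways, n_kos, size_range = c(1L, 30L),
                                 overlap_prob = 0.2, seed = 1L) {
  stopifnot(n_pathways >= 1, length(size_range) == 2)
  size_range <- as.integer(sort(size_range))
  if (size_range[1] < 1L) {
    stop("size_range lower bound must be >= 1", call. = FALSE)
  }
  assert_probability(overlap_prob, "overlap_prob")
  if (n_kos < size_range[2]) {
    stop("n_kos must be at least max(size_range)", call. = FALSE)
  }
  universe <- sprintf("K%04d", seq_len(n_kos))
  with_seed(seed, {
    sizes <- size_range[1] - 1L +
      sample.int(size_range[2] - size_range[1] + 1L, n_pathways, replace = TRUE)
    if (n_kos < max(sizes) ||
        (overlap_prob == 0 && sum(sizes) > n_kos)) {
      stop("n_kos insufficient to satisfy pathway sizes without overlap",
           call. = FALSE)
    }
    assigned <- character(0)
    pathways <- vector("list", n_pathways)
    names(pathways) <- sprintf("path%03d", seq_len(n_pathways))
    for (p in seq_len(n_pathways)) {
      members <- character(0)
      for (slot in seq_len(sizes[p])) {
        reuse_pool <- setdiff(assigned, members)
        fresh_pool <- setdiff(universe, c(assigned, members))
        reuse <- length(reuse_pool) > 0 && stats::runif(1) < overlap_prob
        pool <- if (reuse) reuse_pool else fresh_pool
        if (!length(pool)) pool <- reuse_pool  # fresh KOs exhausted
        if (!length(pool)) {
          stop("n_kos insufficient to satisfy pathway sizes", call. = FALSE)
        }
        members <- c(members, pool[sample.int(length(pool), 1L)])
      }
      pathways[[p]] <- members
      assigned <- union(assigned, members)
    }
    pathway_map(pathways, universe)
  })
}

#' Read a pathway map from a two-column TSV
#'
#' Expects columns `pathway_id` and `ko_id` (one membership link per row,
#' as KEGG ontology link dumps are usually laid out). Duplicate rows are
#' collapsed; the universe is every KO id seen.
#'
#' @param path TSV file path.
#' @return A [pathway_map()].
#' @export
read_pathway_map <- function(path) {
  df <- read_tsv_strict(path)
  if (nrow(df) == 0L) stop("pathway map file is empty: ", path, call. = FALSE)
  if (!all(c("pathway_id", "ko_id") %in% names(df))) {
    stop("pathway map TSV needs columns pathway_id, ko_id", call. = FALSE)
  }
  bad <- !nzchar(trimws(df$pathway_id)) | !nzchar(trimws(df$ko_id)) |
    is.na(df$pathway_id) | is.na(df$ko_id)
  if (any(bad)) {
    stop("pathway map rows with missing fields at line(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  pathway_map(split(df$ko_id, factor(df$pathway_id, levels = unique(df$pathway_id))))
}

#' Write a pathway map as a two-column TSV
#'
#' @param map a [pathway_map()].
#' @param path output file path.
#' @return The path, invisibly. Pathway-free universe KOs are not written
#'   (the two-column layout cannot carry them); round-trips preserve all
#'   pathway memberships.
#' @export
write_pathway_map <- function(map, path) {
  stopifnot(inherits(map, "pathway_map"))
  df <- data.frame(
    pathway_id = rep(names(map$pathways), lengths(map$pathways)),
    ko_id = unlist(map$pathways, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv_strict(df, path)
}
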