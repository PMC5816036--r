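#' Load the packaged CSR trait registry
#'
#' The registry freezes the manual curation of KEGG pathways into Grime's
#' life-strategy classes: Competitor (C; monopolization of local
#' resources), Stress-tolerator (S; maintenance of cell integrity under
#' chronic stress), Ruderal (R; re-establishment after disturbance), one
#' conditional entry (ABC transporters, classified C or S depending on the
#' nature of the enriched transporters; resolved at scoring time, default
#' S), and a suite of foraging pathways (chemotaxis, motility, regulatory
#' plasticity) outside the three axes. Entries whose provenance is
#' `criteria-reconstructed` are stand-ins rebuilt from the published trait
#' definition criteria where the printed treatment table does not name the
#' pathway; see the registry TSV's provenance column.
#'
#' Two printed pathway names may share a trait (the TCA cycle is part of
#' KEGG's carbon-metabolism overview pathway), so class tallies count
#' distinct traits. At load the tallies are checked against the frozen
#' classification: 9 C, 6 S (including the conditional entry), 9 R,
#' 1 conditional, 6 foraging.
#'
#' @param path registry TSV; defaults to the packaged file.
#' @return A data.frame of class `trait_registry` with columns
#'   `pathway_name`, `class`, `trait`, `provenance`.
#' @export
load_trait_registry <- function(path = system.file("extdata",
                                                   "csr_trait_registry.tsv",
                                                   package = "catraits")) {
  reg <- read_tsv_strict(path)
  need <- c("pathway_name", "class", "trait", "provenance")
  if (!all(need %in% names(reg))) {
    stop("malformed registry: needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c("C", "S", "R", "conditional_CS", "foraging", "unclassified")
  if (any(!reg$class %in% allowed)) {
    stop("malformed registry: unknown class label(s) ",
         paste(setdiff(reg$class, allowed), collapse = ", "), call. = FALSE)
  }
  reg$key <- normalize_name(reg$pathway_name)
  if (anyDuplicated(reg$key)) {
    stop("duplicate pathway names in registry: ",
         paste(reg$pathway_name[duplicated(reg$key)], collapse = ", "),
         call. = FALSE)
  }
  class(reg) <- c("trait_registry", "data.frame")
  counts <- registry_class_counts(reg)
  expect <- c(C = 9L, S = 6L, R = 9L)
  if (!identical(counts[names(expect)], expect) ||
      sum(reg$class == "conditional_CS") != 1L ||
      registry_class_counts(reg)[["foraging"]] != 6L) {
    stop("registry class tallies do not match the frozen classification ",
         "(9 C / 6 S / 9 R / 1 conditional / 6 foraging)", call. = FALSE)
  }
  reg
}

#' Distinct-trait tallies per CSR class
#'
#' @param registry a [load_trait_registry()] result.
#' @param conditional which class the conditional (ABC transporters) entry
#'   counts toward: `"S"` (default) or `"C"`.
#' @return Named integer vector over `C`, `S`, `R`, `foraging`,
#'   `unclassified` (conditional entries folded into `conditional`'s
#'   class).
#' @export
registry_class_counts <- function(registry, conditional = c("S", "C")) {
  conditional <- match.arg(conditional)
  cls <- ifelse(registry$class == "conditional_CS", conditional, registry$class)
  tallies <- vapply(c("C", "S", "R", "foraging", "unclassified"),
                    function(k) length(unique(registry$trait[cls == k])),
                    integer(1))
  tallies
}

#' Classify pathway calls of one comparison into CSR trait profiles
#'
#' Pathways called `enriched` in the treatment direction populate the
#' class-wise enriched sets; pathways called `enriched` in the baseline
#' direction populate the class-wise depleted sets (the treatment's
#' "decreased" traits). Registry matching is by pathway name,
#' case-insensitive and whitespace-normalized; called pathways absent from
#' the registry are reported under `unclassified`, never dropped silently.
#'
#' @param calls data.frame from [call_pathways()] for one comparison.
#' @param registry a [load_trait_registry()] result.
#' @param treatment label of the treatment cell (for the profile).
#' @param conditional resolution of the conditional ABC-transporters
#'   entry, `"S"` (default) or `"C"`.
#' @return An object of class `treatment_trait_profile`: per class the
#'   disjoint sets of enriched and depleted trait names, plus
#'   `unclassified` pathway ids and foraging traits.
#' @export
classify_calls <- function(calls, registry, treatment = "treatment",
                           conditional = c("S", "C")) {
  conditional <- match.arg(conditional)
  stopifnot(inherits(registry, "trait_registry"),
            all(c("pathway_id", "direction", "call") %in% names(calls)))
  cls <- ifelse(registry$class == "conditional_CS", conditional, registry$class)
  lookup <- function(direction) {
    hit <- calls$call == "enriched" & calls$direction == direction
    ids <- unique(calls$pathway_id[hit])
    idx <- match(normalize_name(ids), registry$key)
    list(
      traits = split(registry$trait[idx[!is.na(idx)]],
                     cls[idx[!is.na(idx)]]),
      unclassified = ids[is.na(idx)]
    )
  }
  up <- lookup("treatment")
  down <- lookup("baseline")
  classes <- lapply(stats::setNames(nm = c("C", "S", "R", "foraging")),
                    function(k) {
    enr <- unique(up$traits[[k]] %||% character(0))
    dep <- unique(down$traits[[k]] %||% character(0))
    both <- intersect(enr, dep)  # one trait, several pathway names
    list(enriched = setdiff(enr, both), depleted = setdiff(dep, both))
  })
  structure(list(treatment = treatment, classes = classes,
                 unclassified = list(enriched = up$unclassified,
                                     depleted = down$unclassified),
                 conditional = conditional),
            class = "treatment_trait_profile")
}

#' @export
print.treatment_trait_profile <- function(x, ...) {
  cat(sprintf("treatment_trait_profile [%s]\n", x$treatment))
  for (k in names(x$classes)) {
    cat(sprintf("  %s: %d enriched / %d depleted\n", k,
                length(x$classes[[k]]$enriched),
                length(x$classes[[k]]$depleted)))
  }
  if (length(unlist(x$unclassified))) {
    cat("  unclassified:", length(x$unclassified$enriched), "enriched /",
        length(x$unclassified$depleted), "depleted\n")
  }
  invisible(x)
}

#' CSR net-change score of a treatment
#'
#' For each class X in {C, S, R}:
#' `delta_X = (enriched_X / N_X - depleted_X / N_X) * 100`,
#' where `N_X` is the number of registry traits in class X (each axis is
#' scaled by the number of traits detected for that class) and the
#' depleted count is the number of X traits enriched in the baseline
#' direction of the pairwise comparison. Foraging and unclassified
#' pathways never enter the three axes. With `denominator = "global"` all
#' axes are scaled by the total CSR trait count instead.
#'
#' @param profile a [classify_calls()] profile.
#' @param registry a [load_trait_registry()] result.
#' @param denominator `"per_class"` (default) or `"global"`.
#' @return An object of class `csr_score`: `treatment`, `delta_C`,
#'   `delta_S`, `delta_R` (each in `[-100, 100]`).
#' @export
csr_score <- function(profile, registry, denominator = c("per_class", "global")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(profile, "treatment_trait_profile"),
            inherits(registry, "trait_registry"))
  sizes <- registry_class_counts(registry, conditional = profile$conditional)
  if (any(sizes[c("C", "S", "R")] == 0)) {
    stop("registry class sizes must be positive for C, S and R", call. = FALSE)
  }
  total <- sum(sizes[c("C", "S", "R")])
  delta <- vapply(c("C", "S", "R"), function(k) {
    n_k <- if (denominator == "global") total else sizes[[k]]
    100 * (length(profile$classes[[k]]$enriched) -
             length(profile$classes[[k]]$depleted)) / n_k
  }, numeric(1))
  structure(list(treatment = profile$treatment,
                 delta_C = delta[["C"]], delta_S = delta[["S"]],
                 delta_R = delta[["R"]]),
            class = "csr_score")
}

#' @export
print.csr_score <- function(x, ...) {
  cat(sprintf("csr_score [%s]: dC = %.2f, dS = %.2f, dR = %.2f\n",
              x$treatment, x$delta_C, x$delta_S, x$delta_R))
  invisible(x)
}

#' Tidy table of CSR coordinates across treatments
#'
#' Collects per-treatment scores into the coordinate table behind the
#' three-dimensional CSR representation, ordered by treatment label.
#'
#' @param scores list of [csr_score()] objects.
#' @return A data.frame (`treatment`, `delta_C`, `delta_S`, `delta_R`).
#' @export
csr_coordinates <- function(scores) {
  if (inherits(scores, "csr_score")) scores <- list(scores)
  stopifnot(all(vapply(scores, inherits, TRUE, "csr_score")))
  df <- data.frame(
    treatment = vapply(scores, `[[`, "", "treatment"),
    delta_C = vapply(scores, `[[`, 0, "delta_C"),
    delta_S = vapply(scores, `[[`, 0, "delta_S"),
    delta_R = vapply(scores, `[[`, 0, "delta_R"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$treatment)) {
    stop("duplicate treatment labels in scores", call. = FALSE)
  }
  df <- df[order(df$treatment), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Plot CSR coordinates as pairwise projections
#'
#' Renders the three pairwise projections of the (delta C, delta S,
#' delta R) coordinates — a flat stand-in for the three-dimensional trait
#' representation.
#'
#' @param coords data.frame from [csr_coordinates()].
#' @param ... passed to [graphics::plot()].
#' @return `coords`, invisibly.
#' @export
plot_csr_coordinates <- function(coords, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  panels <- list(c("delta_C", "delta_S"), c("delta_C", "delta_R"),
                 c("delta_S", "delta_R"))
  for (p in panels) {
    graphics::plot(coords[[p[1]]], coords[[p[2]]], xlab = p[1], ylab = p[2],
                   xlim = c(-100, 100), ylim = c(-100, 100), pch = 19, ...)
    graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
    graphics::text(coords[[p[1]]], coords[[p[2]]], coords$treatment,
                   pos = 3, cex = 0.7)
  }
  invisible(coords)
}
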