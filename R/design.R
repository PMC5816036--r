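#' Factorial study design: compartment x Cd dose
#'
#' Describes the microcosm layout the pipeline analyses: soil compartment
#' (bulk vs rhizosphere) crossed with cadmium dose (0, 20, 100 mg Cd per kg
#' soil; the dose is a factor label, not a covariate). The baseline cell —
#' uncontaminated bulk soil — is the reference every treatment cell is
#' compared against.
#'
#' @param replicates replicates per design cell (positive integer), or a
#'   data.frame with columns `sample_id`, `compartment`, `cd_dose` to wrap
#'   an explicit layout.
#' @param compartments factor levels for the compartment.
#' @param cd_doses factor levels for the Cd dose.
#' @return An object of class `study_design`: a data.frame with columns
#'   `sample_id`, `compartment`, `cd_dose`, `cell` (compartment.dose label).
#' @examples
#' design <- study_design(replicates = 5)
#' table(design$cell)
#' @export
study_design <- function(replicates = 5L,
                         compartments = c("bulk", "rhizosphere"),
                         cd_doses = c(0, 20, 100)) {
  if (is.data.frame(replicates)) {
    df <- replicates
    need <- c("sample_id", "compartment", "cd_dose")
    if (!all(need %in% names(df))) {
      stop("design data.frame needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df <- df[, need]
  } else {
    stopifnot(is.numeric(replicates), replicates >= 1)
    grid <- expand.grid(compartment = compartments, cd_dose = cd_doses,
                        rep = seq_len(replicates), stringsAsFactors = FALSE)
    df <- data.frame(
      sample_id = sprintf("%s_cd%s_r%d", substr(grid$compartment, 1, 4),
                          grid$cd_dose, grid$rep),
      compartment = grid$compartment,
      cd_dose = grid$cd_dose,
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  df$cell <- design_cell(df$compartment, df$cd_dose)
  df <- df[order(df$cell, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Canonical cell label for a compartment/dose pair
#' @param compartment compartment level(s).
#' @param cd_dose dose level(s).
#' @return Character label(s) like `"rhizosphere.20"`.
#' @export
design_cell <- function(compartment, cd_dose) {
  paste(compartment, cd_dose, sep = ".")
}

#' Sample ids belonging to a design cell
#' @param design a [study_design()].
#' @param cell a cell label as produced by [design_cell()].
#' @return Character vector of sample ids.
#' @export
cell_samples <- function(design, cell) {
  design$sample_id[design$cell == cell]
}

#' Planted pathway-level effect for the synthetic generator
#'
#' Ground-truth descriptor: in one design cell, a fixed random fraction of
#' one pathway's KOs has its negative-binomial mean multiplied by
#' `2^log2_fc` (direction `"down"` flips the sign of `log2_fc`).
#'
#' @param pathway_id pathway the effect targets.
#' @param cell target design cell label.
#' @param log2_fc log2 fold-change magnitude (>= 0).
#' @param affected_fraction fraction of the pathway's KOs affected, in
#'   `[0, 1]`.
#' @param direction `"up"` or `"down"`.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(pathway_id, cell, log2_fc = 2,
                           affected_fraction = 1, direction = c("up", "down")) {
  direction <- match.arg(direction)
  assert_probability(affected_fraction, "affected_fraction")
  stopifnot(is.numeric(log2_fc), log2_fc >= 0)
  structure(list(pathway_id = pathway_id, cell = cell,
                 log2_fc = log2_fc, affected_fraction = affected_fraction,
                 direction = direction),
            class = "planted_effect")
}
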