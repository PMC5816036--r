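#' Sample x KO count table
#'
#' Container for a predicted-functional-profile count table (as produced by
#' predictive metagenome profiling tools): non-negative integer counts of
#' KEGG orthologs per sample, joined with the sample design. Counts are
#' stored features-by-samples (rows = KOs, columns = samples), the
#' convention of count-based differential-abundance tools.
#'
#' @param counts integer matrix, rows = KO ids, columns = sample ids.
#' @param design a [study_design()] covering exactly the count columns.
#' @return An object of class `ko_count_table` with elements `counts` and
#'   `design`.
#' @export
ko_count_table <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique KO row names and sample column names",
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing count at KO '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at KO '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "double"  # integer-valued; double avoids overflow
  if (!all(colnames(counts) %in% design$sample_id)) {
    stop("samples without metadata: ",
         paste(utils::head(setdiff(colnames(counts), design$sample_id), 5),
               collapse = ", "), call. = FALSE)
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "ko_count_table")
}

#' @export
print.ko_count_table <- function(x, ...) {
  cat(sprintf("ko_count_table: %d KOs x %d samples; cells: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$design$cell)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ko_count_table <- function(x) dim(x$counts)

#' Read a KO count table and its sample metadata
#'
#' The count TSV has KO ids in the first column (`ko_id`) and one column
#' per sample (the features-by-samples layout predictive-profiling tools
#' export; use `biom_layout = FALSE` for the transposed samples-by-KOs
#' layout). Metadata TSV needs `sample_id`, `compartment`, `cd_dose`.
#'
#' @param counts_path count TSV path.
#' @param metadata_path sample metadata TSV path.
#' @param biom_layout if `TRUE` (default) rows are observations (KOs) as in
#'   BIOM-style exports; if `FALSE` rows are samples.
#' @return A [ko_count_table()].
#' @export
read_ko_table <- function(counts_path, metadata_path, biom_layout = TRUE) {
  df <- read_tsv_strict(counts_path)
  if (names(df)[1] != "ko_id" && biom_layout) {
    names(df)[1] <- "ko_id"
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated ids in first column of ", counts_path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells in ", counts_path, call. = FALSE)
  rownames(m) <- ids
  if (!biom_layout) m <- t(m)
  meta <- read_tsv_strict(metadata_path)
  ko_count_table(m, study_design(meta))
}

#' Write a KO count table (and optionally its metadata) as TSV
#'
#' @param x a [ko_count_table()].
#' @param counts_path output TSV (rows = KOs, columns = samples).
#' @param metadata_path optional metadata TSV path.
#' @return `counts_path`, invisibly.
#' @export
write_ko_table <- function(x, counts_path, metadata_path = NULL) {
  stopifnot(inherits(x, "ko_count_table"))
  df <- data.frame(ko_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, counts_path)
  if (!is.null(metadata_path)) {
    write_tsv_strict(x$design[, c("sample_id", "compartment", "cd_dose")],
                     metadata_path)
  }
  invisible(counts_path)
}
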