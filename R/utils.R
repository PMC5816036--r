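`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Independent analysis strands (one per comparison and direction) each get
#' their own RNG substream so that adding a comparison never perturbs the
#' draws of another. The derivation is a plain integer hash of the labels
#' folded into the master seed; it is stable across platforms and R versions
#' and always lies in `[0, 2^31 - 1)`.
#'
#' @param seed integer master seed.
#' @param ... character labels identifying the substream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 5381
  for (code in utf8ToInt(labels)) {
    h <- (h * 33 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Canonical TSV dialect: tab-separated, header, UTF-8, no quoting.
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Normalize pathway names for registry matching: case-insensitive,
# whitespace-collapsed, stray punctuation from table extraction trimmed.
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("‘|’", "", x)
  gsub("[[:space:]]+", " ", x)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
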