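#' Derive a stage-specific seed from a global seed
#'
#' Expands one global integer seed into independent per-stage substreams keyed
#' by a stage name, so that inserting or re-running one pipeline stage does not
#' perturb the randomness of the others. The derived seed is kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name (e.g. `"syndata"`, `"pcsf"`).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261
  for (b in utf8ToInt(stage)) {
    h <- (xor(h, b) * 16777619) %% 2147483629
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483629 + 1)
}

#' Write a table as TSV
#'
#' @param x data.frame/data.table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return A data.table.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = c("", "NA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp helper used by several modules
clip01 <- function(x) pmin(pmax(x, 0), 1)
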