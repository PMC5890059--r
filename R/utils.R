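# Internal helpers shared across the package.

#' Iron biomarkers covered by the weight table
#'
#' Canonical biomarker labels, in the column order of the packaged weight
#' table. `"tsat"` is accepted everywhere as a shorthand for
#' `"transferrin_saturation"`.
#'
#' @return Character vector of the four biomarker labels.
#' @export
iron_biomarkers <- function() {
  c("iron", "ferritin", "transferrin", "transferrin_saturation")
}

# column suffix used in the weight-table TSV for each biomarker
.bm_suffix <- c(
  iron = "iron",
  ferritin = "ferritin",
  transferrin = "transferrin",
  transferrin_saturation = "tsat"
)

match_biomarker <- function(biomarker) {
  if (!is.character(biomarker) || length(biomarker) != 1L || is.na(biomarker)) {
    stop("`biomarker` must be a single string", call. = FALSE)
  }
  if (identical(biomarker, "tsat")) {
    return("transferrin_saturation")
  }
  ok <- iron_biomarkers()
  if (!biomarker %in% ok) {
    stop(
      "unknown biomarker '", biomarker, "'; expected one of: ",
      paste(ok, collapse = ", "), " (or 'tsat')",
      call. = FALSE
    )
  }
  biomarker
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. A NULL seed runs `code` on the current
# stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# k sub-seeds derived deterministically from the current RNG stream
draw_seeds <- function(k) {
  sample.int(.Machine$integer.max, k)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "."
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path,
    na.strings = c("", ".", "NA"),
    check.names = FALSE, stringsAsFactors = FALSE, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
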