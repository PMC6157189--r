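# Internal helpers: seeded RNG scoping, sample alignment, seed derivation.

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state,
# so library calls are deterministic without clobbering the session stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stop unless the sample id vectors are identical (same ids, same order).
checkAligned <- function(..., what = "inputs") {
  ids <- list(...)
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (length(ids[[i]]) != length(ref) || !all(ids[[i]] == ref))
      stop("sample misalignment between ", what,
           ": ids must be identical and identically ordered", call. = FALSE)
  }
  invisible(TRUE)
}

#' Deterministic per-gene Monte-Carlo seed
#'
#' Derives a seed from the master seed and a stable hash of the gene id
#' (not the gene's position in the list), so that scan results are
#' independent of gene order and any single gene can be rerun standalone
#' with the seed its scan used.
#'
#' @param masterSeed master scan seed.
#' @param geneId gene identifier.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
deriveGeneSeed <- function(masterSeed, geneId) {
  h <- 0
  for (k in utf8ToInt(as.character(geneId)))
    h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(masterSeed) * 48271 + h) %% 2147483629 + 1)
}

# Classed condition for tests that cannot be defined (e.g. rank-zero V).
undefinedTest <- function(msg) {
  stop(structure(class = c("pedaSPU_undefined_test", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.fitCounter <- new.env(parent = emptyenv())
.fitCounter$n <- 0L

#' Count null-model fits
#'
#' `fitNull()` increments an internal counter each time a model is fitted.
#' The counter lets callers verify the scan's efficiency contract: one null
#' model per genome scan, however many genes are tested.
#'
#' @param reset if `TRUE`, zero the counter after reading it.
#' @return integer number of `fitNull()` calls since the last reset.
#' @export
nullFitCount <- function(reset = FALSE) {
  n <- .fitCounter$n
  if (reset) .fitCounter$n <- 0L
  n
}
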