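#' @keywords internal
"_PACKAGE"

#' @importFrom stats pf phyper pchisq var cov sd hclust dist as.dendrogram
#'   is.leaf rlnorm rnorm rpois rmultinom runif cor setNames aggregate
#' @importFrom utils read.delim write.table head modifyList
NULL

# Tokens treated as missing in metadata files (configurable per call).
DEFAULT_NA_TOKENS <- c("", "NA", "na", "NaN")

# Reserved observation id collecting mass with no ancestor at a rank.
UNANNOTATED_ID <- "(unannotated)"

kmsg <- function(..., verbose = getOption("kitomeR.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[kitomeR] ", ...)
  invisible(NULL)
}

kwarn <- function(...) warning(..., call. = FALSE)

kstop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# Run a pipeline stage, re-labelling any error with the stage name so CLI
# failures say where they happened.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(e) else kstop(stage, msg)
  })
}

# Deterministic RNG scope: evaluates expr under set.seed(seed) and restores
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
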