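## Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats runif rnorm plogis median
#' @importFrom utils read.delim write.table packageVersion
NULL

## Validation failures carry their own condition class so callers (and the
## command-line wrapper) can distinguish bad input (exit 2) from numerical
## failure (exit 3).
.valStop <- function(...) {
  stop(errorCondition(paste0(...), class = c("nccm_validation_error", "nccm_error")))
}

.numStop <- function(...) {
  stop(errorCondition(paste0(...), class = c("nccm_numerical_error", "nccm_error")))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.pkgVersion <- function() as.character(utils::packageVersion("nccm"))

## Threshold grid t1, t1+0.1, ..., t2 rounded to one decimal so grid values
## compare exactly.
.thresholdGrid <- function(t1, t2) {
  grid <- round(seq(0.1, 0.9, by = 0.1), 1)
  t1 <- round(t1, 10); t2 <- round(t2, 10)
  if (!(t1 %in% grid) || !(t2 %in% grid) || t1 >= t2) {
    .valStop("thresholds must satisfy t1 < t2 with both in {0.1, ..., 0.9}; got (",
             t1, ", ", t2, ")")
  }
  round(seq(t1, t2, by = 0.1), 1)
}

## Metadata header written at the top of every TSV the pipeline emits.
.metaHeader <- function(...) {
  fields <- c(list(...), list(tool = paste0("nccm ", .pkgVersion())))
  vapply(names(fields), function(nm) {
    sprintf("# %s: %s", nm, paste(format(fields[[nm]], trim = TRUE), collapse = " "))
  }, character(1L))
}
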