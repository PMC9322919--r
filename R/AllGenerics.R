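#' Accessors for nccm classes
#'
#' Small accessor generics: \code{geneIds} (node/gene identifiers),
#' \code{networkEdges} (edge table of a \code{LogicNetwork}),
#' \code{thresholds} (grid of a \code{ControlProfile}),
#' \code{profileValues} (genes x thresholds matrix),
#' \code{screenTable} (per-gene table of a \code{ScreenResult}),
#' \code{targetGenes} (planted targets of a \code{SyntheticTruth}).
#'
#' @param x an nccm S4 object.
#' @return the slot contents named above.
#' @name nccm-accessors
#' @examples
#' net <- new("LogicNetwork", geneIds = c("A", "B"),
#'            edges = data.frame(source = "A", target = "B", weight = 0.8),
#'            threshold = 0.5, alpha = 0, k = 3L, group = "Con")
#' geneIds(net)
#' networkEdges(net)
NULL

#' @rdname nccm-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname nccm-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname nccm-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname nccm-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname nccm-accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname nccm-accessors
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname nccm-accessors
#' @export
setMethod("geneIds", "LogicNetwork", function(x) x@geneIds)

#' @rdname nccm-accessors
#' @export
setMethod("geneIds", "ControlProfile", function(x) x@geneIds)

#' @rdname nccm-accessors
#' @export
setMethod("networkEdges", "LogicNetwork", function(x) x@edges)

#' @rdname nccm-accessors
#' @export
setMethod("thresholds", "ControlProfile", function(x) x@thresholds)

#' @rdname nccm-accessors
#' @export
setMethod("profileValues", "ControlProfile", function(x) x@values)

#' @rdname nccm-accessors
#' @export
setMethod("screenTable", "ScreenResult", function(x) x@table)

#' @rdname nccm-accessors
#' @export
setMethod("targetGenes", "SyntheticTruth", function(x) x@targetGenes)

setMethod("show", "LogicNetwork", function(object) {
  cat("LogicNetwork:", length(object@geneIds), "genes,",
      nrow(object@edges), "directed edges\n")
  cat("  threshold:", object@threshold, " alpha:", object@alpha,
      " k:", object@k, "\n")
  if (length(object@group) && nzchar(object@group))
    cat("  group:", object@group, "\n")
})

setMethod("show", "ControlProfile", function(object) {
  cat("ControlProfile (", object@metric, "): ",
      length(object@geneIds), " genes x ", length(object@thresholds),
      " thresholds [", min(object@thresholds), ", ",
      max(object@thresholds), "]\n", sep = "")
  cat("  group:", object@group, " mode:",
      if (is.null(object@params$mode)) "-" else object@params$mode, "\n")
})

setMethod("show", "ScreenResult", function(object) {
  sel <- sum(object@table$selected)
  cat(object@method, " screen over grid (", object@grid[1], ", ",
      object@grid[2], "), cutoff ", object@cutoff, ": ",
      sel, " of ", nrow(object@table), " genes selected\n", sep = "")
  top <- object@table[order(-object@table$score), , drop = FALSE]
  print(utils::head(top, 5L), row.names = FALSE)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(unique(c(object@netCon$source, object@netCon$target,
                                         object@targetGenes))), "+ genes;",
      nrow(object@netCon), "control edges,", nrow(object@netExp), "rewired-group edges;",
      length(object@targetGenes), "target genes\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  v <- object@values
  for (nm in names(v))
    cat("  ", nm, ": ", paste(format(v[[nm]]), collapse = " "), "\n", sep = "")
})
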