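#' S4 classes for logic-network screening
#'
#' @description
#' \code{LogicNetwork} holds the weighted directed graph inferred for one
#' sample group at one weight threshold.  Edges are stored as a
#' \code{data.frame} with columns \code{source}, \code{target},
#' \code{weight}; the adjacency convention used by the controllability code
#' is \eqn{a_{ij} = } weight of the edge \eqn{j \to i}
#' (see \code{\link{adjacencyMatrix}}).
#'
#' @slot geneIds character vector of node identifiers (all genes, including
#'   isolated ones).
#' @slot edges data.frame(source, target, weight) with weights in (0, 1].
#' @slot threshold numeric scalar; the weight floor applied (edges with
#'   weight below it were dropped).
#' @slot alpha numeric scalar; the direction threshold used when the network
#'   was built.
#' @slot k integer scalar; the bin exponent (the unit interval is split into
#'   2^k parts before entropies are estimated).
#' @slot group character scalar naming the sample group the network was
#'   inferred from ("" when unknown, e.g. after reading from file).
#'
#' @name nccm-classes
#' @aliases LogicNetwork-class
#' @exportClass LogicNetwork
setClass("LogicNetwork",
  representation(geneIds = "character", edges = "data.frame",
                 threshold = "numeric", alpha = "numeric",
                 k = "integer", group = "character"))

setValidity("LogicNetwork", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!all(c("source", "target", "weight") %in% names(e)))
    return("edges must have columns source, target, weight")
  if (anyDuplicated(object@geneIds))
    msgs <- c(msgs, "gene ids must be unique")
  if (nrow(e)) {
    if (!all(e$source %in% object@geneIds) || !all(e$target %in% object@geneIds))
      msgs <- c(msgs, "edge endpoints must be in geneIds")
    if (any(e$source == e$target))
      msgs <- c(msgs, "self-loops are not allowed")
    key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
    if (anyDuplicated(key))
      msgs <- c(msgs, "at most one direction per gene pair is allowed")
    if (any(e$weight <= 0) || any(e$weight > 1 + 1e-9))
      msgs <- c(msgs, "edge weights must lie in (0, 1]")
    if (length(object@threshold) == 1L && any(e$weight < object@threshold - 1e-9))
      msgs <- c(msgs, "all edge weights must be >= threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn nccm-classes Per-gene capability (or degree) values across an
#'   ascending threshold grid for one group.
#' @slot thresholds ascending numeric grid (step 0.1).
#' @slot values integer matrix, genes x thresholds.
#' @slot metric "capability" or "degree".
#' @slot params list of inference parameters (k, alpha, mode) recorded for
#'   reproducibility.
#' @aliases ControlProfile-class
#' @exportClass ControlProfile
setClass("ControlProfile",
  representation(geneIds = "character", thresholds = "numeric",
                 values = "matrix", metric = "character",
                 group = "character", params = "list"))

setValidity("ControlProfile", function(object) {
  msgs <- character(0)
  if (!object@metric %in% c("capability", "degree"))
    msgs <- c(msgs, "metric must be 'capability' or 'degree'")
  if (nrow(object@values) != length(object@geneIds))
    msgs <- c(msgs, "values must have one row per gene")
  if (ncol(object@values) != length(object@thresholds))
    msgs <- c(msgs, "values must have one column per threshold")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msgs <- c(msgs, "thresholds must be strictly ascending")
  N <- length(object@geneIds)
  if (object@metric == "capability" && length(object@values) &&
      (any(object@values < 1L) || any(object@values > N)))
    msgs <- c(msgs, "capabilities must lie in {1, ..., N}")
  if (object@metric == "degree" && length(object@values) && any(object@values < 0L))
    msgs <- c(msgs, "degrees must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn nccm-classes Per-gene screening scores, selection flags and
#'   fold-change categories for one method (NCCM or DDM).
#' @slot table data.frame with columns gene, score, capability_fc,
#'   expression_fc, category, selected (input gene order).
#' @slot method "NCCM" or "DDM".
#' @slot grid numeric length-2 (t1, t2).
#' @slot cutoff numeric scalar; the beta (NCCM) or gamma (DDM) cut applied.
#' @slot profiles list with the two \code{ControlProfile} objects
#'   (\code{con}, \code{exp}) the scores were computed from (may be empty).
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(table = "data.frame", method = "character",
                 grid = "numeric", cutoff = "numeric", params = "list",
                 profiles = "list"))

setValidity("ScreenResult", function(object) {
  msgs <- character(0)
  need <- c("gene", "score", "capability_fc", "expression_fc", "category", "selected")
  if (!all(need %in% names(object@table)))
    msgs <- c(msgs, paste("table must have columns", paste(need, collapse = ", ")))
  if (!object@method %in% c("NCCM", "DDM"))
    msgs <- c(msgs, "method must be 'NCCM' or 'DDM'")
  if ("score" %in% names(object@table) && any(object@table$score < -1e-12))
    msgs <- c(msgs, "scores must be non-negative")
  if (all(c("score", "selected") %in% names(object@table)) &&
      length(object@cutoff) == 1L &&
      !identical(object@table$selected, object@table$score > object@cutoff))
    msgs <- c(msgs, "selected flag must equal score > cutoff (strict)")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn nccm-classes Ground truth of the two-group simulator: the
#'   generating networks of both groups and the genes touched by the planted
#'   rewiring.
#' @slot netCon,netExp data.frame(source, target, weight) generating DAGs.
#' @slot targetGenes endpoints of the edges in the symmetric difference of
#'   the two DAGs.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(netCon = "data.frame", netExp = "data.frame",
                 targetGenes = "character", params = "list"))

#' @describeIn nccm-classes Validated configuration of a full screening run;
#'   see \code{\link{runConfig}}.
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig", representation(values = "list"))
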