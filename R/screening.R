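## Differential screening between the two groups: separability of the mean
## curves, per-gene CC_v / D_u scores, strict selection cuts, and the
## fold-change categories.

#' Are two mean curves separable over the threshold grid?
#'
#' Two groups' capability (or degree) curves are separable when they never
#' intersect at any sampled threshold: the gap keeps one strict sign across
#' the whole grid. Separability indicates a genuine structural difference
#' between the two groups' networks and is the stated precondition for the
#' differential screening.
#'
#' @param curveCon,curveExp equal-length numeric vectors of per-threshold
#'   means (see \code{\link{networkCapability}}).
#' @return logical scalar.
#' @examples
#' separable(c(2, 3, 4), c(5, 6, 7))   # TRUE
#' separable(c(2, 6, 4), c(5, 3, 7))   # FALSE (curves cross)
#' @export
separable <- function(curveCon, curveExp) {
  if (length(curveCon) != length(curveExp))
    .valStop("curves must have equal length")
  d <- curveCon - curveExp
  all(d > 0) || all(d < 0)
}

## Shared score kernel: per-gene mean absolute per-threshold difference.
.profileScore <- function(profCon, profExp, what) {
  stopifnot(is(profCon, "ControlProfile"), is(profExp, "ControlProfile"))
  if (profCon@metric != what || profExp@metric != what)
    .valStop("profiles must carry metric '", what, "'")
  if (!identical(profCon@geneIds, profExp@geneIds)) {
    diffs <- c(setdiff(profCon@geneIds, profExp@geneIds),
               setdiff(profExp@geneIds, profCon@geneIds))
    .valStop("gene sets differ between profiles: ",
             paste(unique(diffs), collapse = ", "))
  }
  if (!isTRUE(all.equal(profCon@thresholds, profExp@thresholds)))
    .valStop("profiles must share the same threshold grid")
  if (!separable(colMeans(profCon@values), colMeans(profExp@values)))
    warning("mean ", what, " curves are not separable over the grid; ",
            "scores may not indicate a consistent structural difference",
            call. = FALSE)
  scores <- rowMeans(abs(profCon@values - profExp@values))
  names(scores) <- profCon@geneIds
  scores
}

#' Per-gene control-capability difference score CC_v
#'
#' \eqn{CC_v = \frac{1}{\lambda}\sum_{i=1}^{\lambda} |v^{Con}_i -
#' v^{Exp}_i|}: the mean absolute difference of node v's control
#' capability between the two groups' networks across the threshold grid.
#' Symmetric under swapping the groups; warns (but proceeds) when the mean
#' curves are not separable.
#'
#' @param profCon,profExp capability profiles of the two groups on the same
#'   gene set and grid.
#' @return named numeric vector of non-negative scores.
#' @export
ccScore <- function(profCon, profExp) .profileScore(profCon, profExp, "capability")

#' Per-gene degree difference score D_u (degree-difference comparator)
#'
#' Same aggregation as \code{\link{ccScore}} but on total node degree:
#' \eqn{D_u = \frac{1}{\lambda}\sum_i |u^{Con}_i - u^{Exp}_i|}.
#'
#' @param degCon,degExp degree profiles of the two groups.
#' @return named numeric vector of non-negative scores.
#' @export
dScore <- function(degCon, degExp) .profileScore(degCon, degExp, "degree")

#' Select differential genes by a strict score cut
#'
#' \code{selectDCCG} returns the genes with \eqn{CC_v > \beta} (strictly);
#' \code{selectDDG} the genes with \eqn{D_u > \gamma}. A gene exactly at
#' the cut is not selected.
#'
#' @param scores named numeric vector from \code{\link{ccScore}} or
#'   \code{\link{dScore}}.
#' @param beta,gamma positive cut value.
#' @return character vector of selected gene ids.
#' @export
selectDCCG <- function(scores, beta) {
  if (length(beta) != 1L || is.na(beta) || beta <= 0)
    .valStop("beta must be a positive number")
  names(scores)[scores > beta]
}

#' @rdname selectDCCG
#' @export
selectDDG <- function(scores, gamma) {
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    .valStop("gamma must be a positive number")
  names(scores)[scores > gamma]
}

#' Degree profile of one group across a threshold sweep
#'
#' Total degree (in + out) of every gene in the group's logic network at
#' each threshold of the grid; the degree-based analogue of
#' \code{\link{capabilityProfile}} used by the degree-difference
#' comparator.
#'
#' @inheritParams capabilityProfile
#' @return a \code{\linkS4class{ControlProfile}} with metric
#'   \code{"degree"}.
#' @export
degreeProfile <- function(se, group, t1 = 0.1, t2 = 0.9, k = 1L, alpha = 0,
                          normalize = c("group", "pooled")) {
  .sweepProfile(se, group, t1, t2, k, alpha, metric = "degree",
                normalize = match.arg(normalize))
}

#' Fold-changes and categories between the two groups
#'
#' For every gene: the capability fold-change is the ratio of the
#' across-threshold mean profile values, experimental over control group
#' (AMI/Control direction in the case-control setting); the expression
#' fold-change is the relative difference of raw group mean expression,
#' (Exp - Con)/Con. Genes are tagged by two conventional cuts: capability
#' fold-change > 2 counts as high control-capability change (CA_high),
#' expression fold-change > 0.2 as high expression change (GeExp_high).
#' Genes with a zero control-group denominator get NA fold-changes and the
#' category \code{"undefined"}.
#'
#' @param profCon,profExp profiles (capability for NCCM, degree for DDM) of
#'   the two groups.
#' @param se the raw expression object the profiles were computed from.
#' @return data.frame(gene, capability_fc, expression_fc, category).
#' @export
foldChanges <- function(profCon, profExp, se) {
  stopifnot(is(profCon, "ControlProfile"), is(profExp, "ControlProfile"))
  if (!identical(profCon@geneIds, profExp@geneIds))
    .valStop("profiles must share the same gene set")
  ids <- profCon@geneIds
  capCon <- rowMeans(profCon@values)
  capExp <- rowMeans(profExp@values)
  capFC <- ifelse(capCon == 0, NA_real_, capExp / capCon)

  matCon <- .groupMatrix(se, profCon@group)
  matExp <- .groupMatrix(se, profExp@group)
  if (!identical(rownames(matCon), ids))
    matCon <- matCon[ids, , drop = FALSE]
  if (!identical(rownames(matExp), ids))
    matExp <- matExp[ids, , drop = FALSE]
  mCon <- rowMeans(matCon)
  mExp <- rowMeans(matExp)
  exprFC <- ifelse(mCon == 0, NA_real_, (mExp - mCon) / mCon)

  category <- ifelse(is.na(capFC) | is.na(exprFC), "undefined",
              paste0(ifelse(capFC > 2, "CA_high", "CA_low"), "_",
                     ifelse(exprFC > 0.2, "GeExp_high", "GeExp_low")))
  data.frame(gene = ids, capability_fc = capFC, expression_fc = exprFC,
             category = category, stringsAsFactors = FALSE)
}

#' Screen differential genes between the two groups
#'
#' End-to-end screening on an in-memory expression object: builds both
#' groups' profiles over the threshold grid, checks separability of the
#' mean curves, computes per-gene scores (CC_v for \code{method = "nccm"},
#' D_u for \code{method = "ddm"}), applies the strict cut, and attaches
#' fold-changes and categories.
#'
#' @param se \code{SummarizedExperiment} from \code{\link{readExpression}}
#'   (first group level = control by convention).
#' @param method \code{"nccm"} (control capability) or \code{"ddm"}
#'   (degree comparator).
#' @param cutoff the beta (NCCM) or gamma (DDM) selection cut, strict.
#' @param conGroup,expGroup group labels; default to the first and second
#'   level of \code{colData(se)$group}.
#' @inheritParams capabilityProfile
#' @return a \code{\linkS4class{ScreenResult}}; rows keep the input gene
#'   order (use \code{\link{writeScreenTable}} for the score-sorted file).
#' @export
screenGenes <- function(se, method = c("nccm", "ddm"), cutoff,
                        conGroup = NULL, expGroup = NULL,
                        t1 = 0.1, t2 = 0.9, k = 1L, alpha = 0,
                        mode = c("weighted", "structural"),
                        normalize = c("group", "pooled"),
                        R = 5L, tol = 1e-9, seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  if (missing(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0)
    .valStop("a positive selection cutoff (beta or gamma) is required")
  grp <- .groupLabels(se)
  if (is.null(conGroup)) conGroup <- levels(grp)[1L]
  if (is.null(expGroup)) expGroup <- levels(grp)[2L]
  mkProf <- function(g) {
    if (method == "nccm")
      capabilityProfile(se, g, t1, t2, k = k, alpha = alpha, mode = mode,
                        normalize = normalize, R = R, tol = tol, seed = seed)
    else
      degreeProfile(se, g, t1, t2, k = k, alpha = alpha, normalize = normalize)
  }
  profCon <- mkProf(conGroup)
  profExp <- mkProf(expGroup)
  scores <- if (method == "nccm") ccScore(profCon, profExp)
            else dScore(profCon, profExp)
  fc <- foldChanges(profCon, profExp, se)
  tab <- data.frame(gene = fc$gene, score = as.numeric(scores),
                    capability_fc = fc$capability_fc,
                    expression_fc = fc$expression_fc,
                    category = fc$category,
                    selected = as.numeric(scores) > cutoff,
                    stringsAsFactors = FALSE)
  new("ScreenResult", table = tab,
      method = if (method == "nccm") "NCCM" else "DDM",
      grid = c(t1, t2), cutoff = cutoff,
      params = list(k = as.integer(k), alpha = alpha, mode = mode,
                    normalize = normalize, conGroup = conGroup,
                    expGroup = expGroup, seed = seed),
      profiles = list(con = profCon, exp = profExp))
}
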