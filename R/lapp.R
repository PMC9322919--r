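## Logic-network construction: per-gene min-max scaling, dyadic binning,
## plug-in entropies, mutual information, uncertainty coefficients, and the
## direction filter that turns pairwise U values into a directed network.

#' Min-max normalise a genes-by-samples matrix
#'
#' Rescales every gene (row) linearly onto [0, 1] across the samples of the
#' matrix. Constant genes map to all zeros: a gene with no variation carries
#' no information (entropy 0) and will be isolated in the inferred network.
#'
#' @param x numeric matrix, genes in rows.
#' @return matrix of the same shape with all entries in [0, 1].
#' @examples
#' minmaxNormalize(rbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5)))
#' @export
minmaxNormalize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    .valStop("expression values must be finite and non-missing")
  rmin <- apply(x, 1L, min)
  rng <- apply(x, 1L, max) - rmin
  out <- (x - rmin) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  out
}

#' Snap normalised values onto the dyadic grid l / 2^k
#'
#' The unit interval is divided into \code{2^k} parts. A value below 0.5 in
#' \eqn{[l/2^k, (l+1)/2^k)} is replaced by the left grid point \eqn{l/2^k};
#' a value of at least 0.5 in \eqn{(l/2^k, (l+1)/2^k]} is replaced by the
#' right grid point \eqn{(l+1)/2^k}. Values already on a grid point and
#' >= 0.5 are unchanged. This refines the 0/1 dichotomy of classical logic
#' profiles while keeping the number of symbols per gene bounded by
#' \code{2^k + 1}.
#'
#' @param x numeric matrix or vector with entries in [0, 1].
#' @param k positive integer bin exponent.
#' @return object of the same shape whose entries all equal l / 2^k for
#'   integer l.
#' @examples
#' binExpression(c(0.3, 0.6, 0.5), k = 2)   # 0.25 0.75 0.50
#' @export
binExpression <- function(x, k = 1L) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    .valStop("k must be a positive integer")
  if (anyNA(x) || any(x < -1e-9) || any(x > 1 + 1e-9))
    .valStop("binning requires values in [0, 1]; normalise first")
  m <- 2^as.integer(k)
  y <- pmin(pmax(x, 0), 1) * m
  ## guard against values sitting a rounding error off a grid point
  yr <- round(y)
  y[abs(y - yr) < 1e-9] <- yr[abs(y - yr) < 1e-9]
  out <- ifelse(x < 0.5, floor(y), ceiling(y)) / m
  if (is.matrix(x)) dimnames(out) <- dimnames(x)
  out
}

#' Plug-in Shannon entropy of one binned row
#'
#' Empirical entropy \eqn{H = -\sum_x p(x) \log_2 p(x)} (bits) over the
#' observed symbol frequencies; no pseudocounts are added.
#'
#' @param x vector of binned values (any discrete values work).
#' @param base logarithm base; 2 (bits) by default. The base cancels in the
#'   uncertainty coefficient, so the inferred edge set does not depend on it.
#' @return non-negative scalar; 0 iff all values are identical.
#' @examples
#' shannonEntropy(c(0, 0, 1, 1))   # 1 bit
#' @export
shannonEntropy <- function(x, base = 2) {
  if (length(x) == 0L) .valStop("entropy of an empty row is undefined")
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log(p, base = base))
}

#' Plug-in joint entropy of two binned rows
#'
#' \eqn{H(X,Y) = -\sum p(x,y) \log_2 p(x,y)} over empirical pair
#' frequencies. Always satisfies
#' \eqn{\max(H(X), H(Y)) \le H(X,Y) \le H(X) + H(Y)}.
#'
#' @param x,y equal-length vectors of binned values.
#' @inheritParams shannonEntropy
#' @return non-negative scalar (bits by default).
#' @export
jointEntropy <- function(x, y, base = 2) {
  if (length(x) != length(y)) .valStop("rows must have equal length")
  shannonEntropy(paste(x, y, sep = "\r"), base = base)
}

#' Plug-in mutual information of two binned rows
#'
#' \eqn{I(X,Y) = H(X) + H(Y) - H(X,Y)}; non-negative for the plug-in
#' estimator and symmetric in its arguments.
#'
#' @inheritParams jointEntropy
#' @return non-negative scalar (bits by default).
#' @export
mutualInformation <- function(x, y, base = 2) {
  i <- shannonEntropy(x, base) + shannonEntropy(y, base) - jointEntropy(x, y, base)
  max(i, 0)
}

#' Uncertainty coefficient U(X|Y)
#'
#' \eqn{U(X|Y) = I(X,Y) / H(X)}: the fraction of X's uncertainty removed by
#' knowing Y, in [0, 1]. A constant X (H(X) = 0) needs no explanation and
#' returns 0, which also avoids division by zero.
#'
#' @inheritParams jointEntropy
#' @return scalar in [0, 1].
#' @export
uValue <- function(x, y) {
  hx <- shannonEntropy(x)
  if (hx <= 1e-12) return(0)
  min(mutualInformation(x, y) / hx, 1)
}

## Directed candidate edges for one group's (raw) submatrix.
## Returns all direction-filtered edges with their U weights, *before* any
## weight-threshold floor, so a threshold sweep can reuse them.
## Convention: support for i -> j is U(j | i) = I(i, j) / H(j); for each
## unordered pair the larger support wins, ties (within alpha) give no edge.
.lappEdges <- function(mat, k = 1L, alpha = 0, prenormalized = FALSE) {
  if (alpha < 0) .valStop("alpha must be >= 0")
  b <- binExpression(if (prenormalized) mat else minmaxNormalize(mat), k = k)
  n <- nrow(b)
  ids <- rownames(b)
  H <- apply(b, 1L, shannonEntropy)
  src <- character(0); tgt <- character(0); wt <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        mi <- mutualInformation(b[i, ], b[j, ])
        x <- if (H[j] > 1e-12) min(mi / H[j], 1) else 0  # U(j|i): i -> j
        y <- if (H[i] > 1e-12) min(mi / H[i], 1) else 0  # U(i|j): j -> i
        if (x - y > alpha) {
          src <- c(src, ids[i]); tgt <- c(tgt, ids[j]); wt <- c(wt, x)
        } else if (y - x > alpha) {
          src <- c(src, ids[j]); tgt <- c(tgt, ids[i]); wt <- c(wt, y)
        }
      }
    }
  }
  data.frame(source = src, target = tgt, weight = wt,
             stringsAsFactors = FALSE)
}

## Extract one group's genes x samples raw submatrix from a
## SummarizedExperiment carrying a colData 'group' column.
.groupMatrix <- function(se, group) {
  grp <- .groupLabels(se)
  if (!group %in% levels(grp))
    .valStop("unknown group '", group, "'; available: ",
             paste(levels(grp), collapse = ", "))
  SummarizedExperiment::assay(se)[, grp == group, drop = FALSE]
}

.groupLabels <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"group" %in% names(cd))
    .valStop("expression object must carry a colData column 'group'")
  factor(cd$group, levels = unique(as.character(cd$group)))
}

#' Build one group's first-order logic network
#'
#' Runs the full inference for the samples of one group: per-gene min-max
#' normalisation within the group, dyadic binning with exponent \code{k},
#' pairwise plug-in mutual information, uncertainty coefficients
#' \eqn{U(X|Y) = I(X,Y)/H(X)}, the direction filter (for every unordered
#' pair the better-supported direction is kept when the two supports differ
#' by more than \code{alpha}; equal supports give no edge), and finally the
#' weight floor \code{t} (edges with weight below \code{t} are dropped).
#' All genes remain as nodes, possibly isolated.
#'
#' @param se \code{SummarizedExperiment} with a colData column \code{group}
#'   (see \code{\link{readExpression}}), or a plain numeric matrix with gene
#'   rownames when \code{group} is omitted.
#' @param group group label to use (ignored for a plain matrix).
#' @param t weight threshold in [0, 1]; an edge is retained iff its weight
#'   is >= t (inclusive floor).
#' @param alpha direction threshold; 0 keeps every strictly better-supported
#'   direction.
#' @param k bin exponent, see \code{\link{binExpression}}.
#' @param normalize \code{"group"} (default) rescales within the group's own
#'   submatrix; \code{"pooled"} rescales across all samples before
#'   subsetting.
#' @return a \code{\linkS4class{LogicNetwork}}.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12),
#'            c = c(6, 1, 4, 2, 5, 3))
#' buildLogicNetwork(m, t = 0.5, k = 2)
#' @export
buildLogicNetwork <- function(se, group = NULL, t = 0.1, alpha = 0, k = 1L,
                              normalize = c("group", "pooled")) {
  normalize <- match.arg(normalize)
  if (length(t) != 1L || is.na(t) || t < 0 || t > 1)
    .valStop("threshold t must lie in [0, 1]")
  prenorm <- FALSE
  if (is(se, "SummarizedExperiment")) {
    if (is.null(group)) .valStop("'group' is required for a SummarizedExperiment")
    if (normalize == "pooled") {
      pooled <- minmaxNormalize(SummarizedExperiment::assay(se))
      grp <- .groupLabels(se)
      if (!group %in% levels(grp))
        .valStop("unknown group '", group, "'")
      mat <- pooled[, grp == group, drop = FALSE]
      prenorm <- TRUE
    } else {
      mat <- .groupMatrix(se, group)
    }
  } else {
    mat <- as.matrix(se)
    if (is.null(rownames(mat))) .valStop("matrix input requires gene rownames")
    if (is.null(group)) group <- ""
  }
  base <- .lappEdges(mat, k = k, alpha = alpha, prenormalized = prenorm)
  keep <- base$weight >= t - 1e-12
  new("LogicNetwork", geneIds = rownames(mat),
      edges = base[keep, , drop = FALSE],
      threshold = t, alpha = alpha, k = as.integer(k),
      group = as.character(group))
}
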