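## Node control capability: rank of the single-input Kalman controllability
## matrix C = (b, Ab, ..., A^(N-1) b), computed by an Arnoldi-style Krylov
## iteration so that no explicit matrix power is ever formed.

#' Adjacency matrix of a logic network
#'
#' Returns the N x N matrix A with \eqn{a_{ij}} equal to the weight of the
#' directed edge \eqn{j \to i} (column index = source, row index = target),
#' the convention under which the network dynamics read
#' \eqn{\dot x = A x + B u}.
#'
#' @param net a \code{\linkS4class{LogicNetwork}}.
#' @return numeric matrix with dimnames equal to \code{geneIds(net)}.
#' @export
adjacencyMatrix <- function(net) {
  stopifnot(is(net, "LogicNetwork"))
  ids <- net@geneIds
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net@edges
  if (nrow(e))
    A[cbind(match(e$target, ids), match(e$source, ids))] <- e$weight
  A
}

## Dimension of the Krylov space span{b, Ab, A^2 b, ...} by Arnoldi with
## full re-orthogonalisation. The per-step relative residual test makes the
## result invariant under rescaling of A.
.krylovRank <- function(A, v, tol = 1e-9) {
  N <- nrow(A)
  q <- numeric(N); q[v] <- 1
  Q <- matrix(q, N, 1L)
  for (step in seq_len(N - 1L)) {
    w <- as.numeric(A %*% Q[, ncol(Q)])
    pre <- sqrt(sum(w * w))
    if (pre == 0) break
    w <- w - Q %*% crossprod(Q, w)
    w <- w - Q %*% crossprod(Q, w)   # second pass for numerical safety
    nw <- sqrt(sum(w * w))
    if (nw <= tol * pre) break
    Q <- cbind(Q, w / nw)
  }
  ncol(Q)
}

#' Control capability of a node
#'
#' With a single input acting on node \code{v} (\eqn{B = e_v}), the control
#' capability is the rank of the controllability matrix
#' \eqn{C = (B, AB, A^2B, \ldots, A^{N-1}B)}: the dimension of the subspace
#' of the network the node can steer (Kalman rank criterion). It is an
#' integer between 1 (the node controls only itself) and N (the node
#' controls the whole network).
#'
#' The rank is computed as the dimension of the Krylov subspace
#' \eqn{span\{e_v, A e_v, A^2 e_v, \ldots\}} built with per-step
#' orthogonalisation, which avoids forming explicit powers of A (those
#' under/overflow already for a hundred genes) and is invariant under
#' rescaling of the weights.
#'
#' @param net a \code{\linkS4class{LogicNetwork}}.
#' @param v node identifier (gene id) or index.
#' @param mode \code{"weighted"} (default) uses the network's U-value
#'   weights as-is; \code{"structural"} takes the maximum rank over
#'   \code{R} random re-weightings of the existing edges (uniform on
#'   [0.5, 1.5]), approximating the generic rank of the topology.
#' @param R number of re-weightings in structural mode.
#' @param tol relative residual tolerance of the Krylov iteration.
#' @param seed RNG seed for structural mode (ignored in weighted mode).
#' @return integer in \{1, ..., N\}.
#' @examples
#' path3 <- new("LogicNetwork", geneIds = c("a", "b", "c"),
#'   edges = data.frame(source = c("a", "b"), target = c("b", "c"),
#'                      weight = c(0.9, 0.8)),
#'   threshold = 0, alpha = 0, k = 3L, group = "")
#' controlCapability(path3, "a")  # 3: the head steers the whole path
#' controlCapability(path3, "c")  # 1: the sink steers only itself
#' @export
controlCapability <- function(net, v, mode = c("weighted", "structural"),
                              R = 5L, tol = 1e-9, seed = 1L) {
  mode <- match.arg(mode)
  ids <- geneIds(net)
  if (is.character(v)) {
    vi <- match(v, ids)
    if (is.na(vi)) .valStop("node '", v, "' is not in the network")
  } else {
    vi <- as.integer(v)
    if (is.na(vi) || vi < 1L || vi > length(ids))
      .valStop("node index out of range")
  }
  A <- adjacencyMatrix(net)
  if (mode == "weighted") return(.krylovRank(A, vi, tol))
  e <- net@edges
  idx <- cbind(match(e$target, ids), match(e$source, ids))
  .withSeed(seed, {
    best <- 1L
    for (r in seq_len(R)) {
      if (nrow(e)) A[idx] <- runif(nrow(e), 0.5, 1.5)
      best <- max(best, .krylovRank(A, vi, tol))
    }
    best
  })
}

## Capabilities of every node of one fixed network (shared A).
.allCapabilities <- function(edges, ids, mode, R = 5L, tol = 1e-9, seed = 1L) {
  N <- length(ids)
  A <- matrix(0, N, N)
  idx <- NULL
  if (nrow(edges)) {
    idx <- cbind(match(edges$target, ids), match(edges$source, ids))
    A[idx] <- edges$weight
  }
  if (mode == "weighted")
    return(vapply(seq_len(N), function(v) .krylovRank(A, v, tol), integer(1L)))
  .withSeed(seed, {
    best <- rep(1L, N)
    for (r in seq_len(R)) {
      if (!is.null(idx)) A[idx] <- runif(nrow(edges), 0.5, 1.5)
      best <- pmax(best, vapply(seq_len(N), function(v) .krylovRank(A, v, tol),
                                integer(1L)))
    }
    best
  })
}

#' Control-capability profile of one group across a threshold sweep
#'
#' Builds the group's logic network at every threshold
#' \eqn{t_1, t_1 + 0.1, \ldots, t_2} and records each gene's control
#' capability, giving \eqn{\lambda = (t_2 - t_1)/0.1 + 1} columns. The
#' pairwise U values are computed once and re-thresholded, so the sweep
#' costs one network inference plus \eqn{\lambda} rank passes.
#'
#' Genes isolated at a high threshold stay in the node set with capability
#' 1, so column-wise averages are always over the full gene set.
#'
#' @inheritParams buildLogicNetwork
#' @param t1,t2 grid bounds, both in \{0.1, ..., 0.9\} with t1 < t2.
#' @inheritParams controlCapability
#' @return a \code{\linkS4class{ControlProfile}} with metric
#'   \code{"capability"}.
#' @export
capabilityProfile <- function(se, group, t1 = 0.1, t2 = 0.9, k = 1L,
                              alpha = 0, mode = c("weighted", "structural"),
                              normalize = c("group", "pooled"),
                              R = 5L, tol = 1e-9, seed = 1L) {
  mode <- match.arg(mode)
  .sweepProfile(se, group, t1, t2, k, alpha, metric = "capability",
                mode = mode, normalize = match.arg(normalize),
                R = R, tol = tol, seed = seed)
}

## Shared threshold-sweep driver for capability and degree profiles.
.sweepProfile <- function(se, group, t1, t2, k, alpha, metric,
                          mode = "weighted", normalize = "group",
                          R = 5L, tol = 1e-9, seed = 1L) {
  grid <- .thresholdGrid(t1, t2)
  if (is(se, "SummarizedExperiment")) {
    if (normalize == "pooled") {
      pooled <- minmaxNormalize(SummarizedExperiment::assay(se))
      grp <- .groupLabels(se)
      if (!group %in% levels(grp)) .valStop("unknown group '", group, "'")
      mat <- pooled[, grp == group, drop = FALSE]
      base <- .lappEdges(mat, k = k, alpha = alpha, prenormalized = TRUE)
    } else {
      mat <- .groupMatrix(se, group)
      base <- .lappEdges(mat, k = k, alpha = alpha)
    }
  } else {
    mat <- as.matrix(se)
    if (is.null(rownames(mat))) .valStop("matrix input requires gene rownames")
    if (is.null(group)) group <- ""
    base <- .lappEdges(mat, k = k, alpha = alpha)
  }
  ids <- rownames(mat)
  vals <- matrix(0L, length(ids), length(grid),
                 dimnames = list(ids, format(grid)))
  for (i in seq_along(grid)) {
    e <- base[base$weight >= grid[i] - 1e-12, , drop = FALSE]
    vals[, i] <- if (metric == "capability") {
      .allCapabilities(e, ids, mode = mode, R = R, tol = tol, seed = seed)
    } else {
      .nodeDegrees(e, ids)
    }
  }
  new("ControlProfile", geneIds = ids, thresholds = grid, values = vals,
      metric = metric, group = as.character(group),
      params = list(k = as.integer(k), alpha = alpha, mode = mode,
                    normalize = normalize, tol = tol))
}

.nodeDegrees <- function(edges, ids) {
  deg <- integer(length(ids))
  if (nrow(edges)) {
    t1 <- tabulate(match(edges$source, ids), nbins = length(ids))
    t2 <- tabulate(match(edges$target, ids), nbins = length(ids))
    deg <- t1 + t2
  }
  deg
}

#' Network-average control capability per threshold
#'
#' The control capability of a network is the arithmetic mean of its nodes'
#' capabilities; applied column-wise this gives the capability curve over
#' the threshold grid that the separability assessment compares between
#' groups.
#'
#' @param profile a \code{\linkS4class{ControlProfile}}.
#' @return named numeric vector, one mean per threshold.
#' @export
networkCapability <- function(profile) {
  stopifnot(is(profile, "ControlProfile"))
  if (!length(profile@geneIds)) .valStop("profile is empty")
  colMeans(profile@values)
}
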