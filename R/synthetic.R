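## Two-group expression simulator with a planted structural difference:
## a random DAG drives the control group, a rewired copy (E deletions +
## E additions) drives the experimental group, so the genes touched by the
## rewiring are a recoverable ground truth for the screening stage.

#' Simulate two-group expression data with planted network rewiring
#'
#' Draws a random DAG over \code{N} genes (each forward pair is an edge
#' with probability \eqn{p = 2/N}; signed weights uniform on
#' \eqn{\pm[0.5, 1.5]}), then rewires it for the experimental group by
#' deleting \code{E} existing edges and adding \code{E} new forward edges.
#' For every sample, root genes are drawn i.i.d. uniform on [0, 1] and each
#' child is the logistic squashing of its centred weighted parent sum plus
#' Gaussian noise (sd \code{sigma}), clipped to [0, 1]. Both groups get
#' \code{M} samples; the control group is generated from the original DAG,
#' the experimental group from the rewired one.
#'
#' The seed fully determines the output: the same \code{seed} reproduces
#' the matrices bit for bit, and the two groups' sampling noise is
#' independent.
#'
#' @param N number of genes (>= 10).
#' @param M samples per group (>= 10).
#' @param sigma sampling-noise standard deviation on the [0, 1] scale.
#' @param E number of edges deleted (and added) in the rewiring,
#'   1 <= E <= N/4; E = 0 is allowed and plants no difference.
#' @param seed integer seed controlling all randomness.
#' @param matchSeeds if TRUE, both groups' samples are drawn from the same
#'   RNG stream position, so with \code{E = 0} and \code{sigma = 0} the two
#'   matrices are identical (useful for no-planted-difference checks). The
#'   default FALSE draws the groups' sampling noise independently.
#' @return list with \code{se}, a \code{SummarizedExperiment} whose first
#'   group level \code{"ConGroup"} is the control group, and \code{truth},
#'   a \code{\linkS4class{SyntheticTruth}} holding both generating DAGs and
#'   the planted target genes (endpoints of the edges in which the two DAGs
#'   differ).
#' @examples
#' sim <- simulateExpression(N = 12, M = 12, sigma = 0.05, E = 2, seed = 7)
#' sim$se
#' targetGenes(sim$truth)
#' @export
simulateExpression <- function(N = 30L, M = 40L, sigma = 0.05, E = 4L,
                               seed = 1L, matchSeeds = FALSE) {
  N <- as.integer(N); M <- as.integer(M); E <- as.integer(E)
  if (is.na(N) || N < 10L) .valStop("N must be >= 10")
  if (is.na(M) || M < 10L) .valStop("M must be >= 10")
  if (is.na(E) || E < 0L || E > N / 4) .valStop("E must satisfy 0 <= E <= N/4")
  if (sigma < 0) .valStop("sigma must be >= 0")
  genes <- sprintf("G%02d", seq_len(N))

  .withSeed(seed, {
    ## random DAG on the fixed topological order 1..N
    pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 2 / N
    ## the rewiring needs at least E edges to delete
    if (sum(keep) < E) keep[sample(which(!keep), E - sum(keep))] <- TRUE
    edgeIdx <- which(keep)
    wcon <- runif(length(edgeIdx), 0.5, 1.5) *
      sample(c(-1, 1), length(edgeIdx), replace = TRUE)

    ## rewire: delete E, add E new forward edges with fresh weights
    expIdx <- edgeIdx; wexp <- wcon
    if (E > 0L) {
      drop <- sample(seq_along(edgeIdx), E)
      free <- setdiff(seq_len(nrow(pairs)), edgeIdx)
      addn <- sample(free, E)
      expIdx <- c(edgeIdx[-drop], addn)
      wexp <- c(wcon[-drop],
                runif(E, 0.5, 1.5) * sample(c(-1, 1), E, replace = TRUE))
    }

    mkNet <- function(idx, w) {
      data.frame(source = genes[pairs[idx, 1L]],
                 target = genes[pairs[idx, 2L]],
                 weight = w, stringsAsFactors = FALSE)
    }
    netCon <- mkNet(edgeIdx, wcon)
    netExp <- mkNet(expIdx, wexp)

    keyCon <- paste(netCon$source, netCon$target)
    keyExp <- paste(netExp$source, netExp$target)
    changed <- c(setdiff(keyCon, keyExp), setdiff(keyExp, keyCon))
    targets <- as.character(sort(unique(unlist(strsplit(changed, " ", fixed = TRUE)))))

    ## propagate values down the DAG; gain 6 spreads the logistic response
    ## over most of [0, 1] for unit-scale parent sums
    sampleGroup <- function(net) {
      x <- matrix(0, N, M, dimnames = list(genes, NULL))
      parents <- split(seq_len(nrow(net)), match(net$target, genes))
      srcIdx <- match(net$source, genes)
      for (g in seq_len(N)) {
        pe <- parents[[as.character(g)]]
        if (is.null(pe)) {
          x[g, ] <- runif(M)
        } else {
          z <- colSums(matrix(net$weight[pe] * (x[srcIdx[pe], , drop = FALSE] - 0.5),
                              nrow = length(pe)))
          x[g, ] <- pmin(pmax(plogis(6 * z) + rnorm(M, 0, sigma), 0), 1)
        }
      }
      x
    }
    if (matchSeeds) {
      groupSeed <- as.integer(seed) %% 1000000L + 1000003L
      set.seed(groupSeed); matCon <- sampleGroup(netCon)
      set.seed(groupSeed); matExp <- sampleGroup(netExp)
    } else {
      matCon <- sampleGroup(netCon)
      matExp <- sampleGroup(netExp)
    }

    mat <- cbind(matCon, matExp)
    colnames(mat) <- c(sprintf("Con_%02d", seq_len(M)),
                       sprintf("Exp_%02d", seq_len(M)))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = mat),
      colData = S4Vectors::DataFrame(
        group = factor(rep(c("ConGroup", "ExpGroup"), each = M),
                       levels = c("ConGroup", "ExpGroup")),
        row.names = colnames(mat)))
    truth <- new("SyntheticTruth", netCon = netCon, netExp = netExp,
                 targetGenes = targets,
                 params = list(N = N, M = M, sigma = sigma, E = E,
                               seed = as.integer(seed)))
    list(se = se, truth = truth)
  })
}

#' Recovery benchmark of the screening stage on simulated data
#'
#' Runs the full pipeline (simulate, profile both groups, CC_v or D_u
#' scores) over seeded replicates and asks, per replicate, whether the
#' median score of the planted target genes exceeds the median score of the
#' non-target genes -- a ranking property that a working screening stage
#' must recover.
#'
#' @param nrep number of replicates; replicate r uses seed
#'   \code{seed + r - 1}.
#' @inheritParams simulateExpression
#' @param method \code{"nccm"} or \code{"ddm"}.
#' @inheritParams capabilityProfile
#' @return data.frame with one row per replicate: \code{seed},
#'   \code{medianTarget}, \code{medianNonTarget}, \code{success}.
#' @export
benchmarkRecovery <- function(nrep = 20L, N = 30L, M = 40L, sigma = 0.05,
                              E = 4L, seed = 1L,
                              method = c("nccm", "ddm"),
                              t1 = 0.1, t2 = 0.9, k = 1L, alpha = 0) {
  method <- match.arg(method)
  res <- lapply(seq_len(nrep), function(r) {
    s <- as.integer(seed) + r - 1L
    sim <- simulateExpression(N = N, M = M, sigma = sigma, E = E, seed = s)
    prof <- function(g) {
      if (method == "nccm")
        capabilityProfile(sim$se, g, t1, t2, k = k, alpha = alpha)
      else degreeProfile(sim$se, g, t1, t2, k = k, alpha = alpha)
    }
    scores <- suppressWarnings(
      if (method == "nccm") ccScore(prof("ConGroup"), prof("ExpGroup"))
      else dScore(prof("ConGroup"), prof("ExpGroup")))
    tgt <- names(scores) %in% targetGenes(sim$truth)
    mT <- median(scores[tgt]); mN <- median(scores[!tgt])
    data.frame(seed = s, medianTarget = mT, medianNonTarget = mN,
               success = mT > mN)
  })
  do.call(rbind, res)
}
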