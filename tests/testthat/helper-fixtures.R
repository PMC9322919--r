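# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdir().

# A LogicNetwork from bare edge vectors.
mkNet <- function(ids, src = character(0), tgt = character(0),
                  w = numeric(0), threshold = 0, alpha = 0, k = 1L) {
  new("LogicNetwork", geneIds = ids,
      edges = data.frame(source = src, target = tgt, weight = w,
                         stringsAsFactors = FALSE),
      threshold = threshold, alpha = alpha, k = as.integer(k), group = "")
}

# A SummarizedExperiment with an explicit group assignment.
mkSE <- function(mat, groups) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(
      group = factor(groups, levels = unique(groups)),
      row.names = colnames(mat)))
}

# A capability/degree profile with given values.
mkProfile <- function(values, thresholds, metric = "capability",
                      group = "Con") {
  new("ControlProfile", geneIds = rownames(values),
      thresholds = thresholds, values = values, metric = metric,
      group = group, params = list(k = 1L, alpha = 0, mode = "weighted"))
}

# Write a small expression + label fixture pair; returns the two paths.
writeExprFixture <- function(mat, groups, dir = tempfile("expr")) {
  dir.create(dir)
  se <- mkSE(mat, groups)
  paths <- c(expr = file.path(dir, "expr.tsv"),
             labels = file.path(dir, "labels.tsv"))
  writeExpression(se, paths["expr"], paths["labels"])
  paths
}

# Explicitly assembled controllability matrix; rank via QR. Independent of
# the Krylov path, valid for small well-conditioned cases.
bruteCapability <- function(A, v, tol = 1e-9) {
  N <- nrow(A)
  C <- matrix(0, N, N)
  C[v, 1L] <- 1
  for (j in seq_len(N - 1L)) C[, j + 1L] <- A %*% C[, j]
  qr(C, tol = tol)$rank
}

# Random weighted digraph adjacency with dyadic weights num/8.
randomDigraph <- function(maxN = 12L, denom = 8L) {
  N <- sample(2:maxN, 1L)
  A <- matrix(0L, N, N)
  off <- which(row(A) != col(A))
  m <- sample(0:length(off), 1L)
  idx <- if (m > 0L) sample(off, m) else integer(0)
  A[idx] <- sample.int(denom, length(idx), replace = TRUE)
  A  # integer numerators; true weights are A/denom
}

# Like randomDigraph but with at most one direction per unordered pair, so
# the result is a valid LogicNetwork topology.
randomOrientedDigraph <- function(maxN = 12L, denom = 8L) {
  A <- randomDigraph(maxN, denom)
  lower <- which(row(A) > col(A) & A > 0 & t(A) > 0)
  A[lower] <- 0L
  A
}
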