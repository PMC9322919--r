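## Reading expression matrices with group labels; serialising networks,
## profiles and screening tables.

#' Read a two-group expression matrix
#'
#' Loads a genes x samples matrix (TSV or CSV; first column = gene id,
#' remaining columns numeric sample values) together with a two-column label
#' file mapping every sample to one of two groups, and returns a validated
#' \code{SummarizedExperiment} whose \code{colData$group} factor keeps the
#' groups in order of first appearance in the label file (by convention the
#' first level is treated as the control group downstream).
#'
#' Validation is strict: duplicated gene ids, non-numeric or missing
#' expression values, samples without a label (or labels without a sample),
#' and empty groups are all hard errors -- the pipeline has no imputation
#' step, and silently dropped or imputed entries would change the
#' entropies. Groups with fewer than 3 samples load with a warning, since
#' binned distributions over so few samples are degenerate.
#'
#' @param path expression matrix file (.csv is comma-separated, anything
#'   else tab-separated).
#' @param labelPath two-column file (sample id, group label); an optional
#'   header line \code{sample<TAB>group} is skipped.
#' @return \code{SummarizedExperiment} with assay \code{"expr"}.
#' @export
readExpression <- function(path, labelPath) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 2L) .valStop("expression file needs a gene-id column plus samples")
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .valStop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat)) {
    bad <- ids[apply(raw[, -1L, drop = FALSE], 1L,
                     function(r) anyNA(suppressWarnings(as.numeric(r))))]
    .valStop("non-numeric or missing expression values for gene(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
  }
  rownames(mat) <- ids

  lab <- utils::read.delim(labelPath, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(lab) < 2L) .valStop("label file must have two columns: sample, group")
  if (tolower(lab[1L, 1L]) == "sample") lab <- lab[-1L, , drop = FALSE]
  samples <- as.character(lab[[1L]])
  groups <- as.character(lab[[2L]])
  miss <- setdiff(colnames(mat), samples)
  if (length(miss))
    .valStop("sample(s) in matrix without a label: ", paste(miss, collapse = ", "))
  extra <- setdiff(samples, colnames(mat))
  if (length(extra))
    .valStop("label(s) without a matrix sample: ", paste(extra, collapse = ", "))
  if (anyDuplicated(samples))
    .valStop("duplicated sample id(s) in label file")
  groups <- groups[match(colnames(mat), samples)]
  lev <- unique(groups)
  if (length(lev) != 2L)
    .valStop("exactly two groups are required; found: ", paste(lev, collapse = ", "))
  n <- table(factor(groups, levels = lev))
  if (any(n == 0L)) .valStop("empty group: ", names(n)[n == 0L][1L])
  if (any(n < 3L))
    warning("group(s) with fewer than 3 samples: ",
            paste(names(n)[n < 3L], collapse = ", "),
            " -- binned distributions will be degenerate", call. = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(group = factor(groups, levels = lev),
                                   row.names = colnames(mat)))
}

#' Write a two-group expression matrix
#'
#' Inverse of \code{\link{readExpression}}: writes the assay as a TSV with a
#' leading \code{gene} column and the group assignment as a two-column label
#' TSV with header. \code{readExpression(path, labelPath)} recovers the
#' object exactly (values are printed at full precision).
#'
#' @param se \code{SummarizedExperiment} with assay values and
#'   \code{colData$group}.
#' @param path,labelPath output files for the matrix and the labels.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(se, path, labelPath) {
  mat <- SummarizedExperiment::assay(se)
  grp <- .groupLabels(se)
  tab <- data.frame(gene = rownames(mat),
                    format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE)
  names(tab) <- c("gene", colnames(mat))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(mat),
                                group = as.character(grp)),
                     labelPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a logic network
#'
#' \code{writeNetwork} serialises a \code{\linkS4class{LogicNetwork}} either
#' as a 3-column edge-list TSV (\code{source}, \code{target}, \code{weight},
#' weights printed with 6 decimal digits) or as GraphML with the weight as
#' edge attribute \code{"U"}. Edge-list files carry the inference
#' parameters (k, alpha, threshold, group) in \code{#}-comment header
#' lines. \code{readNetwork} inverts either format; weights survive the
#' round trip to 1e-6.
#'
#' @param net a \code{\linkS4class{LogicNetwork}}.
#' @param path output (input) file path.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return \code{writeNetwork}: invisibly, \code{path};
#'   \code{readNetwork}: a \code{LogicNetwork}.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "LogicNetwork"))
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.metaHeader(k = net@k, alpha = net@alpha,
                           threshold = net@threshold, group = net@group,
                           nodes = paste(net@geneIds, collapse = ",")),
               con)
    writeLines("source\ttarget\tweight", con)
    if (nrow(net@edges))
      writeLines(sprintf("%s\t%s\t%.6f", net@edges$source, net@edges$target,
                         net@edges$weight), con)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(net@geneIds), name = net@geneIds)
    if (nrow(net@edges)) {
      ends <- rbind(net@edges$source, net@edges$target)
      g <- igraph::add_edges(g, as.vector(ends), U = net@edges$weight)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    meta <- list(k = NA_integer_, alpha = NA_real_, threshold = 0, group = "",
                 nodes = "")
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    for (nm in c("k", "alpha", "threshold", "group", "nodes")) {
      hit <- grep(paste0("^# ", nm, ": "), hdr, value = TRUE)
      if (length(hit))
        meta[[nm]] <- sub(paste0("^# ", nm, ": "), "", hit[1L])
    }
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
    edges <- data.frame(source = as.character(tab$source),
                        target = as.character(tab$target),
                        weight = as.numeric(tab$weight),
                        stringsAsFactors = FALSE)
    ids <- if (nzchar(meta$nodes)) strsplit(meta$nodes, ",", fixed = TRUE)[[1L]]
           else unique(c(edges$source, edges$target))
    new("LogicNetwork", geneIds = ids, edges = edges,
        threshold = suppressWarnings(as.numeric(meta$threshold)),
        alpha = suppressWarnings(as.numeric(meta$alpha)),
        k = suppressWarnings(as.integer(meta$k)),
        group = as.character(meta$group))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(source = as.character(el[, 1L]),
                        target = as.character(el[, 2L]),
                        weight = if (igraph::ecount(g)) igraph::E(g)$U else numeric(0),
                        stringsAsFactors = FALSE)
    new("LogicNetwork", geneIds = igraph::V(g)$name, edges = edges,
        threshold = 0, alpha = 0, k = NA_integer_, group = "")
  }
}

#' Write a screening table
#'
#' Serialises a \code{\linkS4class{ScreenResult}} as TSV sorted by
#' descending score. The score column is named \code{CC} for NCCM and
#' \code{D} for DDM; remaining columns are the capability and expression
#' fold-changes, the category tag, and the selection flag.
#'
#' @param result a \code{\linkS4class{ScreenResult}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeScreenTable <- function(result, path) {
  stopifnot(is(result, "ScreenResult"))
  tab <- result@table[order(-result@table$score), , drop = FALSE]
  names(tab)[names(tab) == "score"] <- if (result@method == "NCCM") "CC" else "D"
  con <- file(path, "w")
  on.exit(close(con))
  p <- result@params
  writeLines(.metaHeader(method = result@method, grid = result@grid,
                         cutoff = result@cutoff,
                         k = if (is.null(p$k)) NA else p$k,
                         alpha = if (is.null(p$alpha)) NA else p$alpha,
                         mode = if (is.null(p$mode)) NA else p$mode), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a capability/degree profile
#'
#' Genes x thresholds TSV with a metadata header recording k, alpha, mode,
#' the grid, and the tool version.
#'
#' @param profile a \code{\linkS4class{ControlProfile}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ControlProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- profile@params
  writeLines(.metaHeader(metric = profile@metric, group = profile@group,
                         k = p$k, alpha = p$alpha, mode = p$mode,
                         grid = range(profile@thresholds)), con)
  tab <- data.frame(gene = profile@geneIds, profile@values,
                    check.names = FALSE)
  names(tab) <- c("gene", sprintf("t%.1f", profile@thresholds))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix expression table (convenience)
#'
#' Minimal reader for the series-matrix TSV dialect: the block between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end} is
#' parsed into a genes x samples numeric matrix (probe/gene ids from the
#' first column). Group labels are not inferred -- pair the result with a
#' label file and \code{SummarizedExperiment} construction yourself.
#'
#' @param path series-matrix file (uncompressed).
#' @return numeric matrix with probe/gene rownames and sample colnames.
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    .valStop("no series-matrix table block found in ", path)
  block <- lines[(beg + 1L):(end - 1L)]
  tab <- utils::read.delim(text = block, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- gsub('"', "", as.character(tab[[1L]]))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  colnames(mat) <- gsub('"', "", colnames(mat))
  mat
}
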