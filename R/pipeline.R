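## Full screening workflow with on-disk outputs and a run manifest, plus the
## validated configuration object behind the command-line wrapper.

.configDefaults <- function() {
  list(expr = NA_character_, labels = NA_character_,
       method = "nccm", t1 = 0.1, t2 = 0.9, k = 1L, alpha = 0,
       cutoff = NA_real_, mode = "weighted", normalize = "group",
       control_group = NA_character_, seed = 1L, out = NA_character_)
}

#' Build / read a validated run configuration
#'
#' \code{runConfig} assembles a \code{\linkS4class{RunConfig}} from named
#' arguments; \code{readRunConfig} loads the same keys from a YAML file and
#' applies overrides on top. Unknown keys are rejected, every field is
#' echoed into the run manifest written next to the outputs.
#'
#' Recognised keys: \code{expr}, \code{labels} (input file paths),
#' \code{method} ("nccm"/"ddm"), \code{t1}, \code{t2}, \code{k},
#' \code{alpha}, \code{cutoff} (beta or gamma), \code{mode}
#' ("weighted"/"structural"), \code{normalize} ("group"/"pooled"),
#' \code{control_group}, \code{seed}, \code{out} (output directory).
#'
#' @param ... named configuration values.
#' @return a \code{\linkS4class{RunConfig}}.
#' @export
runConfig <- function(...) {
  vals <- list(...)
  defs <- .configDefaults()
  unknown <- setdiff(names(vals), names(defs))
  if (length(unknown))
    .valStop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (length(vals) && (is.null(names(vals)) || any(names(vals) == "")))
    .valStop("all configuration values must be named")
  defs[names(vals)] <- vals
  defs$method <- match.arg(tolower(defs$method), c("nccm", "ddm"))
  defs$mode <- match.arg(defs$mode, c("weighted", "structural"))
  defs$normalize <- match.arg(defs$normalize, c("group", "pooled"))
  defs$k <- as.integer(defs$k)
  defs$seed <- as.integer(defs$seed)
  for (nm in c("t1", "t2", "alpha", "cutoff"))
    defs[[nm]] <- as.numeric(defs[[nm]])
  .thresholdGrid(defs$t1, defs$t2)
  new("RunConfig", values = defs)
}

#' @rdname runConfig
#' @param path YAML file with configuration keys.
#' @export
readRunConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(runConfig, vals)
}

#' Run the full screening workflow
#'
#' Executes read/validate, per-group normalisation and binning, network
#' construction over the threshold grid, capability (or degree) profiles,
#' the separability check, CC_v / D_u scores, the strict selection cut, and
#' fold-change categories. When the configuration names an output
#' directory, writes: the score-sorted screening TSV, both groups' edge
#' lists at every grid threshold, the per-gene profile TSVs, the mean
#' capability-curve TSV, and a JSON run manifest echoing every
#' configuration field plus the package version. All outputs are
#' deterministic in weighted mode: re-running the same configuration
#' reproduces them byte for byte.
#'
#' @param config a \code{\linkS4class{RunConfig}} from
#'   \code{\link{runConfig}}, or a \code{SummarizedExperiment} combined
#'   with arguments passed through \code{...} to \code{runConfig} (then
#'   \code{expr}/\code{labels} paths are not needed).
#' @param ... configuration overrides when \code{config} is an expression
#'   object.
#' @return the \code{\linkS4class{ScreenResult}}, invisibly when files are
#'   written.
#' @export
runScreen <- function(config, ...) {
  se <- NULL
  if (is(config, "SummarizedExperiment")) {
    se <- config
    config <- runConfig(...)
  }
  stopifnot(is(config, "RunConfig"))
  v <- config@values
  if (is.null(se)) {
    if (is.na(v$expr) || is.na(v$labels))
      .valStop("configuration must name 'expr' and 'labels' input files")
    se <- readExpression(v$expr, v$labels)
  }
  grp <- .groupLabels(se)
  conGroup <- if (is.na(v$control_group)) levels(grp)[1L] else v$control_group
  if (!conGroup %in% levels(grp))
    .valStop("control group '", conGroup, "' not found among labels")
  expGroup <- setdiff(levels(grp), conGroup)[1L]

  result <- screenGenes(se, method = v$method, cutoff = v$cutoff,
                        conGroup = conGroup, expGroup = expGroup,
                        t1 = v$t1, t2 = v$t2, k = v$k, alpha = v$alpha,
                        mode = v$mode, normalize = v$normalize,
                        seed = v$seed)
  if (is.na(v$out)) return(result)

  dir.create(v$out, recursive = TRUE, showWarnings = FALSE)
  writeScreenTable(result, file.path(v$out, "screen.tsv"))
  for (p in result@profiles)
    writeProfile(p, file.path(v$out, sprintf("profile_%s.tsv", p@group)))

  grid <- .thresholdGrid(v$t1, v$t2)
  for (g in c(conGroup, expGroup)) {
    for (t in grid) {
      net <- buildLogicNetwork(se, g, t = t, alpha = v$alpha, k = v$k,
                               normalize = v$normalize)
      writeNetwork(net, file.path(v$out, sprintf("network_%s_t%.1f.tsv", g, t)))
    }
  }

  curves <- data.frame(threshold = grid,
                       con = colMeans(result@profiles$con@values),
                       exp = colMeans(result@profiles$exp@values))
  names(curves) <- c("threshold", conGroup, expGroup)
  con <- file(file.path(v$out, "curves.tsv"), "w")
  writeLines(.metaHeader(metric = result@profiles$con@metric,
                         k = v$k, alpha = v$alpha, grid = c(v$t1, v$t2),
                         mode = v$mode), con)
  utils::write.table(curves, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  manifest <- c(v, list(control_group = conGroup, exp_group = expGroup,
                        separable = separable(curves[[2L]], curves[[3L]]),
                        n_selected = sum(result@table$selected),
                        version = .pkgVersion()))
  jsonlite::write_json(manifest, file.path(v$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

#' Write simulated data and its ground truth to disk
#'
#' Companion of \code{\link{simulateExpression}} for shell use: writes the
#' expression TSV, the label TSV, and a JSON ground-truth file (both
#' generating networks, the target genes, and the simulation parameters).
#'
#' @param sim result of \code{\link{simulateExpression}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExpression(sim$se, file.path(dir, "expression.tsv"),
                  file.path(dir, "labels.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(params = tr@params, target_genes = tr@targetGenes,
         net_con = tr@netCon, net_exp = tr@netExp),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
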