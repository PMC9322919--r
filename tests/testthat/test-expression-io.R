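# File round trips and validation of the expression/label loader.

test_that("expression loader accepts a small two-group matrix and keeps order", {
  m <- matrix(1:12, 3, 4, dimnames = list(c("G1", "G2", "G3"),
                                          c("s1", "s2", "s3", "s4")))
  p <- writeExprFixture(m, c("Con", "Con", "Exp", "Exp"))
  expect_warning(se <- readExpression(p["expr"], p["labels"]),
                 "fewer than 3")
  expect_equal(dim(se), c(3L, 4L))
  expect_equal(rownames(se), c("G1", "G2", "G3"))
  expect_equal(colnames(se), c("s1", "s2", "s3", "s4"))
  expect_equal(as.vector(table(SummarizedExperiment::colData(se)$group)),
               c(2L, 2L))
  expect_equal(levels(SummarizedExperiment::colData(se)$group), c("Con", "Exp"))
})

test_that("loader errors name the offending gene or sample", {
  d <- tempfile(); dir.create(d)
  writeLines(c("gene\ts1\ts2\ts3\ts4", "G1\t1\t2\t3\t4", "G1\t5\t6\t7\t8"),
             file.path(d, "dup.tsv"))
  writeLines(c("s1\tCon", "s2\tCon", "s3\tExp", "s4\tExp"),
             file.path(d, "lab.tsv"))
  expect_error(readExpression(file.path(d, "dup.tsv"), file.path(d, "lab.tsv")),
               "G1")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "G1\t1\t2\t3\t4", "G2\t5\tx\t7\t8"),
             file.path(d, "bad.tsv"))
  expect_error(readExpression(file.path(d, "bad.tsv"), file.path(d, "lab.tsv")),
               "G2")
  writeLines(c("s1\tCon", "s2\tCon", "s3\tExp"), file.path(d, "short.tsv"))
  writeLines(c("gene\ts1\ts2\ts3\ts4", "G1\t1\t2\t3\t4", "G2\t5\t6\t7\t8"),
             file.path(d, "ok.tsv"))
  expect_error(readExpression(file.path(d, "ok.tsv"), file.path(d, "short.tsv")),
               "s4")
  writeLines(c("s1\tCon", "s2\tCon", "s3\tCon", "s4\tCon"),
             file.path(d, "onegrp.tsv"))
  expect_error(readExpression(file.path(d, "ok.tsv"), file.path(d, "onegrp.tsv")),
               "two groups")
})

test_that("expression matrices survive a write/read round trip", {
  withr::with_seed(5, {
    m <- matrix(runif(5 * 8), 5, 8,
                dimnames = list(paste0("G", 1:5), paste0("s", 1:8)))
    p <- writeExprFixture(m, rep(c("Con", "Exp"), each = 4))
    se <- readExpression(p["expr"], p["labels"])
    expect_equal(SummarizedExperiment::assay(se), m, tolerance = 1e-12)
  })
})

test_that("edge-list serialisation prints weights at 6 decimals and round-trips", {
  net <- mkNet(c("A", "B"), "A", "B", 0.8, threshold = 0.5)
  f <- tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  lines <- readLines(f)
  data <- lines[!grepl("^#", lines)]
  expect_equal(data[1], "source\ttarget\tweight")
  expect_equal(data[2], "A\tB\t0.800000")
  expect_length(data, 2L)

  back <- readNetwork(f)
  expect_equal(geneIds(back), c("A", "B"))
  expect_equal(networkEdges(back)$weight, 0.8, tolerance = 1e-6)
  expect_equal(back@threshold, 0.5)

  # empty network: header-only file, node set preserved
  empty <- mkNet(c("A", "B", "C"))
  writeNetwork(empty, f)
  expect_length(readLines(f)[!grepl("^#", readLines(f))], 1L)
  expect_equal(geneIds(readNetwork(f)), c("A", "B", "C"))
})

test_that("a network round-trips through edgelist and GraphML to 1e-6", {
  sim <- simulateExpression(N = 10, M = 12, E = 2, seed = 3)
  net <- buildLogicNetwork(sim$se, "ConGroup", t = 0.3)
  for (fmt in c("edgelist", "graphml")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeNetwork(net, f, format = fmt)
    back <- readNetwork(f, format = fmt)
    expect_setequal(geneIds(back), geneIds(net))
    a <- networkEdges(net); b <- networkEdges(back)
    ord <- order(a$source, a$target)
    orb <- order(b$source, b$target)
    expect_equal(a$source[ord], b$source[orb])
    expect_equal(a$target[ord], b$target[orb])
    expect_equal(a$weight[ord], b$weight[orb], tolerance = 1e-6)
  }
  # GraphML carries the weight as the "U" edge attribute
  f <- tempfile(fileext = ".graphml")
  writeNetwork(net, f, format = "graphml")
  expect_true(any(grepl('attr.name="U"', readLines(f))))
})

test_that("screen tables are sorted by descending score with category tags", {
  tab <- data.frame(gene = c("A", "B"), score = c(3, 11),
                    capability_fc = c(2.5, 0.5), expression_fc = c(0.3, 0.1),
                    category = c("CA_high_GeExp_high", "CA_low_GeExp_low"),
                    selected = c(FALSE, TRUE), stringsAsFactors = FALSE)
  res <- new("ScreenResult", table = tab, method = "NCCM",
             grid = c(0.1, 0.7), cutoff = 10, params = list(k = 1L),
             profiles = list())
  f <- tempfile(fileext = ".tsv")
  writeScreenTable(res, f)
  out <- utils::read.delim(f, comment.char = "#")
  expect_equal(out$gene, c("B", "A"))          # 11 before 3
  expect_equal(names(out)[2], "CC")
  expect_equal(out$category[2], "CA_high_GeExp_high")
  # empty selection serialises with all flags false
  res@table$selected <- c(FALSE, FALSE)
  res@cutoff <- 20
  writeScreenTable(res, f)
  expect_false(any(utils::read.delim(f, comment.char = "#")$selected))
})

test_that("series-matrix blocks parse into a numeric matrix", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"synthetic fixture\"",
               "!series_matrix_table_begin",
               "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
               "\"G1\"\t1.5\t2.5",
               "\"G2\"\t3\t4",
               "!series_matrix_table_end"), f)
  m <- readSeriesMatrix(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["G1", "GSM2"], 2.5)
  noblock <- tempfile(fileext = ".txt")
  writeLines("!Series_title\t\"no table\"", noblock)
  expect_error(readSeriesMatrix(noblock), "table block")
})
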