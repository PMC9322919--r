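# Normalisation, binning, the information-theoretic estimators, and the
# direction-filtered network construction.

test_that("min-max normalisation maps genes onto [0,1] and handles constants", {
  m <- rbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5))
  n <- minmaxNormalize(m)
  expect_equal(n["g1", ], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(n["g2", ], c(0, 0, 0), ignore_attr = TRUE)
  # idempotent on already-normalised data
  expect_equal(minmaxNormalize(n), n)
  expect_error(minmaxNormalize(rbind(c(1, NA))), "missing")
})

test_that("binning follows the round-down-below-0.5 / round-up-above rule", {
  expect_equal(binExpression(0.3, k = 2), 0.25)   # 0.3 in [0.25, 0.5)
  expect_equal(binExpression(0.6, k = 2), 0.75)   # 0.6 in (0.5, 0.75]
  expect_equal(binExpression(0.5, k = 1), 0.5)    # grid point, unchanged
  expect_equal(binExpression(0.49, k = 1), 0)
  expect_equal(binExpression(c(0, 1), k = 3), c(0, 1))
  # every output sits on the dyadic grid
  x <- seq(0, 1, length.out = 101)
  for (k in 1:3) {
    y <- binExpression(x, k)
    expect_true(all(abs(y * 2^k - round(y * 2^k)) < 1e-12))
  }
  expect_error(binExpression(0.5, k = 0), "positive integer")
  expect_error(binExpression(1.4, k = 1), "\\[0, 1\\]")
})

test_that("entropy, joint entropy and mutual information match closed forms", {
  expect_equal(shannonEntropy(c(0, 0, 1, 1)), 1)
  expect_equal(shannonEntropy(c(0.5, 0.5, 0.5)), 0)
  expect_equal(shannonEntropy(c(0, 1, 1, 1)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-12)
  expect_equal(jointEntropy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(jointEntropy(c(0, 0, 1, 1), c(0, 1, 0, 1)), 2)
  expect_equal(jointEntropy(c(0, 0, 1, 1), c(0, 0, 0, 1)), 1.5)
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 0, 1)),
               1 + -(0.25 * log2(0.25) + 0.75 * log2(0.75)) - 1.5,
               tolerance = 1e-12)
  expect_error(jointEntropy(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("U value is I/H(X) with the H(X)=0 convention", {
  x <- c(0, 0, 1, 1)
  expect_equal(uValue(x, x), 1)
  expect_equal(uValue(x, c(0, 1, 0, 1)), 0)       # empirically independent
  expect_equal(uValue(c(0.5, 0.5, 0.5), x), 0)    # constant X
})

test_that("entropy bounds and U range hold on random binned rows", {
  withr::with_seed(7, {
    for (r in 1:300) {
      n <- sample(4:30, 1)
      k <- sample(1:3, 1)
      x <- binExpression(runif(n), k)
      y <- binExpression(runif(n), k)
      hx <- shannonEntropy(x); hy <- shannonEntropy(y)
      hxy <- jointEntropy(x, y)
      expect_gte(hxy, max(hx, hy) - 1e-12)
      expect_lte(hxy, hx + hy + 1e-12)
      expect_gte(mutualInformation(x, y), 0)
      u <- uValue(x, y)
      expect_gte(u, 0); expect_lte(u, 1)
    }
  })
})

test_that("direction filter keeps the better-supported direction with its U weight", {
  # H(A)=1 > H(B)=0.811; support A->B = I/H(B) wins
  m <- rbind(A = c(0, 0, 1, 1), B = c(0, 1, 1, 1))
  hab <- shannonEntropy(c("00", "01", "11", "11"))
  i <- 1 + shannonEntropy(m["B", ]) - hab   # I = H(A) + H(B) - H(A,B)
  net <- buildLogicNetwork(m, t = 0, k = 1)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(e$source, "A")
  expect_equal(e$target, "B")
  expect_equal(e$weight, i / shannonEntropy(m["B", ]), tolerance = 1e-12)

  # equal supports (x = y) give no edge at alpha = 0
  sym <- rbind(A = c(0, 0, 1, 1), B = c(1, 1, 0, 0))
  expect_equal(nrow(networkEdges(buildLogicNetwork(sym, t = 0, k = 1))), 0L)

  # the weight floor drops the edge
  high <- buildLogicNetwork(m, t = 0.95, k = 1)
  expect_equal(nrow(networkEdges(high)), 0L)
  expect_equal(geneIds(high), c("A", "B"))   # nodes remain
})

test_that("networks are nested in the threshold, antisymmetric and deterministic", {
  sim <- simulateExpression(N = 12, M = 15, sigma = 0.1, E = 2, seed = 11)
  n1 <- buildLogicNetwork(sim$se, "ConGroup", t = 0.2)
  n2 <- buildLogicNetwork(sim$se, "ConGroup", t = 0.5)
  e1 <- networkEdges(n1); e2 <- networkEdges(n2)
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e2) %in% key(e1)))
  expect_equal(e2$weight, e1$weight[match(key(e2), key(e1))])
  # no pair present in both directions
  expect_false(any(duplicated(rbind(paste(e1$source, e1$target),
                                    paste(e1$target, e1$source)))))
  expect_true(all(e1$weight >= 0.2))
  # same inputs, same edges
  expect_identical(networkEdges(buildLogicNetwork(sim$se, "ConGroup", t = 0.2)), e1)
})

test_that("the inferred edge set does not depend on the entropy log base", {
  withr::with_seed(3, {
    m <- matrix(runif(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), NULL))
    b <- binExpression(minmaxNormalize(m), 1)
    for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
      x <- b[pair[1], ]; y <- b[pair[2], ]
      u2 <- if (shannonEntropy(x) > 0)
        mutualInformation(x, y) / shannonEntropy(x) else 0
      ue <- if (shannonEntropy(x, base = exp(1)) > 0)
        (shannonEntropy(x, exp(1)) + shannonEntropy(y, exp(1)) -
           jointEntropy(x, y, exp(1))) / shannonEntropy(x, exp(1)) else 0
      expect_equal(u2, ue, tolerance = 1e-12)
    }
  })
})

test_that("build rejects invalid thresholds and unknown groups", {
  sim <- simulateExpression(N = 10, M = 10, E = 2, seed = 2)
  expect_error(buildLogicNetwork(sim$se, "NoSuchGroup", t = 0.1), "unknown group")
  expect_error(buildLogicNetwork(sim$se, "ConGroup", t = 1.2), "\\[0, 1\\]")
  expect_error(buildLogicNetwork(sim$se, "ConGroup", t = 0.1, alpha = -1), "alpha")
})
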