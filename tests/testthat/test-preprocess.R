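test_that("probe collapsing averages on the raw scale", {
  pv <- matrix(c(1, 3,
                 0, 0,
                 6, 2,
                 5, 5), 4, 2, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3", "p4"), c("s1", "s2")))
  map <- c(p1 = "gA", p2 = "gB", p3 = "gB", p4 = "gC")
  ed <- collapseProbes(pv, map)
  expect_equal(exprValues(ed)["gA", ], c(s1 = 1, s2 = 3))
  expect_equal(exprValues(ed)["gB", ], c(s1 = 3, s2 = 1))   # mean of probes
  expect_equal(exprValues(ed)["gC", ], c(s1 = 5, s2 = 5))   # single probe
  expect_equal(unname(collapseProbes(
    matrix(c(0, 0, 6), 3, 1, dimnames = list(paste0("q", 1:3), "s")),
    c(q1 = "g", q2 = "g", q3 = "g")) |> exprValues())[1], 2)
  expect_error(collapseProbes(pv, map[-2]), "unmapped")
})

test_that("detection filter applies the one-sided exact binomial test", {
  n <- 1400
  dp <- matrix(1, 3, n)
  dp[1, seq_len(0.05 * n)] <- 0.01     # exactly the chance rate: excluded
  dp[2, ] <- 0.01                      # detected everywhere: retained
  dp[3, seq_len(200)] <- 0.01          # clearly above chance: retained
  x <- mkExpr(matrix(rnorm(3 * n), 3, n), detection = dp)
  res <- detectionFilter(x)
  expect_equal(unname(res$report$keep), c(FALSE, TRUE, TRUE))
  expect_equal(rownames(res$expression), c("g2", "g3"))

  # n = 100, 11 detected: decision equals the exact upper-tail binomial sum
  dp2 <- matrix(1, 1, 100); dp2[1, 1:11] <- 0.01
  x2 <- mkExpr(matrix(rnorm(100), 1, 100), detection = dp2)
  r2 <- detectionFilter(x2)
  pOracle <- oracleBinomTail(11, 100, 0.05)
  expect_equal(r2$report$pTail, pOracle, tolerance = 1e-12)
  expect_equal(r2$report$keep, pOracle < 0.05)

  expect_error(detectionFilter(mkExpr(matrix(1:4, 2, 2))), "detection")
})

test_that("detection decisions agree with enumeration for all n <= 50", {
  for (n in c(10, 27, 50)) {
    for (k in 0:n) {
      pTail <- stats::pbinom(k - 1, n, 0.05, lower.tail = FALSE)
      expect_equal(pTail, oracleBinomTail(k, n, 0.05), tolerance = 1e-10)
    }
  }
})

test_that("gene-name filter drops placeholder prefixes and keeps real genes", {
  ids <- c("KIAA0101", "LYZ", "C9orf72", "YEATS4", "LOC100", "HS.1234",
           "FLJ10", "ENSG000123", "NT_0771", "MGC555", "CORF1")
  x <- mkExpr(matrix(rnorm(length(ids) * 3), length(ids), 3,
                     dimnames = list(ids, paste0("s", 1:3))))
  kept <- rownames(geneNameFilter(x))
  expect_setequal(kept, c("LYZ", "YEATS4", "CORF1"))
})

test_that("arcsinh transform is exact, monotone and single-shot", {
  x <- mkExpr(matrix(c(0, 1, 10, 150, 2, 5, 300, 1000), 2, 4))
  tx <- arcsinhTransform(x)
  expect_equal(exprValues(tx)[1, 1], 0)
  expect_equal(transformState(tx), "arcsinh")
  v <- exprValues(x); tv <- exprValues(tx)
  expect_equal(order(v[1, ]), order(tv[1, ]))
  big <- v[v >= 100]
  expect_true(all(abs(asinh(big) - log(2 * big)) < 1e-3))
  expect_error(arcsinhTransform(tx), "raw")
})

test_that("standardization centres and scales every gene", {
  set.seed(1)
  x <- mkExpr(matrix(rnorm(200, mean = 5), 10, 20), state = "arcsinh")
  sx <- standardizeGenes(x)
  v <- exprValues(sx)
  expect_true(max(abs(rowMeans(v))) < 1e-8)
  expect_true(max(abs(apply(v, 1, var) - 1)) < 1e-8)
  expect_equal(transformState(sx), "standardized")
  # fixed point: re-standardizing returns the same values
  expect_equal(exprValues(standardizeGenes(sx)), v, tolerance = 1e-12)
  # explicit row (1,2,3)
  r <- exprValues(standardizeGenes(mkExpr(matrix(c(1, 2, 3), 1, 3),
                                          state = "arcsinh")))
  expect_equal(mean(r), 0)
  expect_equal(var(as.numeric(r)), 1)
  bad <- mkExpr(rbind(rnorm(5), rep(2, 5)), state = "arcsinh")
  expect_error(standardizeGenes(bad), "zero-variance")
})

test_that("the preprocessing chain ends standardized in the fixed order", {
  set.seed(2)
  n <- 30
  ids <- c("LYZ", "CRIP1", "LOC999", paste0("G", 1:7))
  vals <- matrix(abs(rnorm(10 * n, mean = 4)), 10, n,
                 dimnames = list(ids, paste0("s", 1:n)))
  dp <- matrix(0.01, 10, n, dimnames = dimnames(vals))
  dp[2, ] <- 0.5                        # CRIP1 never detected
  x <- ExpressionData(vals, detectionP = dp, transformState = "raw")
  out <- preprocessExpression(x)
  expect_equal(transformState(out), "standardized")
  expect_false("CRIP1" %in% rownames(out))   # detection filter
  expect_false("LOC999" %in% rownames(out))  # name filter
  expect_true("LYZ" %in% rownames(out))
  expect_true(max(abs(rowMeans(exprValues(out)))) < 1e-8)
})
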