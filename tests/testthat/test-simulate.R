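test_that("simulated genotypes follow Hardy-Weinberg class frequencies", {
  g <- simulateGenotypes(1, 1e5, maf = 0.5, seed = 1)
  freq <- as.numeric(table(factor(doseMatrix(g), levels = 0:2))) / 1e5
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.01))

  g2 <- simulateGenotypes(5, 100, maf = 0.01, seed = 2)
  expect_true(all(doseMatrix(g2) %in% 0:2))
  expect_error(simulateGenotypes(5, 10, maf = 0, seed = 1), "0, 0.5")
  expect_error(simulateGenotypes(5, 10, maf = 0.6, seed = 1), "0, 0.5")

  expect_identical(doseMatrix(simulateGenotypes(10, 50, 0.3, seed = 7)),
                   doseMatrix(simulateGenotypes(10, 50, 0.3, seed = 7)))
})

test_that("generated genotypes pass the package's own HWE exact test", {
  fails <- 0L; total <- 0L
  for (s in 1:3) {
    g <- doseMatrix(simulateGenotypes(200, 400, maf = runif(200, 0.05, 0.5),
                                      seed = s))
    p <- apply(g, 1, function(r)
      hweExactTest(sum(r == 0), sum(r == 1), sum(r == 2)))
    fails <- fails + sum(p < 1e-3); total <- total + length(p)
  }
  expect_gte(1 - fails / total, 0.99)
})

test_that("noise-free single-component dataset is an exact outer product", {
  cfg <- simulationConfig(nSamples = 60, nGenes = 200, nSnps = 5, kTrue = 1,
                          moduleSizes = 20, patternSnpR2 = 0,
                          nCisPerComponent = 0, noiseSd = 0, seed = 4)
  sim <- simulateDataset(cfg)
  X <- exprValues(sim$expression)
  expect_equal(X, sim$truth@trueLoadings %*% sim$truth@trueActivations,
               tolerance = 1e-12)
  expect_equal(sum(svd(X)$d > 1e-8), 1)
})

test_that("planted SNP-to-pattern R2 is recovered by OLS on the truth", {
  cfg <- simulationConfig(nSamples = 1e4, nGenes = 50, nSnps = 3, kTrue = 1,
                          moduleSizes = 10, patternSnpR2 = 0.2, seed = 5)
  sim <- simulateDataset(cfg)
  a <- sim$truth@trueActivations[1, ]
  g <- doseMatrix(sim$genotypes)[sim$truth@driverSnp[1], ]
  r2 <- summary(stats::lm(a ~ g))$r.squared
  expect_lt(abs(r2 - 0.2), 0.03)
})

test_that("module gene co-expression signs follow the loading products", {
  cfg <- simulationConfig(nSamples = 200, nGenes = 100, nSnps = 2, kTrue = 1,
                          moduleSizes = 10, patternSnpR2 = 0,
                          nCisPerComponent = 0, noiseSd = 0.01, seed = 6)
  sim <- simulateDataset(cfg)
  mem <- sim$truth@moduleMembership[[1]]
  X <- exprValues(sim$expression)[mem, ]
  lo <- sim$truth@trueLoadings[mem, 1]
  cc <- stats::cor(t(X))
  for (i in 1:5) for (j in 6:10)
    expect_equal(unname(sign(cc[i, j])), unname(sign(lo[i] * lo[j])))
})

test_that("recovery evaluation is exact on the truth and sign-invariant", {
  cfg <- simulationConfig(nSamples = 50, nGenes = 150, nSnps = 2, kTrue = 2,
                          moduleSizes = c(15, 15), patternSnpR2 = c(0, 0),
                          seed = 8)
  sim <- simulateDataset(cfg)
  truth <- sim$truth
  d <- new("Decomposition", S = truth@trueLoadings,
           A = truth@trueActivations,
           componentIds = colnames(truth@trueLoadings),
           kurtosis = numeric(2), individualSpecific = logical(2),
           kurtosisPass = logical(2), negentropy = numeric(2))
  mods <- lapply(1:2, function(k) new("GeneModule",
    componentId = colnames(truth@trueLoadings)[k],
    members = S4Vectors::DataFrame(gene = truth@moduleMembership[[k]],
      loading = rep(1, 15), q = rep(0, 15)), fdrMax = 1e-3))
  rec <- evaluateRecovery(truth, d, mods)
  expect_equal(rec$absCor, c(1, 1), tolerance = 1e-12)
  expect_equal(rec$jaccard, c(1, 1))

  dFlip <- d; dFlip@A <- -d@A
  recF <- evaluateRecovery(truth, dFlip, list())
  expect_equal(recF$absCor, c(1, 1), tolerance = 1e-12)
  expect_equal(recF$jaccard, c(0, 0))

  dEmpty <- new("Decomposition", S = truth@trueLoadings[, 0, drop = FALSE],
                A = truth@trueActivations[0, , drop = FALSE],
                componentIds = character(), kurtosis = numeric(),
                individualSpecific = logical(), kurtosisPass = logical(),
                negentropy = numeric())
  recE <- evaluateRecovery(truth, dEmpty, list())
  expect_true(all(is.na(recE$matchedComponent)))
  expect_equal(recE$jaccard, c(0, 0))
})

test_that("simulation is reproducible and rejects invalid configurations", {
  cfg <- simulationConfig(nSamples = 40, nGenes = 80, nSnps = 4, kTrue = 1,
                          moduleSizes = 10, seed = 9)
  s1 <- simulateDataset(cfg); s2 <- simulateDataset(cfg)
  expect_identical(exprValues(s1$expression), exprValues(s2$expression))
  expect_error(simulationConfig(nSamples = 10, nGenes = 20, kTrue = 30,
                                moduleSizes = rep(5, 30)), "K_true")
  expect_error(simulationConfig(kTrue = 1, moduleSizes = 5000, nGenes = 100),
               "module sizes")
  expect_error(simulationConfig(kTrue = 1, moduleSizes = 10,
                                patternSnpR2 = 1.2), "R2")
})

test_that("contamination block adds fraction-driven signal on listed genes", {
  cfg <- simulationConfig(nSamples = 150, nGenes = 600, nSnps = 5, kTrue = 1,
                          moduleSizes = 30, patternSnpR2 = 0,
                          contamination = list(nCellTypes = 2,
                                               genesPerType = 25,
                                               fractionSd = 0.1),
                          seed = 10)
  sim <- simulateDataset(cfg)
  truth <- sim$truth
  expect_equal(dim(truth@contaminationFractions), c(150, 2))
  expect_true(all(truth@contaminationFractions >= 0 &
                    truth@contaminationFractions <= 0.5))
  # mean expression of a type's genes tracks that type's fraction
  for (t in 1:2) {
    m <- colMeans(exprValues(sim$expression)[
      truth@contaminationGenes[[t]], ])
    expect_gt(stats::cor(m, truth@contaminationFractions[, t]), 0.9)
  }
})
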