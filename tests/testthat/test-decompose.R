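test_that("component-number selection finds planted rank and rejects noise", {
  sig <- mkSparseSignal(G = 1000, N = 200, moduleSize = 60, k = 3,
                        noiseSd = 0.35, seed = 11)
  expect_equal(chooseNumComponents(mkStd(sig$X), seed = 1), 3L)

  ks <- vapply(1:5, function(s) {
    set.seed(s)
    chooseNumComponents(mkStd(matrix(rnorm(500 * 100), 500, 100)),
                        seed = s + 50)
  }, integer(1))
  expect_true(all(ks == 0L))

  set.seed(2)
  r1 <- outer(rnorm(50), rnorm(30))
  expect_equal(chooseNumComponents(mkStd(r1), seed = 3), 1L)

  twoSamples <- mkExpr(matrix(rep(c(-1, 1) * sqrt(0.5), each = 4), 4, 2,
                              byrow = FALSE), state = "standardized")
  expect_error(chooseNumComponents(twoSamples), "at least 3")
  expect_error(chooseNumComponents(mkExpr(matrix(rnorm(16), 4, 4))),
               "standardized")
})

test_that("ICA recovers sparse supergaussian sources up to sign and order", {
  set.seed(42)
  G <- 5000; N <- 200
  S <- matrix(rnorm(G * 2, sd = 0.02), G, 2)
  S[1:300, 1] <- rexp(300) * sample(c(-1, 1), 300, TRUE)   # Laplace loadings
  S[301:600, 2] <- rexp(300) * sample(c(-1, 1), 300, TRUE)
  A <- matrix(rnorm(2 * N), 2, N)
  X <- S %*% A + matrix(rnorm(G * N, sd = 0.5), G, N)
  std <- mkStd(X)
  d <- runICA(std, K = 2, seed = 3)
  # rotation is identified: activations recovered almost perfectly
  patCor <- apply(abs(cor(t(A), t(patterns(d)))), 1, max)
  expect_true(all(patCor > 0.99))
  # signatures match the truth on the standardized scale (estimation noise
  # on weakly loaded genes bounds the global correlation)
  sScaled <- S / sqrt(apply(X, 1, var))
  sigCor <- apply(abs(cor(sScaled, signatures(d))), 1, max)
  expect_true(all(sigCor > 0.9))
  expect_true(all(componentKurtosis(d) > 3))
})

test_that("the decomposition is an exact rotation of the rank-K truncation", {
  sig <- mkSparseSignal(G = 800, N = 120, moduleSize = 40, k = 3, seed = 12)
  std <- mkStd(sig$X)
  d <- runICA(std, K = 3, seed = 5)
  X <- exprValues(std)
  sv <- svd(X, nu = 3, nv = 3)
  trunc <- sv$u %*% (sv$d[1:3] * t(sv$v))
  rec <- signatures(d) %*% patterns(d)
  expect_lt(norm(rec - trunc, "F") / norm(trunc, "F"), 1e-6)
  # S columns have unit variance; signature skewness >= 0 (sign convention)
  expect_true(max(abs(apply(signatures(d), 2, var) - 1)) < 1e-6)
  skews <- apply(signatures(d), 2, function(s) mean((s - mean(s))^3))
  expect_true(all(skews >= 0))
  # duality: regressing X on S returns A
  Ahat <- solve(crossprod(signatures(d)), crossprod(signatures(d), X))
  expect_lt(max(abs(Ahat - patterns(d))), 1e-6)
})

test_that("identical seeds give bitwise-identical decompositions", {
  sig <- mkSparseSignal(G = 400, N = 80, moduleSize = 30, k = 2, seed = 13)
  std <- mkStd(sig$X)
  d1 <- runICA(std, K = 2, seed = 9)
  d2 <- runICA(std, K = 2, seed = 9)
  expect_identical(signatures(d1), signatures(d2))
  expect_identical(patterns(d1), patterns(d2))
})

test_that("kurtosis matches the analytic values of known distributions", {
  set.seed(21)
  expect_lt(abs(computeKurtosis(rnorm(1e5))), 0.1)
  lap <- rexp(1e5) * sample(c(-1, 1), 1e5, TRUE)
  expect_lt(abs(computeKurtosis(lap) - 3), 0.2)
  expect_equal(computeKurtosis(rep(c(-1, 1), 50)), -2)
  expect_equal(computeKurtosis(rep(c(-1, 1), 50), excess = FALSE), 1)
  expect_error(computeKurtosis(rep(2, 10)), "zero variance")
  expect_error(computeKurtosis(1:3), "at least 4")
})

test_that("individual-specific flag implements the variance-share rule", {
  a <- c(10, rep(0, 99))
  fl <- flagIndividualSpecific(a)
  expect_true(fl$flag)
  expect_equal(fl$maxShare, 98.01 / 99.0, tolerance = 1e-12)
  expect_equal(fl$sample, 1L)

  # max share exactly at the threshold is NOT flagged (strict 'more than')
  even <- rep(c(1, -1), 5)
  flEven <- flagIndividualSpecific(even, threshold = 0.10)
  expect_equal(flEven$maxShare, 0.10)
  expect_false(flEven$flag)

  flags <- vapply(1:5, function(s) {
    set.seed(s); flagIndividualSpecific(rnorm(1490))$flag
  }, logical(1))
  expect_false(any(flags))
  expect_error(flagIndividualSpecific(rep(1, 10)), "zero-variance")
})

test_that("component filtering drops flagged and gaussian components", {
  set.seed(22)
  G <- 2000
  sGauss <- rnorm(G)
  sSparse <- c(rep(8, 50), rnorm(G - 50, sd = 0.5))
  mk <- function(cols, indiv) {
    S <- do.call(cbind, cols)
    S <- sweep(S, 2, apply(S, 2, sd), `/`)
    K <- ncol(S)
    new("Decomposition", S = S, A = matrix(rnorm(K * 30), K, 30),
        componentIds = paste0("IC", seq_len(K)),
        kurtosis = apply(S, 2, computeKurtosis),
        individualSpecific = indiv,
        kurtosisPass = apply(S, 2, computeKurtosis) >= 3,
        negentropy = rep(1, K))
  }
  dAllGauss <- mk(list(sGauss, rnorm(G)), c(FALSE, FALSE))
  expect_warning(fAll <- filterComponents(dAllGauss), "all components")
  expect_equal(numComponents(fAll), 0)

  dMix <- mk(list(sSparse, sGauss, sSparse), c(FALSE, FALSE, TRUE))
  f <- filterComponents(dMix)
  # sparse component retained; gaussian dropped; flagged dropped despite
  # high kurtosis
  expect_equal(componentIds(f), "IC1")
})
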