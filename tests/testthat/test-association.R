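test_that("HWE exact test matches enumeration and flags distortions", {
  # all configurations with n <= 6 agree with the enumeration oracle
  for (n in 1:6) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactTest(nAA, nAa, naa), oracleHWE(nAA, nAa, naa),
                   tolerance = 1e-10,
                   label = sprintf("(%d,%d,%d)", nAA, nAa, naa))
    }
  }
  expect_lt(hweExactTest(0, 50, 0), 1e-10)   # all-heterozygote excess
  expect_gte(hweExactTest(25, 50, 25), 1e-4) # perfect HWE proportions
})

test_that("SNP QC drops monomorphic, HWE-failing and low-call SNPs", {
  d <- rbind(mono = rep(0, 50),
             het  = rep(1, 50),
             good = rep(c(0, 1, 1, 2), length.out = 50),
             lowc = c(rep(NA, 10), rep(c(0, 1), 20)))
  g <- mkGeno(d)
  res <- snpQC(g)
  expect_setequal(rownames(res$genotypes), "good")
  rep <- res$report
  expect_false(rep$keep[rep$snp == "mono"])   # maf 0
  expect_false(rep$keep[rep$snp == "het"])    # HWE p < 1e-10
  expect_false(rep$keep[rep$snp == "lowc"])   # call rate 0.8
  expect_lt(rep$hweP[rep$snp == "het"], 1e-10)
})

test_that("the 2-df ANOVA reproduces hand-computed sums of squares", {
  # three classes of four samples with distinct means plus fixed residuals
  y <- c(1.2, 0.8, 1.1, 0.9,   3.1, 2.9, 3.2, 2.8,   5.0, 5.3, 4.8, 4.9)
  g <- rep(0:2, each = 4)
  rec <- anova2df(y, g)
  m <- mean(y)
  ssb <- sum(4 * (tapply(y, g, mean) - m)^2)
  sst <- sum((y - m)^2)
  Fhand <- (ssb / 2) / ((sst - ssb) / 9)
  expect_equal(rec$F, Fhand, tolerance = 1e-10)
  expect_equal(rec$r2, ssb / sst, tolerance = 1e-10)
  expect_equal(rec$df1, 2L)
  expect_equal(rec$df2, 9L)
  # cross-check against R's own linear-model ANOVA
  a <- anova(lm(y ~ factor(g)))
  expect_equal(rec$F, a$`F value`[1], tolerance = 1e-10)
  expect_equal(rec$p, a$`Pr(>F)`[1], tolerance = 1e-10)

  # identical class means: F = 0, p = 1
  y0 <- rep(c(1, 2), 6)
  expect_equal(anova2df(y0, rep(0:2, each = 4))$F, 0)
  expect_equal(anova2df(y0, rep(0:2, each = 4))$p, 1)
  # only two genotype classes: 1 df between
  expect_equal(anova2df(rnorm(10), rep(0:1, 5))$df1, 1L)
  # single class: untestable
  expect_equal(anova2df(rnorm(5), rep(1, 5))$status, "untestable")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(41)
  ps <- vapply(1:1e4, function(i) {
    g <- rbinom(30, 2, 0.3)
    anova2df(rnorm(30), g)$p
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the scan returns exactly the sub-threshold records", {
  set.seed(42)
  pat <- matrix(rnorm(5 * 100), 5, 100,
                dimnames = list(paste0("P", 1:5), paste0("s", 1:100)))
  g <- mkGeno(matrix(rbinom(20 * 100, 2, 0.3), 20, 100))
  colnames(g) <- colnames(pat)
  all <- scanAssociations(pat, g, pMax = 1)
  expect_equal(nrow(all), 100)            # 5 patterns x 20 SNPs
  expect_equal(attr(all, "nTested"), 100)
  # agreement with the scalar ANOVA on a spot check
  one <- all[all$snp == "snp3" & all$target == "P2", ]
  rec <- anova2df(pat[2, ], doseMatrix(g)[3, ])
  expect_equal(one$p, rec$p, tolerance = 1e-12)
  expect_equal(one$r2, rec$r2, tolerance = 1e-12)

  # null panels yield no hits at the suggestive threshold
  hits <- vapply(1:3, function(s) {
    set.seed(s)
    pat <- matrix(rnorm(10 * 300), 10, 300,
                  dimnames = list(paste0("P", 1:10), paste0("s", 1:300)))
    gg <- mkGeno(matrix(rbinom(1000 * 300, 2, 0.3), 1000, 300))
    colnames(gg) <- colnames(pat)
    nrow(scanAssociations(pat, gg, pMax = 1e-7))
  }, integer(1))
  expect_true(all(hits == 0))

  # a planted strong effect is found
  set.seed(43)
  gg <- mkGeno(matrix(rbinom(50 * 300, 2, 0.3), 50, 300))
  gdose <- doseMatrix(gg)[7, ]
  pat2 <- matrix(rnorm(3 * 300), 3, 300,
                 dimnames = list(paste0("P", 1:3), colnames(gg)))
  pat2[1, ] <- sqrt(0.25) * scale(gdose)[, 1] + sqrt(0.75) * rnorm(300)
  found <- scanAssociations(pat2, gg, pMax = 1e-7)
  expect_true(any(found$snp == "snp7" & found$target == "P1"))

  expect_error(scanAssociations(pat2[, 1:299], gg), "sample ids")
})

test_that("the study-wise threshold reproduces the Bonferroni arithmetic", {
  expect_equal(as.numeric(studyWiseThreshold(64, 675350)), 1.15e-9)
  expect_equal(as.numeric(studyWiseThreshold(1, 1)), 0.05)
  expect_equal(as.numeric(studyWiseThreshold(10, 10)), 5e-4)
  expect_error(studyWiseThreshold(0, 10), "positive")
})

test_that("step-2 module enrichment equals the exact hypergeometric tail", {
  mk <- function(genes) new("GeneModule", componentId = "m",
    members = S4Vectors::DataFrame(gene = genes,
      loading = rep(1, length(genes)), q = rep(0, length(genes))),
    fdrMax = 1e-3)
  universe <- paste0("g", 1:1000)
  m <- mk(paste0("g", 1:50))
  hits <- c(paste0("g", 36:50), paste0("g", 996:1000))  # 15 in, 5 out
  r <- moduleEnrichmentStep(m, hits, universe, threshold = 1e-9)
  pOracle <- sum(vapply(15:20, function(j)
    choose(20, j) * choose(980, 50 - j), numeric(1))) / choose(1000, 50)
  expect_equal(r$p, pOracle, tolerance = 1e-10)
  expect_equal(r$kHit, 15)
  expect_true(r$pass)

  r0 <- moduleEnrichmentStep(m, character(), universe, 0.05)
  expect_equal(r0$p, 1)
  expect_false(r0$pass)

  rSat <- moduleEnrichmentStep(mk(universe), universe, universe, 0.05)
  expect_equal(rSat$p, 1)
})

test_that("mediation adjustment separates mediated from direct effects", {
  set.seed(44)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  cis <- 0.8 * g + rnorm(n)
  trans <- cis + rnorm(n)
  full <- mediationAdjust(trans, g, cbind(cis))
  expect_lt(full$r2Adjusted, 0.2 * full$r2Unadjusted)

  indep <- mediationAdjust(0.5 * g + rnorm(n), g, cbind(rnorm(n)))
  expect_lt(abs(indep$r2Adjusted - indep$r2Unadjusted), 0.02)

  none <- mediationAdjust(trans, g, NULL)
  expect_equal(none$r2Adjusted, none$r2Unadjusted)
  expect_warning(mediationAdjust(trans, g, cbind(cis, cis)), "collinear")
})

test_that("pattern-phenotype correlation matches a permutation null", {
  a <- rnorm(30)
  expect_equal(patternPhenotypeCorr(a, a)$r, 1, tolerance = 1e-12)

  set.seed(45)
  big <- patternPhenotypeCorr(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(big$r), 0.05)

  set.seed(46)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- patternPhenotypeCorr(x, y)
  robs <- abs(res$r)
  perm <- vapply(1:2e4, function(i) abs(cor(x, sample(y))), numeric(1))
  pPerm <- (sum(perm >= robs) + 1) / (2e4 + 1)
  mcSd <- sqrt(res$p * (1 - res$p) / 2e4)
  expect_lt(abs(pPerm - res$p), 4 * mcSd + 1e-4)

  expect_error(patternPhenotypeCorr(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(patternPhenotypeCorr(c(1, 2), c(1, 2)), "at least 3")
})
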