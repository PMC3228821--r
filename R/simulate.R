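# Synthetic genotype-driven transcriptomes with known ground truth.
#
# The generator plants the exact latent structure the analysis assumes:
# sparse supergaussian signatures (module genes at +-loadingEffect with 10%
# multiplicative jitter, background loadings Gaussian), activations driven
# additively by a SNP under a 0/1/2 dose model and scaled analytically so the
# SNP explains a target fraction of the pattern variance, cis genes receiving
# a direct dose effect, optional additive contamination by non-target cell
# types, and iid Gaussian gene-level noise on the arcsinh scale.

#' Configuration of the synthetic dataset generator
#'
#' @param nSamples,nGenes,nSnps dimensions of the simulated study.
#' @param kTrue number of planted latent components.
#' @param moduleSizes integer vector (length `kTrue`): genes per module.
#' @param loadingEffect mean absolute loading of module genes on their
#'   component (arcsinh scale).
#' @param backgroundSd standard deviation of non-member loadings.
#' @param patternSnpR2 numeric vector (length `kTrue`) in [0, 1): target
#'   fraction of each pattern's variance explained by its driver SNP; 0
#'   disables the driver for that component.
#' @param maf per-SNP minor allele frequency in (0, 0.5]; recycled.
#' @param nCisPerComponent cis eQTLs planted inside each SNP-driven module.
#' @param cisR2 target fraction of a cis gene's expression variance explained
#'   directly by the driver SNP.
#' @param noiseSd standard deviation of the iid expression noise.
#' @param contamination `NULL`, or a list with elements `nCellTypes`,
#'   `genesPerType` and `fractionSd` enabling additive contamination.
#' @param seed global seed; per-purpose sub-seeds are derived from it so the
#'   pieces of the simulation can be regenerated independently.
#' @return A \linkS4class{SimulationConfig} object.
#' @examples
#' cfg <- simulationConfig(nSamples = 100, nGenes = 500, nSnps = 20,
#'                         kTrue = 2, moduleSizes = c(30, 30), seed = 7)
#' @export
simulationConfig <- function(nSamples = 300L, nGenes = 2000L, nSnps = 100L,
                             kTrue = 3L,
                             moduleSizes = rep(50L, kTrue),
                             loadingEffect = 1,
                             backgroundSd = 0.05,
                             patternSnpR2 = c(0.2, rep(0, max(kTrue - 1, 0))),
                             maf = 0.3,
                             nCisPerComponent = 2L,
                             cisR2 = 0.4,
                             noiseSd = 0.5,
                             contamination = NULL,
                             seed = 1L) {
  maf <- rep_len(maf, nSnps)
  patternSnpR2 <- rep_len(patternSnpR2, kTrue)
  cont <- list()
  if (!is.null(contamination) && length(contamination)) {
    stopIfNot(all(c("nCellTypes", "genesPerType", "fractionSd") %in%
                    names(contamination)),
              "contamination needs nCellTypes, genesPerType, fractionSd")
    cont <- list(nCellTypes = as.integer(contamination$nCellTypes),
                 genesPerType = as.integer(contamination$genesPerType),
                 fractionSd = as.numeric(contamination$fractionSd))
    stopIfNot(cont$fractionSd > 0, "fractionSd must be positive")
  }
  new("SimulationConfig",
    nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
    nSnps = as.integer(nSnps), kTrue = as.integer(kTrue),
    moduleSizes = as.integer(moduleSizes),
    loadingEffect = as.numeric(loadingEffect),
    backgroundSd = as.numeric(backgroundSd),
    patternSnpR2 = as.numeric(patternSnpR2),
    maf = as.numeric(maf),
    nCisPerComponent = as.integer(nCisPerComponent),
    cisR2 = as.numeric(cisR2), noiseSd = as.numeric(noiseSd),
    contamination = cont, seed = as.integer(seed))
}

#' Simulate a SNP-by-sample genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each SNP's minor-allele counts are independent Binomial(2, maf) draws,
#' giving Hardy-Weinberg genotype class frequencies.
#'
#' @param nSnps,nSamples dimensions.
#' @param maf per-SNP minor allele frequency in (0, 0.5]; recycled.
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- simulateGenotypes(10, 50, maf = 0.25, seed = 3)
#' table(doseMatrix(g))
#' @export
simulateGenotypes <- function(nSnps, nSamples, maf, seed) {
  maf <- rep_len(as.numeric(maf), nSnps)
  if (any(maf <= 0 | maf > 0.5))
    stop("minor allele frequencies must lie in (0, 0.5]", call. = FALSE)
  set.seed(as.integer(seed))
  dose <- matrix(stats::rbinom(nSnps * nSamples, size = 2,
                               prob = rep(maf, times = nSamples)),
                 nrow = nSnps, ncol = nSamples)
  dimnames(dose) <- list(paste0("snp", seq_len(nSnps)),
                         paste0("sample", seq_len(nSamples)))
  GenotypeData(dose)
}

#' Simulate an expression + genotype dataset with known latent structure
#'
#' Builds \eqn{x_{ij} = \sum_k s_{ik} a_{kj} + \epsilon_{ij}} on the arcsinh
#' scale: sparse signatures, SNP-driven activations (additive dose model,
#' analytic scaling to the target R2), direct cis effects inside the driven
#' modules, optional additive cell-type contamination, and Gaussian noise.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list with elements `expression` (\linkS4class{ExpressionData},
#'   state `"arcsinh"`), `genotypes` (\linkS4class{GenotypeData}) and
#'   `truth` (\linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateDataset(simulationConfig(nSamples = 80, nGenes = 300,
#'   nSnps = 10, kTrue = 1, moduleSizes = 20, seed = 11))
#' dim(exprValues(sim$expression))
#' @export
simulateDataset <- function(cfg) {
  stopIfNot(is(cfg, "SimulationConfig"), "cfg must be a SimulationConfig")
  validObject(cfg)
  G <- cfg@nGenes; N <- cfg@nSamples; K <- cfg@kTrue
  geneIds <- paste0("gene", seq_len(G))
  sampleIds <- paste0("sample", seq_len(N))
  cisR2 <- cfg@cisR2

  geno <- simulateGenotypes(cfg@nSnps, N, cfg@maf, subSeed(cfg@seed, 1))
  colnames(geno) <- sampleIds
  dose <- assay(geno, "dose")

  ## --- signatures -------------------------------------------------------
  set.seed(subSeed(cfg@seed, 2))
  S <- matrix(stats::rnorm(G * K, sd = cfg@backgroundSd), G, K,
              dimnames = list(geneIds, paste0("true", seq_len(K))))
  membership <- vector("list", K)
  available <- seq_len(G)
  for (k in seq_len(K)) {
    idx <- sample(available, cfg@moduleSizes[k])
    available <- setdiff(available, idx)
    sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
    jit <- 1 + 0.1 * stats::rnorm(length(idx))
    S[idx, k] <- sgn * cfg@loadingEffect * jit
    membership[[k]] <- geneIds[idx]
  }

  ## --- activations ------------------------------------------------------
  set.seed(subSeed(cfg@seed, 3))
  A <- matrix(0, K, N, dimnames = list(colnames(S), sampleIds))
  driver <- rep(NA_integer_, K)
  for (k in seq_len(K)) {
    eps <- stats::rnorm(N)
    r2 <- cfg@patternSnpR2[k]
    if (r2 > 0) {
      driver[k] <- k  # driver SNP k for component k
      p <- cfg@maf[k]
      beta <- sqrt(r2 / ((1 - r2) * 2 * p * (1 - p)))
      a <- beta * dose[k, ] + eps
    } else {
      a <- eps
    }
    A[k, ] <- (a - mean(a)) / stats::sd(a)
  }

  X <- S %*% A

  ## --- cis effects ------------------------------------------------------
  cis <- rep(list(character()), K)
  set.seed(subSeed(cfg@seed, 6))
  for (k in seq_len(K)) {
    if (is.na(driver[k]) || cfg@nCisPerComponent < 1) next
    pickFrom <- membership[[k]]
    nCis <- min(cfg@nCisPerComponent, length(pickFrom))
    cisIds <- sample(pickFrom, nCis)
    cis[[k]] <- cisIds
    g <- dose[driver[k], ]
    gc <- g - mean(g)
    for (gene in cisIds) {
      vOther <- stats::var(X[gene, ]) + cfg@noiseSd^2
      betaCis <- sqrt(cisR2 / (1 - cisR2) * vOther / stats::var(g))
      X[gene, ] <- X[gene, ] + betaCis * gc
    }
  }

  ## --- contamination ----------------------------------------------------
  contFrac <- matrix(0, N, 0)
  contGenes <- list()
  if (length(cfg@contamination)) {
    ct <- cfg@contamination
    set.seed(subSeed(cfg@seed, 5))
    contFrac <- matrix(pmin(abs(stats::rnorm(N * ct$nCellTypes,
                                             sd = ct$fractionSd)), 0.5),
                       N, ct$nCellTypes,
                       dimnames = list(sampleIds,
                                       paste0("cellType", seq_len(ct$nCellTypes))))
    pool <- setdiff(geneIds, unlist(membership))
    stopIfNot(length(pool) >= ct$nCellTypes * ct$genesPerType,
              "not enough non-module genes for contamination profiles")
    for (t in seq_len(ct$nCellTypes)) {
      ids <- sample(pool, ct$genesPerType)
      pool <- setdiff(pool, ids)
      contGenes[[paste0("cellType", t)]] <- ids
      profile <- stats::runif(length(ids), 3, 6)
      X[ids, ] <- X[ids, ] + outer(profile, contFrac[, t])
    }
  }

  ## --- noise ------------------------------------------------------------
  if (cfg@noiseSd > 0) {
    set.seed(subSeed(cfg@seed, 4))
    X <- X + matrix(stats::rnorm(G * N, sd = cfg@noiseSd), G, N)
  }

  truth <- new("GroundTruth",
    trueLoadings = S, trueActivations = A, driverSnp = driver,
    moduleMembership = membership, cisGenes = cis,
    contaminationFractions = contFrac, contaminationGenes = contGenes)

  list(expression = ExpressionData(X, transformState = "arcsinh"),
       genotypes = geno, truth = truth)
}

#' Jaccard index of two gene sets
#' @param a,b character vectors of gene ids.
#' @return |intersection| / |union|; 0 when both sets are empty.
#' @export
jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Evaluate recovery of planted components and modules
#'
#' Matches each true component to an estimated component by maximal absolute
#' Pearson correlation between activations (greedy by descending |r|, each
#' estimated component used at most once), and scores module recovery by the
#' Jaccard index of the gene sets.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param decomp a \linkS4class{Decomposition} on the same samples.
#' @param modules list of \linkS4class{GeneModule}, one per retained
#'   component of `decomp` (may be empty).
#' @return data.frame with one row per true component: `trueComponent`,
#'   `matchedComponent`, `absCor`, `jaccard`.
#' @export
evaluateRecovery <- function(truth, decomp, modules = list()) {
  At <- truth@trueActivations
  Ae <- patterns(decomp)
  Kt <- nrow(At)
  out <- data.frame(trueComponent = rownames(At),
                    matchedComponent = NA_character_,
                    absCor = NA_real_, jaccard = 0,
                    stringsAsFactors = FALSE)
  if (nrow(Ae) == 0) return(out)
  stopIfNot(ncol(At) == ncol(Ae),
            "truth and decomposition must share the same samples")
  cc <- abs(stats::cor(t(At), t(Ae)))  # Kt x Ke
  modIds <- vapply(modules, function(m) m@componentId, character(1))
  used <- rep(FALSE, ncol(cc))
  ord <- order(cc, decreasing = TRUE)
  assigned <- rep(FALSE, Kt)
  for (o in ord) {
    i <- (o - 1) %% Kt + 1
    j <- (o - 1) %/% Kt + 1
    if (assigned[i] || used[j]) next
    assigned[i] <- TRUE; used[j] <- TRUE
    estId <- componentIds(decomp)[j]
    out$matchedComponent[i] <- estId
    out$absCor[i] <- cc[i, j]
    if (length(modules)) {
      w <- which(modIds == estId)
      if (length(w) == 1)
        out$jaccard[i] <- jaccardIndex(truth@moduleMembership[[i]],
                                       moduleGenes(modules[[w]]))
    }
    if (all(assigned)) break
  }
  out
}
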