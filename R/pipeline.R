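# The end-to-end driver: preprocess -> outlier QC -> component-number
# selection -> ICA -> component filters -> module extraction -> two-step
# SNP-pattern association (-> contamination adjustment), plus a file-based
# wrapper with a YAML configuration.

#' Run the module discovery and trans-association analysis in memory
#'
#' Executes the analysis chain on an expression matrix and genotypes:
#' preprocessing to the standardized matrix, optional MDS outlier removal,
#' permutation-corrected choice of K (unless fixed), multi-restart ICA,
#' individual-specific and kurtosis component filters, empirical-null module
#' extraction, SNP QC, and the two-step association scan (2-df ANOVA of
#' patterns at `pStep1`, then module enrichment in per-gene associations at
#' `pStep2`, judged at the study-wise Bonferroni threshold).
#'
#' @param expr \linkS4class{ExpressionData} (state `"raw"` or `"arcsinh"`).
#' @param geno \linkS4class{GenotypeData} on the same samples.
#' @param K fixed number of components, or `NULL` to choose by the
#'   permutation-corrected screeplot.
#' @param seed integer seed driving permutations and ICA restarts.
#' @param nRestarts ICA restarts (default 10).
#' @param pStep1 suggestive SNP-pattern threshold (default 1e-7).
#' @param pStep2 per-gene association threshold (default 1e-5).
#' @param alphaStudy family-wise alpha of the study-wise enrichment
#'   threshold (default 0.05).
#' @param kurtosisMin signature kurtosis filter (default 3, excess scale).
#' @param fdrMax module membership threshold (default 1e-3).
#' @param outlierRounds MDS outlier-flagging rounds on the expression
#'   distance (default 0 = skip).
#' @param namePatterns gene-name filter patterns (default `character(0)`:
#'   synthetic gene ids carry no placeholder prefixes).
#' @param mafMin,hweAlpha,callMin SNP QC thresholds.
#' @return list: `standardized`, `K`, `decomposition`, `retained`, `modules`,
#'   `snpQC`, `step1`, `step2`, `threshold`, `universe`,
#'   `flaggedSamples`.
#' @export
runModuleDiscovery <- function(expr, geno, K = NULL, seed = 1,
                               nRestarts = 10, pStep1 = 1e-7, pStep2 = 1e-5,
                               alphaStudy = 0.05, kurtosisMin = 3,
                               fdrMax = 1e-3, outlierRounds = 0,
                               namePatterns = character(0),
                               mafMin = 0.01, hweAlpha = 1e-4,
                               callMin = 0.95) {
  stopIfNot(identical(colnames(expr), colnames(geno)),
            "expression and genotype samples must match")
  flagged <- character()
  if (outlierRounds > 0) {
    pre <- if (transformState(expr) == "raw") arcsinhTransform(expr) else expr
    flagged <- flagOutliers(expressionDistance(pre),
                            maxRounds = outlierRounds)$flagged
    if (length(flagged)) {
      keep <- setdiff(colnames(expr), flagged)
      expr <- expr[, keep]
      geno <- geno[, keep]
    }
  }
  std <- preprocessExpression(expr, namePatterns = namePatterns)
  qc <- snpQC(geno, mafMin = mafMin, hweAlpha = hweAlpha, callMin = callMin)
  geno <- qc$genotypes

  if (is.null(K))
    K <- chooseNumComponents(std, seed = subSeed(seed, 11))
  if (K < 1) stop("no components above the permutation null", call. = FALSE)
  decomp <- runICA(std, K, nRestarts = nRestarts, seed = subSeed(seed, 12),
                   kurtosisMin = kurtosisMin)
  retained <- filterComponents(decomp, kurtosisMin = kurtosisMin)
  modules <- extractModules(retained, fdrMax = fdrMax)
  universe <- rownames(std)

  if (numComponents(retained) == 0)
    return(list(standardized = std, K = K, decomposition = decomp,
                retained = retained, modules = modules, snpQC = qc$report,
                step1 = NULL, step2 = NULL, threshold = NA_real_,
                universe = universe, flaggedSamples = flagged))
  step1 <- scanAssociations(patterns(retained), geno, pMax = pStep1)
  thr <- studyWiseThreshold(numComponents(retained), nrow(geno),
                            alpha = alphaStudy)
  step2 <- NULL
  if (nrow(step1) > 0) {
    exprMat <- exprValues(std)
    rows <- lapply(seq_len(nrow(step1)), function(i) {
      snp <- step1$snp[i]
      comp <- step1$target[i]
      geneHits <- scanAssociations(exprMat, geno[snp, ], pMax = pStep2)
      enr <- moduleEnrichmentStep(modules[[comp]], unique(geneHits$target),
                                  universe, thr)
      cbind(data.frame(snp = snp, component = comp,
                       pStep1 = step1$p[i], r2 = step1$r2[i]), enr)
    })
    step2 <- do.call(rbind, rows)
  }
  list(standardized = std, K = K, decomposition = decomp,
       retained = retained, modules = modules, snpQC = qc$report,
       step1 = step1, step2 = step2, threshold = thr, universe = universe,
       flaggedSamples = flagged)
}

.pipelineDefaults <- function() list(
  expression = NULL, detection = NULL, genotypes = NULL, genotypeMap = NULL,
  geneSets = NULL, outDir = NULL, seed = 1L, K = NULL, nRestarts = 10L,
  pStep1 = 1e-7, pStep2 = 1e-5, alphaStudy = 0.05, kurtosisMin = 3,
  fdrMax = 1e-3, outlierRounds = 3L, namePatterns = NULL,
  mafMin = 0.01, hweAlpha = 1e-4, callMin = 0.95,
  transformState = "raw")

#' Run the full pipeline from files
#'
#' Reads the inputs named in a configuration (a YAML file or an equivalent
#' named list), runs [runModuleDiscovery()], optionally tests gene-set
#' enrichment of every module, and persists all stage outputs plus the
#' resolved configuration into `outDir`. Unknown configuration keys are
#' rejected before any computation.
#'
#' @param config path to a YAML file, or a named list. Recognized keys:
#'   `expression` (TSV/GCT path), `detection`, `genotypes` (VCF/TSV),
#'   `genotypeMap`, `geneSets` (GMT), `outDir`, `transformState`, and the
#'   parameters of [runModuleDiscovery()].
#' @return (invisibly) the [runModuleDiscovery()] result list, with
#'   `enrichment` appended when gene sets were given.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  stopIfNot(!is.null(cfg$expression) && !is.null(cfg$genotypes) &&
              !is.null(cfg$outDir),
            "config needs 'expression', 'genotypes' and 'outDir'")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  expr <- readExpression(cfg$expression, detectionPath = cfg$detection,
                         transformState = cfg$transformState)
  geno <- readGenotypes(cfg$genotypes, mapPath = cfg$genotypeMap)
  namePatterns <- if (is.null(cfg$namePatterns)) character(0)
    else as.character(cfg$namePatterns)

  res <- runModuleDiscovery(expr, geno, K = cfg$K, seed = cfg$seed,
                            nRestarts = cfg$nRestarts, pStep1 = cfg$pStep1,
                            pStep2 = cfg$pStep2, alphaStudy = cfg$alphaStudy,
                            kurtosisMin = cfg$kurtosisMin,
                            fdrMax = cfg$fdrMax,
                            outlierRounds = cfg$outlierRounds,
                            namePatterns = namePatterns, mafMin = cfg$mafMin,
                            hweAlpha = cfg$hweAlpha, callMin = cfg$callMin)

  out <- cfg$outDir
  writeDecomposition(res$retained, file.path(out, "decomposition"))
  modTab <- do.call(rbind, lapply(res$modules, moduleTable))
  utils::write.table(modTab, file.path(out, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$snpQC, file.path(out, "snp_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$step1, file.path(out, "associations_step1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$step2))
    utils::write.table(res$step2, file.path(out, "associations_step2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(res$flaggedSamples))
    writeLines(res$flaggedSamples, file.path(out, "flagged_samples.txt"))

  if (!is.null(cfg$geneSets)) {
    sets <- readGmt(cfg$geneSets)
    enr <- do.call(rbind, lapply(names(res$modules), function(id) {
      e <- genesetEnrichment(res$modules[[id]], sets, res$universe)
      if (nrow(e)) cbind(component = id, e) else NULL
    }))
    if (!is.null(enr))
      utils::write.table(enr, file.path(out, "geneset_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    res$enrichment <- enr
  }

  resolved <- cfg
  resolved$K <- res$K
  resolved$version <- as.character(utils::packageVersion("transICA"))
  yaml::write_yaml(resolved, file.path(out, "config_resolved.yaml"))
  invisible(res)
}
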