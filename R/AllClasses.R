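#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowData colData rowData<-
NULL

## ---------------------------------------------------------------------------
## ExpressionData
## ---------------------------------------------------------------------------

#' ExpressionData: a gene-by-sample expression matrix with a transform state
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding the expression
#' matrix \eqn{X} (genes in rows, samples in columns) that the decomposition
#' consumes, an optional parallel matrix of detection p-values, and a
#' `transformState` recording where the data sit in the fixed preprocessing
#' chain `raw -> arcsinh -> standardized`.
#'
#' @slot transformState character, one of `"raw"`, `"arcsinh"`,
#'   `"standardized"`.
#' @export
setClass("ExpressionData",
  contains = "SummarizedExperiment",
  slots = c(transformState = "character")
)

.validExpressionData <- function(object) {
  msg <- character()
  if (!object@transformState %in% c("raw", "arcsinh", "standardized"))
    msg <- c(msg, "transformState must be 'raw', 'arcsinh' or 'standardized'")
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if ("detection" %in% assayNames(object)) {
    dp <- assay(object, "detection")
    if (!all(dim(dp) == dim(assay(object, "exprs"))))
      msg <- c(msg, "detection assay must match exprs dimensions")
    rng <- range(dp, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if (object@transformState == "standardized") {
    x <- assay(object, "exprs")
    if (nrow(x) > 0 && ncol(x) > 1) {
      m <- rowMeans(x)
      v <- rowVars(x)
      if (max(abs(m)) > 1e-6 || max(abs(v - 1)) > 1e-6)
        msg <- c(msg, "standardized rows must have mean 0 and variance 1")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionData", .validExpressionData)

#' Construct an ExpressionData object
#'
#' @param values numeric matrix, genes x samples, with unique row and column
#'   names (gene and sample ids).
#' @param detectionP optional matrix of detection p-values of the same shape.
#' @param transformState state of the values; defaults to `"raw"`.
#' @return An \linkS4class{ExpressionData} object.
#' @examples
#' x <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ed <- ExpressionData(x, transformState = "arcsinh")
#' @export
ExpressionData <- function(values, detectionP = NULL,
                           transformState = c("raw", "arcsinh",
                                              "standardized")) {
  transformState <- match.arg(transformState)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  assays <- list(exprs = values)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    dimnames(detectionP) <- dimnames(values)
    assays$detection <- detectionP
  }
  se <- SummarizedExperiment(assays = assays)
  new("ExpressionData", se, transformState = transformState)
}

## ---------------------------------------------------------------------------
## GenotypeData
## ---------------------------------------------------------------------------

#' GenotypeData: SNP-by-sample minor-allele dose matrix with a variant map
#'
#' Extension of \linkS4class{SummarizedExperiment}: assay `dose` holds
#' minor-allele counts in \{0, 1, 2\} with `NA` for missing calls; `rowData`
#' carries the variant map (`chrom`, `pos`).
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- character()
  if (!"dose" %in% assayNames(object))
    msg <- c(msg, "assay 'dose' is required")
  else {
    d <- assay(object, "dose")
    ok <- is.na(d) | d %in% c(0, 1, 2)
    if (!all(ok)) msg <- c(msg, "doses must be 0, 1, 2 or NA")
  }
  if (!all(c("chrom", "pos") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must have 'chrom' and 'pos'")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param dose integer/numeric matrix of minor-allele counts (SNPs x samples),
#'   values 0/1/2 or NA; rownames are SNP ids, colnames sample ids.
#' @param chrom,pos optional variant map vectors (1-based positions, VCF
#'   convention); defaults place all SNPs on chromosome "1" at their row
#'   index.
#' @return A \linkS4class{GenotypeData} object.
#' @export
GenotypeData <- function(dose, chrom = NULL, pos = NULL) {
  dose <- as.matrix(dose)
  if (is.null(rownames(dose)))
    rownames(dose) <- paste0("snp", seq_len(nrow(dose)))
  if (is.null(colnames(dose)))
    colnames(dose) <- paste0("sample", seq_len(ncol(dose)))
  if (is.null(chrom)) chrom <- rep("1", nrow(dose))
  if (is.null(pos)) pos <- seq_len(nrow(dose))
  se <- SummarizedExperiment(
    assays = list(dose = dose),
    rowData = DataFrame(chrom = as.character(chrom), pos = as.integer(pos))
  )
  new("GenotypeData", se)
}

## ---------------------------------------------------------------------------
## Decomposition
## ---------------------------------------------------------------------------

#' Decomposition: the ICA factorization X ~ S A
#'
#' Holds the signature matrix `S` (genes x K; column k is the vector of
#' contributions of component k to each gene) and the pattern matrix `A`
#' (K x samples; row k is the activation of component k in each individual),
#' together with per-component excess kurtosis of the signature and the two
#' retention flags (individual-specific pattern, kurtosis filter).
#'
#' @slot S numeric matrix, genes x K, unit-variance columns.
#' @slot A numeric matrix, K x samples.
#' @slot componentIds character.
#' @slot kurtosis numeric, excess kurtosis of each signature over genes.
#' @slot individualSpecific logical flag per component.
#' @slot kurtosisPass logical flag per component.
#' @slot negentropy numeric, logcosh negentropy proxy per component.
#' @export
setClass("Decomposition",
  slots = c(
    S = "matrix", A = "matrix", componentIds = "character",
    kurtosis = "numeric", individualSpecific = "logical",
    kurtosisPass = "logical", negentropy = "numeric"
  )
)

.validDecomposition <- function(object) {
  msg <- character()
  K <- ncol(object@S)
  if (nrow(object@A) != K) msg <- c(msg, "ncol(S) must equal nrow(A)")
  if (length(object@componentIds) != K)
    msg <- c(msg, "componentIds length must equal K")
  for (nm in c("kurtosis", "individualSpecific", "kurtosisPass",
               "negentropy")) {
    v <- slot(object, nm)
    if (length(v) && length(v) != K)
      msg <- c(msg, sprintf("%s length must equal K", nm))
  }
  if (length(msg)) msg else TRUE
}
setValidity("Decomposition", .validDecomposition)

## ---------------------------------------------------------------------------
## NullFit and GeneModule
## ---------------------------------------------------------------------------

#' NullFit: empirical null for a signature's loading distribution
#'
#' Gaussian null fitted to the central bulk of one signature: `center` is the
#' median loading, `sigma0` the null scale estimated by truncated-Gaussian
#' maximum likelihood on a central quantile window, and `eta0` the estimated
#' null proportion (Storey-type), clipped to (0, 1].
#'
#' @export
setClass("NullFit",
  slots = c(center = "numeric", sigma0 = "numeric", eta0 = "numeric")
)
setValidity("NullFit", function(object) {
  msg <- character()
  if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be > 0")
  if (object@eta0 <= 0 || object@eta0 > 1)
    msg <- c(msg, "eta0 must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneModule: the FDR-selected gene set characterizing one signature
#'
#' @slot componentId character.
#' @slot members DataFrame with columns `gene`, `loading`, `q`.
#' @slot fdrMax numeric membership threshold applied.
#' @export
setClass("GeneModule",
  slots = c(componentId = "character", members = "DataFrame",
            fdrMax = "numeric")
)
setValidity("GeneModule", function(object) {
  msg <- character()
  need <- c("gene", "loading", "q")
  if (!all(need %in% colnames(object@members)))
    msg <- c(msg, "members must have columns gene, loading, q")
  else if (nrow(object@members) &&
           any(object@members$q >= object@fdrMax))
    msg <- c(msg, "every member must have q below the membership threshold")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' SimulationConfig: parameters of the synthetic genotype-driven transcriptome
#'
#' See [simulationConfig()] for field semantics and defaults.
#' @export
setClass("SimulationConfig",
  slots = c(
    nSamples = "integer", nGenes = "integer", nSnps = "integer",
    kTrue = "integer", moduleSizes = "integer",
    loadingEffect = "numeric", backgroundSd = "numeric",
    patternSnpR2 = "numeric", maf = "numeric",
    nCisPerComponent = "integer", cisR2 = "numeric", noiseSd = "numeric",
    contamination = "list", seed = "integer"
  )
)

.validSimulationConfig <- function(object) {
  msg <- character()
  if (length(object@moduleSizes) != object@kTrue)
    msg <- c(msg, "moduleSizes must have one entry per component")
  if (any(object@moduleSizes > object@nGenes))
    msg <- c(msg, "module sizes must not exceed n_genes")
  if (object@kTrue > min(object@nGenes, object@nSamples))
    msg <- c(msg, "K_true must not exceed min(n_genes, n_samples)")
  if (any(object@patternSnpR2 < 0 | object@patternSnpR2 >= 1))
    msg <- c(msg, "pattern SNP R2 values must lie in [0, 1)")
  if (any(object@maf <= 0 | object@maf > 0.5))
    msg <- c(msg, "minor allele frequencies must lie in (0, 0.5]")
  if (object@loadingEffect <= 0 || object@backgroundSd <= 0 ||
      object@noiseSd < 0)
    msg <- c(msg, "effect and noise scales must be positive")
  if (length(msg)) msg else TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)

#' GroundTruth: planted structure of a simulated dataset
#'
#' @slot trueLoadings genes x K matrix of planted loadings.
#' @slot trueActivations K x samples matrix of planted activations.
#' @slot driverSnp integer index of the driver SNP per component (NA when the
#'   component is not genotype-driven).
#' @slot moduleMembership list of gene-id character vectors per component.
#' @slot cisGenes list of gene-id character vectors per component.
#' @slot contaminationFractions samples x cell-types matrix (0 columns when
#'   contamination is disabled).
#' @slot contaminationGenes list of gene-id vectors per cell type.
#' @export
setClass("GroundTruth",
  slots = c(
    trueLoadings = "matrix", trueActivations = "matrix",
    driverSnp = "integer", moduleMembership = "list",
    cisGenes = "list", contaminationFractions = "matrix",
    contaminationGenes = "list"
  )
)
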