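# Preprocessing: probe collapsing, detection filter, gene-name filter,
# arcsinh variance stabilization and per-gene standardization. The pipeline
# order is fixed: collapse -> detection filter -> name filter -> arcsinh ->
# standardize.

#' Collapse probe-level intensities to gene level
#'
#' Gene value = arithmetic mean of its probes' values per sample, computed on
#' the raw scale before any transformation.
#'
#' @param probeValues probes x samples numeric matrix with probe ids as
#'   rownames.
#' @param probeToGene named character vector or two-column data.frame
#'   (probe, gene) mapping every probe to exactly one gene.
#' @param detectionP optional probes x samples detection p-value matrix;
#'   collapsed by the per-gene minimum (a gene is as detectable as its best
#'   probe).
#' @return An \linkS4class{ExpressionData} in state `"raw"`.
#' @export
collapseProbes <- function(probeValues, probeToGene, detectionP = NULL) {
  probeValues <- as.matrix(probeValues)
  if (is.data.frame(probeToGene))
    probeToGene <- stats::setNames(as.character(probeToGene[[2]]),
                                   as.character(probeToGene[[1]]))
  probes <- rownames(probeValues)
  unmapped <- setdiff(probes, names(probeToGene))
  if (length(unmapped))
    stop("unmapped probes: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  genes <- probeToGene[probes]
  gLevels <- unique(genes)
  idx <- split(seq_along(probes), factor(genes, levels = gLevels))
  collapse <- function(m, fun) {
    out <- matrix(NA_real_, length(gLevels), ncol(m),
                  dimnames = list(gLevels, colnames(m)))
    for (g in seq_along(idx)) {
      rows <- idx[[g]]
      out[g, ] <- if (length(rows) == 1) m[rows, ] else apply(m[rows, , drop = FALSE], 2, fun)
    }
    out
  }
  vals <- collapse(probeValues, mean)
  dp <- if (!is.null(detectionP)) collapse(as.matrix(detectionP), min)
  ExpressionData(vals, detectionP = dp, transformState = "raw")
}

#' Filter genes by detection rate
#'
#' Keeps a gene only when the fraction of samples in which it is detected
#' (detection p-value below `detectAt`) is significantly higher than the
#' chance rate, by a one-sided exact binomial test.
#'
#' @param x \linkS4class{ExpressionData} with a detection assay.
#' @param nullRate chance detection rate under the null (default 0.05).
#' @param alpha significance level of the one-sided exact test.
#' @param detectAt detection p-value below which a sample counts as detected.
#' @return list with `expression` (the filtered \linkS4class{ExpressionData})
#'   and `report` (data.frame: gene, nDetected, nSamples, pTail, keep).
#' @export
detectionFilter <- function(x, nullRate = 0.05, alpha = 0.05,
                            detectAt = 0.05) {
  dp <- detectionP(x)
  if (is.null(dp))
    stop("detection filter requires detection p-values", call. = FALSE)
  n <- ncol(x)
  k <- rowSums(dp < detectAt)
  # P(X >= k) under Binomial(n, nullRate)
  pTail <- stats::pbinom(k - 1, n, nullRate, lower.tail = FALSE)
  keep <- pTail < alpha
  report <- data.frame(gene = rownames(x), nDetected = k, nSamples = n,
                       pTail = pTail, keep = keep, row.names = NULL)
  list(expression = x[keep, ], report = report)
}

#' Default prefixes of putative / poorly characterized gene names
#' @export
defaultNameFilterPatterns <- function() {
  c("^KIAA", "^FLJ", "^HS\\.", "^C[0-9]+orf[0-9]+", "^MGC", "^LOC",
    "^NT_", "^ENSG")
}

#' Remove putative or poorly characterized genes by name
#'
#' Drops genes whose id matches any of the supplied regular expressions. The
#' default set encodes the conventional placeholder prefixes (KIAA, FLJ,
#' HS., C<n>orf<n>, MGC, LOC, NT_, ENSG).
#'
#' @param x \linkS4class{ExpressionData}.
#' @param patterns character vector of regular expressions.
#' @return Filtered \linkS4class{ExpressionData}.
#' @export
geneNameFilter <- function(x, patterns = defaultNameFilterPatterns()) {
  ids <- rownames(x)
  drop <- Reduce(`|`, lapply(patterns, function(p) grepl(p, ids)))
  if (all(drop)) warning("gene-name filter removed all genes")
  x[!drop, ]
}

#' Variance-stabilizing arcsinh transform
#'
#' Applies \eqn{\mathrm{arcsinh}(x) = \ln(x + \sqrt{x^2 + 1})} elementwise.
#' Refuses to run twice (state machine).
#'
#' @param x \linkS4class{ExpressionData} in state `"raw"`.
#' @return \linkS4class{ExpressionData} in state `"arcsinh"`.
#' @export
arcsinhTransform <- function(x) {
  if (transformState(x) != "raw")
    stop("arcsinh transform requires raw data (state is '",
         transformState(x), "')", call. = FALSE)
  out <- x
  assays(out)$exprs <- asinh(assay(x, "exprs"))
  out@transformState <- "arcsinh"
  validObject(out)
  out
}

#' Centre and standardize each gene across individuals
#'
#' Each gene row is centred to mean 0 and scaled to variance 1 (n-1
#' denominator), the normalization the decomposition expects.
#'
#' @param x \linkS4class{ExpressionData} in state `"arcsinh"`.
#' @param requireArcsinh set `FALSE` to standardize data that entered the
#'   pipeline already variance-stabilized.
#' @return \linkS4class{ExpressionData} in state `"standardized"`.
#' @export
standardizeGenes <- function(x, requireArcsinh = TRUE) {
  if (requireArcsinh && transformState(x) == "raw")
    stop("standardization expects arcsinh-transformed data", call. = FALSE)
  v <- assay(x, "exprs")
  vars <- rowVars(v)
  if (any(vars == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[vars == 0], 5), collapse = ", "),
         call. = FALSE)
  v <- (v - rowMeans(v)) / sqrt(vars)
  out <- x
  assays(out)$exprs <- v
  out@transformState <- "standardized"
  validObject(out)
  out
}

#' Run the fixed preprocessing chain
#'
#' Probe collapsing (when a map is given), detection filter (when detection
#' p-values are present), gene-name filter, arcsinh transform and per-gene
#' standardization, in that order. Genes with zero variance are dropped with
#' a warning before standardization.
#'
#' @param x \linkS4class{ExpressionData} in state `"raw"` or `"arcsinh"`
#'   (the arcsinh step is skipped for the latter).
#' @param nullRate,alpha,detectAt detection-filter parameters.
#' @param namePatterns regular expressions for the gene-name filter;
#'   `character(0)` disables it.
#' @return \linkS4class{ExpressionData} in state `"standardized"`.
#' @export
preprocessExpression <- function(x, nullRate = 0.05, alpha = 0.05,
                                 detectAt = 0.05,
                                 namePatterns = defaultNameFilterPatterns()) {
  if (!is.null(detectionP(x)))
    x <- detectionFilter(x, nullRate, alpha, detectAt)$expression
  if (length(namePatterns))
    x <- geneNameFilter(x, namePatterns)
  if (transformState(x) == "raw")
    x <- arcsinhTransform(x)
  vars <- rowVars(assay(x, "exprs"))
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance gene(s) dropped")
    x <- x[vars > 0, ]
  }
  standardizeGenes(x)
}
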