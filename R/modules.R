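# Gene-module definition: empirical Gaussian null fitted to the central bulk
# of a signature's loading distribution, tail-area FDR (q-values) for module
# membership, module overlap, and hypergeometric gene-set enrichment.

#' Fit an empirical Gaussian null to a loading distribution
#'
#' The null is centred at the median of the loadings; its scale is the
#' maximum-likelihood sigma of a Gaussian truncated to the central
#' `centralFraction` quantile window, and the null proportion `eta0` is the
#' observed mass of that window relative to the fitted null mass there
#' (Storey-type), clipped to (0, 1].
#'
#' @param loadings numeric vector of at least 100 signature loadings.
#' @param centralFraction central quantile window used for the fit
#'   (default 0.75).
#' @return A \linkS4class{NullFit}.
#' @export
fitEmpiricalNull <- function(loadings, centralFraction = 0.75) {
  stopIfNot(length(loadings) >= 100, "need at least 100 loadings")
  center <- stats::median(loadings)
  qs <- stats::quantile(loadings,
                        c((1 - centralFraction) / 2,
                          (1 + centralFraction) / 2),
                        names = FALSE)
  a <- qs[1]; b <- qs[2]
  if (b <= a) stop("degenerate loading distribution", call. = FALSE)
  inWin <- loadings[loadings >= a & loadings <= b]
  nll <- function(logSigma) {
    s <- exp(logSigma)
    mass <- stats::pnorm(b, center, s) - stats::pnorm(a, center, s)
    -sum(stats::dnorm(inWin, center, s, log = TRUE)) +
      length(inWin) * log(max(mass, 1e-300))
  }
  sdw <- stats::sd(inWin)
  opt <- stats::optimize(nll, interval = log(c(sdw / 10,
                                               10 * stats::sd(loadings))))
  sigma0 <- exp(opt$minimum)
  nullMass <- stats::pnorm(b, center, sigma0) - stats::pnorm(a, center, sigma0)
  eta0 <- (length(inWin) / length(loadings)) / max(nullMass, 1e-12)
  eta0 <- min(max(eta0, 1e-6), 1)
  new("NullFit", center = center, sigma0 = sigma0, eta0 = eta0)
}

#' Define a signature's gene module by tail-area FDR on its loadings
#'
#' Each loading gets a two-sided p-value under the fitted null
#' Normal(center, sigma0^2). Under the default `"qvalue"` rule the tail-area
#' FDR at threshold t is `eta0 * G * P0(t) / #\{|z| >= t\}`, evaluated at the
#' observed |z| values and monotonized so q-values are non-increasing in |z|;
#' genes with q below `fdrMax` are members. The `"nullp"` rule instead admits
#' genes whose plain two-sided null tail probability is below `fdrMax`.
#'
#' @param loadings named numeric vector (names are gene ids).
#' @param fit a \linkS4class{NullFit} for these loadings.
#' @param fdrMax membership threshold (default 1e-3).
#' @param componentId id stored in the module (default "IC").
#' @param method `"qvalue"` (default) or `"nullp"`.
#' @return A \linkS4class{GeneModule}; the `q` column holds the criterion
#'   value used (q-value or null tail probability).
#' @export
assignModule <- function(loadings, fit, fdrMax = 1e-3, componentId = "IC",
                         method = c("qvalue", "nullp")) {
  method <- match.arg(method)
  validObject(fit)
  G <- length(loadings)
  if (is.null(names(loadings))) names(loadings) <- paste0("gene", seq_len(G))
  z <- abs(loadings - fit@center) / fit@sigma0
  p2 <- 2 * stats::pnorm(-z)
  if (method == "qvalue") {
    ord <- order(z, decreasing = TRUE)
    fdr <- pmin(fit@eta0 * G * p2[ord] / seq_len(G), 1)
    q <- rev(cummin(rev(fdr)))        # monotone non-increasing in |z|
    crit <- numeric(G)
    crit[ord] <- q
  } else {
    crit <- p2
  }
  sel <- which(crit < fdrMax)
  sel <- sel[order(abs(loadings[sel]), decreasing = TRUE)]
  members <- DataFrame(gene = names(loadings)[sel],
                       loading = unname(loadings[sel]),
                       q = unname(crit[sel]))
  new("GeneModule", componentId = componentId, members = members,
      fdrMax = fdrMax)
}

#' Extract the module of every retained component
#'
#' @param d a \linkS4class{Decomposition}.
#' @param fdrMax membership threshold (default 1e-3).
#' @param centralFraction see [fitEmpiricalNull()].
#' @param method see [assignModule()].
#' @return named list of \linkS4class{GeneModule}, one per component.
#' @export
extractModules <- function(d, fdrMax = 1e-3, centralFraction = 0.75,
                           method = "qvalue") {
  S <- signatures(d)
  out <- lapply(seq_len(ncol(S)), function(k) {
    lo <- stats::setNames(S[, k], rownames(S))
    assignModule(lo, fitEmpiricalNull(lo, centralFraction), fdrMax,
                 componentId = componentIds(d)[k], method = method)
  })
  names(out) <- componentIds(d)
  out
}

#' Overlap ratio of two modules
#'
#' The number of genes shared by A and B over the total number of genes
#' belonging to A or B (Jaccard); 0 when both are empty.
#'
#' @param a,b \linkS4class{GeneModule} objects or character vectors.
#' @return numeric in [0, 1].
#' @export
moduleOverlap <- function(a, b) {
  ga <- if (is(a, "GeneModule")) moduleGenes(a) else as.character(a)
  gb <- if (is(b, "GeneModule")) moduleGenes(b) else as.character(b)
  jaccardIndex(ga, gb)
}

#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test of each gene set against the module within
#' a gene universe, with a Bonferroni family threshold computed over the sets
#' actually tested (those with at least `minSet` genes in the universe).
#'
#' @param m a \linkS4class{GeneModule} whose genes lie in `universe`.
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of all analyzed gene ids.
#' @param alphaFamily family-wise alpha for the Bonferroni threshold
#'   (default 0.05).
#' @param minSet smallest in-universe set size tested (default 5).
#' @return data.frame: set, setSize, moduleSize, overlap, p, threshold,
#'   significant.
#' @export
genesetEnrichment <- function(m, sets, universe, alphaFamily = 0.05,
                              minSet = 5) {
  genes <- moduleGenes(m)
  if (!all(genes %in% universe))
    stop("module genes outside the universe", call. = FALSE)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[vapply(sets, length, integer(1)) >= minSet]
  nFam <- length(sets)
  N <- length(universe)
  n <- length(genes)
  if (nFam == 0)
    return(data.frame(set = character(), setSize = integer(),
                      moduleSize = integer(), overlap = integer(),
                      p = numeric(), threshold = numeric(),
                      significant = logical()))
  thr <- alphaFamily / nFam
  res <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(sets[[nm]], genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, setSize = K, moduleSize = n, overlap = k,
               p = p, threshold = thr, significant = p < thr)
  })
  do.call(rbind, res)
}
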