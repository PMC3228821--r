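# Readers and writers for the plain-text formats the pipeline touches:
# TSV/GCT expression, VCF/TSV genotypes, GMT gene sets, JSON ground truth.

#' Read a gene-by-sample expression matrix
#'
#' TSV: first column gene ids, header sample ids. GCT 1.2: `#1.2` line,
#' dimensions line, then `Name`/`Description` columns before the samples.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"` (default guessed from the extension).
#' @param detectionPath optional TSV of detection p-values with the same
#'   layout as the TSV expression matrix.
#' @param transformState state of the stored values (default `"raw"`).
#' @return An \linkS4class{ExpressionData}.
#' @export
readExpression <- function(path, format = c("auto", "tsv", "gct"),
                           detectionPath = NULL,
                           transformState = "raw") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    lines <- readLines(path, n = 2)
    if (!startsWith(lines[1], "#1.2"))
      stop("not a GCT 1.2 file: ", path, call. = FALSE)
    tab <- utils::read.delim(path, skip = 2, check.names = FALSE,
                             stringsAsFactors = FALSE)
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(vals) <- tab[[1]]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE, row.names = 1)
    vals <- as.matrix(tab)
  }
  dp <- NULL
  if (!is.null(detectionPath)) {
    dtab <- utils::read.delim(detectionPath, check.names = FALSE,
                              stringsAsFactors = FALSE, row.names = 1)
    dp <- as.matrix(dtab)[rownames(vals), colnames(vals), drop = FALSE]
  }
  ExpressionData(vals, detectionP = dp, transformState = transformState)
}

#' Write an expression matrix as TSV (or GCT)
#'
#' @param x \linkS4class{ExpressionData}.
#' @param path output path.
#' @param format `"tsv"` (default) or `"gct"`.
#' @export
writeExpression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  v <- exprValues(x)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    tab <- data.frame(Name = rownames(v), Description = rownames(v),
                      v, check.names = FALSE)
    utils::write.table(format(tab, digits = 12, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .writeMatrixTsv(v, path, "gene")
  }
  invisible(path)
}

.writeMatrixTsv <- function(m, path, idColumn) {
  tab <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1] <- idColumn
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse a diploid GT string ("0/1", "0|1", "./.") into an allele-count dose.
.parseGT <- function(gt, line) {
  a <- strsplit(sub(":.*$", "", gt), "[/|]")
  vapply(seq_along(a), function(i) {
    if (is.na(gt[i])) return(NA_real_)   # vcfR reports ./. as NA
    al <- a[[i]]
    if (length(al) != 2)
      stop("non-diploid GT '", gt[i], "' at VCF record ", line, call. = FALSE)
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }, numeric(1))
}

#' Read genotypes from VCF or a 0/1/2 TSV matrix
#'
#' VCF GT fields are mapped to allele dose and oriented to the rarer allele;
#' `./.` becomes missing and multi-allelic sites are skipped with a warning.
#' A TSV must already hold 0/1/2 doses (first column SNP ids, header sample
#' ids), with an optional variant map (snp, chrom, pos).
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"vcf"` or `"tsv"`.
#' @param mapPath optional variant-map TSV for the TSV format.
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          mapPath = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s) skipped")
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    for (i in seq_len(nrow(gt)))
      dose[i, ] <- .parseGT(gt[i, ], i)
    altFreq <- rowMeans(dose, na.rm = TRUE) / 2
    flip <- !is.na(altFreq) & altFreq > 0.5
    dose[flip, ] <- 2 - dose[flip, , drop = FALSE]
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
      is.na(ids) | ids == "."]
    rownames(dose) <- ids
    return(GenotypeData(dose, chrom = fix$CHROM, pos = as.integer(fix$POS)))
  }
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  dose <- as.matrix(tab)
  if (!all(is.na(dose) | dose %in% c(0, 1, 2)))
    stop("TSV genotypes must be coded 0/1/2 (NA for missing)", call. = FALSE)
  chrom <- NULL; pos <- NULL
  if (!is.null(mapPath)) {
    map <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
    m <- match(rownames(dose), map[[1]])
    chrom <- map[[2]][m]; pos <- map[[3]][m]
  }
  GenotypeData(dose, chrom = chrom, pos = pos)
}

#' Write genotypes as a dose TSV or a minimal VCFv4.2 (GT fields only)
#'
#' @param g \linkS4class{GenotypeData}.
#' @param path output path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @export
writeGenotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  d <- doseMatrix(g)
  if (format == "tsv") return(.writeMatrixTsv(d, path, "snp"))
  map <- variantMap(g)
  gtChar <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  gtChar[is.na(d)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
  body <- cbind(map$chrom, map$pos, map$snp, "A", "B", ".", "PASS", ".",
                "GT", gtChar)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, member genes. Duplicates
#' within a set are removed; empty sets are dropped with a warning.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file")
    return(stats::setNames(list(), character()))
  }
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("empty gene set '", f[1], "' dropped")
      next
    }
    out[[f[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default "na").
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a decomposition (S, A and component metadata) as TSVs
#' @param d \linkS4class{Decomposition}.
#' @param dir output directory (created if needed).
#' @export
writeDecomposition <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeMatrixTsv(signatures(d), file.path(dir, "signatures.tsv"), "gene")
  .writeMatrixTsv(patterns(d), file.path(dir, "patterns.tsv"), "component")
  meta <- data.frame(component = componentIds(d), kurtosis = d@kurtosis,
                     individualSpecific = d@individualSpecific,
                     kurtosisPass = d@kurtosisPass,
                     negentropy = d@negentropy)
  utils::write.table(meta, file.path(dir, "components.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write the ground truth of a simulated dataset as JSON
#' @param truth \linkS4class{GroundTruth}.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    driverSnp = truth@driverSnp,
    moduleMembership = truth@moduleMembership,
    cisGenes = truth@cisGenes,
    contaminationGenes = truth@contaminationGenes,
    contaminationFractions = truth@contaminationFractions,
    trueActivations = truth@trueActivations
  ), path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}
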