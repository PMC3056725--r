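#' Load an expression dataset from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (or the transpose, with \code{orientation =
#' "samples-in-rows"}), plus a labels file with one class label per
#' sample (one per line, or a single-column delimited file). Missing or
#' non-numeric cells are rejected with their coordinates; duplicate gene
#' identifiers are disambiguated with a suffix and a message.
#'
#' @param path expression matrix file (TSV by default).
#' @param labelsPath labels file.
#' @param orientation "genes-in-rows" (default) or "samples-in-rows".
#' @param sep field separator.
#' @return a [GeneExpressionSet-class].
#' @export
loadExpression <- function(path, labelsPath,
                           orientation = c("genes-in-rows", "samples-in-rows"),
                           sep = "\t") {
  orientation <- match.arg(orientation)
  for (f in c(path, labelsPath))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  tab <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = NA)
  x <- as.matrix(tab)
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(apply(tab, 2L, as.numeric))),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d ('%s'), column %d ('%s')",
                 bad[1L], rownames(tab)[bad[1L]], bad[2L],
                 colnames(tab)[bad[2L]]), call. = FALSE)
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("missing value at row %d ('%s'), column %d ('%s')",
                 bad[1L], rownames(x)[bad[1L]], bad[2L],
                 colnames(x)[bad[2L]]), call. = FALSE)
  }
  if (orientation == "samples-in-rows") x <- t(x)
  labels <- readLabels(labelsPath, sep)
  if (length(labels) != ncol(x))
    stop(sprintf("%d labels for %d samples", length(labels), ncol(x)),
         call. = FALSE)
  if (length(unique(labels)) < 3L)
    stop("at least 3 classes are required (M >= 3)", call. = FALSE)
  if (anyDuplicated(rownames(x))) {
    message("duplicate gene identifiers disambiguated with a numeric suffix")
    rownames(x) <- make.unique(rownames(x))
  }
  geneExpressionSet(x, labels, provenance = normalizePath(path))
}

readLabels <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, sep), function(x) trimws(x[[length(x)]]),
         character(1))
}

#' Write an expression dataset as delimited text
#'
#' Inverse of [loadExpression()] (genes in rows).
#'
#' @param ds a [GeneExpressionSet-class].
#' @param path expression matrix output file.
#' @param labelsPath labels output file (one label per line).
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(ds, path, labelsPath, sep = "\t") {
  x <- exprsMatrix(ds)
  utils::write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  writeLines(as.character(classLabels(ds)), labelsPath)
  invisible(path)
}

#' Run the full Monte Carlo evaluation protocol for one family
#'
#' For each stratified Monte Carlo 4:1 partition: select (n, Q) by
#' nested 10-fold CV at C = 1 on the training part, optionally tune C on
#' the same training part, fit the final model on the full training part,
#' and evaluate it once on the untouched test part. Per-partition errors,
#' gene counts and selected-gene sets are collected, and selection
#' stability is summarized over all partition pairs. A failed partition
#' is recorded with its error message without invalidating the others.
#'
#' @param ds a [GeneExpressionSet-class].
#' @param family "LDPC" or "OAA".
#' @param eta n-range expansion factor (LDPC).
#' @param partitions number of Monte Carlo partitions (protocol: 200).
#' @param ratio train fraction (default 4/5).
#' @param trainSize exact training-set size, overriding \code{ratio}.
#' @param folds inner CV folds.
#' @param qGrid optional reduced gene-fraction grid (see [selectNQ()]).
#' @param tuneC run the two-step C search (default TRUE).
#' @param seed integer master seed; every stage derives its seeds from it.
#' @param outDir optional directory for TSV outputs (per-partition table,
#'   per-partition gene lists, run manifest).
#' @return list with \code{perPartition} (data.frame: partition, n, Q, g,
#'   C, testError, totalGenes, status), \code{geneSets} (per-partition
#'   selected-gene unions), \code{stability} (a
#'   [StabilityReport-class]) and \code{manifest}.
#' @export
runExperiment <- function(ds, family = c("LDPC", "OAA"), eta = 10,
                          partitions = 200, ratio = 4 / 5, trainSize = NULL,
                          folds = 10, qGrid = NULL, tuneC = TRUE, seed = 1,
                          outDir = NULL) {
  family <- match.arg(family)
  stopifnot(is(ds, "GeneExpressionSet"))
  parts <- montecarloPartitions(classLabels(ds), count = partitions,
                                ratio = ratio, trainSize = trainSize,
                                seed = seed)
  rows <- vector("list", partitions)
  geneSets <- vector("list", partitions)
  for (i in seq_len(partitions)) {
    rows[[i]] <- tryCatch({
      train <- ds[, parts[[i]]$train]
      test <- ds[, parts[[i]]$test]
      sel <- selectNQ(train, family, eta = eta,
                      seed = deriveSeed(seed, i), folds = folds,
                      qGrid = qGrid)
      C <- if (tuneC) optimizeC(train, sel, folds = folds) else sel@C
      model <- fitFinal(train, sel, C = C)
      pred <- predict(model, test)
      genes <- unique(unlist(lapply(model@columns, `[[`, "genes")))
      geneSets[[i]] <- genes
      data.frame(partition = i, n = sel@n, Q = sel@Q, g = sel@g, C = C,
                 testError = mean(pred != classLabels(test)),
                 totalGenes = length(genes), status = "ok")
    }, error = function(e)
      data.frame(partition = i, n = NA_integer_, Q = NA_real_,
                 g = NA_integer_, C = NA_real_, testError = NA_real_,
                 totalGenes = NA_integer_,
                 status = paste("failed:", conditionMessage(e))))
  }
  perPartition <- do.call(rbind, rows)
  okSets <- geneSets[!vapply(geneSets, is.null, logical(1))]
  stability <- if (length(okSets) >= 2L) meanStability(okSets) else NULL
  manifest <- list(
    family = family, eta = eta, partitions = partitions, ratio = ratio,
    trainSize = trainSize, folds = folds,
    qGrid = qGrid, tuneC = tuneC, seed = seed,
    M = nClasses(ds), p = nGenes(ds), q = nSamples(ds),
    package = as.character(utils::packageVersion("sparseECOC")))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(perPartition, file.path(outDir, "per_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(okSets))
      writeLines(okSets[[i]],
                 file.path(outDir, sprintf("genes_partition_%03d.txt", i)))
    writeLines(paste(names(manifest),
                     vapply(manifest, function(v)
                       paste(format(v), collapse = ","), character(1)),
                     sep = "="),
               file.path(outDir, "manifest.txt"))
  }
  list(perPartition = perPartition, geneSets = okSets,
       stability = stability, manifest = manifest)
}

#' Fraction of planted markers recovered by a run
#'
#' @param geneSets list of per-partition selected-gene vectors (the
#'   \code{geneSets} element of [runExperiment()]).
#' @param markers ground-truth marker ids, a vector or the per-class list
#'   returned by [generateGaussianDataset()].
#' @return fraction of markers present in the union of selected genes.
#' @export
markerRecall <- function(geneSets, markers) {
  truth <- unique(unlist(markers))
  mean(truth %in% unique(unlist(geneSets)))
}
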