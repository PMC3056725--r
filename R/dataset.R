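#' Construct a GeneExpressionSet
#'
#' Wraps a p x q expression matrix and its sample labels into the
#' validated [GeneExpressionSet-class] container used throughout the
#' pipeline (genes in rows, samples in columns).
#'
#' @param exprs numeric matrix, p genes x q samples, no missing values.
#' @param labels class labels, one per sample (coerced to factor, M >= 3
#'   levels required).
#' @param geneIds,sampleIds optional identifier vectors; defaults are
#'   taken from dimnames or generated (\code{g1..gp}, \code{s1..sq}).
#' @param provenance free-form character recorded in metadata (source
#'   file or generator seed).
#' @return a [GeneExpressionSet-class].
#' @examples
#' x <- matrix(rnorm(30), nrow = 5)
#' ds <- geneExpressionSet(x, rep(c("A", "B", "C"), each = 2))
#' nClasses(ds)
#' @export
geneExpressionSet <- function(exprs, labels, geneIds = NULL, sampleIds = NULL,
                              provenance = "in-memory") {
  exprs <- as.matrix(exprs)
  if (length(labels) != ncol(exprs))
    stop(sprintf("%d labels for %d samples", length(labels), ncol(exprs)),
         call. = FALSE)
  if (is.null(geneIds)) geneIds <- rownames(exprs)
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(exprs)))
  if (is.null(sampleIds)) sampleIds <- colnames(exprs)
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(exprs)))
  dimnames(exprs) <- list(geneIds, sampleIds)
  labels <- factor(labels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds),
    metadata = list(provenance = provenance))
  new("GeneExpressionSet", se)
}

#' Accessors for GeneExpressionSet
#'
#' \code{exprsMatrix} returns the p x q expression matrix,
#' \code{classLabels} the per-sample label factor, \code{nClasses} the
#' number of classes M, \code{nGenes}/\code{nSamples} the dimensions.
#'
#' @param x a [GeneExpressionSet-class].
#' @return see Description.
#' @name geneExpressionSet-accessors
NULL

#' @rdname geneExpressionSet-accessors
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname geneExpressionSet-accessors
#' @export
classLabels <- function(x) x$label

#' @rdname geneExpressionSet-accessors
#' @export
nClasses <- function(x) nlevels(x$label)

#' @rdname geneExpressionSet-accessors
#' @export
nGenes <- function(x) nrow(x)

#' @rdname geneExpressionSet-accessors
#' @export
nSamples <- function(x) ncol(x)
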