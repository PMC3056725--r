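#' @import methods
#' @importFrom stats sd rnorm rbinom predict setNames
NULL

#' Gene budget for one output-coding configuration
#'
#' Holds the closed-form information-theoretic quantities that bound how
#' many genes any single binary classifier may select when an M-class
#' problem over p genes is reduced to n binary tasks: the binary entropy
#' \eqn{H(f)} of a gene expressed with probability \eqn{f}, the per-task
#' information share \eqn{H_b = \log_2(M)/n}, the maximal selectable gene
#' fraction \eqn{Q_{max}} and the induced integer gene cap.
#'
#' @slot M integer, number of classes (>= 3).
#' @slot p integer, total number of genes.
#' @slot n integer, number of binary classifiers (>= 1).
#' @slot f numeric, probability that a gene is expressed (defaults to 1/p).
#' @slot Hf numeric, binary entropy of \code{f} in bits.
#' @slot HM numeric, \eqn{\log_2 M} in bits.
#' @slot Hb numeric, per-classifier information \eqn{H_M/n} in bits.
#' @slot Qmax numeric, maximal fraction of genes per binary classifier.
#' @slot gMax integer, gene cap \eqn{\max(1, \lfloor p Q_{max} \rfloor)}.
#'
#' @seealso [geneBudget()], [qMax()], [geneCap()]
#' @export
setClass("GeneBudget",
  representation(M = "integer", p = "integer", n = "integer",
                 f = "numeric", Hf = "numeric", HM = "numeric",
                 Hb = "numeric", Qmax = "numeric", gMax = "integer"))

setValidity("GeneBudget", function(object) {
  msg <- character()
  if (object@M < 3L) msg <- c(msg, "M must be >= 3")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@f <= 0 || object@f >= 1) msg <- c(msg, "f must lie in (0, 1)")
  if (abs(object@Hb - object@HM / object@n) > 1e-12)
    msg <- c(msg, "Hb must equal HM / n")
  # Eq.-1 identity at equality: Qmax * p * n * H(f) = log2 M
  lhs <- object@Qmax * object@p * object@n * object@Hf
  if (abs(lhs - object@HM) > 1e-12 * max(1, abs(object@HM)))
    msg <- c(msg, "Qmax * p * n * H(f) must equal log2(M)")
  if (object@gMax < 1L || object@gMax > object@p)
    msg <- c(msg, "gMax must lie in [1, p]")
  if (length(msg)) msg else TRUE
})

#' Sparse bipartite parity-check graph
#'
#' An LDPC code's Tanner graph: \code{n} message nodes (codeword
#' coordinates) on one side, \code{m} parity-check nodes on the other.
#' Codewords are the binary vectors whose neighbouring positions sum to
#' zero (mod 2) at every check node, so the graph protects
#' \eqn{k = n - m} information bits once the parity matrix has full
#' GF(2) row rank.
#'
#' @slot n integer, number of message nodes (code length).
#' @slot m integer, number of check nodes.
#' @slot j integer, target message-node (column) degree.
#' @slot edges two-column integer matrix of (check, message) pairs.
#' @slot seed integer, RNG seed used for the construction.
#'
#' @seealso [buildLdpcGraph()], [parityMatrix()]
#' @export
setClass("ParityCheckGraph",
  representation(n = "integer", m = "integer", j = "integer",
                 edges = "matrix", seed = "integer"))

setValidity("ParityCheckGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (anyDuplicated(paste(e[, 1L], e[, 2L]))) msg <- c(msg, "duplicate edges")
  if (any(e[, 1L] < 1L | e[, 1L] > object@m)) msg <- c(msg, "check index out of range")
  if (any(e[, 2L] < 1L | e[, 2L] > object@n)) msg <- c(msg, "message index out of range")
  if (length(setdiff(seq_len(object@n), e[, 2L])))
    msg <- c(msg, "every message node needs degree >= 1")
  cdeg <- tabulate(e[, 1L], nbins = object@m)
  if (any(cdeg < 2L)) msg <- c(msg, "every check node needs degree >= 2")
  if (object@m >= object@n) msg <- c(msg, "need m < n (k = n - m >= 1)")
  if (length(msg)) msg else TRUE
})

#' Class-to-codeword matrix for output coding
#'
#' A binary M x n matrix whose i-th row encodes class i and whose j-th
#' column defines the binary split learned by the j-th binary classifier.
#' \code{kind} is \code{"OAA"} (identity code, n = M) or \code{"LDPC"}
#' (rows are codewords of the linear code defined by \code{graph}).
#'
#' @slot M integer, number of classes.
#' @slot n integer, code length (number of binary classifiers).
#' @slot codewords M x n binary integer matrix.
#' @slot kind character, "OAA" or "LDPC".
#' @slot graph the [ParityCheckGraph-class] when kind is "LDPC", else NULL.
#' @slot seed integer, seed used for the class-to-codeword assignment.
#'
#' @seealso [oaaCode()], [enumerateCodebook()], [softDecode()], [hingeDecode()]
#' @export
setClass("CodeMatrix",
  representation(M = "integer", n = "integer", codewords = "matrix",
                 kind = "character", graph = "ANY", seed = "integer"))

setValidity("CodeMatrix", function(object) {
  msg <- character()
  cw <- object@codewords
  if (nrow(cw) != object@M || ncol(cw) != object@n)
    msg <- c(msg, "codewords must be M x n")
  if (!all(cw %in% c(0L, 1L))) msg <- c(msg, "codewords must be binary")
  if (anyDuplicated(apply(cw, 1L, paste, collapse = "")))
    msg <- c(msg, "codeword rows must be distinct")
  if (any(apply(cw, 2L, function(col) length(unique(col))) == 1L))
    msg <- c(msg, "no column may be constant across classes")
  if (!object@kind %in% c("OAA", "LDPC")) msg <- c(msg, "kind must be OAA or LDPC")
  if (object@kind == "LDPC") {
    if (!is(object@graph, "ParityCheckGraph"))
      msg <- c(msg, "LDPC code needs its ParityCheckGraph")
    else {
      H <- parityMatrix(object@graph)
      if (any((H %*% t(cw)) %% 2L != 0L))
        msg <- c(msg, "every row must satisfy every parity check")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Additive white Gaussian noise channel model
#'
#' Models binary-classifier error statistics: a code bit b is transmitted
#' as the symbol \eqn{(-1)^b} (0 -> +1, 1 -> -1) and observed plus
#' N(0, sigma^2) noise, so the per-coordinate log-likelihood ratio of a
#' received value r is \eqn{2 r / \sigma^2}.
#'
#' @slot sigma positive numeric, channel noise standard deviation.
#' @export
setClass("ChannelModel", representation(sigma = "numeric"))

setValidity("ChannelModel", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    "sigma must be a single positive number" else TRUE
})

#' @describeIn ChannelModel-class constructor.
#' @param sigma positive channel noise standard deviation.
#' @export
channelModel <- function(sigma = 1) {
  new("ChannelModel", sigma = as.numeric(sigma))
}

#' Genes ranked by decreasing S2N score
#'
#' @slot ids character, all p gene identifiers ordered by decreasing score.
#' @slot scores numeric, the S2N scores in the same (non-increasing) order.
#' @seealso [s2nScores()], [rankGenes()], [selectTopGenes()]
#' @export
setClass("RankedGeneList",
  representation(ids = "character", scores = "numeric"))

setValidity("RankedGeneList", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@scores))
    msg <- c(msg, "ids and scores must have equal length")
  if (is.unsorted(rev(object@scores)))
    msg <- c(msg, "scores must be non-increasing along the order")
  if (anyDuplicated(object@ids)) msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Expression dataset for multiclass classification
#'
#' A \linkS4class{SummarizedExperiment} carrying one \code{"exprs"} assay
#' (p genes x q samples, no missing values) and a \code{label} factor with
#' M >= 3 levels in \code{colData}. This is the single data carrier through
#' selection, training and evaluation.
#'
#' @seealso [geneExpressionSet()], [loadExpression()]
#' @export
#' @import SummarizedExperiment
setClass("GeneExpressionSet", contains = "SummarizedExperiment")

setValidity("GeneExpressionSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  x <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(x)) msg <- c(msg, "expression matrix must have no missing values")
  if (!is.numeric(x)) msg <- c(msg, "expression values must be numeric")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData column 'label' is required")
  lab <- object$label
  if (!is.factor(lab)) msg <- c(msg, "label must be a factor")
  else if (nlevels(lab) < 3L)
    msg <- c(msg, "at least 3 classes are required (multiclass setting)")
  if (length(msg)) msg else TRUE
})

#' Result of the nested-CV (n, Q) model selection
#'
#' @slot family character, "OAA" or "LDPC".
#' @slot n integer, chosen number of binary classifiers.
#' @slot Q numeric, chosen gene fraction.
#' @slot g integer, chosen (even) gene count per binary classifier.
#' @slot C numeric, complexity hyperparameter (1 until [optimizeC()] runs).
#' @slot surface data.frame with columns n, Q, g, error: the inner-CV
#'   error surface over the explored grid.
#' @slot eta numeric, n-range expansion factor.
#' @slot seed integer, protocol seed.
#' @export
setClass("SelectionResult",
  representation(family = "character", n = "integer", Q = "numeric",
                 g = "integer", C = "numeric", surface = "data.frame",
                 eta = "numeric", seed = "integer"))

#' Trained output-coded multiclass classifier
#'
#' @slot code the [CodeMatrix-class] in use.
#' @slot columns list of length n; each element holds the selected gene ids,
#'   training standardization statistics, the fitted binary SVM and its
#'   margin scale.
#' @slot channel the [ChannelModel-class] used for soft decoding.
#' @slot decoding character, "sum-product" (LDPC) or "hinge" (OAA).
#' @slot classLevels character, the M class labels in codebook row order.
#' @slot geneIds character, the full gene universe the model was trained on.
#' @slot C numeric, SVM complexity used for the final fit.
#' @slot gMax integer, the per-column gene budget in force.
#' @slot seed integer.
#' @seealso [fitFinal()], [predict,EcocModel-method]
#' @export
setClass("EcocModel",
  representation(code = "CodeMatrix", columns = "list",
                 channel = "ChannelModel", decoding = "character",
                 classLevels = "character", geneIds = "character",
                 C = "numeric", gMax = "integer", seed = "integer"))

setValidity("EcocModel", function(object) {
  msg <- character()
  if (length(object@columns) != object@code@n)
    msg <- c(msg, "need one fitted column per code column")
  sizes <- vapply(object@columns, function(col) length(col$genes), integer(1))
  if (any(sizes > object@gMax))
    msg <- c(msg, "a column exceeds the gene budget gMax")
  if (!object@decoding %in% c("sum-product", "hinge"))
    msg <- c(msg, "decoding must be 'sum-product' or 'hinge'")
  if (length(msg)) msg else TRUE
})

#' Gene-selection stability report
#'
#' All pairwise Salton cosine coefficients between the per-partition
#' selected-gene sets, plus their mean.
#'
#' @slot sets list of character vectors (per-partition overall gene sets).
#' @slot coefficients numeric, the P(P-1)/2 pairwise Salton coefficients.
#' @slot mean numeric, mean stability.
#' @slot pairs integer, number of unordered pairs.
#' @seealso [meanStability()], [saltonCoefficient()]
#' @export
setClass("StabilityReport",
  representation(sets = "list", coefficients = "numeric",
                 mean = "numeric", pairs = "integer"))

setValidity("StabilityReport", function(object) {
  P <- length(object@sets)
  msg <- character()
  if (object@pairs != P * (P - 1L) / 2L)
    msg <- c(msg, "pairs must equal P(P-1)/2")
  if (length(object@coefficients) != object@pairs)
    msg <- c(msg, "one coefficient per unordered pair")
  if (any(object@coefficients < 0 | object@coefficients > 1))
    msg <- c(msg, "coefficients must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Two-group stochastic-dominance comparison for one metric
#'
#' Distributions of one performance metric for two classifier families
#' (F and G) over a common partition scheme, with Shapiro-Wilk normality
#' p-values, two-sided and one-sided Kolmogorov-Smirnov statistics and
#' p-values, one-sided Mann-Whitney p-values, and the first-order
#' stochastic-dominance verdict.
#'
#' @slot metric character, metric name.
#' @slot F,G numeric, metric samples for the two groups.
#' @slot shapiroPF,shapiroPG numeric, Shapiro-Wilk p-values (NA if the
#'   sample is degenerate).
#' @slot D,Dplus,Dminus numeric, KS statistics on the pooled points
#'   (D = max(Dplus, Dminus)).
#' @slot pTwo,pGreater,pLess numeric, KS p-values (two-sided; alternative
#'   "greater"; alternative "less", in the reference ks.test orientation).
#' @slot pMwLess,pMwGreater numeric, one-sided Mann-Whitney p-values.
#' @slot alpha numeric, significance level of the verdict.
#' @slot direction character, "higher-is-better" or "lower-is-better".
#' @slot verdict character, one of "F dominates", "G dominates",
#'   "ambiguous", "no difference".
#' @seealso [dominanceAnalysis()], [summarizeRuns()]
#' @export
setClass("ComparisonReport",
  representation(metric = "character", F = "numeric", G = "numeric",
                 shapiroPF = "numeric", shapiroPG = "numeric",
                 D = "numeric", Dplus = "numeric", Dminus = "numeric",
                 pTwo = "numeric", pGreater = "numeric", pLess = "numeric",
                 pMwLess = "numeric", pMwGreater = "numeric",
                 alpha = "numeric", direction = "character",
                 verdict = "character"))

setValidity("ComparisonReport", function(object) {
  msg <- character()
  if (abs(object@D - max(object@Dplus, object@Dminus)) > 1e-12)
    msg <- c(msg, "D must equal max(Dplus, Dminus)")
  ps <- c(object@pTwo, object@pGreater, object@pLess,
          object@pMwLess, object@pMwGreater)
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) msg <- c(msg, "p-values must lie in [0, 1]")
  if (!object@verdict %in% c("F dominates", "G dominates", "ambiguous", "no difference"))
    msg <- c(msg, "unknown verdict")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset specification
#'
#' Parameters of the seeded generators: a Gaussian model with
#' class-exclusive marker genes whose means are shifted by
#' \code{effectSize} noise-sd units in their class, and a probabilistic
#' boolean model in which every gene is expressed (state 1) with
#' probability \code{f} independently of everything else.
#'
#' @slot M integer, classes.
#' @slot p integer, genes.
#' @slot q integer, samples.
#' @slot markersPerClass integer, class-informative genes per class.
#' @slot effectSize numeric, marker mean shift in noise-sd units.
#' @slot noiseSigma positive numeric, per-gene noise sd.
#' @slot classProportions numeric simplex vector of length M.
#' @slot model character, "gaussian" or "boolean".
#' @slot f numeric in (0,1), expression probability (boolean model).
#' @slot seed integer.
#' @seealso [syntheticSpec()], [generateGaussianDataset()],
#'   [generateBooleanDataset()]
#' @export
setClass("SyntheticSpec",
  representation(M = "integer", p = "integer", q = "integer",
                 markersPerClass = "integer", effectSize = "numeric",
                 noiseSigma = "numeric", classProportions = "numeric",
                 model = "character", f = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@M < 3L) msg <- c(msg, "M must be >= 3")
  if (object@markersPerClass * object@M > object@p)
    msg <- c(msg, "markersPerClass * M must not exceed p")
  if (length(object@classProportions) != object@M ||
      abs(sum(object@classProportions) - 1) > 1e-8 ||
      any(object@classProportions <= 0))
    msg <- c(msg, "classProportions must be a length-M positive simplex vector")
  if (!object@model %in% c("gaussian", "boolean"))
    msg <- c(msg, "model must be 'gaussian' or 'boolean'")
  if (object@f < 0 || object@f > 1) msg <- c(msg, "f must lie in [0, 1]")
  if (object@noiseSigma <= 0) msg <- c(msg, "noiseSigma must be positive")
  if (length(msg)) msg else TRUE
})
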