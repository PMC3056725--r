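#' Specify a synthetic dataset
#'
#' @param M classes (>= 3).
#' @param p genes.
#' @param q samples.
#' @param markersPerClass class-exclusive marker genes per class
#'   (markers are disjoint across classes so ground-truth recall is
#'   unambiguous).
#' @param effectSize marker mean shift in units of \code{noiseSigma}.
#' @param noiseSigma per-gene noise standard deviation.
#' @param classProportions length-M simplex vector (default uniform).
#' @param model "gaussian" (real-valued, feeds the classifier pipeline)
#'   or "boolean" (Bernoulli gene states, validates the information
#'   bound's assumptions).
#' @param f expression probability for the boolean model.
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(M = 4, p = 1000, q = 100, markersPerClass = 10,
                          effectSize = 2, noiseSigma = 1,
                          classProportions = rep(1 / M, M),
                          model = c("gaussian", "boolean"), f = 0.5,
                          seed = 1) {
  model <- match.arg(model)
  new("SyntheticSpec", M = as.integer(M), p = as.integer(p),
      q = as.integer(q), markersPerClass = as.integer(markersPerClass),
      effectSize = as.numeric(effectSize), noiseSigma = as.numeric(noiseSigma),
      classProportions = as.numeric(classProportions), model = model,
      f = as.numeric(f), seed = as.integer(seed))
}

drawLabels <- function(M, q, proportions) {
  # deterministic per-class counts by largest remainder, every class
  # non-empty, then a random permutation of sample positions
  target <- proportions * q
  counts <- floor(target)
  counts <- pmax(counts, 1)
  while (sum(counts) > q) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  rem <- target - floor(target)
  while (sum(counts) < q) {
    i <- which.max(rem); counts[i] <- counts[i] + 1; rem[i] <- -1
  }
  sample(rep.int(seq_len(M), times = counts))
}

#' Generate Gaussian expression data with planted markers
#'
#' Background genes are i.i.d. Normal(0, sigma^2) in every sample; the
#' \code{markersPerClass} marker genes of class c have their mean shifted
#' by \code{+effectSize * noiseSigma} in the samples of class c only.
#' Labels are drawn according to \code{classProportions} with every class
#' non-empty. Deterministic under the spec's seed.
#'
#' @param spec a [SyntheticSpec-class] with \code{model = "gaussian"}.
#' @return list with \code{dataset} (a [GeneExpressionSet-class]) and
#'   \code{markers} (named list of marker gene ids per class).
#' @export
generateGaussianDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  withSeed(spec@seed, {
    M <- spec@M; p <- spec@p; q <- spec@q
    labels <- drawLabels(M, q, spec@classProportions)
    X <- matrix(rnorm(p * q, sd = spec@noiseSigma), nrow = p, ncol = q)
    geneIds <- paste0("g", seq_len(p))
    markers <- vector("list", M)
    names(markers) <- paste0("class", seq_len(M))
    shift <- spec@effectSize * spec@noiseSigma
    for (cl in seq_len(M)) {
      rows <- ((cl - 1L) * spec@markersPerClass + 1L):(cl * spec@markersPerClass)
      X[rows, labels == cl] <- X[rows, labels == cl] + shift
      markers[[cl]] <- geneIds[rows]
    }
    ds <- geneExpressionSet(X, paste0("class", labels), geneIds = geneIds,
                            provenance = sprintf("gaussian generator seed %d",
                                                 spec@seed))
    list(dataset = ds, markers = markers)
  })
}

#' Generate probabilistic boolean expression data
#'
#' Every entry is an independent Bernoulli(f) gene state (1 = expressed).
#' By the ergodic argument behind the gene budget, the per-sample
#' fraction of expressed genes concentrates on f as p grows, and the
#' empirical per-gene entropy approaches \eqn{H(f)} as q grows. Labels
#' carry no signal in this model; it validates the bound's assumptions,
#' not the classifiers.
#'
#' @param spec a [SyntheticSpec-class] with \code{model = "boolean"}.
#' @return a [GeneExpressionSet-class] of 0/1 values.
#' @export
generateBooleanDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@model != "boolean")
    stop("spec@model must be 'boolean'", call. = FALSE)
  withSeed(spec@seed, {
    labels <- drawLabels(spec@M, spec@q, spec@classProportions)
    X <- matrix(rbinom(spec@p * spec@q, 1L, spec@f),
                nrow = spec@p, ncol = spec@q)
    geneExpressionSet(X, paste0("class", labels),
                      provenance = sprintf("boolean generator seed %d f=%g",
                                           spec@seed, spec@f))
  })
}
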