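#' Stratified Monte Carlo train/test partitions
#'
#' Repeated stratified splits of the samples into a training and a test
#' part. Two modes are supported: a train fraction (\code{ratio}, default
#' 4:1) with per-class largest-remainder rounding, or an exact
#' \code{trainSize} (the benchmark convention of 45 training and 15 test
#' samples out of 60 corresponds to \code{trainSize = 45}). Every class
#' keeps at least one training sample; train and test are disjoint and
#' exhaustive. Deterministic under the seed.
#'
#' @param labels per-sample class labels (factor or vector).
#' @param count number of partitions (default 200).
#' @param ratio train fraction in (0, 1), used when \code{trainSize} is NULL.
#' @param trainSize exact number of training samples, overrides ratio.
#' @param seed integer RNG seed.
#' @return list of \code{count} lists with integer \code{train} and
#'   \code{test} sample indices.
#' @export
montecarloPartitions <- function(labels, count = 200, ratio = 4 / 5,
                                 trainSize = NULL, seed = 1) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop(sprintf("class '%s' has fewer than 2 samples; cannot partition",
                 names(counts)[which.min(counts)]), call. = FALSE)
  q <- length(labels)
  total <- if (is.null(trainSize)) round(q * ratio) else
    assertCount(trainSize, "trainSize", length(counts))
  if (total >= q) stop("training size must leave at least one test sample",
                       call. = FALSE)
  perClass <- allocateStratified(as.integer(counts), total)
  idxByClass <- split(seq_len(q), labels)
  withSeed(seed, {
    lapply(seq_len(count), function(i) {
      train <- unlist(lapply(seq_along(idxByClass), function(cl) {
        ids <- idxByClass[[cl]]
        ids[sample.int(length(ids), perClass[cl])]
      }), use.names = FALSE)
      train <- sort(train)
      list(train = train, test = setdiff(seq_len(q), train))
    })
  })
}

# Largest-remainder allocation of `total` training slots across classes,
# each class getting between 1 and (size - 0) slots, never the full class
# unless unavoidable.
allocateStratified <- function(counts, total) {
  q <- sum(counts)
  target <- counts * total / q
  t <- pmax(1L, floor(target))
  t <- pmin(t, counts)
  rem <- target - floor(target)
  while (sum(t) < total) {
    cand <- which(t < counts)
    i <- cand[which.max(rem[cand])]
    t[i] <- t[i] + 1L
    rem[i] <- -1
  }
  while (sum(t) > total) {
    cand <- which(t > 1L)
    i <- cand[which.min(rem[cand])]
    t[i] <- t[i] - 1L
    rem[i] <- 2
  }
  t
}

# Stratified k-fold assignment; every fold's training portion must contain
# all classes. Resamples up to `maxAttempts` before failing.
stratifiedFolds <- function(y, k = 10, seed = 1, maxAttempts = 20) {
  y <- as.integer(y)
  n <- length(y)
  k <- min(k, n)
  withSeed(seed, {
    for (a in seq_len(maxAttempts)) {
      fold <- integer(n)
      for (cl in unique(y)) {
        ids <- which(y == cl)
        ids <- ids[sample.int(length(ids))]
        fold[ids] <- 1L + (sample.int(k, 1L) + seq_along(ids) - 2L) %% k
      }
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[fold != f])) == length(unique(y)), logical(1)))
      if (ok) return(fold)
    }
    stop("could not build folds with every class present in each training portion",
         call. = FALSE)
  })
}

# Fit one binary column: standardize the selected genes with training
# statistics, fit a linear SVM at complexity C, record the decision-value
# orientation and the training margin scale (margins are standardized to
# unit variance on the training data before decoding).
fitBinarySvm <- function(Xtr, bitTr, C) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- scale(Xtr, center = ctr, scale = scl)
  yf <- factor(ifelse(bitTr == 1L, "b1", "b0"), levels = c("b1", "b0"))
  fit <- e1071::svm(Xs, yf, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  dv <- attr(predict(fit, Xs, decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1L], "b1")
  m <- as.numeric(dv[, 1L]) * if (flip) -1 else 1
  ms <- stats::sd(m)
  if (!is.finite(ms) || ms == 0) ms <- 1
  list(center = ctr, scale = scl, fit = fit, flip = flip, marginScale = ms)
}

scoreBinarySvm <- function(col, Xnew) {
  Xs <- scale(Xnew, center = col$center, scale = col$scale)
  dv <- attr(predict(col$fit, Xs, decision.values = TRUE), "decision.values")
  (as.numeric(dv[, 1L]) * if (col$flip) -1 else 1) / col$marginScale
}

# Decode a samples x n margin matrix (positive margin = bit 1) to class
# indices with the decoder matching the code kind.
decodeMargins <- function(code, margins, channel = channelModel(1),
                          iterations = 1) {
  if (code@kind == "LDPC") {
    apply(margins, 1L, function(m)
      softDecode(code, -m, channel = channel, iterations = iterations)$class)
  } else {
    apply(margins, 1L, function(m) as.integer(hingeDecode(code, m)))
  }
}

# Build the codebook for a given n: the OAA identity, or an LDPC code with
# k = ceiling(log2 M) information bits. One graph per n at a fixed derived
# seed; the graph is resampled (new derived seed) if no constant-column-free
# class assignment exists.
codeForN <- function(M, n, family, seed) {
  if (family == "OAA") {
    if (n != M) stop("OAA preselects n = M", call. = FALSE)
    return(oaaCode(M))
  }
  k <- as.integer(ceiling(log2(M)))
  err <- NULL
  for (t in 0:19) {
    s <- deriveSeed(seed, n * 100L + t)
    code <- tryCatch({
      g <- buildLdpcGraph(n, k, j = 3, seed = s)
      enumerateCodebook(g, M, seed = s)
    }, error = function(e) e)
    if (is(code, "CodeMatrix")) return(code)
    err <- code
  }
  stop("could not construct an LDPC codebook for n = ", n, ": ",
       conditionMessage(err), call. = FALSE)
}

# Inner stratified CV over a vector of gene counts at fixed code and C.
# The per-(fold, column) S2N ranking is computed once and shared across
# the g values. Returns the pooled multiclass error per g.
innerCvGrid <- function(X, y, code, gValues, C, folds = 10, seed = 1,
                        channel = channelModel(1)) {
  fold <- stratifiedFolds(y, k = folds, seed = seed)
  k <- max(fold)
  nG <- length(gValues)
  wrong <- numeric(nG)
  for (f in seq_len(k)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    margins <- replicate(nG, matrix(0, length(testIdx), code@n),
                         simplify = FALSE)
    for (j in seq_len(code@n)) {
      bits <- code@codewords[y, j]
      ranked <- rankGenes(s2nScores(X[, trainIdx, drop = FALSE],
                                    bits[trainIdx]))
      for (gi in seq_len(nG)) {
        genes <- selectTopGenes(ranked, gValues[gi])
        col <- fitBinarySvm(t(X[genes, trainIdx, drop = FALSE]),
                            bits[trainIdx], C)
        margins[[gi]][, j] <- scoreBinarySvm(
          col, t(X[genes, testIdx, drop = FALSE]))
      }
    }
    for (gi in seq_len(nG)) {
      pred <- decodeMargins(code, margins[[gi]], channel = channel)
      wrong[gi] <- wrong[gi] + sum(pred != y[testIdx])
    }
  }
  wrong / length(y)
}

#' Inner cross-validation error for one configuration
#'
#' Stratified 10-fold CV on the training set only: in each fold and for
#' each code column, genes are ranked by S2N on the fold-training split,
#' the top two-ended g genes are selected, features are standardized with
#' fold-training statistics, a linear SVM is fitted at complexity C, the
#' held-out samples are scored, and the margin vectors are decoded to
#' class predictions. Returns the pooled multiclass error fraction.
#'
#' @param train a [GeneExpressionSet-class] (training data only).
#' @param family "LDPC" or "OAA".
#' @param n number of binary classifiers (OAA forces n = M).
#' @param g even gene count per binary classifier (within the budget).
#' @param C SVM complexity.
#' @param folds number of CV folds (default 10).
#' @param seed integer RNG seed (folds, code construction).
#' @return the CV error rate in [0, 1].
#' @export
innerCvError <- function(train, family = c("LDPC", "OAA"), n, g, C = 1,
                         folds = 10, seed = 1) {
  family <- match.arg(family)
  M <- nClasses(train)
  cap <- geneCap(M, nGenes(train), n)
  if (g > cap)
    stop(sprintf("g = %d exceeds geneCap = %d at n = %d", g, cap, n),
         call. = FALSE)
  code <- codeForN(M, n, family, seed)
  innerCvGrid(exprsMatrix(train), as.integer(classLabels(train)), code,
              g, C, folds = folds, seed = seed)
}

# Pick the best row of an (n, Q, g, error) surface: minimal error, ties
# broken by the largest n, then the smallest Q.
pickBest <- function(surface) {
  best <- surface[surface$error <= min(surface$error) + 1e-15, , drop = FALSE]
  best <- best[best$n == max(best$n), , drop = FALSE]
  best[which.min(best$Q), , drop = FALSE]
}

#' Select the number of classifiers and the gene fraction by nested CV
#'
#' Evaluates the inner-CV error at C = 1 for every n in the exploration
#' range (for LDPC codes; OAA preselects n = M) and every gene count of
#' the budget-capped multi-scale Q grid, and returns the minimizing
#' (n, Q) pair. Among ties the largest n — equivalently the smallest
#' selected gene fraction — wins, then the smallest Q at that n.
#'
#' @param train a [GeneExpressionSet-class] (training data only).
#' @param family "LDPC" or "OAA".
#' @param eta n-range expansion factor (5, 10 or 15 in the protocol).
#' @param seed integer RNG seed.
#' @param folds inner CV folds.
#' @param qGrid optional numeric vector of gene fractions replacing the
#'   full 121-point grid (they are still budget-capped and mapped to even
#'   gene counts); use for reduced-scale runs.
#' @param C SVM complexity during the (n, Q) search (protocol: 1).
#' @return a [SelectionResult-class] carrying the chosen n, Q, g, the
#'   full inner-CV error surface and the seeds.
#' @export
selectNQ <- function(train, family = c("LDPC", "OAA"), eta = 10, seed = 1,
                     folds = 10, qGrid = NULL, C = 1) {
  family <- match.arg(family)
  M <- nClasses(train)
  p <- nGenes(train)
  nVals <- if (family == "OAA") M else {
    r <- nRange(M, eta)
    if (!r$feasible || !length(r$values))
      stop(sprintf("infeasible n range for M = %d, eta = %g", M, eta),
           call. = FALSE)
    r$values
  }
  X <- exprsMatrix(train)
  y <- as.integer(classLabels(train))
  surface <- NULL
  for (n in nVals) {
    Qcap <- min(1, qMax(M, p, n))
    grid <- tryCatch(buildQGrid(Qcap, p), error = function(e) NULL)
    if (is.null(grid)) next
    if (!is.null(qGrid)) {
      g <- pmax(2L, as.integer(2 * round(qGrid * p / 2)))
      keep <- qGrid <= Qcap & g <= floor(Qcap * p) & !duplicated(g)
      if (!any(keep)) next
      grid <- data.frame(Q = qGrid[keep], g = g[keep])
    }
    code <- codeForN(M, n, family, seed)
    errs <- innerCvGrid(X, y, code, grid$g, C, folds = folds,
                        seed = deriveSeed(seed, n))
    surface <- rbind(surface,
                     data.frame(n = n, Q = grid$Q, g = grid$g, error = errs))
  }
  if (is.null(surface))
    stop("empty (n, Q) grid: no feasible configuration under the budget",
         call. = FALSE)
  top <- pickBest(surface)
  out <- new("SelectionResult", family = family, n = as.integer(top$n),
             Q = top$Q, g = as.integer(top$g), surface = surface,
             eta = as.numeric(eta), seed = as.integer(seed))
  out@C <- as.numeric(C)   # named arg would partial-match new()'s Class
  validObject(out)
  out
}

# Two monotone ladder searches from C = 1 (factor 2 down, factor 2 up),
# each stopped after `patience` consecutive evaluations without improving
# on the best error seen so far. Returns the best C; ties prefer the C
# closest to 1, then the smaller C. `evalFn(C)` must return an error rate.
cLadderSearch <- function(evalFn, start = 1, factor = 2, patience = 3,
                          maxSteps = 20) {
  evals <- data.frame(C = start, error = evalFn(start))
  for (dirFactor in c(1 / factor, factor)) {
    bad <- 0L
    C <- start
    best <- min(evals$error)
    for (s in seq_len(maxSteps)) {
      C <- C * dirFactor
      e <- evalFn(C)
      evals <- rbind(evals, data.frame(C = C, error = e))
      if (e < best) { best <- e; bad <- 0L } else bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  cand <- evals[evals$error <= min(evals$error) + 1e-15, , drop = FALSE]
  cand <- cand[abs(log(cand$C)) <= min(abs(log(cand$C))) + 1e-12, , drop = FALSE]
  min(cand$C)
}

#' Optimize the SVM complexity C at the chosen (n, Q)
#'
#' With (n, Q) fixed at the pair selected at C = 1, C is decreased and
#' increased on a factor-2 ladder until the inner-CV error shows no
#' improvement for three consecutive steps in each direction. Ties return
#' the C closest to 1, then the smaller value.
#'
#' @param train a [GeneExpressionSet-class] (training data only).
#' @param selection a [SelectionResult-class] from [selectNQ()].
#' @param folds inner CV folds.
#' @param seed integer RNG seed.
#' @return the best complexity C (numeric).
#' @export
optimizeC <- function(train, selection, folds = 10, seed = selection@seed) {
  stopifnot(is(selection, "SelectionResult"))
  X <- exprsMatrix(train)
  y <- as.integer(classLabels(train))
  code <- codeForN(nClasses(train), selection@n, selection@family,
                   selection@seed)
  cLadderSearch(function(C)
    innerCvGrid(X, y, code, selection@g, C, folds = folds,
                seed = deriveSeed(seed, selection@n)))
}

#' Fit the final output-coded classifier on the full training set
#'
#' Builds the codebook for the selected n (the same seeded code used
#' during selection), ranks genes by S2N per column on the full training
#' set, selects the chosen two-ended g genes, and fits the linear SVMs at
#' the chosen C. The test set is never touched here: each original test
#' set is used exactly once, by [predict()].
#'
#' @param train a [GeneExpressionSet-class] (training data only).
#' @param selection a [SelectionResult-class].
#' @param C SVM complexity (default the selection's C; pass the result of
#'   [optimizeC()] to use the tuned value).
#' @param sigma AWGN channel noise sd for soft decoding (default 1;
#'   margins are standardized to unit training variance).
#' @return an [EcocModel-class].
#' @export
fitFinal <- function(train, selection, C = selection@C, sigma = 1) {
  stopifnot(is(selection, "SelectionResult"))
  M <- nClasses(train)
  p <- nGenes(train)
  code <- codeForN(M, selection@n, selection@family, selection@seed)
  X <- exprsMatrix(train)
  y <- as.integer(classLabels(train))
  cap <- geneCap(M, p, selection@n)
  if (selection@g > cap)
    stop("selected g exceeds the gene budget", call. = FALSE)
  columns <- lapply(seq_len(code@n), function(j) {
    bits <- code@codewords[y, j]
    genes <- selectTopGenes(rankGenes(s2nScores(X, bits)), selection@g)
    c(list(genes = genes), fitBinarySvm(t(X[genes, , drop = FALSE]), bits, C))
  })
  model <- new("EcocModel", code = code, columns = columns,
               channel = channelModel(sigma),
               decoding = if (code@kind == "LDPC") "sum-product" else "hinge",
               classLevels = levels(classLabels(train)), geneIds = rownames(X),
               gMax = cap, seed = selection@seed)
  model@C <- as.numeric(C)  # named arg would partial-match new()'s Class
  validObject(model)
  model
}

#' Predict classes with a trained output-coded model
#'
#' For each code column the sample is restricted to that column's
#' selected genes, standardized with the stored training statistics and
#' scored by the fitted SVM; the assembled margin vector is decoded by
#' single-iteration sum-product (LDPC) or hinge-loss (OAA) decoding.
#'
#' @param object an [EcocModel-class].
#' @param newdata a [GeneExpressionSet-class] or a genes x samples matrix
#'   covering the model's gene universe.
#' @param ... ignored.
#' @return factor of predicted class labels, one per sample.
#' @export
setMethod("predict", "EcocModel", function(object, newdata, ...) {
  X <- if (is(newdata, "GeneExpressionSet")) exprsMatrix(newdata)
       else as.matrix(newdata)
  missing <- setdiff(object@geneIds, rownames(X))
  if (length(missing))
    stop(sprintf("newdata lacks %d of the model's genes (e.g. %s)",
                 length(missing), missing[1L]), call. = FALSE)
  margins <- vapply(object@columns, function(col)
    scoreBinarySvm(col, t(X[col$genes, , drop = FALSE])),
    numeric(ncol(X)))
  if (ncol(X) == 1L) margins <- matrix(margins, nrow = 1L)
  idx <- decodeMargins(object@code, margins, channel = object@channel)
  factor(object@classLevels[idx], levels = object@classLevels)
})
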