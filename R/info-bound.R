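#' Binary entropy in bits
#'
#' \eqn{H(f) = -f \log_2 f - (1-f)\log_2(1-f)}: the average information
#' content, in bits, of a gene that is expressed with probability f and
#' silent with probability 1 - f. Endpoints use the limit convention
#' \eqn{0 \log_2 0 = 0}.
#'
#' @param f numeric vector of probabilities in [0, 1].
#' @return numeric vector of entropies in [0, 1] bits.
#' @examples
#' binaryEntropy(0.5)   # 1 bit
#' binaryEntropy(c(0, 1))  # degenerate genes carry no information
#' @export
binaryEntropy <- function(f) {
  if (!is.numeric(f) || anyNA(f) || any(f < 0 | f > 1))
    stop("'f' must be a probability in [0, 1]", call. = FALSE)
  h <- numeric(length(f))
  inner <- f > 0 & f < 1
  fi <- f[inner]
  h[inner] <- -fi * log2(fi) - (1 - fi) * log2(1 - fi)
  h
}

checkBoundArgs <- function(M, p, n) {
  M <- assertCount(M, "M", 3L)
  p <- assertCount(p, "p", 2L)
  n <- assertCount(n, "n", 1L)
  list(M = M, p = p, n = n)
}

#' Maximum gene fraction per binary classifier
#'
#' The information budget: reducing an M-class problem over p genes to n
#' independent binary classifiers leaves \eqn{\log_2(M)/n} bits per
#' classifier, while each selected gene carries at most \eqn{H(f)} bits.
#' Under the ergodic estimate \eqn{f = 1/p} the selectable fraction is
#' bounded by \deqn{Q_{max} = \frac{\log_2 M}{p \, n \, H(1/p)}.}
#' A general expression probability can be supplied through \code{f}.
#'
#' @param M integer >= 3, number of classes.
#' @param p integer >= 2, number of genes.
#' @param n integer >= 1, number of binary classifiers.
#' @param f expression probability in (0, 1); default 1/p.
#' @return the maximal gene fraction (may exceed 1 for tiny p).
#' @examples
#' qMax(3, 4026, 11)   # Lymphoma-sized configuration
#' @export
qMax <- function(M, p, n, f = 1 / p) {
  a <- checkBoundArgs(M, p, n)
  if (f <= 0 || f >= 1) stop("'f' must lie in (0, 1)", call. = FALSE)
  log2(a$M) / (a$p * a$n * binaryEntropy(f))
}

#' Integer gene cap per binary classifier
#'
#' \eqn{g_{max} = \max(1, \lfloor p \, Q_{max} \rfloor)}: the largest
#' number of genes any one binary classifier may select. The floor is
#' applied only to the final count; degenerate configurations are clipped
#' to one gene so a classifier always has at least one input.
#'
#' @inheritParams qMax
#' @return integer gene cap in [1, p].
#' @examples
#' geneCap(3, 4026, 11)
#' @export
geneCap <- function(M, p, n, f = 1 / p) {
  a <- checkBoundArgs(M, p, n)
  g <- floor(a$p * qMax(a$M, a$p, a$n, f = f))
  as.integer(max(1, min(a$p, g)))
}

#' Fano lower bound on the misclassification probability
#'
#' When a class label y with entropy \code{Hy} bits is estimated through
#' features carrying \code{I} bits of mutual information about y, the
#' error probability obeys
#' \eqn{p_e \ge (H(y) - I - 1)/\log_2 M}, clamped below at 0.
#'
#' @param Hy entropy of the class variable in bits (>= 0).
#' @param I mutual information in bits (>= 0).
#' @param M number of classes (>= 2).
#' @return the lower bound on the error probability.
#' @examples
#' fanoLowerBound(log2(4), 0, 4)  # 0.5
#' @export
fanoLowerBound <- function(Hy, I, M) {
  if (Hy < 0 || I < 0) stop("'Hy' and 'I' must be non-negative", call. = FALSE)
  M <- assertCount(M, "M", 2L)
  max(0, (Hy - I - 1) / log2(M))
}

#' Exploration range for the number of binary classifiers
#'
#' n is explored from \eqn{n_{min} = \lceil \log_2 M \rceil + 2} up to
#' \eqn{n_{max} = \lceil \eta \log_2 M \rceil}. The value
#' \eqn{\lceil 15 \log_2 M\rceil + 1} is never generated: it would yield a
#' code able only to detect, not correct, binary errors.
#'
#' @param M integer >= 3, number of classes.
#' @param eta expansion factor >= 1 (the protocol uses 5, 10 or 15).
#' @return a list with \code{nMin}, \code{nMax}, the integer vector
#'   \code{values} (empty when infeasible) and the flag \code{feasible}.
#' @examples
#' nRange(4, 5)   # nMin 4, nMax 10
#' @export
nRange <- function(M, eta = 10) {
  M <- assertCount(M, "M", 3L)
  if (!is.numeric(eta) || length(eta) != 1L || eta < 1)
    stop("'eta' must be a single number >= 1", call. = FALSE)
  nMin <- as.integer(ceiling(log2(M)) + 2)
  nMax <- as.integer(ceiling(eta * log2(M)))
  feasible <- nMax >= nMin
  values <- if (feasible) seq.int(nMin, nMax) else integer(0)
  values <- values[values != as.integer(ceiling(15 * log2(M)) + 1)]
  list(nMin = nMin, nMax = nMax, values = values, feasible = feasible)
}

#' Assemble a gene budget
#'
#' Bundles all bound quantities for one (M, p, n, f) configuration into a
#' validated [GeneBudget-class] object.
#'
#' @inheritParams qMax
#' @return a [GeneBudget-class].
#' @examples
#' geneBudget(4, 1000, 9)
#' @export
geneBudget <- function(M, p, n, f = 1 / p) {
  a <- checkBoundArgs(M, p, n)
  Qm <- qMax(a$M, a$p, a$n, f = f)
  new("GeneBudget", M = a$M, p = a$p, n = a$n, f = f,
      Hf = binaryEntropy(f), HM = log2(a$M), Hb = log2(a$M) / a$n,
      Qmax = Qm, gMax = geneCap(a$M, a$p, a$n, f = f))
}

#' Budget curve over a range of n
#'
#' Tabulates \eqn{Q_{max}} and the gene cap against n, for plotting the
#' hyperbolic decay of the per-classifier budget.
#'
#' @inheritParams qMax
#' @param nValues integer vector of classifier counts.
#' @return data.frame with columns n, Qmax, gMax.
#' @export
budgetCurve <- function(M, p, nValues) {
  data.frame(n = as.integer(nValues),
             Qmax = vapply(nValues, function(n) qMax(M, p, n), numeric(1)),
             gMax = vapply(nValues, function(n) geneCap(M, p, n), integer(1)))
}
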