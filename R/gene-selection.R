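#' Signal-to-noise (S2N) scores for one binary task
#'
#' Per-gene class separation, \deqn{S2N(j) = \frac{\mu_j^+ - \mu_j^-}
#' {\sigma_j^+ + \sigma_j^-},} with per-class means and population
#' standard deviations (divide by the class size) computed on the current
#' binary training split. A small epsilon stabilizes the denominator when
#' both class variances vanish. Scores are antisymmetric under a label
#' swap.
#'
#' @param X numeric matrix, genes x samples.
#' @param y binary labels, one per sample: logical, or coercible to
#'   \code{{0,1}}/\code{{-1,+1}} (TRUE/1/+1 marks the positive class).
#' @param eps denominator stabilizer, default 1e-9.
#' @return numeric vector of one score per gene (named by rownames).
#' @examples
#' X <- rbind(gA = c(2, 4, 0, 2))
#' s2nScores(X, c(TRUE, TRUE, FALSE, FALSE))  # (3-1)/(1+1) = 1
#' @export
s2nScores <- function(X, y, eps = 1e-9) {
  X <- as.matrix(X)
  pos <- binaryAsLogical(y)
  if (length(pos) != ncol(X))
    stop("one label per sample is required", call. = FALSE)
  if (!any(pos) || all(pos))
    stop("both classes must be present in the binary task", call. = FALSE)
  popStats <- function(M) {
    mu <- rowMeans(M)
    list(mu = mu, sd = sqrt(rowMeans((M - mu)^2)))
  }
  a <- popStats(X[, pos, drop = FALSE])
  b <- popStats(X[, !pos, drop = FALSE])
  (a$mu - b$mu) / (a$sd + b$sd + eps)
}

binaryAsLogical <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  u <- sort(unique(y))
  if (all(u %in% c(0, 1))) return(y == 1)
  if (all(u %in% c(-1, 1))) return(y == 1)
  stop("binary labels must be logical, {0,1} or {-1,+1}", call. = FALSE)
}

#' Rank genes by decreasing S2N score
#'
#' Ties keep the original gene order (stable sort), so rankings are
#' deterministic.
#'
#' @param scores named numeric vector as returned by [s2nScores()].
#' @return a [RankedGeneList-class].
#' @export
rankGenes <- function(scores) {
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("g", seq_along(scores))
  ord <- order(-scores)  # stable: ties by original index
  new("RankedGeneList", ids = ids[ord], scores = unname(scores[ord]))
}

#' Two-ended top-g gene selection
#'
#' Most discriminative genes under the S2N metric are the first g/2 and
#' the last g/2 genes of the ranked list: large positive scores separate
#' the positive class upward, large negative scores downward.
#'
#' @param ranked a [RankedGeneList-class].
#' @param g even gene count, 2 <= g <= p.
#' @return character vector of exactly g gene ids.
#' @examples
#' r <- rankGenes(c(a = 5, b = 4, c = 3, d = 2, e = 1))
#' selectTopGenes(r, 4)  # a, b, d, e
#' @export
selectTopGenes <- function(ranked, g) {
  stopifnot(is(ranked, "RankedGeneList"))
  p <- length(ranked@ids)
  g <- assertCount(g, "g", 2L)
  if (g %% 2L != 0L) stop("'g' must be even (g/2 genes from each end)",
                          call. = FALSE)
  if (g > p) stop(sprintf("g = %d exceeds the %d available genes", g, p),
                  call. = FALSE)
  half <- g %/% 2L
  c(ranked@ids[seq_len(half)], ranked@ids[seq.int(p - half + 1L, p)])
}

#' Multi-scale Q grid under a budget cap
#'
#' The gene-fraction dimension is quantized on a base-10 logarithmic
#' scale with anchors 0.001, 0.01, 0.1, 1; the first two logarithmic
#' segments are split into 10 equal linear parts each and the last into
#' 100, giving 121 distinct fractions before capping. Fractions above
#' \code{Qcap} are dropped, and each retained Q is mapped to an even gene
#' count \code{g = round(Q * p)} (nearest even, at least 2), deduplicated
#' and capped at \code{floor(Qcap * p)}.
#'
#' @param Qcap budget cap in (0, 1], typically [qMax()] of the
#'   configuration.
#' @param p number of genes.
#' @return data.frame with columns \code{Q} (strictly increasing) and
#'   \code{g} (even, distinct, within the cap).
#' @export
buildQGrid <- function(Qcap, p) {
  if (Qcap <= 0 || Qcap > 1) stop("'Qcap' must lie in (0, 1]", call. = FALSE)
  p <- assertCount(p, "p", 2L)
  qs <- unique(c(seq(0.001, 0.01, length.out = 11L),
                 seq(0.01, 0.1, length.out = 11L),
                 seq(0.1, 1, length.out = 101L)))
  qs <- qs[qs <= Qcap]
  gCap <- floor(Qcap * p)
  if (!length(qs) || gCap < 2L)
    stop("empty Q grid after capping; use a smaller n or more genes",
         call. = FALSE)
  g <- 2 * round(qs * p / 2)          # nearest even (round-half-to-even on Q*p/2)
  g <- pmax(2L, as.integer(g))
  keep <- g <= gCap & !duplicated(g)
  if (!any(keep))
    stop("empty Q grid after capping; use a smaller n or more genes",
         call. = FALSE)
  data.frame(Q = qs[keep], g = g[keep])
}

#' Budget-checked gene selection for one binary task
#'
#' Composes [s2nScores()], [rankGenes()] and [selectTopGenes()], refusing
#' any request beyond the configuration's gene cap.
#'
#' @inheritParams s2nScores
#' @param budget a [GeneBudget-class].
#' @param g even gene count, g <= \code{budget@gMax}.
#' @return character vector of selected gene ids (length g).
#' @export
boundedSelection <- function(X, y, budget, g) {
  stopifnot(is(budget, "GeneBudget"))
  g <- assertCount(g, "g", 2L)
  if (g > budget@gMax)
    stop(sprintf("g = %d exceeds the gene budget gMax = %d", g, budget@gMax),
         call. = FALSE)
  selectTopGenes(rankGenes(s2nScores(X, y)), g)
}
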