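#' Salton's cosine coefficient between two gene sets
#'
#' \eqn{|A \cap B| / \sqrt{|A| |B|}}: the cosine similarity of the sets'
#' indicator vectors. Symmetric, 1 for identical sets, 0 for disjoint
#' ones. Empty sets are an error — an empty selection signals an
#' upstream bug, not zero similarity.
#'
#' @param A,B character (or atomic) vectors treated as sets.
#' @return similarity in [0, 1].
#' @examples
#' saltonCoefficient(c("a", "b", "c"), c("b", "c", "d"))  # 2/3
#' @export
saltonCoefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B))
    stop("Salton coefficient is undefined for empty sets", call. = FALSE)
  length(intersect(A, B)) / sqrt(length(A) * length(B))
}

#' Mean gene-selection stability across partitions
#'
#' All \eqn{P(P-1)/2} pairwise Salton coefficients between the
#' per-partition selected-gene sets, and their mean: 200 partitions give
#' 19900 pairwise measurements.
#'
#' @param sets list of >= 2 non-empty gene-id vectors.
#' @return a [StabilityReport-class].
#' @export
meanStability <- function(sets) {
  P <- length(sets)
  if (P < 2L) stop("need at least two gene sets", call. = FALSE)
  sets <- lapply(sets, unique)
  pairs <- utils::combn(P, 2L)
  coefs <- apply(pairs, 2L, function(ij)
    saltonCoefficient(sets[[ij[1L]]], sets[[ij[2L]]]))
  new("StabilityReport", sets = sets, coefficients = as.numeric(coefs),
      mean = mean(coefs), pairs = as.integer(P * (P - 1L) / 2L))
}

#' Kolmogorov-Smirnov statistics on the pooled sample points
#'
#' Empirical CDFs of the two samples evaluated at the pooled sorted
#' values give \eqn{D^+ = \max_i\{G_v(z_i) - F_u(z_i)\}},
#' \eqn{D^- = \max_i\{F_u(z_i) - G_v(z_i)\}} and the two-sided
#' \eqn{D = \max(D^+, D^-)}.
#'
#' @param F_sample,G_sample non-empty numeric vectors.
#' @return named numeric vector with D, Dplus, Dminus.
#' @export
ksStatistics <- function(F_sample, G_sample) {
  if (!length(F_sample) || !length(G_sample))
    stop("both samples must be non-empty", call. = FALSE)
  z <- sort(unique(c(F_sample, G_sample)))
  Fu <- vapply(z, function(t) mean(F_sample <= t), numeric(1))
  Gv <- vapply(z, function(t) mean(G_sample <= t), numeric(1))
  Dplus <- max(0, max(Gv - Fu))
  Dminus <- max(0, max(Fu - Gv))
  c(D = max(Dplus, Dminus), Dplus = Dplus, Dminus = Dminus)
}

# Asymptotic two-sided Kolmogorov tail: 2 * sum (-1)^{k-1} exp(-2 k^2 t^2).
kolmogorovTail <- function(t, terms = 100) {
  if (t <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic comes from [ksStatistics()]; p-values use the standard
#' asymptotic approximations (the Kolmogorov series for the two-sided
#' test, \eqn{\exp(-2 n_{e} D^2)} with \eqn{n_e = uv/(u+v)} for the
#' one-sided ones), matching the reference \code{ks.test} semantics:
#' \code{"F-right"} (alias \code{"greater"}) tests whether the CDF of
#' \code{F_sample} lies above that of \code{G_sample} (F stochastically
#' smaller) and uses \eqn{D^-}; \code{"F-left"} (alias \code{"less"})
#' the mirror image, using \eqn{D^+}.
#'
#' @inheritParams ksStatistics
#' @param alternative "two-sided", "F-left"/"less", or "F-right"/"greater".
#' @return list with \code{statistic} and \code{p}.
#' @export
ksTest <- function(F_sample, G_sample,
                   alternative = c("two-sided", "F-left", "F-right",
                                   "less", "greater")) {
  alternative <- match.arg(alternative)
  st <- ksStatistics(F_sample, G_sample)
  u <- length(F_sample); v <- length(G_sample)
  nEff <- u * v / (u + v)
  if (alternative == "two-sided") {
    list(statistic = unname(st["D"]),
         p = kolmogorovTail(sqrt(nEff) * st[["D"]]))
  } else if (alternative %in% c("F-left", "less")) {
    list(statistic = unname(st["Dplus"]),
         p = min(1, exp(-2 * nEff * st[["Dplus"]]^2)))
  } else {
    list(statistic = unname(st["Dminus"]),
         p = min(1, exp(-2 * nEff * st[["Dminus"]]^2)))
  }
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Thin wrapper over the rank-sum test with midrank tie handling,
#' \code{"less"} meaning the distribution of \code{F_sample} is shifted
#' left of \code{G_sample}.
#'
#' @inheritParams ksStatistics
#' @param alternative "two-sided", "less" or "greater".
#' @return list with the U \code{statistic} and the \code{p}-value.
#' @export
mwTest <- function(F_sample, G_sample,
                   alternative = c("two-sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  alt <- sub("two-sided", "two.sided", alternative)
  wt <- suppressWarnings(stats::wilcox.test(F_sample, G_sample,
                                            alternative = alt,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

shapiroSafe <- function(x) {
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' First-order stochastic dominance analysis of two metric distributions
#'
#' Shapiro-Wilk normality p-values are reported for both samples (they
#' justify, but never replace, the nonparametric route). The verdict then
#' follows the paired KS decision rule: the two-sided test must reject at
#' \code{alpha}, and exactly one of the two one-sided tests must reject —
#' the non-rejected direction is the dominant one. One-sided Mann-Whitney
#' p-values are reported for concordance. \code{direction} says whether
#' larger metric values are better (stability) or worse (error, gene
#' counts), fixing which group the verdict names as dominant.
#'
#' @inheritParams ksStatistics
#' @param alpha significance level (default 0.05).
#' @param direction "higher-is-better" or "lower-is-better".
#' @param metric metric name recorded in the report.
#' @return a [ComparisonReport-class]; its verdict is one of
#'   "F dominates", "G dominates", "ambiguous", "no difference".
#' @export
dominanceAnalysis <- function(F_sample, G_sample, alpha = 0.05,
                              direction = c("higher-is-better",
                                            "lower-is-better"),
                              metric = "metric") {
  direction <- match.arg(direction)
  st <- ksStatistics(F_sample, G_sample)
  pTwo <- ksTest(F_sample, G_sample, "two-sided")$p
  pGreater <- ksTest(F_sample, G_sample, "F-right")$p
  pLess <- ksTest(F_sample, G_sample, "F-left")$p
  fSmaller <- pGreater < alpha && pLess >= alpha
  gSmaller <- pLess < alpha && pGreater >= alpha
  verdict <- if (pTwo >= alpha) "no difference"
  else if (direction == "higher-is-better") {
    if (gSmaller) "F dominates" else if (fSmaller) "G dominates" else "ambiguous"
  } else {
    if (fSmaller) "F dominates" else if (gSmaller) "G dominates" else "ambiguous"
  }
  new("ComparisonReport", metric = metric,
      F = as.numeric(F_sample), G = as.numeric(G_sample),
      shapiroPF = shapiroSafe(F_sample), shapiroPG = shapiroSafe(G_sample),
      D = st[["D"]], Dplus = st[["Dplus"]], Dminus = st[["Dminus"]],
      pTwo = pTwo, pGreater = pGreater, pLess = pLess,
      pMwLess = mwTest(F_sample, G_sample, "less")$p,
      pMwGreater = mwTest(F_sample, G_sample, "greater")$p,
      alpha = alpha, direction = direction, verdict = verdict)
}

#' @describeIn dominanceAnalysis extract the verdict string.
#' @param report a [ComparisonReport-class].
#' @export
verdict <- function(report) report@verdict

#' Compare two classifier families over a common partition scheme
#'
#' Builds one [ComparisonReport-class] per metric — test error and
#' overall gene count (lower is better), gene-selection stability
#' (higher is better) — from the per-partition results of two families
#' run on the same partitions, plus a flat table of the key numbers.
#'
#' @param runF,runG results of [runExperiment()] for the two families.
#' @param alpha significance level.
#' @return list with \code{reports} (named list of ComparisonReport) and
#'   \code{table} (data.frame, one row per metric: medians, KS/MW
#'   p-values and verdicts).
#' @export
summarizeRuns <- function(runF, runG, alpha = 0.05) {
  if (nrow(runF$perPartition) != nrow(runG$perPartition))
    stop("both families must be evaluated on the same number of partitions",
         call. = FALSE)
  reports <- list(
    testError = dominanceAnalysis(runF$perPartition$testError,
                                  runG$perPartition$testError,
                                  alpha, "lower-is-better", "testError"),
    totalGenes = dominanceAnalysis(runF$perPartition$totalGenes,
                                   runG$perPartition$totalGenes,
                                   alpha, "lower-is-better", "totalGenes"),
    stability = dominanceAnalysis(runF$stability@coefficients,
                                  runG$stability@coefficients,
                                  alpha, "higher-is-better", "stability"))
  table <- do.call(rbind, lapply(reports, function(r)
    data.frame(metric = r@metric,
               medianF = stats::median(r@F), medianG = stats::median(r@G),
               D = r@D, pTwoSided = r@pTwo,
               pOneSidedFLeft = r@pLess, pOneSidedFRight = r@pGreater,
               pMwLess = r@pMwLess, pMwGreater = r@pMwGreater,
               verdict = r@verdict, annotation = "")))
  rownames(table) <- NULL
  list(reports = reports, table = table)
}
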