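test_that("Salton coefficient matches the cosine of indicator vectors", {
  expect_identical(saltonCoefficient(letters[1:3], letters[1:3]), 1)
  expect_identical(saltonCoefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(saltonCoefficient(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  # inner-product / norm formula on random sets
  set.seed(14)
  universe <- paste0("g", 1:40)
  for (t in 1:30) {
    A <- sample(universe, sample(1:20, 1))
    B <- sample(universe, sample(1:20, 1))
    ia <- universe %in% A; ib <- universe %in% B
    expect_equal(saltonCoefficient(A, B),
                 sum(ia * ib) / sqrt(sum(ia) * sum(ib)), tolerance = 1e-12)
  }
  expect_error(saltonCoefficient(character(0), "a"), "empty")
})

test_that("mean stability averages all unordered pairs", {
  sets <- list(c("a", "b"), c("b", "c"), c("a", "b"), c("d"))
  rep <- meanStability(sets)
  expect_identical(rep@pairs, 6L)
  # nested-loop oracle
  acc <- c()
  for (i in 1:3) for (l in (i + 1):4)
    acc <- c(acc, naiveSalton(sets[[i]], sets[[l]]))
  expect_equal(rep@mean, mean(acc), tolerance = 1e-12)
  expect_identical(meanStability(list(1:3, 1:3, 1:3))@mean, 1)
  expect_error(meanStability(list(1:3)), "at least two")
})

test_that("KS statistics match the pooled-ECDF definition", {
  expect_identical(unname(ksStatistics(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  expect_identical(ksStatistics(c(1, 2), c(3, 4))[["D"]], 1)
  set.seed(15)
  for (t in 1:30) {
    f <- rnorm(10); g <- rnorm(12, mean = runif(1, -1, 1))
    expect_equal(ksStatistics(f, g), naiveKs(f, g), tolerance = 1e-12)
    st <- ksStatistics(f, g)
    expect_true(st[["Dplus"]] <= st[["D"]] && st[["Dminus"]] <= st[["D"]])
    expect_true(st[["D"]] <= 1 && st[["D"]] >= 0)
    expect_identical(st[["D"]], max(st[["Dplus"]], st[["Dminus"]]))
  }
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(16)
  for (t in 1:20) {
    f <- rnorm(30); g <- rnorm(25, mean = runif(1, -0.5, 0.5))
    two <- ksTest(f, g, "two-sided")
    ref <- suppressWarnings(stats::ks.test(f, g, exact = FALSE))
    expect_equal(two$statistic, unname(ref$statistic), tolerance = 1e-12)
    # ks.test's C code truncates the asymptotic series at tol 1e-6 and can
    # deviate ~3e-5 near t = 1; agreement is checked at that coarseness and
    # exactly against the independent theta-function form below
    expect_equal(two$p, ref$p.value, tolerance = 1e-4)
    nEff <- length(f) * length(g) / (length(f) + length(g))
    tstat <- sqrt(nEff) * two$statistic
    theta <- 1 - (sqrt(2 * pi) / tstat) *
      sum(exp(-((2 * (1:20) - 1)^2 * pi^2) / (8 * tstat^2)))
    expect_equal(two$p, theta, tolerance = 1e-10)
    gt <- ksTest(f, g, "F-right")
    refG <- suppressWarnings(stats::ks.test(f, g, alternative = "greater",
                                            exact = FALSE))
    expect_equal(gt$statistic, unname(refG$statistic), tolerance = 1e-12)
    expect_equal(gt$p, refG$p.value, tolerance = 1e-6)
    lt <- ksTest(f, g, "F-left")
    refL <- suppressWarnings(stats::ks.test(f, g, alternative = "less",
                                            exact = FALSE))
    expect_equal(lt$statistic, unname(refL$statistic), tolerance = 1e-12)
    expect_equal(lt$p, refL$p.value, tolerance = 1e-6)
  }
  # identical large samples: no evidence under any alternative
  x <- rnorm(200)
  expect_gt(ksTest(x, x, "two-sided")$p, 0.999)
  expect_gt(ksTest(x, x, "F-left")$p, 0.999)
  # p is non-increasing in D at fixed sizes
  d <- seq(0.05, 0.9, by = 0.05)
  ps <- vapply(d, function(D) sparseECOC:::kolmogorovTail(sqrt(15) * D),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("Mann-Whitney U equals the pair count and is rank-invariant", {
  got <- mwTest(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(got$statistic), naiveU(c(1, 2, 3), c(4, 5, 6)))
  expect_identical(unname(got$statistic), 0)
  expect_identical(unname(mwTest(c(4, 5, 6), c(1, 2, 3))$statistic), 9)
  set.seed(17)
  f <- rexp(20); g <- rexp(25)
  expect_identical(unname(mwTest(f, g)$statistic), naiveU(f, g))
  # common monotone transform leaves the rank-based p unchanged
  expect_equal(mwTest(f, g, "less")$p, mwTest(log(f), log(g), "less")$p,
               tolerance = 1e-12)
  x <- rnorm(50)
  expect_gt(mwTest(x, x)$p, 0.99)
})

test_that("dominance analysis applies the paired KS decision rule", {
  set.seed(18)
  G <- rnorm(50)
  F_hi <- G + 10
  rep <- dominanceAnalysis(F_hi, G, direction = "higher-is-better")
  expect_identical(verdict(rep), "F dominates")
  expect_identical(verdict(dominanceAnalysis(F_hi, G, direction = "lower-is-better")),
                   "G dominates")   # mirror image
  expect_identical(verdict(dominanceAnalysis(G, G + 0)), "no difference")
  expect_identical(rep@D, max(rep@Dplus, rep@Dminus))
  expect_true(all(c(rep@pTwo, rep@pLess, rep@pGreater,
                    rep@pMwLess, rep@pMwGreater) >= 0))
  expect_output(show(rep), "verdict")
})

test_that("run summaries assemble one consistent report per metric", {
  set.seed(19)
  fake <- function(err) list(
    perPartition = data.frame(testError = err,
                              totalGenes = sample(20:60, 30, replace = TRUE)),
    stability = meanStability(replicate(12, sample(paste0("g", 1:30), 10),
                                        simplify = FALSE)))
  runF <- fake(rbeta(30, 2, 8)); runG <- fake(rbeta(30, 4, 8))
  out <- summarizeRuns(runF, runG)
  expect_named(out$reports, c("testError", "totalGenes", "stability"))
  expect_identical(nrow(out$table), 3L)
  for (r in out$reports) expect_identical(r@D, max(r@Dplus, r@Dminus))
  # reproducible bit for bit
  out2 <- summarizeRuns(runF, runG)
  expect_identical(out$table, out2$table)
  runShort <- fake(rbeta(10, 2, 8))
  runShort$perPartition <- runShort$perPartition[1:10, ]
  expect_error(summarizeRuns(runF, runShort), "same number")
})
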