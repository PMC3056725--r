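test_that("Monte Carlo partitions are stratified, disjoint and exhaustive", {
  labels <- rep(c("A", "B", "C"), times = c(30, 18, 12))
  parts <- montecarloPartitions(labels, count = 25, trainSize = 45, seed = 3)
  for (p in parts) {
    expect_length(p$train, 45L)   # the 45:15 convention on 60 samples
    expect_length(p$test, 15L)
    expect_identical(sort(c(p$train, p$test)), 1:60)
    expect_length(intersect(p$train, p$test), 0L)
    # every class keeps training representation
    expect_identical(sort(unique(labels[p$train])), c("A", "B", "C"))
  }
  # ratio mode: 4:1 on 60 samples gives 48/12
  parts <- montecarloPartitions(labels, count = 5, ratio = 4 / 5, seed = 3)
  expect_true(all(vapply(parts, function(p) length(p$train), integer(1)) == 48L))
  # determinism
  expect_identical(montecarloPartitions(labels, count = 5, seed = 7),
                   montecarloPartitions(labels, count = 5, seed = 7))
  expect_error(montecarloPartitions(c("A", "A", "B", "C", "C"), count = 2),
               "fewer than 2")
})

test_that("inner CV error vanishes on separable data and is permutation-invariant", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 30)
  err <- innerCvError(ds, "OAA", n = 3, g = 4, seed = 2)
  expect_identical(err, 0)
  # shuffling gene rows does not change the error
  set.seed(6)
  perm <- sample(nGenes(ds))
  ds2 <- geneExpressionSet(exprsMatrix(ds)[perm, ], classLabels(ds))
  expect_identical(innerCvError(ds2, "OAA", n = 3, g = 4, seed = 2), err)
  expect_error(innerCvError(ds, "OAA", n = 3, g = 10000, seed = 2), "geneCap")
})

test_that("inner CV error under permuted labels approaches the null rate", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 60)
  set.seed(9)
  null_ds <- geneExpressionSet(exprsMatrix(ds), sample(as.character(classLabels(ds))))
  err <- innerCvError(null_ds, "OAA", n = 3, g = 4, seed = 2)
  # balanced 3 classes: null error 2/3; binomial 99.9% band around it at q=60
  expect_gt(err, 2 / 3 - 3.3 * sqrt(2 / 9 / 60))
})

test_that("grid minimization picks the tied pair with the largest n, then smallest Q", {
  surface <- data.frame(
    n = c(4, 4, 5, 6, 6),
    Q = c(0.01, 0.05, 0.02, 0.01, 0.03),
    g = c(10, 50, 20, 10, 30),
    error = c(0.10, 0.08, 0.08, 0.08, 0.12))
  top <- sparseECOC:::pickBest(surface)
  expect_identical(top$n, 6)      # tie at 0.08 across n = 4, 5, 6
  expect_identical(top$Q, 0.01)
  # unique minimum wins regardless of n
  surface$error[1] <- 0.01
  expect_identical(sparseECOC:::pickBest(surface)$n, 4)
})

test_that("the C ladder search honours its stopping and tie rules", {
  # flat profile: C = 1 is retained
  calls <- new.env(); calls$C <- numeric(0)
  flat <- function(C) { calls$C <- c(calls$C, C); 0.2 }
  expect_identical(cl <- sparseECOC:::cLadderSearch(flat), 1)
  # three consecutive non-improvements per direction: 1 + 3 + 3 evaluations
  expect_length(calls$C, 7L)
  # injected profile with a unique minimum at C = 0.5
  prof <- function(C) abs(log2(C) + 1) / 10 + 0.05
  expect_identical(sparseECOC:::cLadderSearch(prof), 0.5)
  # ties prefer the C closest to 1, then the smaller C
  tied <- function(C) if (C %in% c(0.5, 1, 2)) 0.1 else 0.3
  expect_identical(sparseECOC:::cLadderSearch(tied), 1)
})

test_that("selectNQ preselects n = M for OAA and attains the surface minimum", {
  ds <- makeSeparableDataset(M = 4, p = 80, q = 40)
  sel <- selectNQ(ds, "OAA", seed = 4, qGrid = c(0.05, 0.1, 0.25))
  expect_identical(sel@n, 4L)
  expect_identical(min(sel@surface$error),
                   sel@surface$error[sel@surface$g == sel@g &
                                     sel@surface$n == sel@n])
  expect_s4_class(sel, "SelectionResult")
  expect_identical(sel@C, 1)
})

test_that("model selection never reads the held-out test samples", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 36, seed = 10)
  parts <- montecarloPartitions(classLabels(ds), count = 1, seed = 1)
  train <- ds[, parts[[1]]$train]
  sel1 <- selectNQ(train, "OAA", seed = 3, qGrid = c(0.02, 0.05))
  # corrupt every test-set value; the selection must be bit-identical
  X <- exprsMatrix(ds)
  X[, parts[[1]]$test] <- 1e6
  ds2 <- geneExpressionSet(X, classLabels(ds))
  sel2 <- selectNQ(ds2[, parts[[1]]$train], "OAA", seed = 3, qGrid = c(0.02, 0.05))
  expect_identical(sel1@surface, sel2@surface)
  expect_identical(c(sel1@n, sel1@g), c(sel2@n, sel2@g))
})

test_that("final models respect the budget, refit identically, and separate training data", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 30)
  sel <- selectNQ(ds, "LDPC", eta = 5, seed = 6, qGrid = c(0.02, 0.05))
  m1 <- fitFinal(ds, sel)
  m2 <- fitFinal(ds, sel)
  expect_true(all(vapply(m1@columns, function(cl) length(cl$genes), integer(1))
                  <= m1@gMax))
  expect_identical(lapply(m1@columns, `[[`, "genes"),
                   lapply(m2@columns, `[[`, "genes"))
  expect_identical(m1@code@codewords, m2@code@codewords)
  expect_identical(predict(m1, ds), predict(m2, ds))
  # zero training error on separable data
  expect_identical(as.character(predict(m1, ds)),
                   as.character(classLabels(ds)))
})

test_that("batch and single-sample prediction agree elementwise", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 30)
  sel <- selectNQ(ds, "OAA", seed = 6, qGrid = c(0.02, 0.05))
  model <- fitFinal(ds, sel)
  batch <- predict(model, ds)
  X <- exprsMatrix(ds)
  single <- vapply(seq_len(ncol(X)), function(s)
    as.character(predict(model, X[, s, drop = FALSE])), character(1))
  expect_identical(as.character(batch), single)
  expect_error(predict(model, X[1:10, ]), "lacks")
})

test_that("both families reach zero test error on separable data", {
  ds <- makeSeparableDataset(M = 3, p = 60, q = 36, seed = 20)
  parts <- montecarloPartitions(classLabels(ds), count = 1, seed = 2)
  train <- ds[, parts[[1]]$train]; test <- ds[, parts[[1]]$test]
  for (fam in c("OAA", "LDPC")) {
    sel <- selectNQ(train, fam, eta = 5, seed = 3, qGrid = c(0.02, 0.05))
    model <- fitFinal(train, sel)
    expect_identical(mean(predict(model, test) != classLabels(test)), 0,
                     info = fam)
  }
})
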