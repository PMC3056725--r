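test_that("graph construction is deterministic and honours its invariants", {
  g1 <- buildLdpcGraph(6, 3, j = 2, seed = 1)
  g2 <- buildLdpcGraph(6, 3, j = 2, seed = 1)
  expect_identical(g1@edges, g2@edges)
  expect_identical(g1@m, 3L)
  g3 <- buildLdpcGraph(6, 3, j = 2, seed = 99)
  expect_false(identical(g1@edges, g3@edges))
  for (s in 1:10) {
    g <- buildLdpcGraph(sample(6:14, 1), sample(2:4, 1), j = 3, seed = s)
    H <- parityMatrix(g)
    expect_true(all(rowSums(H) >= 2))           # check degree >= 2
    expect_true(all(colSums(H) >= 1))           # message degree >= 1
    expect_false(anyDuplicated(g@edges) > 0)
    # full GF(2) rank via an independent elimination oracle
    expect_identical(naiveGf2Rank(H), g@m)
  }
})

test_that("codebooks are the parity-check null space restricted to M rows", {
  for (s in 1:10) {
    n <- sample(6:10, 1); k <- sample(2:3, 1)
    g <- buildLdpcGraph(n, k, j = 2, seed = s)
    H <- parityMatrix(g)
    nullsp <- bruteNullspace(H)
    expect_identical(nrow(nullsp), as.integer(2^k))
    M <- sample(3:(2^k), 1)
    code <- enumerateCodebook(g, M, seed = s)
    key <- function(m) apply(m, 1, paste, collapse = "")
    expect_true(all(key(code@codewords) %in% key(nullsp)))
    expect_false(anyDuplicated(key(code@codewords)) > 0)
    expect_true(all(apply(code@codewords, 2, function(cl) length(unique(cl))) > 1))
  }
  # the all-zero vector satisfies every parity check of any graph
  g <- buildLdpcGraph(9, 3, seed = 5)
  expect_true(all(parityMatrix(g) %*% rep(0, 9) %% 2 == 0))
  # capacity error when 2^k < M
  expect_error(enumerateCodebook(buildLdpcGraph(6, 2, seed = 1), 5), "capacity")
})

test_that("codeword linearity: XOR of codebook rows satisfies all checks", {
  g <- buildLdpcGraph(10, 3, seed = 7)
  code <- enumerateCodebook(g, 6, seed = 7)
  H <- parityMatrix(g)
  cw <- code@codewords
  for (i in 1:5) for (l in (i + 1):6) {
    x <- (cw[i, ] + cw[l, ]) %% 2
    expect_true(all((H %*% x) %% 2 == 0))
  }
})

test_that("the OAA code is the identity with one positive class per column", {
  code <- oaaCode(3)
  expect_identical(code@codewords, diag(1L, 3))
  expect_identical(code@kind, "OAA")
  expect_true(all(colSums(oaaCode(7)@codewords) == 1))
  expect_error(oaaCode(2))
})

test_that("label encoding looks up code rows and rejects unknown labels", {
  code <- oaaCode(3)
  expect_identical(encodeLabels(code, 1L), matrix(c(1L, 0L, 0L), 1))
  lab <- c(2L, 1L, 3L, 2L)
  enc <- encodeLabels(code, lab)
  expect_identical(enc, code@codewords[lab, ])
  expect_error(encodeLabels(code, 4L), "1..M")
  # factors are taken by level index
  expect_identical(encodeLabels(code, factor(c("a", "c"), levels = c("a", "b", "c"))),
                   code@codewords[c(1L, 3L), ])
})

test_that("noiseless soft decoding returns the transmitted class", {
  for (s in c(2, 5, 9)) {
    g <- buildLdpcGraph(8, 3, seed = s)
    code <- enumerateCodebook(g, 5, seed = s)
    for (cl in 1:5) {
      r <- 1 - 2 * code@codewords[cl, ]  # exact symbol image
      for (sigma in c(0.3, 1, 3))
        expect_identical(softDecode(code, r, channelModel(sigma))$class, cl)
    }
  }
})

test_that("decoding with zero iterations equals brute-force nearest-codeword", {
  set.seed(31)
  g <- buildLdpcGraph(10, 3, seed = 11)
  code <- enumerateCodebook(g, 6, seed = 11)
  s <- 1 - 2 * code@codewords
  for (t in 1:100) {
    r <- rnorm(10)
    got <- softDecode(code, r, iterations = 0)$class
    # min Euclidean distance to +-1 codewords == max correlation
    brute <- which.min(apply(s, 1, function(v) sum((r - v)^2)))
    expect_identical(got, brute)
  }
})

test_that("single-iteration decoding corrects single sign flips at distance >= 3", {
  found <- 0
  for (s in 1:60) {
    g <- buildLdpcGraph(10, 3, seed = s)
    code <- enumerateCodebook(g, 5, seed = s)
    if (minimumDistance(code) < 3) next
    found <- found + 1
    for (cl in 1:5) {
      r0 <- 1 - 2 * code@codewords[cl, ]
      for (i in 1:10) {
        r <- r0; r[i] <- -r[i]
        expect_identical(softDecode(code, r)$class, cl)
      }
    }
    if (found >= 5) break
  }
  expect_gte(found, 3)
})

test_that("soft decoding rejects mismatched inputs and OAA codes", {
  g <- buildLdpcGraph(8, 3, seed = 1)
  code <- enumerateCodebook(g, 4, seed = 1)
  expect_error(softDecode(code, rnorm(5)), "length")
  expect_error(softDecode(oaaCode(3), rnorm(3)), "hingeDecode")
})

test_that("hinge decoding minimizes the accumulated hinge loss", {
  code <- oaaCode(3)
  d <- hingeDecode(code, c(2, -1, -1))
  expect_identical(as.integer(d), 1L)
  # hand evaluation of sum_j max(0, 1 - (2b-1) m_j) per class
  expect_equal(attr(d, "losses"), c(0, 5, 5))
  # all-zero margins: every class ties, lowest index wins
  expect_identical(as.integer(hingeDecode(code, c(0, 0, 0))), 1L)
  # appending a column whose hinge contribution is identical for every
  # class (zero margin contributes max(0, 1 - 0) = 1 to each row) never
  # changes the decision
  set.seed(8)
  aug <- new("CodeMatrix", M = 3L, n = 4L,
             codewords = cbind(code@codewords, code@codewords[, 1L]),
             kind = "OAA", graph = NULL, seed = 0L)
  for (t in 1:20) {
    m <- rnorm(3)
    expect_identical(as.integer(hingeDecode(aug, c(m, 0))),
                     as.integer(hingeDecode(code, m)))
  }
  expect_error(hingeDecode(code, c(1, 2)), "length")
})

test_that("codebooks round-trip through the plain-text format", {
  g <- buildLdpcGraph(9, 3, seed = 13)
  code <- enumerateCodebook(g, 6, seed = 13)
  path <- tempfile(fileext = ".txt")
  writeCodeMatrix(code, path)
  back <- readCodeMatrix(path)
  expect_identical(back@codewords, code@codewords)
  expect_identical(back@kind, code@kind)
  expect_identical(parityMatrix(back@graph), parityMatrix(code@graph))
  # decoding behaviour preserved
  r <- 1 - 2 * code@codewords[3, ]
  expect_identical(softDecode(back, r)$class, softDecode(code, r)$class)
  oPath <- tempfile(fileext = ".txt")
  writeCodeMatrix(oaaCode(4), oPath)
  expect_identical(readCodeMatrix(oPath)@codewords, oaaCode(4)@codewords)
})
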