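# Independent brute-force oracles; deliberately naive and written without
# reference to the package internals they check.

# per-gene loop S2N with population standard deviations
naiveS2N <- function(X, pos, eps = 1e-9) {
  out <- numeric(nrow(X))
  for (j in seq_len(nrow(X))) {
    a <- X[j, pos]; b <- X[j, !pos]
    sdp <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
    out[j] <- (mean(a) - mean(b)) / (sdp(a) + sdp(b) + eps)
  }
  out
}

# double loop over pooled points for the KS statistics
naiveKs <- function(f, g) {
  z <- sort(c(f, g))
  dplus <- dminus <- 0
  for (t in z) {
    Fu <- sum(f <= t) / length(f)
    Gv <- sum(g <= t) / length(g)
    dplus <- max(dplus, Gv - Fu)
    dminus <- max(dminus, Fu - Gv)
  }
  c(D = max(dplus, dminus), Dplus = dplus, Dminus = dminus)
}

# pair-count Mann-Whitney U (ties counted half)
naiveU <- function(f, g) {
  u <- 0
  for (a in f) for (b in g) u <- u + (a > b) + 0.5 * (a == b)
  u
}

naiveSalton <- function(A, B)
  length(intersect(A, B)) / sqrt(length(unique(A)) * length(unique(B)))

# boolean-arithmetic GF(2) rank, structured differently from the package's
# elimination (column-sweep over logical vectors)
naiveGf2Rank <- function(H) {
  rows <- lapply(seq_len(nrow(H)), function(i) as.logical(H[i, ] %% 2))
  rank <- 0L
  for (col in seq_len(ncol(H))) {
    piv <- which(vapply(rows, function(r) r[col], logical(1)))
    piv <- piv[piv > rank]
    if (!length(piv)) next
    rank <- rank + 1L
    rows[c(rank, piv[1])] <- rows[c(piv[1], rank)]
    for (i in seq_along(rows))
      if (i != rank && rows[[i]][col]) rows[[i]] <- xor(rows[[i]], rows[[rank]])
  }
  rank
}

# all binary vectors of length n satisfying H c = 0 (mod 2)
bruteNullspace <- function(H) {
  n <- ncol(H)
  all2 <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(all2) <- NULL
  all2[rowSums((all2 %*% t(H)) %% 2) == 0, , drop = FALSE]
}

# small separable fixture: M classes with far-apart class means
makeSeparableDataset <- function(M = 3, p = 60, q = 30, seed = 42) {
  set.seed(seed)
  labels <- rep(seq_len(M), length.out = q)
  X <- matrix(rnorm(p * q, sd = 0.1), p, q)
  for (cl in seq_len(M)) X[cl, labels == cl] <- X[cl, labels == cl] + 10
  geneExpressionSet(X, paste0("class", labels))
}
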