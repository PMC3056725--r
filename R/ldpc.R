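#' Build a sparse random parity-check (Tanner) graph
#'
#' Constructs the bipartite graph of an LDPC code with \code{n} message
#' nodes and \code{m = n - k} check nodes. Each message node receives a
#' near-regular column degree (target \code{j}, reduced to \code{m - 1}
#' when \code{m <= j}, never below 2) and check-node degrees are balanced
#' to within one edge. Construction is rejection-based under the given
#' seed: duplicate edges are never accepted, 4-cycles are avoided while
#' possible within a bounded number of attempts (then the 4-cycle
#' constraint is relaxed), and the parity matrix is required to reach full
#' GF(2) row rank \code{m} so that exactly \code{k} information bits are
#' protected.
#'
#' @param n code length (message nodes), n > k.
#' @param k information bits to protect, k >= 1.
#' @param j target message-node degree (default 3).
#' @param seed integer RNG seed; the same seed reproduces the same graph.
#' @param maxAttempts resampling budget per phase.
#' @return a [ParityCheckGraph-class].
#' @examples
#' g <- buildLdpcGraph(6, 3, j = 2, seed = 1)
#' parityMatrix(g)
#' @export
buildLdpcGraph <- function(n, k, j = 3, seed = 1, maxAttempts = 100) {
  n <- assertCount(n, "n", 2L)
  k <- assertCount(k, "k", 1L)
  if (n <= k) stop("need n > k", call. = FALSE)
  m <- n - k
  j <- assertCount(j, "j", 2L)
  jEff <- if (m >= 3L) max(2L, min(j, m - 1L)) else m
  if (jEff < 2L) stop("infeasible (n, k, j): fewer than 2 checks available",
                      call. = FALSE)
  withSeed(seed, {
    attempt <- function(avoid4) {
      adj <- vector("list", n)
      if (m == 2L) {
        # two checks: every-column-degree-2 is structurally rank 1, so
        # columns mix the patterns {1}, {2}, {1,2}
        for (i in seq_len(n))
          adj[[i]] <- switch(sample.int(3L, 1L), 1L, 2L, c(1L, 2L))
      } else {
        nEdges <- jEff * n
        base <- nEdges %/% m
        caps <- rep.int(base, m)
        extra <- nEdges %% m
        if (extra > 0) caps[sample.int(m, extra)] <- base + 1L
        for (i in sample.int(n)) {
          avail <- which(caps > 0L)
          if (length(avail) < jEff) return(NULL)
          pick <- if (length(avail) == jEff) avail else
            sample(avail, jEff, prob = caps[avail])
          caps[pick] <- caps[pick] - 1L
          adj[[i]] <- pick
        }
      }
      edges <- cbind(check = unlist(adj),
                     message = rep(seq_len(n), times = lengths(adj)))
      if (any(tabulate(edges[, 1L], nbins = m) < 2L)) return(NULL)
      H <- matrix(0L, m, n)
      H[edges] <- 1L
      no4 <- function(A) {
        ov <- tcrossprod(A)
        diag(ov) <- 0L
        !any(ov >= 2L)
      }
      if (avoid4 && !no4(H)) return(NULL)
      # repair: rank-deficient parity matrices (unavoidable when every
      # column degree is even) have dependent rows resampled wholesale;
      # likewise any matrix whose code forces a coordinate constant (a
      # degenerate binary task no class assignment could repair)
      healthy <- function(A) {
        gf2Rank(A) == m && !any(colSums(gf2NullBasis(A)) == 0L)
      }
      firstDependentRow <- function(A) {
        r <- 0L
        for (i in seq_len(nrow(A))) {
          ri <- gf2Rank(A[seq_len(i), , drop = FALSE])
          if (ri == r) return(i)
          r <- ri
        }
        0L
      }
      tries <- 0L
      while (!healthy(H) && tries < 12L * m) {
        tries <- tries + 1L
        bad <- firstDependentRow(H)
        if (bad == 0L) bad <- sample.int(m, 1L)  # forced coordinate: perturb
        deg <- sum(H[bad, ])
        H2 <- H
        H2[bad, ] <- 0L
        H2[bad, sample.int(n, deg)] <- 1L
        if (any(colSums(H2) == 0L)) next
        if (avoid4 && !no4(H2)) next
        if (gf2Rank(H2) < gf2Rank(H)) next
        H <- H2
      }
      if (!healthy(H)) return(NULL)
      ed <- which(H == 1L, arr.ind = TRUE, useNames = FALSE)
      cbind(check = ed[, 1L], message = ed[, 2L])
    }
    edges <- NULL
    for (phase in c(TRUE, FALSE)) {
      for (a in seq_len(maxAttempts)) {
        edges <- attempt(phase)
        if (!is.null(edges)) break
      }
      if (!is.null(edges)) break
    }
    if (is.null(edges))
      stop(sprintf(
        "could not build a full-rank parity graph for n=%d, k=%d, j=%d",
        n, k, jEff), call. = FALSE)
    new("ParityCheckGraph", n = n, m = as.integer(m), j = jEff,
        edges = edges, seed = as.integer(seed))
  })
}

#' Parity matrix of a Tanner graph
#'
#' @param graph a [ParityCheckGraph-class].
#' @return the m x n binary parity-check matrix.
#' @export
parityMatrix <- function(graph) {
  stopifnot(is(graph, "ParityCheckGraph"))
  H <- matrix(0L, graph@m, graph@n)
  H[graph@edges] <- 1L
  H
}

#' Derive the class codebook of an LDPC graph
#'
#' Computes a GF(2) null-space basis of the parity matrix (the code's
#' \code{k = n - m} generator rows) and assigns the M class labels to M
#' distinct codewords. The first assignment maps classes to messages
#' 0..M-1 in natural binary order; if the resulting M rows leave some
#' column constant (a degenerate binary split that no classifier could
#' learn), message assignments are resampled under the seed for a bounded
#' number of attempts.
#'
#' @param graph a [ParityCheckGraph-class].
#' @param M number of classes; requires \code{2^k >= M}.
#' @param seed integer RNG seed for assignment resampling.
#' @param maxAttempts resampling budget.
#' @return a [CodeMatrix-class] of kind "LDPC".
#' @examples
#' g <- buildLdpcGraph(6, 3, j = 2, seed = 1)
#' enumerateCodebook(g, M = 4, seed = 1)
#' @export
enumerateCodebook <- function(graph, M, seed = 1, maxAttempts = 100) {
  stopifnot(is(graph, "ParityCheckGraph"))
  M <- assertCount(M, "M", 2L)
  k <- graph@n - graph@m
  if (2^k < M)
    stop(sprintf("code capacity 2^%d < M = %d classes", k, M), call. = FALSE)
  basis <- gf2NullBasis(parityMatrix(graph))
  msgToCodeword <- function(msgs) {
    bits <- vapply(seq_len(k), function(b) (msgs %/% 2^(b - 1)) %% 2, numeric(M))
    if (M == 1L) bits <- matrix(bits, nrow = 1L)
    (bits %*% basis) %% 2
  }
  ok <- function(cw) !any(apply(cw, 2L, function(col) all(col == col[1L])))
  withSeed(seed, {
    msgs <- 0:(M - 1)
    cw <- msgToCodeword(msgs)
    a <- 0L
    while (!ok(cw)) {
      a <- a + 1L
      if (a > maxAttempts)
        stop("no class-to-codeword assignment without a constant column",
             call. = FALSE)
      msgs <- sample(0:(2^k - 1), M)
      cw <- msgToCodeword(msgs)
    }
    new("CodeMatrix", M = M, n = graph@n,
        codewords = matrix(as.integer(cw), M, graph@n),
        kind = "LDPC", graph = graph, seed = as.integer(seed))
  })
}

#' One-Against-All code
#'
#' The M x M identity codebook: column i discriminates class i (bit 1)
#' from all other classes (bit 0).
#'
#' @param M number of classes (>= 3).
#' @return a [CodeMatrix-class] of kind "OAA".
#' @examples
#' oaaCode(3)
#' @export
oaaCode <- function(M) {
  M <- assertCount(M, "M", 3L)
  new("CodeMatrix", M = M, n = M, codewords = diag(1L, M),
      kind = "OAA", graph = NULL, seed = 0L)
}

#' Encode class labels as code rows
#'
#' @param code a [CodeMatrix-class].
#' @param labels integer class indices in 1..M (or a factor, taken by level).
#' @return a samples x n binary matrix; row s is the codeword of label s.
#' @export
encodeLabels <- function(code, labels) {
  stopifnot(is(code, "CodeMatrix"))
  if (is.factor(labels)) labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L | labels > code@M))
    stop("labels must be class indices in 1..M", call. = FALSE)
  code@codewords[labels, , drop = FALSE]
}

#' Minimum Hamming distance between class codewords
#'
#' @param code a [CodeMatrix-class].
#' @return the smallest pairwise Hamming distance among the M rows.
#' @export
minimumDistance <- function(code) {
  cw <- code@codewords
  d <- code@n
  for (i in seq_len(code@M - 1L))
    for (l in (i + 1L):code@M)
      d <- min(d, sum(cw[i, ] != cw[l, ]))
  as.integer(d)
}

# Bit-to-symbol convention, fixed project-wide: bit b -> (-1)^b,
# so bit 0 -> +1 and bit 1 -> -1, and positive LLRs favour bit 0.
bitsToSymbols <- function(bits) 1 - 2 * bits

#' Soft sum-product decoding of binary-classifier outputs
#'
#' Decodes one received vector of real-valued classifier scores
#' (channel-symbol domain: positive means bit 0 was likely sent) to a
#' class index. Per-coordinate log-likelihood ratios are initialized from
#' the AWGN model, \eqn{LLR_i = 2 r_i / \sigma^2}; then exactly
#' \code{iterations} full rounds of sum-product message passing (check
#' update followed by variable update) on the code's Tanner graph produce
#' posterior bit beliefs. The returned class maximizes the correlation of
#' its (+/-1)-mapped codeword with the posterior LLRs; ties break to the
#' lowest class index. With \code{iterations = 0} the decision reduces to
#' nearest-codeword decoding on the raw LLRs.
#'
#' @param code a [CodeMatrix-class] of kind "LDPC".
#' @param received numeric vector of length n (channel-symbol scores).
#' @param channel a [ChannelModel-class].
#' @param iterations number of full message-passing rounds (default 1,
#'   the protocol's single decoding loop).
#' @return a list with \code{class} (integer index) and \code{posterior}
#'   (numeric, per-bit posterior LLRs; positive favours bit 0).
#' @export
softDecode <- function(code, received, channel = channelModel(1), iterations = 1) {
  stopifnot(is(code, "CodeMatrix"))
  if (code@kind != "LDPC")
    stop("softDecode requires an LDPC code; use hingeDecode for OAA",
         call. = FALSE)
  if (length(received) != code@n)
    stop(sprintf("received vector has length %d, expected n = %d",
                 length(received), code@n), call. = FALSE)
  graph <- code@graph
  lambda <- 2 * received / channel@sigma^2
  edges <- graph@edges
  nE <- nrow(edges)
  v2c <- lambda[edges[, "message"]]
  c2v <- numeric(nE)
  iterations <- assertCount(iterations, "iterations", 0L)
  checkOf <- edges[, "check"]; msgOf <- edges[, "message"]
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      # check update: extrinsic tanh-product per edge
      t <- tanh(pmin(pmax(v2c / 2, -30), 30))
      for (e in seq_len(nE)) {
        others <- which(checkOf == checkOf[e])
        others <- others[others != e]
        prod_t <- prod(t[others])
        prod_t <- min(max(prod_t, -1 + 1e-15), 1 - 1e-15)
        c2v[e] <- 2 * atanh(prod_t)
      }
      # variable update: channel LLR plus extrinsic check messages
      tot <- lambda
      for (e in seq_len(nE)) tot[msgOf[e]] <- tot[msgOf[e]] + c2v[e]
      v2c <- tot[msgOf] - c2v
    }
    posterior <- lambda
    for (e in seq_len(nE)) posterior[msgOf[e]] <- posterior[msgOf[e]] + c2v[e]
  } else {
    posterior <- lambda
  }
  corr <- as.numeric(bitsToSymbols(code@codewords) %*% posterior)
  list(class = which.max(corr), posterior = posterior)
}

#' Hinge-loss decoding of margin vectors
#'
#' Maps code bits b to symbols 2b - 1 (so a positive margin favours
#' bit 1) and returns the class minimizing the accumulated hinge loss
#' \eqn{\sum_j \max(0, 1 - (2 b_{rj} - 1) m_j)}; ties break to the lowest
#' class index. This is the decoder used for One-Against-All models.
#'
#' @param code a [CodeMatrix-class] (any kind; primary use OAA).
#' @param margins numeric vector of n real-valued SVM decision values.
#' @return integer class index, with the per-class losses attached as the
#'   \code{"losses"} attribute.
#' @examples
#' hingeDecode(oaaCode(3), c(2, -1, -1))  # class 1
#' @export
hingeDecode <- function(code, margins) {
  stopifnot(is(code, "CodeMatrix"))
  if (length(margins) != code@n)
    stop(sprintf("margin vector has length %d, expected n = %d",
                 length(margins), code@n), call. = FALSE)
  s <- 2 * code@codewords - 1
  marg <- matrix(margins, code@M, code@n, byrow = TRUE)
  h <- 1 - s * marg
  h[h < 0] <- 0
  losses <- rowSums(h)
  structure(which.min(losses), losses = losses)
}

#' Write or read a codebook as plain text
#'
#' The format is line-oriented: `#`-prefixed `key=value` headers (M, n,
#' kind, seed, and for LDPC codes the graph geometry and edge list),
#' followed by one 0/1 character row per class.
#'
#' @param code a [CodeMatrix-class].
#' @param path file path.
#' @return \code{writeCodeMatrix} returns \code{path} invisibly;
#'   \code{readCodeMatrix} returns the reconstructed [CodeMatrix-class].
#' @export
writeCodeMatrix <- function(code, path) {
  stopifnot(is(code, "CodeMatrix"))
  hdr <- c(sprintf("# M=%d", code@M), sprintf("# n=%d", code@n),
           sprintf("# kind=%s", code@kind), sprintf("# seed=%d", code@seed))
  if (code@kind == "LDPC") {
    g <- code@graph
    hdr <- c(hdr,
             sprintf("# graph=%d,%d,%d,%d", g@n, g@m, g@j, g@seed),
             sprintf("# edges=%s",
                     paste(g@edges[, 1L], g@edges[, 2L], sep = ":",
                           collapse = ",")))
  }
  rows <- apply(code@codewords, 1L, paste, collapse = "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeCodeMatrix
#' @export
readCodeMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  getv <- function(key) {
    hit <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^# %s=", key), "", hit[1L])
  }
  M <- as.integer(getv("M")); n <- as.integer(getv("n"))
  kind <- getv("kind"); seed <- as.integer(getv("seed"))
  cw <- t(vapply(body, function(r) as.integer(strsplit(r, "")[[1L]]),
                 integer(n)))
  graph <- NULL
  if (identical(kind, "LDPC")) {
    geo <- as.integer(strsplit(getv("graph"), ",")[[1L]])
    ep <- strsplit(strsplit(getv("edges"), ",")[[1L]], ":")
    edges <- cbind(check = vapply(ep, function(x) as.integer(x[1L]), integer(1)),
                   message = vapply(ep, function(x) as.integer(x[2L]), integer(1)))
    graph <- new("ParityCheckGraph", n = geo[1L], m = geo[2L], j = geo[3L],
                 edges = edges, seed = geo[4L])
  }
  new("CodeMatrix", M = M, n = n,
      codewords = matrix(as.integer(cw), M, n), kind = kind,
      graph = graph, seed = seed)
}
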