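# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream. seed = NULL runs in the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit signed-integer range.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# GF(2) row reduction. Returns the rank and, optionally, a basis of the
# null space (columns of the returned matrix are basis vectors).
gf2Eliminate <- function(H) {
  H <- H %% 2L
  m <- nrow(H); n <- ncol(H)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    pr <- which(H[row:m, col] == 1L)
    if (!length(pr)) next
    pr <- pr[1L] + row - 1L
    if (pr != row) H[c(row, pr), ] <- H[c(pr, row), ]
    hit <- which(H[, col] == 1L)
    hit <- hit[hit != row]
    if (length(hit))
      H[hit, ] <- (H[hit, , drop = FALSE] + rep(H[row, ], each = length(hit))) %% 2L
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(reduced = H, rank = length(pivots), pivots = pivots)
}

gf2Rank <- function(H) gf2Eliminate(H)$rank

# Null-space basis of H over GF(2): a k x n matrix whose rows span
# {c : H c = 0 (mod 2)}, k = n - rank(H).
gf2NullBasis <- function(H) {
  n <- ncol(H)
  el <- gf2Eliminate(H)
  R <- el$reduced; pivots <- el$pivots
  free <- setdiff(seq_len(n), pivots)
  basis <- matrix(0L, nrow = length(free), ncol = n)
  for (i in seq_along(free)) {
    v <- integer(n)
    v[free[i]] <- 1L
    # back-substitute pivot variables
    for (r in seq_along(pivots)) {
      pc <- pivots[r]
      v[pc] <- sum(R[r, ] * v) %% 2L  # R[r, pc] v[pc] currently 0
    }
    basis[i, ] <- v
  }
  basis
}
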