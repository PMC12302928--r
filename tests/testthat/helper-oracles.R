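# Independent oracles used across the suite. Each re-derives its result
# from first principles (loops, enumeration, closed forms) and shares no
# code with the implementation it checks.

# single-component PLS1 by explicit NIPALS on an already centered/scaled
# matrix and centered response
pls1Oracle <- function(Xc, yc) {
  w <- as.numeric(t(Xc) %*% yc)
  w <- w / sqrt(sum(w * w))
  t <- as.numeric(Xc %*% w)
  p <- as.numeric(t(Xc) %*% t) / sum(t * t)
  c <- sum(yc * t) / sum(t * t)
  r2y <- 1 - sum((yc - c * t)^2) / sum(yc^2)
  list(w = w, t = t, p = p, c = c, r2y = r2y)
}

# independent centering/scaling (column loops, no sweep)
scaleOracle <- function(m, scale = TRUE) {
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- m[, j] - mean(m[, j])
    if (scale) out[, j] <- out[, j] / sd(m[, j])
  }
  out
}

# Benjamini-Hochberg by the literal step-up definition:
# adj_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, in input order
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Spearman rho as rank-then-Pearson, mid-ranks for ties, explicit sums
spearmanOracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# upper-tail hypergeometric probability by enumerating every possible
# draw of n items from a universe of N with K marked
hyperEnumOracle <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the marked ones
  mean(hits >= k)
}

# complete-linkage agglomeration from scratch on a distance matrix:
# returns merge heights (sorted) and the cophenetic distance matrix
completeLinkOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(heights = sort(heights), cophenetic = coph)
}

# brute-force three-set region counts by per-element membership tests
vennOracle <- function(a, b, c) {
  u <- unique(c(a, b, c))
  pat <- sapply(u, function(e)
    paste0(as.integer(e %in% a), as.integer(e %in% b),
           as.integer(e %in% c)))
  counts <- table(factor(pat, levels = c("100", "010", "001", "110",
                                         "101", "011", "111")))
  as.integer(counts)
}
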