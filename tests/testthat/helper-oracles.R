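# Independent brute-force oracles used to validate the pipeline operations.

# Exact two-sided Mann-Whitney p by enumerating all rank assignments.
mw_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  combos <- utils::combn(n + m, n)
  u_null <- apply(combos, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Two-sided Fisher p as the sum of hypergeometric probabilities no larger
# than the observed table's.
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(as, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Weighted Newman modularity of a partition, straight from the formula.
modularity_enum <- function(edges, weights, membership, resolution = 1) {
  m2 <- 2 * sum(weights)
  n <- max(edges)
  strength <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    strength[edges[e, 1]] <- strength[edges[e, 1]] + weights[e]
    strength[edges[e, 2]] <- strength[edges[e, 2]] + weights[e]
  }
  q <- 0
  for (e in seq_len(nrow(edges))) {
    if (membership[edges[e, 1]] == membership[edges[e, 2]]) {
      q <- q + 2 * weights[e] / m2
    }
  }
  for (com in unique(membership)) {
    s <- sum(strength[membership == com])
    q <- q - resolution * (s / m2)^2
  }
  q
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, next_max) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return()
    }
    for (g in seq_len(next_max + 1L)) {
      rec(c(memb, g), max(next_max, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# Brute-force k nearest neighbors by full distance matrix.
knn_brute <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  t(apply(D, 1, function(d) order(d)[seq_len(k)]))
}

# Naive O(n^2)-per-merge average-linkage heights.
avg_linkage_heights <- function(X) {
  groups <- as.list(seq_len(nrow(X)))
  D <- as.matrix(stats::dist(X))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        d <- mean(D[groups[[i]], groups[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# All label pairs whose minimum pixel-center distance is <= r.
neighbor_pairs_brute <- function(mask, r) {
  idx <- which(mask > 0)
  lab <- mask[idx]
  h <- nrow(mask)
  x <- (idx - 1L) %/% h
  y <- (idx - 1L) %% h
  labs <- sort(unique(lab))
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(length(labs) - 1L)) {
    for (j in (i + 1L):length(labs)) {
      xi <- x[lab == labs[i]]; yi <- y[lab == labs[i]]
      xj <- x[lab == labs[j]]; yj <- y[lab == labs[j]]
      d2 <- outer(xi, xj, function(a, b) (a - b)^2) +
        outer(yi, yj, function(a, b) (a - b)^2)
      if (min(d2) <= r^2) pairs <- rbind(pairs, c(labs[i], labs[j]))
    }
  }
  pairs
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
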