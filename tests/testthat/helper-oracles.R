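# Independent oracles used to cross-check package computations, written as
# direct brute-force implementations of the defining formulas.

# Quick constructor for abundance tables in tests.
make_abt <- function(values, kind = "scaled",
                     features = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  abundance_table(values, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Benjamini-Hochberg step-up by the definition: q_(i) = min_{j >= i}
# min(1, (n/j) p_(j)) over the ascending order statistics.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, (n / j) * ps[j])
    q[i] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# AUC as the literal count over all case-control pairs.
auc_bruteforce <- function(score, pos) {
  s1 <- score[pos]
  s0 <- score[!pos]
  wins <- 0
  for (a in s1) for (b in s0) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(s1) * length(s0))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the C(n, nx)
# rank assignments (no ties assumed). Uses the symmetry of the null U
# distribution: two-sided p = share of assignments at least as extreme.
wilcoxon_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  center <- nx * ny / 2
  # under the null every subset of nx ranks is equally likely; the rank-sum
  # of a chosen set of rank positions is just the sum of those positions
  combos <- utils::combn(nx + ny, nx)
  stats_all <- colSums(matrix(seq_len(nx + ny)[combos], nrow = nx))
  u_all <- stats_all - nx * (nx + 1) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Hypergeometric upper tail P(X >= k) from binomial coefficients.
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Hypergeometric upper tail by literal enumeration of all C(N, n) draws
# (feasible only for small N).
hyper_tail_enumeration <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # the set is taken as elements 1..K
  mean(hits >= k)
}

# Naive average-linkage agglomeration cut at `height` on distance matrix d:
# repeatedly merge the pair of clusters with the smallest average
# inter-cluster distance while that distance is <= height.
average_linkage_oracle <- function(d, height) {
  ids <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    if (best_d > height) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  member <- integer(nrow(d))
  for (g in seq_along(clusters)) member[clusters[[g]]] <- g
  stats::setNames(member, ids)
}

# Partition comparison helper: TRUE when two label vectors induce the same
# partition of their (shared) names.
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
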