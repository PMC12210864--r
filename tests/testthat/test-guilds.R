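test_that("Spearman matrix handles monotone, anti-monotone, tied, and flat rows", {
  x <- c(1, 2, 3, 4)
  tab <- make_abt(rbind(x = x, y2 = 2 * x, neg = -x, tied = c(1, 1, 2, 2)),
                  features = c("x", "y2", "neg", "tied"))
  sm <- spearman_matrix(tab)
  expect_equal(sm$rho["x", "y2"], 1)
  expect_equal(sm$rho["x", "neg"], -1)
  # average-rank Pearson for x vs (1,1,2,2): ranks (1.5,1.5,3.5,3.5)
  expect_equal(sm$rho["x", "tied"], 4 / sqrt(20), tolerance = 1e-12)
  # exact two-sided p for a perfect rank agreement at n = 4: 2/4!
  expect_equal(sm$p["x", "y2"], 2 / factorial(4), tolerance = 1e-12)

  tab2 <- make_abt(rbind(a = c(1, 3, 2, 5), flat = c(2, 2, 2, 2)),
                   features = c("a", "flat"))
  expect_warning(sm2 <- spearman_matrix(tab2), "constant")
  expect_equal(sm2$rho["a", "flat"], 0)
  expect_equal(sm2$p["a", "flat"], 1)

  # exact small-sample p agrees with cor.test
  set.seed(51)
  tab3 <- make_abt(matrix(rnorm(4 * 7), nrow = 4))
  sm3 <- spearman_matrix(tab3)
  ct <- cor.test(ab_values(tab3)[1, ], ab_values(tab3)[2, ],
                 method = "spearman", exact = TRUE)
  expect_equal(sm3$p[1, 2], ct$p.value)

  expect_error(spearman_matrix(make_abt(matrix(1:4, 2))), "3 samples")
})

test_that("tree cutting recovers planted blocks and degenerate cuts", {
  rho <- diag(4)
  rownames(rho) <- colnames(rho) <- c("A", "B", "C", "D")
  rho["A", "B"] <- rho["B", "A"] <- 0.9
  rho["C", "D"] <- rho["D", "C"] <- 0.9
  asg <- cluster_features(rho, height = 0.4)
  expect_equal(length(asg$guilds), 2)
  expect_equal(asg$assignment[["A"]], asg$assignment[["B"]])
  expect_equal(asg$assignment[["C"]], asg$assignment[["D"]])
  expect_false(asg$assignment[["A"]] == asg$assignment[["C"]])

  zero <- diag(4); rownames(zero) <- colnames(zero) <- c("A", "B", "C", "D")
  all_single <- cluster_features(zero, height = 0.4)
  expect_equal(length(all_single$guilds), 4)
  one_guild <- cluster_features(zero, height = 2)
  expect_equal(length(one_guild$guilds), 1)

  bad <- rho; bad["A", "B"] <- 0.1
  expect_error(cluster_features(bad, 0.4), "symmetric")
})

test_that("clustering is invariant to feature input order", {
  set.seed(52)
  tab <- make_abt(matrix(rnorm(20 * 15), nrow = 20))
  rho <- spearman_matrix(tab)$rho
  asg <- cluster_features(rho, height = 0.6)
  perm <- sample(nrow(rho))
  asg_p <- cluster_features(rho[perm, perm], height = 0.6)
  expect_identical(asg$assignment[sort(names(asg$assignment))],
                   asg_p$assignment[sort(names(asg_p$assignment))])
})

test_that("average-linkage partitions match an independent brute-force oracle", {
  set.seed(53)
  for (i in 1:20) {
    v <- matrix(rnorm(6 * 12), nrow = 6)
    rownames(v) <- sprintf("f%d", 1:6)
    colnames(v) <- sprintf("s%d", 1:12)
    rho <- spearman_matrix(abundance_table(v - min(v), "intensity"))$rho
    h <- runif(1, 0.2, 1.5)
    asg <- cluster_features(rho, height = h)
    oracle <- average_linkage_oracle(1 - rho, h)
    expect_true(same_partition(asg$assignment, oracle))
  }
})

test_that("guild abundances sum members and conserve per-sample totals", {
  set.seed(54)
  v <- matrix(abs(rnorm(5 * 4)), nrow = 5,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:4)))
  v <- sweep(v, 2, colSums(v), "/")
  tab <- abundance_table(v, "relative_abundance")
  rho <- diag(5); dimnames(rho) <- list(rownames(v), rownames(v))
  singles <- cluster_features(rho, height = 0.1)
  ga <- guild_abundance(tab, singles)
  expect_equal(sort(unname(rowSums(ab_values(ga)))), sort(unname(rowSums(v))))
  expect_equal(colSums(ab_values(ga)), colSums(v))

  merged <- cluster_features(rho, height = 2)
  ga1 <- guild_abundance(tab, merged)
  expect_equal(unname(ab_values(ga1)[1, ]), unname(colSums(v)))
  expect_equal(ab_kind(ga1), "relative_abundance")

  asg_missing <- singles
  asg_missing$assignment <- asg_missing$assignment[-1]
  expect_error(guild_abundance(tab, asg_missing), "without guild")
})

test_that("co-occurrence edges require both |rho| above threshold and q below alpha", {
  ids <- c("a", "b", "c", "d")
  rho <- diag(4); dimnames(rho) <- list(ids, ids)
  p <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(p) <- 0
  rho["a", "b"] <- rho["b", "a"] <- 0.50;  p["a", "b"] <- p["b", "a"] <- 0.001
  rho["a", "c"] <- rho["c", "a"] <- 0.46;  p["a", "c"] <- p["c", "a"] <- 0.001
  rho["b", "c"] <- rho["c", "b"] <- -0.60; p["b", "c"] <- p["c", "b"] <- 0.09
  rho["c", "d"] <- rho["d", "c"] <- -0.80; p["c", "d"] <- p["d", "c"] <- 0.002
  net <- cooccurrence_network(rho, p, threshold = 0.46, alpha = 0.05)
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("a b", "c d"))
  expect_equal(net$edges$sign[net$edges$from == "a"], "+")
  expect_equal(net$edges$sign[net$edges$from == "c"], "-")
  # rho exactly at the threshold is excluded, as is a failing q
  expect_false("a c" %in% key)
  expect_false("b c" %in% key)
  # BH adjustment is applied: the kept q values dominate their raw p
  expect_true(all(net$edges$q >= c(0.001, 0.002)))
})
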