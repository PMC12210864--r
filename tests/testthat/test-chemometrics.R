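# Small helper: a two-class dataset with `n_inf` informative features shifted
# by `d` standard deviations, the rest pure noise.
sim_two_class <- function(n_per = 15, p = 50, n_inf = 10, d = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), nrow = 2 * n_per)
  y <- rep(c("case", "control"), each = n_per)
  if (n_inf > 0) X[y == "case", seq_len(n_inf)] <- X[y == "case", seq_len(n_inf)] + d
  colnames(X) <- sprintf("f%03d", seq_len(p))
  rownames(X) <- sprintf("s%03d", seq_len(2 * n_per))
  list(X = X, y = y)
}

test_that("PLS-DA recovers a response planted as an X column", {
  set.seed(41)
  n <- 30
  y <- rep(c("case", "control"), each = n / 2)
  y01 <- as.numeric(y == "case")
  X <- cbind(2 * y01, matrix(rnorm(n * 20, sd = 0.2), n))
  colnames(X) <- sprintf("f%d", 1:21)
  fit <- fit_plsda(X, y, max_components = 2)
  expect_gt(fit$R2Y, 0.99)
  expect_gt(fit$vip[["f1"]], 1)
})

test_that("NIPALS fits have orthogonal scores, deflated weights, and Q2 <= R2Y", {
  d <- sim_two_class(n_per = 15, p = 30, n_inf = 8, d = 1, seed = 42)
  fit <- fit_plsda(d$X, d$y, max_components = 3, min_q2_gain = -Inf)
  if (fit$ncomp >= 2) {
    gram <- crossprod(fit$Tm)
    off <- gram - diag(diag(gram))
    expect_lt(max(abs(off)), 1e-8)
  }
  expect_lte(fit$Q2, fit$R2Y)
  expect_true(all(abs(colSums(fit$W^2) - 1) < 1e-8))

  # refit manually to check deflation: after extracting each component the
  # weight no longer correlates with the deflated X
  Xc <- scale(d$X, scale = FALSE)
  yc <- as.numeric(d$y == "case") - mean(d$y == "case")
  Xd <- Xc
  for (a in seq_len(fit$ncomp)) {
    Xd <- Xd - tcrossprod(fit$Tm[, a], fit$P[, a])
    expect_lt(max(abs(crossprod(Xd, fit$Tm[, a]))), 1e-6)
  }
})

test_that("VIP scores satisfy their normalization identities", {
  # duplicated informative column: all weights equal in magnitude -> VIP = 1
  set.seed(43)
  n <- 20
  y <- rep(c("case", "control"), each = n / 2)
  v <- as.numeric(y == "case") + rnorm(n, sd = 0.1)
  X <- cbind(v, v, v, v)
  colnames(X) <- sprintf("f%d", 1:4)
  fit <- fit_plsda(X, y, max_components = 1)
  expect_equal(unname(fit$vip), rep(1, 4), tolerance = 1e-10)

  # a feature with zero weight gets VIP 0 (constant column centers to zero)
  X2 <- cbind(X, dead = rep(7, n))
  fit2 <- fit_plsda(X2, y, max_components = 1)
  expect_equal(fit2$vip[["dead"]], 0)

  expect_error(vip_scores(list()), "pls_model")
})

test_that("OPLS-DA with no orthogonal component reproduces 1-component PLS-DA", {
  for (seed in 1:5) {
    d <- sim_two_class(n_per = 12, p = 25, n_inf = 5, d = 1, seed = seed)
    po <- fit_oplsda(d$X, d$y, n_orth = 0)
    pp <- fit_plsda(d$X, d$y, max_components = 1)
    expect_lt(max(abs(abs(po$Tm[, 1]) - abs(pp$Tm[, 1]))), 1e-6)
    expect_equal(po$R2Y, pp$R2Y, tolerance = 1e-10)
  }
})

test_that("orthogonal filtering absorbs a y-orthogonal confound", {
  set.seed(44)
  n <- 30; p <- 40
  y <- rep(c("case", "control"), each = n / 2)
  y01 <- as.numeric(y == "case")
  yc <- y01 - mean(y01)
  conf <- rnorm(n)
  conf <- conf - mean(conf)
  conf <- conf - yc * sum(conf * yc) / sum(yc^2)  # orthogonalize against y
  signal <- outer(yc, c(rep(1, 10), rep(0, p - 10)))
  confound <- outer(conf, c(rep(0, p - 10), rep(3, 10)))
  X <- signal + confound + matrix(rnorm(n * p, sd = 0.1), n)
  colnames(X) <- sprintf("f%02d", 1:p)

  clean_fit <- fit_oplsda(signal + matrix(rnorm(n * p, sd = 0.1), n), y, n_orth = 0)
  fit <- fit_oplsda(X, y, n_orth = 1)
  sep <- function(t) abs(mean(t[y01 == 1]) - mean(t[y01 == 0])) / sd(t)
  expect_gt(sep(fit$Tm[, 1]), 0.9 * sep(clean_fit$Tm[, 1]))
  # predictive scores orthogonal to every orthogonal-component score
  expect_lt(max(abs(crossprod(fit$Tm, fit$T_orth))), 1e-8)
})

test_that("cross-validated Q2 is high for separable data, low for noise", {
  d <- sim_two_class(n_per = 20, p = 30, n_inf = 15, d = 3, seed = 45)
  q2 <- cross_validated_q2(d$X, d$y, ncomp = 1)
  expect_gt(q2, 0.9)

  q2_noise <- vapply(1:10, function(s) {
    dn <- sim_two_class(n_per = 15, p = 50, n_inf = 0, seed = 100 + s)
    cross_validated_q2(dn$X, dn$y, ncomp = 1)
  }, numeric(1))
  expect_lt(median(q2_noise), 0)
})

test_that("permutation report reproduces the original fit and flags noise", {
  d <- sim_two_class(n_per = 10, p = 20, n_inf = 6, d = 2, seed = 46)
  rep1 <- permutation_test(d$X, d$y, model_kind = "plsda", n_perm = 9, seed = 3)
  # the original entry equals an independent refit on unpermuted labels
  fit <- fit_plsda(d$X, d$y)
  expect_equal(rep1$original$Q2, fit$Q2)
  expect_equal(rep1$original$R2Y, fit$R2Y)
  expect_equal(rep1$p_q2, (sum(rep1$perms$Q2 >= rep1$original$Q2) + 1) / 10)
  # determinism
  rep2 <- permutation_test(d$X, d$y, model_kind = "plsda", n_perm = 9, seed = 3)
  expect_equal(rep1$perms, rep2$perms)

  expect_error(fit_plsda(d$X, rep("case", 20)), "two classes")
})
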