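test_that("QC filter keeps low-CV features and drops the rest", {
  # two QC samples: CV = |a - b| / (sqrt(2) * mean); pick pairs hitting the
  # boundary from both sides
  cv_pair <- function(m, cv) c(m * (1 + cv / sqrt(2)), m * (1 - cv / sqrt(2)))
  v <- rbind(flat = c(10, 10, 1, 2),
             low = c(cv_pair(10, 0.29), 1, 2),
             high = c(cv_pair(10, 0.35), 1, 2),
             dead = c(0, 0, 1, 2))
  colnames(v) <- c("QC1", "QC2", "s1", "s2")
  tab <- abundance_table(v, "intensity")

  expect_warning(out <- qc_filter_metabolites(tab, c("QC1", "QC2")),
                 "zero QC mean")
  expect_setequal(ab_features(out), c("flat", "low"))
  expect_setequal(ab_samples(out), c("s1", "s2"))
  expect_error(qc_filter_metabolites(tab, "QC1"), "at least 2")
  expect_error(qc_filter_metabolites(tab, c("QC1", "QCX")), "QCX")
})

test_that("auto-scaling centers, scales, zeroes flat features, and is idempotent", {
  tab <- make_abt(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(sc <- autoscale(tab), "zero-variance")
  expect_equal(unname(ab_values(sc)[1, ]), c(-1, 0, 1))
  expect_equal(unname(ab_values(sc)[2, ]), c(0, 0, 0))
  expect_equal(ab_kind(sc), "scaled")

  set.seed(31)
  r <- make_abt(matrix(rexp(40), 5), kind = "intensity")
  once <- autoscale(r)
  twice <- autoscale(once)
  expect_equal(ab_values(twice), ab_values(once), tolerance = 1e-12)
})

test_that("Student's t matches the closed form and stats::t.test", {
  res <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(-3 / sqrt(2 / 3)), df = 4), tolerance = 1e-12)
  expect_equal(round(res$statistic, 3), -3.674)
  expect_equal(round(res$p.value, 3), 0.021)

  same <- student_t(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(32)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, 0.5)
    mine <- student_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value)
    swapped <- student_t(y, x)
    expect_equal(swapped$statistic, -mine$statistic)
    expect_equal(swapped$p.value, mine$p.value)
  }

  expect_warning(degen <- student_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_equal(degen$p.value, 0)
})

test_that("Wilcoxon rank-sum matches exact enumeration and is rank-invariant", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p.value, 1)

  set.seed(33)
  x <- rnorm(6); y <- rnorm(8)
  base <- wilcoxon_rank_sum(x, y)
  shifted <- wilcoxon_rank_sum(x + 17.3, y + 17.3)
  expect_equal(shifted$statistic, base$statistic)
  expect_equal(shifted$p.value, base$p.value)

  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    vals <- sample(100, nx + ny)  # distinct -> exact branch
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                 wilcoxon_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg matches the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(34)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    q <- benjamini_hochberg(p)
    expect_identical(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

test_that("metabolite selection applies the joint p/VIP rule with directions", {
  set.seed(35)
  n <- 10
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("s%d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n)))
  g <- rep(c(1, 0), each = n)
  v <- rbind(up = rnorm(2 * n) + 3 * g,       # strong case-enriched
             down = rnorm(2 * n) - 3 * g,     # strong case-depleted
             null = rnorm(2 * n))
  colnames(v) <- meta$sample_id
  tab <- abundance_table(v - min(v) + 1, "intensity")
  vip <- c(up = 1.2, down = 1.2, null = 1.2)
  dm <- differential_metabolites(tab, meta, vip = vip)
  expect_true(dm$selected[dm$feature == "up"])
  expect_equal(dm$direction[dm$feature == "up"], "case_enriched")
  expect_equal(dm$direction[dm$feature == "down"], "case_depleted")
  expect_true(all(dm$q >= dm$p))

  # p significant but VIP at/below 1 -> not selected
  vip_low <- c(up = 0.9, down = 1.0, null = 3)
  dm2 <- differential_metabolites(tab, meta, vip = vip_low)
  expect_false(any(dm2$selected[dm2$feature %in% c("up", "down")]))
  # a high VIP alone is not enough: selection still requires p < 0.05
  expect_equal(dm2$selected[dm2$feature == "null"],
               dm2$p[dm2$feature == "null"] < 0.05)

  expect_error(differential_metabolites(tab, meta, vip = c(up = 1, down = 1)),
               "aligned")
})

test_that("species selection enforces the abundance floor and drops absentees", {
  set.seed(36)
  n <- 12
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("s%d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n)))
  g <- rep(c(1, 0), each = n)
  common <- abs(rnorm(2 * n, 0.1, 0.01)) + 0.05 * g       # differential, abundant
  rare <- (abs(rnorm(2 * n, 1, 0.1)) + 0.5 * g) * 1e-7    # differential, below floor
  absent <- rep(0, 2 * n)
  filler <- matrix(abs(rnorm(4 * 2 * n, 0.2, 0.02)), nrow = 4)
  v <- rbind(common = common, rare = rare, absent = absent, filler)
  rownames(v) <- c("common", "rare", "absent", sprintf("bg%d", 1:4))
  colnames(v) <- meta$sample_id
  v <- sweep(v, 2, colSums(v), "/") * 0.999
  v["rare", ] <- rare  # keep the rare species genuinely below the floor
  v["absent", ] <- 0
  tab <- abundance_table(v, "relative_abundance")

  ds <- differential_species(tab, meta)
  expect_false("absent" %in% ds$feature)
  expect_true(ds$selected[ds$feature == "common"])
  rare_row <- ds[ds$feature == "rare", ]
  expect_lt(rare_row$p, 0.05)
  expect_false(rare_row$selected)

  expect_error(differential_species(make_abt(matrix(1:4, 2)), meta),
               "relative-abundance")
})

test_that("KO selection has power on planted shifts with correct directions", {
  co <- generate_cohort(cohort_config(n_case = 20, n_control = 20,
                                      ko_group_effect = 2, seed = 37))
  dk <- differential_kos(co$kos, co$metadata)
  truth <- co$truth$diff_kos
  hit <- dk[match(truth$feature, dk$feature), ]
  expect_gt(mean(hit$selected), 0.9)
  detected <- hit[hit$selected, ]
  planted_sign <- sign(truth$effect[match(detected$feature, truth$feature)])
  expect_true(all(ifelse(planted_sign > 0, "case_enriched", "case_depleted") ==
                    detected$direction))
  # null features stay near the nominal rate
  null_rows <- dk[!dk$feature %in% truth$feature, ]
  expect_lt(mean(null_rows$selected), 0.12)
})
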