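test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(ab_values(a$metabolome), ab_values(c2$metabolome)))
})

test_that("species columns are closed compositions and truth covers all features", {
  co <- generate_cohort(cohort_config(seed = 2))
  expect_true(all(abs(colSums(ab_values(co$microbiome)) - 1) < 1e-9))
  expect_true(all(abs(colSums(ab_values(co$kos)) - 1) < 1e-9))
  # every feature is in exactly one guild or background
  expect_setequal(names(co$truth$metabolite_module), ab_features(co$metabolome))
  expect_setequal(names(co$truth$species_cag), ab_features(co$microbiome))
  expect_true(all(table(names(co$truth$species_cag)) == 1))
  sizes <- table(co$truth$metabolite_module[co$truth$metabolite_module != "background"])
  expect_true(all(sizes >= 5 & sizes <= 15))
})

test_that("within-module correlation matches the latent-factor model", {
  # For log-normal members sharing Pearson correlation r on the log scale,
  # Spearman correlation is (6/pi) asin(r/2) (monotone transform of a
  # bivariate normal).
  r <- 0.8
  expected <- (6 / pi) * asin(r / 2)
  co <- generate_cohort(cohort_config(
    n_case = 2500, n_control = 2500, n_metabolites = 40, n_modules = 1,
    module_size_range = c(10, 10), within_module_rho = r,
    module_group_effect = 0, n_diff_modules = 0,
    n_species = 10, n_cags = 1, n_diff_cags = 1, cag_size_range = c(2, 2),
    n_kos = 10, n_diff_kos = 0, seed = 42))
  members <- names(co$truth$metabolite_module)[co$truth$metabolite_module != "background"]
  ids <- setdiff(ab_samples(co$metabolome), co$qc_sample_ids)
  rho <- cor(t(ab_values(co$metabolome)[members, ids]), method = "spearman")
  mean_rho <- mean(rho[upper.tri(rho)])
  expect_lt(abs(mean_rho - expected), 0.02)
})

test_that("null cohorts are calibrated and planted effects have the right size", {
  # no planted effects: ~5% of metabolite t-tests significant at 0.05
  co <- generate_cohort(cohort_config(
    n_case = 30, n_control = 30, n_metabolites = 1000,
    module_group_effect = 0, species_group_effect = 0, n_diff_kos = 0,
    seed = 8))
  ids <- setdiff(ab_samples(co$metabolome), co$qc_sample_ids)
  grp <- split_groups(co$metadata)
  v <- log(ab_values(co$metabolome)[, ids])
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    student_t(v[i, grp$case], v[i, grp$control])$p.value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)

  # planted standardized effect recovered within 20% at n = 300 per arm
  eff <- 1.5
  co2 <- generate_cohort(cohort_config(
    n_case = 300, n_control = 300, module_group_effect = eff, seed = 9))
  ids2 <- setdiff(ab_samples(co2$metabolome), co2$qc_sample_ids)
  grp2 <- split_groups(co2$metadata)
  lv <- log(ab_values(co2$metabolome)[co2$truth$diff_metabolites$feature, ids2])
  d_hat <- vapply(seq_len(nrow(lv)), function(i) {
    x <- lv[i, grp2$case]; y <- lv[i, grp2$control]
    (mean(x) - mean(y)) / sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                                 (length(x) + length(y) - 2))
  }, numeric(1))
  signed <- d_hat * sign(co2$truth$diff_metabolites$effect)
  expect_true(all(abs(signed - eff) / eff < 0.2))
})

test_that("with phenotype_slope = 0 the clinical flag is uncorrelated with modules", {
  n <- 35
  crit <- qt(0.975, df = n - 2)
  r_crit <- crit / sqrt(n - 2 + crit^2)  # 95% null quantile of |rho|, t-approx
  below <- 0L; total <- 0L
  for (seed in 1:20) {
    co <- generate_cohort(cohort_config(phenotype_slope = 0,
                                        module_group_effect = 0, seed = seed))
    ids <- setdiff(ab_samples(co$metabolome), co$qc_sample_ids)
    flag <- co$metadata$cardiac_amyloidosis[match(ids, co$metadata$sample_id)]
    mm <- co$truth$metabolite_module
    for (m in unique(mm[mm != "background"])) {
      abund <- colSums(ab_values(co$metabolome)[names(mm)[mm == m], ids, drop = FALSE])
      rho <- suppressWarnings(cor(abund, flag, method = "spearman"))
      total <- total + 1L
      if (abs(rho) < r_crit) below <- below + 1L
    }
  }
  expect_gte(below / total, 0.9)
})

test_that("write_cohort round-trips tables, records the seed, and respects --force", {
  co <- generate_cohort(cohort_config(seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_abundance_table(paths["microbiome"], "relative_abundance")
  expect_identical(ab_values(back), ab_values(co$microbiome))
  meta_back <- read_sample_metadata(paths["metadata"])
  expect_equal(meta_back$group, co$metadata$group)
  manifest <- yaml::read_yaml(paths["manifest"])
  expect_equal(manifest$seed, 4L)
  expect_error(write_cohort(co, dir), "not empty")
  expect_silent(write_cohort(co, dir, force = TRUE))
})

test_that("infeasible configurations are rejected before sampling", {
  expect_error(cohort_config(within_module_rho = 1.2), "0, 1")
  expect_error(cohort_config(zero_inflation = 1), "zero_inflation")
  expect_error(cohort_config(n_modules = 40, module_size_range = c(20, 30),
                             n_metabolites = 100), "fit within")
  expect_error(cohort_config(n_diff_modules = 11), "n_diff_modules")
})
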