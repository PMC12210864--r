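#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated two-group multi-omics
#' cohort: block-correlated metabolite modules with group effects on the log
#' scale, a closed (compositional) zero-inflated species table with planted
#' co-abundance guilds, a KEGG-ortholog table mixing null and group-shifted
#' features, and a binary clinical flag driven by the latent factor of a
#' designated metabolite module. Defaults mirror a small case-control study
#' (13 cases vs 22 controls); recovery test suites typically raise the sample
#' size and within-guild correlation.
#'
#' @param n_case,n_control biological sample counts per arm.
#' @param n_qc pooled quality-control injections appended to the metabolite
#'   table only.
#' @param n_metabolites,n_modules,module_size_range metabolome dimensions;
#'   module sizes are drawn uniformly from the range and must fit within
#'   `n_metabolites`.
#' @param within_module_rho latent-factor loading squared: the Pearson
#'   correlation between two members of the same module on the log scale.
#' @param module_group_effect standardized (log-scale) mean difference applied
#'   to the designated differential modules; sign alternates across modules.
#' @param n_diff_modules how many modules carry the group effect.
#' @param n_species,n_cags,cag_size_range,within_cag_rho species-table
#'   analogues of the module parameters.
#' @param species_group_effect,n_diff_cags log-scale effect planted on members
#'   of the designated differential CAGs.
#' @param zero_inflation per-entry probability of zeroing a species value
#'   before compositional closure.
#' @param n_kos,n_diff_kos,ko_group_effect KO table dimensions and planted
#'   shifts.
#' @param phenotype_slope logistic slope linking the driver module's latent
#'   factor to the binary clinical flag (`cardiac_amyloidosis`).
#' @param qc_cv technical coefficient of variation of stable features in QC
#'   injections; `frac_unstable` features instead get `unstable_cv`.
#' @param frac_unstable,unstable_cv fraction and CV of analytically unstable
#'   metabolite features (the ones the QC filter should remove).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 13, n_control = 22, n_qc = 5,
                          n_metabolites = 200, n_modules = 10,
                          module_size_range = c(5, 15),
                          within_module_rho = 0.7,
                          module_group_effect = 1.5,
                          n_diff_modules = 4,
                          n_species = 150, n_cags = 10,
                          cag_size_range = c(4, 12),
                          within_cag_rho = 0.7,
                          species_group_effect = 1.5,
                          n_diff_cags = 3,
                          zero_inflation = 0.3,
                          n_kos = 300, n_diff_kos = 30, ko_group_effect = 1.5,
                          phenotype_slope = 2,
                          qc_cv = 0.10, frac_unstable = 0.05, unstable_cv = 0.5,
                          seed = 1L) {
  cfg <- list(n_case = n_case, n_control = n_control, n_qc = n_qc,
              n_metabolites = n_metabolites, n_modules = n_modules,
              module_size_range = module_size_range,
              within_module_rho = within_module_rho,
              module_group_effect = module_group_effect,
              n_diff_modules = n_diff_modules,
              n_species = n_species, n_cags = n_cags,
              cag_size_range = cag_size_range,
              within_cag_rho = within_cag_rho,
              species_group_effect = species_group_effect,
              n_diff_cags = n_diff_cags,
              zero_inflation = zero_inflation,
              n_kos = n_kos, n_diff_kos = n_diff_kos,
              ko_group_effect = ko_group_effect,
              phenotype_slope = phenotype_slope,
              qc_cv = qc_cv, frac_unstable = frac_unstable,
              unstable_cv = unstable_cv,
              seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_metabolites", "n_modules",
              "n_species", "n_cags", "n_kos")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) {
      stop("'", nm, "' must be a positive count", call. = FALSE)
    }
  }
  for (nm in c("within_module_rho", "within_cag_rho")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop("'", nm, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1) {
    stop("'zero_inflation' must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_diff_modules > cfg$n_modules) stop("n_diff_modules > n_modules", call. = FALSE)
  if (cfg$n_diff_cags > cfg$n_cags) stop("n_diff_cags > n_cags", call. = FALSE)
  if (cfg$n_diff_kos > cfg$n_kos) stop("n_diff_kos > n_kos", call. = FALSE)
  if (cfg$module_size_range[2] * cfg$n_modules > cfg$n_metabolites &&
      cfg$module_size_range[1] * cfg$n_modules > cfg$n_metabolites) {
    stop("module sizes cannot fit within n_metabolites", call. = FALSE)
  }
  if (cfg$cag_size_range[1] * cfg$n_cags > cfg$n_species) {
    stop("CAG sizes cannot fit within n_species", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Draw guild sizes uniformly from `range`, shrinking the draw if the total
# would exceed the feature budget.
draw_guild_sizes <- function(n_guilds, range, budget) {
  pool <- seq(range[1], range[2])
  sizes <- if (length(pool) == 1L) rep(pool, n_guilds)
           else sample(pool, n_guilds, replace = TRUE)
  while (sum(sizes) > budget) {
    i <- which.max(sizes)
    if (sizes[i] <= range[1]) stop("guild sizes infeasible for feature budget", call. = FALSE)
    sizes[i] <- sizes[i] - 1L
  }
  sizes
}

# Equicorrelated block on the log scale: member = sqrt(rho) * latent +
# sqrt(1-rho) * noise (+ effect for case samples), so members share pairwise
# Pearson correlation `rho` and unit variance before the shift.
block_logs <- function(latent, size, rho, effect, g) {
  n <- length(latent)
  noise <- matrix(stats::rnorm(size * n), nrow = size)
  z <- sqrt(rho) * matrix(latent, nrow = size, ncol = n, byrow = TRUE) +
    sqrt(1 - rho) * noise
  if (effect != 0) z <- z + effect * matrix(g, nrow = size, ncol = n, byrow = TRUE)
  z
}

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' See [cohort_config()] for the generative model. The output bundles a
#' metabolite intensity table (with QC injections), a closed species
#' relative-abundance table, a closed KO table, sample metadata with a
#' latent-driven binary clinical flag, GMT-ready metabolite and KO set
#' libraries, and a `truth` list mapping every feature to its planted guild
#' and recording the signed effects — the ground truth used by the recovery
#' tests.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `metabolome`,
#'   `microbiome`, `kos` ([abundance_table()]s), `metadata`
#'   ([sample_metadata()]), `qc_sample_ids`, `sets`, `ko_sets`, `truth`, and
#'   the `config` used.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  sample_ids <- c(sprintf("hATTR_%03d", seq_len(cfg$n_case)),
                  sprintf("HC_%03d", seq_len(cfg$n_control)))
  g <- c(rep(1, cfg$n_case), rep(0, cfg$n_control))

  ## ---- metabolome -------------------------------------------------------
  met_ids <- sprintf("met_%04d", seq_len(cfg$n_metabolites))
  mod_sizes <- draw_guild_sizes(cfg$n_modules, cfg$module_size_range, cfg$n_metabolites)
  member_idx <- sample(cfg$n_metabolites, sum(mod_sizes))
  module_of <- rep("background", cfg$n_metabolites)
  mod_labels <- sprintf("mod%02d", seq_len(cfg$n_modules))
  diff_modules <- mod_labels[seq_len(cfg$n_diff_modules)]
  mod_sign <- stats::setNames(rep(0, cfg$n_modules), mod_labels)
  mod_sign[diff_modules] <- rep_len(c(1, -1), cfg$n_diff_modules)

  latents <- matrix(stats::rnorm(cfg$n_modules * n), nrow = cfg$n_modules,
                    dimnames = list(mod_labels, sample_ids))
  z <- matrix(stats::rnorm(cfg$n_metabolites * n), nrow = cfg$n_metabolites)
  offset <- 0L
  for (m in seq_len(cfg$n_modules)) {
    idx <- member_idx[offset + seq_len(mod_sizes[m])]
    offset <- offset + mod_sizes[m]
    module_of[idx] <- mod_labels[m]
    z[idx, ] <- block_logs(latents[m, ], mod_sizes[m], cfg$within_module_rho,
                           cfg$module_group_effect * mod_sign[mod_labels[m]], g)
  }
  baseline_met <- stats::rnorm(cfg$n_metabolites, mean = 14, sd = 2)
  bio <- exp(z + baseline_met)
  dimnames(bio) <- list(met_ids, sample_ids)

  qc_ids <- sprintf("QC_%02d", seq_len(cfg$n_qc))
  unstable <- sample(c(TRUE, FALSE), cfg$n_metabolites, replace = TRUE,
                     prob = c(cfg$frac_unstable, 1 - cfg$frac_unstable))
  sigma_qc <- ifelse(unstable,
                     sqrt(log(1 + cfg$unstable_cv^2)),
                     sqrt(log(1 + cfg$qc_cv^2)))
  mu_qc <- baseline_met + rowMeans(z)
  qc <- exp(mu_qc + sigma_qc * matrix(stats::rnorm(cfg$n_metabolites * cfg$n_qc),
                                      nrow = cfg$n_metabolites))
  dimnames(qc) <- list(met_ids, qc_ids)
  metabolome <- abundance_table(cbind(bio, qc), "intensity")

  ## ---- microbiome -------------------------------------------------------
  sp_ids <- sprintf("sp_%04d", seq_len(cfg$n_species))
  cag_sizes <- draw_guild_sizes(cfg$n_cags, cfg$cag_size_range, cfg$n_species)
  cag_member_idx <- sample(cfg$n_species, sum(cag_sizes))
  cag_of <- rep("background", cfg$n_species)
  cag_labels <- sprintf("cag%02d", seq_len(cfg$n_cags))
  diff_cags <- cag_labels[seq_len(cfg$n_diff_cags)]
  cag_sign <- stats::setNames(rep(0, cfg$n_cags), cag_labels)
  cag_sign[diff_cags] <- rep_len(c(1, -1), cfg$n_diff_cags)

  cag_latents <- matrix(stats::rnorm(cfg$n_cags * n), nrow = cfg$n_cags,
                        dimnames = list(cag_labels, sample_ids))
  zs <- matrix(stats::rnorm(cfg$n_species * n), nrow = cfg$n_species)
  offset <- 0L
  for (cme in seq_len(cfg$n_cags)) {
    idx <- cag_member_idx[offset + seq_len(cag_sizes[cme])]
    offset <- offset + cag_sizes[cme]
    cag_of[idx] <- cag_labels[cme]
    zs[idx, ] <- block_logs(cag_latents[cme, ], cag_sizes[cme], cfg$within_cag_rho,
                            cfg$species_group_effect * cag_sign[cag_labels[cme]], g)
  }
  baseline_sp <- stats::rnorm(cfg$n_species, mean = 0, sd = 2)
  raw_sp <- exp(zs + baseline_sp)
  mask <- matrix(stats::runif(cfg$n_species * n) < cfg$zero_inflation,
                 nrow = cfg$n_species)
  raw_sp[mask] <- 0
  cs <- colSums(raw_sp)
  if (any(cs == 0)) stop("zero inflation produced an all-zero sample; lower 'zero_inflation'",
                         call. = FALSE)
  closed <- sweep(raw_sp, 2L, cs, "/")
  dimnames(closed) <- list(sp_ids, sample_ids)
  microbiome <- abundance_table(closed, "relative_abundance")

  ## ---- KOs --------------------------------------------------------------
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  zk <- matrix(stats::rnorm(cfg$n_kos * n), nrow = cfg$n_kos)
  diff_ko_idx <- sample(cfg$n_kos, cfg$n_diff_kos)
  ko_sign <- rep_len(c(1, -1), cfg$n_diff_kos)
  zk[diff_ko_idx, ] <- zk[diff_ko_idx, ] +
    cfg$ko_group_effect * ko_sign %o% g
  baseline_ko <- stats::rnorm(cfg$n_kos, mean = 0, sd = 1.5)
  raw_ko <- exp(zk + baseline_ko)
  closed_ko <- sweep(raw_ko, 2L, colSums(raw_ko), "/")
  dimnames(closed_ko) <- list(ko_ids, sample_ids)
  kos <- abundance_table(closed_ko, "relative_abundance")

  # KO "pathway" sets: the shifted KOs are concentrated in two pathways
  # (one per direction) so over-representation analysis has signal to find.
  n_pathways <- 15L
  ko_pathway <- rep(NA_character_, cfg$n_kos)
  ko_pathway[diff_ko_idx[ko_sign > 0]] <- "pathway_01"
  ko_pathway[diff_ko_idx[ko_sign < 0]] <- "pathway_02"
  null_idx <- which(is.na(ko_pathway))
  ko_pathway[null_idx] <- sprintf("pathway_%02d",
                                  sample(3:n_pathways, length(null_idx), replace = TRUE))
  ko_sets <- split(ko_ids, ko_pathway)

  ## ---- metadata ---------------------------------------------------------
  driver <- mod_labels[1L]
  flag <- stats::rbinom(n, 1L, stats::plogis(cfg$phenotype_slope * latents[driver, ]))
  subgroup <- rep(NA_character_, n)
  subgroup[seq_len(cfg$n_case)] <- sample(c("mix", "neurologic", "carrier"),
                                          cfg$n_case, replace = TRUE,
                                          prob = c(0.45, 0.40, 0.15))
  age <- round(stats::rnorm(n, mean = 55, sd = 10))
  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids,
    group = ifelse(g == 1, "case", "control"),
    subgroup = subgroup,
    cardiac_amyloidosis = flag,
    age = age,
    stringsAsFactors = FALSE))

  ## ---- metabolite set library -------------------------------------------
  sets <- lapply(split(met_ids[module_of != "background"],
                       module_of[module_of != "background"]),
                 identity)
  names(sets) <- paste0("MSET_", names(sets))
  for (k in 1:5) {
    sets[[sprintf("RANDSET_%02d", k)]] <- sample(met_ids, 8L)
  }

  truth <- list(
    metabolite_module = stats::setNames(module_of, met_ids),
    species_cag = stats::setNames(cag_of, sp_ids),
    diff_metabolites = data.frame(
      feature = met_ids[module_of %in% diff_modules],
      effect = cfg$module_group_effect *
        unname(mod_sign[module_of[module_of %in% diff_modules]]),
      stringsAsFactors = FALSE),
    diff_species = data.frame(
      feature = sp_ids[cag_of %in% diff_cags],
      effect = cfg$species_group_effect *
        unname(cag_sign[cag_of[cag_of %in% diff_cags]]),
      stringsAsFactors = FALSE),
    diff_kos = data.frame(
      feature = ko_ids[diff_ko_idx],
      effect = cfg$ko_group_effect * ko_sign,
      stringsAsFactors = FALSE),
    driver_module = stats::setNames(driver, "cardiac_amyloidosis"),
    module_latents = latents,
    seed = cfg$seed)

  structure(list(metabolome = metabolome, microbiome = microbiome, kos = kos,
                 metadata = metadata, qc_sample_ids = qc_ids,
                 sets = sets, ko_sets = ko_sets, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes each table as TSV, the set libraries as GMT, the ground truth as
#' YAML, and a manifest (file list plus seed) as YAML. Refuses to write into
#' a non-empty directory unless `force = TRUE`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return Named character vector of written paths (the manifest), invisibly.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory '", out_dir, "' is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metabolome = file.path(out_dir, "metabolome.tsv"),
    microbiome = file.path(out_dir, "species.tsv"),
    kos = file.path(out_dir, "kos.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    sets = file.path(out_dir, "metabolite_sets.gmt"),
    ko_sets = file.path(out_dir, "ko_sets.gmt"),
    truth = file.path(out_dir, "truth.yaml"),
    manifest = file.path(out_dir, "manifest.yaml"))
  write_abundance_table(cohort$metabolome, paths["metabolome"])
  write_abundance_table(cohort$microbiome, paths["microbiome"])
  write_abundance_table(cohort$kos, paths["kos"])
  write_sample_metadata(cohort$metadata, paths["metadata"])
  write_set_library(cohort$sets, paths["sets"])
  write_set_library(cohort$ko_sets, paths["ko_sets"])
  truth <- cohort$truth
  truth$metabolite_module <- as.list(truth$metabolite_module)
  truth$species_cag <- as.list(truth$species_cag)
  truth$module_latents <- NULL  # matrix ground truth stays in-memory only
  yaml::write_yaml(truth, paths["truth"])
  yaml::write_yaml(list(seed = cohort$config$seed,
                        qc_sample_ids = cohort$qc_sample_ids,
                        files = as.list(basename(paths[names(paths) != "manifest"]))),
                   paths["manifest"])
  invisible(paths)
}
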