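#' Run the full guild-based multi-omics workflow on a synthetic cohort
#'
#' Chains every analysis stage the package provides, writing plot-ready TSVs
#' along the way: cohort simulation; QC filtering, auto-scaling, OPLS-DA with
#' permutation validation and VIP, joint p/VIP metabolite selection, metabolite
#' modules (Spearman distance, average linkage, cut 0.4) with cumulative
#' abundances and directional set enrichment; alpha-diversity comparison,
#' species PLS-DA, Wilcoxon key-species selection, CAG detection (cut 0.5)
#' with the signed co-occurrence network; KO differential testing and pathway
#' enrichment; cross-block correlations, Sankey chains, per-module ROC/AUC and
#' Bray-Curtis sample ordering. All randomness derives from `config$seed`, so
#' repeated runs produce byte-identical output files.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param n_perm label permutations for the OPLS-DA validation.
#' @param module_height,cag_height tree-cut heights for metabolite modules and
#'   species CAGs.
#' @param network_threshold absolute Spearman cutoff for co-occurrence edges.
#' @param force overwrite a non-empty `out_dir`.
#' @return Invisibly, a list with every intermediate result (cohort,
#'   differential tables, fitted models, guild assignments, correlation
#'   blocks, ROC table, enrichment tables, file paths).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         n_perm = 99, module_height = 0.4, cag_height = 0.5,
                         network_threshold = 0.46, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory '", out_dir, "' is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    out <- as.data.frame(df)
    for (col in names(out)) {
      if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    path
  }

  cohort <- generate_cohort(config)
  write_cohort(cohort, file.path(out_dir, "inputs"), force = force)
  meta <- cohort$metadata

  ## metabolome ------------------------------------------------------------
  met <- qc_filter_metabolites(cohort$metabolome, cohort$qc_sample_ids)
  scaled <- autoscale(met)
  ofit <- fit_oplsda(scaled, meta)
  operm <- permutation_test(scaled, meta, model_kind = "oplsda",
                            n_perm = n_perm, seed = config$seed)
  dm <- differential_metabolites(scaled, meta, vip = ofit$vip)
  tsv(dm, "differential_metabolites.tsv")

  sel_met <- dm$feature[dm$selected]
  modules <- NULL; mod_ab <- NULL; msea <- NULL
  if (length(sel_met) >= 2) {
    sm <- spearman_matrix(met[sel_met, ])
    modules <- cluster_features(sm$rho, height = module_height, prefix = "M")
    mod_ab <- guild_abundance(met[sel_met, ], modules)
    tsv(data.frame(feature = names(modules$assignment),
                   module = unname(modules$assignment)), "metabolite_modules.tsv")
    write_abundance_table(mod_ab, file.path(out_dir, "module_abundance.tsv"),
                          id_column = "module")
    hits <- split_hits_by_direction(dm)
    universe <- ab_features(met)
    msea <- list(
      depleted = ora_enrichment(hits$depleted, universe, cohort$sets),
      enriched = ora_enrichment(hits$enriched, universe, cohort$sets))
    tsv(msea$depleted, "msea_depleted.tsv")
    tsv(msea$enriched, "msea_enriched.tsv")
  }

  ## microbiome ------------------------------------------------------------
  div <- compare_alpha_diversity(cohort$microbiome, meta)
  tsv(div$per_sample, "alpha_diversity_per_sample.tsv")
  tsv(div$tests, "alpha_diversity_tests.tsv")
  sfit <- fit_plsda(autoscale(cohort$microbiome), meta)
  ds <- differential_species(cohort$microbiome, meta)
  tsv(ds, "differential_species.tsv")

  key <- ds$feature[ds$selected]
  cags <- NULL; cag_ab <- NULL; net <- NULL
  if (length(key) >= 2) {
    ss <- spearman_matrix(cohort$microbiome[key, ])
    cags <- cluster_features(ss$rho, height = cag_height, prefix = "CAG")
    cag_ab <- guild_abundance(cohort$microbiome[key, ], cags)
    tsv(data.frame(feature = names(cags$assignment),
                   cag = unname(cags$assignment)), "species_cags.tsv")
    write_abundance_table(cag_ab, file.path(out_dir, "cag_abundance.tsv"),
                          id_column = "cag")
    net <- cooccurrence_network(ss$rho, ss$p, threshold = network_threshold,
                                assignment = cags)
    write_network(net, file.path(out_dir, "cooccurrence.graphml"), "graphml")
    write_network(net, file.path(out_dir, "cooccurrence_edges.tsv"), "edge_tsv")
  }

  ## KOs --------------------------------------------------------------------
  dk <- differential_kos(cohort$kos, meta)
  tsv(dk, "differential_kos.tsv")
  ko_hits <- split_hits_by_direction(dk)
  ko_ora <- list(
    depleted = ora_enrichment(ko_hits$depleted, ab_features(cohort$kos), cohort$ko_sets),
    enriched = ora_enrichment(ko_hits$enriched, ab_features(cohort$kos), cohort$ko_sets))
  tsv(ko_ora$depleted, "ko_ora_depleted.tsv")
  tsv(ko_ora$enriched, "ko_ora_enriched.tsv")

  ## integration ------------------------------------------------------------
  clin <- clinical_matrix(meta)
  blocks <- list(); sankey <- NULL; roc <- NULL
  if (!is.null(mod_ab)) {
    blocks$module_clinical <- correlate_blocks(mod_ab, clin, "module", "clinical")
    tsv(block_to_df(blocks$module_clinical), "cor_module_clinical.tsv")
    labels <- meta$group[match(ab_samples(mod_ab), meta$sample_id)]
    roc <- do.call(rbind, lapply(ab_features(mod_ab), function(m) {
      r <- roc_auc(ab_values(mod_ab)[m, ], labels)
      data.frame(module = m, auc = r$auc, direction = r$direction,
                 stringsAsFactors = FALSE)
    }))
    tsv(roc, "roc_auc.tsv")
  }
  if (!is.null(mod_ab) && !is.null(cag_ab)) {
    blocks$cag_module <- correlate_blocks(cag_ab, mod_ab, "CAG", "module")
    blocks$cag_clinical <- correlate_blocks(cag_ab, clin, "CAG", "clinical")
    tsv(block_to_df(blocks$cag_module), "cor_cag_module.tsv")
    tsv(block_to_df(blocks$cag_clinical), "cor_cag_clinical.tsv")
    sankey <- build_sankey_links(blocks$cag_module, blocks$module_clinical,
                                 left_sign = "+", right_sign = "+")
    tsv(sankey$links, "sankey_links.tsv")
  }
  bc <- braycurtis_order(cohort$microbiome)
  tsv(data.frame(order = seq_along(bc), sample_id = bc), "braycurtis_order.tsv")

  perm_df <- data.frame(original_R2Y = operm$original$R2Y,
                        original_Q2 = operm$original$Q2,
                        p_q2 = operm$p_q2,
                        q2_intercept = operm$q2_intercept,
                        all_q2_below = operm$valid["all_q2_below"],
                        row.names = NULL)
  tsv(perm_df, "oplsda_permutation.tsv")
  tsv(operm$perms, "oplsda_permutation_draws.tsv")

  invisible(list(cohort = cohort, metabolites = dm, oplsda = ofit,
                 permutation = operm, modules = modules, module_abundance = mod_ab,
                 msea = msea, diversity = div, species_plsda = sfit,
                 species = ds, cags = cags, cag_abundance = cag_ab,
                 network = net, kos = dk, ko_ora = ko_ora, blocks = blocks,
                 sankey = sankey, roc = roc, braycurtis_order = bc,
                 out_dir = out_dir))
}

# Long-format view of a correlation block for TSV export.
block_to_df <- function(block) {
  idx <- expand.grid(row = rownames(block$rho), col = colnames(block$rho),
                     stringsAsFactors = FALSE)
  data.frame(idx,
             rho = as.vector(block$rho),
             p = as.vector(block$p),
             annotation = as.vector(block$annotation),
             stringsAsFactors = FALSE)
}
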