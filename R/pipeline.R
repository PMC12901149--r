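#' Run the full storage-experiment analysis on synthetic data
#'
#' End-to-end orchestration of every stage on one simulated experiment:
#' simulate, transform, diversity + nested PERMANOVA + PERMDISP, ordination
#' with biplot vectors, per-temperature co-occurrence and graphical-lasso
#' networks with centralities, microbiome-metabolome Procrustes concordance,
#' enriched/outcompeted log-ratio trajectories, metabolite responsiveness
#' filtering / k selection / clustering / temperature tests / class
#' enrichment, and random-forest storage-phase classification.
#'
#' Problem sizes follow the simulated design (99 samples, 5 + 5 taxa, 150
#' metabolites). To keep the conditional-dependence estimation light, the
#' graphical lasso runs on the taxa plus the `glasso_max_metabolites`
#' highest-variance metabolites per stratum.
#'
#' @param seed Integer seed driving the simulation and every stochastic
#'   stage.
#' @param cfg A [simulation_config()]; defaults to the standard design with
#'   the given seed.
#' @param n_perm Permutations for PERMANOVA/PERMDISP/Procrustes (default
#'   199 for a quick run; raise to 999/1000 for final inference).
#' @param glasso_max_metabolites Cap on metabolite features entering the
#'   graphical lasso (default 40).
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV.
#' @return A list with the results of every stage (see the vignette for a
#'   walk-through).
#' @export
run_storage_pipeline <- function(seed = 1, cfg = simulation_config(seed = seed),
                                 n_perm = 199, glasso_max_metabolites = 40,
                                 out_dir = NULL) {
  sim <- simulate_experiment(cfg)
  md <- sim$metadata

  ## transforms
  bact_rel <- tss_normalize(sim$bacteria)
  met_filt <- prevalence_filter(sim$metabolites, min_prevalence = 3)
  met_z <- zscore_normalize(met_filt)

  ## diversity
  alpha <- data.frame(
    sample_id = sample_ids(sim$bacteria),
    richness = alpha_diversity(sim$bacteria, "richness"),
    shannon = alpha_diversity(sim$bacteria, "shannon"),
    evenness = alpha_diversity(sim$bacteria, "pielou_evenness"))
  d_bc <- beta_diversity(bact_rel, "braycurtis")
  perm_t <- permanova(d_bc, md$temperature, n_perm = n_perm, seed = seed,
                      factor_name = "temperature")
  disp_t <- permdisp(d_bc, md$temperature, n_perm = n_perm, seed = seed)
  nested <- nested_permanova(d_bc, md$temperature, md$day,
                             n_perm = n_perm, seed = seed)
  ord <- pcoa(d_bc)
  vecs <- biplot_vectors(ord, md[, c("pH", "TTA", "CFU", "acetic_acid",
                                     "maltose", "ethanol")], top_k = 6)

  ## networks per temperature
  met_top <- ft_subset(met_filt, features = order(
    -apply(met_filt$values, 1L, stats::var))[
      seq_len(min(glasso_max_metabolites, nrow(met_filt$values)))])
  nets_co <- per_condition_networks(
    list(sim$bacteria, sim$fungi, sim$metabolites), md,
    method = "cooccurrence", seed = seed)
  nets_gl <- per_condition_networks(
    list(sim$bacteria, sim$fungi, met_top), md,
    method = "glasso", seed = seed)

  ## concordance
  conc <- stratified_concordance(sim$bacteria, sim$metabolites, md,
                                 strata = c("global", "temperature"),
                                 metab_mode = "pcoa-braycurtis",
                                 n_perm = n_perm, seed = seed)

  ## differential abundance -> log-ratio trajectory
  da <- naive_clr_da(sim$bacteria, md)
  sets <- classify_enriched_outcompeted(da, threshold = 0.75)
  logratio <- if (length(sets$enriched) && length(sets$outcompeted)) {
    data.frame(sample_id = sample_ids(bact_rel),
               temperature = md$temperature, day = md$day,
               logratio = sample_logratio(bact_rel, sets$enriched,
                                          sets$outcompeted))
  } else NULL

  ## metabolome dynamics
  met_resp <- anova_responsiveness_filter(met_z, md)
  ksel <- select_k(met_resp, k_range = 2:6, seed = seed)
  clus <- cluster_trajectories(met_resp, ksel$k, seed = seed, metadata = md)
  kw <- kruskal_temperature_tests(met_resp, clus$labels, md)
  archetype <- paste0("archetype_",
                      sim$truth$metabolite_cluster[feature_ids(met_filt)])
  names(archetype) <- feature_ids(met_filt)
  enrich <- class_enrichment(tss_normalize(met_filt), md, archetype)

  ## supervised classification
  design <- build_design(list(sim$bacteria, sim$fungi, sim$metabolites,
                              covariate_table(md)),
                         md, target = "phase_temp")
  cv <- rf_cross_validate(design$X, design$y, seed = seed,
                          provenance = design$provenance)
  topf <- top_features_report(cv, design$X, md, k = 25)

  res <- list(simulation = sim, alpha = alpha, braycurtis = d_bc,
              permanova_temperature = perm_t, permdisp_temperature = disp_t,
              nested_permanova = nested, ordination = ord,
              biplot_vectors = vecs,
              cooccurrence = nets_co, glasso = nets_gl,
              concordance = conc, da = da, da_sets = sets,
              logratio = logratio,
              k_selection = ksel, clusters = clus, kruskal = kw,
              class_enrichment = enrich,
              classifier = cv, top_features = topf)

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_feature_table(res$simulation$bacteria, p("bacteria_counts.tsv"))
  write_feature_table(res$simulation$fungi, p("fungi_counts.tsv"))
  write_feature_table(res$simulation$metabolites, p("metabolite_intensities.tsv"))
  write_tsv(as.data.frame(res$simulation$metadata), p("metadata.tsv"))
  write_tsv(res$simulation$truth$taxon_trajectories, p("truth_taxa.tsv"))
  write_tsv(data.frame(feature = names(res$simulation$truth$metabolite_cluster),
                       cluster = res$simulation$truth$metabolite_cluster),
            p("truth_metabolite_clusters.tsv"))
  write_tsv(res$alpha, p("alpha_diversity.tsv"))
  write_tsv(res$nested_permanova, p("nested_permanova.tsv"))
  write_tsv(data.frame(group = names(res$permdisp_temperature$group_means),
                       mean_dist_to_centroid =
                         as.vector(res$permdisp_temperature$group_means)),
            p("permdisp_group_means.tsv"))
  write_tsv(res$biplot_vectors, p("biplot_vectors.tsv"))
  for (cc in names(res$cooccurrence$networks)) {
    write_edge_list(res$cooccurrence$networks[[cc]]$cooccurrence,
                    p(sprintf("network_cooccurrence_T%s.tsv", cc)))
  }
  for (cc in names(res$glasso$networks)) {
    write_edge_list(res$glasso$networks[[cc]]$glasso,
                    p(sprintf("network_glasso_T%s.tsv", cc)))
  }
  write_tsv(res$cooccurrence$centrality_table, p("centralities_cooccurrence.tsv"))
  write_tsv(res$glasso$centrality_table, p("centralities_glasso.tsv"))
  write_tsv(res$concordance, p("concordance.tsv"))
  write_tsv(as.data.frame(res$da), p("differential_abundance.tsv"))
  if (!is.null(res$logratio)) write_tsv(res$logratio, p("logratio.tsv"))
  write_tsv(res$k_selection$diagnostics, p("k_diagnostics.tsv"))
  write_tsv(data.frame(feature = names(res$clusters$labels),
                       cluster = res$clusters$labels),
            p("metabolite_clusters.tsv"))
  write_tsv(res$kruskal, p("kruskal_temperature.tsv"))
  write_tsv(res$class_enrichment, p("class_enrichment.tsv"))
  write_tsv(data.frame(fold = seq_along(res$classifier$fold_auc),
                       macro_auc = res$classifier$fold_auc),
            p("classifier_fold_auc.tsv"))
  write_tsv(res$classifier$importances, p("classifier_importances.tsv"))
  write_tsv(res$top_features$table, p("top_features.tsv"))
  invisible(out_dir)
}

#' Eigenvector-centrality rank of a node per condition
#'
#' Ranks nodes within each condition's network by eigenvector centrality
#' (rank 1 = least central, higher = more central) and returns the focal
#' node's rank per condition - used to track how a taxon's network position
#' shifts across storage temperatures.
#'
#' @param centrality_table Long table from [per_condition_networks()].
#' @param node Node id.
#' @param method Network kind to use (default `"cooccurrence"`).
#' @return Named numeric vector of ranks per condition.
#' @export
eigenvector_rank <- function(centrality_table, node,
                             method = "cooccurrence") {
  ct <- centrality_table[centrality_table$method == method, , drop = FALSE]
  out <- vapply(unique(ct$condition), function(cc) {
    sub <- ct[ct$condition == cc, , drop = FALSE]
    r <- rank(sub$eigenvector, ties.method = "average")
    r[match(node, sub$node)]
  }, numeric(1))
  stats::setNames(out, unique(ct$condition))
}
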