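# End-to-end orchestration: load -> rarefy -> diversity -> differential
# abundance -> network modules -> balances + LASSO -> lipid statistics ->
# PROTEST, with TSV/JSON outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param rarefaction_depth even sampling depth (54,000 for the emulated
#'   study scale; use ~10,000 for default synthetic data).
#' @param filter_total_min,filter_mean_min rare-taxon thresholds.
#' @param network_r_min,network_p_max co-occurrence edge thresholds.
#' @param louvain_restarts Louvain restarts.
#' @param philr_variant "summed" or "gmean".
#' @param lasso_lambda LASSO penalty.
#' @param lasso_k maximum selected balances.
#' @param protest_n_perm PROTEST permutations.
#' @param permanova_n_perm PERMANOVA permutations.
#' @param pseudocount shared log-ratio pseudocount.
#' @param alpha test level for flags.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return `mblink_config` list.
#' @export
pipeline_config <- function(rarefaction_depth = 54000,
                            filter_total_min = 500, filter_mean_min = 3,
                            network_r_min = 0.5, network_p_max = 0.05,
                            louvain_restarts = 20,
                            philr_variant = "summed",
                            lasso_lambda = 3000, lasso_k = 5,
                            protest_n_perm = 10000,
                            permanova_n_perm = 999,
                            pseudocount = 1,
                            alpha = 0.05,
                            seed = 1) {
  structure(as.list(environment()), class = "mblink_config")
}

# PERMANOVA restricted to groups with n >= 2 (small categorical covariates
# such as marital status can have singleton levels).
permanova_covariate <- function(dm, groups, n_perm, seed) {
  tab <- table(groups)
  keep_levels <- names(tab)[tab >= 2]
  if (length(keep_levels) < 2) return(list(pseudo_F = NA_real_, p = NA_real_))
  keep <- groups %in% keep_levels
  permanova(dm[keep, keep, drop = FALSE], groups[keep], n_perm, seed)
}

#' Run the full paired microbiome-lipidome analysis
#'
#' Stages: rarefaction; Faith's PD with Kruskal-Wallis group tests and
#' socioeconomic regressions; unweighted UniFrac + PCoA + PERMANOVA (IBS
#' status, subtype group, income, marital status); HFCS ANOVA + Dunn;
#' rare-taxon filter + CLR; ANCOM (status and subtype) + LEfSe; taxon-lipid
#' co-occurrence network, Louvain modules, module Kruskal-Wallis; balance
#' basis + transform + LASSO selection vs HFCS; lipid panel statistics;
#' Bray-Curtis PROTEST of microbiome vs lipidome.
#'
#' @param input list with `counts`, `tree`, `lipids`, `metadata` (objects,
#'   or file paths which are read with the package readers).
#' @param config from [pipeline_config()].
#' @param output_dir optional directory for stage TSVs, `summary.json` and
#'   `manifest.json`.
#' @return `mblink_report` list of per-stage results plus `summary`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         output_dir = NULL) {
  if (is.character(input$counts)) input$counts <-
      read_feature_table(input$counts)
  if (is.character(input$tree)) input$tree <- read_newick(input$tree)
  if (is.character(input$lipids)) input$lipids <-
      read_lipid_panel(input$lipids)
  if (is.character(input$metadata)) input$metadata <-
      read_sample_metadata(input$metadata)
  counts <- input$counts; tree <- input$tree
  lipids <- input$lipids; metadata <- input$metadata

  seeds <- derive_seeds(config$seed, 10L)

  # --- rarefaction -------------------------------------------------------
  rare <- rarefy(counts, config$rarefaction_depth, seeds[1])
  metadata <- metadata[metadata$sample_id %in% rownames(rare), , drop = FALSE]
  rare <- rare[metadata$sample_id, , drop = FALSE]
  lipids_al <- lipids[metadata$sample_id, , drop = FALSE]
  groups <- metadata$group
  status <- metadata$ibs_status

  # --- alpha diversity ---------------------------------------------------
  pd <- faiths_pd(rare, tree)
  alpha_div <- list(
    faiths_pd = pd,
    kw_subtype = kruskal_wallis(pd, groups),
    kw_status = kruskal_wallis(pd, status),
    mean_ibs = mean(pd[status == "IBS"]),
    mean_control = mean(pd[status == "Control"]),
    reg_alcohol = alpha_regression(pd, metadata$alcohol),
    reg_occupants = alpha_regression(pd, metadata$occupants),
    kw_income = kruskal_wallis(pd, metadata$income_bracket),
    kw_marital = kruskal_wallis(pd, metadata$marital_status))

  # --- beta diversity ----------------------------------------------------
  uf <- unweighted_unifrac(rare, tree)
  ord <- pcoa(uf)
  beta <- list(
    unifrac = uf, pcoa = ord,
    permanova_status = permanova(uf, status, config$permanova_n_perm,
                                 seeds[2]),
    permanova_subtype = permanova(uf, groups, config$permanova_n_perm,
                                  seeds[3]),
    permanova_income = permanova_covariate(uf, metadata$income_bracket,
                                           config$permanova_n_perm, seeds[4]),
    permanova_marital = permanova_covariate(uf, metadata$marital_status,
                                            config$permanova_n_perm,
                                            seeds[5]))

  # --- HFCS by group -----------------------------------------------------
  hfcs_test <- anova_dunn(metadata$hfcs_monthly, groups)

  # --- differential abundance -------------------------------------------
  filt <- filter_rare_taxa(rare, config$filter_total_min,
                           config$filter_mean_min)
  clr <- clr_transform(filt, config$pseudocount)
  ancom_status <- ancom(filt, status, config$alpha,
                        pseudocount = config$pseudocount)
  ancom_subtype <- ancom(filt, groups, config$alpha,
                         pseudocount = config$pseudocount)
  rel_filt <- filt / rowSums(filt)
  lefse_status <- lefse(rel_filt, status, config$alpha, seed = seeds[6])
  cd <- groups %in% c("IBS-C", "IBS-D")
  lefse_cd <- lefse(rel_filt[cd, , drop = FALSE], droplevels(groups[cd]),
                    config$alpha, seed = seeds[7])

  # --- co-occurrence network --------------------------------------------
  feats <- cbind(clr, lipids_al)
  kind <- setNames(c(rep("taxon", ncol(clr)), rep("lipid", ncol(lipids_al))),
                   colnames(feats))
  pear <- pairwise_pearson(feats)
  graph <- build_graph(pear$r, pear$p, config$network_r_min,
                       config$network_p_max, kind)
  partition <- louvain(graph, seeds[8], config$louvain_restarts)
  mod_ab <- module_abundances(filt, partition)
  network <- list(
    graph = graph, partition = partition, module_abundances = mod_ab,
    test_status = module_group_test(mod_ab, status),
    test_subtype = module_group_test(mod_ab, groups))

  # --- balances + LASSO --------------------------------------------------
  basis <- build_balance_basis(tree)
  balances <- philr_transform(rare, basis, config$pseudocount,
                              config$philr_variant)
  lasso_sel <- select_top_balances(balances, metadata$hfcs_monthly,
                                   config$lasso_lambda, config$lasso_k)

  # --- lipid statistics --------------------------------------------------
  lipid_tests <- lipid_group_tests(lipids_al, metadata, config$alpha)
  zprof <- z_profile(lipids_al, metadata)

  # --- PROTEST -----------------------------------------------------------
  pro <- protest(bray_curtis(rel_filt), bray_curtis(lipids_al),
                 config$protest_n_perm, seeds[9])

  summary <- list(
    n_samples = nrow(rare), n_taxa = ncol(rare),
    n_taxa_filtered = ncol(filt),
    faiths_pd_mean_ibs = alpha_div$mean_ibs,
    faiths_pd_mean_control = alpha_div$mean_control,
    alpha_kw_subtype_H = alpha_div$kw_subtype$H,
    alpha_kw_subtype_p = alpha_div$kw_subtype$p,
    pc1_percent = 100 * ord$proportion_explained[1],
    pc2_percent = 100 * ord$proportion_explained[2],
    permanova_status_F = beta$permanova_status$pseudo_F,
    permanova_status_p = beta$permanova_status$p,
    permanova_subtype_F = beta$permanova_subtype$pseudo_F,
    permanova_subtype_p = beta$permanova_subtype$p,
    permanova_income_F = beta$permanova_income$pseudo_F,
    permanova_income_p = beta$permanova_income$p,
    permanova_marital_F = beta$permanova_marital$pseudo_F,
    permanova_marital_p = beta$permanova_marital$p,
    hfcs_anova_F = hfcs_test$F, hfcs_anova_p = hfcs_test$p,
    ancom_status_max_W = max(ancom_status$W),
    ancom_status_m_minus_1 = ancom_status$m - 1L,
    ancom_subtype_max_W = max(ancom_subtype$W),
    ancom_n_flagged_status = sum(ancom_status$flag),
    lefse_n_status = nrow(lefse_status),
    n_modules = length(unique(partition$membership)),
    module_min_p_status = min(network$test_status$p),
    module_best_H_status =
      network$test_status$H[which.min(network$test_status$p)],
    module_min_p_subtype = min(network$test_subtype$p),
    module_best_H_subtype =
      network$test_subtype$H[which.min(network$test_subtype$p)],
    lasso_selected = lasso_sel$selected,
    lasso_adj_r2 = lasso_sel$adj_r_squared,
    lasso_F = lasso_sel$F, lasso_p = lasso_sel$p,
    n_lipids_sig_mw = sum(lipid_tests$sig_mw),
    max_abs_log2fc = max(abs(lipid_tests$log2fc)),
    protest_m2 = pro$m2,
    protest_p_better = pro$p_better,
    protest_p_conventional = pro$p_conventional)

  report <- structure(list(
    alpha = alpha_div, beta = beta, hfcs = hfcs_test,
    ancom_status = ancom_status, ancom_subtype = ancom_subtype,
    lefse_status = lefse_status, lefse_cd = lefse_cd,
    network = network, basis = basis, lasso = lasso_sel,
    lipid_tests = lipid_tests, z_profile = zprof, protest = pro,
    summary = summary,
    manifest = list(config = unclass(config), stage_seeds = seeds,
                    r_version = as.character(getRversion()),
                    package_version =
                      as.character(utils::packageVersion("mblink")))),
    class = "mblink_report")

  if (!is.null(output_dir)) write_report(report, rare, output_dir)
  report
}

# Persist stage outputs: TSVs for tables/matrices, JSON for the summary
# and manifest.
write_report <- function(report, rare, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  fp <- function(f) file.path(output_dir, f)
  write_feature_table(rare, fp("rarefied_table.tsv"))
  write.table(data.frame(sample_id = names(report$alpha$faiths_pd),
                         faiths_pd = report$alpha$faiths_pd),
              fp("faiths_pd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_distance_matrix(report$beta$unifrac, fp("unifrac.tsv"))
  ord <- report$beta$pcoa
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE),
              fp("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  anc <- data.frame(taxon = names(report$ancom_status$W),
                    W_status = as.integer(report$ancom_status$W),
                    flag_status = report$ancom_status$flag,
                    W_subtype = as.integer(report$ancom_subtype$W),
                    flag_subtype = report$ancom_subtype$flag)
  write.table(anc, fp("ancom.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$lefse_status, fp("lefse_status.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_graph(report$network$graph, report$network$partition,
              fp("network_edges.tsv"), fp("network_membership.tsv"))
  write.table(report$network$test_status, fp("module_tests_status.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$network$test_subtype, fp("module_tests_subtype.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_balance_basis(report$basis, fp("balances.tsv"))
  write.table(report$lipid_tests, fp("lipid_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(group = rownames(report$z_profile),
                         report$z_profile, check.names = FALSE),
              fp("lipid_z_profile.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_protest_null(report$protest, fp("protest_null.tsv"))
  jsonlite::write_json(report$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
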