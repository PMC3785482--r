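#' Write a simulated study to disk as plain-text artifacts
#'
#' Generates a study with [generate_study()] and
#' [generate_signed_gene_sets()] and writes the intensity and call
#' matrices, design table, probeset annotation, signed GMT collection,
#' truth tables and a manifest to a directory. Runs with the same
#' configuration (including seed) produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the study list from [generate_study()] with the
#'   gene-set element attached.
#' @export
simulate_study_files <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config)
  gs <- generate_signed_gene_sets(study$truth, config)
  write_intensity_matrix(study$expr,
                         file.path(out_dir, "intensity.tsv"),
                         file.path(out_dir, "calls.tsv"))
  write_design_table(study$design, file.path(out_dir, "design.tsv"))
  write_probe_gene_map(study$map, file.path(out_dir, "annotation.tsv"))
  write_signed_gene_sets(gs$sets, file.path(out_dir, "gene_sets.gmt"))
  truth_sets <- data.frame(
    name = vapply(gs$sets, `[[`, character(1), "name"),
    enriched = gs$enriched)
  write_results_tables(list(truth_genes = study$truth$genes,
                            truth_sets = truth_sets), out_dir)
  .write_manifest(out_dir, config)
  study$gene_sets <- gs
  invisible(study)
}

.write_manifest <- function(out_dir, config, extra = list()) {
  cfg <- unclass(config)
  kv <- c(
    vapply(names(cfg), function(k)
      sprintf("config.%s=%s", k, paste(format(cfg[[k]], digits = 15),
                                       collapse = ",")), character(1)),
    vapply(names(extra), function(k)
      sprintf("%s=%s", k, paste(format(extra[[k]], digits = 15),
                                collapse = ",")), character(1))
  )
  files <- setdiff(sort(list.files(out_dir)), "MANIFEST.txt")
  sums <- tools::md5sum(file.path(out_dir, files))
  kv <- c(kv, sprintf("md5.%s=%s", files, unname(sums)))
  writeLines(sort(kv), file.path(out_dir, "MANIFEST.txt"))
  invisible(file.path(out_dir, "MANIFEST.txt"))
}

#' Run the full enrichment pipeline on a study
#'
#' Executes, in order: chip QC and outlier/tissue-swap screening (flagged
#' samples are dropped), 75th-percentile normalization, probeset-to-gene
#' collapse, the developmental branch (z-standardization of baseline
#' samples, the S-squared variation filter, seeded profile clustering), the
#' treatment-response branch (per-tissue two-way ANOVA selections, overlap
#' statistics, ratio profiles, regulated-KS screening of the gene-set
#' collection against the 12 h hippocampal log2-ratio profile by default,
#' membership matrix and pathway-relevant intersection), and the nested
#' NBQX branch (per-tissue thresholds, epileptogenic set, Fisher-exact
#' screening). All tables plus a reproducibility manifest are written to
#' \code{out_dir}.
#'
#' @param study a study list as returned by [generate_study()] (elements
#'   \code{expr}, \code{design}, \code{map}); \code{NULL} simulates one
#'   from \code{config}.
#' @param collection list of [gene_set()] objects; \code{NULL} generates
#'   them from the study truth.
#' @param config a [sim_config()] used when simulating and recorded in the
#'   manifest.
#' @param out_dir output directory.
#' @param n_perm permutations per null shape in the KS screening.
#' @param seed seed for permutation draws and display clustering.
#' @param enrich_tissue,enrich_time_h profile used for the KS screening
#'   (defaults: hippocampus at 12 h, the point of maximum transcriptional
#'   modulation).
#' @param hs_threshold threshold_spec for the treatment-response ANOVA
#'   (default FDR 0.25).
#' @param nbqx_thresholds named list of per-tissue threshold_specs for the
#'   NBQX arm (defaults: hippocampus FDR 0.25; cortex raw P 0.01).
#' @param fdr_max,c_min gene-set selection thresholds (defaults 0.25, 2).
#' @param n_top genes kept by the variation filter (default 1000).
#' @return Invisibly, a list with every stage's result tables.
#' @export
run_pipeline <- function(study = NULL, collection = NULL,
                         config = sim_config(), out_dir,
                         n_perm = 2000, seed = 1,
                         enrich_tissue = "hippocampus", enrich_time_h = 12,
                         hs_threshold = list(mode = "fdr", value = 0.25),
                         nbqx_thresholds = list(
                           hippocampus = list(mode = "fdr", value = 0.25),
                           cortex = list(mode = "raw_p", value = 0.01)),
                         fdr_max = 0.25, c_min = 2, n_top = 1000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) study <- generate_study(config)
  if (is.null(collection)) {
    gs <- generate_signed_gene_sets(study$truth, config)
    collection <- gs$sets
  }
  expr <- study$expr
  design <- study$design

  ## QC and sample screening
  qc <- chip_qc_summary(expr)
  flags <- flag_outliers(qc, expr, design)
  drop <- flags$sample_id[flags$summary_outlier | flags$tissue_swap]
  if (length(drop) > 0) {
    message(sprintf("dropping %d flagged sample(s)", length(drop)))
    keep <- setdiff(colnames(expr$intensity), drop)
    expr <- expr_matrix(expr$intensity[, keep], expr$calls[, keep])
    design <- design[design$sample_id %in% keep, ]
  }

  ## normalization and gene collapse
  norm <- normalize_to_common_percentile(expr)
  gene_mat <- collapse_to_genes(norm$expr, study$map)

  ## developmental branch: baseline samples only
  base_ids <- design$sample_id[design$treatment == "noHS"]
  z <- standardize_genes(gene_mat, base_ids)
  s2 <- variation_statistic(gene_mat[, base_ids, drop = FALSE])
  top <- top_variable_genes(s2, min(n_top, length(s2)))
  clust <- cluster_gene_profiles(z[top, , drop = FALSE],
                                 n_clusters = min(5, length(top)),
                                 seed = seed)

  ## treatment-response branch
  tissues <- unique(design$tissue)
  hs_sets <- lapply(stats::setNames(tissues, tissues), function(t)
    select_response_set(norm$expr, study$map, design, t,
                        c("noHS", "HS"), hs_threshold)$genes)
  hs_algebra <- if (length(tissues) == 2) {
    set_algebra(hs_sets[[1]], hs_sets[[2]])
  } else {
    set_algebra(hs_sets[[1]], hs_sets[[1]])
  }
  hs_overlap <- overlap_statistics(hs_algebra$n_a, hs_algebra$n_b,
                                   nrow(gene_mat),
                                   hs_algebra$n_intersection)
  ratios <- lapply(stats::setNames(tissues, tissues), function(t)
    ratio_profile(norm$expr, study$map, design, "noHS", "HS", t))
  rt <- ratios[[enrich_tissue]]
  rt <- rt[rt$time_h == enrich_time_h, ]
  profile <- stats::setNames(rt$log2_ratio, rt$gene)
  profile <- profile[rownames(gene_mat)[rownames(gene_mat) %in%
                                          names(profile)]]
  enrichment <- screen_collection(profile, collection, fdr_max = fdr_max,
                                  c_min = c_min, n_perm = n_perm,
                                  seed = seed)
  membership <- build_membership_matrix(enrichment, min_sets = 2,
                                        seed = seed)
  pathway_genes <- pathway_relevant_intersection(colnames(membership$matrix),
                                                 hs_algebra$union)

  ## NBQX branch
  nbqx_sets <- lapply(stats::setNames(tissues, tissues), function(t)
    select_response_set(norm$expr, study$map, design, t,
                        c("HS", "HS_NBQX"),
                        nbqx_thresholds[[t]] %||%
                          list(mode = "fdr", value = 0.25))$genes)
  epi <- derive_epileptogenic_set(hs_sets, nbqx_sets)
  fisher <- fisher_screen(collection, epi$gene, nrow(gene_mat))

  ## serialize
  memb_df <- data.frame(name = rownames(membership$matrix),
                        membership$matrix * 1L, check.names = FALSE)
  write_results_tables(list(
    qc_summary = qc,
    qc_flags = flags,
    scale_factors = norm$factors,
    developmental_order = data.frame(
      gene = clust$order,
      cluster = unname(clust$cluster[clust$order]),
      s2 = unname(s2[clust$order])),
    hs_response_set = data.frame(gene = hs_algebra$union),
    hs_overlap = hs_overlap,
    enrichment = enrichment,
    membership_matrix = memb_df,
    pathway_relevant_genes = data.frame(gene = pathway_genes),
    epileptogenic_set = epi,
    fisher_enrichment = fisher
  ), out_dir)
  for (t in tissues) {
    write_results_tables(stats::setNames(
      list(ratios[[t]]), paste0("ratios_", t)), out_dir)
  }
  .write_manifest(out_dir, config, extra = list(
    n_perm = n_perm, seed = seed,
    enrich_tissue = enrich_tissue, enrich_time_h = enrich_time_h,
    hs_threshold = paste(hs_threshold$mode, hs_threshold$value),
    fdr_max = fdr_max, c_min = c_min, n_top = n_top))

  invisible(list(qc = qc, flags = flags, factors = norm$factors,
                 gene_matrix = gene_mat, clustering = clust,
                 hs_sets = hs_sets, hs_algebra = hs_algebra,
                 hs_overlap = hs_overlap, ratios = ratios,
                 profile = profile, enrichment = enrichment,
                 membership = membership, pathway_genes = pathway_genes,
                 nbqx_sets = nbqx_sets, epileptogenic = epi,
                 fisher = fisher))
}
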