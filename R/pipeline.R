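## End-to-end orchestration of the cohort analysis stages.

#' Run the full cohort analysis pipeline
#'
#' Either analyzes provided inputs (`catalog`, `meta`, `segments`, pathway
#' list) or simulates a cohort from a `simulate` block, then runs every
#' stage in the order of the study: spectrum and mutation load, sign and
#' Kruskal-Wallis tests, arm-density permutation test, multivariable load
#' regression, signature refit (and optionally de novo extraction), the VAF
#' clonality scan, pathway burden + diversity, and SCA summaries. Writes all
#' stage tables as TSV plus a machine-readable `summary.json`.
#'
#' @param config A list (or YAML file path) with components:
#'   `simulate` (arguments for [cohort_truth]) or `inputs` (paths: `catalog`,
#'   `covariates`, `pathways` (GMT), `segments`); optional `thresholds`
#'   (`vaf_grid`, `pathway_fdr`, `gene_fdr`, `min_snv`), `extract_denovo`
#'   (logical), `seed`, `outdir`.
#' @return Invisibly, a list with every stage result (also serialized under
#'   `outdir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config needs either a 'simulate' block or an 'inputs' block")
  }
  outdir <- config$outdir %||% "pipeline_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  th <- utils::modifyList(
    list(vaf_grid = seq(0.05, 0.50, by = 0.05), vaf_headline = 0.3,
         pathway_fdr = 0.2, gene_fdr = 0.1, min_snv = 50L),
    config$thresholds %||% list()
  )
  arm_table <- load_arm_table()
  reference <- make_reference_signatures()

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- sim$seed %||% seed
    truth <- cohort_truth_from_config(sim)
    gene_table <- synthetic_gene_table()
    pathways <- synthetic_pathways(gene_table)
    cohort <- generate_cohort(truth, pathways, reference, gene_table,
                              arm_table)
    catalog <- cohort$catalog; meta <- cohort$meta
    segments <- cohort$segments
    write_truth(truth, file.path(outdir, "truth.json"))
    write_catalog(catalog, file.path(outdir, "catalog.tsv"))
    write_covariates(meta, file.path(outdir, "covariates.tsv"))
    write_gmt(pathways, file.path(outdir, "pathways.gmt"))
    write_segments(segments, file.path(outdir, "segments.tsv"))
  } else {
    inp <- config$inputs
    meta <- read_covariates(inp$covariates)
    catalog <- read_catalog(inp$catalog, meta)
    pathways <- read_gmt(inp$pathways)
    segments <- if (!is.null(inp$segments)) read_segments(inp$segments)
      else NULL
  }
  grp <- meta$nsaid_user

  ## spectrum & load
  spectrum <- build_spectrum(catalog, meta)
  write_spectrum(spectrum, file.path(outdir, "spectrum.tsv"))
  load_all <- mutation_load(catalog, meta, "all")
  load_fun <- mutation_load(catalog, meta, "functional")
  med_diff <- apply(spectrum[!grp, , drop = FALSE], 2L, stats::median) -
    apply(spectrum[grp, , drop = FALSE], 2L, stats::median)
  tests <- list(
    sign_96 = sign_test(med_diff),
    kw_total_load = kruskal_wallis(load_all$n[grp], load_all$n[!grp]),
    kw_functional_load = kruskal_wallis(load_fun$n[grp], load_fun$n[!grp])
  )
  density <- arm_density_table(catalog, arm_table, meta)
  tests$arm_density_perm <-
    group_effect_on_arm_density(density, meta, n_perm = 2000L, seed = seed)
  covs <- meta[c("nsaid_user", "ever_smoker", "tp53_mutant")]
  covs <- covs[vapply(covs, function(x) length(unique(x)) > 1L, logical(1))]
  lm_tab <- multivariable_lm(load_all$n, covs)

  ## signatures
  refit <- refit_cohort(spectrum, reference, min_snv = th$min_snv)
  sig_reg <- signature_load_regression(
    refit$assigned_counts, meta,
    intersect(c("nsaid_user", "ever_smoker"), names(covs)))
  pct_contrib <- 100 * colSums(refit$assigned_counts) /
    max(sum(refit$assigned_counts), 1)
  top_sigs <- names(pct_contrib)[pct_contrib >= 5]
  denovo <- NULL
  if (isTRUE(config$extract_denovo)) {
    denovo <- extract_signatures_nmf(spectrum, k_range = 1:4, seed = seed)
  }

  ## clonality
  diploid <- if (!is.null(segments)) {
    filter_diploid(catalog, segments)
  } else {
    catalog
  }
  scan_fun <- vaf_threshold_scan(diploid, meta, th$vaf_grid, "functional")
  scan_non <- vaf_threshold_scan(diploid, meta, th$vaf_grid, "nonfunctional")
  headline <- count_high_vaf(diploid, meta, th$vaf_headline, "functional")
  tests$kw_high_vaf_functional <-
    kruskal_wallis(headline$n_above[grp], headline$n_above[!grp])

  ## pathways & diversity
  burden <- assign_mutations_to_pathways(catalog, meta, pathways)
  pw_fun <- pathway_burden_test(burden, meta, "functional", th$pathway_fdr)
  pw_non <- pathway_burden_test(burden, meta, "nonfunctional", th$pathway_fdr)
  genes <- gene_burden_test(catalog, meta, fdr = th$gene_fdr)
  sig_pw <- pw_fun$pathway[pw_fun$significant]
  div_sig <- if (length(sig_pw) >= 1) {
    diversity_group_test(burden, meta, subset = sig_pw)
  } else {
    NULL
  }
  div_rest <- diversity_group_test(
    burden, meta, subset = setdiff(pw_fun$pathway, sig_pw))

  ## SCA
  sca <- NULL
  if (!is.null(segments)) {
    sca_load <- arm_sca_load(segments, arm_table, meta)
    tests$focal_amp_fisher <- focal_amp_prevalence_test(segments, meta)
    wgd <- vapply(meta$patient_id, function(p) {
      isTRUE(genome_doubling_flag(
        segments[segments$patient_id == p, , drop = FALSE], arm_table))
    }, logical(1))
    sca <- list(load = sca_load, wgd = wgd)
    utils::write.table(sca_load, file.path(outdir, "sca_arm_load.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## serialize
  utils::write.table(test_results_table(tests),
                     file.path(outdir, "tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pw_fun, file.path(outdir, "pathway_burden_functional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pw_non,
                     file.path(outdir, "pathway_burden_nonfunctional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan_fun, file.path(outdir, "vaf_scan_functional.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lm_tab, file.path(outdir, "load_regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sig_reg, file.path(outdir, "signature_regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(div_sig)) {
    utils::write.table(div_sig$si, file.path(outdir, "diversity_si.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = seed,
    n_patients = nrow(meta),
    n_mutations = nrow(catalog),
    mean_snvs_user = mean(mutation_load(catalog, meta, "snv")$n[grp]),
    mean_snvs_nonuser = mean(mutation_load(catalog, meta, "snv")$n[!grp]),
    median_mut_per_mb_user = stats::median(load_all$load_per_mb[grp]),
    median_mut_per_mb_nonuser = stats::median(load_all$load_per_mb[!grp]),
    sign_test_p = tests$sign_96$p_value,
    kw_total_load_p = tests$kw_total_load$p_value,
    top_signatures = as.list(round(pct_contrib[top_sigs], 2)),
    n_significant_pathways = length(sig_pw),
    mean_pathway_reduction_pct =
      mean(pw_fun$reduction_pct[pw_fun$significant]),
    diversity_p_significant_set =
      if (!is.null(div_sig)) div_sig$test$p_value else NA,
    focal_amp_fisher_p =
      if (!is.null(sca)) tests$focal_amp_fisher$p_value else NA,
    n_wgd_user = if (!is.null(sca)) sum(sca$wgd & grp) else NA,
    n_wgd_nonuser = if (!is.null(sca)) sum(sca$wgd & !grp) else NA
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    catalog = catalog, meta = meta, segments = segments,
    spectrum = spectrum, tests = tests, lm = lm_tab,
    refit = refit, signature_regression = sig_reg, denovo = denovo,
    vaf_scan = list(functional = scan_fun, nonfunctional = scan_non),
    burden = burden, pathway_tests = list(functional = pw_fun,
                                          nonfunctional = pw_non),
    gene_tests = genes,
    diversity = list(significant = div_sig, rest = div_rest),
    sca = sca, summary = summary
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
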