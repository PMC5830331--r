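test_that("mutations link to genes within 1 kb and to every containing pathway", {
  meta <- data.frame(patient_id = "P1", nsaid_user = TRUE,
                     ever_smoker = FALSE, tp53_mutant = FALSE, target_mb = 10)
  gi <- data.frame(gene = c("GA", "GB"), chrom = "chr1",
                   start = c(10000L, 50000L), end = c(12000L, 53000L))
  pw <- list(PW1 = c("GA"), PW2 = c("GA", "GB"))
  mk <- function(pos) {
    d <- data.frame(patient_id = "P1", chrom = "chr1", pos = pos,
                    ref = "C", alt = "T", mut_type = "SNV", context3 = "ACG",
                    vaf = 0.2, category = "exon-non-synonymous",
                    stringsAsFactors = FALSE)
    d$genes <- replicate(length(pos), character(0), simplify = FALSE)
    d
  }
  # 800 bp upstream of GA (gene starts at 0-based 10000 -> 1-based 10001)
  b1 <- assign_mutations_to_pathways(mk(10001L - 800L), meta, pw,
                                     gene_intervals = gi)
  expect_identical(unname(b1$functional["P1", ]), c(1L, 1L))

  # 1500 bp upstream: outside the window
  b2 <- assign_mutations_to_pathways(mk(10001L - 1500L), meta, pw,
                                     gene_intervals = gi)
  expect_identical(unname(b2$functional["P1", ]), c(0L, 0L))

  # GA sits in both pathways: one mutation increments both burdens
  b3 <- assign_mutations_to_pathways(mk(11000L), meta, pw,
                                     gene_intervals = gi)
  expect_identical(unname(b3$functional["P1", ]), c(1L, 1L))

  # a pathway gene with no interval is skipped with a warning
  pw2 <- list(PW1 = c("GA", "GZ"))
  expect_warning(assign_mutations_to_pathways(mk(11000L), meta, pw2,
                                              gene_intervals = gi),
                 "no interval")
})

test_that("interval-based and genes-column assignment agree on generated cohorts", {
  sc <- small_cohort(seed = 41)
  co <- sc$cohort
  b_genes <- assign_mutations_to_pathways(co$catalog, co$meta, sc$pathways)
  b_iv <- assign_mutations_to_pathways(co$catalog, co$meta, sc$pathways,
                                       gene_intervals = sc$gene_table)
  expect_identical(b_genes$functional, b_iv$functional)
  expect_identical(b_genes$nonfunctional, b_iv$nonfunctional)
})

test_that("burden counts at least the pathway-assigned mutations (conservation)", {
  sc <- small_cohort(seed = 43)
  co <- sc$cohort
  b <- assign_mutations_to_pathways(co$catalog, co$meta, sc$pathways)
  pw_genes <- unique(unlist(sc$pathways))
  hits_any <- vapply(co$catalog$genes,
                     function(g) any(g %in% pw_genes), logical(1))
  per_patient <- table(factor(co$catalog$patient_id[hits_any],
                              levels = co$meta$patient_id))
  total <- rowSums(b$functional) + rowSums(b$nonfunctional)
  expect_true(all(total >= as.integer(per_patient)))
})

test_that("pathway burden test reports Table-1-style summaries", {
  sc <- small_cohort(seed = 47)
  co <- sc$cohort
  b <- assign_mutations_to_pathways(co$catalog, co$meta, sc$pathways)
  res <- pathway_burden_test(b, co$meta, "functional", fdr = 0.2)
  expect_identical(res$pathway, names(sc$pathways))
  expect_equal(res$reduction_pct,
               100 * (1 - res$mean_user / res$mean_nonuser))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-12))

  # identical groups: constant-count pathways give p = 1
  b0 <- b
  b0$functional[] <- 2L
  res0 <- pathway_burden_test(b0, co$meta, "functional")
  expect_true(all(res0$p >= 0.9))
})

test_that("gene burden testing applies the carrier threshold", {
  n <- 12L
  meta <- data.frame(patient_id = sprintf("P%02d", 1:n),
                     nsaid_user = rep(c(TRUE, FALSE), each = n / 2),
                     ever_smoker = FALSE, tp53_mutant = FALSE, target_mb = 10)
  mk_cat <- function(patients, gene) {
    d <- data.frame(patient_id = patients, chrom = "chr1",
                    pos = seq_along(patients) * 1000L,
                    ref = "C", alt = "T", mut_type = "SNV", context3 = "ACG",
                    vaf = 0.2, category = "exon-non-synonymous",
                    stringsAsFactors = FALSE)
    d$genes <- replicate(length(patients), gene, simplify = FALSE)
    d
  }
  # GLOW: 4 user + 4 non-user carriers -> below threshold, not tested
  # GHIT: 5 user carriers -> tested
  cat <- rbind(mk_cat(meta$patient_id[c(1:4, 7:10)], "GLOW"),
               mk_cat(meta$patient_id[1:5], "GHIT"))
  res <- gene_burden_test(cat, meta, min_carriers = 5L, fdr = 0.1)
  expect_identical(res$gene, "GHIT")
  expect_identical(res$n_carriers_user, 5L)
})

test_that("percent reduction follows its definition", {
  expect_equal(percent_reduction(1, 2), 50)
  expect_equal(percent_reduction(0.83, 1.71), 100 * (1 - 0.83 / 1.71))
  expect_equal(percent_reduction(0.83, 1.71), 51.46, tolerance = 1e-3)
  expect_equal(percent_reduction(3.7, 3.7), 0)
  expect_true(is.na(percent_reduction(1, 0)))
})

test_that("the Shannon pathway index matches hand-computed cases and its bounds", {
  # uniform normalized burden over 9 pathways
  expect_equal(shannon_pathway_diversity(rep(3, 9), rep(10, 9)), log(9),
               tolerance = 1e-12)
  # point mass
  expect_equal(shannon_pathway_diversity(c(8, 0, 0), c(5, 5, 5)), 0)
  # genes (10, 20), counts (2, 2): p = (2/3, 1/3)
  expect_equal(shannon_pathway_diversity(c(2, 2), c(10, 20)),
               -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3),
               tolerance = 1e-12)
  expect_equal(shannon_pathway_diversity(c(2, 2), c(10, 20)), 0.6365,
               tolerance = 1e-4)
  # zero burden
  expect_equal(shannon_pathway_diversity(rep(0, 5), rep(10, 5)), 0)
  # scale invariance and bounds on random cases
  set.seed(53)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    counts <- rpois(k, 3)
    genes <- sample(5:50, k, replace = TRUE)
    si <- shannon_pathway_diversity(counts, genes)
    expect_gte(si, 0)
    expect_lte(si, log(k) + 1e-12)
    expect_equal(shannon_pathway_diversity(counts * 7, genes), si,
                 tolerance = 1e-12)
  }
})

test_that("diversity group test is Kruskal-Wallis on the per-patient SI", {
  sc <- small_cohort(seed = 59)
  co <- sc$cohort
  b <- assign_mutations_to_pathways(co$catalog, co$meta, sc$pathways)
  subset <- names(sc$pathways)[1:9]
  dt <- diversity_group_test(b, co$meta, subset = subset)
  si <- apply(b$functional, 1, shannon_pathway_diversity,
              genes_per_pathway = b$genes_per_pathway, subset = subset)
  kw <- kruskal_wallis(si[co$meta$nsaid_user], si[!co$meta$nsaid_user])
  expect_equal(dt$test$p_value, kw$p_value)
  expect_equal(dt$si$si, unname(si))
})
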