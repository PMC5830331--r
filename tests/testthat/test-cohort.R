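test_that("cohort truth validates its invariants", {
  expect_error(cohort_truth(load_mean_user = -1), "load_mean_user")
  expect_error(cohort_truth(purity = 1.2), "purity")
  expect_error(cohort_truth(pathway_effects = c(PW01 = 1.5)),
               "pathway_effects")
  tr <- cohort_truth(seed = 2L)
  expect_s3_class(tr, "cohort_truth")
  expect_length(tr$clone_prevalences, 82L)
  expect_true(all(vapply(tr$clone_prevalences,
                         function(m) all(m[, "prevalence"] > 0 &
                                           m[, "prevalence"] <= 1),
                         logical(1))))
  for (w in tr$signature_weights) expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("the generator is byte-identical under the same seed", {
  gt <- synthetic_gene_table(800L)
  pw <- synthetic_pathways(gt, sizes = c(rep(50L, 9L), 25L))
  truth <- cohort_truth(n_per_group = 6L, load_mean_user = 40,
                        load_sd_user = 15, load_mean_nonuser = 50,
                        load_sd_nonuser = 18, seed = 77L)
  a <- generate_cohort(truth, pw, gene_table = gt)
  b <- generate_cohort(truth, pw, gene_table = gt)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$meta, b$meta)
  expect_identical(a$segments, b$segments)

  # and a different seed changes the draw
  truth2 <- cohort_truth(n_per_group = 6L, load_mean_user = 40,
                         load_sd_user = 15, load_mean_nonuser = 50,
                         load_sd_nonuser = 18, seed = 78L)
  c <- generate_cohort(truth2, pw, gene_table = gt)
  expect_false(identical(a$catalog$pos, c$catalog$pos))
})

test_that("sample group means land near the configured study loads", {
  co <- generate_cohort(cohort_truth(seed = 101L))
  grp <- co$meta$nsaid_user
  snv <- mutation_load(co$catalog, co$meta, "snv")$n
  ind <- mutation_load(co$catalog, co$meta, "indel")$n
  se_u <- 209.69 / sqrt(41); se_n <- 362.68 / sqrt(41)
  expect_lt(abs(mean(snv[grp]) - 290.93), 3 * se_u)
  expect_lt(abs(mean(snv[!grp]) - 402.49), 3 * se_n)
  expect_lt(abs(mean(ind[grp]) - 17.95), 3 * 12.25 / sqrt(41))
  expect_lt(abs(mean(ind[!grp]) - 22.42), 3 * 13.77 / sqrt(41))
  # matched smoking: identical within pairs by construction
  expect_identical(co$meta$ever_smoker[grp], co$meta$ever_smoker[!grp])
})

test_that("catalog channel frequencies converge to the signature mixture", {
  ref <- make_reference_signatures()
  truth <- cohort_truth(
    n_per_group = 41L,
    load_mean_user = 1250, load_sd_user = 80,
    load_mean_nonuser = 1250, load_sd_nonuser = 80,
    smoking_prob = 0, # single stratum
    seed = 31L
  )
  co <- generate_cohort(truth, reference = ref)
  sp <- build_spectrum(co$catalog, co$meta)
  expect_gt(sum(sp), 1e5)
  mix <- as.numeric(ref %*% truth$signature_weights$never_smoker[colnames(ref)])
  emp <- colSums(sp) / sum(sp)
  tv <- 0.5 * sum(abs(emp - mix))
  expect_lt(tv, 0.02)
})

test_that("the user-specific pathway effect reduces functional hit probability as configured", {
  gt <- synthetic_gene_table()
  pw <- synthetic_pathways(gt)
  truth <- cohort_truth(load_mean_nonuser = 290.93,
                        load_sd_nonuser = 209.69, seed = 41L)
  co <- generate_cohort(truth, pw, gene_table = gt)
  affected <- unique(unlist(pw[names(truth$pathway_effects)]))
  func <- co$catalog[classify_functional(co$catalog$category) &
                       lengths(co$catalog$genes) > 0, ]
  in_aff <- vapply(func$genes, function(g) any(g %in% affected), logical(1))
  grp <- func$patient_id %in% co$meta$patient_id[co$meta$nsaid_user]
  p_user <- mean(in_aff[grp])
  p_non <- mean(in_aff[!grp])
  # conditional hit probability halves (binomial error margins)
  expect_lt(abs(p_user / p_non - 0.5), 0.08)
})

test_that("segment generation honors rates, produces non-overlap, and matches expected MB", {
  arm <- load_arm_table()
  set.seed(83)
  none <- generate_segments("P1", c(loss = 0, focal_amp = 0), arm)
  expect_identical(nrow(none), 0L)

  amp_only <- generate_segments("P2", c(focal_amp = 1), arm, wgd = FALSE)
  expect_true(all(amp_only$class == "focal_amp" | nrow(amp_only) == 0))

  # non-overlap within a patient
  set.seed(89)
  segs <- generate_segments("P3", c(loss = 4, cnLOH = 4, allele_gain = 4),
                            arm)
  by_chrom <- split(segs, segs$chrom)
  for (s in by_chrom) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }

  # Monte-Carlo mean MB against the closed-form expectation
  rates <- c(loss = 1.5, cnLOH = 1.0, HD = 0.2, focal_amp = 0.2)
  e_len_mb <- c(loss = exp(log(20) + 0.7^2 / 2),
                cnLOH = exp(log(20) + 0.7^2 / 2),
                HD = 1.1, focal_amp = 1.6)
  expected_mb <- sum(rates * e_len_mb[names(rates)])
  set.seed(97)
  total <- replicate(200, {
    s <- generate_segments("PX", rates, arm)
    if (nrow(s)) sum(s$end - s$start) / 1e6 else 0
  })
  expect_lt(abs(mean(total) - expected_mb) / expected_mb, 0.10)
})

test_that("focal amplifications appear only in the group configured with a positive rate", {
  truth <- cohort_truth(n_per_group = 15L, load_mean_user = 30,
                        load_sd_user = 12, load_mean_nonuser = 30,
                        load_sd_nonuser = 12,
                        sca_rates = data.frame(
                          class = c("HD", "loss", "cnLOH", "balanced_gain",
                                    "allele_gain", "focal_amp"),
                          user = c(0, 0, 0, 0, 0, 0),
                          nonuser = c(0, 0, 0, 0, 0, 1)),
                        wgd_prob_nonuser = 0,
                        seed = 51L)
  gt <- synthetic_gene_table(500L)
  co <- generate_cohort(truth, synthetic_pathways(gt, sizes = 25L),
                        gene_table = gt)
  amp_pat <- unique(co$segments$patient_id[co$segments$class == "focal_amp"])
  expect_gt(length(amp_pat), 0L)
  expect_true(all(amp_pat %in% co$meta$patient_id[!co$meta$nsaid_user]))
  # everything the users have is... nothing
  user_segs <- co$segments[co$segments$patient_id %in%
                             co$meta$patient_id[co$meta$nsaid_user], ]
  expect_identical(nrow(user_segs), 0L)
})

test_that("truth serializes to JSON and rebuilds from a config list", {
  tr <- cohort_truth(n_per_group = 3L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$load_mean_user, 290.93)
  expect_length(parsed$clone_prevalences, 6L)

  tr2 <- cohort_truth_from_config(list(n_per_group = 3L, seed = 7L))
  expect_identical(tr2$clone_prevalences, tr$clone_prevalences)
  expect_error(cohort_truth_from_config(list(bogus = 1)), "unknown")
})
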