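test_that("segment classification reproduces the six-class definitional table", {
  expect_identical(classify_segment(0L, 0L, 1e6), "HD")
  expect_identical(classify_segment(1L, 0L, 1e6), "loss")
  expect_identical(classify_segment(2L, 0L, 1e6), "cnLOH")
  expect_identical(classify_segment(2L, 1L, 1e6), "diploid")
  expect_identical(classify_segment(4L, 2L, 1e6), "balanced_gain")
  expect_identical(classify_segment(3L, 1L, 1e6), "allele_gain")
  expect_identical(classify_segment(8L, 1L, 1.5e6), "focal_amp")
  expect_identical(classify_segment(8L, 1L, 5e6), "allele_gain")
  expect_identical(classify_segment(6L, 3L, 5e6), "balanced_gain")
  # at ploidy 4 (post-doubling), 3 copies is a loss and 2 no longer cnLOH
  expect_identical(classify_segment(3L, 1L, 1e6, ploidy = 4L), "loss")
  expect_identical(classify_segment(8L, 1L, 1.5e6, ploidy = 4L), "focal_amp")
  expect_error(classify_segment(2L, 2L, 1e6), "minor")

  # totality: every lattice point gets exactly one known class
  grid <- expand.grid(total = 0:8, minor = 0:4, len = c(1e6, 5e6))
  grid <- grid[grid$minor <= grid$total / 2, ]
  cls <- classify_segment(grid$total, grid$minor, grid$len)
  expect_true(all(cls %in% c("HD", "loss", "cnLOH", "balanced_gain",
                             "allele_gain", "focal_amp", "diploid")))
  # unknown minor: only total-CN calls
  expect_identical(classify_segment(2L, NA_integer_, 1e6), "diploid")
  expect_identical(classify_segment(4L, NA_integer_, 9e6), "allele_gain")
})

test_that("noise-free tracks are segmented with exact breakpoints", {
  arm <- load_arm_table()
  arm1 <- arm[arm$chrom == "chr1", ]
  true_seg <- data.frame(chrom = "chr1", start = 30e6, end = 40e6,
                         total_cn = 1L, minor_cn = 0L)
  set.seed(61)
  track <- simulate_probe_track(true_seg, arm1, spacing_bp = 100000L,
                                lr_sd = 0, het_fraction = 0.4, baf_sd = 0)
  called <- segment_and_call(track, arm_table = arm1)
  chr1 <- called[called$chrom == "chr1", ]
  expect_identical(nrow(chr1), 3L)
  mid <- chr1[2, ]
  expect_identical(mid$total_cn, 1L)
  expect_identical(mid$minor_cn, 0L)
  expect_identical(mid$class, "loss")
  expect_equal(mid$start, 30e6)
  expect_equal(mid$end, 40e6)

  # noise-free cnLOH: flat log-ratio, BAF deviation carries the breakpoints
  true_loh <- data.frame(chrom = "chr1", start = 150e6, end = 170e6,
                         total_cn = 2L, minor_cn = 0L)
  track2 <- simulate_probe_track(true_loh, arm1, spacing_bp = 100000L,
                                 lr_sd = 0, het_fraction = 0.4, baf_sd = 0)
  called2 <- segment_and_call(track2, arm_table = arm1)
  expect_true(all(called2$total_cn == 2L))
  loh <- called2[called2$class == "cnLOH", ]
  expect_identical(nrow(loh), 1L)
  expect_lt(abs(loh$start - 150e6), 1e6)
  expect_lt(abs(loh$end - 170e6), 1e6)
})

test_that("BAF-shifted segments are classified cnLOH when log-ratio is informative", {
  arm <- load_arm_table()
  arm1 <- arm[arm$chrom %in% c("chr1", "chr2"), ]
  true_seg <- data.frame(
    chrom = c("chr1", "chr2"), start = c(30e6, 120e6), end = c(50e6, 140e6),
    total_cn = c(3L, 1L), minor_cn = c(1L, 0L)
  )
  set.seed(67)
  track <- simulate_probe_track(true_seg, arm1, spacing_bp = 100000L,
                                lr_sd = 0.05, het_fraction = 0.4,
                                baf_sd = 0.01)
  called <- segment_and_call(track, arm_table = arm1)
  gain <- called[called$chrom == "chr1" & called$start < 50e6 &
                   called$end > 30e6 & called$total_cn == 3L, ]
  expect_identical(unique(gain$class), "allele_gain")
  del <- called[called$chrom == "chr2" & called$total_cn == 1L, ]
  expect_identical(unique(del$class), "loss")
})

test_that("noisy tracks still classify at least 95% of bases correctly", {
  arm <- load_arm_table()
  arms <- arm[arm$chrom %in% paste0("chr", 1:4), ]
  true_seg <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr4"),
    start = c(20e6, 60e6, 100e6, 50e6, 80e6),
    end = c(25e6, 80e6, 110e6, 53e6, 100e6),
    total_cn = c(0L, 1L, 3L, 4L, 2L),
    minor_cn = c(0L, 0L, 1L, 2L, 0L)
  )
  set.seed(71)
  track <- simulate_probe_track(true_seg, arms, spacing_bp = 50000L,
                                lr_sd = 0.25, het_fraction = 0.3,
                                baf_sd = 0.03)
  called <- segment_and_call(track, arm_table = arms)
  # per-probe true vs called class
  true_cls <- classify_segment(track$true_total, track$true_minor,
                               rep(1e6, nrow(track)))
  called_cls <- rep("diploid", nrow(track))
  for (i in seq_len(nrow(called))) {
    hit <- track$chrom == called$chrom[i] & track$start >= called$start[i] &
      track$start < called$end[i]
    called_cls[hit] <- classify_segment(called$total_cn[i],
                                        called$minor_cn[i],
                                        called$end[i] - called$start[i])
  }
  expect_gt(mean(called_cls == true_cls), 0.95)
})

test_that("arm SCA loads are additive and invariant under segment splitting", {
  arm <- load_arm_table()
  segs <- data.frame(
    patient_id = "P1", chrom = "chr1", start = 10e6, end = 20e6,
    n_probes = NA_integer_, log_ratio = -1, total_cn = 1L, minor_cn = 0L,
    class = "loss", stringsAsFactors = FALSE
  )
  load1 <- arm_sca_load(segs, arm)
  expect_equal(load1$mb, 10)
  expect_equal(load1$n_per_mb, 1 / arm$length_mb[arm$chrom == "chr1" &
                                                   arm$arm == "p"])
  # split into two adjacent pieces: MB unchanged
  split <- rbind(segs, segs)
  split$end[1] <- 14e6; split$start[2] <- 14e6
  load2 <- arm_sca_load(split, arm)
  expect_equal(sum(load2$mb), sum(load1$mb))

  # a segment crossing the centromere lands in both arms
  cross <- segs
  cross$start <- 120e6; cross$end <- 130e6 # chr1 centromere at ~121.5-124.5
  loadc <- arm_sca_load(cross, arm)
  expect_identical(sort(loadc$arm), c("p", "q"))
  expect_lt(sum(loadc$mb), 10) # the centromeric gap itself is not counted

  # diploid-only input: nothing to report
  dip <- segs; dip$class <- "diploid"
  expect_identical(nrow(arm_sca_load(dip, arm)), 0L)
})

test_that("total SCA MB equals a brute-force overlap computation", {
  sc <- small_cohort(seed = 73)
  segs <- sc$cohort$segments
  arm <- load_arm_table()
  got <- sum(arm_sca_load(segs, arm)$mb)
  alt <- segs[segs$class != "diploid", ]
  manual <- 0
  for (i in seq_len(nrow(alt))) {
    for (j in seq_len(nrow(arm))) {
      if (alt$chrom[i] != arm$chrom[j]) next
      ov <- min(alt$end[i], arm$end[j]) - max(alt$start[i], arm$start[j])
      if (ov > 0) manual <- manual + ov / 1e6
    }
  }
  expect_equal(got, manual, tolerance = 1e-9)
})

test_that("genome doubling is flagged from major-CN territory", {
  arm <- load_arm_table()
  none <- data.frame(patient_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     n_probes = integer(0), log_ratio = numeric(0),
                     total_cn = integer(0), minor_cn = integer(0),
                     class = character(0))
  expect_false(genome_doubling_flag(none, arm))

  whole <- data.frame(patient_id = "P1", chrom = arm$chrom,
                      start = arm$start, end = arm$end,
                      n_probes = NA_integer_, log_ratio = 1,
                      total_cn = 4L, minor_cn = 2L, class = "balanced_gain",
                      stringsAsFactors = FALSE)
  expect_true(genome_doubling_flag(whole, arm))

  # 60% of the genome at major >= 2
  genome_bp <- sum(arm$end - arm$start)
  cum <- cumsum(as.numeric(arm$end - arm$start))
  k <- which(cum >= 0.6 * genome_bp)[1]
  part <- whole[seq_len(k), ]
  part$end[k] <- part$end[k] - (cum[k] - 0.6 * genome_bp)
  expect_true(genome_doubling_flag(part, arm))
})

test_that("focal amplification prevalence uses the exact Fisher contrast", {
  n <- 41L
  meta <- data.frame(patient_id = sprintf("P%02d", 1:(2 * n)),
                     nsaid_user = rep(c(TRUE, FALSE), each = n),
                     ever_smoker = FALSE, tp53_mutant = FALSE, target_mb = 100)
  amp_patients <- meta$patient_id[!meta$nsaid_user][1:8]
  segs <- data.frame(
    patient_id = amp_patients, chrom = "chr7", start = 55e6, end = 56e6,
    n_probes = NA_integer_, log_ratio = 2, total_cn = 8L, minor_cn = 1L,
    class = "focal_amp", stringsAsFactors = FALSE
  )
  r <- focal_amp_prevalence_test(segs, meta)
  expect_equal(r$p_value,
               oracle_fisher_p(matrix(c(0, 41, 8, 33), 2, byrow = TRUE)),
               tolerance = 1e-9)
  expect_identical(r$detail$nonuser_amp, 8L)

  r0 <- focal_amp_prevalence_test(segs[0, ], meta)
  expect_equal(r0$p_value, 1)
})
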