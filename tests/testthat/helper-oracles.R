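# Independent brute-force oracles and shared fixtures. The oracles never call
# the implementation they check.

# exact two-sided sign-test p: sum of binomial(0.5) point masses no larger
# than the observed one
oracle_sign_p <- function(n_pos, n_used) {
  if (n_used == 0L) return(1)
  probs <- stats::dbinom(0:n_used, n_used, 0.5)
  obs <- probs[n_pos + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# two-sided Fisher p by full hypergeometric enumeration over tables with the
# observed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# definitional BH step-up: reject the max k with p_(k) <= k * fdr / m
oracle_bh_rejected <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * fdr / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# reverse complement, written independently of the package's helper
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(s) paste(rev(comp[s]), collapse = ""),
         character(1))
}

# brute-force count of catalog mutations overlapping altered segments
oracle_overlap_count <- function(catalog, altered) {
  hit <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    for (j in seq_len(nrow(altered))) {
      if (catalog$patient_id[i] == altered$patient_id[j] &&
          catalog$chrom[i] == altered$chrom[j] &&
          catalog$pos[i] - 1L >= altered$start[j] &&
          catalog$pos[i] - 1L < altered$end[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

# a small, fast cohort for unit tests (reduced loads, fewer patients)
small_cohort <- function(seed = 5L, n_per_group = 10L) {
  truth <- cohort_truth(
    n_per_group = n_per_group,
    load_mean_user = 60, load_sd_user = 25,
    load_mean_nonuser = 80, load_sd_nonuser = 30,
    indel_mean_user = 4, indel_sd_user = 3,
    indel_mean_nonuser = 5, indel_sd_nonuser = 3.5,
    seed = seed
  )
  gene_table <- synthetic_gene_table(1000L)
  pathways <- synthetic_pathways(gene_table, sizes = c(rep(60L, 9L), 30L))
  list(
    cohort = generate_cohort(truth, pathways, gene_table = gene_table),
    pathways = pathways, gene_table = gene_table
  )
}

# a fully null truth: identical group parameters everywhere
null_truth <- function(seed, n_per_group = 41L) {
  cohort_truth(
    n_per_group = n_per_group,
    load_mean_nonuser = 290.93, load_sd_nonuser = 209.69,
    indel_mean_nonuser = 17.95, indel_sd_nonuser = 12.25,
    tp53_prob_nonuser = 6 / 41,
    clone_prev_shapes = list(
      user = rbind(c(3, 6), c(2.5, 7.5), c(1.5, 8.5)),
      nonuser = rbind(c(3, 6), c(2.5, 7.5), c(1.5, 8.5))
    ),
    pathway_effects = stats::setNames(numeric(0), character(0)),
    sca_rates = data.frame(
      class = c("HD", "loss", "cnLOH", "balanced_gain", "allele_gain",
                "focal_amp"),
      user = c(0.3, 2.5, 2.5, 0.8, 2.2, 0.217),
      nonuser = c(0.3, 2.5, 2.5, 0.8, 2.2, 0.217)
    ),
    wgd_prob_user = 4 / 41, wgd_prob_nonuser = 4 / 41,
    seed = seed
  )
}
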