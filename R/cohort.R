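## Synthetic matched-cohort generator with known ground truth: a 41 vs 41
## NSAID user/non-user cohort with group-specific mutation loads, stratum
## signature mixtures, clonal VAF structure, pathway-specific selection
## against functional mutations in users, and copy-number segments.

#' Synthetic gene model
#'
#' Places genes deterministically along the packaged chromosome arms,
#' proportionally to arm length, with lengths cycling through a small set.
#' Spacing is large (hundreds of kb), so 1 kb mutation-to-gene linking is
#' unambiguous.
#'
#' @param n_genes Number of genes.
#' @param arm_table Arm table.
#' @return data.frame `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
synthetic_gene_table <- function(n_genes = 4000L,
                                 arm_table = load_arm_table()) {
  lens <- c(10e3, 15e3, 20e3, 30e3)
  arm_bp <- as.numeric(arm_table$end - arm_table$start)
  n_per_arm <- pmax(1L, as.integer(round(n_genes * arm_bp / sum(arm_bp))))
  rows <- lapply(seq_len(nrow(arm_table)), function(j) {
    n <- n_per_arm[j]
    step <- arm_bp[j] / (n + 1)
    start <- as.integer(arm_table$start[j] + round(step * seq_len(n)))
    data.frame(chrom = arm_table$chrom[j], start = start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[seq_len(min(nrow(out), n_genes)), ]
  out$end <- out$start + rep_len(lens, nrow(out))
  out$gene <- sprintf("G%05d", seq_len(nrow(out)))
  out[c("gene", "chrom", "start", "end")]
}

#' Synthetic pathway database
#'
#' Draws `n_pathways` gene sets from a gene table, allowing overlap between
#' pathways. The default sizes make the first nine pathways large (150 genes
#' each, the scale of curated cancer-associated pathways, which in the
#' emulated study together span ~900 genes) and the remainder smaller
#' (40-90 genes). Deterministic for a given seed.
#'
#' @param gene_table Gene model from [synthetic_gene_table].
#' @param n_pathways Number of pathways.
#' @param sizes Pathway sizes (recycled to `n_pathways`).
#' @param seed RNG seed.
#' @return Named list of gene vectors (`PW01` ...).
#' @export
synthetic_pathways <- function(gene_table, n_pathways = 35L,
                               sizes = c(rep(150L, 9L),
                                         rep_len(c(40L, 60L, 80L, 50L,
                                                   70L, 90L, 55L), 26L)),
                               seed = 11L) {
  sizes <- rep_len(sizes, n_pathways)
  withr::with_seed(seed, {
    db <- lapply(seq_len(n_pathways), function(k) {
      sort(sample(gene_table$gene, sizes[k]))
    })
  })
  names(db) <- sprintf("PW%02d", seq_len(n_pathways))
  db
}

.default_signature_weights <- function(reference) {
  sigs <- colnames(reference)
  base <- stats::setNames(rep(0, length(sigs)), sigs)
  fill <- function(w) {
    rest <- setdiff(sigs, names(w))
    out <- base
    out[names(w)] <- w
    out[rest] <- (1 - sum(w)) / length(rest)
    out
  }
  list(
    never_smoker = fill(c(SS17 = 0.22, SS1 = 0.26, SS9 = 0.078, SS5 = 0.071,
                          SS8 = 0.055)),
    ever_smoker = fill(c(SS17 = 0.40, SS1 = 0.18, SS9 = 0.078, SS5 = 0.071,
                         SS8 = 0.055))
  )
}

.default_sca_rates <- function() {
  data.frame(
    class = c("HD", "loss", "cnLOH", "balanced_gain", "allele_gain",
              "focal_amp"),
    user = c(0.20, 1.5, 1.0, 0.2, 0.6, 0),
    nonuser = c(0.30, 2.5, 2.5, 0.8, 2.2, 0.217),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth parameters for a synthetic cohort
#'
#' Defaults emulate the study conditions: 41 patients per group; SNV loads
#' negative-binomial with mean 290.93 (SD 209.69) in users and 402.49
#' (SD 362.68) in non-users; indel loads 17.95 (SD 12.25) vs 22.42 (SD 13.77);
#' epithelium purity 0.98 with 80x read depth; smoking matched between groups;
#' TP53-mutant fractions 6/41 vs 11/41 with a load multiplier (renormalized so
#' group means stay at their configured values); signature mixtures by smoking
#' stratum; three clones per patient whose prevalences come from group-specific
#' Beta distributions; a 50 percent selection effect against functional
#' mutations in users in nine of the 35 pathways; and per-class SCA rates with
#' focal amplifications and genome doubling in non-users only.
#'
#' `pathway_effects` is the multiplicative reduction, in users, of the
#' per-mutation probability that a functional mutation lands in the pathway --
#' selection beyond the general load reduction, so the observed mean burden
#' reduction compounds the two.
#'
#' @param n_per_group Patients per group.
#' @param load_mean_user,load_sd_user,load_mean_nonuser,load_sd_nonuser SNV
#'   load parameters.
#' @param indel_mean_user,indel_sd_user,indel_mean_nonuser,indel_sd_nonuser
#'   Indel load parameters.
#' @param target_mb Captured territory per patient (Mb).
#' @param purity Epithelial purity in (0, 1].
#' @param depth Mean sequencing depth.
#' @param signature_weights List with `never_smoker`/`ever_smoker` weight
#'   vectors over the reference signatures (each summing to 1).
#' @param smoking_prob Probability a matched pair is ever-smoker.
#' @param tp53_prob_user,tp53_prob_nonuser TP53-mutant probability by group.
#' @param tp53_load_multiplier Load multiplier for TP53-mutant patients.
#' @param clone_fractions Mutation fractions of the three clones.
#' @param clone_prev_shapes List `user`/`nonuser` of 3x2 Beta shape matrices
#'   (rows = clones).
#' @param pathway_effects Named vector: pathway -> reduction in [0, 1].
#' @param sca_rates data.frame `class`, `user`, `nonuser` expected counts.
#' @param wgd_prob_user,wgd_prob_nonuser Genome-doubling probability by group.
#' @param reference Reference signature matrix the weights refer to.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `cohort_truth` list, including materialized per-patient clone
#'   prevalences.
#' @export
cohort_truth <- function(n_per_group = 41L,
                         load_mean_user = 290.93, load_sd_user = 209.69,
                         load_mean_nonuser = 402.49, load_sd_nonuser = 362.68,
                         indel_mean_user = 17.95, indel_sd_user = 12.25,
                         indel_mean_nonuser = 22.42, indel_sd_nonuser = 13.77,
                         target_mb = 104,
                         purity = 0.98, depth = 80,
                         signature_weights = NULL,
                         smoking_prob = 0.5,
                         tp53_prob_user = 6 / 41,
                         tp53_prob_nonuser = 11 / 41,
                         tp53_load_multiplier = 1.6,
                         clone_fractions = c(0.35, 0.40, 0.25),
                         clone_prev_shapes = list(
                           user = rbind(c(3, 6), c(2.5, 7.5), c(1.5, 8.5)),
                           nonuser = rbind(c(5, 4), c(2.5, 7.5), c(1.5, 8.5))
                         ),
                         pathway_effects = stats::setNames(
                           rep(0.5, 9), sprintf("PW%02d", 1:9)),
                         sca_rates = .default_sca_rates(),
                         wgd_prob_user = 0,
                         wgd_prob_nonuser = 4 / 41,
                         reference = make_reference_signatures(),
                         seed = 1L) {
  if (is.null(signature_weights)) {
    signature_weights <- .default_signature_weights(reference)
  }
  stopifnot(
    n_per_group >= 2L,
    load_mean_user > 0, load_sd_user > 0,
    load_mean_nonuser > 0, load_sd_nonuser > 0,
    indel_mean_user > 0, indel_mean_nonuser > 0,
    purity > 0, purity <= 1, depth > 0,
    abs(sum(clone_fractions) - 1) < 1e-9,
    all(vapply(signature_weights,
               function(w) abs(sum(w) - 1) < 1e-9, logical(1))),
    all(pathway_effects >= 0 & pathway_effects <= 1)
  )
  truth <- list(
    n_per_group = as.integer(n_per_group),
    load_mean_user = load_mean_user, load_sd_user = load_sd_user,
    load_mean_nonuser = load_mean_nonuser, load_sd_nonuser = load_sd_nonuser,
    indel_mean_user = indel_mean_user, indel_sd_user = indel_sd_user,
    indel_mean_nonuser = indel_mean_nonuser,
    indel_sd_nonuser = indel_sd_nonuser,
    target_mb = target_mb, purity = purity, depth = depth,
    signature_weights = signature_weights,
    smoking_prob = smoking_prob,
    tp53_prob_user = tp53_prob_user, tp53_prob_nonuser = tp53_prob_nonuser,
    tp53_load_multiplier = tp53_load_multiplier,
    clone_fractions = clone_fractions,
    clone_prev_shapes = clone_prev_shapes,
    pathway_effects = pathway_effects,
    sca_rates = sca_rates,
    wgd_prob_user = wgd_prob_user, wgd_prob_nonuser = wgd_prob_nonuser,
    seed = as.integer(seed)
  )
  # materialize per-patient clone prevalences (part of the hidden truth)
  n <- 2L * truth$n_per_group
  truth$clone_prevalences <- withr::with_seed(truth$seed, {
    lapply(seq_len(n), function(i) {
      user <- i <= truth$n_per_group
      sh <- if (user) clone_prev_shapes$user else clone_prev_shapes$nonuser
      prev <- stats::rbeta(nrow(sh), sh[, 1], sh[, 2])
      cbind(prevalence = pmin(pmax(prev, 1e-3), 1),
            fraction = clone_fractions)
    })
  })
  class(truth) <- "cohort_truth"
  truth
}

## draw counts from a (mean, sd) negative binomial; Poisson fallback
.rload <- function(n, mean, sd) {
  v <- sd^2
  if (v <= mean) {
    warning("variance <= mean; falling back to Poisson")
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
  }
}

.channel_parts <- function() {
  chans <- channel_order()
  sub <- sub("^.\\[(.*)\\].$", "\\1", chans)
  ref <- substr(sub, 1, 1)
  alt <- substr(sub, 3, 3)
  ctx <- paste0(substr(chans, 1, 1), ref, substr(chans, 7, 7))
  list(ref = ref, alt = alt, ctx = ctx)
}

## category sampling probabilities for SNVs and indels
SNV_CATEGORY_PROBS <- c(
  "exon-non-synonymous" = 0.28, "3'utr-exon" = 0.08, "5'utr-exon" = 0.04,
  "coding-splicing" = 0.03, "utr-splicing" = 0.02,
  "exon-synonymous" = 0.12, "intron-coding-gene" = 0.25,
  "3'utr-intron" = 0.02, "5'utr-intron" = 0.02,
  "upstream-1kb" = 0.05, "downstream-1kb" = 0.05,
  "non-coding-RNA-exon" = 0.01, "non-coding-RNA-intron" = 0.01,
  "intergenic-near-capture" = 0.015, "other" = 0.005
)

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the full catalog + covariates + copy-number segments implied by a
#' [cohort_truth]. Per patient, the SNV count is negative-binomial from the
#' group (mean, sd); each SNV's 96-channel is drawn from the smoking-stratum
#' signature mixture and converted to a concrete reference-strand context
#' (either strand with equal probability); functional mutations are placed in
#' genes with user-specific down-weighting of affected-pathway genes; VAF is
#' binomial read sampling around purity x prevalence / 2 at the configured
#' depth; segments are drawn per group SCA rates, and mutations falling in an
#' altered segment are flagged non-diploid. Fully reproducible from
#' `truth$seed`.
#'
#' @param truth A [cohort_truth].
#' @param pathways PathwayDB; defaults to [synthetic_pathways] on the default
#'   gene table.
#' @param reference Reference signature matrix (96 x K, columns sum to 1).
#' @param gene_table Gene model.
#' @param arm_table Arm table.
#' @return List `catalog`, `meta`, `segments`, `truth`.
#' @export
generate_cohort <- function(truth,
                            pathways = NULL,
                            reference = make_reference_signatures(),
                            gene_table = synthetic_gene_table(),
                            arm_table = load_arm_table()) {
  stopifnot(inherits(truth, "cohort_truth"))
  stopifnot(all(abs(colSums(reference) - 1) < 1e-6))
  if (is.null(pathways)) pathways <- synthetic_pathways(gene_table)
  withr::with_seed(truth$seed + 1L, {
    n_g <- truth$n_per_group
    n <- 2L * n_g
    meta <- data.frame(
      patient_id = c(sprintf("U%02d", seq_len(n_g)),
                     sprintf("N%02d", seq_len(n_g))),
      nsaid_user = rep(c(TRUE, FALSE), each = n_g),
      # matched design: each user shares smoking status with a non-user
      ever_smoker = rep(stats::runif(n_g) < truth$smoking_prob, times = 2L),
      tp53_mutant = c(stats::runif(n_g) < truth$tp53_prob_user,
                      stats::runif(n_g) < truth$tp53_prob_nonuser),
      target_mb = truth$target_mb,
      stringsAsFactors = FALSE
    )

    # per-patient loads (TP53 multiplier, renormalized within group)
    mult <- ifelse(meta$tp53_mutant, truth$tp53_load_multiplier, 1)
    e_mult_u <- 1 + (truth$tp53_load_multiplier - 1) * truth$tp53_prob_user
    e_mult_n <- 1 + (truth$tp53_load_multiplier - 1) * truth$tp53_prob_nonuser
    scale <- mult / ifelse(meta$nsaid_user, e_mult_u, e_mult_n)
    n_snv <- integer(n); n_indel <- integer(n)
    for (i in seq_len(n)) {
      if (meta$nsaid_user[i]) {
        n_snv[i] <- .rload(1, truth$load_mean_user * scale[i],
                           truth$load_sd_user * scale[i])
        n_indel[i] <- .rload(1, truth$indel_mean_user * scale[i],
                             truth$indel_sd_user * scale[i])
      } else {
        n_snv[i] <- .rload(1, truth$load_mean_nonuser * scale[i],
                           truth$load_sd_nonuser * scale[i])
        n_indel[i] <- .rload(1, truth$indel_mean_nonuser * scale[i],
                             truth$indel_sd_nonuser * scale[i])
      }
    }
    n_snv <- pmax(n_snv, 1L); n_indel <- pmax(n_indel, 1L)

    # segments first (diploid flags depend on them)
    segments <- do.call(rbind, lapply(seq_len(n), function(i) {
      generate_segments(meta$patient_id[i],
                        rates = .patient_rates(truth, meta$nsaid_user[i]),
                        arm_table = arm_table,
                        wgd = stats::runif(1) < if (meta$nsaid_user[i])
                          truth$wgd_prob_user else truth$wgd_prob_nonuser)
    }))

    parts <- .channel_parts()
    affected_genes <- unique(unlist(pathways[names(truth$pathway_effects)]))
    gene_len <- gene_table$end - gene_table$start
    w_base <- gene_len / sum(gene_len)
    in_affected <- gene_table$gene %in% affected_genes
    # user-specific down-weighting of affected-pathway genes for functional
    # mutations (mean effect across the affected pathways), scaled so the
    # per-mutation probability of hitting an affected gene is exactly
    # (1 - effect) times the baseline probability
    eff <- if (length(truth$pathway_effects)) mean(truth$pathway_effects) else 0
    w_aff <- sum(w_base[in_affected])
    w_user_func <- w_base
    if (w_aff > 0 && w_aff < 1) {
      w_user_func[in_affected] <- w_base[in_affected] * (1 - eff)
      w_user_func[!in_affected] <- w_base[!in_affected] *
        (1 - (1 - eff) * w_aff) / (1 - w_aff)
    }

    cat_list <- vector("list", n)
    for (i in seq_len(n)) {
      stratum <- if (meta$ever_smoker[i]) "ever_smoker" else "never_smoker"
      mix <- as.numeric(reference %*%
                          truth$signature_weights[[stratum]][colnames(reference)])
      ns <- n_snv[i]; ni <- n_indel[i]; tot <- ns + ni
      chan <- sample.int(96L, ns, replace = TRUE, prob = mix)
      flip <- stats::runif(ns) < 0.5
      ref <- ifelse(flip, chartr("ACGT", "TGCA", parts$ref[chan]),
                    parts$ref[chan])
      alt <- ifelse(flip, chartr("ACGT", "TGCA", parts$alt[chan]),
                    parts$alt[chan])
      ctx <- parts$ctx[chan]
      ctx[flip] <- revcomp(ctx[flip])

      category <- c(
        sample(names(SNV_CATEGORY_PROBS), ns, replace = TRUE,
               prob = SNV_CATEGORY_PROBS),
        sample(names(SNV_CATEGORY_PROBS), ni, replace = TRUE,
               prob = SNV_CATEGORY_PROBS)
      )
      func <- classify_functional(category)
      user <- meta$nsaid_user[i]
      gidx <- integer(tot)
      no_gene <- category %in% c("intergenic-near-capture", "other")
      w_func <- if (user) w_user_func else w_base
      sel_f <- func & !no_gene
      sel_o <- !func & !no_gene
      gidx[sel_f] <- sample.int(nrow(gene_table), sum(sel_f), replace = TRUE,
                                prob = w_func)
      gidx[sel_o] <- sample.int(nrow(gene_table), sum(sel_o), replace = TRUE,
                                prob = w_base)
      pos <- integer(tot)
      chrom <- character(tot)
      has_gene <- gidx > 0L
      gs <- gene_table$start[gidx[has_gene]]
      ge <- gene_table$end[gidx[has_gene]]
      pos[has_gene] <- gs - 999L +
        as.integer(floor(stats::runif(sum(has_gene)) * (ge - gs + 1999L))) + 1L
      chrom[has_gene] <- gene_table$chrom[gidx[has_gene]]
      # gene-free mutations: midway between consecutive genes (always > 1 kb
      # from both, given the gene spacing)
      if (any(no_gene)) {
        k <- sample.int(nrow(gene_table) - 1L, sum(no_gene), replace = TRUE)
        same <- gene_table$chrom[k] == gene_table$chrom[k + 1L]
        mid <- ifelse(same,
                      (gene_table$end[k] + gene_table$start[k + 1L]) %/% 2,
                      gene_table$end[k] + 50000)
        pos[no_gene] <- as.integer(mid)
        chrom[no_gene] <- gene_table$chrom[k]
      }

      clones <- truth$clone_prevalences[[i]]
      cl <- sample.int(nrow(clones), tot, replace = TRUE,
                       prob = clones[, "fraction"])
      p_true <- truth$purity * clones[cl, "prevalence"] / 2
      dp <- pmax(stats::rpois(tot, truth$depth), 1L)
      altr <- pmax(stats::rbinom(tot, dp, pmin(p_true, 1)), 1L)
      vaf <- pmin(altr / dp, 1)

      genes_col <- ifelse(has_gene, gene_table$gene[pmax(gidx, 1L)], "")
      cat_list[[i]] <- data.frame(
        patient_id = meta$patient_id[i],
        chrom = chrom,
        pos = pos,
        ref = c(ref, rep("A", ni)),
        alt = c(alt, rep("AC", ni)),
        mut_type = c(rep("SNV", ns),
                     sample(c("INS", "DEL"), ni, replace = TRUE)),
        context3 = c(ctx, rep(NA_character_, ni)),
        vaf = vaf,
        genes = genes_col,
        category = category,
        stringsAsFactors = FALSE
      )
    }
    catalog <- do.call(rbind, cat_list)
    # indel ref/alt orientation: deletions are ref "AC" -> alt "A"
    del <- catalog$mut_type == "DEL"
    catalog$ref[del] <- "AC"; catalog$alt[del] <- "A"
    ins <- catalog$mut_type == "INS"
    catalog$ref[ins] <- "A"; catalog$alt[ins] <- "AC"
    catalog$genes <- .split_genes(catalog$genes)

    # diploid flag from the generated segments (patients without any drawn
    # segment are simply all-diploid, so the missing-data warning is moot)
    flagged <- suppressWarnings(filter_diploid(catalog, segments))
    key <- paste(catalog$patient_id, catalog$chrom, catalog$pos)
    catalog$diploid_balanced <- key %in%
      paste(flagged$patient_id, flagged$chrom, flagged$pos)
    rownames(catalog) <- NULL

    list(catalog = catalog, meta = meta, segments = segments, truth = truth)
  })
}

.patient_rates <- function(truth, user) {
  r <- truth$sca_rates
  stats::setNames(if (user) r$user else r$nonuser, r$class)
}

SEGMENT_CN <- list(
  HD = c(total = 0L, minor = 0L),
  loss = c(total = 1L, minor = 0L),
  cnLOH = c(total = 2L, minor = 0L),
  balanced_gain = c(total = 4L, minor = 2L),
  allele_gain = c(total = 3L, minor = 1L),
  focal_amp = c(total = 8L, minor = 1L)
)

#' Draw one patient's true copy-number segments
#'
#' Per SCA class, the segment count is Poisson with the configured rate;
#' focal amplifications are short (<= 3 Mb) and high-level, other classes
#' have log-normal lengths around tens of Mb. Segments are placed uniformly
#' on random arms without overlap; the rest of the genome is diploid
#' balanced. A genome-doubled patient additionally gets arm-wide (4, 2)
#' segments over most arms.
#'
#' @param patient_id Patient label.
#' @param rates Named vector of expected counts per class.
#' @param arm_table Arm table.
#' @param wgd Whether this patient has a genome doubling.
#' @return SEG-like data.frame (possibly zero rows), with true `class`.
#' @export
generate_segments <- function(patient_id, rates, arm_table, wgd = FALSE) {
  stopifnot(all(rates >= 0))
  segs <- list()
  occupied <- list() # per arm: matrix of (start, end)
  place <- function(len_bp) {
    for (try in 1:50) {
      j <- sample.int(nrow(arm_table), 1L)
      lo <- arm_table$start[j]; hi <- arm_table$end[j]
      if (hi - lo <= len_bp) next
      s <- lo + floor(stats::runif(1) * (hi - lo - len_bp))
      key <- as.character(j)
      occ <- occupied[[key]]
      if (!is.null(occ) &&
          any(s < occ[, 2] & s + len_bp > occ[, 1])) next
      occupied[[key]] <<- rbind(occ, c(s, s + len_bp))
      return(list(chrom = arm_table$chrom[j], start = s, end = s + len_bp))
    }
    NULL
  }
  if (wgd) {
    cover <- stats::runif(nrow(arm_table)) < 0.8
    for (j in which(cover)) {
      segs[[length(segs) + 1L]] <- data.frame(
        patient_id = patient_id, chrom = arm_table$chrom[j],
        start = arm_table$start[j], end = arm_table$end[j],
        n_probes = NA_integer_, log_ratio = 1,
        total_cn = 4L, minor_cn = 2L, stringsAsFactors = FALSE)
      occupied[[as.character(j)]] <-
        rbind(occupied[[as.character(j)]],
              c(arm_table$start[j], arm_table$end[j]))
    }
  }
  for (cls in names(rates)) {
    k <- stats::rpois(1L, rates[[cls]])
    if (k == 0L) next
    cn <- SEGMENT_CN[[cls]]
    for (s in seq_len(k)) {
      len <- if (cls == "focal_amp") {
        stats::runif(1, 0.3e6, 2.9e6)
      } else if (cls == "HD") {
        stats::runif(1, 0.2e6, 2e6)
      } else {
        exp(stats::rnorm(1, log(20e6), 0.7))
      }
      loc <- place(as.integer(len))
      if (is.null(loc)) next
      segs[[length(segs) + 1L]] <- data.frame(
        patient_id = patient_id, chrom = loc$chrom,
        start = loc$start, end = loc$end,
        n_probes = NA_integer_,
        log_ratio = log2(max(cn[["total"]], 0.5) / 2),
        total_cn = cn[["total"]], minor_cn = cn[["minor"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), log_ratio = numeric(0),
                      total_cn = integer(0), minor_cn = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  # truth labels are always against the diploid reference; WGD territory
  # reads as arm-wide balanced gain
  out$class <- classify_segment(out$total_cn, out$minor_cn,
                                out$end - out$start, ploidy = 2L)
  out
}

#' Write the hidden truth parameters as JSON
#'
#' @param truth A [cohort_truth].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  out <- unclass(truth)
  out$clone_prevalences <- lapply(out$clone_prevalences, function(m) {
    list(prevalence = unname(m[, "prevalence"]),
         fraction = unname(m[, "fraction"]))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a cohort_truth from a YAML config block
#'
#' The YAML keys mirror the arguments of [cohort_truth]; unknown keys are an
#' error.
#'
#' @param config A list (already parsed YAML) or a YAML file path.
#' @return A `cohort_truth`.
#' @export
cohort_truth_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- names(formals(cohort_truth))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown cohort_truth field: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$pathway_effects)) {
    config$pathway_effects <- unlist(config$pathway_effects)
  }
  do.call(cohort_truth, config)
}
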