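## Pathway burden, per-gene burden, percent reduction, and the
## gene-count-normalized Shannon diversity index.

#' Assign mutations to pathways through nearby genes
#'
#' A mutation is linked to gene g when its position lies within 1 kb of g
#' (`[gene_start - 1000, gene_end + 1000)` on 0-based half-open gene
#' intervals), and then to every pathway containing g. A mutation is counted
#' at most once per pathway, but a mutation whose gene sits in several
#' pathways increments each of them (documented double counting across
#' pathways). When `gene_intervals` is NULL, the catalog's `genes` list-column
#' (populated by the reader or the generator) supplies the gene links
#' directly.
#'
#' @param catalog Mutation catalog.
#' @param meta Patient table.
#' @param pathways Named list of gene vectors (a `PathwayDB`).
#' @param gene_intervals Optional BED-like data.frame `gene`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param flank Linking distance in bp (default 1000).
#' @return List of two patients x pathways integer matrices, `functional` and
#'   `nonfunctional`, plus `genes_per_pathway`.
#' @export
assign_mutations_to_pathways <- function(catalog, meta, pathways,
                                         gene_intervals = NULL,
                                         flank = 1000L) {
  stopifnot(length(pathways) >= 1L, all(lengths(pathways) >= 1L))
  if (!is.null(gene_intervals)) {
    known <- unique(gene_intervals$gene)
    missing_genes <- setdiff(unique(unlist(pathways)), known)
    if (length(missing_genes)) {
      warning(length(missing_genes),
              " pathway gene(s) have no interval and are skipped")
    }
    gi <- gene_intervals[gene_intervals$gene %in% unique(unlist(pathways)), ,
                         drop = FALSE]
    lv <- union(catalog$chrom, gi$chrom)
    mut_gr <- GenomicRanges::GRanges(
      factor(catalog$chrom, levels = lv),
      IRanges::IRanges(start = catalog$pos, width = 1L))
    gene_gr <- GenomicRanges::GRanges(
      factor(gi$chrom, levels = lv),
      IRanges::IRanges(start = pmax(gi$start - flank, 0L) + 1L,
                       end = gi$end + flank))
    hits <- GenomicRanges::findOverlaps(mut_gr, gene_gr)
    mut_genes <- split(gi$gene[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    genes_of <- replicate(nrow(catalog), character(0), simplify = FALSE)
    genes_of[as.integer(names(mut_genes))] <- lapply(mut_genes, unique)
  } else {
    genes_of <- catalog$genes
    stopifnot(is.list(genes_of))
  }
  func <- classify_functional(catalog$category)
  pid <- factor(catalog$patient_id, levels = meta$patient_id)
  n_pat <- nrow(meta)
  mk <- function(mask) {
    m <- matrix(0L, n_pat, length(pathways),
                dimnames = list(meta$patient_id, names(pathways)))
    idx <- which(mask & lengths(genes_of) > 0L)
    if (!length(idx)) return(m)
    long_pid <- rep(as.integer(pid)[idx], times = lengths(genes_of[idx]))
    long_gene <- unlist(genes_of[idx], use.names = FALSE)
    for (k in seq_along(pathways)) {
      in_pw <- long_gene %in% pathways[[k]]
      if (!any(in_pw)) next
      # one count per mutation per pathway, even via several genes
      mut_idx <- rep(idx, times = lengths(genes_of[idx]))[in_pw]
      u <- !duplicated(mut_idx)
      counts <- tabulate(long_pid[in_pw][u], nbins = n_pat)
      m[, k] <- m[, k] + counts
    }
    m
  }
  list(
    functional = mk(func),
    nonfunctional = mk(!func),
    genes_per_pathway = lengths(pathways)
  )
}

#' Per-pathway burden comparison between NSAID users and non-users
#'
#' One Kruskal-Wallis test per pathway on per-patient mutation counts, BH
#' adjustment across pathways at the given FDR, plus group means, standard
#' errors of the mean and the percent reduction in users.
#'
#' @param burden Output of [assign_mutations_to_pathways].
#' @param meta Patient table with `nsaid_user`.
#' @param which `"functional"` or `"nonfunctional"`.
#' @param fdr FDR level for the BH flag.
#' @return data.frame with one row per pathway.
#' @export
pathway_burden_test <- function(burden, meta,
                                which = c("functional", "nonfunctional"),
                                fdr = 0.2) {
  which <- match.arg(which)
  m <- burden[[which]]
  grp <- meta$nsaid_user
  if (sum(grp) < 2L || sum(!grp) < 2L) stop("need >= 2 patients per group")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(colnames(m), function(pw) {
    u <- m[grp, pw]; nu <- m[!grp, pw]
    kw <- kruskal_wallis(u, nu)
    data.frame(
      pathway = pw,
      n_genes = unname(burden$genes_per_pathway[pw]),
      mean_user = mean(u), sem_user = sem(u),
      mean_nonuser = mean(nu), sem_nonuser = sem(nu),
      reduction_pct = percent_reduction(mean(u), mean(nu)),
      H = kw$statistic, p = kw$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  adj <- bh_adjust(out$p, fdr)
  out$q <- adj$q_values
  out$significant <- adj$rejected
  out
}

#' Per-gene functional burden comparison
#'
#' Genes are tested only when at least `min_carriers` users OR
#' `min_carriers` non-users carry a functional mutation in (within 1 kb of)
#' the gene; each tested gene gets a Kruskal-Wallis test on per-patient
#' functional counts and BH adjustment at `fdr`.
#'
#' @param catalog Mutation catalog with the `genes` list-column.
#' @param meta Patient table.
#' @param min_carriers Carrier threshold per group.
#' @param fdr FDR level.
#' @return data.frame with one row per tested gene.
#' @export
gene_burden_test <- function(catalog, meta, min_carriers = 5L, fdr = 0.1) {
  func <- catalog[classify_functional(catalog$category), , drop = FALSE]
  long <- data.frame(
    patient_id = rep(func$patient_id, times = lengths(func$genes)),
    gene = unlist(func$genes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(long) == 0L) {
    return(data.frame(gene = character(0), n_carriers_user = integer(0),
                      n_carriers_nonuser = integer(0), H = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  grp <- meta$nsaid_user
  counts <- table(factor(long$gene),
                  factor(long$patient_id, levels = meta$patient_id))
  carriers_u <- rowSums(counts[, grp, drop = FALSE] > 0)
  carriers_n <- rowSums(counts[, !grp, drop = FALSE] > 0)
  test_genes <- names(which(carriers_u >= min_carriers |
                              carriers_n >= min_carriers))
  rows <- lapply(test_genes, function(g) {
    cnt <- as.integer(counts[g, ])
    kw <- kruskal_wallis(cnt[grp], cnt[!grp])
    data.frame(gene = g,
               n_carriers_user = as.integer(carriers_u[g]),
               n_carriers_nonuser = as.integer(carriers_n[g]),
               mean_user = mean(cnt[grp]),
               mean_nonuser = mean(cnt[!grp]),
               H = kw$statistic, p = kw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(0), n_carriers_user = integer(0),
                      n_carriers_nonuser = integer(0), H = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  adj <- bh_adjust(out$p, fdr)
  out$q <- adj$q_values
  out$significant <- adj$rejected
  out[order(out$p), ]
}

#' Percent reduction of a mean in users relative to non-users
#'
#' @param user_mean,nonuser_mean Group means; `nonuser_mean` must be positive
#'   for a defined value.
#' @return `100 * (1 - user_mean / nonuser_mean)`, or NA when undefined.
#' @export
percent_reduction <- function(user_mean, nonuser_mean) {
  ifelse(nonuser_mean > 0, 100 * (1 - user_mean / nonuser_mean), NA_real_)
}

#' Gene-count-normalized Shannon diversity of pathway burden
#'
#' Each pathway's mutation count is normalized by its gene count
#' (m_i = count_i / genes_i), converted to proportions p_i = m_i / sum(m),
#' and summarized as SI = -sum(p_i log p_i) with 0 log 0 := 0. A patient with
#' no mutations in the subset gets SI = 0 (maximally concentrated).
#'
#' @param counts Per-pathway mutation counts (one patient).
#' @param genes_per_pathway Parallel vector of pathway gene counts.
#' @param subset Optional names/indices selecting the pathway subset.
#' @return Non-negative scalar, at most `log(length(subset))`.
#' @export
shannon_pathway_diversity <- function(counts, genes_per_pathway,
                                      subset = NULL) {
  stopifnot(length(counts) == length(genes_per_pathway))
  if (!is.null(subset)) {
    counts <- counts[subset]
    genes_per_pathway <- genes_per_pathway[subset]
  }
  stopifnot(length(counts) >= 1L, all(genes_per_pathway >= 1))
  m <- counts / genes_per_pathway
  tot <- sum(m)
  if (tot == 0) return(0)
  p <- m / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-patient SI table and group comparison
#'
#' Computes each patient's Shannon pathway diversity over a pathway subset and
#' compares NSAID users to non-users by Kruskal-Wallis.
#'
#' @param burden Output of [assign_mutations_to_pathways].
#' @param meta Patient table.
#' @param subset Pathway names to restrict to (e.g. the significant set).
#' @param which `"functional"` or `"nonfunctional"` burden.
#' @return List with `si` (data.frame patient_id, si, zero_burden flag) and
#'   `test` (the Kruskal-Wallis result).
#' @export
diversity_group_test <- function(burden, meta, subset = NULL,
                                 which = "functional") {
  m <- burden[[which]]
  gpp <- burden$genes_per_pathway
  si <- apply(m, 1L, shannon_pathway_diversity,
              genes_per_pathway = gpp, subset = subset)
  zero <- if (is.null(subset)) rowSums(m) == 0 else rowSums(m[, subset, drop = FALSE]) == 0
  tab <- data.frame(patient_id = meta$patient_id, si = si,
                    zero_burden = zero, stringsAsFactors = FALSE)
  test <- kruskal_wallis(si[meta$nsaid_user], si[!meta$nsaid_user])
  list(si = tab, test = test)
}
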