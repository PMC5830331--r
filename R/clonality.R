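## VAF-based clonality: diploid-region filtering, high-VAF counts, and the
## threshold-scan group comparison.

#' Restrict a catalog to mutations in diploid, copy-neutral-balanced regions
#'
#' Copy number gain, loss and copy-neutral LOH all distort VAF, so clonality
#' comparisons use only mutations lying in no altered segment (background is
#' assumed diploid with minor copy number 1). Patients without any segment
#' data keep all their mutations, with a warning.
#'
#' @param catalog Mutation catalog.
#' @param segments Segment data.frame (SEG-like; only segments with
#'   `!(total_cn == 2 & minor_cn == 1)` exclude mutations).
#' @return The filtered catalog with an updated `diploid_balanced` column.
#' @export
filter_diploid <- function(catalog, segments) {
  altered <- segments[!(segments$total_cn == 2L &
                          !is.na(segments$minor_cn) &
                          segments$minor_cn == 1L) &
                        segments$class != "diploid", , drop = FALSE]
  no_seg <- setdiff(unique(catalog$patient_id), unique(segments$patient_id))
  if (length(no_seg)) {
    warning("no segment data for patient(s): ",
            paste(no_seg, collapse = ", "), "; retaining all their mutations")
  }
  keep <- rep(TRUE, nrow(catalog))
  if (nrow(altered)) {
    cat_key <- paste0(catalog$patient_id, ":", catalog$chrom)
    seg_key <- paste0(altered$patient_id, ":", altered$chrom)
    lv <- union(cat_key, seg_key) # shared seqlevels for the overlap
    cat_gr <- GenomicRanges::GRanges(
      factor(cat_key, levels = lv),
      IRanges::IRanges(start = catalog$pos, width = 1L)
    )
    seg_gr <- GenomicRanges::GRanges(
      factor(seg_key, levels = lv),
      IRanges::IRanges(start = altered$start + 1L, end = altered$end)
    )
    hits <- GenomicRanges::findOverlaps(cat_gr, seg_gr)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- catalog[keep, , drop = FALSE]
  out$diploid_balanced <- TRUE
  out
}

#' Per-patient counts of mutations above a VAF threshold
#'
#' Strict inequality (`vaf > threshold`); mutations with missing VAF are
#' excluded from both numerator and denominator.
#'
#' @param catalog Mutation catalog (typically diploid-filtered).
#' @param meta Patient table.
#' @param threshold VAF threshold in (0, 1).
#' @param which `"functional"`, `"nonfunctional"`, or `"all"`.
#' @return data.frame `patient_id`, `n_total`, `n_above`, `proportion_above`
#'   (NA when `n_total` is 0), plus the threshold as an attribute.
#' @export
count_high_vaf <- function(catalog, meta, threshold = 0.3,
                           which = c("functional", "nonfunctional", "all")) {
  which <- match.arg(which)
  stopifnot(threshold > 0, threshold < 1)
  keep <- !is.na(catalog$vaf)
  if (which == "functional") {
    keep <- keep & classify_functional(catalog$category)
  } else if (which == "nonfunctional") {
    keep <- keep & !classify_functional(catalog$category)
  }
  sub <- catalog[keep, , drop = FALSE]
  pid <- factor(sub$patient_id, levels = meta$patient_id)
  n_total <- as.integer(table(pid))
  n_above <- as.integer(table(pid[sub$vaf > threshold]))
  out <- data.frame(
    patient_id = meta$patient_id,
    n_total = n_total,
    n_above = n_above,
    proportion_above = ifelse(n_total > 0, n_above / n_total, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  out
}

#' Scan VAF thresholds for a group difference in high-VAF mutation counts
#'
#' At each threshold, NSAID users and non-users are compared by
#' Kruskal-Wallis on the per-patient count of mutations above the threshold
#' (raw) and on the per-patient proportion (controlling for total mutation
#' number). The scan is exploratory: raw p-values per threshold are reported,
#' with a BH-adjusted column alongside.
#'
#' @param catalog Mutation catalog (diploid-filtered for the headline use).
#' @param meta Patient table with `nsaid_user`.
#' @param thresholds Numeric grid in (0, 1).
#' @param which Mutation class, as in [count_high_vaf].
#' @return data.frame: `threshold`, `median_user`, `median_nonuser`, `H`,
#'   `p_raw`, `p_proportion`, `q_raw`, `significant` (p_raw < 0.05).
#' @export
vaf_threshold_scan <- function(catalog, meta,
                               thresholds = seq(0.05, 0.50, by = 0.05),
                               which = "functional") {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  grp <- meta$nsaid_user
  rows <- lapply(thresholds, function(th) {
    cts <- count_high_vaf(catalog, meta, threshold = th, which = which)
    raw <- kruskal_wallis(cts$n_above[grp], cts$n_above[!grp])
    prop <- cts$proportion_above
    ok <- !is.na(prop)
    padj <- if (sum(ok & grp) >= 1 && sum(ok & !grp) >= 1) {
      kruskal_wallis(prop[ok & grp], prop[ok & !grp])$p_value
    } else {
      NA_real_
    }
    data.frame(
      threshold = th,
      median_user = stats::median(cts$n_above[grp]),
      median_nonuser = stats::median(cts$n_above[!grp]),
      H = raw$statistic,
      p_raw = raw$p_value,
      p_proportion = padj
    )
  })
  out <- do.call(rbind, rows)
  out$q_raw <- bh_adjust(out$p_raw, 0.05)$q_values
  out$significant <- out$p_raw < 0.05
  out
}
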