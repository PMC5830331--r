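## Somatic chromosome alteration (SCA) calling from exome-style
## log-ratio/B-allele-frequency tracks: binary segmentation, copy-number and
## allele-specific classification into six classes, arm-normalized loads,
## genome-doubling and focal-amplification summaries.

SCA_CLASSES <- c("HD", "loss", "cnLOH", "balanced_gain", "allele_gain",
                 "focal_amp", "diploid")

#' Classify a copy-number segment into one of six SCA classes (or diploid)
#'
#' Rules, applied in order against the reference `ploidy`:
#' homozygous deletion (`HD`) when total = 0; `loss` when 0 < total < ploidy;
#' `cnLOH` when total = ploidy and minor = 0; `focal_amp` when
#' total >= ploidy + `focal_cn_gain` and length <= `focal_max_bp`;
#' `balanced_gain` when total > ploidy with major = minor; `allele_gain` for
#' the remaining gains; `diploid` otherwise. With unknown minor copy number
#' only total-CN classes are called (gains fall back to `allele_gain`, and
#' total = ploidy is reported `diploid`).
#'
#' @param total_cn,minor_cn Integer copy numbers (minor may be NA).
#' @param length_bp Segment length in bp.
#' @param ploidy Reference ploidy (2, or 4 after genome doubling).
#' @param focal_cn_gain Copies above ploidy required for a focal
#'   amplification.
#' @param focal_max_bp Maximum focal-amplification length.
#' @return Character vector of classes.
#' @export
classify_segment <- function(total_cn, minor_cn, length_bp, ploidy = 2L,
                             focal_cn_gain = 4L, focal_max_bp = 3e6) {
  n <- length(total_cn)
  minor_cn <- rep_len(minor_cn, n)
  length_bp <- rep_len(length_bp, n)
  stopifnot(all(total_cn >= 0))
  known <- !is.na(minor_cn)
  if (any(known & minor_cn > total_cn / 2)) {
    stop("minor copy number exceeds total/2")
  }
  major <- total_cn - minor_cn
  cls <- rep("diploid", n)
  cls[total_cn == 0] <- "HD"
  cls[total_cn > 0 & total_cn < ploidy] <- "loss"
  cls[known & total_cn == ploidy & minor_cn == 0 & ploidy > 0] <- "cnLOH"
  gain <- total_cn > ploidy
  cls[gain & known & major == minor_cn] <- "balanced_gain"
  cls[gain & (!known | major != minor_cn)] <- "allele_gain"
  focal <- total_cn >= ploidy + focal_cn_gain & length_bp <= focal_max_bp
  cls[focal] <- "focal_amp"
  cls
}

## Recursive binary segmentation on one chromosome's log-ratios.
## Returns sorted breakpoint indices (last probe of each left part).
.binseg <- function(x, min_probes = 5L, penalty_mult = 2) {
  n <- length(x)
  out <- integer(0)
  recurse <- function(lo, hi) {
    n_seg <- hi - lo + 1L
    if (n_seg < 2L * min_probes) return(invisible())
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    tot <- cs[n_seg]
    i <- seq.int(min_probes, n_seg - min_probes)
    # residual sum of squares for a split after position i
    rss_split <- (sum(xs^2) - cs[i]^2 / i - (tot - cs[i])^2 / (n_seg - i))
    best <- which.min(rss_split)
    rss1 <- rss_split[best]
    rss0 <- sum(xs^2) - tot^2 / n_seg
    # BIC-style acceptance; exact (zero-noise) steps always split
    sigma2 <- max(rss0 / n_seg, 1e-12)
    gain <- (rss0 - rss1) / sigma2
    if (gain > penalty_mult * log(n)) {
      cut <- lo + i[best] - 1L
      out <<- c(out, cut)
      recurse(lo, cut)
      recurse(cut + 1L, hi)
    }
    invisible()
  }
  recurse(1L, n)
  sort(out)
}

## Mode of the log-ratio density (diploid baseline estimate).
.lr_baseline <- function(lr) {
  d <- stats::density(lr, n = 512)
  d$x[which.max(d$y)]
}

#' Segment an exome probe track and call copy-number classes
#'
#' Change points are found per chromosome by greedy binary segmentation of the
#' log-ratio with a BIC stopping rule. Per segment, total copy number is
#' `round(2 * 2^(mean log-ratio - baseline))`, where the baseline is the mode
#' of the genome-wide log-ratio density; minor copy number comes from the mean
#' B-allele-frequency deviation at heterozygous sites
#' (`minor = round(total * (0.5 - dev))`, clipped to `[0, total/2]`), and is
#' NA for segments without heterozygous sites. Adjacent segments with
#' identical (total, minor) are merged, and classes are assigned by
#' [classify_segment]. If the resulting segments show genome doubling
#' ([genome_doubling_flag]), classification is re-run at ploidy 4.
#'
#' @param track data.frame `chrom`, `start`, `end`, `log_ratio`, `baf`
#'   (`baf` NA at non-heterozygous targets), sorted by coordinate.
#' @param patient_id Patient label for the output.
#' @param arm_table Arm table (for the genome-doubling re-check).
#' @param min_probes_chrom Minimum targets required per chromosome.
#' @param params List of overrides: `min_probes`, `penalty_mult`,
#'   `focal_cn_gain`, `focal_max_bp`.
#' @return SEG-like data.frame of called segments.
#' @export
segment_and_call <- function(track, patient_id = "sample",
                             arm_table = load_arm_table(),
                             min_probes_chrom = 50L, params = list()) {
  p <- utils::modifyList(list(min_probes = 5L, penalty_mult = 2,
                              focal_cn_gain = 4L, focal_max_bp = 3e6), params)
  stopifnot(all(is.finite(track$log_ratio)))
  baseline <- .lr_baseline(track$log_ratio)
  segs <- list()
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom, , drop = FALSE]
    if (nrow(tr) < min_probes_chrom) next
    cuts <- .binseg(tr$log_ratio, p$min_probes, p$penalty_mult)
    # cnLOH has a flat log-ratio: also cut on the BAF deviation of
    # heterozygous probes, mapped back to probe indices
    het <- which(!is.na(tr$baf))
    if (length(het) >= 2L * p$min_probes) {
      baf_cuts <- het[.binseg(abs(tr$baf[het] - 0.5), p$min_probes,
                              p$penalty_mult)]
      # keep only BAF breakpoints that add information beyond the
      # log-ratio ones (avoid near-duplicate sliver segments)
      if (length(cuts)) {
        near <- vapply(baf_cuts, function(b) {
          min(abs(b - cuts)) <= 2L * p$min_probes
        }, logical(1))
        baf_cuts <- baf_cuts[!near]
      }
      cuts <- sort(unique(c(cuts, baf_cuts)))
    }
    bounds <- c(0L, cuts, nrow(tr))
    for (si in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[si] + 1L):bounds[si + 1L]
      lr <- mean(tr$log_ratio[idx])
      total <- max(0L, as.integer(round(2 * 2^(lr - baseline))))
      baf <- tr$baf[idx]
      baf <- baf[!is.na(baf)]
      minor <- if (length(baf) == 0L) {
        NA_integer_
      } else {
        dev <- mean(abs(baf - 0.5))
        max(0L, min(as.integer(floor(total / 2)),
                    as.integer(round(total * (0.5 - dev)))))
      }
      segs[[length(segs) + 1L]] <- data.frame(
        patient_id = patient_id, chrom = chrom,
        start = tr$start[idx[1L]], end = tr$end[idx[length(idx)]],
        n_probes = length(idx), log_ratio = lr,
        total_cn = total, minor_cn = minor,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) stop("no chromosome with >= ", min_probes_chrom, " targets")
  out <- .merge_identical(out)
  out$class <- classify_segment(out$total_cn, out$minor_cn,
                                out$end - out$start, ploidy = 2L,
                                focal_cn_gain = p$focal_cn_gain,
                                focal_max_bp = p$focal_max_bp)
  if (isTRUE(genome_doubling_flag(out, arm_table))) {
    out$class <- classify_segment(out$total_cn, out$minor_cn,
                                  out$end - out$start, ploidy = 4L,
                                  focal_cn_gain = p$focal_cn_gain,
                                  focal_max_bp = p$focal_max_bp)
  }
  rownames(out) <- NULL
  out
}

.merge_identical <- function(segs) {
  keep <- list()
  for (chrom in unique(segs$chrom)) {
    s <- segs[segs$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    i <- 1L
    while (i < nrow(s)) {
      m1 <- s$minor_cn[i]; m2 <- s$minor_cn[i + 1L]
      # segments without heterozygous probes (minor unknown) merge into an
      # equal-total neighbor
      same <- s$total_cn[i] == s$total_cn[i + 1L] &&
        (identical(m1, m2) || is.na(m1) || is.na(m2))
      if (same) {
        w <- c(s$n_probes[i], s$n_probes[i + 1L])
        s$log_ratio[i] <- stats::weighted.mean(s$log_ratio[i:(i + 1L)], w)
        s$minor_cn[i] <- if (is.na(m1)) m2 else m1
        s$end[i] <- s$end[i + 1L]
        s$n_probes[i] <- sum(w)
        s <- s[-(i + 1L), , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    keep[[chrom]] <- s
  }
  do.call(rbind, keep)
}

#' Arm-normalized SCA load
#'
#' Intersects altered segments with chromosome arms; segments crossing an arm
#' boundary are split and counted in each arm. Reports per (patient, arm,
#' class): MB of overlap, segment count, and the count normalized by arm
#' length in Mb.
#'
#' @param segments SEG-like data.frame with a `class` column.
#' @param arm_table Arm table.
#' @param meta Optional patient table fixing the patient set.
#' @return data.frame `patient_id`, `chrom`, `arm`, `class`, `mb`,
#'   `n_segments`, `n_per_mb`.
#' @export
arm_sca_load <- function(segments, arm_table, meta = NULL) {
  alt <- segments[segments$class != "diploid", , drop = FALSE]
  patients <- if (is.null(meta)) unique(segments$patient_id) else meta$patient_id
  rows <- list()
  for (j in seq_len(nrow(arm_table))) {
    on_chrom <- alt[alt$chrom == arm_table$chrom[j], , drop = FALSE]
    if (nrow(on_chrom) == 0L) next
    ov_start <- pmax(on_chrom$start, arm_table$start[j])
    ov_end <- pmin(on_chrom$end, arm_table$end[j])
    hit <- ov_end > ov_start
    if (!any(hit)) next
    h <- on_chrom[hit, , drop = FALSE]
    rows[[j]] <- data.frame(
      patient_id = h$patient_id, chrom = arm_table$chrom[j],
      arm = arm_table$arm[j], class = h$class,
      mb = (ov_end[hit] - ov_start[hit]) / 1e6,
      arm_mb = arm_table$length_mb[j],
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) {
    return(data.frame(patient_id = character(0), chrom = character(0),
                      arm = character(0), class = character(0),
                      mb = numeric(0), n_segments = integer(0),
                      n_per_mb = numeric(0)))
  }
  agg <- stats::aggregate(
    cbind(mb = long$mb, n_segments = 1) ~ patient_id + chrom + arm + class +
      arm_mb,
    data = long, FUN = sum
  )
  agg$n_segments <- as.integer(agg$n_segments)
  agg$n_per_mb <- agg$n_segments / agg$arm_mb
  agg$arm_mb <- NULL
  agg$patient_id <- as.character(agg$patient_id)
  agg[order(agg$patient_id, agg$chrom, agg$arm), ]
}

#' Genome-doubling flag
#'
#' TRUE when the major allele copy number is >= 2 over more than half of the
#' assessable autosomal genome. With `background_diploid = TRUE` (the
#' convention for sparse alteration lists), territory not covered by any
#' segment counts as major copy number 1.
#'
#' @param segments One patient's segments.
#' @param arm_table Arm table defining the autosomal territory.
#' @param background_diploid Treat uncovered territory as diploid.
#' @return TRUE/FALSE, or NA when less than half the genome is assessable.
#' @export
genome_doubling_flag <- function(segments, arm_table,
                                 background_diploid = TRUE) {
  genome_bp <- sum(arm_table$end - arm_table$start)
  known <- !is.na(segments$minor_cn)
  segs <- segments[known, , drop = FALSE]
  major <- segs$total_cn - segs$minor_cn
  len <- as.numeric(segs$end - segs$start)
  covered <- sum(len)
  doubled <- sum(len[major >= 2])
  if (background_diploid) {
    assessable <- genome_bp
  } else {
    assessable <- covered
    if (assessable < 0.5 * genome_bp) return(NA)
  }
  doubled > 0.5 * assessable
}

#' Fisher test on focal-amplification prevalence by group
#'
#' Builds the 2x2 table of (NSAID group) x (any focal amplification) and
#' applies [fisher_exact_2x2].
#'
#' @param segments Cohort segments with `class`.
#' @param meta Patient table with `nsaid_user`.
#' @return A test result; `detail` holds the table cells.
#' @export
focal_amp_prevalence_test <- function(segments, meta) {
  has_amp <- meta$patient_id %in%
    unique(segments$patient_id[segments$class == "focal_amp"])
  tab <- matrix(c(
    sum(has_amp & meta$nsaid_user), sum(!has_amp & meta$nsaid_user),
    sum(has_amp & !meta$nsaid_user), sum(!has_amp & !meta$nsaid_user)
  ), 2L, 2L, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  res$detail <- list(user_amp = tab[1, 1], user_none = tab[1, 2],
                     nonuser_amp = tab[2, 1], nonuser_none = tab[2, 2])
  res
}

#' Simulate an exome probe track from true segments
#'
#' Lays probes at fixed spacing along each arm, sets the log-ratio from each
#' probe's true total copy number plus Gaussian noise, and BAF at a fraction
#' of (heterozygous) probes from the true allele ratio plus noise. Territory
#' not covered by `true_segments` is diploid (2, minor 1).
#'
#' @param true_segments data.frame `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn` (one patient).
#' @param arm_table Arm table.
#' @param spacing_bp Probe spacing.
#' @param lr_sd Log-ratio noise SD.
#' @param het_fraction Fraction of probes with a heterozygous site.
#' @param baf_sd BAF noise SD.
#' @return Track data.frame for [segment_and_call].
#' @export
simulate_probe_track <- function(true_segments, arm_table,
                                 spacing_bp = 50000L, lr_sd = 0,
                                 het_fraction = 0.3, baf_sd = 0.02) {
  rows <- lapply(seq_len(nrow(arm_table)), function(j) {
    pos <- seq.int(arm_table$start[j], arm_table$end[j] - 1L, by = spacing_bp)
    data.frame(chrom = arm_table$chrom[j], start = pos,
               end = pos + spacing_bp, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  total <- rep(2L, nrow(track))
  minor <- rep(1L, nrow(track))
  ts <- true_segments
  if (!is.null(ts) && nrow(ts)) {
    for (i in seq_len(nrow(ts))) {
      hit <- track$chrom == ts$chrom[i] & track$start >= ts$start[i] &
        track$start < ts$end[i]
      total[hit] <- ts$total_cn[i]
      minor[hit] <- ts$minor_cn[i]
    }
  }
  lr <- log2(pmax(total, 0.5) / 2) + stats::rnorm(nrow(track), 0, lr_sd)
  het <- stats::runif(nrow(track)) < het_fraction
  baf <- rep(NA_real_, nrow(track))
  frac <- ifelse(total > 0, minor / total, 0.5)
  noisy <- frac[het] + stats::rnorm(sum(het), 0, baf_sd)
  baf[het] <- pmin(pmax(noisy, 0), 1)
  track$log_ratio <- lr
  track$baf <- baf
  track$true_total <- total
  track$true_minor <- minor
  track
}
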