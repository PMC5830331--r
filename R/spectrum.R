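## 96-channel trinucleotide spectra and mutation-load summaries.

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The fixed 96-channel order
#'
#' Channels are ordered by substitution block (C>A, C>G, C>T, T>A, T>C, T>G),
#' and within each block by 5' flanking base then 3' flanking base, each in
#' A, C, G, T order. Labels follow the conventional `A[C>T]G` style so that
#' spectrum matrices interoperate with external signature tables.
#'
#' @return Character vector of length 96.
#' @export
channel_order <- function() {
  labs <- character(96)
  i <- 1L
  for (sub in SUBSTITUTIONS) {
    for (five in BASES) {
      for (three in BASES) {
        labs[i] <- paste0(five, "[", sub, "]", three)
        i <- i + 1L
      }
    }
  }
  labs
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""), character(1)
  ))
}

#' Pyrimidine-strand normalization of a base substitution
#'
#' A somatic substitution is referred to the pyrimidine of the mutated
#' Watson-Crick pair: if the reference base is a purine (A or G), both the
#' substitution and its trinucleotide context are reverse-complemented so the
#' mutated base reads as C or T.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context3 3-letter reference-strand context centered on the mutated
#'   base; `substr(context3, 2, 2)` must equal `ref`.
#' @return A data.frame with columns `substitution` (one of the 6 pyrimidine
#'   substitutions), `context` (pyrimidine-strand trinucleotide) and `channel`
#'   (the `A[C>T]G`-style label).
#' @examples
#' normalize_substitution("G", "T", "AGA") # C>A at TCT
#' @export
normalize_substitution <- function(ref, alt, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context3) == n)
  ok_chars <- grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt) &
    grepl("^[ACGT]{3}$", context3)
  if (!all(ok_chars)) stop("non-ACGT character in ref/alt/context3")
  if (any(ref == alt)) stop("ref and alt must differ for an SNV")
  mid <- substr(context3, 2L, 2L)
  if (any(mid != ref)) stop("context3 center base does not match ref")

  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, chartr("ACGT", "TGCA", ref), ref)
  a <- ifelse(purine, chartr("ACGT", "TGCA", alt), alt)
  ctx <- context3
  if (any(purine)) ctx[purine] <- revcomp(context3[purine])
  sub <- paste0(r, ">", a)
  channel <- paste0(substr(ctx, 1, 1), "[", sub, "]", substr(ctx, 3, 3))
  data.frame(substitution = sub, context = ctx, channel = channel,
             stringsAsFactors = FALSE)
}

#' Build a patients x 96 spectrum matrix from a mutation catalog
#'
#' Counts each patient's SNVs on the 96 pyrimidine-referenced channels; indels
#' carry no trinucleotide channel and are excluded. Patients with no SNVs get
#' all-zero rows; row order follows `meta$patient_id`.
#'
#' @param catalog Mutation catalog data.frame (see [read_catalog]).
#' @param meta Patient covariate data.frame with a `patient_id` column.
#' @return Integer matrix, `nrow(meta)` x 96, dimnames patient x channel.
#' @export
build_spectrum <- function(catalog, meta) {
  chans <- channel_order()
  patients <- meta$patient_id
  m <- matrix(0L, nrow = length(patients), ncol = 96L,
              dimnames = list(patients, chans))
  snv <- catalog[catalog$mut_type == "SNV", , drop = FALSE]
  if (nrow(snv) == 0L) return(m)
  norm <- normalize_substitution(snv$ref, snv$alt, snv$context3)
  tab <- table(factor(snv$patient_id, levels = patients),
               factor(norm$channel, levels = chans))
  m[] <- as.integer(tab)
  m
}

#' Per-patient mutation load and load per megabase
#'
#' @param catalog Mutation catalog.
#' @param meta Patient table with `patient_id` and `target_mb` (captured
#'   territory in Mb).
#' @param which One of `"all"`, `"functional"` (the five functional
#'   categories), `"snv"`, `"indel"`.
#' @return data.frame with `patient_id`, `n`, `load_per_mb`.
#' @export
mutation_load <- function(catalog, meta,
                          which = c("all", "functional", "snv", "indel")) {
  which <- match.arg(which)
  if (any(meta$target_mb <= 0)) stop("target_mb must be positive")
  keep <- switch(which,
    all        = rep(TRUE, nrow(catalog)),
    functional = classify_functional(catalog$category),
    snv        = catalog$mut_type == "SNV",
    indel      = catalog$mut_type %in% c("INS", "DEL")
  )
  sub <- catalog[keep, , drop = FALSE]
  n <- as.integer(table(factor(sub$patient_id, levels = meta$patient_id)))
  data.frame(patient_id = meta$patient_id, n = n,
             load_per_mb = n / meta$target_mb,
             stringsAsFactors = FALSE)
}

#' Per-patient, per-arm mutation density
#'
#' Assigns each mutation to a chromosome arm by position (1-based positions
#' against 0-based half-open arm intervals) and reports mutations per Mb of
#' arm. Mutations falling in no arm (centromeric/telomeric gaps) are dropped;
#' their count is attached as attribute `n_dropped`.
#'
#' @param catalog Mutation catalog.
#' @param arm_table Arm table as returned by [load_arm_table].
#' @param meta Patient table.
#' @return data.frame with one row per (patient, arm): `patient_id`, `chrom`,
#'   `arm`, `n`, `density` (/Mb).
#' @export
arm_density_table <- function(catalog, arm_table, meta) {
  arm_id <- paste0(arm_table$chrom, arm_table$arm)
  # map each mutation to an arm
  idx <- rep(NA_integer_, nrow(catalog))
  for (j in seq_len(nrow(arm_table))) {
    hit <- catalog$chrom == arm_table$chrom[j] &
      catalog$pos - 1L >= arm_table$start[j] &
      catalog$pos - 1L < arm_table$end[j]
    idx[hit] <- j
  }
  dropped <- sum(is.na(idx))
  kept <- !is.na(idx)
  tab <- table(factor(catalog$patient_id[kept], levels = meta$patient_id),
               factor(idx[kept], levels = seq_len(nrow(arm_table))))
  out <- data.frame(
    patient_id = rep(meta$patient_id, times = nrow(arm_table)),
    chrom = rep(arm_table$chrom, each = nrow(meta)),
    arm = rep(arm_table$arm, each = nrow(meta)),
    n = as.integer(tab),
    stringsAsFactors = FALSE
  )
  len_mb <- rep(arm_table$length_mb, each = nrow(meta))
  out$density <- out$n / len_mb
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a spectrum matrix as TSV (96 rows x patients)
#'
#' @param spectrum Matrix from [build_spectrum].
#' @param path Output file.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(channel = colnames(spectrum), t(spectrum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
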