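## Readers/writers for mutation catalogs, covariates, pathways, arms, segments.

CATALOG_COLUMNS <- c("patient_id", "chrom", "pos", "ref", "alt", "mut_type",
                     "context3", "vaf", "genes", "category")

.validate_catalog <- function(df, meta = NULL, source = "catalog") {
  df$pos <- as.integer(df$pos)
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  bad <- character(0)
  is_snv <- df$mut_type == "SNV"
  row_id <- function(i) paste0("line ", i + 1L) # +1 for the header line

  chk <- which(!df$mut_type %in% c("SNV", "INS", "DEL"))
  if (length(chk)) bad <- c(bad, paste0(row_id(chk), ": unknown mut_type"))
  chk <- which(is_snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L |
                           df$ref == df$alt))
  if (length(chk)) bad <- c(bad, paste0(row_id(chk), ": invalid SNV ref/alt"))
  chk <- which(is_snv & substr(df$context3, 2, 2) != df$ref)
  if (length(chk)) {
    bad <- c(bad, paste0(row_id(chk), ": context3 center does not match ref"))
  }
  chk <- which(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))
  if (length(chk)) bad <- c(bad, paste0(row_id(chk), ": vaf out of range"))
  chk <- which(!df$category %in% MUTATION_CATEGORIES)
  if (length(chk)) bad <- c(bad, paste0(row_id(chk), ": unknown category"))
  if (length(bad)) {
    stop("malformed rows in ", source, ":\n  ", paste(bad, collapse = "\n  "))
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(df$patient_id), meta$patient_id)
    if (length(unknown)) {
      stop("patient_id not in covariate table: ",
           paste(unknown, collapse = ", "))
    }
  }
  df
}

#' Read a somatic mutation catalog
#'
#' Accepts the canonical tab-separated dialect (header
#' `patient_id chrom pos ref alt mut_type context3 vaf genes category`;
#' `genes` is a comma-separated list, empty for none) or a VCF 4.x file with
#' `CTX3`, `VAF`, `GENES`, `CAT` INFO keys and the patient id in a `PID` INFO
#' key (one call per record). Malformed rows are reported with line numbers.
#'
#' @param path Input file (`.vcf` extension triggers VCF parsing).
#' @param meta Optional patient covariate table; if given, every patient in the
#'   catalog must appear in it.
#' @return data.frame with the canonical columns; `genes` is a list-column of
#'   character vectors.
#' @export
read_catalog <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    df <- .read_catalog_vcf(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
    if (length(missing_cols)) {
      stop("missing required column: ", paste(missing_cols, collapse = ", "))
    }
    df <- df[CATALOG_COLUMNS]
  }
  df <- .validate_catalog(df, meta, source = path)
  df$genes <- .split_genes(df$genes)
  df
}

.split_genes <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE),
         function(g) sort(unique(g[nzchar(g)])))
}

.read_catalog_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF catalogs requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF gives a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info1 <- function(key) {
    unname(vcfR::extract.info(v, element = key))
  }
  ref <- fix$REF
  alt <- fix$ALT
  mut_type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                     ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
  data.frame(
    patient_id = info1("PID"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = ref, alt = alt, mut_type = mut_type,
    context3 = info1("CTX3"),
    vaf = suppressWarnings(as.numeric(info1("VAF"))),
    genes = info1("GENES"),
    category = info1("CAT"),
    stringsAsFactors = FALSE
  )
}

#' Write a catalog in the canonical TSV dialect
#'
#' Read -> write -> read is the identity on records.
#'
#' @param catalog Catalog data.frame.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog[CATALOG_COLUMNS]
  if (is.list(out$genes)) {
    out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient covariate table
#'
#' TSV with header `patient_id nsaid_user ever_smoker tp53_mutant target_mb`,
#' booleans coded 0/1.
#'
#' @param path Input file.
#' @return data.frame with logical covariates and numeric `target_mb`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "nsaid_user", "ever_smoker", "tp53_mutant",
            "target_mb")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in covariates")
  if (any(df$target_mb <= 0)) stop("target_mb must be positive")
  for (col in c("nsaid_user", "ever_smoker", "tp53_mutant")) {
    df[[col]] <- as.logical(as.integer(df[[col]]))
  }
  df$target_mb <- as.numeric(df$target_mb)
  df[need]
}

#' Write a patient covariate table
#' @param meta Covariate data.frame.
#' @param path Output file.
#' @export
write_covariates <- function(meta, path) {
  out <- meta[c("patient_id", "nsaid_user", "ever_smoker", "tp53_mutant",
                "target_mb")]
  for (col in c("nsaid_user", "ever_smoker", "tp53_mutant")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, fields `name`, `description`, then gene
#' symbols, tab-separated. Gene sets are deduplicated.
#'
#' @param path GMT file.
#' @return Named list of character vectors (a `PathwayDB`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  short <- which(nfields < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields")
  }
  db <- fgsea::gmtPathways(path)
  db <- lapply(db, function(g) sort(unique(g[nzchar(g)])))
  if (any(lengths(db) == 0L)) stop("empty pathway in GMT")
  db
}

#' Write gene sets to a GMT file
#' @param pathways Named list of gene vectors.
#' @param path Output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a chromosome-arm table
#'
#' BED-like TSV with columns `chrom`, `arm`, `start`, `end` (0-based
#' half-open). The package ships hg19 autosome arm boundaries as the default.
#'
#' @param path Arm table file; default is the packaged hg19 table.
#' @return data.frame with an added `length_mb` column.
#' @export
load_arm_table <- function(path = system.file("extdata", "hg19_arms.tsv",
                                              package = "besomatic")) {
  at <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(at)))
  if (any(at$end <= at$start)) stop("arm with non-positive length")
  at$length_mb <- (at$end - at$start) / 1e6
  at
}

SEGMENT_COLUMNS <- c("patient_id", "chrom", "start", "end", "n_probes",
                     "log_ratio", "total_cn", "minor_cn", "class")

#' Read/write SCA segments in a SEG-like TSV
#'
#' Columns: `patient_id chrom start end n_probes log_ratio total_cn minor_cn
#' class`; intervals are 0-based half-open.
#'
#' @param path File path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SEGMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required column: ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$end <= df$start)) stop("segment with end <= start")
  df[SEGMENT_COLUMNS]
}

#' @rdname read_segments
#' @param segments Segment data.frame.
#' @export
write_segments <- function(segments, path) {
  for (col in setdiff(SEGMENT_COLUMNS, names(segments))) {
    segments[[col]] <- NA
  }
  utils::write.table(segments[SEGMENT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
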