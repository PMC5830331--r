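test_that("the 15-category taxonomy partitions into exactly 5 functional classes", {
  expect_length(MUTATION_CATEGORIES, 15L)
  expect_length(FUNCTIONAL_CATEGORIES, 5L)
  expect_length(intersect(FUNCTIONAL_CATEGORIES, NONFUNCTIONAL_CATEGORIES), 0L)
  expect_setequal(MUTATION_CATEGORIES,
                  c(FUNCTIONAL_CATEGORIES, NONFUNCTIONAL_CATEGORIES))
  flags <- classify_functional(MUTATION_CATEGORIES)
  expect_identical(sum(flags), 5L)
})

test_that("functional classification matches the study's definition", {
  expect_true(classify_functional("exon-non-synonymous"))
  expect_true(classify_functional("coding-splicing"))
  expect_true(all(classify_functional(c("3'utr-exon", "5'utr-exon",
                                        "utr-splicing"))))
  expect_false(classify_functional("intron-coding-gene"))
  expect_false(classify_functional("exon-synonymous"))
  expect_error(classify_functional("missense"), "unknown mutation category")
})

make_tsv <- function(rows, path) {
  header <- paste(c("patient_id", "chrom", "pos", "ref", "alt", "mut_type",
                    "context3", "vaf", "genes", "category"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("catalog TSV parsing is the identity on well-formed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_tsv(c(
    "P1\tchr1\t100\tC\tT\tSNV\tACG\t0.25\tG1\texon-non-synonymous",
    "P1\tchr2\t500\tG\tA\tSNV\tTGC\t0.10\t\tintron-coding-gene",
    "P2\tchr1\t900\tA\tAC\tINS\tNA\t0.40\tG2,G3\t3'utr-exon"
  ), path)
  cat <- read_catalog(path)
  expect_identical(nrow(cat), 3L)
  expect_identical(cat$pos, c(100L, 500L, 900L))
  expect_identical(cat$genes[[3]], c("G2", "G3"))
  expect_identical(cat$genes[[2]], character(0))
})

test_that("malformed catalog rows are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_tsv("P1\tchr1\t100\tC\tT\tSNV\tACG\t1.2\tG1\texon-non-synonymous",
           path)
  expect_error(read_catalog(path), "line 2.*vaf out of range")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tchrom\tpos", "P1\tchr1\t1"), path2)
  expect_error(read_catalog(path2), "missing required column.*ref")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  make_tsv("P9\tchr1\t100\tC\tT\tSNV\tACG\t0.2\tG1\texon-non-synonymous",
           path3)
  meta <- data.frame(patient_id = "P1", nsaid_user = TRUE,
                     ever_smoker = FALSE, tp53_mutant = FALSE,
                     target_mb = 100)
  expect_error(read_catalog(path3, meta), "patient_id not in covariate")
})

test_that("catalog read -> write -> read is the identity", {
  sc <- small_cohort()
  cat1 <- sc$cohort$catalog
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat1, path)
  cat2 <- read_catalog(path)
  for (col in c("patient_id", "chrom", "pos", "ref", "alt", "mut_type",
                "category")) {
    expect_identical(cat2[[col]], cat1[[col]])
  }
  expect_equal(cat2$vaf, cat1$vaf, tolerance = 1e-12)
  expect_identical(cat2$genes, unname(cat1$genes))
})

test_that("a VCF record round-trips to the same record as its TSV form", {
  skip_if_not_installed("vcfR")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  make_tsv("P1\tchr2\t1234\tG\tT\tSNV\tAGA\t0.3\tG7\texon-non-synonymous",
           tsv)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PID,Number=1,Type=String,Description=\"patient\">",
    "##INFO=<ID=CTX3,Number=1,Type=String,Description=\"context\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"vaf\">",
    "##INFO=<ID=GENES,Number=1,Type=String,Description=\"genes\">",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"category\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr2\t1234\t.\tG\tT\t.\tPASS\t",
           "PID=P1;CTX3=AGA;VAF=0.3;GENES=G7;CAT=exon-non-synonymous")
  ), vcf)
  a <- read_catalog(tsv)
  b <- read_catalog(vcf)
  expect_identical(a$patient_id, b$patient_id)
  expect_identical(a$pos, b$pos)
  expect_identical(a$ref, b$ref)
  expect_identical(a$context3, b$context3)
  expect_equal(a$vaf, b$vaf, tolerance = 1e-9)
  expect_identical(a$genes, b$genes)
  expect_identical(a$category, b$category)
})

test_that("GMT parsing deduplicates and keeps pathways independent", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA\tB", "P2\tdesc\tA\tA\tC"), path)
  db <- read_gmt(path)
  expect_identical(db$P1, c("A", "B"))
  expect_identical(db$P2, c("A", "C")) # duplicate collapsed
  expect_true("A" %in% db$P1 && "A" %in% db$P2)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA", "P2\tonlytwo"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("covariate table round-trips with 0/1 booleans", {
  sc <- small_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_covariates(sc$cohort$meta, path)
  meta2 <- read_covariates(path)
  expect_identical(meta2, sc$cohort$meta)
})

test_that("the packaged arm table is a valid non-overlapping partition", {
  at <- load_arm_table()
  expect_identical(nrow(at), 44L) # 22 autosomes x 2 arms
  expect_true(all(at$end > at$start))
  expect_equal(at$length_mb, (at$end - at$start) / 1e6)
  by_chrom <- split(at, at$chrom)
  for (arms in by_chrom) {
    expect_identical(nrow(arms), 2L)
    expect_true(arms$end[arms$arm == "p"] <= arms$start[arms$arm == "q"])
  }
})
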