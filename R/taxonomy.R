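#' Mutation annotation taxonomy
#'
#' Somatic calls are annotated into a fixed 15-category functional-impact
#' taxonomy. Five categories are "functional" (expected to alter the gene
#' product or its regulation): exon-non-synonymous, 3'utr-exon, 5'utr-exon,
#' coding-splicing, and utr-splicing. The remaining ten categories are a
#' stable non-functional partition of everything else a padded exome+UTR
#' capture can see.
#'
#' @format Character vectors of category names.
#' @name taxonomy
NULL

#' @rdname taxonomy
#' @export
FUNCTIONAL_CATEGORIES <- c(
  "exon-non-synonymous",
  "3'utr-exon",
  "5'utr-exon",
  "coding-splicing",
  "utr-splicing"
)

#' @rdname taxonomy
#' @export
NONFUNCTIONAL_CATEGORIES <- c(
  "exon-synonymous",
  "intron-coding-gene",
  "3'utr-intron",
  "5'utr-intron",
  "upstream-1kb",
  "downstream-1kb",
  "non-coding-RNA-exon",
  "non-coding-RNA-intron",
  "intergenic-near-capture",
  "other"
)

#' @rdname taxonomy
#' @export
MUTATION_CATEGORIES <- c(FUNCTIONAL_CATEGORIES, NONFUNCTIONAL_CATEGORIES)

#' Is an annotation category functional?
#'
#' @param category Character vector of annotation categories; each must be one
#'   of the 15 categories in [MUTATION_CATEGORIES].
#' @return Logical vector, `TRUE` for the five functional categories.
#' @examples
#' classify_functional("exon-non-synonymous") # TRUE
#' classify_functional("intron-coding-gene")  # FALSE
#' @export
classify_functional <- function(category) {
  bad <- setdiff(unique(category), MUTATION_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown mutation category: ", paste(bad, collapse = ", "))
  }
  category %in% FUNCTIONAL_CATEGORIES
}
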