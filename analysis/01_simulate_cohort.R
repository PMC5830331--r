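#!/usr/bin/env Rscript
# Stage 1: draw the default synthetic cohort -- 41 NSAID users vs 41 matched
# non-users with the study-condition mutation loads, signature mixtures,
# clonal VAF structure, pathway selection effect, and copy-number segments --
# and write every input the downstream stages need.

library(besomatic)

outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L

truth <- cohort_truth(seed = seed)
gene_table <- synthetic_gene_table()
pathways <- synthetic_pathways(gene_table)
reference <- make_reference_signatures()

cohort <- generate_cohort(truth, pathways, reference, gene_table)

write_catalog(cohort$catalog, file.path(outdir, "catalog.tsv"))
write_covariates(cohort$meta, file.path(outdir, "covariates.tsv"))
write_segments(cohort$segments, file.path(outdir, "segments.tsv"))
write_gmt(pathways, file.path(outdir, "pathways.gmt"))
write_truth(truth, file.path(outdir, "truth.json"))
utils::write.table(gene_table, file.path(outdir, "gene_intervals.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

grp <- cohort$meta$nsaid_user
snv <- mutation_load(cohort$catalog, cohort$meta, "snv")$n
ind <- mutation_load(cohort$catalog, cohort$meta, "indel")$n
cat(sprintf("cohort: %d patients, %d somatic calls\n",
            nrow(cohort$meta), nrow(cohort$catalog)))
cat(sprintf("mean SNVs/biopsy: %.2f (users) vs %.2f (non-users)\n",
            mean(snv[grp]), mean(snv[!grp])))
cat(sprintf("mean indels/biopsy: %.2f vs %.2f\n",
            mean(ind[grp]), mean(ind[!grp])))
cat("inputs written under", outdir, "\n")
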