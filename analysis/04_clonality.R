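#!/usr/bin/env Rscript
# Stage 4: VAF-based clonality. Restrict to diploid copy-neutral-balanced
# territory, compare high-VAF functional and non-functional mutation counts
# between groups at the 0.3 headline threshold, and scan the 0.05-0.50
# threshold grid.

library(besomatic)

indir <- "results/cohort"
outdir <- "results/clonality"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

meta <- read_covariates(file.path(indir, "covariates.tsv"))
catalog <- read_catalog(file.path(indir, "catalog.tsv"), meta)
segments <- read_segments(file.path(indir, "segments.tsv"))
grp <- meta$nsaid_user

diploid <- filter_diploid(catalog, segments)
cat(sprintf("%d of %d mutations lie in diploid balanced territory\n",
            nrow(diploid), nrow(catalog)))

for (which in c("functional", "nonfunctional")) {
  cts <- count_high_vaf(diploid, meta, 0.3, which)
  kw <- kruskal_wallis(cts$n_above[grp], cts$n_above[!grp])
  cat(sprintf("%s mutations with VAF > 0.3: median %d vs %d, KW p = %.3g\n",
              which, median(cts$n_above[grp]), median(cts$n_above[!grp]),
              kw$p_value))
}

for (which in c("functional", "nonfunctional")) {
  scan <- vaf_threshold_scan(diploid, meta, which = which)
  utils::write.table(scan,
                     file.path(outdir, paste0("vaf_scan_", which, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- scan$threshold[scan$q_raw <= 0.05]
  cat(sprintf("%s scan: thresholds flagged after BH: %s\n", which,
              if (length(sig)) paste(sig, collapse = " ") else "none"))
}
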