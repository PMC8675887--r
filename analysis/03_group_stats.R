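#!/usr/bin/env Rscript
# Pairwise Wilcoxon rank-sum tests of every JIP parameter across the
# bracket contrasts of the factorial design (day vs night, summer vs
# winter, population vs population), BH-corrected per parameter.
# Reads results/parameters.tsv + results/metadata.tsv;
# writes results/group_tests.tsv.

suppressPackageStartupMessages(library(ojipcap))

params <- utils::read.delim("results/parameters.tsv", stringsAsFactors = FALSE)
metadata <- read_metadata("results/metadata.tsv")
out <- pairwise_parameter_tests(params, metadata)
write_table(out$results, "results/group_tests.tsv")
if (nrow(out$skipped)) write_table(out$skipped, "results/skipped_contrasts.tsv")

sig <- out$results[out$results$p_adj < 0.05, ]
cat(sprintf("%d of %d contrasts significant after BH correction\n",
            nrow(sig), nrow(out$results)))
tab <- sort(table(sig$parameter), decreasing = TRUE)
cat("significant contrasts per parameter:\n")
print(tab)
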