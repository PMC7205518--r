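#!/usr/bin/env Rscript
# CRISPR-cas adaptive immunity: strict 1e-3 cas hit filter, multigene module
# calling by the <=5-ORF-spacing rule, type/subtype classification from
# signature domains, and per-phylum cas-gene abundance.

suppressMessages(library(defenscan))

ds <- read_dataset(file.path("results", "data"))
out_dir <- file.path("results", "cas")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

th <- thresholds()
ch <- filter_cas_hits(ds$hits, th)
cas_genes <- ds$genes[ds$genes$gene_id %in% unique(ch$gene_id), ]
modules <- classify_cas_modules(call_cas_modules(cas_genes, th), ch)
stats <- cas_abundance_stats(unique(ch$gene_id), modules, ds$genes, ds$taxonomy)

write.table(modules, file.path(out_dir, "cas_modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(stats$per_phylum, file.path(out_dir, "cas_per_phylum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(stats$type_distribution, file.path(out_dir, "cas_types.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(stats$subtype_distribution, file.path(out_dir, "cas_subtypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cas genes: %d on %d contigs; modules: %d (%d classified)\n",
            length(unique(ch$gene_id)), length(unique(cas_genes$contig_id)),
            nrow(modules), sum(modules$type != "unclassified")))
td <- stats$type_distribution
cat("Type shares:", paste(sprintf("%s=%.1f%%", td$type, 100 * td$fraction),
                          collapse = ", "), "\n")
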