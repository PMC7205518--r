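#!/usr/bin/env Rscript
# Marker-based defense-system annotation: E-value filtering of domain hits,
# per-gene system assignment, locus grouping and the per-phylum abundance
# tables (counts, log10(n+1) heatmap values, within-phylum fractions and the
# percent of defense genes per phylum).

suppressMessages(library(defenscan))

ds <- read_dataset(file.path("results", "data"))
out_dir <- file.path("results", "defense")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

th <- thresholds()
fh <- filter_defense_hits(ds$hits, th)
assignments <- assign_defense_systems(fh)
loci <- call_defense_loci(assignments, ds$genes, th)
mat <- phylum_defense_matrix(assignments, ds$genes, ds$taxonomy)
rel <- system_relative_abundance(mat)
pct <- defense_gene_percentage(mat)
hm <- heatmap_values(mat)

write.table(assignments, file.path(out_dir, "assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(loci, file.path(out_dir, "defense_loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rel, file.path(out_dir, "system_relative_abundance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(hm, file.path(out_dir, "phylum_system_log10.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(phylum = names(pct), pct_defense = unname(pct)),
            file.path(out_dir, "pct_defense_per_phylum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_amb <- sum(assignments$status == "ambiguous")
per_sys <- sort(table(assignments$system[assignments$status == "assigned"]),
                decreasing = TRUE)
cat(sprintf("Defense genes: %d (%d assigned, %d ambiguous), %.1f%% of all genes\n",
            nrow(assignments), nrow(assignments) - n_amb, n_amb,
            100 * nrow(assignments) / nrow(ds$genes)))
cat("Top systems:", paste(sprintf("%s=%d", names(per_sys), per_sys),
                          collapse = ", "), "\n")
cat("Loci called:", nrow(loci), "| tables in", out_dir, "\n")
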