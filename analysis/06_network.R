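#!/usr/bin/env Rscript
# Bipartite spacer-virome similarity network: nodes are spacers and matched
# viral contigs (colored by set in downstream viewers via the `kind`
# attribute), edges are threshold-passing alignments weighted by normalized
# score. Also categorizes viral gene annotations into virulence/evasion
# classes.

suppressMessages(library(defenscan))

ds <- read_dataset(file.path("results", "data"))
out_dir <- file.path("results", "network")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

arrays <- detect_arrays(ds$contigs)
spacers <- extract_spacers(arrays, ds$taxonomy)
matches <- do.call(rbind, lapply(unique(ds$viral$set), function(s) {
  match_spacers(spacers, ds$viral[ds$viral$set == s, ], target_set = s)
}))

net <- build_network(matches, spacers)
export_network(net, file.path(out_dir, "network.graphml"), "graphml")
export_network(net, file.path(out_dir, "network.sif"), "sif")
export_network(net, file.path(out_dir, "network"), "tsv")
hubs <- hub_report(net, k = 2)
write.table(hubs, file.path(out_dir, "hubs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# virulence/evasion categorization of (synthetic) viral gene annotations:
# a small description list dominated by methylases, as expected for phages
# evading restriction systems
set.seed(106)
pool <- c(rep("DNA methylase", 8), rep("Adenine-specific methyltransferase", 5),
          rep("Cytosine-specific DNA methylase", 2), "Chitinase class I",
          "Virulence-associated protein E", "Antirestriction ArdA family protein",
          rep("hypothetical protein", 40), rep("terminase large subunit", 6),
          rep("portal protein", 4))
desc <- data.frame(gene_id = sprintf("virgene%03d", seq_along(pool)),
                   description = sample(pool), stringsAsFactors = FALSE)
cats <- categorize_annotations(desc)
write.table(cats, file.path(out_dir, "virulence_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

comp <- igraph::components(net)
cat(sprintf("Network: %d nodes, %d edges, %d components\n",
            igraph::vcount(net), igraph::ecount(net), comp$no))
cat(sprintf("Hub viral contigs (>=2 spacers): %d; top degree: %s\n",
            nrow(hubs), if (nrow(hubs)) hubs$degree[1] else "-"))
cat("Gene categories (nonzero):\n")
print(cats[cats$n_genes > 0, ], row.names = FALSE)
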