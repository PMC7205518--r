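#!/usr/bin/env Rscript
# Build the synthetic hypolith-like community the downstream analyses run on:
# ~200 contigs (~5 Mb) with planted defense loci, cas modules, CRISPR arrays
# and two viral contig sets carrying protospacer copies. Ground truth goes to
# results/data/manifest.json. Run from the repository root.

suppressMessages(library(defenscan))

data_dir <- file.path("results", "data")
cfg <- sim_config(seed = 101)
bundle <- generate_dataset(cfg, out_dir = data_dir)

cat("Synthetic community written to", data_dir, "\n")
cat(sprintf("  contigs: %d (%.1f Mb), genes: %d\n",
            nrow(bundle$contigs), sum(bundle$contigs$length) / 1e6,
            nrow(bundle$genes)))
cat(sprintf("  planted defense loci: %d, cas modules: %d, arrays: %d\n",
            length(bundle$manifest$planted_loci),
            length(bundle$manifest$planted_cas_modules),
            length(bundle$manifest$planted_arrays)))
cat(sprintf("  viral contigs: %d internal + %d external, protospacers: %d\n",
            sum(bundle$viral$set == "internal"),
            sum(bundle$viral$set == "external"),
            length(bundle$manifest$protospacer_placements)))
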