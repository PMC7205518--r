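#!/usr/bin/env Rscript
# Spacer-to-virome matching with the dual identity thresholds: >90% identity
# against the community's own (internal) viral contigs, >95% against the
# external reference set, both at >=80% query coverage.

suppressMessages(library(defenscan))

ds <- read_dataset(file.path("results", "data"))
out_dir <- file.path("results", "match")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

arrays <- detect_arrays(ds$contigs)
spacers <- extract_spacers(arrays, ds$taxonomy)

matches <- do.call(rbind, lapply(unique(ds$viral$set), function(s) {
  match_spacers(spacers, ds$viral[ds$viral$set == s, ], target_set = s)
}))
summ <- match_summary(matches, nrow(spacers),
                      c(internal = sum(ds$viral$set == "internal"),
                        external = sum(ds$viral$set == "external")))

write.table(matches, file.path(out_dir, "matches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summ, file.path(out_dir, "match_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Matches: %d over %d spacers and %d viral contigs\n",
            nrow(matches), nrow(spacers), nrow(ds$viral)))
print(summ, row.names = FALSE)
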