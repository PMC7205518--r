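# Small in-code fixtures shared across test files.

mini_marker_table <- function() {
  read_marker_table()  # shipped default; placeholder accessions
}

# genes on one or more contigs from a compact spec:
# list(ctg1 = c(ordinals...)) -> gene calls with synthetic coordinates
genes_at_ordinals <- function(spec) {
  rows <- lapply(names(spec), function(ctg) {
    ords <- spec[[ctg]]
    data.frame(gene_id = sprintf("%s_g%03d", ctg, ords + 1L),
               contig_id = ctg,
               start = ords * 1000L, end = ords * 1000L + 900L,
               strand = "+", ordinal = ords, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

hit <- function(gene_id, acc, e, bit = 100) {
  data.frame(gene_id = gene_id, domain_accession = acc, e_value = e,
             bitscore = bit, stringsAsFactors = FALSE)
}

random_hits <- function(n, genes = sprintf("g%03d", 1:50),
                        accs = sprintf("ACC%03d", 1:30)) {
  data.frame(gene_id = sample(genes, n, replace = TRUE),
             domain_accession = sample(accs, n, replace = TRUE),
             e_value = 10^runif(n, -30, 1),
             bitscore = round(runif(n, 20, 500), 1),
             stringsAsFactors = FALSE)
}

# contig with one planted array; returns list(sequence, record)
contig_with_array <- function(len = 2000, n_spacers = 4, repeat_len = 28,
                              spacer_len = 33, at = 600) {
  seq <- defenscan:::rand_dna(len)
  plant_crispr_array(seq, n_spacers, repeat_len, spacer_len, at)
}

# small zero-noise synthetic bundle reused by several test files
small_bundle <- function(seed = 42) {
  generate_dataset(sim_config(
    seed = seed, n_contigs = 30, n_arrays = 5, n_cas_modules = 3,
    n_defense_loci_per_system = c(RM = 3, BREX = 2, DISARM = 2, Zorya = 1),
    n_viral_contigs = 6, n_external_viral = 3,
    protospacer_mutation_rate = 0, noise_hits_per_gene = 0))
}
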