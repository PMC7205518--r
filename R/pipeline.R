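#' Run the full analysis pipeline on a dataset
#'
#' Executes every stage in order on an in-memory bundle (from
#' [generate_dataset()]) or a dataset directory (files as written by
#' [write_dataset()]): defense E-value filtering and system assignment,
#' per-phylum abundance matrices, cas filtering / module calling / typing,
#' CRISPR array detection and spacer extraction, spacer matching against
#' the internal (and, when present, external) viral sets, network
#' construction, and report compilation. All steps are deterministic given
#' the inputs.
#'
#' @param dataset A bundle list or a directory path.
#' @param th [thresholds()].
#' @param cparams [crispr_params()].
#' @param mparams [match_params()].
#' @param marker_table,signatures Marker and cas-signature tables.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   (assignments, matrices, modules, arrays, spacers FASTA, matches,
#'   network exports, report JSON/TSVs).
#' @return List with `assignments`, `loci`, `matrix`, `relative_abundance`,
#'   `defense_pct`, `cas_hits`, `cas_modules`, `cas_stats`, `arrays`,
#'   `spacers`, `histogram`, `majority_cutoff`, `matches`, `match_summary`,
#'   `network`, `report`.
#' @export
run_pipeline <- function(dataset,
                         th = thresholds(),
                         cparams = crispr_params(),
                         mparams = match_params(),
                         marker_table = read_marker_table(),
                         signatures = read_cas_signatures(),
                         out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  genes <- dataset$genes
  taxonomy <- dataset$taxonomy

  # innate + adaptive defense annotation
  fh <- filter_defense_hits(dataset$hits, th)
  assignments <- assign_defense_systems(fh, marker_table)
  loci <- call_defense_loci(assignments, genes, th)
  mat <- phylum_defense_matrix(assignments, genes, taxonomy)
  rel <- system_relative_abundance(mat)
  pct <- defense_gene_percentage(mat)
  hm <- heatmap_values(mat)
  matrix_long <- merge(hm, rel[rel$system != "ambiguous", ],
                       by = c("phylum", "system", "count"), all.x = TRUE)
  matrix_long$pct_of_genes <- unname(pct[matrix_long$phylum])
  matrix_long <- matrix_long[order(matrix_long$phylum, matrix_long$system), ]
  rownames(matrix_long) <- NULL

  # cas modules
  ch <- filter_cas_hits(dataset$hits, th,
                        cas_accessions(marker_table, signatures))
  cas_genes <- genes[genes$gene_id %in% unique(ch$gene_id), , drop = FALSE]
  modules <- call_cas_modules(cas_genes, th)
  modules <- classify_cas_modules(modules, ch, signatures)
  cas_stats <- cas_abundance_stats(unique(ch$gene_id), modules, genes, taxonomy)

  # CRISPR arrays
  arrays <- detect_arrays(dataset$contigs, cparams)
  spacers <- extract_spacers(arrays, taxonomy)
  hist <- if (nrow(arrays)) array_size_histogram(arrays) else NULL
  cutoff <- if (!is.null(hist)) majority_cutoff(hist, th$majority_cutoff) else NULL

  # spacer-virome matching
  matches <- NULL
  viral <- dataset$viral
  if (!is.null(viral) && nrow(spacers) > 0) {
    matches <- do.call(rbind, lapply(unique(viral$set), function(s) {
      match_spacers(spacers, viral[viral$set == s, , drop = FALSE],
                    target_set = s, params = mparams, th = th)
    }))
  }
  msum <- if (!is.null(matches) && nrow(matches)) {
    match_summary(matches, nrow(spacers),
                  stats::setNames(as.integer(table(viral$set)[unique(matches$target_set)]),
                                  unique(matches$target_set)))
  } else NULL

  # network
  network <- if (!is.null(matches) && nrow(matches)) {
    build_network(matches, spacers)
  } else NULL

  report <- compile_report(
    defense = list(assignments = assignments, matrix = mat,
                   matrix_long = matrix_long),
    cas = list(modules = modules, stats = cas_stats),
    crispr = if (nrow(arrays)) list(arrays = arrays, spacers = spacers,
                                    histogram = hist,
                                    majority_cutoff = as.integer(cutoff)) else NULL,
    match = if (!is.null(matches) && nrow(matches)) list(matches = matches,
                                                         summary = msum) else NULL,
    network = if (!is.null(network)) list(
      n_nodes = igraph::vcount(network),
      n_edges = igraph::ecount(network),
      n_components = igraph::components(network)$no) else NULL,
    config = list(thresholds = unclass(th), crispr = unclass(cparams),
                  match = unclass(mparams)),
    label = "synthetic_community"
  )

  out <- list(assignments = assignments, loci = loci, matrix = mat,
              relative_abundance = rel, defense_pct = pct,
              matrix_long = matrix_long,
              cas_hits = ch, cas_modules = modules, cas_stats = cas_stats,
              arrays = arrays, spacers = spacers, histogram = hist,
              majority_cutoff = cutoff, matches = matches,
              match_summary = msum, network = network, report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return A bundle list (manifest included when present).
#' @export
read_dataset <- function(dir) {
  viral_files <- list.files(dir, pattern = "^viral_.*\\.fasta$", full.names = TRUE)
  viral <- do.call(rbind, lapply(viral_files, function(f) {
    v <- read_fasta(f)
    v$set <- sub("^viral_(.*)\\.fasta$", "\\1", basename(f))
    v
  }))
  manifest_path <- file.path(dir, "manifest.json")
  list(
    contigs = read_fasta(file.path(dir, "contigs.fasta")),
    genes = read_gff(file.path(dir, "genes.gff")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    hits = read_hit_table(file.path(dir, "hits.tsv")),
    viral = viral,
    manifest = if (file.exists(manifest_path))
      jsonlite::read_json(manifest_path, simplifyVector = FALSE) else NULL
  )
}

write_pipeline_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(out$assignments, "assignments.tsv")
  wt(out$loci, "defense_loci.tsv")
  wt(out$matrix_long, "phylum_matrix.tsv")
  wt(out$cas_modules, "cas_modules.tsv")
  arr <- out$arrays
  if (nrow(arr)) {
    arr_flat <- arr[, c("array_id", "contig_id", "start", "end", "period",
                        "repeat_len", "n_repeats", "size", "repeat_consensus")]
    wt(arr_flat, "arrays.tsv")
    write_spacers(out$spacers, file.path(dir, "spacers.fasta"))
    wt(out$histogram, "array_size_histogram.tsv")
  }
  if (!is.null(out$matches)) wt(out$matches, "matches.tsv")
  if (!is.null(out$network)) {
    export_network(out$network, file.path(dir, "network.graphml"), "graphml")
    export_network(out$network, file.path(dir, "network.sif"), "sif")
  }
  write_report(out$report, dir)
  invisible(dir)
}
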