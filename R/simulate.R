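#' Synthetic community configuration
#'
#' Defaults emulate, at desk scale, the statistical structure the analysis
#' assumes for a cold-desert soil metagenome: ~200 contigs totalling ~5 Mb,
#' a phylum mix dominated by Proteobacteria/Actinobacteria with a large
#' unknown fraction, defense loci planted with RM/BREX/DISARM most
#' abundant, a handful of multigene cas modules, CRISPR arrays with a
#' right-skewed size distribution starting at 2 spacers, and viral contigs
#' carrying (optionally mutated) copies of planted spacers.
#'
#' @param seed Integer RNG seed; the whole bundle is a pure function of it.
#' @param n_contigs Number of microbial contigs.
#' @param contig_length_range Min/max contig length (bp).
#' @param phyla Named numeric vector of phylum weights (sum 1).
#' @param n_defense_loci_per_system Named integer vector, loci per system
#'   (CRISPR excluded; cas modules are planted separately).
#' @param n_cas_modules Number of multigene cas modules to plant.
#' @param cas_module_subtypes Subtypes cycled over when planting modules.
#' @param n_arrays Number of CRISPR arrays to plant.
#' @param array_size_distribution Named numeric vector: P(size); names are
#'   spacer counts (>= 2).
#' @param repeat_length_range,spacer_length_range Array geometry (bp).
#' @param n_viral_contigs,n_external_viral Internal / external viral contig
#'   counts.
#' @param viral_length_range Viral contig length range (bp).
#' @param protospacer_per_viral_range Protospacers per viral contig.
#' @param protospacer_mutation_rate Per-base substitution probability
#'   applied to protospacer copies (substitutions only).
#' @param noise_hits_per_gene Mean count of spurious domain hits per gene
#'   (Poisson); noise accessions never collide with marker accessions.
#' @param noise_e_value_range Log-uniform bounds for noise hit E-values.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 200L,
                       contig_length_range = c(18000L, 32000L),
                       phyla = c(Proteobacteria = 0.15, Actinobacteria = 0.12,
                                 Bacteroidetes = 0.08, Cyanobacteria = 0.06,
                                 Acidobacteria = 0.04, Chloroflexi = 0.03,
                                 Firmicutes = 0.03, Gemmatimonadetes = 0.02,
                                 Planctomycetes = 0.02, Verrucomicrobia = 0.02,
                                 Euryarchaeota = 0.02, `Deinococcus-Thermus` = 0.01,
                                 unknown = 0.40),
                       n_defense_loci_per_system = c(RM = 8L, BREX = 5L,
                                                     DISARM = 4L, Zorya = 3L,
                                                     Abi = 2L, Thoeris = 1L,
                                                     Shedu = 1L, Gabija = 1L,
                                                     Hachiman = 1L),
                       n_cas_modules = 6L,
                       cas_module_subtypes = c("I-C", "I-E", "I-U", "II-A",
                                               "III-A", "I-B"),
                       n_arrays = 12L,
                       array_size_distribution = NULL,
                       repeat_length_range = c(19L, 38L),
                       spacer_length_range = c(19L, 48L),
                       n_viral_contigs = 30L,
                       n_external_viral = 12L,
                       viral_length_range = c(5000L, 15000L),
                       protospacer_per_viral_range = c(1L, 4L),
                       protospacer_mutation_rate = 0.02,
                       noise_hits_per_gene = 0.3,
                       noise_e_value_range = c(1e-6, 1)) {
  if (is.null(array_size_distribution)) {
    array_size_distribution <- default_array_size_distribution()
  }
  if (abs(sum(array_size_distribution) - 1) > 1e-9) {
    stop("array_size_distribution probabilities must sum to 1")
  }
  if (abs(sum(phyla) - 1) > 1e-9) stop("phylum weights must sum to 1")
  if (protospacer_mutation_rate < 0 || protospacer_mutation_rate > 1) {
    stop("mutation rate must lie in [0, 1]")
  }
  stopifnot(diff(contig_length_range) >= 0, diff(viral_length_range) >= 0,
            all(as.integer(names(array_size_distribution)) >= 2))
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted array-size distribution
#'
#' Right-skewed truncated geometric over 2..25 spacers (P(k) proportional
#' to 0.85^k), emulating the short-array-dominated size spectra seen in
#' soil metagenomes.
#' @return Named numeric vector of probabilities.
#' @export
default_array_size_distribution <- function() {
  sizes <- 2:25
  p <- 0.85^sizes
  stats::setNames(p / sum(p), sizes)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_evalue <- function(n, lo_exp, hi_exp) 10^stats::runif(n, lo_exp, hi_exp)

#' Plant a CRISPR array into a sequence
#'
#' Overwrites `(n_spacers + 1)` identical copies of a random repeat
#' interleaved with `n_spacers` mutually distinct random spacers at
#' position `at` (0-based). The bases immediately flanking the block are
#' adjusted to break the repeat periodicity at the boundary, so the planted
#' coordinates are exactly recoverable. Uses the current RNG stream.
#'
#' @param sequence Contig sequence (string).
#' @param n_spacers Number of spacers (>= 2).
#' @param repeat_len,spacer_len Repeat and spacer length (bp).
#' @param at 0-based start of the block.
#' @return List with `sequence` (modified) and `record` (`start`, `end`,
#'   `period`, `repeat_len`, `repeat_consensus`, `spacers`).
#' @export
plant_crispr_array <- function(sequence, n_spacers, repeat_len, spacer_len, at) {
  if (n_spacers < 2) stop("arrays need at least 2 spacers")
  block_len <- (n_spacers + 1L) * repeat_len + n_spacers * spacer_len
  if (at < 0 || at + block_len > nchar(sequence)) {
    stop("insufficient room: block of ", block_len, " bp at position ", at,
         " does not fit in ", nchar(sequence), " bp")
  }
  repeat_seq <- rand_dna(repeat_len)
  spacers <- character(n_spacers)
  for (i in seq_len(n_spacers)) {
    repeat {
      s <- rand_dna(spacer_len)
      ok <- TRUE
      if (i > 1) {
        prev <- spacers[seq_len(i - 1)]
        sim <- vapply(prev, function(p) {
          mean(strsplit(s, "")[[1]] == strsplit(p, "")[[1]])
        }, numeric(1))
        ok <- all(sim <= 0.55)
      }
      if (ok) break
    }
    spacers[i] <- s
  }
  block <- paste0(paste0(repeat_seq, spacers, collapse = ""), repeat_seq)
  stopifnot(nchar(block) == block_len)
  d <- repeat_len + spacer_len
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  seq_chars[(at + 1):(at + block_len)] <- strsplit(block, "", fixed = TRUE)[[1]]
  # boundary sentinels: break periodic agreement just outside the block
  if (at >= 1) {
    inner <- seq_chars[at + d]  # last base of spacer 1's period partner
    seq_chars[at] <- sample(setdiff(c("A", "C", "G", "T"), inner), 1)
  }
  if (at + block_len < length(seq_chars)) {
    inner <- seq_chars[at + repeat_len + 1]  # first base of first spacer
    seq_chars[at + block_len + 1] <- sample(setdiff(c("A", "C", "G", "T"), inner), 1)
  }
  list(sequence = paste(seq_chars, collapse = ""),
       record = list(start = as.integer(at),
                     end = as.integer(at + block_len),
                     period = as.integer(d),
                     repeat_len = as.integer(repeat_len),
                     repeat_consensus = repeat_seq,
                     spacers = spacers))
}

mutate_substitutions <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(sequence = paste(chars, collapse = ""), n_mutations = length(hit))
}

#' Generate a synthetic community dataset with ground truth
#'
#' Produces microbial contigs with tiled gene calls and taxonomy, planted
#' defense loci (each laid out as the contiguous core marker genes of one
#' system/subtype, with marker-accession domain hits below the defense
#' E-value cutoff), planted multigene cas modules with signature domains,
#' planted CRISPR arrays in gene-free contig tails, Poisson noise domain
#' hits to non-marker accessions, and internal/external viral contig sets
#' carrying (optionally substituted) protospacer copies of planted spacers.
#' The bundle is a pure function of `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `contigs.fasta`, `genes.gff`, `taxonomy.tsv`, `hits.tsv`,
#'   `viral_internal.fasta`, `viral_external.fasta` and `manifest.json`.
#' @param marker_table Marker table used for planting (default shipped).
#' @return List with `contigs`, `genes`, `taxonomy`, `hits`, `viral`
#'   (data.frames; `viral` has a `set` column) and `manifest` (list).
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL,
                             marker_table = read_marker_table()) {
  set.seed(config$seed, kind = "Mersenne-Twister")
  cl <- config$contig_length_range
  tail_reserve <- 2600L

  n <- config$n_contigs
  contig_ids <- sprintf("ctg%04d", seq_len(n))
  lens <- sample(cl[1]:cl[2], n, replace = TRUE)
  seqs <- vapply(lens, rand_dna, character(1))

  phyla <- sample(names(config$phyla), n, replace = TRUE,
                  prob = unname(config$phyla))
  taxonomy <- data.frame(contig_id = contig_ids, phylum = phyla,
                         stringsAsFactors = FALSE)

  # tile genes over the head of each contig, leaving a gene-free tail
  gene_rows <- vector("list", n)
  for (ci in seq_len(n)) {
    pos <- 60L
    limit <- lens[ci] - tail_reserve
    starts <- integer(0); ends <- integer(0)
    while (TRUE) {
      glen <- sample(seq(600L, 1200L, by = 3L), 1)
      if (pos + glen > limit) break
      starts <- c(starts, pos); ends <- c(ends, pos + glen)
      pos <- pos + glen + sample(60:180, 1)
    }
    if (length(starts)) {
      gene_rows[[ci]] <- data.frame(
        gene_id = sprintf("%s_g%03d", contig_ids[ci], seq_along(starts)),
        contig_id = contig_ids[ci], start = starts, end = ends,
        strand = sample(c("+", "-"), length(starts), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  genes <- assign_ordinals(do.call(rbind, gene_rows))

  # bookkeeping for locus placement: per contig, which gene ordinals are free
  used <- stats::setNames(lapply(gene_rows, function(g) {
    if (is.null(g)) logical(0) else logical(nrow(g))
  }), contig_ids)
  place_locus <- function(k) {
    for (try in 1:2000) {
      ci <- sample(contig_ids, 1)
      m <- length(used[[ci]])
      if (m < k) next
      s <- sample(seq_len(m - k + 1), 1)
      if (any(used[[ci]][s:(s + k - 1)])) next
      used[[ci]][s:(s + k - 1)] <<- TRUE
      return(list(contig_id = ci, idx = s:(s + k - 1)))
    }
    stop("could not place a locus of ", k, " genes: requested features ",
         "exceed available gene space (", sum(lengths(used)), " genes)")
  }
  gene_id_at <- function(ci, idx) sprintf("%s_g%03d", ci, idx)

  hits_rows <- list()
  add_hits <- function(gene_ids, accessions, e_max_exp) {
    hits_rows[[length(hits_rows) + 1L]] <<- data.frame(
      gene_id = gene_ids, domain_accession = accessions,
      e_value = rand_evalue(length(gene_ids), -30, e_max_exp),
      bitscore = round(stats::runif(length(gene_ids), 50, 500), 1),
      stringsAsFactors = FALSE)
  }

  # --- defense loci ---------------------------------------------------
  map <- marker_accession_map(marker_table)
  first_acc <- map[!duplicated(paste(map$system, map$marker_name)), ]
  planted_loci <- list()
  for (sys in names(config$n_defense_loci_per_system)) {
    subtypes <- unique(marker_table$subtype[marker_table$system == sys])
    for (r in seq_len(config$n_defense_loci_per_system[[sys]])) {
      sub <- if (length(subtypes) > 1) sample(subtypes, 1) else subtypes
      mk <- first_acc[first_acc$system == sys & first_acc$subtype == sub, ]
      loc <- place_locus(nrow(mk))
      gids <- gene_id_at(loc$contig_id, loc$idx)
      add_hits(gids, mk$accession, -2.2)
      planted_loci[[length(planted_loci) + 1L]] <- list(
        system = sys, subtype = sub, contig_id = loc$contig_id,
        gene_ids = gids, marker_names = mk$marker_name)
    }
  }

  # --- cas modules ------------------------------------------------------
  cas_marker_for <- function(subtype) {
    sig <- switch(substr(subtype, 1, 1),
                  "I" = "cas3", "II" = "cas9", "III" = "cas10")
    sub_marker <- switch(subtype,
                         "I-A" = "cas8a", "I-B" = "cas8b", "I-C" = "cas8c",
                         "I-E" = "cse1", "I-F" = "csy1", "I-U" = "GSU0054",
                         "II-A" = "csn2", "III-A" = "csm2", "III-B" = "cmr5",
                         NULL)
    type_sig <- switch(subtype, "II-A" = "cas9", "III-A" = "cas10",
                       "III-B" = "cas10", "cas3")
    unique(c("cas1", "cas2", "cas4", type_sig, sub_marker))
  }
  planted_modules <- list()
  for (r in seq_len(config$n_cas_modules)) {
    subtype <- config$cas_module_subtypes[((r - 1) %% length(config$cas_module_subtypes)) + 1]
    markers <- cas_marker_for(subtype)
    mk <- first_acc[first_acc$system == "CRISPR" &
                      first_acc$marker_name %in% markers, ]
    mk <- mk[match(markers, mk$marker_name), ]
    loc <- place_locus(nrow(mk))
    gids <- gene_id_at(loc$contig_id, loc$idx)
    add_hits(gids, mk$accession, -3.2)
    planted_modules[[length(planted_modules) + 1L]] <- list(
      contig_id = loc$contig_id, gene_ids = gids,
      type = substr(subtype, 1, regexpr("-", subtype) - 1), subtype = subtype)
    planted_loci[[length(planted_loci) + 1L]] <- list(
      system = "CRISPR", subtype = "", contig_id = loc$contig_id,
      gene_ids = gids, marker_names = mk$marker_name)
  }

  # --- CRISPR arrays in gene-free tails --------------------------------
  if (config$n_arrays > n) {
    stop("requested ", config$n_arrays, " arrays but only ", n, " contigs")
  }
  array_contigs <- sample(contig_ids, config$n_arrays)
  planted_arrays <- list()
  size_lv <- as.integer(names(config$array_size_distribution))
  for (ai in seq_len(config$n_arrays)) {
    ci <- array_contigs[ai]
    k <- sample(size_lv, 1, prob = unname(config$array_size_distribution))
    rl <- sample(config$repeat_length_range[1]:config$repeat_length_range[2], 1)
    sl <- sample(config$spacer_length_range[1]:config$spacer_length_range[2], 1)
    block <- (k + 1L) * rl + k * sl
    L <- lens[match(ci, contig_ids)]
    at <- L - tail_reserve + 50L
    if (at + block + 1 > L) {  # long arrays: shrink to fit the tail
      k <- max(2L, (tail_reserve - 100L - rl) %/% (rl + sl))
      block <- (k + 1L) * rl + k * sl
    }
    res <- plant_crispr_array(seqs[match(ci, contig_ids)], k, rl, sl, at)
    seqs[match(ci, contig_ids)] <- res$sequence
    rec <- res$record
    rec$array_ref <- sprintf("parr%03d", ai)
    rec$contig_id <- ci
    rec$size <- k
    planted_arrays[[ai]] <- rec
  }

  # --- noise domain hits ------------------------------------------------
  if (config$noise_hits_per_gene > 0) {
    nh <- stats::rpois(nrow(genes), config$noise_hits_per_gene)
    idx <- rep(seq_len(nrow(genes)), nh)
    if (length(idx)) {
      lo <- log10(config$noise_e_value_range[1])
      hi <- log10(config$noise_e_value_range[2])
      hits_rows[[length(hits_rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[idx],
        domain_accession = sprintf("NOISE%03d", sample(1:200, length(idx), replace = TRUE)),
        e_value = rand_evalue(length(idx), lo, hi),
        bitscore = round(stats::runif(length(idx), 20, 60), 1),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits_rows)
  hits <- hits[order(hits$gene_id, hits$domain_accession), , drop = FALSE]
  rownames(hits) <- NULL

  # --- viral contigs with protospacers ----------------------------------
  all_spacers <- do.call(rbind, lapply(planted_arrays, function(a) {
    data.frame(spacer_ref = paste(a$array_ref, seq_along(a$spacers) - 1, sep = ":"),
               sequence = a$spacers, stringsAsFactors = FALSE)
  }))
  make_viral_set <- function(n_viral, set, prefix) {
    if (n_viral == 0) return(list(viral = NULL, placements = list()))
    vlens <- sample(config$viral_length_range[1]:config$viral_length_range[2],
                    n_viral, replace = TRUE)
    vseqs <- vapply(vlens, rand_dna, character(1))
    vids <- sprintf("%s%03d", prefix, seq_len(n_viral))
    placements <- list()
    for (vi in seq_len(n_viral)) {
      kk <- sample(config$protospacer_per_viral_range[1]:config$protospacer_per_viral_range[2], 1)
      taken <- integer(0)
      for (p in seq_len(kk)) {
        sp <- all_spacers[sample(nrow(all_spacers), 1), ]
        mut <- mutate_substitutions(sp$sequence, config$protospacer_mutation_rate)
        ins <- mut$sequence
        strand <- sample(c("+", "-"), 1)
        if (strand == "-") ins <- revcomp(ins)
        Lp <- nchar(ins)
        ok <- FALSE
        for (try in 1:50) {
          at <- sample(0:(vlens[vi] - Lp), 1)
          if (!any(abs(at - taken) < 60L)) { ok <- TRUE; break }
        }
        if (!ok) next
        taken <- c(taken, at)
        s <- vseqs[vi]
        vseqs[vi] <- paste0(substr(s, 1, at), ins, substr(s, at + Lp + 1, nchar(s)))
        placements[[length(placements) + 1L]] <- list(
          viral_contig_id = vids[vi], spacer_ref = sp$spacer_ref,
          position = as.integer(at), strand = strand,
          n_mutations = mut$n_mutations, set = set)
      }
    }
    list(viral = data.frame(contig_id = vids, sequence = vseqs,
                            length = nchar(vseqs), set = set,
                            stringsAsFactors = FALSE),
         placements = placements)
  }
  internal <- make_viral_set(config$n_viral_contigs, "internal", "vir")
  external <- make_viral_set(config$n_external_viral, "external", "ext")
  viral <- rbind(internal$viral, external$viral)

  contigs <- data.frame(contig_id = contig_ids, sequence = seqs,
                        length = nchar(seqs), stringsAsFactors = FALSE)
  manifest <- list(
    schema_version = "1.0",
    seed = config$seed,
    planted_loci = planted_loci,
    planted_cas_modules = planted_modules,
    planted_arrays = planted_arrays,
    protospacer_placements = c(internal$placements, external$placements)
  )
  bundle <- list(contigs = contigs, genes = genes, taxonomy = taxonomy,
                 hits = hits, viral = viral, manifest = manifest)
  if (!is.null(out_dir)) write_dataset(bundle, out_dir)
  bundle
}

#' Write a synthetic dataset bundle to disk
#'
#' @param bundle Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(bundle$contigs, file.path(dir, "contigs.fasta"))
  write_gff(bundle$genes, file.path(dir, "genes.gff"))
  write_taxonomy(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_hit_table(bundle$hits, file.path(dir, "hits.tsv"))
  for (s in unique(bundle$viral$set)) {
    write_fasta(bundle$viral[bundle$viral$set == s, ],
                file.path(dir, paste0("viral_", s, ".fasta")))
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
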