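#' Read assembled contigs from FASTA
#'
#' Sequences are uppercased and RNA-style `U` is mapped to `T`. Returns one
#' row per record.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `contig_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(contig_id = ids, sequence = unname(seqs),
             length = nchar(unname(seqs)), stringsAsFactors = FALSE)
}

#' Write contigs to FASTA
#'
#' @param contigs Data.frame with `contig_id` and `sequence`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 60L) {
  set <- Biostrings::BStringSet(contigs$sequence)
  names(set) <- contigs$contig_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene calls from GFF3
#'
#' CDS and gene features carrying an `ID` attribute become gene calls.
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' Ordinals (the index of a gene along its contig) are assigned per contig
#' by ascending start, ties broken by ascending end, then gene id.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `ordinal`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("GFF feature(s) without an ID attribute in ", path)
  }
  genes <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(genes$start >= genes$end)) stop("gene with start >= end in ", path)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in ", path)
  assign_ordinals(genes)
}

#' Assign per-contig gene ordinals
#'
#' @param genes Data.frame with `gene_id`, `contig_id`, `start`, `end`.
#' @return The input with an `ordinal` column, rows sorted by contig then
#'   ordinal.
#' @export
assign_ordinals <- function(genes) {
  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                              FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Write gene calls to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to 1-based
#' inclusive GFF3 coordinates.
#'
#' @param genes Data.frame from [read_gff()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tdefenscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$contig_id, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tabular domain-hit table
#'
#' Expects a TSV with header containing at least `gene_id`,
#' `domain_accession`, `e_value` and `bitscore` (extra columns are ignored);
#' this is the tabular-BLAST-style output of an upstream conserved-domain
#' search. Scientific-notation E-values are accepted.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four canonical columns.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "domain_accession", "e_value", "bitscore")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    return(data.frame(gene_id = character(), domain_accession = character(),
                      e_value = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  ev <- suppressWarnings(as.numeric(df$e_value))
  if (anyNA(ev)) {
    stop("non-numeric e_value in hit table row(s): ",
         paste(which(is.na(ev)), collapse = ", "))
  }
  bs <- suppressWarnings(as.numeric(df$bitscore))
  if (anyNA(bs)) {
    stop("non-numeric bitscore in hit table row(s): ",
         paste(which(is.na(bs)), collapse = ", "))
  }
  if (any(ev < 0)) stop("negative e_value in hit table")
  data.frame(gene_id = df$gene_id, domain_accession = df$domain_accession,
             e_value = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Write a domain-hit table
#'
#' @param hits Data.frame of hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(gene_id = hits$gene_id,
                    domain_accession = hits$domain_accession,
                    e_value = format(hits$e_value, scientific = TRUE, digits = 8),
                    bitscore = format(hits$bitscore, digits = 8),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contig taxonomy table
#'
#' Two-column TSV: `contig_id<TAB>phylum`. Contigs may be labelled
#' `"unknown"`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `contig_id` and `phylum`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("contig_id", "phylum") %in% names(df))) {
    stop("taxonomy table needs columns contig_id and phylum")
  }
  if (anyDuplicated(df$contig_id)) stop("duplicate contig_id in taxonomy table")
  df[, c("contig_id", "phylum")]
}

#' Write a contig taxonomy table
#' @param taxonomy Data.frame with `contig_id`, `phylum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("contig_id", "phylum")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
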