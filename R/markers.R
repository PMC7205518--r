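#' Read a defense-system marker table
#'
#' TSV columns: `system`, `subtype` (may be empty), `marker_name`,
#' `accessions` (comma-separated conserved-domain accessions) and
#' `canonical` (0/1). One row per marker gene; an accession may appear under
#' several systems (such shared domains produce "ambiguous" assignments).
#'
#' @param path Path to the TSV; defaults to the table shipped with the
#'   package, whose accessions are placeholders meant to be replaced by a
#'   curated COG/Pfam list.
#' @return A data.frame with columns `system`, `subtype`, `marker_name`,
#'   `accessions` (comma-separated string) and `canonical` (logical).
#' @export
read_marker_table <- function(path = default_marker_path()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("system", "subtype", "marker_name", "accessions", "canonical")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("system", "marker_name")])) {
    stop("duplicate (system, marker_name) row in marker table")
  }
  if (any(!nzchar(df$accessions))) stop("marker row with empty accession list")
  df$canonical <- df$canonical %in% c("1", "TRUE", "true")
  df[, need]
}

default_marker_path <- function() {
  system.file("extdata", "marker_table.tsv", package = "defenscan", mustWork = TRUE)
}

#' Expand a marker table to one row per accession
#'
#' @param marker_table Data.frame from [read_marker_table()].
#' @return A data.frame with `accession`, `system`, `subtype`,
#'   `marker_name`, `canonical`; the join table used by
#'   [assign_defense_systems()].
#' @export
marker_accession_map <- function(marker_table) {
  accs <- strsplit(marker_table$accessions, ",", fixed = TRUE)
  n <- lengths(accs)
  out <- data.frame(
    accession = trimws(unlist(accs)),
    system = rep(marker_table$system, n),
    subtype = rep(marker_table$subtype, n),
    marker_name = rep(marker_table$marker_name, n),
    canonical = rep(marker_table$canonical, n),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("accession", "system", "marker_name")])
  out[!dup, , drop = FALSE]
}

#' Read a cas signature table
#'
#' Maps cas domain accessions to CRISPR-Cas types (I/II/III) and optionally
#' subtypes (e.g. the GSU0054 domain diagnoses subtype I-U). Lower
#' `priority` wins when a module matches several subtype signatures.
#'
#' @param path Path to the TSV; defaults to the shipped table.
#' @return A data.frame with `accession`, `type`, `subtype`, `priority`.
#' @export
read_cas_signatures <- function(path = default_cas_signature_path()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("accession", "type", "subtype", "priority")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cas signature table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$priority <- as.integer(df$priority)
  sub <- df[nzchar(df$subtype), ]
  if (anyDuplicated(sub$priority)) stop("subtype priorities must be unique")
  if (any(!df$type %in% c("I", "II", "III"))) {
    stop("cas signature types must be I, II or III")
  }
  df[, need]
}

default_cas_signature_path <- function() {
  system.file("extdata", "cas_signatures.tsv", package = "defenscan", mustWork = TRUE)
}

#' Accessions treated as cas-domain hits
#'
#' Union of the CRISPR rows of the marker table and the signature table.
#'
#' @param marker_table Marker table data.frame.
#' @param signatures Cas signature data.frame.
#' @return Character vector of accessions.
#' @export
cas_accessions <- function(marker_table = read_marker_table(),
                           signatures = read_cas_signatures()) {
  map <- marker_accession_map(marker_table)
  sort(unique(c(map$accession[map$system == "CRISPR"], signatures$accession)))
}
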