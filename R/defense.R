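#' Filter domain hits at the defense E-value cutoff
#'
#' Keeps exactly the hits with `e_value < defense_e_max` (strict, so a hit
#' exactly at the cutoff is dropped), preserving input order.
#'
#' @param hits Data.frame of domain hits.
#' @param th A [thresholds()] object.
#' @return The filtered data.frame.
#' @export
filter_defense_hits <- function(hits, th = thresholds()) {
  hits[hits$e_value < th$defense_e_max, , drop = FALSE]
}

#' Assign genes to defense systems from marker hits
#'
#' Each gene with at least one hit to a marker accession receives exactly
#' one assignment, supported by its best marker hit (lowest E-value, ties by
#' highest bitscore, then lexicographically smallest accession). If the
#' winning accession is listed under a single system the gene is `assigned`
#' to that system/subtype; if the accession is shared between systems the
#' gene is `ambiguous` (it still counts as a defense gene but joins no
#' system). Genes without marker hits are absent from the output.
#'
#' Hits are expected to be E-value filtered already (see
#' [filter_defense_hits()]).
#'
#' @param hits Data.frame of (filtered) domain hits.
#' @param marker_table Marker table from [read_marker_table()].
#' @param all_hits If `TRUE`, emit one row per qualifying marker hit instead
#'   of one per gene (alternative counting convention; the default per-gene
#'   convention keeps gene counts well defined).
#' @return A data.frame with `gene_id`, `status` (`assigned`/`ambiguous`),
#'   `system`, `subtype`, `marker_name`, `canonical`, `accession`,
#'   `e_value`, `bitscore`.
#' @export
assign_defense_systems <- function(hits, marker_table = read_marker_table(),
                                   all_hits = FALSE) {
  map <- marker_accession_map(marker_table)
  m <- hits[hits$domain_accession %in% map$accession, , drop = FALSE]
  empty <- data.frame(gene_id = character(), status = character(),
                      system = character(), subtype = character(),
                      marker_name = character(), canonical = logical(),
                      accession = character(), e_value = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  if (nrow(m) == 0) return(empty)
  # deterministic best-hit order: E ascending, bitscore descending, accession
  o <- order(m$gene_id, m$e_value, -m$bitscore, m$domain_accession)
  m <- m[o, , drop = FALSE]
  if (!all_hits) m <- m[!duplicated(m$gene_id), , drop = FALSE]

  systems_per_acc <- tapply(map$system, map$accession,
                            function(s) sort(unique(s)), simplify = FALSE)
  one <- function(acc) {
    sys <- systems_per_acc[[acc]]
    if (length(sys) == 1L) {
      row <- map[map$accession == acc & map$system == sys, , drop = FALSE][1L, ]
      list(status = "assigned", system = row$system, subtype = row$subtype,
           marker_name = row$marker_name, canonical = row$canonical)
    } else {
      list(status = "ambiguous", system = NA_character_,
           subtype = NA_character_, marker_name = NA_character_,
           canonical = NA)
    }
  }
  info <- lapply(m$domain_accession, one)
  out <- data.frame(
    gene_id = m$gene_id,
    status = vapply(info, `[[`, character(1), "status"),
    system = vapply(info, `[[`, character(1), "system"),
    subtype = vapply(info, `[[`, character(1), "subtype"),
    marker_name = vapply(info, `[[`, character(1), "marker_name"),
    canonical = vapply(info, `[[`, logical(1), "canonical"),
    accession = m$domain_accession,
    e_value = m$e_value,
    bitscore = m$bitscore,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Group same-system assignments into defense loci
#'
#' On each contig, maximal runs of genes assigned to one system whose
#' consecutive members are separated by at most `max_orf_gap` intervening
#' ORFs form a locus (the same spacing rule used for multigene cas
#' modules). Ambiguous genes never seed or join a locus.
#'
#' @param assignments Output of [assign_defense_systems()].
#' @param genes Gene calls with ordinals.
#' @param th A [thresholds()] object.
#' @return A data.frame with `locus_id`, `system`, `contig_id`, `n_genes`,
#'   `gene_ids` (comma-separated, in ordinal order).
#' @export
call_defense_loci <- function(assignments, genes, th = thresholds()) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  g <- merge(a, genes[, c("gene_id", "contig_id", "ordinal")], by = "gene_id")
  g <- g[order(g$system, g$contig_id, g$ordinal), , drop = FALSE]
  if (nrow(g) == 0) {
    return(data.frame(locus_id = character(), system = character(),
                      contig_id = character(), n_genes = integer(),
                      gene_ids = character(), stringsAsFactors = FALSE))
  }
  key <- paste(g$system, g$contig_id, sep = "\r")
  new_chain <- c(TRUE, key[-1] != key[-nrow(g)] |
                   diff(g$ordinal) - 1L > th$max_orf_gap)
  chain <- cumsum(new_chain)
  out <- do.call(rbind, lapply(split(g, chain), function(d) {
    data.frame(system = d$system[1], contig_id = d$contig_id[1],
               n_genes = nrow(d),
               gene_ids = paste(d$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$contig_id, out$system), , drop = FALSE]
  out <- cbind(locus_id = sprintf("locus%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Per-phylum defense gene count matrix
#'
#' Counts each assigned gene once under (phylum of its contig, system);
#' ambiguous genes enter the per-phylum defense total but no system cell.
#' Genes on contigs without a taxonomy row fall under `"unknown"`.
#'
#' @param assignments Output of [assign_defense_systems()].
#' @param genes Gene calls.
#' @param taxonomy Contig taxonomy data.frame.
#' @return A list of class `"phylum_defense_matrix"` with elements `counts`
#'   (data.frame phylum/system/count), `phylum_total_genes`,
#'   `phylum_total_defense` (named integer vectors).
#' @export
phylum_defense_matrix <- function(assignments, genes, taxonomy) {
  phy <- stats::setNames(taxonomy$phylum, taxonomy$contig_id)
  gene_phy <- phy[genes$contig_id]
  gene_phy[is.na(gene_phy)] <- "unknown"
  names(gene_phy) <- genes$gene_id
  total_genes <- table(gene_phy)

  a_phy <- gene_phy[assignments$gene_id]
  a_phy[is.na(a_phy)] <- "unknown"
  total_defense <- table(a_phy)

  assigned <- assignments$status == "assigned"
  counts <- as.data.frame(table(phylum = a_phy[assigned],
                                system = assignments$system[assigned]),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "count"
  counts <- counts[order(counts$phylum, counts$system), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(
    counts = counts,
    phylum_total_genes = stats::setNames(as.integer(total_genes), names(total_genes)),
    phylum_total_defense = stats::setNames(as.integer(total_defense), names(total_defense))
  ), class = "phylum_defense_matrix")
}

#' Relative abundance of each system within each phylum
#'
#' The fraction for (phylum, system) is the system's gene count divided by
#' the phylum's total defense genes (ambiguous genes included in the
#' denominator, so per-phylum fractions plus the ambiguous share sum to 1).
#' Phyla with zero defense genes are excluded.
#'
#' @param mat A [phylum_defense_matrix()].
#' @return Data.frame `phylum`, `system`, `count`, `fraction`; the
#'   ambiguous remainder appears as system `"ambiguous"`.
#' @export
system_relative_abundance <- function(mat) {
  td <- mat$phylum_total_defense
  td <- td[td > 0]
  cnt <- mat$counts[mat$counts$phylum %in% names(td), , drop = FALSE]
  cnt$fraction <- cnt$count / as.numeric(td[cnt$phylum])
  amb_count <- td - vapply(names(td), function(p) {
    sum(cnt$count[cnt$phylum == p])
  }, numeric(1))
  amb <- data.frame(phylum = names(td), system = "ambiguous",
                    count = as.integer(amb_count),
                    fraction = as.numeric(amb_count) / as.numeric(td),
                    stringsAsFactors = FALSE)
  out <- rbind(cnt, amb)
  out <- out[order(out$phylum, out$system), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of defense genes among all genes, per phylum
#'
#' @param mat A [phylum_defense_matrix()].
#' @return Named numeric vector, percent per phylum
#'   (100 * defense genes / total genes).
#' @export
defense_gene_percentage <- function(mat) {
  tg <- mat$phylum_total_genes
  td <- mat$phylum_total_defense[names(tg)]
  td[is.na(td)] <- 0L
  stats::setNames(100 * as.numeric(td) / as.numeric(tg), names(tg))
}

#' Log-scaled heatmap values for per-phylum system counts
#'
#' `log10(count + 1)`: a pseudo-count keeps empty cells at 0 and finite.
#'
#' @param mat A [phylum_defense_matrix()].
#' @return Data.frame `phylum`, `system`, `count`, `log10p1`.
#' @export
heatmap_values <- function(mat) {
  out <- mat$counts
  out$log10p1 <- log10(out$count + 1)
  out
}
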