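#' Filter cas-domain hits at the cas E-value cutoff
#'
#' Restricts hits to cas-domain accessions and keeps those with
#' `e_value < cas_e_max` (strict).
#'
#' @param hits Data.frame of domain hits.
#' @param th A [thresholds()] object.
#' @param accessions Character vector of cas-domain accessions
#'   (default: the shipped marker + signature union).
#' @return The filtered data.frame, input order preserved.
#' @export
filter_cas_hits <- function(hits, th = thresholds(), accessions = cas_accessions()) {
  hits[hits$domain_accession %in% accessions & hits$e_value < th$cas_e_max,
       , drop = FALSE]
}

#' Call multigene cas modules by the ORF-spacing rule
#'
#' Per contig, cas-annotated genes sorted by ordinal are chained while the
#' number of intervening ORFs between consecutive cas genes
#' (`ordinal[i+1] - ordinal[i] - 1`) is at most `max_orf_gap`. Maximal
#' chains with at least two genes are modules; solitary cas genes are not.
#'
#' @param cas_genes Gene calls (with ordinals) of cas-annotated genes.
#' @param th A [thresholds()] object.
#' @return Data.frame `module_id`, `contig_id`, `n_genes`, `gene_ids`
#'   (comma-separated in ordinal order).
#' @export
call_cas_modules <- function(cas_genes, th = thresholds()) {
  empty <- data.frame(module_id = character(), contig_id = character(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cas_genes) == 0) return(empty)
  g <- cas_genes[order(cas_genes$contig_id, cas_genes$ordinal), , drop = FALSE]
  new_chain <- c(TRUE, g$contig_id[-1] != g$contig_id[-nrow(g)] |
                   diff(g$ordinal) - 1L > th$max_orf_gap)
  chain <- cumsum(new_chain)
  mods <- do.call(rbind, lapply(split(g, chain), function(d) {
    data.frame(contig_id = d$contig_id[1], n_genes = nrow(d),
               gene_ids = paste(d$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  mods <- mods[mods$n_genes >= 2L, , drop = FALSE]
  if (nrow(mods) == 0) return(empty)
  mods <- cbind(module_id = sprintf("cas_mod%04d", seq_len(nrow(mods))), mods)
  rownames(mods) <- NULL
  mods
}

#' Classify a cas module into CRISPR-Cas type and subtype
#'
#' All signature rows matched by the module's hit accessions are collected.
#' The subtype is the matched subtype signature with the best (lowest)
#' priority (e.g. the GSU0054 domain diagnoses subtype I-U) and fixes the
#' type. Failing a subtype, the type is the one implied by matched
#' type-level signatures (cas3 for I, cas9 for II, cas10 for III);
#' conflicting type-level signatures, or no signature at all (e.g. an
#' adaptation-only cas1+cas2 module), yield `"unclassified"`.
#'
#' @param module One row of [call_cas_modules()] output.
#' @param hits Cas-filtered domain hits.
#' @param signatures Cas signature table.
#' @return List with `type` (`"I"`, `"II"`, `"III"` or `"unclassified"`)
#'   and `subtype` (string or `NA`).
#' @export
classify_cas_module <- function(module, hits, signatures = read_cas_signatures()) {
  gene_ids <- strsplit(module$gene_ids, ",", fixed = TRUE)[[1]]
  accs <- unique(hits$domain_accession[hits$gene_id %in% gene_ids])
  sig <- signatures[signatures$accession %in% accs, , drop = FALSE]
  sub <- sig[nzchar(sig$subtype), , drop = FALSE]
  if (nrow(sub) > 0) {
    best <- sub[which.min(sub$priority), ]
    return(list(type = best$type, subtype = best$subtype))
  }
  types <- unique(sig$type[!nzchar(sig$subtype)])
  if (length(types) == 1L) return(list(type = types, subtype = NA_character_))
  list(type = "unclassified", subtype = NA_character_)
}

#' Classify every cas module
#'
#' @param modules Output of [call_cas_modules()].
#' @param hits Cas-filtered domain hits.
#' @param signatures Cas signature table.
#' @return `modules` with `type` and `subtype` columns appended.
#' @export
classify_cas_modules <- function(modules, hits, signatures = read_cas_signatures()) {
  if (nrow(modules) == 0) {
    modules$type <- character(0); modules$subtype <- character(0)
    return(modules)
  }
  cls <- lapply(seq_len(nrow(modules)), function(i) {
    classify_cas_module(modules[i, ], hits, signatures)
  })
  modules$type <- vapply(cls, `[[`, character(1), "type")
  modules$subtype <- vapply(cls, `[[`, character(1), "subtype")
  modules
}

#' Cas gene and module abundance statistics
#'
#' Per-phylum cas-gene relative abundance (cas gene count over total gene
#' count for the phylum) and the distribution of classified modules over
#' types and subtypes, as fractions of classified modules.
#'
#' @param cas_gene_ids Character vector of cas-annotated gene ids.
#' @param modules Classified modules (with `type`/`subtype`).
#' @param genes Gene calls.
#' @param taxonomy Contig taxonomy.
#' @return List with `per_phylum` (data.frame phylum, n_cas, n_genes,
#'   fraction), `type_distribution` and `subtype_distribution` (data.frames
#'   over classified modules; empty when none are classified).
#' @export
cas_abundance_stats <- function(cas_gene_ids, modules, genes, taxonomy) {
  phy <- stats::setNames(taxonomy$phylum, taxonomy$contig_id)
  gene_phy <- phy[genes$contig_id]
  gene_phy[is.na(gene_phy)] <- "unknown"
  total <- table(gene_phy)
  cas_phy <- gene_phy[match(cas_gene_ids, genes$gene_id)]
  cas_phy[is.na(cas_phy)] <- "unknown"
  ncas <- table(factor(cas_phy, levels = names(total)))
  per_phylum <- data.frame(phylum = names(total),
                           n_cas = as.integer(ncas),
                           n_genes = as.integer(total),
                           stringsAsFactors = FALSE)
  per_phylum$fraction <- per_phylum$n_cas / per_phylum$n_genes

  classified <- modules[modules$type != "unclassified", , drop = FALSE]
  if (nrow(classified) == 0) {
    type_distribution <- data.frame(type = character(), n = integer(),
                                    fraction = numeric(), stringsAsFactors = FALSE)
    subtype_distribution <- data.frame(subtype = character(), n = integer(),
                                       fraction = numeric(), stringsAsFactors = FALSE)
  } else {
    tt <- table(classified$type)
    type_distribution <- data.frame(type = names(tt), n = as.integer(tt),
                                    fraction = as.integer(tt) / nrow(classified),
                                    stringsAsFactors = FALSE)
    st <- table(classified$subtype[!is.na(classified$subtype)])
    subtype_distribution <- data.frame(subtype = names(st), n = as.integer(st),
                                       fraction = as.integer(st) / nrow(classified),
                                       stringsAsFactors = FALSE)
  }
  list(per_phylum = per_phylum,
       type_distribution = type_distribution,
       subtype_distribution = subtype_distribution)
}
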