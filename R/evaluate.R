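#' @name recovery
#' @title Recovery metrics against a synthetic ground-truth manifest
#'
#' @description Precision/recall of each pipeline stage against the truth
#' manifest of a [generate_dataset()] bundle. The manifest may be the
#' in-memory list or the re-read `manifest.json` (both shapes are
#' normalized).
NULL

mf_chr <- function(x) as.character(unlist(x, use.names = FALSE))

#' Planted spacer table from a manifest
#' @param manifest Truth manifest.
#' @return Data.frame `spacer_ref`, `sequence`, `contig_id`.
#' @export
manifest_spacers <- function(manifest) {
  do.call(rbind, lapply(manifest$planted_arrays, function(a) {
    sp <- mf_chr(a$spacers)
    data.frame(spacer_ref = paste(a$array_ref, seq_along(sp) - 1, sep = ":"),
               sequence = sp, contig_id = a$contig_id,
               stringsAsFactors = FALSE)
  }))
}

pr <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       tp = tp, n_pred = length(pred), n_truth = length(truth))
}

#' @rdname recovery
#' @param assignments Output of [assign_defense_systems()].
#' @param manifest Truth manifest.
#' @return Each function returns a list with `precision`, `recall`, `tp`,
#'   `n_pred`, `n_truth`.
#' @export
defense_recovery <- function(assignments, manifest) {
  truth <- unlist(lapply(manifest$planted_loci, function(l) {
    paste(mf_chr(l$gene_ids), l$system, sep = "|")
  }))
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  pred <- paste(a$gene_id, a$system, sep = "|")
  pr(unique(pred), unique(truth))
}

#' @rdname recovery
#' @param modules Classified module table from [classify_cas_modules()].
#' @export
cas_module_recovery <- function(modules, manifest) {
  norm <- function(gene_ids, type, subtype) {
    paste(paste(sort(gene_ids), collapse = ","), type,
          ifelse(is.na(subtype) | subtype == "", ".", subtype), sep = "|")
  }
  truth <- vapply(manifest$planted_cas_modules, function(m) {
    norm(mf_chr(m$gene_ids), m$type, m$subtype)
  }, character(1))
  pred <- vapply(seq_len(nrow(modules)), function(i) {
    norm(strsplit(modules$gene_ids[i], ",")[[1]], modules$type[i],
         modules$subtype[i])
  }, character(1))
  pr(unique(pred), unique(truth))
}

#' @rdname recovery
#' @param arrays Output of [detect_arrays()].
#' @export
array_recovery <- function(arrays, manifest) {
  truth <- vapply(manifest$planted_arrays, function(a) {
    paste(a$contig_id, a$start, a$end,
          paste(mf_chr(a$spacers), collapse = ","), sep = "|")
  }, character(1))
  pred <- vapply(seq_len(nrow(arrays)), function(i) {
    paste(arrays$contig_id[i], arrays$start[i], arrays$end[i],
          paste(arrays$spacers[[i]], collapse = ","), sep = "|")
  }, character(1))
  pr(unique(pred), unique(truth))
}

#' @rdname recovery
#' @param matches Output of [match_spacers()] (rbind over sets is fine).
#' @param spacers Output of [extract_spacers()].
#' @param eligible_only Keep only placements whose substitution count still
#'   permits a match at the set's identity threshold (exact arithmetic on
#'   the planted spacer length); with a mutation rate of 0 every placement
#'   is eligible.
#' @param th [thresholds()], used for the eligibility arithmetic.
#' @export
protospacer_recovery <- function(matches, spacers, manifest,
                                 eligible_only = TRUE, th = thresholds()) {
  msp <- manifest_spacers(manifest)
  truth <- unique(unlist(lapply(manifest$protospacer_placements, function(p) {
    seqc <- msp$sequence[msp$spacer_ref == p$spacer_ref]
    L <- nchar(seqc)
    if (eligible_only) {
      idmin <- if (p$set == "internal") th$identity_min_internal_pct
               else th$identity_min_external_pct
      if (100 * (L - p$n_mutations) / L <= idmin) return(NULL)
    }
    paste(seqc, p$viral_contig_id, sep = "|")
  })))
  seq_of <- stats::setNames(spacers$sequence, spacers$spacer_id)
  pred <- unique(paste(unname(seq_of[matches$spacer_id]),
                       matches$target_contig_id, sep = "|"))
  pr(pred, truth)
}
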