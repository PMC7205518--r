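#' Reverse complement of a DNA string
#' @param x Character vector over ACGTN.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

merge_windows <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- starts[i]; me <- ends[i] }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

best_alignment_for_pair <- function(qfwd, qrev, tseq, params) {
  L <- nchar(qfwd)
  best <- NULL
  for (strand in if (is.null(qrev)) "+" else c("+", "-")) {
    q <- if (strand == "+") qfwd else qrev
    seeds <- find_seeds_cpp(q, tseq, params$word_size)
    if (length(seeds) == 0) next
    win <- merge_windows(pmax(1L, seeds - L - 25L),
                         pmin(nchar(tseq), seeds + params$word_size + L + 25L))
    for (w in seq_len(nrow(win))) {
      aln <- sw_align_cpp(q, substr(tseq, win[w, 1], win[w, 2]),
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
      if (aln$score <= 0) next
      aln$tstart <- aln$tstart + win[w, 1] - 1L
      aln$tend <- aln$tend + win[w, 1] - 1L
      aln$strand <- strand
      if (is.null(best) || aln$score > best$score ||
          (aln$score == best$score && strand == "+" && best$strand == "-") ||
          (aln$score == best$score && strand == best$strand &&
           aln$tstart < best$tstart)) {
        best <- aln
      }
    }
  }
  best
}

#' Match spacers against a viral contig set
#'
#' Seed-and-extend local alignment of each spacer against each target on
#' both strands: exact `word_size`-mer seeds are located, extended by local
#' alignment under the configured score scheme, and the best alignment per
#' (spacer, target) pair is kept. A match is reported when query coverage
#' is at least `qcov_min_pct` and percent identity strictly exceeds the
#' identity threshold of the target set (internal virome 90, external
#' reference viromes 95, by default). Identity is computed over alignment
#' columns including gaps; coverage is the aligned fraction of the spacer.
#'
#' @param spacers Data.frame from [extract_spacers()] (needs `spacer_id`,
#'   `sequence`), or a named character vector.
#' @param targets Data.frame of viral contigs (`contig_id`, `sequence`).
#' @param target_set One of `"internal"`, `"external"`, `"regional"`.
#' @param params A [match_params()] object.
#' @param th A [thresholds()] object.
#' @param identity_min_pct Optional explicit identity threshold overriding
#'   the per-set default.
#' @param best_only If `TRUE`, keep only the single best target per spacer.
#' @return Data.frame `spacer_id`, `target_contig_id`, `target_set`,
#'   `strand`, `identity_pct`, `qcov_pct`, `aln_start`, `aln_end` (0-based
#'   half-open on the target), `score`, `matches`, `columns`.
#' @export
match_spacers <- function(spacers, targets, target_set = c("internal", "external", "regional"),
                          params = match_params(), th = thresholds(),
                          identity_min_pct = NULL, best_only = FALSE) {
  target_set <- match.arg(target_set)
  if (!is.data.frame(spacers)) {
    spacers <- data.frame(spacer_id = names(spacers), sequence = unname(spacers),
                          stringsAsFactors = FALSE)
  }
  idmin <- if (!is.null(identity_min_pct)) identity_min_pct
           else if (target_set == "internal") th$identity_min_internal_pct
           else th$identity_min_external_pct
  rows <- vector("list", 0)
  for (si in seq_len(nrow(spacers))) {
    q <- spacers$sequence[si]
    L <- nchar(q)
    if (L < params$word_size) {
      warning("spacer ", spacers$spacer_id[si], " shorter than word size; skipped")
      next
    }
    qrev <- if (params$both_strands) revcomp(q) else NULL
    for (ti in seq_len(nrow(targets))) {
      best <- best_alignment_for_pair(q, qrev, targets$sequence[ti], params)
      if (is.null(best)) next
      identity <- 100 * best$matches / best$columns
      qcov <- 100 * (best$qend - best$qstart + 1) / L
      if (identity > idmin && qcov >= th$qcov_min_pct) {
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = spacers$spacer_id[si],
          target_contig_id = targets$contig_id[ti],
          target_set = target_set,
          strand = best$strand,
          identity_pct = identity,
          qcov_pct = qcov,
          aln_start = best$tstart - 1L,
          aln_end = best$tend,
          score = best$score,
          matches = best$matches,
          columns = best$columns,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer_id = character(), target_contig_id = character(),
               target_set = character(), strand = character(),
               identity_pct = numeric(), qcov_pct = numeric(),
               aln_start = integer(), aln_end = integer(), score = numeric(),
               matches = integer(), columns = integer(), stringsAsFactors = FALSE)
  if (best_only && nrow(out) > 0) {
    o <- order(out$spacer_id, -out$score, out$target_contig_id)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$spacer_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Exhaustive local-alignment oracle
#'
#' Full dynamic-programming local alignment of one spacer against one
#' target (both strands, no seeding). Used as the reference the seeded
#' search is checked against; intended for targets up to ~20 kb.
#'
#' @param spacer Spacer sequence (string).
#' @param target Target sequence (string).
#' @param params A [match_params()] object.
#' @return List with `score`, `strand`, `identity_pct`, `qcov_pct`,
#'   `aln_start`, `aln_end`, `matches`, `columns`; `score` 0 when no
#'   positive-scoring local alignment exists.
#' @export
exhaustive_match_oracle <- function(spacer, target, params = match_params()) {
  L <- nchar(spacer)
  cand <- list()
  for (strand in if (params$both_strands) c("+", "-") else "+") {
    q <- if (strand == "+") spacer else revcomp(spacer)
    aln <- sw_align_cpp(q, target, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
    aln$strand <- strand
    cand[[strand]] <- aln
  }
  best <- cand[["+"]]
  if (!is.null(cand[["-"]]) && cand[["-"]]$score > best$score) best <- cand[["-"]]
  if (best$score <= 0) {
    return(list(score = 0, strand = NA_character_, identity_pct = NA_real_,
                qcov_pct = NA_real_, aln_start = NA_integer_,
                aln_end = NA_integer_, matches = 0L, columns = 0L))
  }
  list(score = best$score, strand = best$strand,
       identity_pct = 100 * best$matches / best$columns,
       qcov_pct = 100 * (best$qend - best$qstart + 1) / L,
       aln_start = best$tstart - 1L, aln_end = best$tend,
       matches = best$matches, columns = best$columns)
}

#' Summarize spacer-virome matching
#'
#' Counts and one-decimal percentages of distinct spacers with at least one
#' match and distinct targets with at least one match, per target set and
#' overall.
#'
#' @param matches Data.frame from [match_spacers()] (possibly rbind-ed over
#'   sets).
#' @param n_spacers_total Total number of spacers searched.
#' @param n_targets_total Named integer vector: total targets per target
#'   set (names are set labels), or a single total.
#' @return Data.frame `target_set`, `n_spacers_matched`, `pct_spacers`,
#'   `n_targets_matched`, `pct_targets`; last row is `"overall"`.
#' @export
match_summary <- function(matches, n_spacers_total, n_targets_total) {
  stopifnot(n_spacers_total > 0, all(n_targets_total > 0))
  sets <- unique(matches$target_set)
  if (length(n_targets_total) == 1L && is.null(names(n_targets_total))) {
    n_targets_total <- stats::setNames(rep(n_targets_total, length(sets)), sets)
  }
  one <- function(m, n_t) {
    ns <- length(unique(m$spacer_id))
    nt <- length(unique(m$target_contig_id))
    data.frame(n_spacers_matched = ns,
               pct_spacers = percentage(ns, n_spacers_total),
               n_targets_matched = nt,
               pct_targets = if (is.na(n_t)) NA_real_ else percentage(nt, n_t),
               stringsAsFactors = FALSE)
  }
  per_set <- do.call(rbind, lapply(sets, function(s) {
    cbind(target_set = s,
          one(matches[matches$target_set == s, , drop = FALSE],
              unname(n_targets_total[s])),
          stringsAsFactors = FALSE)
  }))
  overall <- cbind(target_set = "overall",
                   one(matches, sum(n_targets_total, na.rm = TRUE)),
                   stringsAsFactors = FALSE)
  out <- rbind(per_set, overall)
  rownames(out) <- NULL
  out
}
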