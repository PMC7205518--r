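#' Analysis thresholds
#'
#' Container for the cutoffs used across the pipeline. Defaults follow
#' standard practice for marker-based defense-system screening:
#' conserved-domain hits count as defense evidence below an E-value of 1e-2
#' (strict `<`), cas genes are held to the stricter 1e-3, multigene cas
#' modules allow at most 5 intervening ORFs between consecutive cas genes,
#' spacer-to-virome matches require at least 80% query coverage and strictly
#' more than 90% identity against the community's own (internal) virome or
#' 95% against external reference viromes, and the array-size "majority"
#' cutoff marks the largest size below which at most 85% of arrays fall.
#'
#' @param defense_e_max Numeric. Defense hits kept when `e_value < defense_e_max`.
#' @param cas_e_max Numeric. Cas hits kept when `e_value < cas_e_max`.
#' @param max_orf_gap Integer. Maximum number of intervening ORFs between
#'   consecutive genes of one locus/module.
#' @param qcov_min_pct Numeric percent. Query-coverage floor (`>=`).
#' @param identity_min_internal_pct Numeric percent, strict `>`, internal virome.
#' @param identity_min_external_pct Numeric percent, strict `>`, external viromes.
#' @param majority_cutoff Fraction in (0,1) for the array-size majority rule.
#' @return A list of class `"defenscan_thresholds"`.
#' @export
thresholds <- function(defense_e_max = 1e-2,
                       cas_e_max = 1e-3,
                       max_orf_gap = 5L,
                       qcov_min_pct = 80,
                       identity_min_internal_pct = 90,
                       identity_min_external_pct = 95,
                       majority_cutoff = 0.85) {
  stopifnot(defense_e_max > 0, cas_e_max > 0, max_orf_gap >= 0)
  pcts <- c(qcov_min_pct, identity_min_internal_pct, identity_min_external_pct)
  if (any(pcts <= 0 | pcts > 100)) stop("percentage thresholds must lie in (0, 100]")
  if (majority_cutoff <= 0 || majority_cutoff >= 1) stop("majority_cutoff must lie in (0, 1)")
  structure(list(
    defense_e_max = defense_e_max,
    cas_e_max = cas_e_max,
    max_orf_gap = as.integer(max_orf_gap),
    qcov_min_pct = qcov_min_pct,
    identity_min_internal_pct = identity_min_internal_pct,
    identity_min_external_pct = identity_min_external_pct,
    majority_cutoff = majority_cutoff
  ), class = "defenscan_thresholds")
}

#' CRISPR array detection parameters
#'
#' Defaults mirror the documented defaults of the classical direct-repeat
#' recognition tools: at least 3 repeats per array, repeat length 19-38 bp,
#' spacer length 19-48 bp, an 8-mer exact search word, exact repeat copies
#' (no mismatches), and rejection of arrays whose spacers are more than 60%
#' identical to one another (tandem-repeat guard).
#'
#' @param min_repeats Minimum number of repeat copies (array size is
#'   `min_repeats - 1` spacers at minimum).
#' @param repeat_len_min,repeat_len_max Admissible repeat length range (bp).
#' @param spacer_len_min,spacer_len_max Admissible spacer length range (bp).
#' @param seed_word Exact-match word length used to find candidate repeats.
#' @param max_repeat_mismatches Mismatches tolerated per repeat copy against
#'   the consensus (0 keeps detection exact and oracle-testable).
#' @param spacer_identity_max Maximum pairwise spacer identity fraction;
#'   arrays with any spacer pair above this are rejected.
#' @return A list of class `"crispr_params"`.
#' @export
crispr_params <- function(min_repeats = 3L,
                          repeat_len_min = 19L, repeat_len_max = 38L,
                          spacer_len_min = 19L, spacer_len_max = 48L,
                          seed_word = 8L,
                          max_repeat_mismatches = 0L,
                          spacer_identity_max = 0.6) {
  stopifnot(min_repeats >= 3, seed_word > 0, seed_word <= repeat_len_min,
            repeat_len_min <= repeat_len_max, spacer_len_min <= spacer_len_max,
            max_repeat_mismatches >= 0,
            spacer_identity_max > 0, spacer_identity_max < 1)
  structure(list(
    min_repeats = as.integer(min_repeats),
    repeat_len_min = as.integer(repeat_len_min),
    repeat_len_max = as.integer(repeat_len_max),
    spacer_len_min = as.integer(spacer_len_min),
    spacer_len_max = as.integer(spacer_len_max),
    seed_word = as.integer(seed_word),
    max_repeat_mismatches = as.integer(max_repeat_mismatches),
    spacer_identity_max = spacer_identity_max
  ), class = "crispr_params")
}

#' Spacer alignment parameters
#'
#' Score scheme and seeding of the spacer-vs-virome search. Defaults are the
#' classical nucleotide-BLAST task defaults: +2 match, -3 mismatch, gap open
#' 5, gap extend 2, word size 11, both strands searched, no masking.
#' Identity and coverage thresholds live in [thresholds()] because they
#' differ per target set.
#'
#' @param word_size Exact seed length; spacers shorter than this are skipped.
#' @param match,mismatch Per-column scores (match > 0 > mismatch).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param both_strands Search the reverse complement as well.
#' @return A list of class `"match_params"`.
#' @export
match_params <- function(word_size = 11L, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2, both_strands = TRUE) {
  stopifnot(word_size >= 4, match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  structure(list(
    word_size = as.integer(word_size),
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    both_strands = isTRUE(both_strands)
  ), class = "match_params")
}
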