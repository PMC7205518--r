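#' Detect CRISPR arrays in contigs
#'
#' Direct-repeat array detection in the style of the classical CRISPR
#' recognition tools: an exact `seed_word`-mer is sought again downstream at
#' an admissible period, periodic copies are accumulated, and the repeat is
#' extended maximally while all copies agree. Arrays need at least
#' `min_repeats` identical repeats (so at least two spacers), repeat and
#' spacer lengths within the configured ranges, and mutually dissimilar
#' spacers. Overlapping candidates are resolved greedily left to right.
#'
#' @param contigs Data.frame of contigs (`contig_id`, `sequence`) or a
#'   single sequence string.
#' @param params A [crispr_params()] object.
#' @return A data.frame with one row per array: `array_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `period`, `repeat_len`,
#'   `n_repeats`, `size` (spacer count), `repeat_consensus`, and
#'   list-columns `repeat_positions` (0-based starts) and `spacers`
#'   (character vectors).
#' @export
detect_arrays <- function(contigs, params = crispr_params()) {
  if (is.character(contigs)) {
    contigs <- data.frame(contig_id = names(contigs) %||% sprintf("seq%03d", seq_along(contigs)),
                          sequence = unname(contigs), stringsAsFactors = FALSE)
  }
  res <- lapply(seq_len(nrow(contigs)), function(ci) {
    seq <- contigs$sequence[ci]
    hits <- detect_arrays_cpp(seq, params$min_repeats,
                              params$repeat_len_min, params$repeat_len_max,
                              params$spacer_len_min, params$spacer_len_max,
                              params$seed_word, params$max_repeat_mismatches,
                              params$spacer_identity_max)
    if (nrow(hits) == 0) return(NULL)
    hits$contig_id <- contigs$contig_id[ci]
    hits$size <- hits$n_repeats - 1L
    hits$repeat_consensus <- substr(rep(seq, nrow(hits)),
                                    hits$start + 1L, hits$start + hits$repeat_len)
    hits$repeat_positions <- lapply(seq_len(nrow(hits)), function(i) {
      hits$start[i] + (0:(hits$n_repeats[i] - 1L)) * hits$period[i]
    })
    hits$spacers <- lapply(seq_len(nrow(hits)), function(i) {
      sp_start <- hits$start[i] + hits$repeat_len[i] +
        (0:(hits$size[i] - 1L)) * hits$period[i]
      substring(seq, sp_start + 1L, sp_start + hits$period[i] - hits$repeat_len[i])
    })
    hits
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(), period = integer(),
                      repeat_len = integer(), n_repeats = integer(),
                      contig_id = character(), size = integer(),
                      repeat_consensus = character(), stringsAsFactors = FALSE)
    res$repeat_positions <- list()
    res$spacers <- list()
  }
  res <- cbind(array_id = if (nrow(res)) sprintf("arr%04d", seq_len(nrow(res))) else character(),
               res)
  cols <- c("array_id", "contig_id", "start", "end", "period", "repeat_len",
            "n_repeats", "size", "repeat_consensus", "repeat_positions", "spacers")
  rownames(res) <- NULL
  res[, cols]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract spacers from detected arrays
#'
#' Spacers are emitted in array order with ids `array_id:index` (index from
#' 0) and inherit the phylum of their host contig.
#'
#' @param arrays Output of [detect_arrays()].
#' @param taxonomy Optional contig taxonomy data.frame.
#' @return Data.frame `spacer_id`, `array_id`, `index`, `sequence`,
#'   `contig_id`, `phylum`.
#' @export
extract_spacers <- function(arrays, taxonomy = NULL) {
  if (nrow(arrays) == 0) {
    return(data.frame(spacer_id = character(), array_id = character(),
                      index = integer(), sequence = character(),
                      contig_id = character(), phylum = character(),
                      stringsAsFactors = FALSE))
  }
  n <- arrays$size
  out <- data.frame(
    array_id = rep(arrays$array_id, n),
    index = unlist(lapply(n, function(k) seq_len(k) - 1L)),
    sequence = unlist(arrays$spacers),
    contig_id = rep(arrays$contig_id, n),
    stringsAsFactors = FALSE
  )
  out$spacer_id <- paste(out$array_id, out$index, sep = ":")
  phy <- if (is.null(taxonomy)) character(0) else
    stats::setNames(taxonomy$phylum, taxonomy$contig_id)
  out$phylum <- ifelse(out$contig_id %in% names(phy),
                       unname(phy[out$contig_id]), "unknown")
  rownames(out) <- NULL
  out[, c("spacer_id", "array_id", "index", "sequence", "contig_id", "phylum")]
}

#' Write spacers to FASTA
#' @param spacers Output of [extract_spacers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spacers <- function(spacers, path) {
  write_fasta(data.frame(contig_id = spacers$spacer_id,
                         sequence = spacers$sequence,
                         stringsAsFactors = FALSE), path)
}

#' Array-size histogram as percentages
#'
#' @param arrays Output of [detect_arrays()], or an integer vector of sizes.
#' @return Data.frame `size`, `n`, `percent`; percents sum to 100.
#' @export
array_size_histogram <- function(arrays) {
  sizes <- if (is.data.frame(arrays)) arrays$size else as.integer(arrays)
  if (length(sizes) == 0) stop("no arrays: size histogram undefined")
  tab <- table(sizes)
  data.frame(size = as.integer(names(tab)), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(sizes),
             stringsAsFactors = FALSE)
}

#' Majority array-size cutoff
#'
#' The largest size k such that the cumulative fraction of arrays with size
#' <= k is at most `threshold`. If even the smallest size exceeds the
#' threshold, the smallest size minus one is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param hist Output of [array_size_histogram()].
#' @param threshold Fraction in (0,1); default 0.85.
#' @return Integer size (with attribute `degenerate` when flagged).
#' @export
majority_cutoff <- function(hist, threshold = 0.85) {
  h <- hist[order(hist$size), , drop = FALSE]
  cum <- cumsum(h$percent) / 100
  ok <- cum <= threshold + 1e-12
  if (!any(ok)) {
    return(structure(h$size[1] - 1L, degenerate = TRUE))
  }
  h$size[max(which(ok))]
}

#' Compare two array-size distributions
#'
#' Aligns the two size histograms in long format, reports each sample's
#' majority cutoff and size range, and a two-sample rank-sum
#' (Wilcoxon/Mann-Whitney) test on the underlying size samples, reported
#' descriptively.
#'
#' @param sizes_a,sizes_b Integer vectors of array sizes for the two
#'   metagenomes.
#' @param labels Character vector of length 2 naming the samples.
#' @param threshold Majority cutoff threshold.
#' @return List with `table` (long-format data.frame sample/size/n/percent),
#'   `summary` (per-sample cutoff, min, max, n) and `rank_sum`
#'   (statistic, p_value).
#' @export
compare_size_distributions <- function(sizes_a, sizes_b,
                                       labels = c("a", "b"),
                                       threshold = 0.85) {
  ha <- array_size_histogram(sizes_a)
  hb <- array_size_histogram(sizes_b)
  tab <- rbind(cbind(sample = labels[1], ha, stringsAsFactors = FALSE),
               cbind(sample = labels[2], hb, stringsAsFactors = FALSE))
  summ <- data.frame(
    sample = labels,
    n_arrays = c(length(sizes_a), length(sizes_b)),
    min_size = c(min(sizes_a), min(sizes_b)),
    max_size = c(max(sizes_a), max(sizes_b)),
    majority_cutoff = c(as.integer(majority_cutoff(ha, threshold)),
                        as.integer(majority_cutoff(hb, threshold))),
    stringsAsFactors = FALSE
  )
  wt <- suppressWarnings(stats::wilcox.test(sizes_a, sizes_b, exact = FALSE))
  list(table = tab, summary = summ,
       rank_sum = list(statistic = unname(wt$statistic), p_value = wt$p.value))
}
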