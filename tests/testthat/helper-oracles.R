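# Independent brute-force oracles the fast implementations are checked
# against. These deliberately take different algorithmic routes:
# - array detection: shift-and-compare equality masks + run-length chaining
#   (no k-mer seeding);
# - module calling: O(n^2) pairwise chain construction.

# Enumerate periodic exact-repeat structures by scanning, for every period
# d, the equality mask seq[x] == seq[x + d]; chain >=rmin runs at period d,
# then apply the same acceptance rules as the detector and resolve overlaps
# greedily leftmost-longest.
oracle_detect_arrays <- function(seq, params = crispr_params()) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rmin <- params$repeat_len_min; rmax <- params$repeat_len_max
  smin <- params$spacer_len_min; smax <- params$spacer_len_max
  cands <- list()
  for (d in (rmin + smin):(rmax + smax)) {
    if (d >= n - rmin) next
    eq <- ch[1:(n - d)] == ch[(1 + d):n]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values & rl$lengths >= rmin
    for (k in which(keep)) {
      lo <- starts[k]; hi <- ends[k]  # common interval of copies (1,2), 1-based
      m <- 2L
      repeat {
        xs <- (lo:hi) + (m - 1L) * d
        v <- logical(length(xs))
        ok <- xs <= length(eq)
        v[ok] <- eq[xs[ok]]
        rv <- rle(v)
        re <- cumsum(rv$lengths); rs <- re - rv$lengths + 1L
        tr <- which(rv$values & rv$lengths >= rmin)
        if (!length(tr)) break
        best <- tr[which.max(rv$lengths[tr])]
        lo2 <- lo + rs[best] - 1L; hi2 <- lo + re[best] - 1L
        lo <- lo2; hi <- hi2; m <- m + 1L
      }
      if (m < params$min_repeats) next
      r_full <- hi - lo + 1L
      r <- min(r_full, rmax, d - smin)
      if (r < rmin) next
      sp <- d - r
      if (sp < smin || sp > smax) next
      start0 <- lo - 1L               # 0-based; right-trimmed to the cap
      end0 <- start0 + (m - 1L) * d + r
      if (end0 > n) next
      spacers <- vapply(0:(m - 2L), function(t) {
        substr(seq, start0 + r + t * d + 1L, start0 + (t + 1L) * d)
      }, character(1))
      bad <- FALSE
      if (length(spacers) >= 2) {
        for (i in 1:(length(spacers) - 1)) {
          for (j in (i + 1):length(spacers)) {
            idy <- mean(strsplit(spacers[i], "")[[1]] == strsplit(spacers[j], "")[[1]])
            if (idy > params$spacer_identity_max) bad <- TRUE
          }
        }
      }
      if (bad) next
      cands[[length(cands) + 1L]] <- data.frame(
        start = start0, end = end0, period = d, repeat_len = r, n_repeats = m)
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      repeat_len = integer(), n_repeats = integer()))
  }
  cand <- unique(do.call(rbind, cands))
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  sel <- list(); last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      sel[[length(sel) + 1L]] <- cand[i, ]
      last_end <- cand$end[i]
    }
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

# O(n^2) chain oracle for the <=max_orf_gap module rule: connect every pair
# of cas genes on one contig whose ordinal gap admits chaining through
# intermediate cas genes, then report connected components of size >= 2.
oracle_cas_modules <- function(cas_genes, max_orf_gap) {
  res <- list()
  for (ctg in unique(cas_genes$contig_id)) {
    g <- cas_genes[cas_genes$contig_id == ctg, , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    nn <- nrow(g)
    parent <- seq_len(nn)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nn)) {
      for (j in seq_len(nn)) {
        if (i < j && is_adjacent_in_sorted(g$ordinal, i, j, max_orf_gap)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(nn), find, integer(1))
    for (rt in unique(roots)) {
      members <- g$gene_id[roots == rt]
      if (length(members) >= 2) {
        res[[length(res) + 1L]] <- list(contig_id = ctg, gene_ids = members)
      }
    }
  }
  res
}

# i and j (i < j in sorted order) are chainable directly iff adjacent in the
# sorted ordinal sequence with <= max_orf_gap intervening ORFs
is_adjacent_in_sorted <- function(ordinals, i, j, max_orf_gap) {
  j == i + 1 && (ordinals[j] - ordinals[i] - 1) <= max_orf_gap
}
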