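test_that("a planted array is detected exactly once with exact coordinates", {
  set.seed(30)
  res <- contig_with_array(len = 2000, n_spacers = 4, repeat_len = 28,
                           spacer_len = 33, at = 600)
  arr <- detect_arrays(c(c1 = res$sequence))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$size, 4L)
  expect_equal(arr$start, res$record$start)
  expect_equal(arr$end, res$record$end)
  expect_equal(arr$repeat_consensus, res$record$repeat_consensus)
  expect_equal(arr$spacers[[1]], res$record$spacers)
})

test_that("random background yields no arrays and short contigs are impossible", {
  set.seed(31)
  for (rep in 1:100) {
    expect_equal(nrow(detect_arrays(defenscan:::rand_dna(10000))), 0L)
  }
  p <- crispr_params()
  short <- defenscan:::rand_dna(2 * p$repeat_len_min + p$spacer_len_min - 1)
  expect_equal(nrow(detect_arrays(short)), 0L)
})

test_that("detector equals the brute-force periodic-repeat enumerator", {
  set.seed(32)
  p <- crispr_params()
  for (rep in 1:60) {
    n_sp <- sample(2:5, 1)
    rl <- sample(p$repeat_len_min:p$repeat_len_max, 1)
    sl <- sample(p$spacer_len_min:p$spacer_len_max, 1)
    len <- sample(1200:2000, 1)
    block <- (n_sp + 1) * rl + n_sp * sl
    at <- sample(50:(len - block - 50), 1)
    res <- plant_crispr_array(defenscan:::rand_dna(len), n_sp, rl, sl, at)
    got <- detect_arrays(c(x = res$sequence), p)
    want <- oracle_detect_arrays(res$sequence, p)
    expect_equal(got[, c("start", "end", "period", "repeat_len", "n_repeats")],
                 want, label = sprintf("rep %d", rep))
  }
  # and on pure background (both must stay silent)
  for (rep in 1:20) {
    s <- defenscan:::rand_dna(1500)
    expect_equal(nrow(detect_arrays(s, p)), nrow(oracle_detect_arrays(s, p)))
  }
})

test_that("detected arrays are internally consistent and never overlap", {
  b <- small_bundle(seed = 101)
  arr <- detect_arrays(b$contigs)
  expect_gt(nrow(arr), 0)
  seqs <- stats::setNames(b$contigs$sequence, b$contigs$contig_id)
  for (i in seq_len(nrow(arr))) {
    s <- seqs[[arr$contig_id[i]]]
    # repeats all equal the consensus at the reported positions
    for (pos in arr$repeat_positions[[i]]) {
      expect_identical(substr(s, pos + 1, pos + arr$repeat_len[i]),
                       arr$repeat_consensus[i])
    }
    expect_equal(arr$size[i], arr$n_repeats[i] - 1L)
    expect_gte(arr$size[i], 2L)
  }
  for (ctg in unique(arr$contig_id)) {
    d <- arr[arr$contig_id == ctg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("recall degrades monotonically as repeat copies are mutated", {
  set.seed(33)
  recall_at <- function(n_mut) {
    found <- 0L
    for (rep in 1:25) {
      res <- contig_with_array(len = 1500, n_spacers = 3, repeat_len = 30,
                               spacer_len = 35, at = 400)
      s <- res$sequence
      if (n_mut > 0) {
        # mutate bases inside randomly chosen repeat copies
        ch <- strsplit(s, "")[[1]]
        for (mu in seq_len(n_mut)) {
          copy <- sample(0:3, 1)
          off <- sample(0:29, 1)
          pos <- res$record$start + copy * res$record$period + off + 1
          ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
        }
        s <- paste(ch, collapse = "")
      }
      hits <- detect_arrays(c(x = s))
      if (nrow(hits) == 1 && hits$start == res$record$start) found <- found + 1L
    }
    found / 25
  }
  r <- vapply(c(0, 2, 6), recall_at, numeric(1))
  expect_equal(r[1], 1)
  expect_true(all(diff(r) <= 0))
  expect_lt(r[3], r[1])
})

test_that("spacer extraction conserves counts, coordinates and taxonomy", {
  b <- small_bundle(seed = 112)
  arr <- detect_arrays(b$contigs)
  sp <- extract_spacers(arr, b$taxonomy)
  expect_equal(nrow(sp), sum(arr$size))
  expect_equal(sp$spacer_id, paste(sp$array_id, sp$index, sep = ":"))
  # indices contiguous from 0 per array
  for (a in unique(sp$array_id)) {
    expect_equal(sp$index[sp$array_id == a],
                 seq_len(sum(sp$array_id == a)) - 1L)
  }
  # slicing the contig at reported geometry reproduces each spacer
  seqs <- stats::setNames(b$contigs$sequence, b$contigs$contig_id)
  phy <- stats::setNames(b$taxonomy$phylum, b$taxonomy$contig_id)
  for (i in seq_len(nrow(arr))) {
    sps <- sp[sp$array_id == arr$array_id[i], ]
    expect_equal(sps$sequence, arr$spacers[[i]])
    expect_equal(unique(sps$phylum), unname(phy[arr$contig_id[i]]))
  }
})

test_that("array-size histogram is a percent tally summing to 100", {
  h <- array_size_histogram(c(2L, 2L, 4L))
  expect_equal(h$percent[h$size == 2], 200 / 3)
  expect_equal(h$percent[h$size == 4], 100 / 3)
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_equal(array_size_histogram(rep(7L, 5))$percent, 100)
  expect_error(array_size_histogram(integer(0)), "no arrays")

  set.seed(34)
  sizes <- sample(2:30, 500, replace = TRUE)
  h2 <- array_size_histogram(sizes)
  tab <- table(sizes)
  expect_equal(h2$n, as.integer(tab))
  expect_equal(sum(h2$percent), 100, tolerance = 1e-9)
})

test_that("majority cutoff matches a brute-force cumulative scan", {
  h <- array_size_histogram(c(rep(2L, 50), rep(3L, 30), rep(10L, 20)))
  expect_equal(majority_cutoff(h, 0.85), 3L)  # cum 0.5, 0.8 <= 0.85 < 1.0
  # degenerate: smallest size already exceeds the threshold
  h1 <- array_size_histogram(rep(5L, 10))
  mc <- majority_cutoff(h1, 0.85)
  expect_equal(as.integer(mc), 4L)
  expect_true(attr(mc, "degenerate"))

  set.seed(35)
  for (rep in 1:50) {
    sizes <- sample(2:40, sample(5:300, 1), replace = TRUE)
    h <- array_size_histogram(sizes)
    got <- as.integer(majority_cutoff(h, 0.85))
    uniq <- sort(unique(sizes))
    cum <- vapply(uniq, function(k) mean(sizes <= k), numeric(1))
    ok <- uniq[cum <= 0.85 + 1e-12]
    want <- if (length(ok)) max(ok) else uniq[1] - 1L
    expect_equal(got, want)
  }
})

test_that("size-distribution comparison detects a shifted sample", {
  set.seed(36)
  a <- sample(2:18, 300, replace = TRUE)
  cmp_same <- compare_size_distributions(a, a)
  expect_equal(cmp_same$summary$majority_cutoff[1],
               cmp_same$summary$majority_cutoff[2])
  expect_gt(cmp_same$rank_sum$p_value, 0.99)
  for (s in unique(cmp_same$table$sample)) {
    expect_equal(sum(cmp_same$table$percent[cmp_same$table$sample == s]), 100,
                 tolerance = 1e-9)
  }
  b <- a + 10L
  cmp <- compare_size_distributions(a, b, labels = c("hypolith", "groundwater"))
  expect_gt(cmp$summary$majority_cutoff[2], cmp$summary$majority_cutoff[1])
  expect_lt(cmp$rank_sum$p_value, 1e-6)
})
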