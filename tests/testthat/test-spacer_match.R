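embed_at <- function(target, insert, at) {
  paste0(substr(target, 1, at), insert,
         substr(target, at + nchar(insert) + 1, nchar(target)))
}

substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("an embedded spacer gives a full-identity, full-coverage match", {
  set.seed(40)
  sp <- defenscan:::rand_dna(36)
  tg <- embed_at(defenscan:::rand_dna(500), sp, 200)
  m <- match_spacers(c(s1 = sp), data.frame(contig_id = "v1", sequence = tg),
                     "internal")
  expect_equal(nrow(m), 1L)
  expect_equal(m$identity_pct, 100)
  expect_equal(m$qcov_pct, 100)
  expect_equal(m$strand, "+")
  expect_equal(m$aln_start, 200L)
  expect_equal(m$aln_end, 236L)
  expect_identical(substr(tg, m$aln_start + 1, m$aln_end), sp)
})

test_that("a reverse-complement embedding is reported on the minus strand", {
  set.seed(41)
  sp <- defenscan:::rand_dna(36)
  tg <- embed_at(defenscan:::rand_dna(400), revcomp(sp), 100)
  m <- match_spacers(c(s1 = sp), data.frame(contig_id = "v1", sequence = tg),
                     "internal")
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(m$identity_pct, 100)
})

test_that("the dual identity thresholds separate internal from external sets", {
  set.seed(42)
  sp <- defenscan:::rand_dna(36)
  # two interior substitutions: identity 34/36 = 94.4%
  tg2 <- embed_at(defenscan:::rand_dna(400), substitute_at(sp, c(10, 20)), 150)
  targets <- data.frame(contig_id = "v1", sequence = tg2)
  m_int <- match_spacers(c(s1 = sp), targets, "internal")
  m_ext <- match_spacers(c(s1 = sp), targets, "external")
  expect_equal(nrow(m_int), 1L)
  expect_equal(m_int$identity_pct, 100 * 34 / 36, tolerance = 1e-9)
  expect_equal(nrow(m_ext), 0L)  # 94.4 fails the strict >95 rule
  # four interior substitutions leaving an 11-mer run: 32/36 = 88.9%, fails both
  tg4 <- embed_at(defenscan:::rand_dna(400), substitute_at(sp, c(4, 16, 28, 34)), 150)
  targets4 <- data.frame(contig_id = "v1", sequence = tg4)
  expect_equal(nrow(match_spacers(c(s1 = sp), targets4, "internal")), 0L)
  expect_equal(nrow(match_spacers(c(s1 = sp), targets4, "external")), 0L)
})

test_that("spacers shorter than the word size are skipped with a warning", {
  expect_warning(
    m <- match_spacers(c(s1 = "ACGTACGT"),
                       data.frame(contig_id = "v1", sequence = defenscan:::rand_dna(100)),
                       "internal"),
    "shorter than word size")
  expect_equal(nrow(m), 0L)
})

test_that("seeded search equals the exhaustive oracle when the optimum holds a seed", {
  set.seed(43)
  p <- match_params()
  n_checked <- 0L
  for (rep in 1:300) {
    L <- sample(20:48, 1)
    sp <- defenscan:::rand_dna(L)
    tg <- defenscan:::rand_dna(sample(200:800, 1))
    if (runif(1) < 0.7) {
      # plant a (possibly mutated) copy so seeds usually exist
      ins <- if (runif(1) < 0.5) sp else substitute_at(sp, sample(L, sample(0:4, 1)))
      if (runif(1) < 0.5) ins <- revcomp(ins)
      tg <- embed_at(tg, ins, sample(0:(nchar(tg) - L), 1))
    }
    oracle <- exhaustive_match_oracle(sp, tg, p)
    seeded <- defenscan:::best_alignment_for_pair(sp, revcomp(sp), tg, p)
    if (!is.null(seeded)) {
      # the seeded result never beats the optimum
      expect_lte(seeded$score, oracle$score)
    }
    # the guarantee applies when the optimal alignment itself contains an
    # exact word_size run: i.e. a seed lies inside the oracle's interval
    if (oracle$score <= 0) next
    q <- if (oracle$strand == "+") sp else revcomp(sp)
    seeds <- defenscan:::find_seeds_cpp(q, tg, p$word_size)
    inside <- any(seeds >= oracle$aln_start + 1 &
                    seeds + p$word_size - 1 <= oracle$aln_end)
    if (inside) {
      n_checked <- n_checked + 1L
      expect_false(is.null(seeded))
      expect_equal(seeded$score, oracle$score, label = sprintf("rep %d", rep))
    }
  }
  expect_gt(n_checked, 100)
})

test_that("the aligner agrees with an independent reference implementation", {
  set.seed(44)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (rep in 1:40) {
    q <- defenscan:::rand_dna(sample(15:40, 1))
    t <- defenscan:::rand_dna(sample(60:300, 1))
    if (runif(1) < 0.6) t <- embed_at(t, substitute_at(q, sample(nchar(q), sample(0:3, 1))),
                                      sample(0:(nchar(t) - nchar(q)), 1))
    ours <- defenscan:::sw_align_cpp(q, t, 2, -3, 5, 2)
    ref <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(ours$score, max(0, Biostrings::score(ref)))
  }
})

test_that("stored identity and coverage re-validate from alignment counts", {
  b <- small_bundle(seed = 131)
  out <- run_pipeline(b)
  m <- out$matches
  expect_gt(nrow(m), 0)
  expect_equal(m$identity_pct, 100 * m$matches / m$columns)
  sp_len <- nchar(out$spacers$sequence[match(m$spacer_id, out$spacers$spacer_id)])
  th <- thresholds()
  expect_true(all(m$qcov_pct >= th$qcov_min_pct))
  for (s in unique(m$target_set)) {
    idmin <- if (s == "internal") th$identity_min_internal_pct else th$identity_min_external_pct
    expect_true(all(m$identity_pct[m$target_set == s] > idmin))
  }
  # coordinates live on the target
  vir <- stats::setNames(b$viral$sequence, b$viral$contig_id)
  expect_true(all(m$aln_end <= nchar(vir[m$target_contig_id])))
  expect_true(all(m$aln_start >= 0))
})

test_that("raising the identity threshold never enlarges the match set", {
  set.seed(45)
  sp <- vapply(rep(30, 15), defenscan:::rand_dna, character(1))
  names(sp) <- sprintf("s%02d", 1:15)
  tg <- data.frame(contig_id = sprintf("v%02d", 1:5),
                   sequence = vapply(rep(400, 5), defenscan:::rand_dna, character(1)),
                   stringsAsFactors = FALSE)
  for (i in 1:10) {
    k <- sample(15, 1); v <- sample(5, 1)
    ins <- substitute_at(sp[[k]], sample(30, sample(0:3, 1)))
    tg$sequence[v] <- embed_at(tg$sequence[v], ins, sample(0:(400 - 30), 1))
  }
  prev <- NULL
  for (idmin in c(80, 90, 95, 99)) {
    m <- match_spacers(sp, tg, "internal", identity_min_pct = idmin)
    key <- paste(m$spacer_id, m$target_contig_id)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("match summaries reproduce count/percentage arithmetic", {
  m <- data.frame(spacer_id = c("a", "a", "b"),
                  target_contig_id = c("v1", "v2", "v1"),
                  target_set = "internal", stringsAsFactors = FALSE)
  s <- match_summary(m, n_spacers_total = 20, n_targets_total = c(internal = 10))
  expect_equal(s$n_spacers_matched[s$target_set == "internal"], 2L)
  expect_equal(s$pct_spacers[s$target_set == "internal"], 10.0)
  expect_equal(s$n_targets_matched[s$target_set == "internal"], 2L)
  expect_equal(s$pct_targets[s$target_set == "internal"], 20.0)
  s0 <- match_summary(m[0, ], 10, c(internal = 5))
  expect_equal(s0$n_spacers_matched[s0$target_set == "overall"], 0L)
  expect_equal(s0$pct_spacers[s0$target_set == "overall"], 0)
})

test_that("planted protospacers are recovered exactly at zero mutation", {
  b <- small_bundle(seed = 151)
  out <- run_pipeline(b)
  rec <- protospacer_recovery(out$matches, out$spacers, b$manifest)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})
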