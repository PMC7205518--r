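test_that("cas hit filtering is strict at 1e-3 and restricted to cas accessions", {
  h <- rbind(hit("g1", "CAS0001", 1e-4), hit("g2", "CAS0001", 1e-3),
             hit("g3", "MRK0101", 1e-9))
  out <- filter_cas_hits(h, thresholds())
  expect_equal(out$gene_id, "g1")
  expect_equal(nrow(filter_cas_hits(h[0, ], thresholds())), 0L)

  set.seed(20)
  h <- random_hits(400, accs = c(cas_accessions(), sprintf("X%02d", 1:10)))
  th <- thresholds()
  keep <- h$domain_accession %in% cas_accessions() & h$e_value < th$cas_e_max
  expect_equal(filter_cas_hits(h, th), h[keep, ])
})

test_that("module calling follows the <=5 ORF spacing rule on worked examples", {
  th <- thresholds()
  # ordinals 2,3,8: gaps 0 and 4 -> one module of 3
  g <- genes_at_ordinals(list(c1 = c(2L, 3L, 8L)))
  mods <- call_cas_modules(g, th)
  expect_equal(nrow(mods), 1L)
  expect_equal(mods$n_genes, 3L)
  # ordinals 0 and 7: gap 6 -> no module
  g2 <- genes_at_ordinals(list(c1 = c(0L, 7L)))
  expect_equal(nrow(call_cas_modules(g2, th)), 0L)
  # gap exactly 5 chains
  g3 <- genes_at_ordinals(list(c1 = c(0L, 6L)))
  expect_equal(nrow(call_cas_modules(g3, th)), 1L)
})

test_that("module calling equals the O(n^2) chain oracle on random layouts", {
  set.seed(21)
  th <- thresholds()
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    spec <- list(cA = sort(sample(0:40, n)))
    if (runif(1) < 0.5) spec$cB <- sort(sample(0:20, sample(2:6, 1)))
    g <- genes_at_ordinals(spec)
    mods <- call_cas_modules(g, th)
    truth <- oracle_cas_modules(g, th$max_orf_gap)
    got <- sort(vapply(seq_len(nrow(mods)), function(i) {
      paste(sort(strsplit(mods$gene_ids[i], ",")[[1]]), collapse = ",")
    }, character(1)))
    want <- sort(vapply(truth, function(m) {
      paste(sort(m$gene_ids), collapse = ",")
    }, character(1)))
    expect_equal(got, want)
  }
})

test_that("module calling is invariant under input order reversal and modules are disjoint", {
  set.seed(22)
  g <- genes_at_ordinals(list(c1 = sort(sample(0:60, 15))))
  m1 <- call_cas_modules(g, thresholds())
  m2 <- call_cas_modules(g[rev(seq_len(nrow(g))), ], thresholds())
  expect_equal(m1, m2)
  ids <- unlist(strsplit(m1$gene_ids, ","))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("module classification follows subtype priority and conflict rules", {
  sig <- read_cas_signatures()
  mod <- function(genes) data.frame(module_id = "m", contig_id = "c",
                                    n_genes = length(genes),
                                    gene_ids = paste(genes, collapse = ","),
                                    stringsAsFactors = FALSE)
  # cas1 + cas2 + GSU0054 -> subtype I-U, type I
  h <- rbind(hit("a", "CAS0001", 1e-9), hit("b", "CAS0002", 1e-9),
             hit("c", "CAS0054", 1e-9))
  cls <- classify_cas_module(mod(c("a", "b", "c")), h, sig)
  expect_equal(cls$type, "I")
  expect_equal(cls$subtype, "I-U")
  # adaptation module only (cas1, cas2): no signature -> unclassified
  cls2 <- classify_cas_module(mod(c("a", "b")), h[1:2, ], sig)
  expect_equal(cls2$type, "unclassified")
  # conflicting type signatures (cas9 + cas10), no subtype -> unclassified
  h3 <- rbind(hit("a", "CAS0009", 1e-9), hit("b", "CAS0010", 1e-9))
  cls3 <- classify_cas_module(mod(c("a", "b")), h3, sig)
  expect_equal(cls3$type, "unclassified")
})

test_that("type distribution over classified modules sums to one", {
  mods <- data.frame(module_id = sprintf("m%d", 1:10), contig_id = "c",
                     n_genes = 2L, gene_ids = "x,y",
                     type = c(rep("I", 7), "II", "III", "unclassified"),
                     subtype = NA_character_, stringsAsFactors = FALSE)
  genes <- genes_at_ordinals(list(c = 0:9))
  taxonomy <- data.frame(contig_id = "c", phylum = "Proteobacteria",
                         stringsAsFactors = FALSE)
  st <- cas_abundance_stats(genes$gene_id[1:3], mods, genes, taxonomy)
  td <- st$type_distribution
  expect_equal(sum(td$fraction), 1)
  expect_equal(td$fraction[td$type == "I"], 7 / 9)

  # no classified modules: empty distribution, no division by zero
  mods$type <- "unclassified"
  st2 <- cas_abundance_stats(character(0), mods, genes, taxonomy)
  expect_equal(nrow(st2$type_distribution), 0L)
})

test_that("planted cas modules are recovered with exact gene sets and subtypes", {
  b <- small_bundle(seed = 91)
  th <- thresholds()
  ch <- filter_cas_hits(b$hits, th)
  cas_genes <- b$genes[b$genes$gene_id %in% unique(ch$gene_id), ]
  mods <- classify_cas_modules(call_cas_modules(cas_genes, th), ch)
  rec <- cas_module_recovery(mods, b$manifest)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})
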