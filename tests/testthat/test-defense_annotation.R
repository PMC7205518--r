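test_that("defense E-value filtering is strict at the boundary", {
  h <- rbind(hit("g1", "A", 1e-3), hit("g2", "B", 1e-2), hit("g3", "C", 5e-2))
  out <- filter_defense_hits(h, thresholds())
  expect_equal(out$gene_id, "g1")  # 1e-2 itself is excluded
  expect_equal(nrow(filter_defense_hits(h[0, ], thresholds())), 0L)

  set.seed(10)
  h <- random_hits(500)
  th <- thresholds()
  expect_equal(filter_defense_hits(h, th),
               h[sapply(h$e_value, function(e) e < th$defense_e_max), ])
})

test_that("genes are assigned to the system of their best marker hit", {
  mt <- mini_marker_table()
  # MRK0303 is drmA (DISARM only); MRK0999 is shared RM/DISARM
  h <- rbind(hit("g1", "MRK0303", 1e-9),
             hit("g2", "MRK0999", 1e-10),
             hit("g2", "MRK0303", 1e-6),
             hit("g3", "NOISE01", 1e-20))
  a <- assign_defense_systems(h, mt)
  expect_equal(nrow(a), 2L)  # g3 has no marker hit
  expect_equal(a$status[a$gene_id == "g1"], "assigned")
  expect_equal(a$system[a$gene_id == "g1"], "DISARM")
  expect_equal(a$marker_name[a$gene_id == "g1"], "drmA")
  # g2's best hit is the shared accession -> ambiguous
  expect_equal(a$status[a$gene_id == "g2"], "ambiguous")
  expect_true(is.na(a$system[a$gene_id == "g2"]))
})

test_that("assignment is invariant to hit order and ties break deterministically", {
  mt <- mini_marker_table()
  h <- rbind(hit("g1", "MRK0206", 1e-8, bit = 90),   # pglW, BREX
             hit("g1", "MRK0101", 1e-8, bit = 90),   # hsdM, RM; tie -> smaller acc
             hit("g1", "MRK0303", 1e-6, bit = 500))
  a1 <- assign_defense_systems(h, mt)
  a2 <- assign_defense_systems(h[3:1, ], mt)
  expect_equal(a1, a2)
  expect_equal(a1$accession, "MRK0101")  # lexicographically smallest on tie
  expect_equal(a1$system, "RM")
})

test_that("all-hits mode emits one row per qualifying marker hit", {
  mt <- mini_marker_table()
  h <- rbind(hit("g1", "MRK0303", 1e-9), hit("g1", "MRK0301", 1e-5))
  expect_equal(nrow(assign_defense_systems(h, mt)), 1L)
  expect_equal(nrow(assign_defense_systems(h, mt, all_hits = TRUE)), 2L)
})

test_that("defense loci chain same-system genes by the ORF-gap rule", {
  genes <- genes_at_ordinals(list(c1 = c(0:15)))
  mt <- mini_marker_table()
  mk <- function(g, acc) hit(sprintf("c1_g%03d", g + 1L), acc, 1e-9)
  # BREX genes at ordinals 4, 6, 11: gaps 1 and 4 -> one locus
  a <- assign_defense_systems(rbind(mk(4, "MRK0206"), mk(6, "MRK0207"),
                                    mk(11, "MRK0206")), mt)
  loci <- call_defense_loci(a, genes, thresholds())
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_genes, 3L)
  # ordinals 0 and 9: gap 8 > 5 -> two singleton loci
  a2 <- assign_defense_systems(rbind(mk(0, "MRK0206"), mk(9, "MRK0207")), mt)
  loci2 <- call_defense_loci(a2, genes, thresholds())
  expect_equal(nrow(loci2), 2L)
  expect_equal(loci2$n_genes, c(1L, 1L))
})

test_that("per-phylum matrix counts assigned genes and keeps ambiguous in totals", {
  mt <- mini_marker_table()
  genes <- genes_at_ordinals(list(c1 = 0:9, c2 = 0:9))
  taxonomy <- data.frame(contig_id = c("c1", "c2"),
                         phylum = c("Proteobacteria", "unknown"),
                         stringsAsFactors = FALSE)
  h <- rbind(hit("c1_g001", "MRK0101", 1e-9),  # RM
             hit("c1_g002", "MRK0101", 1e-9),  # RM
             hit("c1_g003", "MRK0999", 1e-9),  # ambiguous
             hit("c2_g001", "MRK0206", 1e-9))  # BREX on unknown
  a <- assign_defense_systems(h, mt)
  m <- phylum_defense_matrix(a, genes, taxonomy)
  cnt <- m$counts
  expect_equal(cnt$count[cnt$phylum == "Proteobacteria" & cnt$system == "RM"], 2L)
  expect_equal(m$phylum_total_defense[["Proteobacteria"]], 3L)  # incl. ambiguous
  expect_equal(m$phylum_total_defense[["unknown"]], 1L)
  expect_equal(m$phylum_total_genes[["Proteobacteria"]], 10L)

  # gene conservation: system cells + ambiguous = total assignments
  expect_equal(sum(cnt$count) + sum(a$status == "ambiguous"), nrow(a))

  rel <- system_relative_abundance(m)
  for (p in unique(rel$phylum)) {
    expect_equal(sum(rel$fraction[rel$phylum == p]), 1, tolerance = 1e-12)
  }
  expect_equal(rel$fraction[rel$phylum == "Proteobacteria" & rel$system == "RM"],
               2 / 3)

  pct <- defense_gene_percentage(m)
  expect_equal(pct[["Proteobacteria"]], 100 * 3 / 10)
  expect_equal(pct[["unknown"]], 100 * 1 / 10)
})

test_that("defense percentage matches direct division on random counts", {
  set.seed(11)
  for (rep in 1:20) {
    tg <- sample(50:5000, 4)
    td <- pmin(tg, sample(0:50, 4))
    m <- structure(list(counts = data.frame(phylum = letters[1:4],
                                            system = "RM", count = td,
                                            stringsAsFactors = FALSE),
                        phylum_total_genes = stats::setNames(tg, letters[1:4]),
                        phylum_total_defense = stats::setNames(td, letters[1:4])),
                   class = "phylum_defense_matrix")
    expect_equal(unname(defense_gene_percentage(m)), 100 * td / tg)
  }
})

test_that("heatmap values are log10(count + 1)", {
  m <- structure(list(counts = data.frame(phylum = "p", system = c("RM", "BREX", "Abi"),
                                          count = c(0L, 9L, 999L),
                                          stringsAsFactors = FALSE)),
                 class = "phylum_defense_matrix")
  hv <- heatmap_values(m)
  expect_equal(hv$log10p1, c(0, 1, 3))
})

test_that("annotation achieves perfect precision/recall on zero-noise truth", {
  b <- small_bundle(seed = 55)
  a <- assign_defense_systems(filter_defense_hits(b$hits), mini_marker_table())
  rec <- defense_recovery(a, b$manifest)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})

test_that("noise hits to non-marker accessions never degrade precision", {
  cfg <- sim_config(seed = 77, n_contigs = 20, n_arrays = 2, n_cas_modules = 1,
                    n_defense_loci_per_system = c(RM = 2, BREX = 1),
                    n_viral_contigs = 2, n_external_viral = 0,
                    protospacer_mutation_rate = 0, noise_hits_per_gene = 3)
  b <- generate_dataset(cfg)
  a <- assign_defense_systems(filter_defense_hits(b$hits), mini_marker_table())
  rec <- defense_recovery(a, b$manifest)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})
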