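---
title: "Methods: antiphage defense annotation, CRISPR detection and phage-host linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antiphage defense annotation, CRISPR detection and phage-host linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`defenscan` implements a complete desk-scale pipeline for studying antiphage
immunity in an assembled metagenome: (i) marker-based annotation of innate
and adaptive defense systems from conserved-domain hits, (ii) calling and
typing of multigene CRISPR-cas modules, (iii) de novo CRISPR array detection
with spacer extraction and size statistics, (iv) spacer-to-virome matching
under identity/coverage thresholds, and (v) construction of the bipartite
spacer-virome network. Upstream steps (read QC, assembly, contig taxonomy,
viral-contig identification, domain searches themselves) are consumed as
inputs: contig FASTA, GFF3 gene calls, a contig-to-phylum TSV, a tabular
domain-hit table and viral contig FASTA sets. A seeded synthetic community
generator with a ground-truth manifest provides the test bed.

# Defense-system annotation

## Model

A *marker table* maps conserved-domain accessions to marker genes of named
defense systems (RM, BREX, DISARM, Abi, Zorya, Thoeris, Shedu, Gabija,
Hachiman, CRISPR-Cas), optionally with a subtype (e.g. *hsdM* for RM type I,
*pglW* for BREX type 2, *drmA*/*drmD* for the two DISARM classes). Domain
hits are first screened at `E < 1e-2` (strict inequality; a hit exactly at
the cutoff is excluded). Each gene with at least one hit to a marker
accession receives **one** assignment, supported by its best marker hit
(lowest E-value; ties broken by higher bitscore, then lexicographically
smallest accession, so classification is invariant to input order). If the
winning accession is listed under a single system, the gene is *assigned*;
if the accession is shared between systems (e.g. a methyltransferase domain
common to RM and DISARM), the gene is *ambiguous*: it counts as a defense
gene but joins no system and is excluded from system-level statistics.

The per-gene convention (rather than one call per hit) keeps gene counts
well defined; `assign_defense_systems(all_hits = TRUE)` provides the
per-hit alternative. No locus-context rescue of ambiguous genes is applied
by default — the upstream curation such rescue would emulate is not
mechanically reproducible — but `call_defense_loci()` provides the
same-system locus grouping (maximal runs with at most `max_orf_gap = 5`
intervening ORFs) that such a rule would operate on.

The shipped marker table is a structural stand-in: its accessions
(`MRK*`/`CAS*`) are placeholders expected to be replaced by a curated
COG/Pfam list; it is data (TSV), not code. The *canonical* flag partitions
systems into long-established (RM, Abi, CRISPR) versus recently described
(BREX, DISARM, Zorya, Thoeris, Shedu, Gabija, Hachiman) classes and is
user-editable.

## Abundance statistics

Per phylum (taxonomy is consumed per contig; contigs without a row count as
`unknown`), the pipeline reports:

* counts per (phylum, system), ambiguous genes entering only the phylum
  totals;
* within-phylum relative abundance: count / total defense genes of the
  phylum, so system fractions plus the ambiguous share sum to 1;
* percent of defense genes among all genes of the phylum;
* heat-map values `log10(count + 1)`. The pseudo-count keeps empty cells at
  0 and finite; the transform without it is undefined at zero and the
  source convention does not specify zero handling.

# Cas modules and typing

Cas-domain hits are held to the stricter `E < 1e-3`. Multigene modules are
maximal chains of cas genes on one contig in which consecutive members have
at most 5 intervening ORFs ("ordinal gap" = difference of gene ordinals
minus 1). "Spacing" is read as *genes between*; users preferring
ordinal-difference ≤ 5 can pass `thresholds(max_orf_gap = 4)`. Two genes
minimum ("multigene"); solitary cas genes are never typed.

Typing is table-driven (`cas_signatures.tsv`): subtype signatures (e.g.
cas8 family domains for I-A..I-F, GSU0054 for I-U, csn2 for II-A, csm2 for
III-A) carry unique priorities, and the matched subtype with the best
(lowest) priority decides both subtype and type. Without a subtype match,
type-level signatures decide (cas3 → I, cas9 → II, cas10 → III); conflicts
or an adaptation-only module (cas1+cas2) yield `unclassified`. Fractions
over classified modules sum to 1 by construction.

# CRISPR array detection

The detector is a direct-repeat scanner in the style of the classical
CRISPR recognition tools, with their documented defaults: at least 3
repeats, repeat length 19–38 bp, spacer length 19–48 bp, an 8-bp exact
search word. Scanning left to right, the current 8-mer is looked up for its
next exact occurrence at an admissible period *d* (repeat + spacer length);
periodic copies of the word are counted, and the repeat is extended
maximally on both sides while all copies agree, trimmed on the right if the
repeat-length maximum or spacer-length minimum would be violated. An array
is accepted if ≥ 3 repeats remain, all length constraints hold, and no
spacer pair exceeds 60% ungapped identity (tandem-repeat guard; the
threshold follows common practice, the tool convention does not state one).
Overlapping candidates are resolved greedily left to right
(leftmost-longest), which makes output deterministic and independent of
candidate enumeration order. Repeat copies are exact by default
(`max_repeat_mismatches = 0`), which makes the detector testable against a
brute-force enumerator of periodic exact-repeat structures; a per-copy
mismatch budget (against the first copy as consensus) is available for
realism, at the cost of that exactness.

Array *size* is the spacer count (repeats − 1, minimum 2). Size statistics:
the percentage histogram, and the *majority cutoff* — the largest size `k`
such that the cumulative share of arrays of size ≤ `k` is at most 85%. If
even the smallest size exceeds the threshold the smallest size − 1 is
returned flagged `degenerate`. Two size distributions are compared by
aligned histograms, their cutoffs and ranges, and a two-sample rank-sum
test reported descriptively (no hypothesis-testing machinery beyond that).

The detector kernel is compiled (Rcpp): the scan hashes every 8-mer of a
contig once, so a ~5 Mb community is processed in seconds on one core.

# Spacer-virome matching

Each spacer is aligned against each viral contig on both strands by
seed-and-extend local alignment: exact 11-mer seeds locate candidate
windows, each window is aligned by an affine-gap Smith-Waterman (Gotoh)
kernel under the classical nucleotide-BLAST task scheme (+2 match, −3
mismatch, gap open 5, gap extend 2; a gap of length L costs 5 + 2L), and
the best alignment per (spacer, target) pair is kept. No masking is
applied; `N` never counts as a match. Decisions that change boundary cases,
made explicit here: identity = matching columns / all alignment columns
*including gaps*; query coverage = aligned query residues / spacer length;
coverage uses ≥ 80 (a floor), identity uses strict > (90 for the internal
virome, 95 for external reference sets). One best alignment per pair is
reported; all pairs are kept by default (`best_only = FALSE`) and the
network layer decides multiplicity.

`exhaustive_match_oracle()` runs the same scoring as a full
dynamic-programming alignment of spacer versus entire target without
seeding. The seeded search provably finds the optimum whenever the optimal
alignment contains an exact run of at least the word size; a spacer whose
best placement has no surviving 11-mer run (e.g. a 31-bp protospacer with 3
evenly spread substitutions is 90.3% identical yet has a maximal run of 8)
is invisible to any word-11 seeded search — a faithful property of the
emulated tool, not a defect, and the reason the oracle-equivalence tests
condition on a seed within the optimal interval. E-values are not computed;
thresholds are identity/coverage only.

# Network and annotation categories

The network is bipartite: spacer nodes and matched viral-contig nodes
(kind = target set), edges weighted by alignment score normalized to (0, 1]
by the per-spacer maximum — storing alignment strength rather than a layout
distance, which is a rendering concern. Exports: GraphML (round-trip safe),
SIF, and node/edge TSV; connected components are labelled, and
`hub_report()` lists viral contigs matched by ≥ k spacers. Viral gene
functional descriptions are categorized into virulence/evasion classes
(methylases and methyltransferases, chitinase, antirestriction, repressor
and virulence-associated proteins) by case-insensitive substring match in
priority order, more specific categories first; each description counts
once, unmatched ones under `other`, so category counts conserve input size.

# Synthetic community generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, as a pure function of one integer seed (two runs are
byte-identical): i.i.d. uniform ACGT background (so any repeat structure is
planted, and detector false positives on background measure specificity),
genes tiled at 600–1,200 bp with 60–180 bp gaps over the head of each
contig, and a gene-free tail where arrays are planted. Defaults, chosen
once as desk-scale study conditions: 200 contigs of 18–32 kb (~5 Mb); a
phylum mix dominated by Proteobacteria and Actinobacteria with 40% of
contigs unassigned, mirroring the large unknown fraction typical of soil
communities; defense loci proportioned RM > BREX > DISARM > Zorya with
singleton loci for the rarer systems — a planting density (~2% of genes)
chosen so every system is statistically visible at 200 contigs rather than
to reproduce any global percentage; 6 cas modules cycling through subtypes
I-C, I-E, I-U, II-A, III-A, I-B; 12 arrays with sizes drawn from a
truncated geometric (P(k) ∝ 0.85^k on 2..25, right-skewed as in real
communities, minimum 2 spacers); 30 internal plus 12 external viral contigs
of 5–15 kb carrying 1–4 protospacers each.

Details that make ground-truth recovery exact:

* each planted locus lays out the chosen system/subtype's marker genes
  contiguously, each gene hit to its marker accession with E-value drawn
  log-uniformly below the relevant cutoff;
* noise hits (Poisson per gene, default 0.3) go to a dedicated non-marker
  accession namespace, so annotation precision is identically measurable at
  any noise level;
* planted repeats are identical copies and spacers are regenerated until
  pairwise identity ≤ 0.55; the single bases flanking the array block are
  resampled to break repeat periodicity at the boundary, otherwise chance
  agreement (probability 1/4 per side) extends the repeat consensus past
  the planted edge and exact-coordinate recovery is ill-posed;
* protospacer mutations are substitutions only (each mutated base changes),
  keeping identity arithmetic exact for threshold boundary tests; indel
  stress tests can be built with the alignment API directly;
* viral contigs carry no gene or taxonomy records — they are matched by
  sequence only.

What the generator does **not** emulate: real phage genome architecture,
codon structure, GC skew, repeat families shared across contigs,
read-level error, or taxonomically structured spacer-host biases. Passing
recovery tests therefore demonstrates correctness of the pipeline's rules
and arithmetic on data satisfying its assumptions, not performance on real
metagenomes, where repeat-like elements (e.g. tandem repeats, transposons)
and diverged protospacers dominate the error budget.

# Numerical conventions

* Coordinates are 0-based half-open internally; 1-based inclusive only at
  the GFF3 and alignment-output boundaries. Ordinals ignore strand.
* E-value comparisons are strict (`<`); identity thresholds strict (`>`);
  coverage is a floor (`>=`).
* Printed percentages use one decimal with ties rounded half away from
  zero (`percentage()`), the convention behind figures like 57.4 or 11.3;
  IEEE half-even rounding differs at `.x5` boundaries (e.g. 1/16 → 6.3,
  not 6.2).
* Reports serialize with sorted keys and schema version; every stored
  percentage recomputes from its stored numerator and denominator, and
  cross-stage totals (array sizes vs spacer counts) are hard-checked.

# Problem sizes

The shipped tests and the acceptance script run: the full default
community (~200 contigs, ~5 Mb) once for end-to-end recovery; 200 short
(≤ 2 kb) contigs for detector-vs-enumerator equivalence; 1,000 random
spacer/target pairs for aligner-vs-oracle equivalence; 100 random gene
layouts for the module-rule oracle; and a 60-contig double run for
byte-level determinism. These sizes were chosen as the smallest at which
every rule, boundary and invariant is exercised with comfortable margins.

# Known limitations

* The marker and signature tables are placeholders; scientific conclusions
  on real data require a curated Table-S2-equivalent marker list.
* The detector's mismatch-tolerant mode uses the first repeat copy as
  consensus and exact seeds, so heavily diverged repeats reduce recall
  (measured by the mutation-sweep test).
* The seeded aligner inherits word-size blindness to seedless optima, as
  discussed above.
* Viral "taxonomy" is not inferred; target-set labels stand in for it, and
  the family-composition statistics of reference viromes are out of scope.
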