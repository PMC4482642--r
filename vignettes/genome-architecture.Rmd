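---
title: "Methods: comparing genome architecture between selfing and outcrossing genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing genome architecture between selfing and outcrossing genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

# The problem

Self-fertile *Caenorhabditis* species have genomes 20–40% smaller than
their outcrossing relatives. Three mechanisms could produce that pattern:
shrinkage of repetitive element content, a genome-wide bias toward small
deletions, or loss of whole genes together with their flanking intergenic
DNA. Distinguishing them requires consistent bookkeeping of where the
bases went (footprint accounting), distribution-level comparisons of gene
and intergenic architecture between chromosome classes and species, and
synteny-level comparisons of aligned blocks — plus the assembly-hygiene
steps (read pre-filtering, contamination screening, residual-polymorphism
and marker QC) that make an inbred outcrosser assembly trustworthy in the
first place. This package implements each stage as a composable function
and ships a ground-truth synthetic genome generator so the whole pipeline
is testable end to end.

# Coordinates and interval algebra

All internal coordinates are 0-based, half-open; GFF3 and VCF (1-based)
are converted at the file boundary, and interval length is always
`end - start`. Interval normalization merges overlapping *and book-ended*
intervals: a gap of zero bases is not an intergenic space. Strand is
recorded but ignored by all length accounting, which is strand-blind.
The algebra (union, complement, intersection, difference) is delegated to
IRanges behind this plain-data-frame surface, and every operation is
checked in the test suite against an independent per-base bitmap oracle.

# Footprint accounting

`summarize_content()` offers two accounting modes because published
per-species content tables are ambiguous about de-duplication:

* **summed** (default): per-transcript exon and intron lengths are added
  up, so a base in two isoforms counts twice and exonic + intronic +
  intergenic can exceed the genome size. This matches the footnote
  convention of the content tables this package is designed to reproduce.
* **union**: exonic bases are the union of all exons; intronic bases are
  intron-covered bases *not* in any exon (so exonic + intronic equals the
  unspliced transcript footprint exactly); the footprint is the union of
  transcript spans.

Intergenic DNA is always total minus the union of gene spans, so
overlapping genes are merged before gaps are measured — the alternative
(per-gene flanks) double-counts shared DNA and can produce negative gaps.
Repeat bases are split into *coding* (overlapping the exonic union;
gene-span overlap available via `repeat_coding_by = "gene_span"` since the
published tables do not state which definition they used) and
*noncoding* (the rest).

# Gene metrics and the canonical transcript

Each gene is measured on its **canonical transcript**, defined as the
transcript with the largest summed exon length, ties broken by
lexicographically smallest transcript id — a deterministic rule that needs
no expression data. Protein size is CDS length / 3 − 1 amino acids (the
stop codon is not an amino acid); genes without an annotated CDS keep
their size metrics but have no protein length. The "total" gene size
reported in summary tables is the *gene span* rather than exon + intron of
the canonical transcript: with multiple isoforms a gene's span can exceed
any single transcript's extent, and the span is the only self-consistent
reading of published tables in which mean Total ≠ mean Exon + mean Intron.
Both quantities are returned, so the discrepancy is visible rather than
reconciled away.

# The statistical battery

Comparisons use Kruskal–Wallis rank-sum tests (tie-corrected H, df = k−1,
chi-square upper tail) within species (X vs autosomes) and between species
per chromosome class, followed by Bonferroni-adjusted pairwise Wilcoxon
rank-sum tests (`p_adj = min(1, p·m)`, m = number of pairs). The tests are
one-way and nonparametric throughout: the underlying quantities are
nucleotide counts with heavy right tails, severe heteroscedasticity and
unbalanced group sizes, and rank tests cannot address interaction terms —
so no interaction is claimed. Small untied samples get exact Wilcoxon
p-values; otherwise the normal approximation with continuity correction is
used (the `stats` default). Degenerate input in which every observation is
identical is intercepted before `kruskal.test` (which returns NaN there)
and reported as H = 0, p = 1, with a `degenerate` flag. Calibration is
part of the acceptance suite: under generator runs with no planted
X–autosome difference the battery's raw p-values are checked for
uniformity (Kolmogorov–Smirnov) and for type-I error at the nominal level.

# Synteny blocks

`chain_blocks()` groups 1:1 ortholog pairs that lie on the same chromosome
in both species and within `join_distance` (default 50,000 bp) of each
other in **both** genomes — the strictest consistent reading of "within
50,000 nucleotides of each other", applied to the gap between gene extents
rather than midpoints. Blocks are the *transitive closure* (single
linkage) of that relation rather than a one-pass sweep in species-A order:
the two differ only in the corner case where a non-consecutive pair is
within range in species B while the consecutive pair is not, and the
transitive definition is the one that is order-invariant, partitions the
input, and is monotone in the join distance; it is verified against a
brute-force O(n²) oracle. Many-to-many orthologs are reduced to 1:1
beforehand (`ortholog_pairs()`: longest gene wins, ties by id).
Single-gene blocks sitting on non-homologous chromosomes are
translocations and are removed by `filter_single_translocations()`; the
homology map relating chromosome labels across species is always supplied,
never inferred. Indel size bias between matched blocks is tested on
r = ln(span_A/span_B) with a one-sample Wilcoxon signed-rank test against
0, with the per-block span table returned for scatter-style inspection;
the ortholog-desert scan classifies a sliding window as divergent when its
fraction of ortholog-bearing genes is at most `max_density` (gene-free
windows count as ortholog-free) and merges qualifying windows into maximal
runs of at least `min_length_bp`.

# k-mer read pre-filter

A two-pass filter: pass one counts every ACGT-only window of length
k = 15 in canonical (strand-collapsed) form over the whole read set; pass
two drops a read when it carries more than `max_singletons = 12` k-mers
seen exactly once in the dataset (signature of sequencing error) or more
than `max_high_count_kmers = 51` k-mers seen more than
`high_count_threshold = 20,000` times (signature of an over-represented
repeat). Canonical counting makes decisions strand-symmetric, which is why
k must be odd (no self-reverse-complementary k-mers). N-containing windows
neither count for nor against a read. The default drops whole pairs when
either mate fails (`pair_mode = "drop_pair"`), preserving pairing for the
assembler; independent dropping is available. The abundance threshold is
dataset-scale: tests and examples use proportionally scaled thresholds on
small read sets, while the defaults mirror the deep-coverage setting the
rule was designed for.

# Scaffold contamination screen

Scaffolds are profiled by GC fraction (over ACGT bases only) and mean
per-base coverage; the classifier fits class-conditional bivariate
Gaussians on (GC, log10 coverage) — coverage is multiplicative, hence the
log — with empirical priors, and retains every scaffold whose posterior
probability of target origin exceeds 0.2, a deliberately permissive
threshold that errs toward keeping DNA. Scaffolds with independent
homology evidence of target origin are retained regardless of posterior.
The published description of this step says "decision tree" while
displaying continuous class probabilities; the Gaussian model is the
simplest generative model that reproduces those posterior semantics, and
the contract is defined on the inputs (GC, coverage, labels) and outputs
(posterior, retention) rather than on the classifier family. Degenerate
training covariances are ridge-regularized with a warning.

# Site classes and residual polymorphism

`classify_sites()` partitions every base into exactly one class by the
precedence **CDS exon > 5′UTR > 3′UTR > intron > TSS > TE > intergenic** —
coding annotation outranks repeat annotation, so a transposon inside an
exon counts as coding sequence; the order is a configurable argument. The
TSS class is a 200 bp window immediately upstream of each transcript
start, strand-aware and clipped at scaffold edges; 200 bp is a
conventional promoter-proximal scale, and the width is exposed because no
standard exists. `polymorphism_by_class()` removes sites with depth > 600
(collapsed repeats masquerading as unique sequence) or quality below Q10
(90% call certainty, Phred+33) from numerator *and* denominator, so the
reported fraction refers only to well-assayed sites; the site quality is
read from the VCF QUAL column. The headline "genic" rate pools CDS exons,
UTRs and introns — the well-assembled gene-body classes — and excludes
intergenic DNA and TEs, whose assembly quality is systematically worse.

`marker_qc()` applies the RIL marker filters in a fixed order: flag
markers whose parental-A frequency (over non-missing, non-heterozygous
calls; RILs are expected to be nearly homozygous) exceeds 80% or falls
below 20%, drop *all* markers on scaffolds with more than 5 flagged
markers (a scaffold-level signal of reproductive incompatibility or
misassembly), then drop markers genotyped in fewer than 40 lines, then
collapse duplicate genotype patterns to one representative while recording
the duplicates for later re-addition. The procedure is idempotent.

# The synthetic genome generator

`simulate_genomes()` draws an ancestral gene complement and derives each
configured species from it, so orthology, deletions and translocations are
known by construction. What it emulates:

* genes of ~6 exons (1 + Poisson) of ~200 bp (log-normal), matching the
  conserved exon architecture of the clade;
* log-normal intron and intergenic lengths with class-specific medians
  (autosome vs X) — the real distributions are heavy-tailed and
  right-skewed, and the log-normal is the simplest family with that shape;
  it is a modelling choice, not an empirical claim about the true family;
* a selfing-derived species that deletes a fixed fraction of genes
  *together with the downstream intergenic gap* (gene loss removes
  flanking DNA, the mechanism under test), applies class-specific intron
  scaling (default 1.5× on the X, emulating the observed X-specific intron
  expansion in selfers), and translocates a fraction of genes;
* planted repeats (several TE families, ~15% of each scaffold by default,
  matching the clade's repeat fractions), i.i.d. sequence at configurable
  GC, reads with substitution errors and a contaminant fraction at
  distinct GC/coverage, all-sites VCFs with per-class Bernoulli
  heterozygosity and planted depth/quality outliers, and RIL genotypes
  with planted segregation distortion.

What it does **not** emulate: realistic sequence evolution (no
substitution model, codon structure or conservation gradients), assembly
artefacts, linked selection, operonic gene organisation, or read-quality
profiles beyond a constant Phred value. Passing tests therefore
demonstrate that the *measurement machinery* recovers planted
architectural signals under the stated sampling models — not that any
biological conclusion transfers automatically to real genomes.

Determinism: a fixed seed fixes every emitted byte. Deleted-gene counts
are exact (`round(gene_loss · n_genes)` deletions; which genes go is
random), so parameter-recovery tests can assert equality, not just
proximity.

# Numerical choices and degenerate inputs

* Adjacent intervals merge during normalization; zero-length gaps are not
  intergenic spaces; scaffold-end flanks are never gaps.
* Ties in rank tests get average ranks with tie correction in both the
  Kruskal–Wallis and Wilcoxon statistics.
* All-tied samples: H = 0, p = 1, flagged — never NaN.
* Empty groups in pairwise testing are skipped with a warning; the
  Bonferroni multiplier counts tested pairs only.
* Posterior computation in the scaffold classifier works in log densities
  with a max-subtraction, so extreme points cannot underflow to 0/0.
* CDS lengths in the generator are forced to codon multiples by widening
  the 3′UTR, so protein sizes are integers ≥ 1 by construction.
* VCF records lacking DP are kept but flagged, excluded from
  depth-filtered analyses, and counted in a message.

# Problem sizes

The shipped tests run the statistical battery at 1,000–2,000 genes per
chromosome class for power checks (100 seeded replicates), 500 replicates
of ~100-gene genomes for null calibration, 100-instance brute-force oracle
sweeps for intervals, footprints, site classes and read filtering, and a
single ~1.4-million-genic-site all-sites VCF for the residual-polymorphism
recovery — sizes chosen so the full suite exercises every claim in minutes
on one CPU while keeping binomial standard errors small relative to the
tested tolerances. `scripts/acceptance.R` regenerates the polymorphism
estimate end to end (generator → VCF file → reader → classifier → tally)
at the same scale.

# Known limitations

* Orthology is an input (or generator ground truth); the package does not
  infer it, and the 1:1 reduction of many-to-many groups is positional,
  not phylogenetic.
* The intergenic-space definition keeps all positive gaps, including the
  few-nucleotide spacers inside operons; downstream analyses wanting to
  exclude operonic gaps must filter the returned lengths.
* The contamination classifier is two-class; nested or multi-taxon
  contamination needs a richer model.
* Footprint accounting trusts the annotation: unannotated genes deflate
  genic footprints and inflate intergenic DNA, which is why the synteny
  and polymorphism modules carry their own QC.
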