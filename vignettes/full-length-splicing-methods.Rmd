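---
title: "Methods: full-length transcriptome splicing analysis with flsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length transcriptome splicing analysis with flsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flsplice)
```

# Overview

flsplice implements the analysis chain used to characterise alternative
splicing (AS) from full-length (long-read) transcriptome sequencing, as
applied to developmental series such as the peanut peg (gynophore, stages
S1-S4) alongside vegetative and floral tissues. The chain is: classify
reads of insert into full-length non-chimeric (FLNC) evidence; collapse
transcript-to-genome alignments into unique isoforms; classify splicing
differences between isoforms into the five canonical event types; call and
profile poly(A) cleavage sites; filter short-read splice-junction call sets
to a consensus; and score tissue/stage specificity of isoform expression.
A synthetic-transcriptome simulator with complete truth manifests makes
every stage testable without external data.

This vignette describes the models and procedures, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data do
and do not establish about behaviour on real data.

# Read classification

A read of insert is **full-length (FL)** when it simultaneously carries the
5' cDNA primer, the 3' cDNA primer and a poly(A) tail; otherwise it is
non-full-length (nFL). An FL read containing an additional primer copy in
its interior is **chimeric** (a concatemer of two inserts); FL and
non-chimeric reads form the **FLNC** set that carries isoform evidence.
The identities `FL + nFL = total` and `FLNC + chimeric = FL` hold by
construction and are validated whenever a summary table is built, so
published summary tables can be checked for internal consistency directly.

Primer matching is semi-global with indels (`Biostrings::matchPattern`),
tolerating an edit distance up to `max_mismatch_fraction` (default 0.1) of
the primer length. A hit within `terminal_margin` (default 100 nt) of a
read end is terminal; anything else is internal and marks a chimera. The
margin reflects that genuine terminal primers sit at the very ends of the
insert, while concatemer junctions fall well inside. Reads whose primer
layout indicates the reverse orientation are reverse-complemented before
classification. Primer sequences are experiment-specific; the package
ships a fixed default pair of 24-nt primers that the simulator uses.

**Poly(A) tail rule.** A tail is called in the terminal window of up to 30
bases as the longest suffix containing more than eight A and fewer than
two non-A bases (at least 9 A, at most 1 non-A). The published wording is
ambiguous about whether the 30-base window may be shortened at read ends;
we evaluate every suffix length up to 30 and keep the longest qualifying
one, which makes short terminal regions callable and is the more permissive
reading. The same rule decides poly(A) presence during classification
(applied to the region 5' of the 3'-primer hit), so there is a single tail
definition in the package.

# Isoform collapse

Alignment footprints (exon-block chains with query coverage and identity)
are collapsed into unique isoforms. Alignments with coverage < 0.8 or
identity < 0.7 are dropped — the standard long-read collapse thresholds.
Among survivors, multi-exon alignments merge when they have identical
intron chains and their 5' and 3' end points lie within tolerances;
single-exon alignments merge on reciprocal overlap ≥ 0.5. Defaults are a
loose 5' tolerance (1000 nt; long-read 5' ends are truncation-prone) and a
tight 3' tolerance (100 nt; 3' ends are anchored at poly(A) sites).

Merging uses single-linkage components of the pairwise mergeability
relation, evaluated on the original alignment end points. This is
order-independent (a pairwise merge-to-fixpoint procedure is not, because
merged boundaries can extend reach), and the merged isoform takes the
outermost observed boundaries and records its supporting alignment count,
so support totals are conserved. Collapsed isoforms are grouped into gene
loci (`PBG.<k>`) by span overlap on the same strand.

# AS-event classification

Isoforms are compared pairwise within a gene through their splice-site
chains. A splice site is an intron boundary with a role — donor at the
transcript-5' end of an intron, acceptor at its 3' end (genomically
flipped on the minus strand). Within the genomic span shared by the two
isoforms, sites present in both chains (same position and role) are
anchors; each maximal run of differing sites between consecutive anchors
(or span boundaries) forms a bubble and yields one event. Bubble patterns,
read in transcript orientation, map to the canonical types and their
site-code strings:

| type | pattern | code |
|------|---------|------|
| intron retention (IR) | donor+acceptor vs none, partner exonic across | `1^2-,0` |
| exon skipping (ES) | acceptor+donor vs none, partner intronic across | `1-2^,0` |
| alternative acceptor (AA) | single acceptor vs single acceptor | `1-,2-` |
| alternative donor (AD) | single donor vs single donor | `1^,2^` |
| mutually exclusive exons (MX) | exon vs non-overlapping exon, both spliced to both flanks | `1-2^,3-4^` |

Anything else — nested retention, overlapping alternatives, compound
bubbles — is typed `other`, never forced into one of the five. Two
deliberate design points:

* **Terminal differences are not events.** Only sites strictly inside the
  shared span participate, so alternative first/last exons and TSS/TES
  shifts yield nothing. This required one subtle geometric check: a
  transcript with no sites inside a bubble may be either exonic *or*
  intronic across it (the latter when its own intron boundaries coincide
  with the bubble flanks); IR demands the former, ES the latter, so both
  are verified against the exon chain rather than inferred from the site
  pattern alone.
* **Gene-level deduplication.** Events are deduplicated across transcript
  pairs by their (type, flanks, variant sites) signature. The published
  event total for the real dataset depends on the grouping granularity of
  the original caller, which is not fully specified; genome-scale event
  totals are therefore validated against planted synthetic truth and
  published ratio arithmetic, not against the absolute published count.

The site codes use ASCII hyphens; some printed versions of the codes use
typographic en-dashes (`1–2^,0`), which are equivalent.

The classifier is cross-checked against an independent brute-force
template matcher (operating on clipped exon-interval geometry instead of
site-role sequences) over every transcript pair constructible from an
8-boundary grid with up to 4 exons, on both strands (~16,000 pairs), and
on random 3-transcript gene models for the deduplication step.

Per-gene isoform counts can also be compared between a query and a
reference annotation: genes are grouped by `log2(n_query / n_reference)`
into group I (≤ −1, fewer isoforms in the query), group II (between −1
and 1) and group III (≥ +1). A published figure caption states these
thresholds self-contradictorily ("group-I (log2Ratio ≤ 1) … group-III
(log2Ratio ≥ 1)"); the implementation follows the evident intent of
fewer/comparable/more.

# Poly(A) sites

The cleavage site of an FLNC read is the genomic position of its last
aligned transcribed base before the untemplated tail (rightmost aligned
base on +, leftmost on −). Sites on the same chromosome and strand within
`merge_window` (default 24 nt, the usual alternative-polyadenylation
clustering scale) merge at the support-weighted modal position, summing
support; clustering runs over sorted positions, so it is independent of
input order. Each merged site is assigned to the nearest gene whose span,
extended by the merge window, contains it. Reported statistics are the
per-gene site counts, the fractions of genes with ≥ 1 and ≥ 5 sites, and
the mean site count over genes with at least one site (the denominator
choice matters and is stated here because published per-gene averages do
not specify theirs).

Flanking composition is profiled over ±50 nt in transcript orientation
(minus-strand windows reverse-complemented), excluding and counting sites
truncated by chromosome edges; the canonical signature is U enrichment
upstream and A enrichment downstream of the cleavage site. Occurrences of
the polyadenylation motifs AAUAAA and UGUA (matched on DNA with T ≡ U,
overlaps counted) are tallied in the 50-nt upstream window with their
offset histogram. De-novo motif discovery is out of scope.

# Junction consensus

Short-read splice-junction call sets from multiple callers are merged by
exact boundary identity (chromosome, strand, donor, acceptor; no fuzz
window) and a junction is retained when at least `min_sources = 2` callers
report it and its read support reaches `min_reads = 5`. Support is
aggregated across callers by maximum, the conservative choice: the same
underlying reads aligned by several tools must not be double-counted, and
whether the published rule pooled support across tools is unstated.
Retention is therefore monotone: adding a caller or support can only gain
junctions. Boundary-order violations are normalised by strand convention
(donor < acceptor on +) with a warning. A STAR-style `SJ.out.tab` column
map is provided; junctions with undefined strand are dropped with a
message.

# Specificity and time-course analysis

**Presence and exclusivity.** An isoform is present in a tissue/stage
group when any sample of the group reaches `presence_threshold` (default
0.1 on FPKM-like values; published work rarely states its detection
threshold, so this is configurable). Exclusive isoforms are present in
exactly one group; all presence-pattern combination counts are emitted for
Venn rendering, and stage-exclusive isoforms additionally report their
distinct parent-gene counts.

**JS specificity.** The expression pattern p (normalised to sum 1) is
scored against each ideal single-tissue pattern e_t as
`score_t = 1 − sqrt(JSD(p, e_t))`, with Jensen-Shannon divergence on
base-2 entropy (0·log 0 := 0), following the transcript-abundance
methodology the approach derives from. Base 2 bounds scores in [0, 1];
the square root makes the distance a metric. The score is scale-invariant,
equals 1 exactly when expression is confined to one tissue, and is
undefined (flagged, excluded from distributions) for all-zero vectors.
Ties in the argmax break lexicographically by tissue label. Score
distributions are compared with the two-sample Kolmogorov-Smirnov test
(asymptotic p-values), cross-checked against a brute-force ECDF sweep.

**Time-course clusters.** Published stage analyses used fuzzy time-course
clustering only to split differential isoforms into rising and falling
groups, so the package uses a transparent equivalent: stage-mean profiles
are z-scored per isoform and k-means (k = 2, fixed seed, 10 random starts)
partitions them; clusters are relabelled `up`/`down` by the sign of the
mean last-minus-first difference. Constant profiles cannot be z-scored and
are excluded with a message. The differential pre-selection criterion in
the source analysis is unstated; the package provides a documented
stand-in (largest stage mean ≥ 1.0 and ≥ 2-fold above the smallest), not a
reproduction.

# The simulator and what it shows

`simulation_config()` fixes every generator parameter; identical
configuration and seed give bit-identical output (each generator seeds a
private RNG stream derived from the configuration seed and restores the
caller's RNG state). Defaults emulate a desk-scale experiment:

* genome: 2 uniform-random chromosomes of 200 kb (GC configurable);
* gene models: 24 non-overlapping genes of 6-9 exons (exons 120-240 nt,
  introns 150-1200 nt, within the 20 nt - 20 kb validity bounds), with
  30 planted events (8 IR, 6 ES, 6 AA, 6 AD, 4 MX — the abundance order
  observed in plant long-read studies, IR first), at most two per gene at
  well-separated slots so each forms a simple bubble; canonical GT..AG is
  written at every intron boundary;
* reads: 5' primer + spliced cDNA + poly(A) tail (20-60 nt) + 3' primer
  reverse complement; 18% nFL (one structural element dropped) and 6%
  chimeric (internal primer + second insert), matching the
  published real-data proportions (17.63% nFL, 6.4% of FL chimeric);
  substitution errors at 1% by default (long-read consensus scale), 0 in
  zero-noise tests;
* expression: 5 tissues (root, leaf, shoot tip, flower, peg) or 4 stages
  (S1-S4), 2 replicates each, lognormal abundance (meanlog log 20, sdlog
  0.5); 25% of isoforms planted group-exclusive with structural zeros
  elsewhere; in stage mode, planted monotone trends doubling per stage
  with 0.2 lognormal noise;
* junctions: three callers at sensitivity 0.95 with 5% source-specific
  false junctions and support 1 + Poisson(19).

Zero-noise settings make recovery exact, and the tests require exactness:
classification flags equal truth read-for-read, planted events are
recovered with the correct type and count (complex bubbles must fall to
`other`, never a wrong type), cleavage sites are recovered exactly,
perfect junction sources reproduce the true junction set, and planted
exclusives are recovered set-for-set. Trend labels must agree ≥ 95% at the
stated noise.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real data: realistic long-read error profiles
(indel-dominated) and quality values, alignment ambiguity (alignments are
derived from the truth, so collapse sees perfect footprints), internal
priming artefacts at genomic A-runs, incomplete splicing backgrounds,
overlapping genes and antisense transcription, and library-size or
composition effects in expression. Results on real data depend on the
upstream aligner and quantifier in ways the synthetic path cannot probe.

# Numerical choices

* Coordinates are 0-based half-open internally; GTF/GFF3 I/O converts to
  and from 1-based inclusive. Written files omit volatile header comments
  so identical runs are byte-identical.
* Report percentages round half-up to two decimals (`percentage()`), so
  77.105 prints as 77.11; this matches published tables, where banker's
  rounding would not.
* Problem sizes in the shipped tests (24-gene simulations, 16k enumerated
  transcript pairs, 150-isoform trend panels) were chosen as the smallest
  scales at which every planted structure is exercised several times over;
  they run in about two minutes in total.
* Sub-seeds are derived from the configuration seed by small fixed offsets
  (+1 annotation, +2 reads, +3/+4 expression, +5 junctions) so stages are
  reproducible independently of call order.

# Known limitations

* Event totals on real data are granularity-dependent (see above); only
  ratios and synthetic truth are validated.
* The collapse merge relation is evaluated on original end points;
  re-collapsing collapsed output is idempotent in all tested regimes, but
  pathological tolerance chains could in principle merge further on a
  second pass.
* ORF finding scans forward frames only (transcripts are oriented) and
  requires a complete start-to-stop ORF; partial ORFs at transcript ends
  are not called.
* Fusion-candidate detection is a read-segment heuristic (≥ 2 segments,
  each ≥ 5% of the read, summing to ≥ 95%, distinct loci — different
  chromosomes or > 100 kb apart); it flags candidates, it does not call
  fusions.
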