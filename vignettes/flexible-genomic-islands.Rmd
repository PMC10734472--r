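---
title: "Methods: recruitment-based discovery and typing of flexible genomic islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flexible genomic islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexgi)
```

# The model

`flexgi` analyses population genomics of streamlined marine bacteria under
three structural assumptions:

1. **Clonal frames.** Strains of one genomospecies share a syntenic core at
   >99% ANI; species are separated by a discontinuity (ANI < 95%).
2. **Flexible islands at fixed loci.** Variation concentrates in islands at
   equivalent positions, delimited by conserved border genes.  An island's
   *version* is a characteristic gene set (fGIp A–H around the *pst*
   operon; fGIphn A–D around the C–P lyase).  Within a version, island
   sequence is highly conserved across carriers — islands spread
   horizontally on a faster clock than the core diverges — which is why an
   island-vs-genome AAI comparison is informative.
3. **Environmental filtering.** The relative abundance of versions in a
   sample tracks phosphate availability monotonically: gene-poor versions
   dominate replete waters, gene-rich versions dominate depleted waters.

A metagenomic island is then an *observation*: a region of a reference
genome that recruits well everywhere except in samples whose population
carries a different version at that locus, where it shows a sharp coverage
depletion at species-level identity while the flanks stay covered.

# Recruitment and presence

Reads are aligned with an internal **ungapped seed-and-extend mapper**
(exact k-mer seeds, k = 15 by default, both strands; best hit per read,
ties to the lowest coordinate): the simulator emits substitution-only reads,
so ungapped identity is exact, and real-data users can ingest 12-column
BLAST tabular instead.  Identity for the internal mapper is
`matches / read length` — the denominator is the full read, a deliberate
choice since the published filters do not fix one; ingested BLAST identity
is taken as-is.

Two inclusive tiers mirror the published filters: **species**
(identity ≥ 98%, length ≥ 50 nt, e-value ≤ 1e−5 when present) and
**permissive** (identity ≥ 70%, length ≥ 50 nt).  Abundance is
`RPKG = n_reads / (genome length / 1 kb) / (metagenome bp / 1 Gb)` with the
metagenome size defined as total bases (not read count).  A genome is
*present* when RPKG ≥ 10 **and** species-tier breadth ≥ 0.60.  "Genome
coverage" is read as breadth (fraction of positions covered ≥ 1×), not mean
depth; this is flagged as an interpretation since the source phrase is
ambiguous.

# Island delimitation parameters

The source analysis delimits islands visually from recruitment plots; the
scan makes that operational with six parameters (`scan_params()`):

| parameter          | default | units | role |
|--------------------|---------|-------|------|
| `window`           | 1000    | nt    | sliding-window width for mean depth |
| `step`             | 500     | nt    | window stride |
| `depletion_alpha`  | 0.2     | —     | flag windows below α × median window depth |
| `bridge_gap`       | 2000    | nt    | merge flagged windows across gaps ≤ this |
| `min_island_length`| 5000    | nt    | drop shorter merged intervals |
| `presence_beta`    | 0.5     | —     | region "present in population" if depth ≥ β × median |

The median (not mean) window depth is the genome baseline so the islands
themselves cannot drag it down.  Defaults were chosen so that islands in
the 5–20 kb range typical of *pst*/*phn* cassettes are recoverable on the
bundled simulation; they were fixed before the acceptance thresholds were
evaluated and are exposed, not hard-coded.  Because window edges quantize
boundaries to the step grid, `refine_boundaries()` snaps each edge to the
nearest gene edge within ±2 kb (start to a gene end, end to a gene start),
so a partially overlapped border gene is excluded and no gene is split.
On simulated data this recovers the truth span exactly; the residual risk
on real data is a border gene that genuinely lies half inside an island.

Loci are unified across samples by reciprocal-50% interval overlap
(connected components), a standard convention chosen for testability.  A
locus is *conserved* when flagged in every sample where the genome is
present, *variable* otherwise; `presence_beta` distinguishes "region well
covered, island absent from the population" from intermediate depletion in
the non-flagged samples, since the source gives no quantitative criterion.
The permissive-tier depth is reported per island but never gates a call —
the 70% cutoff exists for linear-recruitment plotting, not detection.

# ANI, dereplication, genomospecies

`compute_ani()` follows the ANIb convention: consecutive 1020-nt query
fragments, acceptance at ≥ 30% identity and ≥ 70% fragment coverage, ANI =
mean identity of accepted fragments.  Those two thresholds and the fragment
length come from the convention implemented by the cited tool, not from the
paper itself.  Identity and coverage are measured on the best *local
segment* of the ungapped placement (Kadane's maximum-scoring segment under
a BLAST-like +2/−3 scoring): without this, fragments straddling an island
boundary would be force-aligned full-length at ~50% identity and
contaminate ANI, whereas a gapped aligner would report a partial alignment
that the coverage filter rejects.  With it, ANI of a genome against itself
is exactly 100 and a 1%-substituted copy measures 99.0 within sampling
error of the realized substitution count.

Dereplication is single-linkage at ANI > 99 (strict), representative = the
longest ungapped sequence (completeness proxy; no external quality
estimator in scope).  Species clusters are single-linkage at ANI ≥ 95 —
the source does not state a linkage; single linkage matches the
connected-component intuition of clonal frames.  Within a species cluster,
genomes are grouped by ecological distribution: complete-linkage clustering
on 1 − Spearman correlation of RPKG profiles, cut at correlation ≥ 0.7.
Each (ANI cluster × distribution group) is a genomospecies.  The published
analysis fused ANI and distribution by inspection; this rule is an explicit
operationalization and is not claimed to reproduce the original seven units
on the real ocean data.  Genomes recruiting nowhere are `unclassified`.

# Version signatures and typing

Version signatures are **closed controlled-vocabulary gene sets** with
required and forbidden members; free-text annotations map in through an
alias table.  This replaces profile-HMM searches deliberately: the
synthetic path has exact annotations, and an HMM pipeline would add heavy
dependencies without changing the classification logic, which is gene
content.  The long fGIp version (C) is encoded as the 19 genes named in the
source's figure legend and text; the three subtypes of version G collapse
to one label (their common cassette equals version F plus accessory genes —
encoded here as F + a glycosyltransferase so the label is distinct), with
subtype detail treated as annotation.  Forbidden sets encode the "version X
lost gene Y" statements (e.g. fGIphn-B lacks *phnG*; fGIp-E lacks *glpF*),
which is what makes nested inventories (D, E, H ⊂ C) distinguishable.

Scoring: `score(sig) = |genes ∩ required| / |required|`, zeroed when any
forbidden gene is present; winner = highest score, ties to the larger
required set (so a full C inventory is C, not its subset versions).  Labels
fall back to `"unassigned"` when the best score is below 0.8 or the class
core (complete *pst* operon / C–P lyase) is missing — partial islands from
single-amplified genomes should not be force-labelled.

Marker-protein clustering concatenates PstS+PstC+PstA (fixed order),
deduplicates at 100% identity, and emits a neighbor-joining tree on
p-distances.  NJ replaces the published maximum-likelihood tree because the
topology is illustrative here — version identity rests on gene content, and
the source itself notes the tree clusters do not track genomospecies.

AAI is mean identity over bidirectional best-hit pairs (global alignment;
qualification at identity ≥ 30% and ≥ 70% coverage of the shorter
sequence).

# Statistics

All tests are two-sided, matching the published reporting.

* **Wilcoxon signed-rank**: zero differences are dropped (Wilcoxon's
  original prescription — the source defers to a library default), average
  ranks on ties, `T = min(W+, W−)`.  For n ≤ 25 the p-value is exact over
  all 2ⁿ sign assignments, computed by convolution over the realized rank
  multiset — algebraically identical to literal enumeration (the test suite
  checks this against a brute-force enumerator for n ≤ 10) without
  materializing 2²⁵ vectors.  Above the cutoff: normal approximation with
  continuity and tie corrections.
* **Spearman**: Pearson correlation of average ranks; exact permutation
  enumeration for n ≤ 9, t-approximation (n − 2 df) above.
* **Kruskal–Wallis**: tie-corrected H with a χ² (k − 1 df) p-value;
  all-tied input is reported as degenerate (`NA`) rather than zero.
* **Version abundance**: RPKG of species-tier recruitment against
  per-version diagnostic sequences — genes unique to a version's signature
  within its class, falling back to the full island sequence when nothing
  is unique (common: most fGIp inventories nest inside version C).
  "Normalized abundance" is not defined in the source; RPKG with optional
  column-relative scaling is this package's operationalization.  The
  cross-version Kruskal–Wallis uses, per version, the phosphate values of
  the samples where that version is detected (abundance > 0) — one value
  per station-presence, not abundance-weighted; the raw matrix stays
  exportable so either convention can be recomputed.

# The synthetic community: what it emulates, what it does not

`simulation_config()` defaults state the simulated world:

* cores of ~100 kb (desk scale; 1.4 Mb genomes are one parameter away but
  slow the tests without changing any code path), tiled with 900-nt
  codon-clean genes and 3-nt spacers — matching the extreme intergenic
  compression of streamlined genomes (reported means of 2–3 bp);
* within-species pairwise divergence 0.005 (ANI ≈ 99.5, inside the
  dereplication band), between-species 0.08 (ANI ≈ 92, safely below the
  95% species boundary).  Each strain is its species consensus mutated at
  half the pairwise rate; substitution-only, so island loci stay
  positionally equivalent across strains — the property the analysis
  depends on;
* island versions as cassettes of the signature's required genes inserted
  between two conserved border genes.  Versions are generated as
  **independent sequences** (horizontal acquisition from divergent
  donors): one version's reads neither recruit to another at the species
  tier nor inflate core ANI, while within a version the cassette is
  copied verbatim (island AAI 100 > genome AAI).  This was a design
  correction made when ancestor-derived versions (~19% divergence) proved
  enough for ANIb-style fragments to keep aligning and drag strain ANI to
  ~94.  Consequence: cross-version protein homology is absent in
  simulation, so typing rests on annotations, as it should;
* 150-nt reads, i.i.d. substitution errors at 0.005 (an erroneous base
  always changes), per-strain read counts computed (not sampled) as
  `abundance × depth × genome length / read length`, default 30× community
  depth;
* five samples spanning 1 → 0.002 µM phosphate, covering the published
  replete (>0.5 µM) and depleted (0.001–0.005 µM) regimes; version weights
  follow a logistic in log₁₀(phosphate), midpoint 0.05 µM, slope 4 per
  decade, signed by gene-count rank.  The source establishes monotonicity
  but no functional form — the logistic and its parameters are assumptions
  and remain configuration, not constants.

Not emulated: indels and rearrangements, quality-score error profiles,
GC evolution, operon structure, phage/defense dynamics, and real sample
heterogeneity (uneven depth, contamination, strain mixtures beyond the
version pools).  A green acceptance run therefore establishes that the
algorithms are correct on data satisfying the stated assumptions — not
that the biological conclusions replicate on ocean data, which would need
the original multi-terabase read sets.

# Numerical and degenerate-input choices

* All thresholds are inclusive (≥ / ≤), following the "at least" phrasing
  of the published filters.
* Internal coordinates are 0-based half-open everywhere; conversion happens
  only in the GFF3/BLAST writers and readers (1-based inclusive).
* One best hit per read; ties broken by identity, then lowest genome
  coordinate, then forward strand — recruitment is deterministic.
* The single simulation seed drives genome construction; read simulation
  uses seed + 1 so the two stages have disjoint, documented streams and
  identical configurations are byte-identical.
* Degenerate inputs return explained `NA`s rather than numbers: all-zero
  differences (signed-rank), zero variance (Spearman), all-tied values
  (Kruskal–Wallis), no accepted fragments (ANI), no qualifying BBH pair
  (AAI).
* `detect_islands()` refuses genomes that fail the presence call instead of
  reporting the whole genome as one island.

# Known limitations

* The internal mapper is ungapped; real reads with indels should come in as
  BLAST tabular.  No paired-end awareness, no mapper e-values.
* Island detection needs the reference's population depleted below
  α × median in at least one sample; a version present at intermediate
  frequency everywhere leaves no detectable depletion.
* The genomospecies distribution-grouping rule (Spearman ≥ 0.7, complete
  linkage) is one defensible choice among several; with fewer than three
  samples, distribution grouping is skipped.
* CLI configuration files are JSON or flat `key=value` (no YAML parser in
  the supported dependency set).
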