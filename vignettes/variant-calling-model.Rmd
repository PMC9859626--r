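---
title: "The tumorvar calling model: LOD scoring, paired gating, and same-read merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tumorvar calling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorvar)
```

## What the caller computes

`tumorvar` detects somatic SNVs, multi-nucleotide substitutions (MNVs),
insertions, deletions and complex variants from aligned tumor reads, with
or without a matched normal. The design combines two classical somatic
statistics — a Bayesian-classifier log-odds (LOD) score for candidate
discovery and a one-sided Fisher's exact test (FET) for tumor–normal
comparison — with read-level phasing: events observed together on the same
sequencing reads are reported as one variant, which is what distinguishes
a substitution such as `CA>AG` from two independent SNVs, and a complex
allele such as `GG>A` (a one-base gap plus an adjacent mismatch) from a
deletion and an SNV.

### The site model

At a candidate site with reference base $r$ and alternate $m$, every
retained observation $b_i$ with Phred quality $q_i$ has error probability
$e_i = 10^{-q_i/10}$ and likelihood

$$P(b_i \mid a) = \begin{cases} 1 - e_i & b_i = a \\ e_i/3 & b_i \ne a. \end{cases}$$

The mutant model says a fraction $f$ of molecules carry $m$; the null says
$f = 0$. The score is the log10 likelihood ratio at the plug-in estimate
$\hat f$ (the duplicate-collapsed alternate fraction):

$$\mathrm{LOD} = \sum_i \log_{10}
 \frac{\hat f\,P(b_i \mid m) + (1-\hat f)\,P(b_i \mid r)}{P(b_i \mid r)},$$

evaluated in log space (the summands are bounded, so log-space and direct
product evaluation agree to well below $10^{-9}$ at the depths the tests
probe). A candidate is kept iff $\mathrm{LOD} \ge 3.9$, the conventional
threshold for this family of callers (`lod_threshold`). An allele with
$\hat f = 0$ has identical likelihoods under both models and scores
exactly 0. Observations matching neither $r$ nor $m$ contribute 0 — both
models assign them $e_i/3$.

The LOD is computed over *duplicate-collapsed* representatives (one
observation per duplicate group: its majority allele, ties broken
alphabetically, with the group's maximum base quality for that allele), so
the score and the reported allele fraction are estimated from the same
collapsed evidence. A configuration could equally use raw observations;
collapsed counts were chosen so that LOD and VAF never disagree about what
the support is.

### Duplicate collapsing and VAF

Reads sharing an alignment signature — contig, start, CIGAR reference
end, strand, and mate start when paired — are treated as PCR copies of one
molecule. A group *supports* the variant when strictly more than
`dup_support_fraction` (0.8) of its members carry it; the variant allele
frequency is

$$\mathrm{VAF} = 100 \times
  \frac{\text{supporting groups}}{\text{eligible groups}}\,\%$$

For indels and complex alleles only groups whose reads span every altered
site are eligible — a read that ends inside an event can neither support
nor contradict it. The site's reported base quality is the maximum quality
among supporting observations. Duplicating every read $k$-fold leaves the
VAF exactly unchanged (a tested invariant).

One practical consequence, visible at very high depth on short targets:
two *distinct* molecules can collide on the same alignment signature, and
a mixed group whose mutated fraction falls at or below 0.8 counts toward
depth but not support. This deflates VAF estimates slightly — at depth
2000 over a 500 bp contig the effect is on the order of a few percent
relative — and is inherent to coordinate-based duplicate handling, not an
artifact of the simulator.

### Read screens

Before any site is scored: unmapped, secondary/supplementary, QC-fail
reads and reads below `min_mapping_quality` (20) or outside the target
regions are dropped; flag-marked duplicates are kept by default and
handled by collapsing (set `drop_flag_duplicates` to discard them
outright). Base observations below `min_base_quality` (13) are ignored
per site. Reads carrying `max_mismatches_per_read` (3) or more mismatches
are removed from SNV evidence only — complex variants legitimately put
several mismatches next to a gap on the same read, so indel evidence keeps
them. An optional end-of-read distance cut (`end_distance_filter`) exists
and defaults to off.

### Same-read merging

* **SNV runs.** Adjacent (distance-1) SNV candidates whose supporting
  read sets co-occur merge transitively into one MNV record. Exact
  read-set equality is brittle under sequencing error, so co-occurrence
  requires that at least `mnv_cooccurrence` (90%) of the lower-support
  member's reads also support the neighbour. Non-adjacent same-read SNVs
  are never merged without an intervening indel; in paired mode each SNV
  is classified against the normal first, so a germline neighbour is
  dropped rather than absorbed.
* **Gaps and insertions.** Per read, one event per I/D CIGAR operation;
  reads with more than `max_indel_events_per_read` (2) events are treated
  as alignment noise and excluded. Two same-read events merge when their
  inner-edge reference distance is strictly below
  `gap_gap_merge_distance` (10); an SNV within
  `snv_gap_merge_distance` (5) bases — inclusive, measured to the nearest
  event edge — is absorbed. The two different comparison senses follow
  the two different phrasings of the rules ("within five bases" vs "less
  than 10 bases"). The merged allele's reference sequence is read off the
  reference over the span and its alternate off the read; events on
  different reads are never merged. Site-level SNV candidates whose
  supporting reads mostly (≥ 50%) carry an emitted complex allele
  spanning the site are suppressed as components of that allele.

### Representation

Internally everything is 0-based half-open; emitted coordinates are
1-based. Alleles are normalized by shared-suffix trimming with leftward
extension (which left-aligns pure indels through repeats) followed by
shared-prefix trimming that always leaves one base on each side. Pure
insertions and deletions therefore carry a single left anchor base; block
substitutions keep non-empty `ref`/`alt` with no extra anchor, so a
complex allele prints as `GG>A`, matching the tabular convention of the
surrounding literature. Normalization is idempotent, and both call and
truth sides of any comparison are normalized with the same reference.

### The paired cascade

For a tumor candidate with collapsed counts $(c_1, c_0)$ and normal
counts $(n_1, n_0)$, in order:

1. **Frequency gate.** Reject unless the normal VAF is below `nf`
   (2 percentage points) *or* below `normal_ratio` (0.2) times the tumor
   VAF. The disjunction is read literally.
2. **Direct emission.** No normal support, or all normal supporting reads
   on one strand (taken as an artifact signature), emits immediately.
3. **Normal LOD gate.** When the normal VAF is below
   `normal_lod_gate_ratio` (0.5) times the tumor VAF, score the allele in
   the normal: a weak normal LOD (< 3.9) means the normal does not
   credibly carry the allele — emit. A strong normal LOD falls through
   to the exact test.
4. **Fisher's exact test.** The point probability of the observed table
   is the hypergeometric mass
   $p = \binom{n_1+n_0}{n_1}\binom{c_1+c_0}{c_1}/\binom{N}{n_1+c_1}$,
   computed via `lgamma`. A point mass alone is not a valid p-value, so
   the default decision statistic is the one-sided tail toward tumor
   enrichment (sum over tables with normal-variant count $\le n_1$);
   `fet_mode = "point"` gives the literal printed quantity for
   comparison. Emit iff $p \le$ `fet_p_threshold` (0.05).

A candidate with no normal coverage at all is rejected with an explicit
`no_normal_coverage` path rather than being silently emitted. Indels take
the same cascade with spanning-read counts; since the base-level error
model does not directly apply to a gap, the normal-side LOD for an indel
uses one indicator observation per eligible group (exhibits / does not
exhibit the allele) with the group's base quality at the anchor — the
package's own construction, stated here because the underlying method
defines no indel LOD.

### Filters, origin, and output

Quantified candidates then pass the variant-level ledger: collapsed
support ≥ `min_support_reads` (2), collapsed depth ≥ `min_depth` (8),
VAF ≥ `min_vaf` (1%), site quality ≥ `min_base_quality`, and optionally
double-stranded support. These floors are configurable reconstructions of
standard practice, not published constants; the support/depth pair
mirrors common benchmark pruning and `min_vaf` the 1% detection
convention for targeted panels. In tumor-only mode, emitted variants are
annotated against user-supplied population-AF and hotspot site lists:
population AF ≥ `germline_popaf_threshold` (1%) labels `germline`,
hotspot membership labels `somatic`, both label `both`, neither
`unknown`. No remote databases are consulted. Paired-mode output is
somatic by construction. Candidate generation itself requires at least
one supporting duplicate group and two raw supporting observations before
a LOD is computed; anything below that is indistinguishable from a
singleton sequencing error and could never pass the default floors.

Output is VCF 4.2 (block substitutions as such; INFO keys `DP`, `AD`,
`AF`, `SB`, `TLOD`, plus `NDP`/`NAD`/`NLOD`/`FETP` in paired mode and
`ORIGIN` in tumor-only mode), with an optional TSV report using 1-based
inclusive spans. Byte output is deterministic, and the caller's results
are invariant to the number of region chunks (`threads`): chunks own the
candidates whose detection anchor falls inside them, reads are fetched
with full-span padding, and substitution merging runs globally after
chunks are combined. Sorting is contig (header order), position, then
alternate allele — the tie-break is arbitrary but fixed.

## The simulator

`simulate_reads()` emulates a targeted sequencing experiment well enough
to exercise every calling stage with known truth: random contigs with
each variant's reference allele planted at its stated position,
paired-end fragments (default 230–320 bp, reads of 100 bp) drawn
uniformly, constant base quality (default Q30), uniform substitution
error (default $10^{-3}$ per base), and PCR duplication of a fraction of
fragments (default 5%). Each fragment carries the variant haplotype with
probability equal to the target VAF; variant reads receive exact CIGARs
(`M/I/D`), and reads that only partially cover an event are soft-clipped
at its edge, as an aligner tends to do. Everything derives from one seed;
there is no global random state left behind.

Deliberately *not* modelled: platform-specific error spectra and quality
decay along the read, indel sequencing errors, fragment-size biology, GC
bias, mapping ambiguity. Passing tests on this substrate therefore
demonstrate the correctness of the calling logic and its boundary
behaviour, not performance on real libraries — real data adds error
structure this generator does not produce.

Paired-end emission matters for one specific reason: duplicate
signatures. With single-end reads at depth 2000 on a 500 bp contig,
coordinate-only signatures would collapse most distinct molecules and
low-frequency variants would disappear into mixed duplicate groups; the
mate-start component keeps signatures informative at high depth, as in
real paired libraries.

## Problem sizes used by the tests

The suite runs everything at desk scale, chosen to finish in minutes
while leaving no stage untested: unit fixtures use tens of reads;
end-to-end simulations use depth 300–1500 over 500 bp contigs; the
standard-panel recovery exercises all 94 printed variants at depth 2000
(about 10,000 read pairs per contig); exact-test oracles sample tables up
to $N = 200$ and LOD oracles depths up to 100. At the 1% VAF floor a
depth-2000 simulation leaves roughly a 0.2–0.25 percentage-point standard
error on the estimated VAF, so panel variants printed at 1.1–1.5% sit
within two standard errors of the emission floor: an occasional single
miss in the 94-variant recovery is expected behaviour of the study
conditions, not a regression.

## Known limitations

* No local realignment: events at read ends may be soft-clipped by the
  upstream aligner rather than represented, biasing VAF slightly
  downward; the caller does not attempt to recover them.
* Indels longer than a read length cannot be observed by construction;
  the longest events exercised are in the 20–26 bp range.
* No UMI awareness, tumor purity/ploidy adjustment, contamination
  estimation, panel-of-normals, or structural variants.
* Multi-allelic sites are emitted as independent records per alternate
  allele; no joint genotyping.
* The whole contig sequence of each target region is held in memory;
  this suits targeted panels and synthetic contigs, not whole-genome
  references.
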