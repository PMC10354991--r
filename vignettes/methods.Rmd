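---
title: "Methods: integration-site retrieval and clonal quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integration-site retrieval and clonal quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscallr)
```

## The problem

Integrating viral vectors (lentiviral, gammaretroviral) insert semi-randomly
into the host genome. In gene therapy, each transduced cell is marked by its
integration sites (IS), so the set of IS and their relative abundances is a
clonal barcode: tracking it over time detects clonal expansions of clinical
concern. `iscallr` retrieves IS from paired-end linker-mediated PCR
libraries and quantifies each clone's contribution by four readouts, with a
ground-truthed simulator and the statistics needed to validate the whole
chain on synthetic data.

## Read anatomy and oligo parsing

The library design places, on R1,

```
random prefix (12 nt) | sample barcode (8 nt) | LTR (32 nt) | genomic DNA
```

and on R2

```
random prefix (12) | barcode (8) | LC1 (29) | UMI (18) | LC2 (20) | genomic DNA
```

The junction between the LTR's 3' end and the first genomic base on R1 *is*
the integration site. The UMI is two random 6 nt flanks around the fixed
anchor `GTAAGG`; because the anchor is known, any mismatch inside it flags a
sequencing error that may extend into the flanks, and the read is discarded
rather than risk inflating UMI diversity.

Parsing is first-fail and stage-ordered (`too_short`, `unassigned`,
`ltr_fail`, `lc_fail`, `anchor_fail`) so the funnel in
`rejection_funnel()` partitions the input exactly.

Design choices worth stating:

* **Segment identity.** A read passes the LTR/LC gate when at least 90% of
  the segment's bases match (`min_identity` in `oligo_design()`). The
  denominator is always the full segment length, so truncations count
  against identity. A substitution-only check at the expected offset decides
  almost every read; only reads whose fast identity lands in
  `[0.5, 0.9)` — the signature of a possible indel — are re-scored by a
  semi-global `pairwiseAlignment` (segment global, read ends free, +1/−1
  scoring, linear gap cost 2/base). Reads below 0.5 cannot plausibly reach
  0.9 by gapping and are rejected outright; this keeps random background
  reads out of the aligner entirely.
* **Barcodes are matched exactly** by default (the conservative reading of
  a dual-barcode design); `max_mismatch` can relax this per barcode, in
  which case a window must match exactly one sample.
* **Anchor locus.** The anchor is searched as an exact string; across a
  batch the modal hit position is taken as the anchor locus and checked
  against the designed offset (6), which defends against chance anchor
  occurrences in downstream genomic sequence. Indels in the UMI region
  shift the anchor off that locus and the read is rejected wholesale.

## Alignment and junction filters

`builtin_map()` is a deterministic exact-seed mapper for desk-scale
genomes: 31-mer seeds at read offsets 1, 33, 65, ... (so a read whose 5'
end is damaged still seeds downstream, on either strand), ungapped
extension over the full read, at least 75% matching bases to keep a locus.
A unique seed locus gives MAPQ 60; multiple loci give MAPQ 0 with a
deterministic first-locus tie-break. Production data from an external
aligner enters through `ingest_sam()` (primary alignments only; CIGAR
parsed for spans, clips and terminal match runs); the pipeline never
shells out to an aligner itself, which keeps runs reproducible and free of
tool-version coupling.

Post-alignment filters mirror the wet-lab logic:

* **MAPQ/repeat gate** (`mapq_repeat_filter()`): alignments outside
  annotated repeats always pass; repeat-overlapping alignments need
  `mapq >= 12`. The gate is deliberately *not* global — a read mapping
  uniquely outside repeats is trusted regardless of MAPQ — though a global
  mode exists because the narrative convention differs between tools.
  The default of 12 is configurable down to 0.
* **Junction check** (`junction_3nt_check()`): the three query bases at
  the LTR-proximal end of R1 must be reference-consuming (no clip) and
  match the reference perfectly. This is the main defence against
  PCR/sequencing artifacts at the junction; the simulator's mutated reads
  are built to fail it.
* **filter60**: a second, stricter output requiring >= 60 bp of genomic
  match; both filterNo and filter60 tables are always produced.

A surviving pair becomes a junction event: junction position = R1's
LTR-proximal end (1-based in all reports; internally all coordinates are
0-based half-open), strand from R1, fragment length = distance from the
junction to the mate's outer end (the sonication shear site). Mates must
share a chromosome in opposite orientation; this may undercount slightly
relative to pipelines that accept discordant mates, which we accept for
the cleaner contract.

## Site merging and the 7 bp window

Junction positions within 7 bp of each other are one biological event
observed through local fraying and alignment noise. `merge_within_window()`
greedily takes the unmerged position with the highest read abundance
(ties to the lowest coordinate) and absorbs everything within the window;
output peaks are therefore pairwise more than 7 bp apart and the operation
is idempotent. `sweep_window()` reproduces the calibration argument for
the default: on data jittered by a couple of bases around true sites, site
counts fall from window 0 to 3 and are flat from 3 to 7.

## Quantification

Four abundances per site and sample (`quantify()`):

* `reads` — raw read count; inflated by PCR duplication.
* `umi` — distinct UMIs; exact-sequence uniqueness by default, since the
  anchor QC already removes error-prone UMIs. An optional Hamming-1
  directional collapse (absorb a satellite into a neighbour at least twice
  its count) is provided for error-rich data.
* `fragment` — distinct sonication fragment lengths (shear-site
  diversity); lengths never pool across samples.
* `fragment_mle` — the maximum-likelihood correction of shear-site counts
  for length collisions, below.

Relative abundance is per sample and sums to 100%.

### The fragment-length MLE

Distinct fragment lengths undercount progenitors once clones are large:
independent shear events collide on the same length. Model the fragment
count at site $i$ with length $l$ as Poisson with mean
$\theta_i \phi_l$, where $\theta_i$ is the progenitor abundance and
$\phi$ a length distribution shared across sites; only presence
$y_{il} = \mathbb{1}\{\text{count} > 0\}$ is observed, i.e.
$y_{il} \sim \text{Bernoulli}(1 - e^{-\theta_i \phi_l})$.
`estimate_theta_mle()` alternates (i) an exact per-site maximization of
$\theta_i$ by monotone root finding on the score
$\sum_{l: y=1} \phi_l / (e^{\theta \phi_l} - 1) = \sum_{l: y=0} \phi_l$
with (ii) an EM-style update of $\phi$ from the expected counts given
presence, $\mathbb{E}[N \mid N > 0] = \theta\phi/(1 - e^{-\theta\phi})$ —
a hybrid EM. Iteration stops at relative tolerance $10^{-8}$ or 500
sweeps; $\phi$ starts uniform on the pooled observed lengths and
$\theta_i$ at the site's observed diversity $d_i$, a monotone,
reproducible start.

Two exact contracts pin the implementation: with a single site and uniform
$\phi$ over $L$ lengths the estimate equals the closed form
$-L \log(1 - d/L)$, and $\hat\theta \ge d$ always. A site observed at
*every* pooled length has a divergent MLE; it is capped (default $10^6$)
and flagged unconverged rather than silently truncated. With fewer than
two pooled lengths $\phi$ is unidentifiable and the readout falls back to
the raw diversity $d$.

## Collisions, masking, annotation

Samples from independent transduction events (different `group_id`) cannot
truly share a site; shared detections are cross-contamination. After the
global merge (which already unifies positions within the 7 bp window
across groups), `resolve_collisions()` compares each group's normalized
abundance — site abundance over the group's total, under the current
quantification method; normalization by group total is the default, with
a raw-abundance mode available since depth normalization conventions vary.
A group at least 10-fold above every other keeps the site; otherwise the
site is discarded everywhere. The fold default of 10 is deliberately more
conservative than the \(2^{1.5} = 2.83\) implied by the common
differential-expression cutoff \(|\log_2 \text{FC}| \ge 1.5\)
(`collision_fold_reference()`), and is exposed as a parameter.

`vector_mask()` removes sites on vector contigs (internal vector reads,
not junctions) or with peaks inside mask intervals;
`annotate_nearest_gene()` labels each site with the nearest gene
(distance 0 inside; ties to the lexicographically smallest label). The
final wide TSV — one row per site, one abundance column per sample — is
the pipeline's end product.

## The simulator

`simulate_library()` generates the full study conditions from a seed:

* a uniform-composition synthetic genome (default two chromosomes,
  120 kb + 80 kb) standing in for a reference at desk scale, optionally
  with an exact duplicated segment to create genuine multi-mapping;
* truth sites apportioned to chromosomes by length (largest-remainder),
  uniform positions at least 1 kb apart and a full fragment length from
  contig edges, fair-coin strands;
* per pair, a sonication fragment length from Normal(1000, 300) truncated
  to [read length, 3000] — the fragment-size settings of the standard
  MiSeq read simulator — laid from the junction into the genome; R1 reads
  the junction end, R2 the reverse complement of the shear end
  (250 nt reads);
* oligo wrapping with fresh random prefixes, a drawn UMI per template, and
  constant high qualities (base-call errors are not emulated: the noise
  experiments inject *targeted* mutations instead, which is the stress the
  junction filters are designed for);
* optional junction mutations: a seeded `round(fraction * n)` of pairs get
  per-base substitutions in the first 50 genomic bases at a per-read rate
  drawn from 0.4651163–0.9230769 (read as across-read variation), with the
  three junction-proximal bases always altered;
* optional random background pairs with no oligo structure at all;
* optional PCR duplication, each template replicated uniformly up to
  `pcr_max_dup` times, sharing UMI and fragment length;
* UMI pools of chosen size (uniform entropy $\log_2 s$) or tilted
  geometrically to any entropy target within 0.01 bits — the knob accepts
  arbitrary targets rather than pinning any particular published value.

`simulate_preset()` pins the six validation scenarios; the preset
five-site design allocates 3,006 + 4 × 251 pairs (the dominant site is
then 3,006/4,010 = 75.0% of on-target reads) with two minor sites inside
the duplicated segment, and backgrounds default to 100,000 pairs — enough
to demonstrate specificity while keeping a run in minutes on one core; the
full-scale background of a MiSeq run remains a parameter.

What the simulator does *not* emulate — platform error profiles, chimeric
ligation artifacts, mappability structure of a real genome, uneven PCR
efficiency per junction — bounds what green tests mean: they certify the
pipeline's logic (parsing, filtering, geometry, merging, quantification,
collision handling) under controlled noise, not its end-to-end accuracy on
real sequencing runs.

## Evaluation statistics

* `mse()` — mean squared error between observed and expected relative
  abundance, on the percentage scale.
* `pr_roc()` — threshold sweep over call scores with truth matching in the
  same 7 bp window the caller uses; trapezoidal areas. Calls are the
  instances (false calls are the negatives); with no false calls at any
  threshold the ROC is degenerate and AUROC is 1 exactly when recall is
  complete.
* `umi_entropy()` — Shannon entropy in bits, $H = -\sum p \log_2 p$; base
  2 makes the theoretical maximum for the default design
  $\log_2 4^{12} = 24$ bits.
* `bootstrap_uniformity()` — 100 seeded uniform resamples from the unique
  UMI set at the observed total count (times an optional multiplier, for
  data sets where the unique set approaches the total); per-resample
  entropies form the entropy null, mean per-UMI frequencies the reference.
  The two-sample K–S test compares observed counts against the *pooled*
  bootstrap counts: pooling preserves the null sample's multinomial
  spread, whereas testing against the bootstrap mean (spread shrunk by
  $\sqrt{B}$) would reject even when the observed counts are exactly
  uniform-multinomial.
* `procrustes_distance()` — symmetric Procrustes sum of squares between
  two sites-by-samples matrices (centred, unit-scaled, optimally rotated),
  via `vegan::procrustes`; an unscaled variant is a flag since both forms
  are in circulation. `procrustes_null()` draws row subsamples jointly
  from both matrices (default 500) and reports the fraction of null
  distances at or below the observed one.

## Orchestration

`call_sites()` is the in-memory pipeline; `run_pipeline()` is the
file-based one with content-hash checkpoints (input digests plus the
parameters each stage consumes — robust to file copies, unlike
timestamps): an unchanged re-run does no stage work, and editing an input
re-runs only that stage and its descendants. Samples are independent after
demultiplexing, so per-sample stages may be parallelised by a caller;
results are schedule-independent because every operation is deterministic
given its inputs. A thin CLI (`inst/cli/iscallr.R`) exposes `run`,
`simulate`, `evaluate` and `sweep-window`.

## Problem sizes used in the tests

The shipped test-suite runs the clean and mutated single-site libraries at
their full 2,924 pairs, the five-site library with 100,000 background
pairs, mapper-vs-brute-force comparisons on a 100 kb genome, MLE recovery
at 300 pooled lengths across 200 replicate sites, and PCR-duplication
experiments at up to 200-fold duplication over 10-site libraries of ~200
templates. These sizes were chosen so the whole suite completes in a few
minutes on a single core while every rate being tested (survival,
junction-filter loss, background rejection, duplication inflation) is
measured on at least hundreds of reads.

## Known limitations

* The built-in mapper is ungapped and exact-seeded: adequate for synthetic
  genomes and the test scale, not a replacement for BWA on real data —
  which is why SAM ingest is the production path.
* Multi-mapping reads are retained with MAPQ 0 and placed at a
  deterministic first locus; pipelines built on BWA instead scatter them
  across loci. Totals are conserved either way, but per-copy splits inside
  duplicated regions are not comparable between the two.
* Collision identity is site identity after the global merge; sites that
  straddle a window boundary across groups (closer than 7 bp yet merged to
  different peaks) are not re-clustered a second time.
* The UMI entropy knob controls pool entropy, not amplification bias;
  skew introduced by PCR is modelled only through duplication counts.
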