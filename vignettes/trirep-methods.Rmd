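---
title: "Methods: simulation, junction extraction and artifact filtering in trirep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, junction extraction and artifact filtering in trirep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind its pipeline: what the simulator emulates, how junctions
are defined and extracted, what each filter stage assumes, and where the
design was genuinely open.

## The measurement model

The assay being modeled is bulk multiplex RT-PCR amplification of TCRβ
CDR3-spanning amplicons followed by paired-end short-read sequencing,
performed separately on purified leukocyte subpopulations (neutrophils,
monocytes/macrophages, T cells) of the same donors. The analysis unit is
the **clonotype**: a unique CDR3 junction nucleotide sequence with its
V/J context, counted once regardless of read multiplicity. The junction
is delimited by two conserved anchors — the V-segment cysteine of the
`Y[YFLI]C` motif and the J-segment phenylalanine/tryptophan of the
`[FW]GXGT` motif — and **includes both anchor residues**. The competing
convention (anchors excluded) exists; the anchor-inclusive reading was
chosen because the package's uniqueness definition requires a junction
that "contains both translated conserved motifs", and is asserted
throughout (`junction_aa` starts with C and ends with F or W).

Uniqueness defaults to the nucleotide level; an amino-acid collapse is
available (`count_unique(rep, "aa")`, `level = "aa"` in the comparison
functions) because public-clonotype counts are sensitive to this choice.

## The simulator

`simulate_repertoire()` draws `n_clonotypes` distinct productive
rearrangements from the germline library:

* **V/J choice**: uniform over functional segments. The packaged
  synthetic reference has 12 V and 6 J segments (72 potential
  combinations); real repertoire studies report coverage of most of the
  catalogued combination space, and the simulator reproduces that
  saturation behavior at desk scale.
* **End trimming**: uniform on `0..trim_max_v` (default 9 nt) and
  `0..trim_max_j` (default 6 nt). The synthetic V segments carry 12 nt
  of coding sequence 3′ of the anchor codon and the J segments 6 nt 5′
  of theirs, so default trimming never destroys an anchor.
* **Insert (N/D) length**: `gaussian_n_len(mean = 12, sd = 3)` by
  default — the bell-shaped insert profile typical of mononuclear
  cells; `bimodal_n_len()` provides the non-Gaussian alternative needed
  to emulate the neutrophil contrast. Insert bases are uniform random;
  D segments are not modeled as alignable entities (no analysis here
  reports D calls), their contribution is subsumed in the insert.
* **Productivity**: junctions must be in frame (length ≡ 0 mod 3),
  stop-free and anchor-intact; rejection sampling with a bounded
  attempt budget enforces this and junction uniqueness.
* **Clone sizes**: Zipf-like, frequency of rank r ∝ r^−s with
  `abundance_shape = 1` by default. The exponent was fixed a priori at
  the classic Zipf value for clone-size distributions, with the side
  condition that at the package's reference scale (1,000 clonotypes,
  2×10⁵ read pairs) the rarest clone still has ~27× expected coverage —
  i.e. the simulated repertoire is genuinely observable above the
  >1-copy reporting floor, so recovery failures indicate pipeline
  defects rather than undersampling.

`simulate_reads()` samples read pairs proportionally to abundance.
Amplicons are V(1..len−v_trim) + insert + J(j_trim+1..len) + C
(129–168 nt here), read as 2×100 nt mates from the two ends, so every
pair overlaps by ≥32 nt and always covers the junction. Read length and
overlap geometry are configurable, not asserted.

**PCR errors with clonal expansion.** A substitution arising in PCR
cycle c is carried by roughly 2^−c of the final molecules. The model
makes the first `min(8, pcr_cycles)` cycles explicit: per clonotype,
cycle-c events are drawn Poisson(2^(c−1)·L·p) and each final read
inherits each event independently with probability 2^−c. The remaining
cycles are folded into an independent per-read per-base rate
1−(1−p)^(cycles−8). This reproduces the two artifact classes the filter
cascade must face — rare singleton errors and clonally expanded
early-cycle errors that can reach a sizable fraction of a clone's reads
— without simulating the full 2^20-molecule genealogy. Lineage
correlations between events are ignored (independent inheritance), a
deliberate simplification.

**Chimeras.** A fraction `chimera_rate` of reads splice a second parent
template at a breakpoint uniform on amplicon positions 16–70 (the V
region, occasionally reaching a few bases into the junction's V part).
Mid-V breakpoints create the mosaic V signature the chimera filter
detects; junction-proximal breakpoints create hybrid junctions that
present as low-copy novel clonotypes instead. Both routes are flagged in
the truth map.

**Qualities** are constant Q30 symbols; merging uses qualities only for
mismatch resolution, so quality-profile realism is out of scope.
Indel errors are not modeled (the analysis chain is substitution-only).

What the simulator does **not** emulate — and what passing tests
therefore cannot show about real data: primer-specific amplification
bias beyond a global outlier model, indels, quality decay along reads,
allele-level germline variation, cross-sample index hopping, and real
V/J usage skew. Results on simulated data bound the pipeline's
correctness, not the assay's accuracy.

## Read merging

Mates are joined with the overlap (glocal) dialect of global alignment:
end gaps free, internal gaps disallowed, match +1 / mismatch −1. All
overlap offsets are scored; admissibility requires overlap ≥
`min_overlap` (default 30 nt) and mismatch fraction ≤
`max_mismatch_rate` (default 0.1). Ties break toward the longer overlap,
then the smaller offset — deterministic by construction. Within the
overlap, disagreements resolve to the higher-quality base (tie: mate 1)
and agreed bases take the max quality. Unmerged pairs are dropped and
counted, never rescued single-ended. The scoring constants are
configuration, not assertions; the brute-force all-offset scorer in the
test suite is the reference semantics.

Because mate 2 is reverse-complemented inside the merger, the
strand-symmetry property takes the form: merging `(r2, r1)` — the plain
mate swap, which reads the template from the opposite strand — yields
the reverse complement of merging `(r1, r2)`.

## V/J assignment and junction extraction

Assignment uses the package's own seeded gapless local aligner: exact
12-mer seeds hashed over the segment library, extension restricted to
the seeded diagonal, best local block by maximum-subarray. Both strands
are tried and reads canonicalized to V→J orientation. This replaces an
external mapper because "default parameters" of an external tool is not
a reproducible contract; with substitution-only errors the gapless
diagonal model is exact. The identity floor defaults to 0.85 on both the
V and J blocks, and the alignment must cover the anchor codon.

The junction is obtained by projecting the germline anchor offsets
through the diagonal onto the read. Rejection reasons are typed:
`no-V-anchor` / `no-J-anchor` (anchor not covered, or the translated
anchor residue is wrong), `out-of-frame`, `stop-codon`. Coordinates are
0-based half-open internally; only the exported AIRR-style TSV is
1-based where that schema requires.

`decompose_junction()` recovers (v_trim, j_trim, insert length) by
greedy maximal exact matching from both junction ends against the
germline. When the true insert happens to begin with the same base the
trimmed germline would have continued with, greedy matching attributes
it to the germline: recovered trims are lower bounds and the recovered
insert length is biased low by ~0.3 nt per side on random inserts. Ties
between the two greedy matches (very short junctions) are split toward
V — a documented convention, not a biological claim.

`build_repertoire()` keys clonotypes by junction nucleotide sequence;
V/J calls are plurality votes over supporting reads with lexicographic
tie-breaks; frequencies are copies over total and are renormalized to
1 ± 1e−9 after every filter stage.

## The five-checkpoint filter cascade

The five stage names and the >99% artifact-detection goal follow the
published five-filter design; the stage internals were never published,
so every algorithm here is an explicit stand-in — this is the largest
single invention in the package and each choice is documented:

1. **Sequencing-error filter** — a clonotype within Hamming distance 1
   (configurable) of a same-V/J, same-length clonotype with ≥10× its
   copies is *absorbed* (copies added), not deleted, conserving read
   mass as standard denoising practice does. Children are processed in
   ascending copy order; absorption chains resolve to terminal parents.
2. **Mosaic filter** — a read is a two-parent mosaic when the 5′ and 3′
   halves of its V region (everything 5′ of the projected anchor)
   best-align to *different* V segments, each half scoring ≥ 5. A
   clonotype is removed when a majority of its supporting reads are
   mosaics; genuine clonotypes with a few chimeric supporters survive.
3. **Amplification-performance filter** — V segments whose read share
   exceeds median + 5·MAD (scaled MAD, `stats::mad` default) are
   *down-weighted* to the median-share expectation rather than removed:
   uneven amplification distorts quantity, not identity. With fewer
   than 3 distinct V segments the stage is a logged no-op.
4. **Reference filter** — reads whose V or J germline-overlap identity
   *outside the junction* falls below 0.9 are discarded. The identity
   is computed over the full diagonal overlap, not the trimmed local
   block, so error-dense flanks cannot hide from it.
5. **Frequency threshold** — clonotypes with copies ≤ 1 are discarded:
   the singleton floor applied after absorption (stage 1 credits error
   reads back to their parents before the floor is applied; applying it
   to raw copies instead would over-delete).

Stage order is fixed; the report chains per-stage accounting
(input = removed + retained at every stage). The absorbing and
threshold stages are idempotent on the cascade's own output.

At the reference scale (1,000 clonotypes, 2×10⁵ pairs, default noise)
the cascade removes ≥99% of error-derived unique junctions while
keeping true-clonotype recall at 1.0; the survivors are almost entirely
early-cycle PCR errors that expanded to within 10× of their parent —
exactly the artifact class a copy-ratio rule cannot distinguish from a
genuine low-abundance variant.

## Statistics

* **Gaussianity score**: 1 − sup|F_obs − Φ| between the
  frequency-weighted empirical CDF of a length distribution and a
  normal CDF with matched mean/variance. For lattice-valued data the
  normal CDF is evaluated at support midpoints (continuity correction);
  without it, discreteness alone would cap the score near 0.85 for a
  perfectly discretized normal. A single-valued distribution scores 0
  by definition. The score is continuous; no hypothesis test or p-value
  is attached, since none is asserted anywhere in the analysis.
* **Mean ± SD**: the population convention (n divisor) is the
  replication default — it is the convention consistent with the
  per-donor diversity summaries this package mirrors — with the sample
  convention available by flag.
* **Sharing**: presence/absence on junction identity; percentages are
  per-side (each repertoire's own size as denominator). Frequencies are
  deliberately ignored in sharing counts.

## The diversity tree plot

Spot area ∝ clonotype frequency with one global constant
(`area_budget`, default 0.3 of the canvas); x extent partitions by V
usage mass, y within each column by J-given-V mass, so cell area equals
cell mass. Within-cell packing is concentric rings in descending
frequency order — deterministic and simple; no packing convention is
claimed beyond that. Spots are clamped inside their cell; a spot larger
than its cell is centered and flagged `overflow`, and spots below the
`min_radius` floor (default 0.2 px) are flagged `floored` — both at the
documented cost of strict proportionality for those spots. Colors are
unique per clonotype via an injective 24-bit hash of a seeded
permutation. SVG output is plain text with fixed formatting: identical
layouts give byte-identical files.

## Problem sizes and determinism

The test suite runs the full chain at 150–1,000 clonotypes and
2×10³–2×10⁵ read pairs, sizes chosen so the whole suite completes in a
few minutes while still exercising every artifact class; the acceptance
script uses the 1,000 × 2×10⁵ reference scale. Every stochastic
operation takes an explicit seed and runs on a private RNG stream
(caller state restored), so identical seeds give bit-identical
repertoires, reads, tables and SVGs.

## Known limitations

* Substitution-only throughout: indel sequencing errors and
  indel-tolerant alignment are out of scope.
* No UMI support (the modeled assay has none); absorption thresholds,
  not molecular identifiers, separate errors from variants.
* Allele-level (\*01/\*02) nomenclature, D-gene assignment and
  CDR1/CDR2 annotation are out of scope.
* The amplification filter's median/MAD rule assumes roughly uniform
  expected V usage; strongly skewed true usage would be partially
  down-weighted (quantities, never identities).
* Expanded early-PCR artifacts within the copy-ratio of their parent
  are not removable by any stage here and persist as a small
  false-positive residue (<1% of error-derived junctions at the
  reference scale).
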