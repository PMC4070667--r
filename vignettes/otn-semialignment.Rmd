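---
title: "OTN semi-alignment: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OTN semi-alignment: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otnsa)
```

## The problem and the idea

Deep 16S rRNA amplicon surveys are dominated by organisms with no close,
well-curated reference. Multiple sequence alignment of such reads is slow
and, worse, silently error-prone: a misaligned uncharacterized phylotype
looks exactly like a well-aligned one. The semi-alignment implemented here
sidesteps base-by-base alignment. Every read is reduced to the set of
trinucleotides it contains *and where it contains them*: a trinucleotide
observed in the same positional region of two reads is treated as one
shared character, an **orthologous trinucleotide (OTN)**. Relatedness
then becomes a question about shared binary characters rather than about an
alignment.

The pipeline is:

1. **Read preparation** — quality trimming, ambiguity and length filters,
   exact primer matching and orientation, depth normalization
   (`preprocess_reads()`).
2. **OTN fitting** — pooled positional trinucleotide histograms, peak
   detection, binning, binary tabulation, multiplicity discharge
   (`otn_semialign()`).
3. **Phylogenetics** — pairwise generation distances from exponential decay
   of shared OTNs, neighbor joining, column bootstrap
   (`generation_dist()`, `nj_tree()`, `bootstrap_support()`).
4. **Ecology** — Shannon–Wiener and inverse Simpson diversity, exact
   Mann–Whitney group tests, chord-distance beta diversity, centered PCA
   (`diversity_report()`, `chord_distance()`, `pca_ordination()`).

## The positional model

For the pooled, depth-normalized read set we count each of the 64
trinucleotides at every 0-based start offset of the primer-stripped insert
(`build_histogram()`). Offsets are 0-based throughout the package: the
trinucleotide starting at the first base of the insert is at offset 0. The
histogram denominator at offset `p` is the *coverage* — the number of reads
long enough to contribute an unambiguous window at `p` — not the total read
count. Using coverage avoids an artificial decay of relative frequencies
beyond the length of the shorter reads; windows containing an `N` are
excluded from both numerator and denominator, which makes the conservation
identity `colSums(counts) == coverage` exact and lets the test suite assert
it on every build.

Homologous trinucleotides do not sit at identical offsets in different
organisms — indels shift them — but at V3–V4 scale the shifts are local, so
each trinucleotide's occurrences pile up into peaks. Peaks are detected per
trinucleotide by an alternating maxima/minima scan (`peakdet()`): a
candidate maximum is accepted once the series has dropped by at least a
prominence `delta` below the running maximum, symmetrically for minima.
Two conventions deserve note:

* the drop condition is `>= delta` (a drop of exactly `delta` emits the
  peak), and equal-height candidates keep the earliest position;
* `delta` defaults to 0.1 **relative to the row maximum** of each
  trinucleotide's frequency series. No absolute value is defensible across
  datasets of different depth; the relative form keeps the criterion
  scale-free. An absolute mode (`delta_mode = "absolute"`) is available.
  Peaks with relative frequency below `min_peak_freq` (default 0.01) are
  discarded as noise.

Each trinucleotide's coordinate axis is then partitioned into half-open
bins `[start, end)` with boundaries at the midpoints between consecutive
peaks (outer bins bounded by 0 and the coordinate length). A fractional
midpoint is rounded up, which places the equidistant integer offset in the
left bin; an integer midpoint is itself the boundary, i.e. belongs to the
right bin. A valley-based alternative (`boundary = "valley"`), using the
deepest detected minimum between two peaks, is available; midpoints are the
default because they are defined even when no minimum was emitted between
two peaks.

An (trinucleotide, bin) pair is an OTN. A read marks an OTN present if it
has at least one occurrence of that trinucleotide inside that bin. If *any*
read carries two or more occurrences inside one bin, that OTN is removed
globally (the **multiplicity discharge rule**). The rationale is the
dominant error mode of pyrosequencing chemistry: homopolymer tracts cause
±1 indels at high rate, and a repeated trinucleotide inside one bin is the
signature of such a tract. Discharging the column for all reads costs a
little signal and removes a systematic distance bias. An alternative
reading — discharging only the offending read's cell — would keep more
signal but leave the error-prone column in place for every other read; the
global reading is implemented.

Reads with identical OTN bit-vectors collapse into one pattern
(`collapse_patterns()`); patterns act as OTUs at 100% identity. Patterns
observed exactly once across all samples are, by default, excluded from
ecological analyses as likely sequencing errors or chimeras; the singleton
fraction and a heuristic per-position accuracy estimate
`(1 - singleton_reads/total_reads)^(1/L)` (with `L` the pattern length) are
reported alongside.

## The generation distance

The evolutionary model assumes each OTN character mutates independently at
a constant probability `rate` per generation, so the expected shared
fraction decays exponentially and

```
gen = (ln(shared) - ln(total)) / ln(1 - rate)
```

with `shared = 2|A ∩ B|` and `total = |A| + |B|`. Counting the
intersection once per profile makes the distance vanish on identical
profiles, which any distance must; the literal single count
(`shared_convention = "literal"`), under which identity sits at
`ln 2 / |ln(1 - rate)|`, is kept behind a flag for comparability. The
default `rate = 0.5e-9` per generation is a neutral-rate estimate for the
16S gene quoted per position; because a trinucleotide spans three
positions, `rate_mode = "per_position_x3"` (effective `1.5e-9`) is
selectable, and all generation estimates simply rescale by the fixed factor
`ln(1-r)/ln(1-3r) ≈ 1/3` between the two readings. Natural logarithms are
used throughout (the ratio is base-invariant), and `log1p(-rate)` rather
than `log(1 - rate)` keeps full double precision at rates of order `1e-9`;
the test suite checks agreement with a 50-digit arbitrary-precision oracle
to a relative error below `1e-10`.

Pairs sharing no OTN have undefined (infinite) distance. The default is a
hard error listing the pairs; `on_undefined = "cap"` substitutes 1.1 times
the largest finite distance for exploratory trees.

Trees are built by standard Saitou–Nei neighbor joining, delegated to
`ape::nj()`; negative branch lengths, an artifact of non-additive noise,
are clamped to zero with a message. Bootstrap support resamples **OTN
columns** with replacement — the OTN matrix is the character matrix here,
so its columns are the natural resampling unit (resampling sequence
positions would re-run peak detection per replicate and conflate binning
variability with character support). Replicates in which some pair loses
all shared OTNs are dropped; more than 20% dropped replicates aborts with
an error. Support is the percentage of kept replicates containing each
internal bipartition of the full-data tree.

## Ecology choices

Two index conventions are inferred from the magnitudes such indices take on
diverse amplicon libraries and are flagged in the output rather than left
implicit: Shannon–Wiener `H` is reported in **nats** (values near 5.5 for
thousands of OTUs are consistent with the natural log, not log2 or log10),
and Simpson's `D` is the **inverse** form `1/Σp²` (an effective OTU count;
the 0–1 complement form cannot exceed 1 and could not reach values of
70–150). The Mann–Whitney U test is exact by full enumeration of all
`C(nA+nB, nA)` labelings with midrank ties — for triplicate groups the
smallest attainable one-sided p is exactly `1/20 = 0.05`, so a reported
0.05 means complete separation, not approximation. Beta diversity uses the
chord distance (Euclidean distance of unit-normalized abundance vectors,
range 0–√2) on singleton-filtered pattern counts. PCA uses column-mean
centering and SVD; the number of components retained is the smallest `k`
covering 50% of the variance, and component signs are fixed by making the
largest-magnitude loading of each component positive so repeated runs
cannot flip ordinations.

## Read preparation choices

The quality trimmer is a modified-Mott algorithm: with per-base error
probabilities `p_i` (from Phred scores, `p = 10^(-Q/10)`), the kept
subsequence is the contiguous segment maximizing `Σ(limit − p_i)` with
`limit = 0.05`; the read becomes empty when every segment scores
non-positive, and among equal scores the leftmost segment is kept.
Proprietary trimmers advertising the same threshold are not bit-level
specifiable; the Mott formulation has the same threshold semantics and is
fully testable against an exhaustive segment search. Trimming precedes the
ambiguity filter (at most 2 `N`s) and the length filter (at least 300 nt);
primer matching follows. The length cutoff applies to the read *before*
primer removal by default, since the filter is stated in terms of raw
sequence reads; `length_filter = "post_primer"` applies it to the insert
instead — both are exposed because the choice shifts the boundary by the
45 nt of primer sequence.

Primer matching is exact (0 mismatches) in both orientations, with the
forward primer anchored within the first 5 bases and the reverse
complement of the reverse primer within the last 5, tolerating small key or
adapter remnants; matching in both orientations (possible only for
degenerate, near-palindromic constructs) is rejected with a distinct code.
Depth normalization samples uniformly without replacement to the smallest
sample's size (or a given depth), under a single seeded generator, default
seed 1.

## What the simulator emulates — and what it does not

`simulate_taxa()` evolves a random ancestral insert (default 460 nt,
V3–V4-like) along a tree with edge lengths in generations: over an edge of
`g` generations each position substitutes with probability
`1 − (1 − r)^g` to a uniformly chosen different base. Evolution is
substitution-only, so the positional ground truth stays exact;
insertion/deletion errors are modeled separately at the sequencing stage,
where `emit_reads()` injects ±1-base indels into homopolymer tracts (runs
of ≥3) at a configurable per-tract, per-read rate and assigns a linear
error-probability profile rising along the read. Default edge lengths are
drawn uniformly from 2.5×10⁸–10⁹ generations, giving pairwise separations
of order 10⁹ — deep enough that a 460-nt insert accumulates tens of percent
sequence divergence, the regime the method is meant for.

The simulator deliberately omits: chimera formation, flowgram-level 454
noise (indels appear directly as ±1 events, not via flow values), rate
heterogeneity along the molecule, inherited (evolutionary) indels, and
compositional biases of real communities. Passing round-trip tests
therefore demonstrates the internal consistency of the pipeline —
filtering, binning, discharge, distance, and tree stages compose correctly
and invert the generative model they assume — not that real soil data meet
those assumptions. In particular, inherited indels in real data cause
long-range coordinate shifts that positional binning does not correct;
that correction (e.g. anchoring on conserved regions) is outside the scope
of this package.

## Validation design and problem sizes

The test suite pairs every nontrivial operation with an independent oracle:
an exhaustive `O(n²)` segment search for the trimmer, a range-rescan
formulation of the extremum scan for `peakdet` (1,000 random series), a
naive double-loop recount for histograms, a sort-and-group oracle for
pattern collapse, 50-digit arbitrary-precision evaluation for the distance
formula, generating-tree path lengths for neighbor joining (100 random
additive matrices, 4–12 taxa), and binomial closed forms for the simulator.
Parameter recovery uses 200 simulated profile pairs of 10,000 OTN columns
at separations of 10⁷–10⁹ generations, requiring the estimate within 3
binomial standard errors in at least 95% of replicates. Pipeline round
trips use 6 error-free taxa on a fixed two-clade tree (8 reads per taxon,
460-nt inserts), chosen small enough that the whole validation suite runs
in well under a minute while still exercising every stage at realistic
divergence.

## Known limitations

* The peak-detection prominence has no published reference value; peak
  *counts* are therefore not comparable across tools or datasets without
  fixing `delta`, and the default 0.1 (relative) is a package choice.
* Distances between profiles with very few shared OTNs are numerically
  unstable (the log of a small ratio of small counts); the undefined-pair
  machinery flags the extreme case, but users should treat distances from
  a handful of shared characters with suspicion.
* Column bootstrap measures character support conditional on the binning,
  not uncertainty in the binning itself.
* All positional reasoning assumes reads share a common 5' origin (the
  forward primer); the pipeline requires exact primer matches for exactly
  this reason, and data without recoverable primers cannot be analyzed.
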