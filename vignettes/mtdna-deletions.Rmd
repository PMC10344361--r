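---
title: "Detecting and quantifying mtDNA large deletions from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying mtDNA large deletions from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolong)
```

## The problem

The human mitochondrial genome is a 16,569 bp circle present in hundreds to
thousands of copies per cell. In several mitochondrial myopathies
(Kearns-Sayre syndrome, Pearson syndrome, chronic progressive external
ophthalmoplegia) a subset of those copies carries one multi-kilobase
deletion; in disorders of the nuclear mtDNA-maintenance machinery, many
distinct deletions coexist in one tissue. Two quantities matter clinically:
*where* the deletion breakpoints are, and *what fraction* of molecules carry
the deletion (the heteroplasmy).

Nanopore-style long reads can span an entire deletion junction in one
molecule, which removes the two classic failure modes of short-read assays:
junction-spanning evidence is direct rather than inferred, and PCR-free
library preparation avoids amplification bias in the heteroplasmy estimate.
mitolong implements, at desk scale, the complete analysis around this idea:
a read simulator that emulates the two library chemistries, a
circular-aware split-read aligner, breakpoint clustering into deletion
calls, two heteroplasmy estimators, pileup point-variant calling with exact
binomial intervals, and circular summary plots.

## Library chemistries and why linearization matters

A circular molecule cannot be adapter-ligated, so ligation-chemistry
sequencing requires linearization with a restriction endonuclease that cuts
the circle once — BamHI (recognition `GGATCC`, one rCRS site, reported
cleavage near m.14262) or PvuII (`CAGCTG`, near m.2652). The choice is not
neutral: **if the cut site falls inside the deleted interval, deleted
molecules are never cut, are inefficiently sequenced, and the deletion's
heteroplasmy is underestimated** — sometimes drastically. Transposase
(rapid-chemistry) tagmentation fragments the circle at random positions and
has no such blind spot, at the cost of shorter fragments and lower yield.

`simulate_run()` reproduces both mechanisms:

* **endonuclease mode** cuts the realized (post-deletion) molecule at every
  recognition site; a molecule with *no* site yields a fragment only with
  probability `p_uncut`. That uncut circles are nearly invisible to
  adapter ligation is a qualitative observation; the value `p_uncut = 0.1`
  is this package's own choice, picked once to give a strong but not total
  underestimation, and it is an exposed knob, not a measured constant.
  Fragments then suffer random nicks at `breakage_rate` per base
  (default `1e-4`, which gives mean mtDNA read lengths near the ~6.2 kb
  observed with the ligation kit).
* **transposase mode** opens the circle at a uniform phase and partitions
  it into log-normal fragments (`frag_mean = 4403` bp, the average mtDNA
  read length observed with the rapid kit; `frag_sdlog = 0.55` chosen to
  give the broad, right-skewed length spread typical of tagmentation).
  Every base belongs to exactly one fragment, so base composition is
  conserved by construction.

The error model is per-base independent: 2% substitutions, 1.5% insertions,
2.5% deletions (≈6% total, indel-dominated, at the upper end of the 4–6%
usually quoted for R9.4.1 pores), with the deletion rate doubled inside
homopolymer runs of ≥4 bases to mimic nanopore homopolymer shortening.
Reads carry a constant Q12 quality; quality-aware analysis is out of scope.

What the simulator does **not** emulate: raw-signal/squiggle behavior,
realistic per-read quality variation, adapter sequence, chimeras, and real
nuclear background (the `nuclear_fraction` reads are i.i.d.-uniform random
sequence, sufficient for testing mapped/unmapped classification but not for
NUMT-style confusion). Passing tests therefore demonstrate correctness of
the algorithms under a faithful abstraction of the chemistry, not
performance on real flow-cell data.

## Circular-aware split-read alignment

The aligner is a purpose-built replacement for the generic long-read
mapping stage, specialized to a single small circular reference:

1. **Anchoring.** Exact k-mer matches (k = 15 by default) against the
   reference concatenated with itself, so alignments may cross the origin;
   k-mers occurring more than `max_occ = 20` times are masked. Each anchor
   is also duplicated one circle later, letting one chaining pass handle
   any combination of origin crossing and deletion junctions.
2. **Chaining.** A dynamic programme over anchors sorted by read position.
   A reference gap of `g` bases between consecutive anchors costs
   `gap_scale * log2(1 + g)`: co-linearity is enforced, but a 7 kb deletion
   costs only ~13 points against hundreds of matched bases, so
   junction-spanning reads chain straight through their deletion.
3. **Breakpoint refinement.** For every chain gap, the unanchored read
   sequence around the junction is aligned by full edit-distance DP against
   both candidate flanks (±`window = 200` bases); the split minimizing
   total edit distance wins, and ties — which occur whenever the junction
   sits in a direct repeat, as mtDNA deletions often do — resolve to the
   *leftmost* reference placement. The flanking anchors are backed off by
   2k bases first, so placements inside repeats up to ~30 bp can slide to
   their leftmost equivalent.
4. **End extension.** Read ends beyond the outermost anchors are extended
   by banded local alignment scored +1 match / −2 mismatch / −2 gap.
   This scoring sits in the logarithmic phase for DNA, so extension through
   sequence that genuinely diverges (e.g. past an undetected junction, or a
   random nuclear read end) drifts negative and is soft-clipped rather than
   force-aligned — a property the coverage-based heteroplasmy estimator
   depends on.

Default parameter values (`k = 15`, `max_occ = 20`, `min_cov_frac = 0.4`,
`window = 200`, `min_gap = 30`) are this package's own choices for a
~16.6 kb reference and ~5% error reads; all are exposed via
`align_params()`. The aligner reports one best-scoring orientation per
read; chimeric multi-strand reads are out of scope.

## From gaps to deletion calls

Every intra-read reference gap of at least `min_del_size = 100` bases
becomes a deletion signal (smaller gaps are indistinguishable from nanopore
indel noise at a 6% error rate). Signals are clustered by single linkage —
two signals link when both breakpoints agree within `tol = 50` bases,
circularly — and each cluster's consensus breakpoints are the per-cluster
leftmost medians. Clusters with fewer than `min_support = 2` reads are
discarded, the same minimum-support setting used for split-read SV calling
in this application. Calls wrapping the origin are reported with
`start > end` and circular size, and split into two ID-linked records on
VCF export, since linear VCF cannot express a circular deletion.

Two clustering caveats are worth recording. Widening `tol` can only merge
clusters, so the number of *clusters* is monotonically non-increasing in
`tol`; the number of *calls* after the support filter is monotone in
`min_support` but can in principle rise when two sub-threshold clusters
merge past the threshold. And the single-linkage geometry here is a
reasoned choice — the upstream tooling this stage stands in for does not
document its merge rule.

## Heteroplasmy estimation

**Coverage ratio.** For a single deletion, the fraction of molecules
missing the interval is `h = 1 − mean(depth inside) / mean(depth
outside)`. The inside mean is trimmed by `margin = 100` bases at both
breakpoints (breakpoint scatter); the outside mean excludes the same
margins, ±300 bases around any linearization cut site (reads *start* at
the cut, producing a depth spike), and any user-supplied regions. The
margin scheme is a design decision of this package — the source analysis
reports the ratio but not its masking rules.

**Junction reads.** `h = J / (J + W)`, where `J` counts reads whose
reference gap matches the call (within `tol`, with ≥`min_flank = 100`
aligned bases on both sides) and `W` is the per-breakpoint average count of
reads aligned contiguously across a breakpoint with the same flank
requirement. The average matters: a deleted molecule exposes one junction
while an intact molecule exposes two breakpoints, so summing the two
breakpoint counts would halve the estimate. When `J + W = 0` the estimate
is undefined and reported `NA`, never 0.

For multi-deletion samples only the junction-read estimator is reported per
call, because overlapping deletions confound the coverage ratio; this is a
documented limitation, not an attempt to reproduce a published multidel
quantification (none exists).

`downsample_alignments()` implements the robustness check that ~100x
coverage suffices: uniform random read subsampling without replacement
until the mean depth first reaches the target, seed-deterministic.

## Point variants and the error floor

`pileup_counts()` replays every segment's banded alignment with traceback
and counts matched/substituted bases per reference position; read indels
and junction gaps contribute nothing, so base counts always sum to depth.
Site heteroplasmy intervals are exact Clopper–Pearson: the published
analysis says only "asymmetric 95% confidence interval", and the exact
interval is the natural reading — it has guaranteed coverage and a closed
form at the boundary (`upper = 1 − (α/2)^(1/n)` at zero alternate reads,
i.e. 3.6% at 100x), which is what makes the error *floor* interpretable.
Variant calling thresholds on the point estimate only (`min_h = 0.05`,
matching the ~5% practical detection limit of this error rate); the CI is
attached but never drops a call. Strand bias and base quality are ignored —
the simulator emits constant quality — which is a documented gap relative
to production mtDNA variant servers.

## The decision workflow

`recommend_next_step()` encodes the protocol-selection logic after a run:
no calls → done (negative); one call whose interval excludes the cut
site → done (single deletion); one call *containing* the cut site under
endonuclease chemistry → re-digest with PvuII and re-sequence; two or more
calls under endonuclease chemistry → switch to the transposase (rapid)
kit. Transposase runs always terminate. The rule trace is attached to the
returned status.

## Numerical and degenerate-input choices

* Coordinates are 1-based throughout; a deletion `(start, end)` removes
  `start..end−1`, so `size = end − start` circularly — the only convention
  consistent with the worked examples' printed sizes. One published preset
  row (11,570–15,573, size "6,997") is arithmetically inconsistent and is
  excluded from `deletion_presets()` rather than silently corrected.
* Restriction search is top-strand only (both supported enzymes are
  palindromic); `N` never matches; cut coordinates are
  `recognition start + cut_offset`.
* Banded DPs size their bands as `max(24, 2·sqrt(len))` — indel imbalance
  along an optimal path grows like a random walk — with an automatic 4×
  wider retry when a band is blown.
* Ties everywhere (chain selection, breakpoint placement, medians) resolve
  leftmost, so repeat-flanked deletions are reported reproducibly.
* Empty inputs return empty, correctly-typed tibbles; zero outside-depth,
  empty trimmed intervals, and zero denominators are errors, not NAs.

## Problem sizes used in the checks

The automated checks run the full pipeline at 300x (error-free breakpoint
recovery, four presets), 500x (heteroplasmy recovery and downsampling to
~100x, default error model), 40x × 20 replicates (linearization-bias
property), and 150x (control-run false-positive ceiling for point
variants). These sizes were chosen as the smallest at which the respective
claims are statistically crisp; all estimators are exercised well above and
below the ~100x sufficiency threshold the workflow relies on.

## Known limitations

* The aligner is specialized: single circular contig, one orientation per
  read, no supplementary alignments, no base-quality scoring.
* `p_uncut` is a free parameter; only the *direction* and approximate
  strength of the linearization bias is reproducible, not its magnitude on
  real samples.
* The nuclear background is random sequence; NUMT-mediated mis-mapping
  cannot be studied with it.
* Heteroplasmy from the coverage ratio assumes exactly one deletion;
  junction-read estimates for nested or overlapping events are reported
  per call without cross-call deconvolution.
* The rCRS itself is not bundled; reference-fact checks (length 16,569,
  longest homopolymer 8 bp poly-A at 12,418–12,425) run against a local
  copy of NC_012920 when one is provided.
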