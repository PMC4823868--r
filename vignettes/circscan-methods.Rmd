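---
title: "Detecting and characterizing circular RNAs with circscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing circular RNAs with circscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circscan)
```

## The problem

Back-splicing joins a downstream splice donor to an upstream splice
acceptor of the same pre-mRNA, producing a covalently closed circular
RNA (circRNA). In ribosomal-depleted RNA-seq, a circRNA is visible only
through reads that cross its back-splice junction: the 3' part of such a
read maps *upstream* of its 5' part (head-to-tail), so the read fails
ordinary contiguous alignment. circscan implements the full desk-side
workflow around this signal — junction discovery, abundance and
circular-ratio quantification, tissue-specificity and
condition-specificity statistics, host-gene annotation, and
inverted-repeat analysis of flanking introns — together with a
synthetic-data generator that provides exact ground truth for every
stage.

## Junction discovery

Reads are first placed contiguously with an exact 20-mer seed (first
k-mer, last k-mer as fallback, both strands) and full-length gapless
verification allowing at most `max_mismatch = 2` substitutions. Reads
that cannot be placed are reduced to their two terminal 20-nt anchors.
Every same-chromosome pair of anchor hits within `max_span` ($10^6$ nt)
is then extended: each split position $s \in [20, L-20]$ of the read is
tested for a two-part alignment (prefix at the left anchor, suffix
ending at the right anchor) with at most 2 mismatches in total, and a
split is accepted only when the implied breakpoints carry canonical
splice dinucleotides — `GT` immediately after the donor boundary and
`AG` immediately before the acceptor boundary on the forward strand, or
`CT`/`AC` for a minus-strand junction. Junction orientation decides the
type: placements in genomic order give a linear splice, head-to-tail
placements give a back-splice.

Three conventions make the caller deterministic and well-defined:

* **Junction strand comes from the splice motif**, not from the read's
  orientation: the library contains both orientations of each fragment,
  so the read (or its reverse complement) is aligned forward and the
  motif (`GT..AG` vs `CT..AC`) names the strand. For one hit pair all
  splits share the same donor/acceptor offset, so junction type is a
  property of the pair.
* **Coordinates are geometric.** `acceptor_start`/`donor_end` are the
  forward-strand left/right boundaries; a back-splice spans
  `[acceptor_start, donor_end)`. For minus-strand junctions the
  biological donor and acceptor roles are mirrored, and likewise the
  5'/3' labels of the circular ratios below refer to the genomic
  left/right boundary.
* **Total tie-break order**: fewest mismatches, then linear over
  back-splice (conservative toward the null), then the split nearest
  the read midpoint, then smallest coordinate. Anchors with more than
  `max_anchor_hits = 10` occurrences are treated as repeat-derived and
  their reads skipped.

Support is aggregated per junction in two ways: `n_reads`, the count of
spanning reads (the quantity the quantification formulas use), and
`n_unique`, the number of *distinct read sequences*, which collapses
PCR duplicates. Back-splice junctions require `n_unique >= 2`; linear
junctions are all reported. The paper's pipeline gives no mismatch
budget, span bound or anchor-uniqueness rule, so these are exposed as
`junction_params()` with the defaults above.

## Quantification

With $c$ reads spanning a back-splice junction, a sample with $N$
mapped reads (contiguous + linear-spliced + back-spliced) and read
length $R$ (default 100 nt):

$$\mathrm{SRPBM} = \frac{c}{N/10^9 \cdot R}$$

normalizes support to *spliced reads per billion mapped*, comparable
across sequencing depths. At each circle boundary the circular ratio

$$\mathrm{CR} = \frac{c}{c + l}$$

compares back-spliced against linearly spliced reads $l$ at that
boundary: `cr5` matches linear junctions sharing the circle's acceptor
boundary, `cr3` those sharing its donor boundary; a boundary with no
linear mate has CR = 1. The high-abundance screen keeps records with
`cr5 > 0.2`, `cr3 > 0.2` and `SRPBM > 1` (strict inequalities); a
`"max"` mode instead thresholds the larger of the two ratios, the
variant used when a single representative CR per circle is wanted. A
missing CR fails the default screen because the screen demands positive
evidence at both boundaries. Per host gene with at least two circles,
the top circle by SRPBM is the *predominant isoform* when it is at
least twofold above the runner-up; single-circle genes are excluded
from the denominator.

## Specificity statistics

Cross-tissue profiles are built from tissue means of SRPBM (replicates
averaged first), normalized to probabilities without any log transform
(the Jensen-Shannon machinery needs a simplex vector, and scores are
scale-free in the profile). The specificity of circRNA $i$ for tissue
$t$ is

$$S_{i,t} = 1 - \sqrt{\mathrm{JSD}(p_i, e_t)}$$

where $e_t$ is the perfectly specific unit profile, the square root of
the Jensen-Shannon divergence is the Jensen-Shannon distance, and the divergence
uses base-2 logarithms so that disjoint supports give exactly 1 — this
makes the score range $[0, 1]$ literally attainable at both ends, the
property the acceptance checks assert analytically. Tissue-specific
circRNAs are those with best score at least 0.5 **and** maximum tissue
mean at least the grand mean plus twice the standard deviation of all
circRNA-by-tissue means; the population over which that floor is taken
is not fully pinned down by the source description, and the plainest
reading (all circRNA-by-tissue mean values) is used.

For cancer/normal pairs, a read-count floor for condition-specific
calls is derived from a Poisson fit: with rate $\hat\lambda$ equal to
the mean per-circRNA read count, the cutoff is the smallest integer $c$
with $P(X < c) \ge 0.99$ (at $\hat\lambda = 0.8$ this yields 4 reads; at
$\hat\lambda = 1.0$, 5). "Leaves 99% left over" is read as fitted
Poisson mass below the cutoff, not as an empirical retention fraction.
A circRNA is condition-specific when it reaches the cutoff in one
condition and has *zero* reads in the other; the zero on the negative
side is the package's choice, as only the positive side of the rule is
stated. Differential abundance between matched samples uses the
rank-sum test on shared detected circRNAs (SRPBM > 1 in either member)
and reports the median $\log_2$ fold-change with an
$\varepsilon = 0.01$ SRPBM pseudo-value so zeros stay finite.

The rank-sum (Mann-Whitney) test is enumerated exactly for
$n_x + n_y \le 12$ — midranks handle ties, and the two-sided p-value is
the null probability of a rank sum at least as far from its mean as
observed — and otherwise uses the normal approximation with tie and
continuity corrections. The paper applies "Wilcoxon rank-sum" to
matched cancer/normal profiles; a signed-rank reading is possible, but
the stated test is rank-sum and that is what is implemented.

## Annotation and flanking introns

A circle's host is found by exact boundary matching: among same-strand
transcripts with an exon start equal to the circle start and a same-or
-later exon end equal to the circle end, the transcript whose matched
exon run has the longest spliced length wins (ties to the smallest
transcript id). Exactness is deliberate — the caller emits GT/AG
-resolved coordinates and the synthetic annotation is consistent, so a
±1 slack would only mask caller bugs. Genomic origin is classified with
the priority order coding-exonic → lncRNA → intronic (contained in a
same-strand intron) → antisense (opposite-strand overlap only) →
unannotated, a partition by construction.

The two flanking introns of a circle (transcript orientation) are
scored for reverse-complementary repeats — the IRAlus-style pairing
that promotes circularization — by Smith-Waterman local alignment of
the upstream intron against the reverse complement of the downstream
intron, with match +1, mismatch −1 and −2 per gap column (linear
gaps); identity is matched columns over all alignment columns including
gaps. The source reports identity over an alignment length without
naming a tool or scheme, so these conventional parameters are fixed and
documented. Flanking-intron length contrasts between circle sets use
the rank-sum test on the per-circle maximum of the two sides.

## The synthetic-data generator

`sim_config()` defaults define the reference scene: five 1-Mb
chromosomes; 200 genes with 3–8 exons of 150–400 nt and introns of
200–1500 nt, each intron carrying `GT..AG` on its gene's strand; 20% of
genes designate one internal exon (forced ≥ read length) as
circularized with circular fraction $f$ drawn from $[0.2, 0.9]$;
log-normal per-gene expression (σ = 1); 200,000 error-free 100-nt
single-end reads. These choices emulate the structure of a ribominus
RNA-seq experiment at desk scale — one transcript per gene, a
substitution-only error model (off by default; the extension logic is
mismatch-based and indels are out of scope), no GC or positional bias,
no intron retention, and no circles shorter than the read length (the
observed median circRNA is ≈ 500 nt, so rolling-circle multi-wrap reads
are not modeled). Reads start uniformly along molecules; on circles the
start wraps across the junction, so a fraction $(R-1)/L$ of circle
reads spans it, and the share with at least 20 nt on both sides —
the geometry the caller can resolve — is $(R - 39)/(R-1)$ of those.
Molecule weights are abundance × length, so at a circularized locus the
expected CR at either boundary equals $f$ exactly, which is what the
parameter-recovery checks exploit.

Ground truth tallies, per circle, junction-spanning reads at three
levels: by ≥ 1 nt on each side (the plain definition), in callable form
(≥ 20 nt on each side, crossing no other junction), and callable as
distinct sequences, the level at which the caller's `n_unique` is
comparable. One RNG stream is seeded once and consumed in the order
genome → expression → reads, so a seed pins the whole dataset.

One construction detail matters for exactness: a junction context can
by chance admit a second zero-mismatch GT/AG interpretation shifted by
$d \ge 4$ nt (the $d$ boundary-adjacent bases repeat on both sides and
the shifted breakpoints also carry motifs; probability about $10^{-5}$
per junction, so about one event is expected across a 20-seed
reference run). In such a context the true coordinates are
unidentifiable from reads — every caller must guess between two equally
valid junctions — so the generator rewrites a single base of each
shifted motif, outside all true splice signals, to keep the planted
truth identifiable. Shifts of 1–3 nt are impossible because the motifs
would have to overlap incompatibly.

## Numerical choices and degenerate inputs

* `js_distance` treats $0 \log 0 = 0$, validates simplex inputs to
  $10^{-6}$, and clamps the divergence into $[0, 1]$ before the square
  root so the analytic bounds are exact in floating point.
* `circular_ratio(0, 0)` is undefined and reported missing rather than
  0 or 1.
* `poisson_cutoff` requires at least one positive count; `retain = 0`
  degenerates to the smallest admissible cutoff, 1.
* Smith-Waterman ties are broken toward the smallest upstream then
  downstream start by tracing back every maximal cell (capped at 64
  cells; exact ties are rare at these scores).
* Exon-boundary matching, junction keys and BED output are 0-based
  half-open throughout; GTF I/O is the only 1-based inclusive surface.

## Problem sizes used by the test suite

The packaged checks run the reference scene over 20 seeds for junction
-caller exactness, a deeper single-chromosome scene (10 genes, 400k
reads, σ = 0.2, 5 seeds) for CR/SRPBM parameter recovery at loci with
at least 200 junction-covering reads, and small constructed genomes for
the remaining properties. These sizes were chosen so the whole suite
exercises every module end-to-end in a few minutes on one CPU while
keeping per-locus binomial noise well inside the ±0.05 recovery band.

## What passing tests do and do not show

The simulator provides exact, identifiable ground truth under its
stated model. Passing recovery tests therefore demonstrate that the
implementation is faithful to the method — not that the method is
robust to features the generator does not emulate: alignment to a
repeat-rich mammalian genome, indels and structured error profiles,
coverage bias, multi-isoform gene models, intron retention, or
trans-splicing artifacts. Results on real libraries inherit the
method's published caveats accordingly.
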