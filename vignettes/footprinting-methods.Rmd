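---
title: "Models and methods behind footprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind footprintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
signal model the synthetic generator encodes, the tests each stage runs,
the numerical choices, and the places where a design was genuinely open
and we had to pick.

## The signal model

DNaseI-seq reads report single cleavage events; the per-base, per-strand
count of read 5' ends is a sufficient summary for footprinting, so both
the generator and every downstream statistic work on these dense count
vectors (`cut_profile`). Counts are modelled as independent Poisson draws
per base and strand. The generator's rate at a plus-strand position is

```
rate = depth                          inside a DHS (depth/open_fold outside)
     x (1 - protection)              inside a bound footprint
     x shoulder_boost                in the 35 bp upstream shoulder
     x bias(hexamer at the cut)      always
```

with the mirror image on the minus strand (downstream shoulder boosted).
This encodes the canonical footprint signature: elevated cutting in open
chromatin, a protected interior, and strand-polarized pile-ups on the
flanks. The hexamer context of a cut between bases `c-1` and `c` is the
6-mer covering `[c-3, c+3)` on the cut strand — the cleavage sits between
the hexamer's third and fourth bases — and the minus-strand context is
the reverse complement of the corresponding window, because the enzyme
acts on the strand it cuts.

Defaults of `sim_config()` define the reference study: a 1 Mb,
two-chromosome genome at GC 0.45 (plant-like), 60 single-transcript
genes, 40 DHSs of 300–1200 bp, three 11–25 bp footprints per DHS,
`depth = 0.5` cuts per open base per strand, `open_fold = 10`,
`protection = 0.9`, `shoulder_boost = 2`, lognormal hexamer bias with
`sd(log) = 0.25` normalized to mean 1, a second tissue sharing 70% of
footprints, a second species at 5% divergence with 10% of sequence
deleted and 30% footprint turnover, and coding SNP rates of 5%
(unconstrained fourfold-degenerate sites) vs 2.5% (duon FFDS). A quarter
of footprints are placed fully inside coding exons to create duons.
Footprint widths and DHS width bounds follow the ranges reported for real
digital genomic footprinting data; the remaining values are our choice of
a realistic desk-scale regime and are fixed once — tests and the
acceptance script run at these conditions, scaled down in genome size
where a property needs many replicate simulations.

What the generator does **not** emulate: nucleosome positioning, PCR
duplicates (beyond an explicit duplicate knob for complexity metrics),
fragment-length structure, mappability, isoform complexity, and indel
variation. Passing tests therefore demonstrate the statistics recover the
truth *under this model*, not that real libraries are free of those
artifacts.

## DHS calling

Strand-summed counts are scanned in 150 bp windows every 20 bp; a window
is significant when its Poisson upper tail against
`lambda = max(global rate, 5 kb local rate) x 150` falls below `1e-5`.
Significant windows within 150 bp (including bookended) merge; merged
peaks below 150 bp are dropped. The local-lambda term mirrors MACS-style
background correction; full peak-caller machinery (fragment models,
control subtraction) is intentionally out of scope, as is the
irreproducible-discovery-rate framework — replicate agreement is instead
enforced by reciprocal overlap ≥ 0.5, with the Spearman correlation of
matched peak scores reported as a diagnostic. These are documented
simplifications: downstream stages only need DHS intervals with scores.

## Footprint detection

For footprint width `w` and shoulder `s = 35`, the plus-strand evidence
compares shoulder cuts `F` against interior cuts `f`:
`p_fwd = P(X >= F)` with `X ~ Binomial(F + f, s/(s+w))` — one-sided,
because protection can only deplete the interior. The minus strand is
tested symmetrically against the downstream shoulder. A strand with no
cuts contributes p = 1 rather than an error: absence of data is absence
of evidence. The two p-values are independent under the null and are
combined by Fisher's method (chi-square, 4 df).

Candidate generation is exhaustive: every start and every width in 11–25
inside each DHS, best score over the shoulder set (just {35} by default,
matching the generator; the search is configurable). Selection, and a
deliberate design deviation, work as follows. Adjusting all ~10^5
overlapping candidates with Benjamini–Hochberg *before* choosing
non-overlapping winners turned out to be self-defeating: each true
footprint contributes hundreds of near-duplicate rejections, which
inflates the BH threshold and passes pure search maxima — we measured a
realized false-discovery proportion of ~0.22 at nominal 0.01. The
released pipeline therefore (1) greedily selects non-overlapping
candidates by descending score (ties to the leftmost start, so output is
deterministic), (2) Šidák-corrects each selected region's p for the
`sum_w (width + w - 1)` candidates it was maximized over, and (3) applies
BH across these weakly dependent regions, retaining `q <= 0.01`. Under
this order the null simulations show no excess calls and precision sits
near 0.99 at the reference depth.

## Hexamer bias and the mixture-model filter

The bias table divides cleavage-context hexamer frequencies (cut-count
weighted, both strands, pseudocount 1) by genome hexamer frequencies
(both strands, same pseudocount); hexamers containing N are dropped
(reported as NA, treated as preference 1 when applied). On a naked-DNA
simulation the estimator recovers the generating table with Pearson
r > 0.9 on the log scale at depth 1.

The footprint log-likelihood ratio asks whether a call's cut pattern is
better explained by sequence preference than by protection. Each call is
extended by one shoulder per side and its strand-summed counts are
aggregated into 19 bins — 7 per shoulder, 5 across the interior — so
that calls of different widths align on the same shoulder/interior
anatomy (binning also denoises the per-candidate bias shape). The model
is a two-component multinomial mixture: component B's bin probabilities
are the summed local hexamer preferences; component F has a single shape
`theta` shared by all calls, estimated by EM (initialized at the average
normalized profile; mixture weight `pi` clamped to (0,1); stop at
`|delta log L| < 1e-6` or 200 iterations, non-convergence is a warning,
not an error). `flr = log L(y|F) - log L(y|B)`; calls below 0 are flagged
`retained = FALSE` but kept in the table, so the filtering is auditable.
The threshold is exactly 0. Because `theta` is shared while each call's
bias shape is individual, windows actually drawn from the bias model
score `flr <= 0` on average, while planted footprints — whose depleted
interior and boosted shoulders `theta` captures — survive at ~0.99. We
filter after FDR selection (the ratio is only defined for the calls worth
auditing); whether to filter before or after thresholding was an open
choice and the order is recorded in the output.

## Differential footprinting

Two samples are depth-matched by binomial thinning of the deeper profile
(applied within candidate windows with the global ratio — distributionally
identical to global thinning restricted to the bases the statistic
reads). The statistic is the footprint-score difference; its null is
built per candidate by 200 seeded 50/50 splits of the pooled per-base
counts, giving `z` and an empirical p with the `(1 + #)/(n + 1)` floor.
Candidates with zero pooled cuts are skipped with a recorded reason.
Replicate-vs-replicate runs at the reference depth call ≤ the nominal 1%
rate, and tissue-specific planted footprints are recovered essentially
completely.

## Feature annotation

Regions are classified by their midpoint — the single-label partition a
composition chart needs — with precedence 5'UTR > CDS > intron > 3'UTR >
promoter (2000 bp upstream of the TSS, strand-aware) > downstream
(1000 bp past the TTS) > intergenic. Precedence applies across genes
(a CDS of one gene beats the promoter of another); among genes offering
the same class, the nearest TSS wins, then the gene identifier — all
deterministic. UTRs are exon-minus-CDS, split 5'/3' by strand. Midpoint
versus any-overlap classification was an open choice; midpoint keeps the
labels a partition.

## Duons and fourfold-degenerate sites

A CDS base is fourfold degenerate (FFDS) iff all three substitutions
leave the amino acid unchanged (standard codon table, strand-aware
reading); "nonsynonymous sites" in the density comparison are the
complementary extreme, zero-fold sites where every substitution changes
the protein. Two- and three-fold sites belong to neither denominator —
that keeps both densities interpretable as rates over sites free to vary
(or not at all). Duons are the base-level intersection of footprints with
CDS; the comparison territory is the remainder of exactly those exons
that contain a duon. Polymorphism density is `1000 x polymorphic /
eligible sites` — normalizing by eligible sites rather than raw length is
an interpretation we flag (raw-length normalization is available by
flag), since the two region sets differ in codon composition. The test is
a Pearson χ² (1 df) on the 2x2 polymorphic-by-region table, without
continuity correction by default (counts are large in intended use;
Yates by flag). Allele frequencies are read and stored but do not enter
the statistic, since no frequency-weighted test is defined for this
analysis. GC content of both arms is reported as a composition control.

## Motif analysis

PWMs carry raw counts; log-odds are formed at scan time against a
0-order background (the scanned set's composition unless supplied) with
pseudocount 0.1 per cell. Match p-values are exact under that background:
the per-column score distributions are convolved by dynamic programming
with scores discretized to 1e-3. The scan threshold default is 1e-4. A
consequence worth knowing: a 6-mer's best possible p-value is the
background probability of its consensus word (~2.4e-4 at uniform
composition), above that threshold — which is why the generator's planted
consensus elements are 8 bp. De novo discovery is an explicitly
simplified seed-and-extend: canonical k-mer counts (k = 6–10, both
strands) tested foreground-vs-background by one-sided binomial, BH
ranked, redundant seeds merged by substring/reverse-complement
containment, survivors extended to PWMs from their aligned occurrences
±2 bp. Enrichment of motifs in a footprint subset is upper-tail
hypergeometric at the conventional p < 0.001, with BH q also reported;
motif frequency rankings between samples are compared with Kendall's
τ-b (tie-corrected; p exact without ties, normal approximation with).
Frequencies count annotated footprints per motif, not raw hits (hit
counting by flag).

## Conservation and permutation tests

Interval mapping through ungapped alignment blocks translates covered
bases block-wise (orientation-aware) and succeeds when ≥ 50% of the bases
are covered and all map to one target chromosome and orientation — the
0.5 threshold is exposed because chain-mapping tools do not pin it down.
A mapped footprint is conserved-and-occupied if its image overlaps any
target-species footprint by ≥ 1 bp (an interpretation of "occupied" we
flag), conserved-but-unoccupied otherwise, and not-conserved when mapping
fails; the three categories partition any input set. Multi-species
hyperconservation intersects the pairwise conserved-occupied sets against
a reference.

Permutation overlap tests re-place the query intervals uniformly per
chromosome (lengths and chromosome assignment preserved, overlap allowed
— one of several defensible randomizers), with
`p_emp = (1 + #{perm >= obs})/(n_perm + 1)`, so 100 permutations floor at
1/101. The local z profile shifts the query set and recomputes only the
observed count against the same permutation null: random placement is
shift-invariant, so re-permuting per shift would spend compute to
estimate the same distribution. When the permutation spread is zero, z is
reported as NA with the empirical p only. Note that empirical p-values of
a discrete overlap count are conservative under heavy ties; calibration
checks therefore use region sets large enough for the count distribution
to spread (~100+ intervals).

## Determinism and problem sizes

All randomness flows from explicit seeds; generator stages and pipeline
stages derive sub-seeds from one master seed by stage-name hashing, so a
run is reproducible end to end (the test suite checks bit-identical
pipeline reruns). Library-quality metrics (SPOT with its 5M default
subsample, scaled down for small libraries; PBC implemented as ENCODE
PBC1 = N1/Ndistinct, the formula the cited guidelines define) are seeded
the same way. Tests and the acceptance script use the reference 1 Mb
study once and 120–400 kb genomes wherever a property needs 20–100
replicate simulations; the duon power analysis uses a 1.2 Mb, 300-gene
set so both arms exceed 2000 eligible FFDS, and the bias-artifact
specificity check an 800 kb, 50-DHS run so that a few dozen artifact
calls are available for a stable survival fraction.

## Known limitations

The footprint component of the mixture model uses one shared shape, so
heterogeneous footprint families (e.g. different factor classes) are
averaged; the de novo motif module is a stand-in, not a HOMER
replacement; alignment blocks are ungapped, so micro-indel conservation
is out of scope; and the annotation module assumes one transcript per
gene. The FDR guarantee is for the binned, search-corrected region tests
under the Poisson model — heavy-tailed real coverage (PCR artifacts,
mappability) would need the naked-DNA filter to carry more of the load
than it does here.
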