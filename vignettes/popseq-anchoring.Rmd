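---
title: "Methods: population-sequencing maps and genetic anchoring with popanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-sequencing maps and genetic anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popanchor)
```

# The problem

Large polyploid genomes such as hexaploid bread wheat fragment into
hundreds of thousands of scaffolds under short-read shotgun assembly.
`popanchor` implements the POPSEQ strategy for turning such a fragmented
assembly into a chromosome-scale resource: sequence a biparental
doubled-haploid (DH) population at very low coverage, use the
segregation of sequence variants as genetic markers, build an
ultra-dense linkage map, and assign each scaffold a chromosome and cM
position from the segregation pattern of the variants it carries. The
package also implements the assembly-independent branch of that
strategy, in which the markers are pairs of k-mers rather than aligned
SNP calls, so that a genetic map can be built before (or without) any
assembly.

Everything is exercisable end-to-end on synthetic data with full ground
truth; the generator is a first-class, tested module, not a fixture.

# The data model

A DH individual carries one recombinant gamete, doubled. Genotypes at a
segregating site are therefore two-state: A (the allele of parent 1) or
B (parent 2). Heterozygous calls can only arise from error or
contamination, which the method exploits as a quality signal. All call
vectors in the package use the alphabet `A/B/H/-`.

## Two marker-discovery paths

**Matrix path.** Reads from every individual are aligned to a draft
assembly and SNPs are called (alignment and pileup calling are outside
the package's scope; it consumes the genotype matrix, and the generator
can emit one directly). The published filters are applied literally:
quality below 40 fails, more than 90% missing fails, minor allele
frequency below 5% fails; only sites where both parents are homozygous
for opposite alleles are kept, and progeny heterozygotes become
missing.

**k-mer path.** Canonical 51-mers are counted in each parent's reads
and in the pooled population reads. A marker is a pair of 51-mers that
share a 50-mer prefix and differ only in the final base, are the only
two 51-mers with that prefix, are found differentially in the two
parents, and each sit in a narrow frequency window of the pooled
counts. The window is the published 40--50x at a ~90x homozygous pool
depth, i.e. a fraction 0.44--0.56 of the pooled depth; `poolWindow()`
scales it to any depth so reduced-scale runs apply the same screen.
Each individual is then genotyped by membership of the two allele
k-mers in its reads: A / B / H (both) / `-` (neither).

## From markers to a map

Two-point statistics for DH data use recombinant count
`r = min(d, n - d)` over the `n` mutually called individuals (folding
resolves phase) and the LOD score

    LOD = r log10(rf) + (n - r) log10(1 - rf) + n log10 2,  rf = r / n,

with the convention `0 * log(0) = 0`, so perfect co-segregation gives
exactly `n log10 2`. The published work names the LOD threshold (9) but
not the formula; this standard DH likelihood-ratio form is documented
here as the package's choice.

Linkage groups are exact single-linkage components of the graph with an
edge wherever LOD >= 9. Markers with identical segregation (pairwise
Hamming distance 0 under the missing-skip policy) collapse into
recombination bins; the bin representative is the member with the
fewest missing calls. Because missing-skip distance 0 is not
transitive, binning proceeds greedily in a fixed order (descending
number of non-missing calls, then unit id) and a unit joins a bin only
if it has distance 0 to *every* member, which keeps bins internally
consistent and the result deterministic.

Bins are ordered per linkage group by a maximum-LOD spanning tree: its
longest path forms a backbone, remaining bins are inserted at the
adjacent position that least increases the total adjacent recombinant
count, and a deterministic 2-opt pass reverses segments until no move
improves the objective. The orientation with the lexicographically
smaller terminal bin first is reported. This re-implements the function
of MST-based ordering software; the original tool's p-value cutoff
machinery is intentionally not reproduced. Positions are cumulative
Kosambi distances, `d = 25 ln((1 + 2rf)/(1 - 2rf))` cM, from adjacent-bin
recombination fractions.

## Individual screening

Two published screens are implemented:

* k-mer path: individuals whose H-call fraction is an outlier
  (`median + 3 MAD`, with an absolute floor of 0.02 because the MAD
  degenerates to zero when most individuals have no H calls at all) are
  excluded, then any marker with a remaining H call is dropped.
* matrix path: individuals whose missing-consensus fraction is an
  outlier under the same rule (floor 0.05) are excluded before the
  final map. This catches chromosome-arm loss — an individual missing
  an arm would otherwise inflate the missingness of every scaffold on
  that arm past the "fewer than four missing" framework rule and punch
  a hole in the map — as well as heterozygous contaminants, whose H
  calls polarization turns into missing data. The published study
  excluded 12 of 90 individuals this way.

## Anchoring and validation

Scaffold consensus genotypes (majority allele per individual, requiring
at least 3 calls and 95% concordance for map construction, a single
call for anchoring) are placed by nearest-neighbour search against the
framework bins, with the published rejection cascade applied in
sentence order: more than 70% missing fails; nearest Hamming distance
above 3 fails; less than 90% of the nearest neighbours on one
chromosome fails; a median absolute deviation of neighbour positions
above 5 cM fails. The anchored position is the median neighbour
position (the median pairs naturally with the MAD criterion; the
original text does not name the location estimator).

In the k-mer path, markers place onto scaffolds only when exactly one
allele k-mer occurs at exactly one location over both strands; a
scaffold inherits the majority linkage group and median cM of its
placed markers, and scaffolds whose markers span two or more groups are
emitted as conflicts. Mis-join (chimera) screening flags scaffolds
whose terminal mapped markers disagree in linkage group or lie more
than 5 cM apart — 5 cM mirroring the published scaffold/contig
concordance window. The Results section of the source study also
mentions an alternative LOD > 8 co-segregation criterion for
anchoring; the Hamming cascade is the default here because it is the
one specified in full, and the two-point machinery makes the LOD
variant a one-liner for users who want it.

Segregation distortion is scanned per bin with an exact binomial test
of the parent-1 allele frequency against 1:1, Bonferroni-corrected at
alpha = 0.05, skipping bins with fewer than 10 informative calls.

# The synthetic generator

`simParams()` defaults encode the study conditions: 90 DH individuals
at 1.4x coverage, parents at 30x and 19x, a 0.32% parental SNP rate,
135 cM per chromosome (the published 2,826 cM over 21 chromosomes),
read length 150, per-base error 0.005 (at which the expected 51-mer
depth of a 19x parent is about 11x), arm-loss probability 10/90 and
heterozygous-contamination probability 2/90 (the observed counts in the
published population).

Crossovers follow a Poisson (Haldane, no interference) process along
each chromosome; the original work is silent on wheat interference, so
the simplest model is used for generation while Kosambi is, as
published, the estimation-stage map function. Genetic position is
proportional to physical position. Arm loss replaces one arm's
haplotype with missing data; contaminated individuals receive a
configurable fraction of heterozygous calls (matrix path) or an
admixture of reads from both parents (k-mer path). Reads are
single-end, uniformly placed on both strands with i.i.d. substitution
errors; mate pairs, indels, structural variants beyond arm loss and
planted chimeras, and realistic base-quality profiles are deliberately
out of scope. Coordinates are 0-based half-open internally and 1-based
in exported TSV position columns.

`fragmentAssembly()` tiles each chromosome into log-normal scaffolds
and, at a configurable rate, converts scaffolds into chimeras by
concatenating them with a partner drawn from a different chromosome,
recording every origin segment and misjoin in the truth object.

Passing tests on this generator demonstrate the method's correctness
under its own assumptions — clean biallelic SNPs, uniform coverage,
uniform recombination, no paralogy. Real polyploid data add homeologous
k-mer collisions, alignment artefacts and coverage biases that the
generator intentionally does not emulate; the k-mer discovery screens
(bi-allelic prefix condition, pool frequency window) are precisely the
published defences against those effects, and only their mechanics are
validated here.

# Problem sizes and numerical choices

The validation suite and the acceptance script run, by design, at these
scales:

* Matrix-path recovery: 3 chromosomes x 1 Mbp, 0.32% SNP rate, 90 DH
  lines, 30% call rate, 10 kbp scaffolds. At this density a scaffold
  carries ~32 SNPs, so the 3-call consensus rule is satisfiable at low
  call rate, as it was for the published scaffolds.
* Mis-join detection: same genome with 5% planted chimeras, error-free
  calls and 3 kbp scaffolds, which yields a framework bin spacing of
  about 2 cM — the regime of the published map (2,826 cM in 1,335
  bins), where the 5 cM discordance window is meaningful.
* k-mer path: 3 chromosomes x 300 kbp at the same physical:genetic
  density (40.5 cM per chromosome), parents at 25x/19x, population at
  1.4x, per-base error 0.002. Single markers called in only ~60% of a
  1.4x population are too sparse for LOD-9 clustering at desk-scale
  marker counts, so co-segregating markers are first collapsed into
  Hamming-0 bins whose members are combined into near-complete
  haplotype "super-markers" (the published work notes the same
  super-marker construction) before clustering and ordering.

Other numerical choices: spectra are smoothed with a centred width-3
moving average before the error-threshold (first interior local
minimum) and peak (mode above threshold, ties toward lower frequency)
are read off; a spectrum with no interior minimum reports an undefined
threshold rather than a number. k is bounded at 63 for packed 2-bit
arithmetic and must be odd so canonical form is unambiguous. Adjacent
bins with no informative overlap would have an undefined recombination
fraction; positions clamp such fractions to 0.499 rather than failing.
Ties everywhere break lexicographically so every result is
deterministic under a fixed seed.

# Known limitations

* Exact all-pairs linkage computations scale quadratically; the
  published distributed counters and sketch-based clustering tricks for
  terabase inputs are out of scope (correctness over scale).
* Greedy Hamming-0 binning depends on its documented processing order;
  other orders can produce different (equally valid) partitions of the
  non-transitive distance-0 relation.
* Map lengths estimated from tiling scaffold consensus genotypes
  shrink slightly: a crossover inside a scaffold nulls that
  individual's consensus call there, and the missing-skip distance then
  never observes it. The effect vanishes as scaffolds become
  genetically narrow (the published regime) and is quantified in the
  test suite against the realized crossover count per chromosome.
* Within-bin order is unresolvable by construction (no recombinant
  separates the members); anchored positions inherit bin resolution.
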