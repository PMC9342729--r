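---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

plastocomp analyses annotated plastomes: circular genomes of roughly
120–180 kb with a quadripartite layout — a large and a small single-copy
region (LSC, SSC) separated by two identical inverted repeats (IRa, IRb).
This vignette records the models behind each stage, the parameters that
matter, the numerical conventions, and the choices made where the design
was genuinely open. It states no result that the package's tests and
acceptance script do not themselves compute.

## Coordinates and records

All internal coordinates are 0-based half-open; every user-facing table is
1-based inclusive. GenBank locations (1-based inclusive, with `join`,
`complement` and their nestings) are converted at the I/O boundary, which
makes the conversion an involution by construction. Circular genomes are
stored linearized at the deposited origin; origin-spanning features are
handled by modular slicing rather than sequence rotation, so coordinates
stay comparable with the deposited record. Ambiguity codes beyond N are
mapped to N with a warning: the downstream counters (GC, codon usage, K2p)
need a closed alphabet, and N is excluded from all of them.

## Quadripartite detection

The partition is detected from sequence alone as the longest pair of
disjoint, exactly matching inverted segments, found by binary search over
the length with rolling hashes and verified by direct comparison (hash
collisions cannot produce a false positive). The longest pair is
inextensible — any extension would contradict maximality — and ties break
to the leftmost start. Exact matching is deliberate: the IRs of a single
plastome are identical copies maintained by concerted evolution, and
near-identical IR detection with mismatches is out of scope. `min_ir_len`
defaults to 1,000 bp; plastome IRs are tens of kb, and the floor prevents
chance short palindromes from being promoted to a "structure" in degenerate
inputs (a random 10 kb sequence yields a clean error instead).

Junction coordinates are defined between the last base of one region and
the first base of the next. A gene straddling a junction is reported with
split lengths computed on half-open intervals, so the two parts always sum
to the annotated gene length and a gene that ends exactly at the boundary
has distance 0 and no split — this removes the ±1 ambiguity that plagues
junction figures.

## Genome summaries

GC content is 100·(G+C)/(A+C+G+T) with N excluded from numerator and
denominator, reported to two decimals with half-up rounding. Gene counting
has two policies because plastome gene tables are ambiguous about IR
duplicates: the default counts each (gene name, class) once and attaches a
per-name multiplicity table; `count_policy = "all"` counts every annotated
copy. Codon usage defaults to counting every annotated CDS copy (IR
duplicates included) under translation table 11 and is switchable to
per-name de-duplication; published codon totals are frequently not
derivable from published CDS lengths, so both policies are offered and the
choice is surfaced rather than hidden. CDS lengths not divisible by three
lose their trailing partial codon with a note; internal stop codons are
counted as stops and noted, never fatal — annotation noise should not
abort a summary.

Splicing classification: a multi-part feature is cis-spliced when all parts
share a strand and follow transcript order along the genome (ascending for
`+`, descending for `-`), trans-spliced otherwise — which is exactly the
plastid rps12 situation of distant, mixed-strand parts.

## Repeat surveys

**SSRs.** Maximal runs of a primitive 1–6 bp motif, with minimum repeat
counts 10/6/5/5/5/5 for unit sizes 1–6 (the common plastome MISA setting).
A trailing partial motif copy is not counted, runs overlapping a
larger-unit run are suppressed, and the canonical class is the
lexicographic minimum over all rotations of the motif and of its reverse
complement, printed as a `fwd/rc` pair (`A/T`, `AT/AT`, `AGG/CCT`).
Compound/interrupted-SSR merging is off: category counts are the target
output and merging rules vary between tools.

**Tandem repeats.** A deliberately simplified, deterministic detector:
candidate periods (7–500 bp) are seeded by exact self-matches on the period
diagonal and extended with an X-drop rule under match +2 / mismatch −7
weights without indels; tracts score at least 50 and are reported when the
unit is ≥ 30 bp and adjacent-copy identity ≥ 90%. Probabilistic
tandem-repeat finders are not binary-reproducible from their parameter
strings, so this stage is an explicit approximation: its tract counts are
not comparable tool-to-tool and are not used as cross-package targets.

**Dispersed repeats.** All maximal repeated pairs of length ≥ 30 with at
most 3 mismatches, in forward and reverse-complement ("palindromic")
orientation. The definition is per comparison diagonal: a hit is a maximal
window with ≤ h mismatches whose ends are matches; trimming can nest one
budget-bounded window inside another, so contained windows are removed.
Copies must be disjoint and palindromic pairs are canonicalized
(`start1 < start2`), preventing double counting. Seeding uses the
pigeonhole bound — a window of length L with ≤ h mismatches contains an
exact run of ⌈(L−h)/(h+1)⌉ — so no hit can be missed by seeding. The scan
masks one IR by default in pipeline use: the IR pair is itself a ~40 kb
palindromic repeat that would otherwise dominate every output table. The
test suite proves the scanner equivalent to a brute-force enumerator on
hundreds of seeded random sequences, including the maximality property.

## Structural comparison and inversions

Anchors are k-mers (default k = 21) unique in both genomes, counting a
k-mer and its reverse complement as one class; strand-palindromic k-mers
are skipped as orientation-ambiguous, and IR regions are masked during
seeding for inter-genome comparison because IRs are near-identical across
species and cannot anchor uniquely. Anchors are chained into maximal
orientation-consistent collinear blocks (anchor-to-anchor gap ≤ 5 kb); an
inverted block bounded by same-orientation blocks is an inversion call.
Provisional endpoints are the outermost anchors of the inverted block —
accurate to the local inter-anchor gap — and are then snapped to a flanking
palindromic repeat pair when one is found within 500 bp outside the
endpoints, so that the 5' copy abuts the inversion start and the 3' copy
abuts the inversion end. Snapping makes the endpoints exact and invariant
to k (checked for k ∈ {17, 21, 25} on planted inversions). Reported
coordinates are 1-based inclusive. Only inversions are called;
translocations and duplications are out of scope. The homolog search for a
repeat unit in another genome is a local alignment (match +1, mismatch −2,
gap open −5, gap extend −2, both strands, score floor 20).

## Spacer divergence and ranking

Intergenic spacers are the gaps between genomically adjacent annotated
genes on the deposited orientation, including the origin-spanning pair of a
circular genome. Loci spanning any quadripartite junction are dropped
(their two sides evolve under different copy-number regimes), loci
intersecting a caller-supplied exclusion interval (typically an inversion)
are dropped, and IR-duplicated loci are collapsed by dropping the IRb copy.

Alignment is global with affine gaps — match +1, mismatch −1, gap of
length g costs 10 + 2g — computed by a profile–profile Gotoh kernel; more
than two sequences are aligned progressively along an average-linkage guide
tree built from shared 4-mer dissimilarity. The pairwise score is proved
equal to an independent full-DP oracle and to Biostrings'
`pairwiseAlignment` under the same scheme in the tests.

K2p distances use pairwise deletion (columns with a gap or N in either row
are excluded per pair, not globally), matching the behaviour of classic
distance tools on ragged alignments. Distances are reported per 100 sites.
When 1−2P−Q ≤ 0 or 1−2Q ≤ 0 the pair is flagged saturated and the distance
is NA; a saturated pair is real information, not an error.

Published per-region divergence tables rarely state whether the printed
value is a maximum, mean, or specific pair. The ranking statistic therefore
defaults to the **maximum** finite pairwise distance — hypervariable-region
figures conventionally show ranges topped by the most divergent pair — and
the mean is always computed and reported alongside, so the choice is
transparent and reversible (`statistic = "mean"`). The default report keeps
the top 5 loci whose statistic exceeds 5 per 100 sites.

## Marker sites

Every alignment column where taxa differ is a diagnostic site: an indel if
any taxon carries a gap there (indel columns are treated as a fifth state;
adjacent-gap merging is intentionally not applied, as column-wise counting
is the conservative, testable convention), otherwise a SNP. When several
individuals share a taxon label they must agree at the column — diagnostic
markers are definitional, not probabilistic, so intra-taxon polymorphic
columns are skipped and logged rather than majority-voted. The minimal
discriminating set is a greedy set cover over taxon pairs, verified against
the exhaustive optimum whenever ≤ 20 sites are involved (and proved equal
to it on randomized small cases in the tests).

## The synthetic-data generator

`plastome_spec()` defaults describe a full-size plastome: LSC 86,108 bp,
SSC 7,654 bp, IRs 38,455 bp (170,672 bp total), background GC 0.38, and a
repeat complement of 30 SSRs (19 mononucleotide, 8 dinucleotide, 3
trinucleotide), two tandem tracts and four dispersed pairs. Genes are laid
out in evenly spaced slots per region — CDS with valid start/stop codons
and one- to three-exon structures on both strands, tRNA and rRNA genes, an
optional trans-spliced two-part gene — and IRb genes are mirrored into IRa
so the IRs are exactly identical with consistent duplicate annotations.

Two mechanisms make closed-loop tests exact rather than approximate:

* **Rejection resampling** removes chance SSRs (a run of ten A's arises
  spontaneously every few tens of kb at plastome GC) by point-editing run
  interiors, mirrored into IRa when the edit falls in an IR.
* **Flank hardening** forces `max_hamming + 1` mismatching bases
  immediately beyond every planted dispersed repeat, inversion-flank copy,
  and (one base, exact-match case) the IR/SSC boundary, so every planted
  element is maximal under the scanner's definition and recovered with its
  exact planted coordinates.

Divergence simulation draws per-site substitutions from the K80 transition
matrix at the branch's expected distance (so the K2p estimator is
consistent against it), with a transition/transversion rate ratio κ
(default 2, a typical plastid value), per-locus rate multipliers applied to
IGS intervals, and a star topology: each derived genome sits at the
branch-length distance from the base, so derived–derived pairs have twice
the expected distance. The IRs evolve in concert — substitutions are
applied to LSC/IRb/SSC and mirrored — which both matches plastome biology
and keeps derived genomes structurally detectable. Indels (length
1 + geometric) are placed in LSC intergenic positions only and feature
coordinates are lifted through them; restricting indels to single-copy
intergenic space keeps annotation lifting exact without modelling
IR-boundary shifts.

What the generator does **not** emulate: realistic gene content and order,
codon bias, compositional heterogeneity along the genome, IR
expansion/contraction, gene-specific selective constraint, and
alignment-confounding tandem indel processes. Passing closed-loop tests
therefore demonstrates the detectors' correctness against their stated
definitions, not field performance on any particular taxon's data.

## Problem sizes and defaults used in the tests

The tests and the acceptance script run the generator at reduced scale —
21 kb genomes (12/3/3/3 kb regions) for closed-loop replicates, 10.5 kb
genomes for the ranking and calibration simulations, and one full-scale
170,672 bp genome for structure detection — with 20 closed-loop replicates
and 100 simulation runs for the power and optimality checks, and the K2p
calibration at 50 loci × 500 bp for true distances of 5, 10 and 20 per 100
sites. These sizes were chosen once as the smallest at which every stage is
exercised with dense anchor support and stable statistics.

## Known limitations

* IR detection requires exact IR copies and non-origin-wrapping IR
  intervals in the deposited linearization; records deposited with an IR
  across the origin should be rotated first.
* The tandem detector is indel-free and deterministic; its counts are not
  comparable to probabilistic tandem finders.
* Progressive alignment has no iterative refinement; for deeply diverged
  or heavily gapped loci an external aligner can be substituted upstream of
  `k2p_distance()`, which only needs aligned rows.
* Inversion calling assumes a single dominant collinear backbone; nested
  or overlapping rearrangements are not decomposed.
* The marker stage evaluates sites, not primers: product sizes, melting
  temperatures and amplification success are outside the package's scope.
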