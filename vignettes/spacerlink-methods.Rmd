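---
title: "CRISPR spacer-resolved virus-host networks: models and methods"
author: "spacerlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR spacer-resolved virus-host networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Prokaryotic CRISPR arrays are genomic records of past mobile-element
encounters: alternating direct repeats and variable spacers, where each
spacer was sampled from an invading sequence. When a host genome bin
(MAG) carries a spacer whose sequence matches a locus — a protospacer —
on a viral scaffold assembled from the same environment, that match is a
conservative, sequence-level prediction that the virus infects (or
infected) that host. `spacerlink` implements this inference end to end
for metagenome assemblies: array detection and spacer excision,
mismatch-tolerant spacer-to-protospacer search, bipartite virus-host
network construction and summarization, hyper-targeting and cross-phylum
candidate curation, virally encoded arrays and interviral conflicts,
provirus classification, Chi-motif depletion analysis, and temporal
comparison of communities sampled in different years.

Because real assemblies, bins and viral predictions are bulky upstream
products, the package also ships a first-class synthetic community
generator that emulates the statistical structure of such data and
records every planted feature in a ground-truth manifest. Every detector
in the package has a recovery test against that manifest.

## Spacer-to-protospacer matching

The retention criteria for a hit are: at most one mismatch, query
coverage of at least 90%, and E-value at most 1e-4.

The matcher realizes these criteria exactly rather than delegating to an
external aligner:

* **One mismatch means one substitution, no indels.** At spacer lengths
  (15–70 bp) an alignment with at most one difference and at least 90%
  coverage is substitution-like; excluding indels makes the search
  exactly solvable by pigeonhole.
* **Coverage below 100% is contiguous end-clipping.** The only alignment
  shape consistent with "at least 90% of the query aligned, at most one
  mismatch" for short queries is the full spacer with up to
  `floor(0.1 * length)` bases clipped from one end.
* **Pigeonhole search.** Any admissible aligned core contains an exact
  half, and that half contains an exact word of the index size
  (k = 10; spacers of at least 2k are required, shorter ones are routed
  to the exhaustive scanner). Candidate diagonals are collected by
  looking up the first and last k-mer of every admissible clipping, and
  every candidate is verified by direct Hamming evaluation. Per
  diagonal, all maximal-score admissible windows are reported (ties are
  kept, mirroring a local aligner's behaviour, and keeping the output
  invariant under reverse-complementing the target).
* **E-values** use ungapped Karlin-Altschul statistics with the standard
  +2/−3 nucleotide scoring (lambda = 0.625, K = 0.41), with the search
  space `m * n` taken as spacer length times total target length over
  both strands. This makes the E-value criterion computable and
  reproducible in-package; the constants are exposed in
  `match_params()`.
* **N handling:** any alignment column involving N counts as a mismatch
  (conservative), and N-containing words are never index anchors.

`brute_match()` is the independent oracle: an exhaustive sliding-window
Hamming scan over both strands and all admissible clippings with the
same retention rules. The test suite asserts set-equality of the two
routes on randomized fixtures; the acceptance suite does so on twenty
50-spacer x 100-kb fixtures.

Matches whose interval lies at least 50% within a CRISPR array on the
*target* are flagged `in_array`: a spacer integrated in an array carries
no protospacer-adjacent motif (PAM), so spacer-to-spacer matches confer
no immunity. They are excluded from virus-host edges and demote
interviral conflicts to non-genuine.

## Array detection

Detection is a CRT-style periodic seed finder: exact 11-mers recurring
with a period compatible with one repeat plus one spacer (repeat 21–48
bp, spacer 15–70 bp) are chained; the occurrence set is extended
columnwise while per-column majority agreement stays at or above 0.8,
then trimmed back to unanimous boundary columns; inter-repeat gaps
become spacers. Candidates with out-of-range repeat or spacer lengths
are rejected, as are candidates in which any spacer pair exceeds 60%
identity (the tandem-repeat guard). Where candidates overlap — a seed
spanning a spacer/repeat junction can assemble a small fragment of a
larger array — the array with more repeats wins, and surviving arrays
are emitted leftmost-first. The minimum array size is 2 spacers
(3 repeats), matching the smallest arrays reported in environmental
data; arrays flush against a scaffold edge are kept and flagged
`partial` rather than dropped.

The boundary-trimming step deserves a note: with diverged repeats a
majority-agreement rule alone can extend one column past the true
repeat boundary whenever the flanking spacer characters coincidentally
agree, which would shift every excised spacer by one base. Trimming
back to unanimous columns makes boundaries exact whenever the repeats
are identical, which is what the recovery contract of the generator
tests.

Pre-annotated arrays are accepted as GFF3 (`repeat_region` with
`direct_repeat`/`spacer` children); the loader enforces alternation,
counts and in-bounds coordinates. All intervals are 0-based half-open
internally and converted to 1-based inclusive only at the GFF3
boundary.

## Networks, hyper-targeting, curation

An edge connects a host MAG to a viral element when at least one
retained, non-`in_array` match supports the pair; the weight counts
*distinct protospacer loci* (a spacer with several matches on one viral
element contributes each locus). "Unique links" count distinct
(host, virus) pairs regardless of weight. MAGs enter networks only if
they exceed 70% completeness and stay under 10% contamination (both
strict). Hyper-targeting is an inclusive threshold of 20 protospacer
loci from a single host's spacer set on one viral element.

Cross-phylum/domain candidates are viral elements whose linked hosts
differ at the rank in question; hosts with an empty rank make a
candidate "unrankable" rather than inflating the count. Curation
applies, per candidate: the MAG quality gate (hard); a 10-kb floor on
the length of array-bearing scaffolds (flag-only — no published floor
exists, so short scaffolds are recorded, never auto-failed); an
identical-spacer comparison between the implicated arrays, with high
sharing annotated as possible horizontal transfer of the array; and,
when per-scaffold taxonomy is supplied, congruence between the
array-bearing scaffold and its MAG's lineage (hard).

## Interviral conflicts and proviruses

Spacers excised from virally encoded arrays (detected on the
*unclustered* viral set, so that array variation between close
relatives is preserved) are searched against all viral scaffolds under
the standard retention rules; self-hits are excluded. A conflict is
genuine only if supported by at least one match outside the target's
own arrays.

Provirus calling aligns CRISPR-carrying viral scaffolds against host
bins with local Smith-Waterman alignment (match +1, mismatch −2, gap
open 5, gap extend 2; both strands; pairs are screened by shared exact
16-mers first). The alignment engine is Biostrings'
`pairwiseAlignment`, i.e. exact full dynamic programming in C — an
anchored banded heuristic would only approximate it, so the exact DP is
used directly, and the tests cross-check it against a closed-form
planted-alignment oracle and an independently written small-instance
Gotoh DP. Identity is matches over alignment columns including gaps;
bit scores reuse the Karlin-Altschul constants of the matcher. Calls
require bit score at least 50, E-value at most 1e-3, alignment length
at least 2500 bp, and identity at least 70%; a call whose aligned span
covers 90% or more of the host-bin scaffold is reclassified `cobinned`
(a free viral scaffold binned with the host) rather than `integrated`.
The superinfection report attributes each supporting array of a
(host, targeted virus) pair to provirus-encoded versus host-native, and
flags pairs supported only by spacer-to-spacer matches as
non-immunizing.

## Chi analysis

The Chi site is counted as the canonical E. coli octamer
5'-GCTGGTGG-3' (the RecBCD attenuation signal; depletion of Chi on a
virus is associated with elevated spacer acquisition). The source work
cites the motif without printing its sequence, so the motif is a
configurable default. Counting is on both strands with overlaps
allowed (recorded in the output metadata, since one-strand counting is
a defensible alternative), and density is normalized per 1000 bp.
Subset summaries are half-up rounded to two decimals — conventional
reporting style, where 0.115 prints as 0.12 (IEEE half-to-even would
print 0.11). The density-versus-targeting relation is summarized by a
Spearman rank correlation with a seeded 10,000-permutation p-value;
degenerate rank vectors are reported as "undefined" rather than as a
number.

## Viral populations and MAG dereplication

Viral scaffolds are clustered into populations greedily, longest first
(ties by id): a sequence joins the first cluster whose representative
it matches at global identity >= 0.95, defined as identical nucleotides
in the best local alignment (either strand) divided by the length of
the shorter sequence; otherwise it founds a cluster. A word-containment
prefilter (k = 12) skips representative comparisons that cannot
plausibly reach the threshold: at 95% identity roughly `0.95^12 = 54%`
of the shorter sequence's words survive in the other sequence, so
demanding a quarter of that retains every borderline pair while
skipping unrelated ones. (A share-at-least-one-8-mer screen was
considered and rejected: essentially every pair of multi-kilobase
sequences shares an 8-mer, so it filters nothing.)

MAG dereplication collapses the usual multi-step pipeline to one
deterministic estimator: bottom-k MinHash sketches (k = 21, 1000
hashes) of each MAG's scaffold set, the Mash distance transform
`d = -ln(2j/(1+j))/k` of the sketch Jaccard estimate, and
single-linkage components at ANI >= 0.95 — the conventional
species/population cutoff. The 95% threshold and sketch parameters are
configurable.

Temporal network comparison reports shared viral populations and MAG
populations both dataset-wide and restricted to network nodes, plus
shared (host population, viral population) link pairs; shared counts
are symmetric in the reference year, only denominators differ, and
percentages print to one decimal. Array comparison between shared
hosts counts exact full-length shared spacers (either orientation),
checks that shared spacers appear in a common order, and scans the
200-bp flanks for a segment at least 60% identical to the partner's
consensus repeat over at least half its length — evidence of a
partially degraded repeat, hence a common array origin even without
shared spacers.

## The synthetic community generator

The generator emulates what the analysis consumes: host MAGs
(default 20) of 2 scaffolds at 20–40 kbp; viral scaffolds (default 200)
of 5–20 kbp; i.i.d. backgrounds at GC 0.5; arrays of 4–8 spacers
(25–45 bp) between identical 23–40 bp repeats — parameter ranges chosen
to bracket what environmental CRISPR annotations report, up to
generator-built fixtures with 187-spacer arrays. Sites cycle through a
handful of leachate-well/groundwater labels and MAG completeness /
contamination are drawn inside the quality gate.

Three design choices make the recovery tests exact rather than merely
probable:

* **Spacer uniqueness by rejection sampling.** A candidate spacer is
  accepted only if neither it nor its 1-mismatch neighborhood occurs in
  the viral background or previously planted content, on either strand,
  including containment between spacers of different lengths. The check
  is made cheap by a pigeonhole prefilter: any such occurrence of a
  sequence of 24 bp or more implies a shared exact 12-mer, so sorted
  12-mer code sets decide the common case without a scan. A
  shared-spacer scenario (emulating horizontal transfer of an array)
  bypasses the check explicitly and is recorded in the manifest.
* **Protospacer substitutions sit in the clip-protected core** — more
  than `floor(0.1 * length)` bases from either end. Otherwise a second
  substitution at a spacer end could legitimately be clipped away by
  the 90%-coverage rule and a planted "2-mismatch" protospacer would be
  recovered as a 1-mismatch hit, which is a property of alignment
  geometry, not a detection failure. With core placement, planted
  mismatch counts are exactly what the matcher sees, and the recovery
  contract is sharp: 100% of links at <= 1 mismatch, 0% at >= 2.
* **Provirus junctions are forced to mismatch.** Integrated inserts are
  viral prefixes, and the first host bases after the insert are set to
  differ from the continuation of the viral sequence, so the optimal
  local alignment ends exactly at the planted boundary and a 2499-bp
  insert can never reach the 2500-bp threshold by chance extension.

Chi-controlled viruses are scrubbed of background motif occurrences
(single-base edits) before the requested number of motifs is planted;
anything later planted on such a virus is rejection-sampled to be
motif-free, and placements are re-drawn if a motif would span a
junction, so planted counts are exact.

What the generator does **not** emulate: read-level error, assembly
fragmentation and chimerism, real codon/gene content, diverged repeat
copies within an array, and compositional biases of real genomes.
Passing recovery tests therefore demonstrate algorithmic correctness on
sequence-level ground truth, not robustness to upstream assembly or
binning artifacts.

## Numerical and engineering choices

* All randomness flows from one run seed; stage-local streams are
  derived from stable labels, so stage order does not perturb results
  and a rerun with the same seed is byte-identical.
* k-mers are encoded as base-4 integers (exact up to k = 26 in
  doubles, k <= 15 as machine integers); index lookups are binary
  searches on sorted vectors.
* Score ties in the matcher keep all tied windows; clustering ties on
  length break lexicographically by id; greedy cluster membership goes
  to the first (earliest-founded) qualifying representative.
* Degenerate inputs: empty FASTA yields an empty scaffold set; an empty
  network writes header-only tables; undefined correlations are
  reported as such; MAGs shorter than the sketch k are excluded from
  dereplication with a warning.

## Problem sizes used in the shipped checks

The test and acceptance suites run at desk scale, chosen as the
smallest sizes at which every contract is still sharp: recovery on a
20-host / 200-virus community with 60 planted links; oracle equivalence
on twenty 50-spacer x 100-kb fixtures; provirus calling on 8–12 kb
viruses against 25–30 kb host scaffolds; clustering with a brute-force
greedy replay on 50 sequences; and a 187-spacer generator-built array
for the excision fixture.

## Known limitations

* The matcher's no-indel model cannot represent a protospacer with an
  insertion or deletion; such hits (rare at these lengths under the
  strict criteria) are missed by design.
* Array detection assumes near-identical repeats; heavily diverged
  repeat copies fragment or truncate an array, and repeat orientation
  is not inferred.
* The E-value model is ungapped and shared between the spacer matcher
  and the provirus bit score; tools using gapped statistics will rank
  borderline hits slightly differently.
* MAG dereplication is a sketch estimate, not an alignment-based ANI;
  at the 95% boundary a pair within ~1% of the threshold can fall on
  either side.
* Cross-taxon verdicts depend on upstream taxonomy (consumed, never
  recomputed) and on optional per-scaffold taxonomy for the congruence
  check.
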