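---
title: "neochrom: models, design choices and validation scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neochrom: models, design choices and validation scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it
implements: the procedures, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the choices made
where the underlying design was genuinely open.

## The object being modeled

A pan-genome neo-chromosome is a synthetic circular chromosome built
from accessory DNA — sequences present in wild *S. cerevisiae* isolates
but absent from the laboratory reference — concatenated into one
molecule, recoded to Sc2.0 conventions, synthesized as ~10-kb chunks
and reassembled in yeast over iterative transformation rounds. The
package represents a design as an S3 object holding the forward-strand
sequence, a typed feature table (ORF, loxPsym, watermark, marker,
backbone, CEN/ARS, telomere seed) in 0-based half-open coordinates, a
watermark registry, and an ordered edit log together with the pre-edit
concatenated sequence. The edit log is not decoration: `validate_design()`
replays it and requires byte-identical reconstruction, which pins every
coordinate shift the editing functions perform.

## Design-phase edits

**Concatenation.** Fragments are sorted by decreasing length (ties
broken by fragment id, so the order is total and deterministic) and the
centromeric backbone is appended last; topology becomes circular. ORF
annotations are lifted by plain offsets.

**Stop-codon recoding.** Only terminal stop codons are touched: `TAG`
becomes `TAA` on the ORF's own strand; `TAA` and `TGA` terminals and
all internal codons are untouched. This follows the Sc2.0 convention of
freeing the amber codon while leaving the proteome fixed. Non-stop
terminal codons (possible in externally loaded annotations) are skipped
and surface in the validation report rather than aborting the run.

**Watermarks.** The published description of watermarking is "codon
redundancy", so the concrete scheme is this package's own, chosen to be
explicit and invertible: inside a window (default 12 codons starting at
codon 10 — late enough to avoid translation-initiation-sensitive
sequence, early enough that short ORFs still qualify), every codon with
at least one synonym encodes one payload bit. Bit 0 keeps the original
codon; bit 1 swaps to the synonym at maximal nucleotide Hamming
distance, ties resolved to the lexicographically smallest codon, under
the standard nuclear genetic code. A swap that would create a loxPsym,
PmeI or NotI occurrence is skipped and the bit moves to the next
degenerate codon; the skip decision is made against the
already-finalized left context and the original right context, and the
decoder replays exactly that walk from the recorded original codons, so
embedding and decoding stay symmetric by construction. The motif test
uses the ORF-internal context; a motif that would arise only across the
ORF boundary would be caught by `validate_design()` instead — a
documented, deliberate division of labour.

**loxPsym insertion.** The 34-bp loxPsym site is its own reverse
complement (checked once against the configured sequence), which makes
Cre-mediated recombination orientation-independent. It is inserted
exactly 3 bp downstream of the stop codon in the ORF's orientation: at
`end + 3` for a plus-strand ORF, at `start - 3` for a minus-strand ORF
(the site then sits on the lower-coordinate side with the same 3-bp
gap). Insertions are applied in descending coordinate order so earlier
insertion points stay valid, and an insertion point falling inside any
other feature is skipped and reported (configurable to a hard error).
The criteria by which the original designers chose which high-confidence
ORFs received sites are not public, so the selection is an explicit
input; the default is "all high-confidence ORFs whose insertion point is
free".

## Chunking, assembly planning and primers

Chunk boundaries start at even spacing (`length / round(length/10^4)`)
and shift locally (up to 1 kb) until the 200-bp window at the boundary
is unique in the genome — forward and reverse complement, circularly —
and free of PmeI (`GTTTAAAC`) and NotI (`GCGGCCGC`) sites. Uniqueness is
what makes in vivo homologous recombination unambiguous; restriction
freedom is what lets the flanking release sites be the *only*
occurrences. Adjacent chunks share the boundary window exactly, so
`simulate_hr_assembly()` — which joins pieces wherever one piece's
terminal 200 bp equals another's leading 200 bp, refusing ambiguous or
unmatched termini — must reproduce the design up to rotation, and the
joined length obeys `sum(lengths) - 200 * n_joins` exactly. The chunk
count is an *output* of the target-size arithmetic, not a constant:
primary sources themselves disagree on whether the historical design
used 21 or 22 chunks, so the package never asserts either.

Assembly planning groups chunks into rounds of at most
`per_round_max` (1–4), opening with 2 then 3 chunks — the schedule the
first two in vivo rounds used — and alternates URA3/LEU2 strictly,
ending with a swap of the final marker for a BFP cassette. Round count
therefore follows from chunk count and configuration (sources also
disagree on 7 vs 8+1 rounds).

Junction primers are sought outward from each boundary so the amplicon
(400–1000 bp) always spans the full shared overlap window; melting
temperatures use the unified SantaLucia nearest-neighbor parameters
(two-state duplex, terminal initiation terms, entropic salt correction
`0.368 (N-1) ln[Na+]`) at 50 mM monovalent salt and 500 nM primer, the
standard PCR-design operating point; primer uniqueness is verified by
exact circular search. The tests check the implementation against an
independently coded brute-force summation.

## Linearization

The telomerator is modeled as a deterministic sequence transformation:
optional excision of the counter-selectable cassette (the locus is
interpreted in pre-excision coordinates), rotation of the circle to
open at the cut locus, and telomere seeds appended at both ends —
`(CA)30` on the left, `(TG)30` on the right, matching telomeric strand
orientation. Seed unit and copy number are configurable because no
sequence-level description of the retained cassette architecture is
available. `recircularize()` strips the seeds and rotates back; for an
unedited variant this must reproduce the parent byte-identically, which
the tests assert for multiple random loci. The induction chemistry
(galactose, I-SceI, 5-FOA selection) is explicitly out of scope.

## SCRaMbLE simulation and variant calling

The design is reduced to its loxPsym-delimited **segment map**: on a
circle with *n* sites there are exactly *n* maximal site-free segments,
and interleaving them with the site sequence reconstructs the source.
SCRaMbLE state is then a signed circular permutation. Events pick a
site pair uniformly at random: INV reverse-complements the spanned arc
(length and site count unchanged); DEL excises one arc with its
interior sites plus one boundary site, always choosing the arc that
does *not* contain an essential segment (the origin-spanning segment
carrying the centromeric backbone, by default) — a deterministic rule,
so the truth log replays without stored randomness; DUP
tandem-duplicates the arc plus one site. Event counts are fixed or
Poisson(λ = 2), with default type weights DEL 0.45 / INV 0.45 /
DUP 0.10; none of these are quantified in the primary literature, so
all are configurable and the defaults are stated here rather than
hidden.

The caller works purely from segment content: sites are located in the
observed sequence, segments matched to the original map by exact
full-length identity with orientation, and the resulting signed
permutation canonicalized by rotating (and if needed reflecting) onto
an anchor segment. When matching is clean and no duplications are
present, the caller decomposes the permutation by breakpoint-guided
iterative-deepening search — deletions are the runs of missing ids,
inversions are found by undoing reversals whose endpoints sit on
adjacency breakpoints, at most three — and the solution is accepted
only if it reconstructs the observed state exactly. Otherwise it falls
back to run-classification (missing run → DEL, negative run → INV,
multiplicity run → DUP) with an explicit consistency flag.

Two limitations are worth naming. First, stacked events can compose
destructively: a deletion nested inside a later, wider deletion leaves
no trace, and a deletion trimming the edge of a prior inversion is
indistinguishable from a narrower inversion. In those cases *no* caller
can recover the historical event list; the package's recovery criterion
therefore accepts an equivalent explanation only when it reconstructs
the observed circular genome byte-identically (up to rotation). Second,
segment matching is exact full-length identity, with order-preserving
assignment if a design ever contained duplicate segments — adequate for
the unique-segment designs this package generates, inadequate for
repeat-rich designs.

Copy number is reported as `depth(element) / mean(depth of genome
contigs > 200 kb)`, element excluded from the denominator, so an
element gain reads as a ratio above 1. The 200-kb floor keeps small,
assembly-noisy contigs out of the genome average. The source
description of the ratio is orientation-ambiguous; the element/genome
direction was fixed so that reported copy-number increases are values
greater than 1.

## Phenotype statistics

Specific growth rate is `U = ln(x/x0)/t` per hour; the maximum specific
growth rate is the maximum over 5-point sliding windows of the
least-squares slope of `ln(OD)` against time. On a pure exponential
this returns the rate to machine precision; on a logistic curve the
window average of `r (1 - x/K)` gives a small downward bias (about
1.7% at the default inoculum OD 0.025 and capacity 2), which is why
the recovery tolerance is 0.01 absolute on a 0.53/h planted rate.

Maximum curve height `A` is the maximum of the 5-point rolling-median
smoothed kinetic series; the median window suppresses single-point
spikes entirely (a `0,0,500,0,0` series has `A = 0`) at the cost of an
upward-biased per-well maximum under multiplicative noise, so
across-seed aggregates are the meaningful recovery check. The
classification thresholds are applied literally: "exceed the negative
control by at least 50 units" is inclusive (`A >= A_neg + 50` passes),
"failed to reach 100 units" excludes the plate when `A_pos < 100`, the
two-fold rules are `log2(A_test/A_ref) >= 1` and `<= -1` (the decrease
rule made symmetric with the stated increase rule). All three constants
are arguments. A brute-force oracle — a second, independent literal
coding of the same rules over plateau heights — must agree on 1,000
random plates in the acceptance suite.

Mitotic stability assumes independent per-generation loss:
`R(g) = (1 - p)^g`, resistant counts Binomial(n, R(g)). Replicate
summaries use the sample (n−1) standard deviation, matching
"mean ± SD over three biological replicates" reporting, and exact
Clopper–Pearson 95% intervals per replicate. The inverse estimator
`p = 1 - R^(1/g)` is undefined at R = 0 (only a lower bound on p is
identifiable), which is raised as an error rather than silently
returned.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical shape* of the study's inputs
with known truth: 17 fragments log-uniform on 1.1–60.3 kb (log-uniform
matches the strong small-fragment skew and gives totals near the
published 211-kb scale), i.i.d. background at GC 0.40 with planted
non-overlapping ORFs (ATG start, non-stop interior codons sampled with
GC-target-weighted probabilities so coding regions do not drag
composition toward 50%, random stop, random strand, ~80%
high-confidence) at 0.4 ORFs/kb, scrubbed of PmeI/NotI/loxPsym motifs
(synonymous recoding inside ORFs, single-base changes outside) so the
designs are synthesis-ready; 4-parameter-logistic respiration curves
with multiplicative lognormal noise and planted fold-changes, negative
(10 units), positive (250) and blank (4) control wells; binomial
passaging counts at a default loss rate of 0.0191/generation — the
value implied by 61.7% retention at 25 generations under the geometric
model; and per-contig coverage at the 16 reference chromosome lengths
plus a 211,409-bp element contig, with Poisson read-base sampling.

They do **not** emulate: real pan-genome sequence composition (repeats,
paralogy, horizontal-transfer signatures), operon-like ORF clustering,
plate-position or edge effects, growth-phase autocorrelated noise,
nanopore read-level error, or mapping bias in coverage. Passing tests
therefore demonstrate algorithmic correctness and calibration under the
stated models, not robustness to those real-data pathologies — in
particular, exact segment matching and unique 200-bp overlaps are
*guaranteed* by the generator's unique-random segments, and would need
re-validation on repeat-rich natural sequence.

Reproducibility: every generator takes a seed and identical specs give
byte-identical output; multi-stage runs derive per-stage substreams
from one top-level seed as `seed + 10007 * offset (mod 2^31 - 1)`, and
`run_pipeline()` records MD5 checksums of written artifacts so that
identical configs demonstrably reproduce identical files.

## Problem sizes and numerical choices

The test and acceptance suites run at these sizes, chosen to exercise
full study scale where it matters and small scale where only logic is
at stake: one full-default design (~17 fragments, ~200–220 kb, ~60–70
loxPsym sites, 36 watermarks) for the chunk/assembly round trip and
junction primers; 50 three-fragment sets for proteome preservation and
length accounting; a 63-segment circle with 200 seeded 1–3-event
DEL/INV simulations plus 300 single-event trials for the caller; 100
Poisson coverage profiles at 30×; 200 noisy growth curves and 200
passaging experiments at 3 × 96 colonies; 1,000 random plates against
the classification oracle.

Other numerical decisions, stated once: coordinates are 0-based
half-open on the forward strand, circular positions normalized modulo
length; feature edits shift strictly-downstream features and stretch
only features that strictly contain the edited interval (a feature
abutting an insertion keeps its width); chunk boundary search radius is
1 kb (10% of the default spacing); the degenerate zero-site design
yields a single-segment map rather than an error; ambiguous HR joins
and sub-two-site SCRaMbLE requests are hard errors; and the watermark
decoder trusts the recorded original codons and payload length, which
are part of the design's serialized metadata.

## Known limitations

Beyond the synthetic-data caveats above: the planner models marker
logistics, not transformation efficiency or mis-assembly; the Tm model
omits divalent cations, dNTP binding and nearest-neighbor mismatch
corrections; linearization does not model the cassette's internal
architecture; SCRaMbLE copy-number gain is *not* mechanistically
simulated (the mechanism is unknown) — the coverage generator simply
plants a ratio for the estimator to recover; and GFF3 round-tripping
preserves the package's own feature vocabulary but is not a general
GFF3 validator.
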