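---
title: "Measuring translational fidelity from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring translational fidelity from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofidelity)
```

## The problem

Loss of a tRNA anticodon-loop modification — t⁶A37 on the ANN-decoding
tRNAs is the motivating case — rarely breaks translation globally.
Instead it produces discrete, codon-specific defects: a handful of ORFs
where ribosomes leave the annotated frame, a doubling of initiation
events at upstream near-cognate codons, and shifts in how long ribosomes
dwell on particular codons. Each of these signals lives at a different
scale of a ribosome-profiling experiment, and each needs its own
statistic. This vignette describes the model behind each one, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
methodology was genuinely open.

## Geometry: from a read to a ribosome

All coordinates at the package boundary are 1-based closed (the GFF3
convention); conversions to ORF-local coordinates happen in one module so
off-by-one drift has a single home. A footprint's biological 5′ end is
the lowest genomic coordinate of its alignment on the plus strand and
the highest on the minus strand. Only reads of exactly 28 nt (the
dominant protected-fragment length in yeast) that aligned uniquely with
zero mismatches are frame-informative; the filter reports per-criterion
drop counts. Uniqueness is an aligner convention, not a biological fact,
so it is configurable: mapping quality at or above a floor (default 10)
and no secondary flag for BAM/SAM, or an explicit column in the BED-like
dialect.

The P-site is the nucleotide 12 nt downstream of the 5′ end
(`five_prime_pos + 12` on plus, `- 12` on minus). The A-site codon
starts 3 nt downstream of the P-site codon and the E-site 3 nt upstream.
The simulator emits reads with the same offset constant, so a
mis-specified offset is a testable failure mode rather than a silent
bias.

## Frame profiling and ambiguity calls

The frame of a P-site is its ORF-local offset modulo 3; frame 0 is the
annotated frame, and any read in frame +1/+2 is a *translational
ambiguity* — deliberately agnostic about whether the ribosome shifted
mid-ORF or initiated out of frame. Each ORF is tiled into
`k = clamp(round(L/300), 3, 9)` codon-aligned windows; the remainder of
the codon count over `k` is spread over the leftmost windows, so window
lengths differ by at most one codon. Codon alignment keeps "frame within
a window" well defined; `round()` follows R's banker's rounding at exact
half-way lengths, which the clamp makes immaterial in practice. A read
is assigned to the single window containing its P-site (full-read
overlap would let one read touch two windows).

The ambiguity call is a rule, not a test: a window *offends* when it has
at least `min_window_reads = 32` P-sites of which at least
`offframe_fraction = 0.5` are off-frame, and an ORF is ambiguous when
any window offends. Both knobs are exposed; the defaults cleanly
separate full-penetrance programmed-frameshift positives from pure
frame-0 negatives in simulation (sensitivity ≥ 0.95, false-positive
rate ≤ 0.01 on seeded genomes — the test suite measures this). Two
consequences of the windowed rule are worth knowing: a shift landing in
the last half of the final window dilutes below the 0.5 fraction and can
be missed, and low-coverage ORFs never offend regardless of their frame
composition.

Within an ambiguous ORF, the transition point treats each P-site in
frame 0 or the dominant off-frame as a Bernoulli observation ordered
along the ORF and maximizes the two-segment binomial likelihood; the
reported nucleotide is the midpoint between the last observation of the
first segment and the first of the second. On dense full-penetrance
simulations this recovers programmed shift points within 3 nt; the
spacing of informative P-sites bounds the achievable resolution.

Sample-level fidelity sums all in-CDS P-sites into frame fractions
(f0, f1, f2) and compares per-ORF frame-0 fractions between samples with
an unpaired Welch t-test over ORFs with at least 32 P-sites in both
samples. The per-ORF unit makes the test's degrees of freedom scale with
the number of expressed ORFs; per-window units would inflate them with
within-ORF correlation. Identical tracks give t = 0, p = 1 (handled
explicitly when the per-ORF variance is zero).

## Non-AUG initiation scanning

Candidates are enumerated by walking codon-by-codon upstream from the
AUG: a UUG/ACG/GUG (GUC can be added) is a candidate if its first
nucleotide lies within 100 nt of the AUG (inclusive) and no in-frame
stop intervenes; the walk stops at the first in-frame stop or the contig
edge. Offsets are reported in codon units (the nearest upstream codon is
−1) and nucleotides. Because candidates are in-frame, their distances
are multiples of 3; with the inclusive 100-nt boundary the farthest
reportable candidate sits at 99 nt.

Support is counted as P-sites in the *extension region* — from the
candidate codon's first nucleotide to the nucleotide before the AUG —
because ribosomes initiated at the AUG cannot produce footprints there;
the count is therefore specific to upstream initiation. A candidate is
reported at ≥ 128 supporting P-sites. The default codon set follows the
three codons with tabulated outcomes in the motivating analyses rather
than the (internally inconsistent) methods list; both sets are one
argument away.

## Codon dwell metrics

Only in-frame P-sites contribute — an off-frame ribosome has no
well-defined site codons. The first and last 5 codons of each ORF are
excluded (configurable) so initiation and termination piling do not
masquerade as slow codons.

**Codon occupancy (CO).** Site-codon frequency over positional
background frequency, where the background is the codon composition of
the trimmed windows of ORFs with at least one read. CO is 1 for every
codon under uniform dwell, and invariant to uniform depth scaling.

**Ribosome residence time (RRT).** Per gene passing
`min_gene_reads = 100`, the mean P-site density at positions whose
site-s codon is c is divided by the gene's mean density; the per-codon
value is the across-gene mean, rescaled to mean 1 over codons per site.
The per-gene normalization removes expression-level confounding, which
is the reason to keep both metrics: CO is precise but expression-
weighted, RRT is noisier but depth-robust. Both recover log-normal dwell
multipliers with Spearman ≥ 0.9 at 50 reads/codon in simulation.

Between-sample comparisons report per-codon log₂ fold-changes of CO and
RRT, flagged undefined where either sample lacks signal, and annotated
with the decoding category so A-site effects can be read against wobble
chemistry.

## Codon-level efficiency indices

CAI uses the classical relative-adaptiveness weights from a
user-supplied reference gene set (which reference set to use is a
scientific choice, so it is an argument, not a default); unobserved
codons receive a 0.5 pseudo-count before the family ratio. Gene CAI is
the geometric mean over codons excluding Met/Trp.

tAI sums `(1 − s) × gene_copies` over the anticodons able to decode each
codon, with the classical penalties (0 for Watson–Crick and I:U, 0.41
for G₃₄:U₃, 0.28 for I₃₄:C₃, 0.9999 for I₃₄:A₃, 0.68 for U₃₄:G₃),
normalized by the maximum. Two deliberate choices: wobble contributions
are restricted to anticodons of the codon's own amino acid (the
unrestricted classical recipe lets tRNA-Ile(UAU) contribute to AUG via
U:G, which is biologically blocked by anticodon-loop modification), and
monotonicity in gene copies is a property of the *absolute* adaptiveness
W — after max-normalization, boosting the top codon's tRNA necessarily
lowers every other codon's normalized weight, so tests assert
monotonicity of W and rank stability of the boosted codons rather than a
false claim about w.

nTE divides tAI supply by transcriptome-weighted codon demand
(abundance × codon count summed over genes, normalized to frequencies),
rescaled to max 1; it is invariant to uniform scaling of the abundance
table. Decoding classification picks the primary route (Watson–Crick
when a dedicated anticodon exists, with A₃₄ read as inosine when
flagged; otherwise the third-base wobble route) and classes the decoder
rare at ≤ 4 gene copies. The bundled tRNA table is the standard budding
yeast genomic gene-copy census with inosine-34 and t⁶A-37 flags; it is a
replaceable default, and the arginine ranking (AGA/AGG vs CGN) needs
only the annotation, not the table.

## The synthetic-data generator

`make_genome()` builds single-exon ORF catalogs (ATG … sense codons …
stop, ≥ 200-nt spacers, optionally minus-strand) and
`simulate_footprints()` places ribosomes with P-site probability
proportional to the dwell weight of the A-site codon — the decoding
site, where elongation speed acts. Programmed events divert ribosome
classes: a frameshift sends the stated fraction into the shifted frame
downstream of the event codon (the generator re-draws sequence so the
first shifted triplet is not a stop; a user-supplied genome that shifts
straight into a stop truncates that path with a warning), and upstream
initiation starts the stated fraction at a planted near-cognate, in
frame, emitting reads from the leader through the ORF. A stop codon is
planted immediately 5′ of the leader so the candidate set is exactly the
planted one. Read-level noise covers length jitter, mismatch flags,
multimapping flags, and an optional `background_offframe` probability
that displaces a P-site out of frame (default 0: with clean defaults,
programmed events are the only ambiguity source, which keeps ground
truth sharp).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real libraries: sequence-dependent digestion bias
and the resulting 5′-offset heterogeneity across read lengths, rRNA
contamination, uneven coverage beyond Poisson (negative-binomial
overdispersion is not simulated), initiation/termination peaks, nested
or overlapping ORFs, and introns in the simulated catalog (the loaders
and coordinate mapping do handle multi-exon ORFs). The 80 %-in-frame
structure of real data is reproduced only when `background_offframe` is
set to 0.2, as the frame-summary power tests do.

Determinism: the simulation spec's seed drives genome construction and
(offset by one) footprint emission through `withr::with_seed`, so
identical specs give byte-identical truth tables without touching the
session RNG.

## Problem sizes and numerical notes

The shipped tests run genomes of 10–25 ORFs of 0.3–1.8 kb at 5–50
reads/codon — small enough for a laptop core in seconds, large enough
that binomial standard errors on the measured properties are a few
percent. The acceptance script's boundary sweeps are deterministic and
data-free. Degenerate inputs are handled explicitly: empty tracks give
zero-filled profiles, all-identical samples give t = 0/p = 1, codons
with zero background or zero demand are flagged undefined rather than
infinite, W = 0 codons get the geometric-mean imputation standard for
tAI, and ORFs shorter than 9 nt are skipped with a warning. Change-point
ties resolve to the first maximum of the likelihood; window remainders
go leftmost; truncated (non-multiple-of-3) CDS lengths are flagged and
their trailing partial codon absorbed by the last window.

## Known limitations

The ambiguity caller is a threshold rule on windowed fractions: it has
no calibrated false-discovery control and its sensitivity falls for
shifts near ORF ends. The transition locator assumes a single dominant
off-frame. CO and RRT inherit the usual single-footprint limitations
(no disome or collision information), and the E/P/A assignment assumes
the +12 offset holds for every retained read — which is why the read
filter is strict. tAI and nTE depend on the accuracy of the tRNA
gene-copy table and abundance estimates supplied to them.
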