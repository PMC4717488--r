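# ribofidelity

Translational-fidelity analysis of ribosome profiling data for compact,
mostly intron-less genomes such as budding yeast. The package is aimed at
groups studying tRNA modifications (e.g. t⁶A at position 37, mcm⁵s²U at
the wobble position) and other perturbations whose translational
phenotypes are subtle and codon-specific rather than global: discrete
reading-frame errors, initiation at upstream near-cognate (non-AUG)
codons, and codon-resolved changes in elongation speed.

## What it computes

Starting from a genome (FASTA), an ORF annotation (GFF3) and aligned
ribosome-protected fragments (BAM/SAM or a BED-like table):

1. **Frame profiling.** Footprints are filtered to unique, mismatch-free
   28-mers; each read's P-site is the nucleotide +12 nt from its 5′ end,
   and the P-site position modulo 3 within the annotated ORF defines the
   ribosome's frame. Every ORF is tiled into `clamp(round(L/300), 3, 9)`
   codon-aligned windows, and an ORF is called *translationally
   ambiguous* when a window with ≥ 32 reads has ≥ 50 % of them off-frame.
   A two-segment binomial change-point localizes frameshift transitions;
   a two-sample t-test on per-ORF frame-0 fractions compares samples.
2. **Non-AUG initiation scanning.** In-frame UUG/ACG/GUG (optionally GUC)
   codons within 100 nt upstream of an AUG, with no intervening in-frame
   stop, are candidate starts; a candidate is *reported* when ≥ 128
   P-sites fall in the leader extension between it and the AUG.
3. **Codon dwell metrics.** For every in-frame P-site, the codons in the
   E, P and A sites are tallied. Codon occupancy is the site-codon
   frequency over the positional background frequency,
   `CO_s(c) = (n_s(c)/Σn_s) / f_bg(c)`; ribosome residence time is the
   per-gene-normalized footprint density averaged over genes and rescaled
   to mean 1, a depth-robust dwell proxy. Sample comparisons report
   per-codon log₂ fold-changes annotated by wobble-decoding class.
4. **Codon-level efficiency indices.** CAI (relative synonymous usage
   weights from a reference gene set), tAI (tRNA gene copies with the
   classical wobble penalties), nTE (supply over transcriptome-weighted
   demand), wobble-decoding classification (Watson–Crick, G₃₄:U₃,
   I₃₄:C₃/U₃/A₃, rare vs abundant decoders), and gene ranking by
   t⁶A-dependent (AGA/AGG) versus t⁶A-independent (CGN) arginine codons.
5. **A seeded footprint simulator** with per-read ground truth (frame,
   originating event) generates synthetic genomes and footprints with
   per-codon dwell weights, programmed ±1 frameshifts, upstream
   near-cognate initiation and read-level noise — the validation
   scaffold for everything above.

## Worked example

```r
library(ribofidelity)

spec <- simulation_spec(
  orf_lengths = rep(900L, 10), depth = 20,
  events = data.frame(kind = c("frameshift", "upstream_init"),
                      orf_id = c("ORF0001", "ORF0002"),
                      position = c(100L, 20L), shift = c(1L, NA),
                      codon = c(NA, "ACG"), penetrance = c(0.9, 0.5)),
  seed = 42)
g   <- make_genome(spec)
sim <- simulate_footprints(g$genome, g$orfs, spec)
tr  <- assign_psites(filter_reads(sim$reads)$reads, genome = g$genome)

subset(call_ambiguities(frame_profile(tr, g$orfs)), ambiguous)
#>    orf_id ambiguous n_offending offending_windows dominant_offframe
#> 1 ORF0001      TRUE           2               2,3                +1

locate_transition(tr, g$orfs, "ORF0001", 1L)
#> [1] 301

subset(score_candidates(enumerate_candidates(g$orfs, g$genome), tr, g$orfs),
       reported)
#>    orf_id codon offset_codons offset_nt supporting_reads reported
#> 1 ORF0002   ACG           -20       -60              191     TRUE

head(site_codon_table(tr, g$orfs, sample_id = "wt")
       |> subset(site == "A"), 3)
#>   sample_id site codon count       f_bg        co       rrt
#> 1        wt    A   AAA   857 0.01591696 0.9946235 0.9372337
#> 2        wt    A   AAC  1029 0.01833910 1.0365142 1.1074126
#> 3        wt    A   AAG  1037 0.02006920 0.9545232 0.9280096
```

The programmed +1 frameshift at codon 100 (nucleotide 300) is called as
an ambiguity in the two windows downstream of it and localized to
nucleotide 301; the planted ACG start 20 codons upstream of ORF0002's
AUG is reported with 191 extension P-sites; and under uniform dwell the
occupancy and residence-time estimates sit near 1, their null value.

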