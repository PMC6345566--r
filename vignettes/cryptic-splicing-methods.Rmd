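---
title: "Methods: quantifying and classifying cryptic splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and classifying cryptic splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical model, the
design choices behind it, and what the synthetic benchmark does and does
not establish about real data.

## Coordinate model

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
is converted at the boundary on read and write, BED passes through
unchanged. A splice junction is keyed by its intron interval plus strand,
never by flanking exons, because junction-count input (the STAR
`SJ.out.tab` dialect) is expressed at that granularity and several
transcripts can share one intron. Non-ACGT bases are masked to N on
input, and any analysis window containing an N (splice-site scores,
k-mer windows) is excluded rather than scored — masking must not
fabricate motif content.

## PSI and delta-PSI

A local splicing variation (LSV) is the set of junctions sharing one
splice-site anchor: a common donor gives a source LSV, a common acceptor
a target LSV. Every anchor with at least two junctions and a summed read
count of at least `min_total` (default 10, a guard against degenerate
posteriors) defines one LSV; a junction may sit in both a source and a
target LSV.

Within a condition, each replicate's junction-usage posterior is
Dirichlet(counts + α) with α = 1 by default — a flat, documented prior
whose influence shrinks as 1/depth. Replicates enter as an equal-weight
mixture, not as pooled counts: pooling would erase between-animal
variability, which is exactly what the confidence calls must price in.
The ΔPSI posterior is sampled by Monte Carlo (default 10,000 draws; each
draw picks a replicate uniformly per condition and samples its
Dirichlet), and a junction is called high-confidence when
P(|ΔPSI| ≥ V) ≥ 0.95, with tiers at V = 0.10 and V = 0.20. The published
quantification this emulates used a read-stack bootstrap model with
GC-content correction and empirically fitted priors; that machinery is
deliberately not reproduced. What is preserved is the calling contract —
a posterior probability that the absolute change exceeds V — which is
the quantity the downstream event classification consumes. All draws are
seeded; identical inputs and seed give bit-identical calls.

## From calls to events

A cryptic terminal exon has cassette geometry — two junctions delimiting
an exon-sized interval — so a classifier that ordered the terminal-exon
rule after the cassette rule would never reach it. The classifier
therefore tests terminal-exon evidence *inside* the cassette branch:
geometry first, then evidence (read asymmetry ≥ 5 and an AATAAA within
500 nt downstream) promotes the event.
The asymmetry threshold 5 sits well below the worked 14-fold case; the
500-nt window and the exact-AATAAA signal set are configurable, the
signal defaulting to the single hexamer the motivating study names.

High-confidence junctions are merged into events via their reference
junction — the annotated member with the highest pooled count, ties
broken leftmost. The two inclusion junctions of a cassette exon each
share one anchor with the same skip junction, which is how the two LSVs
of one exon are recognised as one event; when only one side reaches the
tier (typical for terminal exons, whose splice-out junction is weak by
definition), the partner junction is searched for in the count table
among junctions sharing the reference's other anchor. Exitron junctions
are exempt from partner search: both their ends lie strictly inside one
annotated exon, and that geometry is classified first. The signed
`delta_length` is always the change to the mature mRNA, computable for
alternative-site events as reference intron length minus variant intron
length, so extension/truncation labels and frame arithmetic follow from
one quantity. Classification is strand-symmetric by construction; a
mirrored fixture must yield the identical class (tested).

## Reading-frame impact

Frame preservation is `delta_length %% 3 == 0`; frame-preserving events
affect |Δ|/3 codons. For insertions the inserted sequence is scanned for
in-frame stops after extending it with the partial codons on either
side — a stop straddling a splice boundary truncates the protein just as
surely as one wholly inside the insert, and the translate-and-compare
oracle in the test suite enforces exactly this equivalence on 1,000
random events. For frame-preserving deletions, the single joined codon at
the new junction is checked the same way. Phase is recomputed by walking
the spliced transcript from the annotated CDS start; GTF frame attributes
are ignored (one source of truth). Events not overlapping the CDS are
`noncoding` — the cryptic terminal exons planted in 5' UTRs come out
here. When several transcripts overlap an event, the longest-CDS
transcript is the default report target. NMD prediction is out of scope:
the claim scored is reading-frame disruption, not decay.

## Splice-site strength and ESE content

The published analysis scored sites with an external percentile server
whose underlying score is not stated; printed percentiles (7.5th vs
57th, 8th vs 41st) are therefore treated as direction anchors only, and
no numeric equality is claimed. The package's own model is one explicit
PWM per site kind — donor −3..+6 (9 nt), acceptor −20..+3 (23 nt,
covering the polypyrimidine tract) — trained with pseudocount 0.5 and
log2-odds against a uniform background, with percentile referencing
against the annotated-site score distribution using the midrank
convention (every member of a reference set averages percentile 50
against it; percentiles are invariant to adding a constant to all
scores). ESE density is overlapping hexamer hits per 100 nt; the hexamer
catalogue is user-supplied because the study does not name its own.

## CLIP enrichment

Crosslink windows are site ± 50 nt; each pentamer counts at most once
per window. Controls default to per-window dinucleotide-preserving
shuffles (Altschul–Erickson Eulerian walks, census-checked in the
tests); the cited study delegates its control construction to earlier
work, so composition-matched shuffling is declared here as the package's
own choice, with user-supplied control regions as the alternative.
Enrichment is log2((f_obs + p)/(f_ctrl + p)) with p defaulting to
1/n_windows, ranked by log-ratio with lexicographic tie-breaks; a
two-proportion z is reported alongside. Control fractions can be
tightened by shuffling each window several times (`n_shuffles`). Motif
maps anchor at the donor side of each junction, cover configurable
exonic/intronic extents, record the per-position fraction of windows
where any query pentamer overlaps, and smooth with a centred running
mean.

## The synthetic benchmark

The generator emulates the motivating study's shape: two conditions ×
three replicates, planted events of all eight classes (20 per class by
default) switching from PSI 0.05 to 0.55 (ΔPSI = 0.5), negative-binomial
LSV depth (mean 100, dispersion 0.1 — the simplest overdispersed model
consistent with visible between-replicate variability) with multinomial
allocation. Cryptic splice sites carry two mismatches from the consensus
(acceptor mismatches purine substitutions in the polypyrimidine tract),
which is what gives the strength-comparison its detectable direction;
cryptic and downstream exons receive equal planted ESE density; 84% of
cryptic internal exons are planted frame-disruptive (half by length, half
by an in-frame stop); terminal exons get an AATAAA exactly 60 nt
downstream with accidental signals scrubbed from the search window; one
exitron per default scenario carries a GC donor. Crosslink sites are
spread evenly through a long third intron so their ±50-nt windows do not
overlap (overlapping windows would make shuffle-based controls
anti-conservative), and a configured fraction of windows receives the
planted pentamer cassette.

Problem sizes in the shipped tests — 160 genes, ~600 junctions, 10,000
ΔPSI draws per LSV, 600 crosslink windows, 1,000 oracle events — run the
whole suite in a few minutes on one CPU and were chosen as the smallest
sizes at which the planted effects are decisively detectable.

Deliberate idealisations, and hence what passing tests do *not* show
about real data: exon interiors near planted events are stop-free by
construction (a T-free alphabet) so the frame ground truth is exact;
splice-site sequence context is consensus-derived rather than drawn from
genomic site distributions; junction counts contain no mapping artefacts,
no multi-mapping, no coverage-dependent biases; crosslink positions are
uniform within their zones rather than following real crosslinking
propensity. The benchmark certifies the pipeline's internal correctness
(recovery of planted truth, oracle equivalences, calibration under the
null), not its robustness to alignment noise.

## Degenerate inputs and tie-breaks

Zero-count LSV members are carried by the prior; an asymmetry ratio with
zero splice-out reads is +Inf (satisfying any threshold) and with both
counts zero is an error, never a number. Undetermined-strand junction
rows are resolved against the annotation or dropped with a warning.
Enrichment ties rank lexicographically; reference-junction ties break
leftmost; classification rule order is fixed. All stochastic stages
require a seed, and every report is reproducible from the seed recorded
in the run manifest.
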