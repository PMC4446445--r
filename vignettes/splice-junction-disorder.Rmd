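---
title: "Splice-junction signals, protein disorder and enhancer density: methods"
author: "junctionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-junction signals, protein disorder and enhancer density: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionscape)
```

This vignette is the package's own account of its methods: the coordinate
model, the statistics, the synthetic-data model that validates them, and
the numerical and design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinate model and exon phases

Genomic coordinates follow the GTF convention (1-based, inclusive); every
internal coordinate — CDS offsets, residue spans — is 0-based half-open,
which keeps the codon arithmetic free of off-by-one special cases. A
transcript is its ordered coding exons (pure-UTR exons are dropped on
read), the CDS including the terminal stop codon, and the protein. The
stop codon is kept in the CDS because the correlation-stage filter needs
to see it, but it never maps to a residue.

The *end phase* of an exon is the cumulative number of coding
nucleotides from the translation start to its 3′ end, modulo 3; the
start phase of the next exon equals it, and the first coding exon has
start phase 0. A phase 1 or 2 junction splits a codon between the two
flanking exons. That split codon is attributed to the junction of the
*upstream* exon — it is that exon's "last codon" — and counted once in
junction composition; for residue spans and classification fractions it
is (partially) encoded by both exons and counts toward both. Codons
containing an uncertain base translate to `X` and are excluded from all
composition counts, which are over the 20 standard amino acids. The
standard nuclear genetic code is used throughout; organisms with variant
codes are out of scope.

## Junction composition statistics

Junction composition is tabulated from each non-terminal exon's last
codon (the final coding exon ends at the stop, not at a junction, and is
excluded). Fold change is the ratio of an amino acid's junction frequency
to its background frequency over all residues of all proteins in scope;
for taxonomic-group comparisons the background is recomputed from the
group's genomes only. Background counts weight every loaded protein
sequence once; isoform redundancy is therefore visible to the background,
a sensitivity noted rather than corrected.

Two 2×2 chi-square comparisons are provided, both computed on raw residue
counts with df = 1 and no continuity correction (counts at genome scale
are large; a continuity correction would be immaterial, and percentages
are not valid chi-square input): membership in the ten most
disorder-promoting amino acids (junction vs background), and membership
in the enriched set (structure- vs disorder-encoding exons). "Enriched"
is defined as fold change strictly above 1 on the all-exon table; the
threshold is an exposed argument. The disorder split uses the TOP-IDP
propensity scale shipped as a packaged constant
(`top_idp_scale()`, most → least disorder-promoting:
`r paste(names(top_idp_scale()), collapse = " ")`); any alternative
published ordering can be passed to `disorder_set_enrichment()` to check
robustness. A warning is attached whenever an expected cell count falls
below 5.

## Exon classification

An exon is *disorder-encoding* if at least 75% of its encoded residues
carry the disorder-consensus flag and none lies in a predicted domain;
*structure-encoding* if at least 75% lie in a domain and none is
disordered; otherwise *other*. The 75% is read as ≥ 0.75 and applied to
all residues the exon (partially) encodes, including split-codon edge
residues — they are formed by the exon, so they count. Whether split
residues should count toward both neighbours is genuinely open; the
swap-symmetry and threshold-monotonicity properties hold either way, and
the choice is flagged for sensitivity testing.

*Constituent* exons contribute the same coding sequence from the same
locus in every transcript of their gene, operationalised as identity of
(chromosome, strand, coding genomic interval) — a literal reading that
avoids sequence-comparison ambiguity; everything else, including exons
whose genomic span matches but whose coding sub-interval differs through
UTR overlap, is *alternative*.

## Distance correlation

The correlation stage first filters transcripts in a fixed order — start
codon, stop codon, premature stop, uncertain base, length divisible by
three — recording the first failing rule per transcript; then discards
each surviving protein's first and last exons; then trims incomplete
codons (an exon with start phase *s* sheds its leading 3−*s* nt, one with
end phase *e* its trailing *e* nt — exactly the nucleotides of codons
shared with neighbours). Usage is then counted at codon distances 2–34
from each exon edge; distance 1 (the junction codon itself) is excluded
by the window definition.

Short exons cannot honour both sides: each codon is assigned to its
nearer edge, and an exact-midpoint codon (odd-length exons) to neither,
which enforces the rule that no residue contributes to both the start and
end side of one exon. Composition fractions are pooled over exons before
correlating (one fraction per distance per stratum), not averaged per
exon.

Spearman's rho is computed as the Pearson correlation of ranks, with
two-sided p-values from the large-sample t approximation
t = ρ√((n−2)/(1−ρ²)) at n = 33; significance is declared at p ≤ 0.001. A
constant fraction vector has undefined rho and is reported NA/not
significant. No exact permutation option is provided: at n = 33 the exact
null is impractical and the t approximation is the method; its adequacy
is checked empirically instead — over 2000 simulated null strata the
p ≤ 0.001 call rate must stay under 0.3% (the suite observes roughly the
nominal rate).

## Enhancer density and introns

The scanned DNA per exon side is the block of codons 2–34 (≤ 99 nt),
built from the same filtered, trimmed exons as the correlation — so on
short exons the window shrinks to the codons assigned to that side.
Hexamers are matched with stride 1, overlapping matches all count,
matching is exact, case-insensitive, and on the mRNA-sense strand only
(enhancers act on pre-mRNA sense sequence). Windows containing `N` are
excluded from the denominator. Start- and end-side windows are scanned
separately: no hexamer window spans the gap between them or leaks into
the junction codon or past codon 34. Intron length is the genomic gap
between consecutive exons of a transcript; each internal exon's statistic
is the mean of its two flanking introns, and classes are compared with a
two-sided Welch t-test (Welch–Satterthwaite df), reported as structured
minus disordered.

## The synthetic genome model

The generator is the package's study-conditions definition, not a demo.
Defaults: ~8 coding exons per gene (1 + negative binomial), exons ~50
codons (σ = 15), junction phases drawn 0.47/0.30/0.23, canonical
splice-site bias β = 0.6 (the exonic consensus is strong but far from
universal in real genomes), enhancer window match rates 10% / 13.5% /
11% in structured / disordered / other exons, intron means 1000 / 600 /
800 nt (σ = 200/150/175), planted class blocks with switch rate 0.4,
alternative-transcript rate 0.3, UTRs on half the genes, uniform codon
usage, and a single default composition gradient — Lysine usage
decreasing with distance from the junction (slope −0.015 on the
log-weight scale), the strongest distance trend the method is designed to
detect. Codon sampling from a uniform background makes the null
calibrations exact rather than approximate.

Construction details that matter to the invariants:

* **Splice-site bias.** With probability β per junction the two exonic
  nucleotides before the 5′ splice site become `AG` and the nucleotide
  after the 3′ splice site becomes `G`. Any stop codon this creates is
  repaired by resampling only unforced positions, so at β = 1 a phase-0
  junction's last codon is exactly `{AAG, CAG, GAG}` (K/Q/E; `TAG` is
  repaired away), a phase-1 split codon is `GG·` (Glycine) and a phase-2
  split codon is `AGG` (Arginine) — the mechanism the junction
  composition figures rest on.
* **Enhancer planting.** Each side-window receives
  ⌊r·n⌋ or ⌈r·n⌉ planted motifs (stochastic rounding of the configured
  per-window rate r over the window's n hexamer positions), placed on
  codon-aligned non-overlapping tiles, skipping motif draws that would
  introduce a stop codon in frame. Incidental background matches inside
  scanned windows are then scrubbed by resampling free codons, so the
  realised match rate equals the configured rate — which is what makes
  "recover the planted rate within binomial error" a meaningful test.
  The generator's own matcher is plain substring hashing, a different
  route from the Biostrings-based scanner it validates.
* **Track alignment.** Planted classes change only across phase-0
  junctions, so a split codon never straddles two classes and residue
  tracks can be exactly exon-aligned; without this, 100% class recovery
  would be impossible by construction, not by defect.
* **Gradients.** In the codon 2–34 window (nearer-edge distance d, ties
  excluded, matching the analysis-side assignment rule) amino acids are
  drawn with weight `bg · exp(slope · (d − 2))`, then a uniform codon of
  that amino acid.
* **Null switch.** `force_terminal_codons = FALSE` drops the forced ATG
  and stop so the junction sample is exactly distribution-matched to the
  background; the forced start codon otherwise shifts Methionine's
  background frequency by ~1/⟨protein length⟩, a real but irrelevant
  artefact that would dominate a large-n null comparison of fold
  changes.
* **Defect injection.** `corrupt_for_filters()` plants one defect per
  chosen transcript; the off-frame defect inserts a non-T base just
  before the stop codon so the length rule — not the stop or
  premature-stop rule — is the first to fail, keeping the filter's
  rule-order contract testable label-for-label.

What the generator does *not* emulate: realistic codon usage or
dinucleotide composition, branch points and polypyrimidine tracts,
alternative splicing beyond frame-preserving exon skipping,
non-standard genetic codes, and enhancer motifs with biological
information content (motif sets are uniform random hexamers, labelled
synthetic). Passing tests therefore demonstrate that the pipeline
measures what was planted under controlled conditions — not that real
genomes behave like the defaults.

## Problem sizes and determinism

The validation suite runs at sizes chosen to make its statistics decisive
on one CPU: 1000 fuzzed transcripts against the per-nucleotide mapping
oracle; 100 generator seeds of ≥ 10⁴ exons each for gradient-sign
recovery; 2000 simulated strata for the null calibration; ≥ 10⁵ scanned
windows per exon class for enhancer-rate recovery; 10⁴ fuzzed sequences
against the substring-scan oracle. Generation is deterministic given the
config seed; chromosome sequences are filled at write time under a seed
derived from the config seed with the caller's RNG state preserved, so
repeated writes of one bundle and repeated pipeline runs under one seed
are byte-identical.

## Known limitations

Exons are analysed per transcript, so exons shared by isoforms contribute
once per transcript to junction composition and window counts (the
paper-style gene-level de-duplication would need a canonical-isoform
choice the inputs do not provide). Group-level profiles summarise
per-genome rho values without phylogenetic correction. The chi-square
variant (df = 1, no continuity correction) and the pooled-fraction
correlation input are stated choices where the upstream description is
silent; both are exposed through the API surface for sensitivity
analysis.
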