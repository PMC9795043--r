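---
title: "Profiling CDR3-restricted somatic hypermutation in truly unmutated B-cell clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CDR3-restricted somatic hypermutation in truly unmutated B-cell clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3shm)
```

## The problem

Risk stratification in chronic lymphocytic leukemia (CLL) rests on the
somatic hypermutation (SHM) status of the rearranged heavy-chain V gene,
conventionally measured over FR1–FR3 only. Clones with 100% germline V
identity over that stretch are called *truly unmutated* — yet this
definition deliberately ignores the VH CDR3, the antigen-contact loop
spanning the V–D–J junction, where SHM could act unobserved. Detecting
CDR3-confined SHM from deep amplicon sequencing is delicate: candidate
variants are rare (on the order of 0.1% of reads), one nucleotide away
from the dominant clone, and must be distinguished from sequencing error.

`cdr3shm` implements the full analysis path for this question on
stereotyped clones with a known CDR3 architecture, and pairs it with a
repertoire simulator whose truth ledger makes every stage testable.

## Stereotyped archetypes

All downstream stages consume a *rearrangement archetype*: a germline V
segment (with FR/CDR boundaries), non-templated N1, a D segment in a fixed
reading frame, N2, and a J segment. Two archetypes are built in:

* **subset #1** — clan I-like V, IGHD6-19-like D in reading frame 1,
  IGHJ4-like J; a 13-aa CDR3 with the D-encoded QWL motif at positions
  4–6, a V-encoded arginine at position 2 and a J-encoded aspartate at
  position 12.
* **subset #6** — IGHV1-69-like V, IGHD3-16-like D in reading frame 2,
  IGHJ3-like J; a 21-aa CDR3 with the D-encoded YDYVWGSY motif (the
  variable valine at position 9) and the J-encoded FDI tail (phenylalanine
  at position 19).

The packaged germline sequences are synthetic stand-ins (and say so in
their file names): the analysis depends only on the constraint sets above
— CDR3 lengths, motif positions, encoding regions, hotspot context — not
on allele-level identity, so no external database download is required or
consulted. Exact patient junctions are not reproduced; archetypes are
constraint-driven surrogates.

CDR3 delimitation is IMGT-like: the CDR3 runs from the codon after the
conserved FR3 cysteine to the codon before the J-region tryptophan, and
CDR3 amino-acid positions are 1-based on that window. Internally all
nucleotide intervals are 0-based and half-open. Each CDR3 codon is
assigned one encoding region (V, N1, D, N2, J) by the majority of its
three nucleotides' origins, ties resolved to the 5'-most contributing
region — junction codons can mix origins, but the analysis (like the
field's reporting convention) speaks of whole positions as V-, D- or
J-encoded.

## The simulator and what it emulates

`simulate_repertoire()` draws read pairs from the archetype and any
injected single-nucleotide CDR3 variants by a multinomial at the target
frequencies, then applies:

* a 2 × 250 nt paired-end layout over the ~320 nt amplicon (ample
  junction-spanning overlap, as with 2×250/2×300 desktop chemistry);
* independent per-base substitution errors at `error_rate` (default
  0.024, the PhiX-calibrated regime the 66-read cutoff is tuned for).
  The error model is substitution-only and uniform: the analysis treats
  error through an aggregate rate and a read cutoff, and length-aberrant
  reads are excluded by the same-CDR3-length rule anyway;
* a two-component quality model: Phred 37 baseline with a configurable
  fraction (default 2%) of Phred-20 bases, so the CDR3-window quality
  filter has real work to do;
* optional isotype tags (IGM/IGG/IGA), switched reads being the same
  nucleotide rearrangement re-emitted under a different isotype, and an
  optional fraction of unrelated background reads (default 0 — no
  published value exists for it).

Everything is deterministic under one master seed; per-sample streams are
derived from it by a fixed linear hash. The truth ledger records each
variant's injected change and realized count, so parameter-recovery tests
compare pipeline output against known truth rather than against itself.

What the simulator does *not* emulate: PCR amplification bias, chimeras,
UMIs, indel errors, or quality degradation along the read. Passing tests
therefore demonstrate correctness of the analysis logic under a clean
error model, not robustness to every artefact of real libraries.

## Read QC

Reads pass, in order: per-mate length/mean-quality filters (defaults
200–350 nt, mean Q ≥ 25, inclusive bounds); merging (best overlap by
minimum mismatches among placements with ≥ 30 nt overlap and ≤ 10%
overlap mismatches; disagreements resolve to the higher-quality base,
read 1 winning ties; merged quality is the per-base maximum); merged-read
filters (250–450 nt); and the CDR3-window filter: every base in the
window upstream of the FR4 G-X-G anchor must reach Phred 30. The anchor
is the first base of the G codon following the conserved tryptophan of
the W-G-x-G motif, searched at the amino-acid level in all three frames
with the rightmost hit winning (FR4 is J-encoded and 3'-terminal).

The phrase "the 30–45 nucleotide stretch ahead of the motif" is
ambiguous; the default reads it literally as the closed offset interval
[−45, −30], which is where the 3' portion of a 13–21 aa CDR3 lies. The
alternative reading — the whole contiguous stretch [−45, −1] — is
available as `mode = "stretch"`, and both window bounds are parameters.

## Annotation

The V(D)J annotator is a deliberately simplified stand-in for full
reference tools: gap-free semi-global alignment (match +1, mismatch −2)
of every V and then J segment, ties by segment name; D by longest exact
substring match (≥ 5 nt) between the junction's V/J-free middle and any
D segment, ties to the longest then 5'-most match, with the reading frame
derived from the match's codon phase. Gap-free alignment is a design
choice, not a shortcut: the question concerns substitutions only, and
indel-bearing variants are excluded downstream by the same-length rule.
Equivalence with reference annotators is claimed only on simulator output
and small fixtures, not on arbitrary noisy data.

Germline identity is computed over FR1–FR3 positions only — a mutation in
the junction tail of V can never reduce it — and alignments that do not
reach the FR3 end are flagged incomplete and excluded. The *truly
unmutated* filter then requires exactly 100% identity.

N regions are defined negatively: junction nucleotides not covered by the
V 3' end, the D match, or the J 5' end. P-nucleotides are not modelled
separately. When no D match reaches 5 nt, the whole middle is labelled N1.

## Clonotypes, cutoff, variants

A clonotype is a unique rearrangement *nucleotide* sequence; the top
clonotype by read count is the main variant (exact ties are resolved
lexicographically and warned about). Subclonal variants share the main's
V gene and CDR3 amino-acid length and differ by at most two amino acids —
Hamming distance on the equal-length CDR3 strings, comparison against the
main variant only (the definition's wording supports main-only rather
than transitive network comparison). Zero amino-acid distance is allowed:
synonymous nucleotide variants are distinct clonotypes.

The read cutoff (default 66, inclusive — a "minimum cutoff of 66" with a
33-read variant described as below it) removes clonotypes too rare to
distinguish from error at a 2.4% sequencing error. An optional exception
retains a below-cutoff variant when every difference from the main
variant *restores the germline residue*: such a variant is evidence that
the main clone's change is a true mutation, not an artefact. Clonotype
frequency is computed over all productive reads by default; a
truly-unmutated-only denominator is a configuration switch.

## Substitution profiling and statistics

Substitutions are called against a hybrid reference: germline bases at
V/D/J-encoded positions, the main variant's bases at N positions — no
germline exists in N regions, so N-only differences are reported but
never classed as SHM against germline. Each nucleotide difference yields
one event (position, amino-acid change, transition/transversion,
frequency); events from one variant share its frequency. Chemistry
defines transition/transversion (purine↔purine / pyrimidine↔pyrimidine
versus cross-class), so a g>a change is always reported as a transition.

Cohort statistics follow the rank-based design:

* per-sample per-position mutation frequency = the sum of frequencies of
  subclonal variants mutated at that position;
* Kruskal-Wallis omnibus across positions at α = 0.05; if significant,
  each position is compared to the pooled remaining positions by a
  Wilcoxon rank-sum post-hoc, Holm-Bonferroni adjusted (the Holm
  step-down is implemented in the package and cross-checked against
  `p.adjust` in the tests). The post-hoc defaults to the one-sided
  "greater" alternative: the scientific question is preferential
  (elevated) targeting, and under a two-sided test every *non*-elevated
  position would eventually be flagged as significantly low merely
  because other positions are elevated;
* between-subset heterogeneity by a two-sided Mann-Whitney U — exact
  enumeration of all group assignments (midranks for ties) when both
  groups have ≤ 8 observations, otherwise the normal approximation with
  tie and continuity correction. The exact path is verified in the tests
  against an independent pair-counting enumeration oracle.

All-zero frequency matrices return an omnibus p of 1 by convention; a
single sample is a precondition error, not a silent pass.

## Hotspot topology

The scanner reports every WRC and GYW occurrence (IUPAC W = A/T,
R = A/G, Y = C/T) plus the 4-nt overlapping WGCW motif; GYW is treated as
the reverse-strand presentation of WRC and scanned on the sense strand,
with the deaminated site at the C (WRC) or the mirroring G (GYW). The
palindromic AGCT both-strand motif is the canonical WGCW instance. A
mutation is `canonical_AID` when it sits on a deaminated site,
`adjacent_AT_noncanonical` when its germline base is A/T within 2 nt of a
hit (the mismatch-repair signature; "adjacent" has no published width, so
the threshold is a parameter defaulting to 2), else `unassociated`.
Junction-created hotspots are hits spanning ≥ 2 regions whose motif is
absent from the direct germline concatenation — motifs that exist only
because of the junction (or a mutation at it).

In the built-in archetypes, the V-encoded position-2 and J-encoded
position-12 a>g changes of subset #1 fall at A bases adjacent to TGC and
AAC hotspots, and the subset #6 position-9 g>a sits on the deaminated G
of a GYW within a TACGTT context — the topology the analysis is designed
to expose. The D-encoded position-4 change has no germline hotspot within
2 nt in the synthetic archetype; in real cohorts its hotspot association
arises from patient-specific junction-created motifs, which the package
detects but the fixed archetype does not instantiate.

## Numerical and scale choices

Tests and the acceptance checks run at reduced but sufficient scale,
chosen so every property remains statistically decisive: frequency
recovery uses 20 seeds at 10^5 reads with 0.1% injections (the binomial
99% interval at that depth is ±2.6·10⁻⁴, so recovery is a sharp test);
error control uses 50 seeds at 10^4 reads and 2.4% per-base error;
statistical power and type-I use 200 and 1000 replicates. Under the
per-base reading of the 2.4% error rate, almost no ~320 nt read is
error-free, so error-rate runs exercise false-positive control while
parameter recovery is evaluated on error-free runs, where clonotype
identity is preserved end-to-end.

## Known limitations

* The annotator is gap-free and allele-blind; it is a pipeline component
  for the CDR3-restricted question, not a general-purpose V(D)J tool.
* The simulator's error model is uniform substitution-only; real
  position-dependent error spectra, PCR bias and chimeras are out of
  scope, and conclusions about real-data robustness should not be drawn
  from simulator-based tests alone.
* Selection-pressure analyses (replacement/silent ratios, 5-mer
  mutability models) and lineage-tree reconstruction are out of scope.
* Cohort-scale quantities from the motivating study design (median main
  clonotype frequencies, read totals) depend on deposited patient data
  and are not reproduced here; the package reproduces the architecture-
  level quantities (positions, lengths, substitution identities) and the
  statistical machinery.
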