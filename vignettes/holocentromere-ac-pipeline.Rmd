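---
title: "Modeling artificial chromosome formation and holocentromere domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling artificial chromosome formation and holocentromere domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoac)
```

## The problem

Microinjected linear DNA in the *C. elegans* syncytial gonad is fused into a
high-molecular-weight concatemer — an artificial chromosome (AC) — that
acquires CENP-A^HCP-3^ chromatin and segregates in mitosis. Three questions
drive the analyses in this package: which injected fragments end up in the
AC (and why), how the resulting AC can be quantified (size, marker copy
number, segregation and transmission rates), and how CENP-A domains
distribute on AC and endogenous sequence (widths, AT-content, occupancy,
spacing, profile shapes). Because the interesting statistics act on
sequence, intervals and binned signal, every stage here runs equally on real
files (FASTA / BED / bedGraph / TSV) and on synthetic data the package
generates itself.

## Coordinate and alphabet conventions

All intervals are 0-based, half-open (BED convention) throughout; 1-based
coordinates appear only inside external formats that require them. Sequences
are uppercased on load; soft-masking is not preserved (no analysis here uses
repeat masking). In consensus scanning, an `N` in the scanned sequence
matches only a consensus `N` and is excluded from both sides of the
AT-content ratio — otherwise gap-padded assemblies would inflate AT%.
Palindromic consensus sites matching both strands at identical coordinates
are counted once by default, so strand-combined site tallies are not
doubled.

## Digestion model

`digest()` severs the duplex at `cut_offset` bases into every occurrence of
each recognition site (AfaI `GT|AC`, PvuII `CAG|CTG` ship as
`ac_donor_enzymes()`). Overlapping occurrences each contribute a cut —
digestion to completion — and both strands are scanned so non-palindromic
(and IUPAC-degenerate) recognitions work, although the default enzymes are
palindromes. Only blunt cutting is modeled: no overhangs, no partial
digestion, no methylation sensitivity. Circular records (e.g. a
mitochondrial genome, via `circular =`) are linearized at their lowest cut
position with the final fragment wrapping the origin; a circular record
without a site yields one circular-flagged fragment. Per linear record the
fragments tile the sequence exactly, which the test suite asserts as a
conservation law.

## Concatemer simulator

`simulate_ac()` repeats until the target length is reached: draw a molecule
from the pool, accept with the logistic incorporation probability
$w(L) = 1/(1+e^{-(L-L_0)/s})$, orient it uniformly at random, and append.

Choices worth making explicit:

* **Molar weights.** A species of relative mass $m_s$ and total molecule
  length $\Lambda_s$ contributes each distinct molecule with draw weight
  $m_s/\Lambda_s$: a digest present at one copy per genome equivalent is
  equimolar across its fragments, and two single-molecule species of equal
  mass draw inversely to their lengths. This is the physical reading of a
  mass ratio; the default 300:1 (digest : marker) mirrors the co-injection
  protocol this analysis targets.
* **Acceptance/rejection is memoryless**: a rejected molecule simply
  returns to the pool, the simplest model consistent with short fragments
  being rare in the product while abundant in the mix. Draws are with
  replacement; re-use of one fragment at several loci subsumes both pool
  multiplicity and true re-ligation, which sequence data cannot
  distinguish.
* **Homology-mediated joins** are off by default (`p_hr = 0`), reflecting
  that no tandemly oriented marker pairs are observed on real ACs. With
  `p_hr > 0`, an incoming molecule whose terminus shares at least `h_min`
  exact bases (default 20, capped at 200) with the AC end is overlap-merged
  with probability `p_hr`, the homology counted once; at least one novel
  base must survive the merge, which excludes the degenerate full-length
  self-overlap.
* **Partial markers** come from an optional pre-fragmentation step
  (`break_prob`): a uniform random double cut of the cassette before
  joining. The mechanism behind incomplete marker fragments on real ACs is
  unknown; this is the least-structured choice.
* **Determinism**: one seeded generator drives every draw; the seed is
  recorded in the truth-table header, and `reconstruct_ac()` independently
  rebuilds the AC from the truth table — the round-trip is byte-exact by
  construction and asserted in the tests.

The simulator emits a single AC molecule; fragmentation into contigs is a
sequencing/assembly artifact, not part of formation, so it is left to
downstream tooling.

## Incorporation analysis

`classify_fragments()` in exact mode calls a fragment incorporated iff its
sequence or reverse complement occurs verbatim in an AC contig (implemented
with a fixed-width prefix dictionary plus full-length verification; a
brute-force oracle in the tests checks it). Exact matching is right for
synthetic data; for polished long-read assemblies, approximate mode
tolerates an edit budget of `1 - min_identity` and falls back to the central
`min_coverage` core of the fragment (defaults 0.95/0.95), since real
comparisons tolerate residual assembly errors but published thresholds are
unavailable. Multiplicity counts distinct match loci, not attributions —
when one fragment contains another, both match independently, because
attribution is unidentifiable from sequence alone.

`fit_length_bias()` is the estimator at the heart of the length-bias claim:
logistic regression of the incorporated indicator on length, reported as
$\hat L_0$ and $\hat s$. Perfectly separated classes (where the MLE
diverges) are detected up front and reported as a step estimate at the
midpoint of the empirical class gap, flagged `separated`, with the gap as
the interval — the fit always brackets a true step inside the gap. The CI
for $\hat L_0$ is a deviance profile over a grid sized by the delta-method
SE (81 points over ±8 SE, chi-square 95% cutoff); a reversed bias (negative
slope) is reported as a negative $\hat s$ with a `reversed` flag rather
than an error.

Tandem markers are defined as two *full-length* copies, same contig, same
strand, separated by at most `max_spacer` (default 1 kb) — the arrangement
that could license homologous-recombination concatemerization. Partial
copies are excluded deliberately: only intact repeats provide the
homology that matters for that question.

## Domain characterization

The internal caller (`call_domains()`) is a threshold-run caller for
synthetic tracks only: maximal runs of bins at or above threshold, gap
merging, minimum width, missing bins below threshold. Real peak calling
stays external (broad-mode callers); its BED output enters via
`read_bed()` — re-implementing an external caller could never be
bit-compatible and is out of scope.

Occupancy uses *merged* domain bases over analyzed length. Merging (rather
than summing raw widths) means overlapping or book-ended domains are never
double-counted, and occupancy is invariant under splitting a domain into
adjacent halves; reproduced percentages can therefore differ slightly from
numbers computed on unmerged widths. The
`exclude_zero_domain_seqs` flag mirrors the practice of dropping contigs
that fail to call any domain from the denominator. Percentages are reported
to 2 decimals, matching the precision such numbers are usually quoted at.

Gap ECDFs pool within-sequence gaps across sequences (a gap spanning two
sequences is undefined); terminal flanks are not gaps. Profile matrices are
centered on domain midpoints with a ±2 kb default flank (a 4-kb variant is
one argument away), out-of-sequence bins NA.
k-means clustering uses k = 4 by default, 10 restarts, a required seed, and
no row standardization — the rows are already log-ratios on a common scale.
Clusters are relabeled by descending peak height so "cluster 1" is stable
across runs; all-identical-row inputs short-circuit to a single populated
cluster rather than erroring inside k-means. Missing bins are imputed as 0
(the log-ratio null) for clustering only.

`marker_enrichment()` averages per-base signal across the copies of a
marker after projecting each copy to gene coordinates (reverse-strand
copies flipped); masked positions — e.g. promoter/3′UTR windows whose reads
cannot be uniquely assigned between the AC and the endogenous locus — are
excluded per copy, and positions excluded in every copy are reported as
gaps, not zeros. The operation is linear in the signal.

## Synthetic data: what it emulates, and what it does not

`synth_genome()` draws bases i.i.d. per region at a target AT (order 0,
matching how random synthetic injection sequences are generated), with an
optional order-1 mode adding base-class autocorrelation at the same
stationary AT for more realistic digest length distributions. High-AT
islands (≥ 83%, emulating yeast CEN-like and mitochondrial sequence) and
marker cassettes overwrite the background. For chromosomes ≥ 10 kb the
realized AT concentrates within ±0.02 of target (binomial concentration;
asserted in tests).

`synth_chip_signal()` places domains with density proportional to
$g(\mathrm{AT}) = \mathrm{AT}$ of the local 1-kb window, zero above
`at_cap = 0.80` and zero where the window overlaps a `ubiquitous` or
`germline` expression feature. The cap is additionally enforced on each
realized domain span (a window can pass while the span hangs over an
island edge). The true functional form linking AT to CENP-A occupancy is
unknown — real data show only a weak correlation — so $g$ is a modeling
choice, not a claim; the expression exclusion is binary, not graded by
transcription level. Widths are log-normal (median 1 kb, σ = 0.4) with a
weak positive AT coupling (`width_at_coupling = 1.5` on the log scale) so
the width–AT correlation analysis has a planted positive signal to
recover; note that on an AT-homogeneous background the 1-kb window AT
barely varies (SD ≈ 0.015), so that correlation is only detectable on
AT-heterogeneous genomes. Domains are aligned to the bin grid, separated
by at least one empty bin, and at least 3 bins wide, which makes noise-free
recovery by the internal caller bit-exact — a deliberate construction, and
the reason passing recovery tests says nothing about caller performance on
ragged real signal.

What the generator does *not* emulate: read-level noise (no FASTQ, no
mapping artifacts), assembly fragmentation and error, copy-number collapse
of repeats (e.g. rDNA), chromatin context beyond the binary expression
classes, and any mechanistic link between AT and nucleosome biophysics.
Tests passing on this synthetic data demonstrate internal consistency of
the estimators and callers, not their accuracy on sequencing data.

## Fixture sizes and runtime choices

`build_fixture()` defaults — a 2-Mb four-chromosome donor at 62% AT (the
yeast-like composition), two high-AT islands, a 500-kb AC, and a 50-bp
signal bin — are chosen so the full chain (genome → digest → AC → signal)
builds in a few seconds and the entire test suite runs in under two
minutes on one CPU. The parameter-recovery experiment uses 50,000 candidate
draws, at which size the logistic fit recovers a planted $L_0 = 500$,
$s = 100$ comfortably within ±15%. The pool is restricted to fragments of
at least 30 bp with distinct sequences: below ~15 bp a random fragment
matches a 500-kb AC by chance, so exact-match classification is only
identifiable on a uniqueness-enforced pool.

## Quantifications

`fisher_exact_2x2()` uses the standard two-sided rule — the sum of
hypergeometric probabilities of all tables (fixed margins) at most as
probable as the observed one, with relative tolerance 1e-7 absorbing
floating-point ties (this is `stats::fisher.test`'s rule; the test suite
checks it against independent full enumeration). `segregation_rate()` adds
a Clopper–Pearson 95% interval to the raw rate — the interval is this
package's addition, as such rates are usually published as points with
test stars. Whether counts pooled across embryos are truly independent is
an upstream design question; this module treats each count as independent.
`ac_size()` and `copy_number()` are the one-line conversions they appear to
be, kept as functions so their assumptions (univalent vs bivalent ploidy;
a 2-copy reference locus) are explicit and testable.

## Known limitations

* Approximate-mode classification is a bounded-edit substring search, not a
  full local aligner; genuinely rearranged or heavily clipped matches need
  an external aligner, whose output can be post-processed with this
  module's thresholds.
* The simulator models neither replication, chromatinization, sequence
  error, nor meiotic loss; transmission and segregation enter only as
  observed counts.
* The relative frequency of HR vs NHEJ joins in vivo is unquantified;
  `p_hr` is a free parameter, defaulted to 0 on the strength of the
  absent-tandem-marker observation, not a measured rate.
* Headline numbers derived from deposited sequencing data (assembly N50s,
  real domain widths and occupancies) require the external
  mapping/assembly/peak-calling toolchain and are out of scope here; the
  package consumes those results as BED/TSV/FASTA inputs.
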