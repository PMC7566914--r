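---
title: "Locating plastid genes by qPCR and counting endosymbiotic transfers"
author: "petfloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating plastid genes by qPCR and counting endosymbiotic transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petfloc)
```

## The inference problem

Endosymbiotic gene transfer (EGT) relocates genes from the chloroplast
genome to the host nucleus. Because every cell carries one nuclear genome
but tens to hundreds of plastid genome copies, the compartment of a gene
leaves a quantitative fingerprint in genomic DNA: a nuclear-encoded gene
is present at roughly the copy number of a nuclear single-copy reference,
a plastid-encoded gene at that of a plastid single-copy reference.
`petfloc` turns that fingerprint into a per-strain verdict for a gene of
interest (the ferredoxin gene *petF* in the diatom genus *Thalassiosira*
is the motivating case), and then asks, across a wider taxonomy, how many
independent transfers the comparative presence/absence pattern requires.

## From fluorescence to Ct

A qPCR well produces a fluorescence trajectory `F_c` over cycles
`c = 1..C`. The model behind both the simulator and the Ct caller is

    F_c = baseline + min(N0 * E^c, plateau) * (1 + eps_c)

with starting template `N0`, per-cycle efficiency `E` (2.0 = perfect
doubling) and multiplicative noise `eps_c`. After subtracting the mean of
the first `baseline_cycles` (default 5) cycles, the threshold cycle Ct is
the fractional cycle where the curve first reaches a fixed threshold
(default 0.2 in baseline-corrected units).

**Interpolation is on the log scale.** Between the two bracketing cycles
the crossing is interpolated linearly in `log F`, not in `F`: the
exponential phase is log-linear, so log-scale interpolation recovers the
closed-form crossing `Ct = log_E(threshold / N0)` exactly on noiseless
curves, whereas linear interpolation on raw fluorescence is biased by up
to ~0.08 cycles at E = 2. When the lower bracketing value is non-positive
(possible after baseline subtraction) the caller falls back to linear
interpolation. Absolute Ct values remain instrument-relative — the
baseline convention and threshold units differ between instruments — so
only Ct differences (ΔCt) carry meaning, which is why the pipeline's
quantitative claims are all ΔCt-derived.

**Efficiency by window of linearity.** For quality control, each
reaction's efficiency is estimated by fitting `log10 F` against cycle
over every contiguous window of 4–6 points lying between a noise floor
(1% of the plateau, configurable) and half the plateau, keeping the
window with the highest r²; `E = 10^slope`. The 4–6-point window and the
floor/ceiling bounds are the package's own constants: they bracket the
informative exponential phase while excluding baseline noise and plateau
saturation. On noiseless curves the estimate is exact to machine
precision; with 2% multiplicative noise it is within ~0.05 of truth.

## The dual-reference classifier

For each strain, mean and sample SD of Ct are aggregated over replicates
(the assay design is triplicates of two biological replicates, n = 6).
Relative copy number against the nuclear reference is `2^ΔCt` with
`ΔCt = Ct(reference) − Ct(interest)`; the reference against itself is
exactly 1. Integer copy numbers are reported with round-half-up, matching
how such tables are conventionally printed.

The decision rule at level α:

1. gene of interest never amplified → `UNKNOWN`;
2. indistinguishable from the nuclear reference, different from the
   plastid one → `NUCLEAR_TRANSFER`;
3. the mirror image → `PLASTID_RETENTION`;
4. different from both → tie-break by log2 distance: with
   `d_nuc = |log2 fold_goi|` and `d_cp = |log2 fold_goi − log2 fold_cp|`,
   the smaller distance wins (`AMBIGUOUS` on an exact tie);
5. different from neither → `AMBIGUOUS`, with a reference-QC warning.

Choices worth making explicit:

* **α = 0.01 by default.** The published strain table this package
  reproduces marks p = 4.6e-3 as significant but p = 1.0e-2 and 1.5e-2
  as not, which brackets the level between those values; 0.01 is the
  conventional choice in that bracket and is exposed as an argument.
* **Paired vs summary-based tests.** With replicate-level Ct values the
  comparison is a paired two-sample t-test, pairing wells by (biological,
  technical) replicate index — the natural pairing on one plate run. From
  summary tables the pairing covariance is lost, so the package computes
  a Welch two-sample t from (mean, SD, n) with Welch–Satterthwaite
  degrees of freedom and labels the method accordingly; when a summary
  table carries externally computed p-values, those are used as given.
* **Degenerate comparisons.** Zero-variance comparisons (exactly
  identical replicates, as arise in noiseless simulations) report
  statistic 0 and p = 1 when the means agree, p = 0 otherwise, flagged
  `degenerate` — conservative, and it keeps noiseless end-to-end tests
  meaningful rather than producing NaN.
* **Reference QC.** The plastid reference must be enriched over the
  nuclear one (`fold_rbcS > 1`); if not, the plate violates the premise
  that plastid genomes outnumber nuclear ones and the strain is reported
  as a reference failure rather than classified.

## Sanger representatives

The assembler is a deliberate re-implementation of the
best-hit-extraction / assembly / longest-similar-representative procedure
as a self-contained, testable unit, not a wrapper around external
binaries. Reads are matched to references by local alignment
(`Biostrings::pairwiseAlignment`; nucleotide scoring +2/−3 with gap open
5 / extend 2, protein scoring BLOSUM62 with gap open 11 / extend 1), and
the best-hit region of each read is extracted; translated mode scans all
six frames, so the chain is strand-safe by construction. Significance is
a raw-score cutoff (40 nucleotide, 50 protein) rather than an e-value —
an e-value needs a database size, which a handful of packaged references
does not meaningfully have; at these cutoffs random 300–500-nt sequences
against unrelated references essentially never pass (seeded negative
controls in the test suite).

Assembly is greedy overlap-layout-consensus: repeatedly merge the pair of
contigs with the best ungapped suffix–prefix overlap (≥ 30 nt, identity
≥ 0.9, reverse complement allowed), consensus by per-column majority over
member reads with ties broken toward the longest member covering the
column. Inputs are canonically sorted first, so the result is independent
of input order. Majority consensus corrects substitution errors wherever
coverage is ≥ 3; columns covered by one or two reads retain the raw read
error rate, which is why the accuracy contract in the tests is stated on
repeated full-length runs of one amplicon (5× coverage) rather than on
thin staggered tilings. Frame determination translates the chosen contig
in six frames and picks the best protein hit; trimming then removes
leading residues up to the first Met (only when the sequence over-runs
the reference length, the signature of a mispredicted start) and a single
trailing `X`.

## Trees and transfer counting

Tree utilities delegate parsing, monophyly and node distances to `ape`
(with validation and classed errors layered on top): `path_length`
resolves selectors (tip label, `"root"`, or the MRCA of a tip set) so
both root-to-tip and clade-to-clade distances in substitutions per site
are one call; `remove_leading_columns` drops an N-terminal alignment
block (default 48 columns, the span typically covering plastid transit
peptides) while flagging rows that become all-gap; `flag_target_peptide`
is deliberately tri-state — PRESENT needs ≥ 10 leading residues starting
with Met (a plastid transit peptide shorter than that is implausible),
ABSENT means the sequence starts at the mature region, and everything
else (short or Met-less N-termini, as with truncated transcript models)
is INCONCLUSIVE rather than forced into a binary.

`min_transfer_events` counts transfers under Dollo parsimony: the
plastid-encoded state is ancestral (a PRESENT ancestor sits above the
root — the gene's cyanobacterial origin makes nucleus-to-plastid
back-transfer biologically implausible), loss is irreversible, and the
minimum number of loss events equals the number of maximal all-absent
clades, with a whole-absent tree counting as a single event on the root
stem. A brute-force enumerator over all internal labelings (feasible to
14 internal nodes) is shipped as an independent oracle and agrees
exhaustively on small trees. ABSENT here means "absent from the plastid
genome annotation": annotation false negatives inflate the count, and
that risk sits with the input, not the algorithm.

The packaged class-level scenario (`stramenopile_*_synthetic.*`) is a
constructed stand-in assembled from described class memberships, not a
copy of any deposited supplementary table — hence the `synthetic` suffix.
On it, three independent transfers are required: the diatom strain, the
two pelagophytes (one clade), and the brown alga each need one.

## What the simulators do and do not emulate

* `simulate_curve` / `simulate_plate` reproduce the statistical structure
  the analysis assumes: Normal per-well Ct noise around compartment-
  determined means (nuclear = 1 copy, plastid = the strain's plastid
  genome copy number, drawn 10–300 per cell), 2 biological × 3 technical
  replicates, optional biological-replicate shifts, optional full curves
  whose noiseless crossing matches the drawn Ct, and designated failed
  wells for primer-failure strains. Not emulated: primer-efficiency
  differences between genes, pipetting outliers, inter-plate calibration
  drift, melt-curve artefacts. Passing recovery tests therefore shows the
  decision logic is sound under the assay's assumed noise model, not that
  the wet-lab assay itself is robust to those unmodelled effects.
* `simulate_sanger_reads` draws evenly spaced, optionally
  reverse-complemented reads with independent substitution errors;
  chromatogram quality profiles, indels and vector contamination are out
  of scope.
* `simulate_loss_states` runs irreversible loss down a tree; the realized
  event count upper-bounds what parsimony can recover (equality whenever
  no loss nests inside another), which is exactly the tested contract.

All generators are reproducible from (configuration, seed) and restore
the caller's RNG state.

## Numerical choices and degenerate inputs

Round-half-up for printed copy numbers; log-scale crossing interpolation
with linear fallback; Welch p-values from `stats::pt`; no-amplification
is a value (`NA` Ct) that propagates to `UNKNOWN`, never an exception;
empty tables yield empty outputs; per-strain reference failures are
reported in-row while other strains still classify; alignment ties break
deterministically (score, then reference order, then leftmost start;
contig ties lexicographically).

Problem sizes used by the test suite and acceptance script — chosen as
comfortable desk-scale demonstrations: 200 simulated plates (4 strains
each) for classifier recovery, 50 consensus replicates on 400-nt
templates at 1% error, exhaustive Dollo state enumeration on trees of 4–8
tips plus 100 random 8-tip trees, and a 3 × 3 grid of (efficiency, N0)
for closed-form Ct recovery.

## Known limitations

* Absolute Ct values are not comparable across instruments; only
  ΔCt-derived quantities are asserted anywhere.
* Copy numbers rounded from *printed* mean Cts can differ by a few
  percent from values computed on unrounded means (e.g. a table printing
  129 where printed means give 137); the package asserts only the stable
  rows and documents the rest.
* The assembler is contract-compatible with, not bit-identical to,
  established assemblers; conflicting base calls resolve by majority, a
  stated assumption.
* Tree inference itself (alignment, model selection, bootstrap) is out
  of scope; published trees are consumed as newick. Deposited archives
  of third-party trees are not redistributed with the package, so
  root-to-tip checks on them require the user to supply the files.
* The t-tests apply no multiple-testing correction across strains,
  matching the assay design they reproduce.
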