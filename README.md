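# petfloc

Did a chloroplast gene move to the nucleus? `petfloc` infers the genomic
compartment of a plastid gene — here the ferredoxin gene *petF* of the
diatom genus *Thalassiosira* — from quantitative PCR evidence, and places
the inferred transfers in a phylogenetic context. It is aimed at molecular
evolution labs studying endosymbiotic gene transfer (EGT) who want the
analysis chain between raw instrument output and a per-strain verdict to
be scripted, tested and reproducible.

## The method

**Compartment calling by relative copy number.** Each strain is assayed by
qPCR for the gene of interest (*petF*) and two single-copy reference
genes: *tef1a* (nuclear) and *rbcS* (chloroplast-encoded; present at many
copies per cell because each cell carries many plastid genome copies).
With threshold cycles Ct measured at a fixed fluorescence threshold, the
relative copy number of gene *g* against the nuclear reference is

    ΔCt = Ct(tef1a) − Ct(g),        fold = 2^ΔCt

so a nuclear single-copy gene folds to ≈ 1 and a plastid-encoded gene to
the plastid genome copy number. The classifier compares *petF* against
both references with two-sample t-tests at level α (default 0.01): not
different from the nuclear reference but different from the plastid one ⇒
**nuclear transfer**; the mirror image ⇒ **plastid retention**; different
from both ⇒ a log2 magnitude tie-break toward the nearer copy number; no
amplification ⇒ **unknown**. Upstream, the package calls fractional Ct
values from raw amplification curves (baseline subtraction, threshold
crossing interpolated on the log scale) and estimates per-reaction
amplification efficiency E = 10^slope from the best log-linear window of
the exponential phase (window-of-linearity method).

**Counting independent transfers.** Presence/absence of the gene across
plastid genome annotations, placed on a rooted taxonomy with the
plastid-encoded state ancestral, is analysed under Dollo parsimony: the
state can be lost (transferred) but never regained. The minimum number of
independent transfer events equals the number of maximal all-absent
clades, and a brute-force enumerator over internal labelings serves as an
oracle for it.

**Sanger support.** A greedy overlap-layout-consensus assembler (with
best-hit region extraction against reference sequences, reading-frame
determination and N-terminal Met / trailing-X trimming) turns raw Sanger
reads into one representative nucleotide and protein sequence per strain;
newick utilities (monophyly tests, root-to-tip path lengths,
leading-column trimming, transit-peptide flagging) support the tree-based
arguments. Every input the pipeline consumes can be generated by the
package's seeded simulators, so all stages are testable without
laboratory data.

## Worked example

The packaged Ct summary table (12 *Thalassiosira* strains, mean ± SD over
triplicates of two biological replicates) runs through the classifier in
one call:

```r
library(petfloc)

summary_csv <- system.file("extdata", "thalassiosira_petf_ct_summary.csv",
                           package = "petfloc")
calls <- run_localization(read_summary_csv(summary_csv), alpha = 0.01)
calls[, c("strain", "status", "fold_goi", "fold_goi_rounded",
          "fold_cp_rounded", "tie_break_used")]
#>      strain            status fold_goi fold_goi_rounded fold_cp_rounded tie_break_used
#> 1  CCMP0999  NUCLEAR_TRANSFER     2.00                2              24           TRUE
#> 2  CCMP1001  NUCLEAR_TRANSFER     3.03                3             194          FALSE
#> 3  CCMP1005  NUCLEAR_TRANSFER     9.85               10             208           TRUE
#> 4  CCMP1006  NUCLEAR_TRANSFER     1.74                2              39          FALSE
#> 5  CCMP1010 PLASTID_RETENTION    24.25               24              23          FALSE
#> 6  CCMP1012 PLASTID_RETENTION     5.28                5               5          FALSE
#> 7  CCMP1013 PLASTID_RETENTION    18.38               18              17          FALSE
#> 8  CCMP1014 PLASTID_RETENTION     3.03                3               2          FALSE
#> 9  CCMP1049 PLASTID_RETENTION    25.99               26              26          FALSE
#> 10 CCMP1052 PLASTID_RETENTION   256.00              256             137           TRUE
#> 11 CCMP1335 PLASTID_RETENTION     6.96                7               6          FALSE
#> 12 CCMP1616           UNKNOWN       NA               NA              NA          FALSE
```

`fold_goi` is the 2^ΔCt copy number of *petF* relative to *tef1a*;
`fold_cp_rounded` the same for *rbcS*. The four *T. oceanica* strains
CCMP0999/1001/1005/1006 carry *petF* at near-nuclear copy number while
*rbcS* is 24–208-fold enriched — the signature of a nuclear transfer. The
*T. pseudonana* and *T. weissflogii* strains track the *rbcS* copy number
instead (plastid retention), and CCMP1616, where no primer pair
amplified, is honestly UNKNOWN.

Counting independent transfers across stramenopile classes from a
presence/absence screen of plastid genome annotations:

```r
tree   <- parse_newick(system.file("extdata",
            "stramenopile_classes_synthetic.nwk", package = "petfloc"))
states <- read_states_tsv(system.file("extdata",
            "stramenopile_petf_states_synthetic.tsv", package = "petfloc"))
scenario <- min_transfer_events(tree, states)
scenario$min_events
#> [1] 3
sapply(scenario$event_clades, paste, collapse = "+")
#> [1] "Thalassiosira_oceanica_CCMP1005"
#> [2] "Aureococcus_anophagefferens+Aureoumbra_lagunensis"
#> [3] "Pleurocladia_lacustris"
```

Under irreversible loss, at least three independent plastid-to-nucleus
transfers are required: one in the diatoms, one in the pelagophytes, one
in the brown algae.

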