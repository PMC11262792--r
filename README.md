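# mirTarScan

Hepatic miRNA studies of metabolic disease follow a recurring
computational path: profile liver miRNA expression in cases and controls,
screen for miRNAs associated with metabolic traits while excluding age-
and BMI-driven signals, check which hits are conserved between human and
mouse, predict and verify target-gene binding sites in 3'-UTRs, and
validate by qPCR. mirTarScan implements that whole layer as a tested R
package for researchers running or re-analysing such screens.

At its core is a canonical seed-match scanner. Numbering mature-miRNA
positions 1..n from the 5' end, the five site classes map to
target-strand motifs

* 8mer = revcomp(nt 2–8) + A, 7mer-m8 = revcomp(nt 2–8),
  7mer-A1 = revcomp(nt 2–7) + A, 6mer = revcomp(nt 2–7),
  offset-6mer = revcomp(nt 3–8),

ranked 8mer > 7mer-m8 > 7mer-A1 > 6mer > offset-6mer. Each detected site
is annotated with binding-context features (local AU content in the 60 nt
around the seed, 3'-supplementary pairing of miRNA nt 12–17, position in
the UTR, stop-codon proximity, cooperative neighbour sites). Around the
scanner sit modules for 7mer-seed conservation between species, a
validated-interaction store, the cohort association screen

    trait or T2D = b0 + b1*NAS + b2*age + b3*sex + b4*BMI + b5*log2(miRNA)

(linear/logistic, Wald test on b5, BH-FDR, confounder exclusion,
candidate selection), ΔΔCt qPCR quantification with a pooled 3-SD outlier
rule (fold = 2^(−ΔΔCt)), and seeded synthetic-data generators that plant
known sites, effect sizes and outliers for testing. See
`vignettes/mirTarScan-methods.Rmd` for the full model descriptions.

## Worked example

The LRP6 3'-UTR fragment used in reporter assays carries a single
7mer-m8 site for hsa-miR-182-5p; mutating the central seed C to A
removes it.

```r
library(mirTarScan)
mir  <- MiRNASet(c("hsa-miR-182-5p" = "UUUGGCAAUGGUAGAACUCACACU"))
utrs <- Biostrings::DNAStringSet(c(LRP6 = "ACGTACGTTGCCAATACGT"))
sites <- scanSeedSites(mir, utrs)
siteTable(sites)
#>   utr_id       mirna_id site_type start0 end0   motif                all_modes
#> 1   LRP6 hsa-miR-182-5p   7mer-m8      7   14 TTGCCAA 7mer-m8,6mer,offset-6mer
```

The site starts at 0-based position 7, its motif is the exact UTR
substring, and the locus also matches the nested 6mer and offset-6mer
classes. Context annotation adds the binding-condition features:

```r
ann <- annotateSites(sites, mir, utrs)
as.data.frame(S4Vectors::mcols(ann))[, c("local_au", "tp_pairing",
                                         "dist_stop", "rel_pos")]
#>   local_au tp_pairing dist_stop   rel_pos
#> 1      0.5          2         7 0.2631579
```

Half the flanking residues are A/T, a 2-bp supplementary run pairs 3' of
the seed, and the site sits 7 nt after the stop codon. A simulated qPCR
validation (40 vs 40 samples, true ΔΔCt −1.2) quantifies like this:

```r
ct  <- genCt(list(ND = c(5.0, 0.2, 40), T2D = c(3.8, 0.2, 40)), seed = 2)
foldChange(deltaCt(ct$ct, "target", "housekeeper"), reference = "ND")
#> ddCt fold changes (reference: ND)
#>  group  n mean_dct      ddct     fold
#>     ND 40 5.019518  0.000000 1.000000
#>    T2D 40 3.792296 -1.227222 2.341157
#> t-test: statistic = -24.179, p = 5.541e-38; 0 outlier(s) excluded
```

i.e. a 2.34-fold upregulation in the simulated diabetic group against a
planted truth of 2^1.2 ≈ 2.30.

A thin command-line wrapper covering scan/conserve/targets/associate/
qpcr/simulate lives at `inst/cli/mirtarscan`; every run writes a JSON
run-log with the tool version, full parameter set, input checksums and
seed.

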