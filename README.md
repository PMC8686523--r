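# qefs — quantitative enhancer reporter design, counting and epistasis analysis

`qefs` is an R package for the computational side of quantitative
enhancer-reporter experiments: designing libraries of barcoded enhancer
variants in which transcription-factor binding sites are combinatorially
destroyed, counting the paired RNA/DNA sequencing readout at the molecule
level, and testing motif effects and motif–motif epistasis.

## The problem

An enhancer's activity is shaped by the binding sites it contains, but
individual site knockouts cannot reveal how sites interact. The assay
modelled here builds, for each enhancer, the full `2^3` allelic series over
three motif classes: every combination of "all sites of class X destroyed by
minimal point substitutions". Each construct carries a neutral 8-mer barcode
and one or more degenerate 20-mer 3' UTR tags. Reporter mRNA (RNA library)
and integrated constructs (DNA library) are sequenced with 8-base unique
molecular identifiers (UMIs) on several days.

Expression of tag *t* on day *d* is the DNA-normalized RNA fraction

```
E(t, d) = [ UMI_RNA(t,d) / Σ_t' UMI_RNA(t',d) ] / [ UMI_DNA(t,d) / Σ_t' UMI_DNA(t',d) ]
```

which cancels both sequencing depth and the uneven abundance of each
construct in the cell pool. Tag × day values are biological replicates.
Allelic series are compared with the Kruskal–Wallis rank test followed by
Conover–Iman pairwise comparisons (Benjamini–Hochberg adjusted, working
alpha 0.1). For each motif pair, epistasis is tested against the
multiplicative null — `lm(log(y) ~ a * b)`, where a zero interaction
coefficient means the two mutations' fold changes simply multiply — and
significant deviations are classified as synergistic, sign, or one of
three alleviating patterns.

The package also contains a full synthetic-experiment simulator with
ground truth (design, activities, molecule counts, FASTQ-level reads with
PCR duplication and base errors), used for its own validation.

See the vignette source (`vignettes/qefs-methods.Rmd`) for the methods in
detail and the rationale behind every default.

## Worked example

Design a 4-enhancer library with one planted synergistic interaction,
simulate a sequencing run, and recover the interaction:

```r
library(qefs)

pwms <- qefsToyPWMs()
classes <- vapply(pwms[1:3], function(p) p@name, character(1))
pair <- sort(classes[1:2])
planted <- data.frame(enhancer_id = "ENH001", class_a = pair[1],
                      class_b = pair[2], effect = -log(4))

truth <- simulateDesign(nEnhancers = 4, tagsPerConstruct = c(4, 4),
                        interactions = planted, seed = 1)
sim     <- simulateReads(truth, depthPerTag = 200, days = 3, seed = 2)
counted <- countExperiment(sim, truth$constructs)
res     <- analyzeExperiment(counted$counts, truth$motifClasses)

head(res$foldChanges)
#>          enhancer_id               allele fold_change         sem n_obs
#> ENH001.1      ENH001               motifA  0.31199986 0.025240909    12
#> ENH001.2      ENH001        motifA+motifB  0.04092344 0.003913996    12
#> ENH001.3      ENH001 motifA+motifB+motifC  0.02499589 0.003328993    12
#> ENH001.4      ENH001        motifA+motifC  0.22219796 0.015026785    12
#> ENH001.5      ENH001               motifB  0.50950535 0.034103481    12
#> ENH001.6      ENH001        motifB+motifC  0.33523724 0.029245409    12

subset(res$epistasis, enhancer_id == "ENH001")
#>          enhancer_id motif_a motif_b interaction_coef interaction_p    category
#> ENH001.1      ENH001  motifA  motifB      -1.37690642  2.272901e-13 synergistic
#> ENH001.2      ENH001  motifA  motifC      -0.04677734  6.836100e-01        none
#> ENH001.3      ENH001  motifB  motifC      -0.15045711  2.289045e-01        none
```

The planted interaction of `-log(4) = -1.386` is recovered as `-1.377`
and classified synergistic; the two unplanted pairs come out `none`.
`res$expression` holds the per-tag-day expression values,
`res$dropLog` every record removed by the QC gates (minimum 65 DNA UMIs
per tag-day, then minimum 4 tags per construct) and why, and
`res$series` the rank-test results per enhancer.

## Package tour

| Stage | Key functions |
|---|---|
| Barcode design | `designBarcodes`, `filterByEscore`, `filterByPWM`, `selectHammingSet` |
| Motif scanning | `readPWM`, `scanPWM`, `occupancyScore`, `filterSitesByOccupancy` |
| Mutagenesis | `designMutation`, `applyEdits`, `buildAllelicSeries`, `constructSequence` |
| Lookup table | `parseLookupReads`, `buildLookup`, `writePseudoGenome` |
| Tag counting | `extractUmi`, `trimConstantRegions`, `assignTag`, `countTags` |
| Quantification | `normalizeExpression`, `qcFilter`, `aggregateReplicates`, `foldChange` |
| Statistics | `kruskalWallis`, `conoverIman`, `bhAdjust`, `epistasisTest`, `classifyEpistasis`, `epistasisScan` |
| Simulation | `simulateDesign`, `simulateReads`, `truthTable` |
| Orchestration | `countExperiment`, `analyzeExperiment` |

A small command-line front end for barcode design is installed as
`exec/qefs` (`qefs design-barcodes --n 96 --out barcodes.tsv`).

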