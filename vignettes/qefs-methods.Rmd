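---
title: "Quantitative enhancer reporter analysis with qefs: methods and design choices"
author: "qefs package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative enhancer reporter analysis with qefs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# Overview

`qefs` implements the computational side of a quantitative
enhancer-reporter assay: a library of barcoded enhancer variants, each
carrying a combinatorial set of destroyed transcription-factor binding
sites, is read out by paired RNA-seq and DNA-seq of degenerate 3' UTR
tags, and per-variant expression is tested for motif effects and pairwise
motif epistasis. The package covers seven stages:

1. **Barcode design** — neutral 8-mer enhancer barcodes.
2. **Motif mutagenesis** — PWM scanning and minimal site-destroying edits.
3. **Allelic series construction** — the $2^3$ combinatorial library.
4. **Lookup table building** — associating degenerate tags with constructs.
5. **Tag counting** — UMI-deduplicated RNA/DNA tag quantification.
6. **Expression quantification** — DNA-normalized expression with QC gates.
7. **Statistics** — rank-based series testing and multiplicative epistasis.

A complete synthetic-experiment simulator with ground truth
(`simulateDesign()`, `simulateReads()`) supports end-to-end validation
without any external data.

# The measurement model

Each construct $c$ carries a known 8-mer barcode and one or more unknown
degenerate 20-mer tags in its 3' UTR. Sequencing the reporter mRNA pool
(RNA) and the integrated construct pool (DNA) and counting distinct
unique molecular identifiers (UMIs) per tag gives molecule-level counts
$\mathrm{UMI}_\mathrm{RNA}(t,d)$ and $\mathrm{UMI}_\mathrm{DNA}(t,d)$ for
tag $t$ on collection day $d$. Expression is the depth-normalized RNA
fraction over the depth-normalized DNA fraction:

$$E(t, d) \;=\;
\frac{\mathrm{UMI}_\mathrm{RNA}(t,d) \,/\, \sum_{t'} \mathrm{UMI}_\mathrm{RNA}(t',d)}
     {\mathrm{UMI}_\mathrm{DNA}(t,d) \,/\, \sum_{t'} \mathrm{UMI}_\mathrm{DNA}(t',d)}.$$

Dividing by the DNA fraction cancels the (uneven) abundance of each
construct in the cell population; dividing each count by its library
total cancels sequencing depth. `normalizeExpression()` implements this
exactly and is therefore invariant to rescaling either library's depth —
a property the test suite asserts. Tags with zero DNA evidence on a day
yield no estimate (the denominator is undefined); tags present in DNA but
absent from RNA score 0.

## Quality control

Two gates run in a fixed order (`qcFilter()`):

* **DNA evidence gate** (default `minDnaPerTagDay = 65`): a (tag, day)
  cell with fewer than 65 distinct DNA UMIs has too noisy a denominator
  and is removed. The gate applies to UMI counts by default because those
  are the molecule-level quantities used in the ratio; `gateOn = "reads"`
  is available when raw read depth is the preferred evidence.
* **Tag replication gate** (default `minTagsPerConstructWeek = 4`): a
  construct whose surviving tags across the aggregated week number fewer
  than 4 lacks internal replication and is removed entirely.

The order matters: a construct can pass the tag gate before the DNA gate
but not after, so the DNA gate always runs first. Every removed record is
returned in a drop log with the rule that removed it.

## Replicates

All (tag × day) expression values of a construct in one week are treated
as biological replicates — three tags observed on three days give nine
observations (`aggregateReplicates()`). Fold changes versus the wildtype
construct propagate the standard errors of both means
(`foldChange()`).

# Statistical testing

Within one enhancer's allelic series the observations are compared with
the **Kruskal–Wallis** rank test (tie-corrected, $\chi^2$ approximation).
Only when the omnibus test rejects at the working $\alpha$ (default 0.1)
are **Conover–Iman** pairwise comparisons computed on the shared ranks:

$$t_{ij} = \frac{\bar R_i - \bar R_j}
{\sqrt{S^2 \cdot \frac{N - 1 - H}{N - k}\left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},$$

with $S^2$ the tie-adjusted rank variance, $H$ the Kruskal–Wallis
statistic, and Student's $t$ with $N-k$ degrees of freedom. The pairwise
p-values are Benjamini–Hochberg adjusted as one family per series. The
rank tests were chosen because per-tag expression ratios are heavy-tailed
at moderate depth; the test suite validates both statistics against
independent from-scratch implementations and the Kruskal–Wallis p-value
against a permutation null.

## Epistasis

For each motif-class pair (A, B) the four cells WT, A, B, AB are fit on
the log scale by `lm(log(y) ~ a * b)` (`epistasisTest()`). Under the
multiplicative null — each mutation contributing a constant fold change —
the interaction coefficient is 0; in the balanced case it equals
$\overline{\log AB} - \overline{\log A} - \overline{\log B} +
\overline{\log WT}$. Zeros are floored to half the smallest positive
observation before the transform. Significant interactions are
classified (`classifyEpistasis()`) into:

* **synergistic** — the double mutant exceeds the multiplicative
  prediction in the same direction;
* **sign** — one motif's effect direction reverses in the other
  mutation's context;
* **alleviating-complementary** — weaker than predicted and the double is
  indistinguishable from both singles;
* **alleviating-complete-suppression** — the double equals the milder
  single and differs from the stronger one;
* **alleviating** — weaker than predicted but matching neither
  sub-pattern. This residual category is deliberate: the two named
  alleviating sub-patterns do not partition the alleviating region, and
  silently forcing borderline cases into one of them would misreport
  them.

Severity equality is operationalized as Conover–Iman non-significance,
so classifications inherit the series-level error control.

# Library design

## Barcodes

`designBarcodes()` enumerates all $4^8$ 8-mers, removes any with
protein-binding-microarray evidence (E-score $> 0.3$, orientation
symmetric — a k-mer and its reverse complement are the same binding
word), removes any scoring above threshold against a PWM panel on either
strand, and finally greedily selects a set with pairwise Hamming distance
$\ge 3$, *including each member's reverse complement* (the barcode also
appears reverse-complemented in the construct). Distance 3 means no
single sequencing error can convert one valid barcode into another, and
1-mismatch correction is unambiguous. The greedy scan order is the
lexicographic input order, making the design deterministic.

## Site destruction

`scanPWM()` scores every window on both strands with the
log-likelihood ratio $\sum_i \log(p_i(b)/\mathrm{bg}(b))$ in nats and
calls sites above 6 (roughly 400-fold likelihood over background). Each
site also gets a **relative occupancy**
$\prod_i p_i(b_i) / p_i(b_i^*)$ — predicted affinity relative to the
optimal site, equal to 1 at the consensus and independent of the
background model. Occupancy is the right filter for long degenerate
motifs, which pass fixed LLR cutoffs with many weak matches
(`filterSitesByOccupancy()`).

`designMutation()` searches substitution sets of sizes 1, 2, 3
exhaustively (smallest first) for the edit that (a) drops the site window
below the calling threshold on both strands, (b) creates no new site of
the target or any guard motif nearby — an edit can otherwise re-create
the same motif at a shifted offset — and (c) destroys no pre-existing
overlapping guard site. Ties are broken by largest score drop, then
leftmost positions, then alphabetical base, so designs are reproducible.
Coordinates throughout the package are 1-based and inclusive, matching R
conventions.

`buildAllelicSeries()` expands each enhancer into all $2^3$ combinations
of the three per-class edit sets (which must not overlap), assigning one
barcode per construct.

# Tag counting

The lookup library pairs each barcode with its construct's tags;
`parseLookupReads()` locates the two constant anchors (1 mismatch each by
default), enforces the 8-base spacing, and excises barcode and tag.
`buildLookup()` accepts a pair when it is pre-validated or its count
reaches `minFrac` (default 0.1) of that barcode's top tag — an absolute
count threshold would depend on depth, whereas a fraction of the top tag
adapts per barcode; 0.1 sits well below the count of a true tag at
realistic per-construct tag numbers and well above sequencing-error
satellites. Tags accepted for two or more barcodes are presumed chimeras
and dropped entirely.

Reporter reads are `8-base UMI + constant + tag + constant`.
`trimConstantRegions()` implements two-pass adapter removal natively: a
non-anchored 5' adapter (leftmost exact occurrence, else leftmost within
`floor(0.3 × length)` mismatches, removed together with everything 5' of
it; pass-through when absent), then the symmetric 3' trim. Partial
adapter overlap hanging off read ends is not searched; such rare reads
fail the downstream length or assignment gates instead. `assignTag()`
assigns each trimmed candidate to the unique lookup tag within 2
mismatches (ties are ambiguous and unassigned; candidates more than 2 nt
from the tag length are rejected). UMIs are deduplicated by exact
sequence per (tag, library, day); an optional Hamming-1 collapse is off
by default because at moderate depth exact deduplication loses almost
nothing while the collapse can merge genuinely distinct molecules.

# The simulator

`simulateDesign()` draws random enhancers, plants non-overlapping
near-consensus sites for three motif classes, runs the package's own
mutagenesis to destroy them class-by-class (guarding the other classes),
expands the allelic series with designed barcodes, and assigns unique
random 20-mer tags. Ground truth activities are exactly multiplicative
over per-class log effects (lognormal around a 2-fold reduction by
default) plus any planted pairwise interaction terms; per-construct
abundances are Dirichlet (concentration 5 — moderately uneven, as in
real pooled libraries).

`simulateReads()` draws, per tag and day, Poisson DNA molecule counts
proportional to abundance and Poisson RNA counts additionally scaled by
activity and a lognormal biological noise term (coefficient of variation
0.2 by default). Every molecule gets a random UMI and `1 + Geometric`
PCR duplicates; every read receives iid substitution errors (0.005 per
base). The simulator deliberately omits indels, quality-score structure,
PCR chimeras and UMI errors: it is a calibration instrument for the
counting and inference machinery, not a sequencer emulator.

A note on validation design: the end-to-end acceptance checks fix **one**
design and repeat only the sequencing + analysis stage across runs. This
isolates the measurement pipeline's variance from design variance; design
feasibility is exercised separately.

# Worked example

```{r example, eval = FALSE}
library(qefs)

## design: 4 enhancers x 8 alleles, one planted synergistic interaction
pwms <- qefsToyPWMs()
classes <- names(pwms)[1:3]
planted <- data.frame(enhancer_id = "ENH001",
                      class_a = sort(classes[1:2])[1],
                      class_b = sort(classes[1:2])[2],
                      effect = -log(4))
truth <- simulateDesign(nEnhancers = 4, tagsPerConstruct = c(4, 4),
                        interactions = planted, seed = 1)

## sequence and count
sim <- simulateReads(truth, depthPerTag = 200, days = 3, seed = 2)
counted <- countExperiment(sim, truth$constructs)

## quantify and test
res <- analyzeExperiment(counted$counts, truth$motifClasses)
subset(res$epistasis, enhancer_id == "ENH001")
```

The `res$epistasis` table reports the interaction coefficient (log
scale), its p-value and the category per motif pair and enhancer;
`res$foldChanges` the per-allele fold changes with propagated standard
errors; `res$dropLog` every record removed by QC and why.

# Defaults at a glance

| Parameter | Default | Rationale |
|---|---|---|
| site LLR threshold | 6 nats | ~400:1 likelihood over background |
| barcode width / distance | 8 / 3 | 1-error correction incl. reverse complements |
| E-score cutoff | 0.3 | standard PBM evidence-of-binding bound |
| max substitutions per site | 3 | smallest edit preserving local context |
| anchor mismatches (lookup) | 1 | barcodes are distance ≥ 3 apart |
| adapter error rate | 0.3 | tolerant trim; errors caught downstream |
| tag assignment mismatches | 2 | unique-minimum rule resolves errors |
| `minFrac` (lookup) | 0.1 | separates true tags from error satellites |
| DNA UMIs per tag-day | 65 | stable Eq. denominator |
| tags per construct-week | 4 | minimum internal replication |
| working alpha | 0.1 | screening-stage error control |
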