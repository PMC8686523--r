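#' Count all libraries of a simulated (or real) experiment
#'
#' Builds the lookup table from the lookup reads and counts every RNA/DNA
#' library against it, returning one combined [UmiCountTable-class].
#'
#' @param sim a [simulateReads()] result, or a list with elements `lookup`,
#'   `rna`, `dna` (read vectors / per-day lists of read vectors or FASTQ
#'   paths).
#' @param design construct design data.frame (e.g. `truth$constructs`).
#' @param lutStructure lookup read structure ([lookupStructure()]).
#' @param expected optional known barcode-tag pairs for [buildLookup()].
#' @param minFrac lookup acceptance threshold (default 0.1).
#' @param ... passed to [countTags()] (adapters, mismatch tolerance, ...).
#' @return list with `lut` (the [LookupTable-class]), `counts`
#'   ([UmiCountTable-class]) and `summaries` (per-library reject tallies).
#' @export
countExperiment <- function(sim, design, lutStructure = lookupStructure(),
                            expected = NULL, minFrac = 0.1, ...) {
  parsed <- parseLookupReads(sim$lookup, lutStructure)
  lut <- buildLookup(parsed$pairs, design, expected = expected,
                     minFrac = minFrac)
  tabs <- list()
  summaries <- list()
  for (d in seq_along(sim$dna)) {
    for (lib in c("DNA", "RNA")) {
      reads <- if (lib == "DNA") sim$dna[[d]] else sim$rna[[d]]
      res <- countTags(reads, lut, library = lib, day = d, ...)
      tabs[[length(tabs) + 1L]] <- res$counts
      summaries[[paste0(lib, "_day", d)]] <- res$summary
    }
  }
  list(lut = lut, counts = combineCounts(tabs), summaries = summaries)
}

#' Quantify and test a counted experiment
#'
#' Runs Eq.-style DNA normalization, the QC gates, replicate aggregation,
#' per-enhancer fold changes and the full allelic-series + epistasis testing.
#'
#' @param counts a [UmiCountTable-class].
#' @param motifClasses the 3 mutated motif class names.
#' @param minDnaPerTagDay,minTagsPerConstructWeek QC thresholds (defaults 65
#'   and 4, see [qcFilter()]).
#' @param alpha significance level (default 0.1).
#' @param adjustInteraction see [epistasisScan()].
#' @return list with `expression`, `dropLog`, `foldChanges` (all enhancers),
#'   `series` (per-enhancer [runAllelicSeries()] results) and `epistasis`
#'   (combined [epistasisScan()] table).
#' @export
analyzeExperiment <- function(counts, motifClasses, minDnaPerTagDay = 65L,
                              minTagsPerConstructWeek = 4L, alpha = 0.1,
                              adjustInteraction = FALSE) {
  expr <- normalizeExpression(counts)
  qc <- qcFilter(expr, minDnaPerTagDay, minTagsPerConstructWeek)
  fcs <- list()
  series <- list()
  epi <- list()
  for (enh in unique(qc$expr$enhancer_id)) {
    sub <- qc$expr[qc$expr$enhancer_id == enh, , drop = FALSE]
    obs <- aggregateReplicates(sub, by = "allele")
    if (length(obs) >= 2L) {
      series[[enh]] <- runAllelicSeries(obs, enh, alpha)
      epi[[enh]] <- epistasisScan(obs, motifClasses, enh, alpha,
                                  adjustInteraction)
    }
    fc <- suppressWarnings(seriesFoldChanges(obs, enh))
    if (!is.null(fc)) fcs[[enh]] <- fc
  }
  list(expression = qc$expr, dropLog = qc$dropLog,
       foldChanges = do.call(rbind, c(fcs, list(NULL))),
       series = series,
       epistasis = do.call(rbind, c(epi, list(NULL))))
}
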