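#' DNA-normalized expression per tag
#'
#' For each collection day, each tag's distinct-UMI count is converted to a
#' library fraction (scaling for sequencing depth), and the RNA fraction is
#' divided by the paired DNA fraction (scaling reporter signal to construct
#' abundance in the population):
#'
#' expression(tag) = (UMI_RNA(tag) / sum UMI_RNA) / (UMI_DNA(tag) / sum UMI_DNA)
#'
#' Tags with zero DNA UMIs on a day yield no record (tallied in the `zero_dna`
#' attribute); tags absent from the RNA library but present in DNA get
#' expression 0.
#'
#' @param counts a [UmiCountTable-class] containing both RNA and DNA rows.
#' @param days which collection days to process (default: all days present).
#' @return data.frame with columns `enhancer_id`, `allele`, `barcode`, `tag`,
#'   `day`, `umi_rna`, `umi_dna`, `expression`; attribute `zero_dna` counts
#'   RNA-only tags skipped per day.
#' @export
normalizeExpression <- function(counts, days = NULL) {
  cc <- umiCounts(counts)
  if (is.null(days)) days <- sort(unique(cc$day))
  out <- list()
  zeroDna <- setNames(integer(length(days)), as.character(days))
  for (d in days) {
    rna <- cc[cc$library == "RNA" & cc$day == d, , drop = FALSE]
    dna <- cc[cc$library == "DNA" & cc$day == d, , drop = FALSE]
    if (!nrow(dna))
      stop("no paired DNA library for day ", d, call. = FALSE)
    if (!nrow(rna))
      stop("no RNA library for day ", d, call. = FALSE)
    rnaTot <- sum(rna$umi_count)
    dnaTot <- sum(dna$umi_count)
    m <- match(dna$tag, rna$tag)
    umiRna <- ifelse(is.na(m), 0L, rna$umi_count[m])
    zeroDna[as.character(d)] <- sum(!(rna$tag %in% dna$tag))
    out[[length(out) + 1L]] <- data.frame(
      enhancer_id = dna$enhancer_id, allele = dna$allele,
      barcode = dna$barcode, tag = dna$tag, day = d,
      umi_rna = umiRna, umi_dna = dna$umi_count,
      expression = (umiRna / rnaTot) / (dna$umi_count / dnaTot),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "zero_dna") <- zeroDna
  res
}

#' Quality-control filters on expression records
#'
#' Two gates, applied in this fixed order: (1) every (tag, day) cell whose
#' DNA evidence is below `minDnaPerTagDay` is removed; (2) every construct
#' whose surviving number of distinct tags across the aggregated week is
#' below `minTagsPerConstructWeek` is removed entirely. The DNA gate applies
#' to distinct DNA UMIs by default (`gateOn = "umi"`, the molecule-level
#' counts all downstream arithmetic uses); `gateOn = "reads"` gates on raw
#' DNA read counts instead, in which case `counts` must be supplied.
#'
#' @param expr expression records from [normalizeExpression()].
#' @param minDnaPerTagDay minimum DNA evidence per tag per day (default 65).
#' @param minTagsPerConstructWeek minimum distinct surviving tags per
#'   construct across the week (default 4).
#' @param gateOn "umi" (default) or "reads".
#' @param counts the [UmiCountTable-class], required when `gateOn = "reads"`.
#' @return list with `expr` (surviving records) and `dropLog` (data.frame
#'   `construct`, `tag`, `day`, `rule`).
#' @export
qcFilter <- function(expr, minDnaPerTagDay = 65L,
                     minTagsPerConstructWeek = 4L,
                     gateOn = c("umi", "reads"), counts = NULL) {
  gateOn <- match.arg(gateOn)
  dnaEvidence <- if (gateOn == "umi") {
    expr$umi_dna
  } else {
    if (is.null(counts)) stop("gateOn = 'reads' requires `counts`")
    cc <- umiCounts(counts)
    dna <- cc[cc$library == "DNA", , drop = FALSE]
    dna$read_count[match(paste(expr$tag, expr$day),
                         paste(dna$tag, dna$day))]
  }
  lowDna <- dnaEvidence < minDnaPerTagDay
  dropLog <- data.frame(construct = constructKey(expr)[lowDna],
                        tag = expr$tag[lowDna], day = expr$day[lowDna],
                        rule = rep("min_dna_per_tag_day", sum(lowDna)),
                        stringsAsFactors = FALSE)
  expr <- expr[!lowDna, , drop = FALSE]

  key <- constructKey(expr)
  tagsPer <- tapply(expr$tag, key, function(x) length(unique(x)))
  lowTags <- key %in% names(tagsPer)[tagsPer < minTagsPerConstructWeek]
  dropLog <- rbind(dropLog,
                   data.frame(construct = key[lowTags],
                              tag = expr$tag[lowTags],
                              day = expr$day[lowTags],
                              rule = rep("min_tags_per_construct_week",
                                         sum(lowTags)),
                              stringsAsFactors = FALSE))
  expr <- expr[!lowTags, , drop = FALSE]
  rownames(expr) <- NULL
  list(expr = expr, dropLog = dropLog)
}

#' Aggregate expression records into replicate observation vectors
#'
#' All (tag x day) expression values for a construct within the aggregated
#' week are treated as independent biological replicates: three tags observed
#' on three days give nine observations.
#'
#' @param expr QC-filtered expression records.
#' @param by group by full construct key (`"construct"`, default) or by
#'   allele only within one enhancer (`"allele"`).
#' @return named list of numeric observation vectors.
#' @export
aggregateReplicates <- function(expr, by = c("construct", "allele")) {
  by <- match.arg(by)
  key <- if (by == "construct") constructKey(expr) else expr$allele
  split(expr$expression, key)
}

#' Fold change of a mutant construct relative to wildtype
#'
#' FC = mean(mutant) / mean(wildtype), with the standard error propagated
#' from the two means: sem = FC * sqrt((sem_mut/mean_mut)^2 +
#' (sem_wt/mean_wt)^2), where sem_x = sd(x)/sqrt(n). A single observation
#' contributes sem 0 for its term.
#'
#' @param mutObs,wtObs numeric observation vectors (non-empty;
#'   `mean(wtObs) > 0`).
#' @return list with `fold_change`, `sem`, `n_obs` (mutant observations).
#' @export
foldChange <- function(mutObs, wtObs) {
  stopifnot(length(mutObs) >= 1L, length(wtObs) >= 1L)
  mWt <- mean(wtObs)
  if (!(mWt > 0)) stop("wildtype mean must be positive")
  mMut <- mean(mutObs)
  semOf <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  fc <- mMut / mWt
  relMut <- if (mMut > 0) semOf(mutObs) / mMut else 0
  sem <- fc * sqrt(relMut^2 + (semOf(wtObs) / mWt)^2)
  list(fold_change = fc, sem = sem, n_obs = length(mutObs))
}

#' Fold changes across one enhancer's allelic series
#'
#' @param obsByAllele named list of observation vectors (names are alleles,
#'   one must be `wtAllele`).
#' @param enhancerId enhancer name for the output.
#' @param wtAllele name of the wildtype allele (default "WT").
#' @return data.frame `enhancer_id`, `allele`, `fold_change`, `sem`, `n_obs`;
#'   NULL (with a warning) if the wildtype failed QC, since no fold change is
#'   defined for the series.
#' @export
seriesFoldChanges <- function(obsByAllele, enhancerId = "enhancer",
                              wtAllele = "WT") {
  if (!wtAllele %in% names(obsByAllele)) {
    warning("wildtype construct absent (failed QC); fold changes undefined ",
            "for ", enhancerId)
    return(NULL)
  }
  wt <- obsByAllele[[wtAllele]]
  rows <- lapply(names(obsByAllele), function(a) {
    fc <- foldChange(obsByAllele[[a]], wt)
    data.frame(enhancer_id = enhancerId, allele = a,
               fold_change = fc$fold_change, sem = fc$sem, n_obs = fc$n_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
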