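#' Split UMIs off the 5' end of reads
#'
#' The first `umiLen` bases of each read are the unique molecular identifier;
#' the remainder carries the constant regions and the reporter tag. Reads not
#' longer than `umiLen` are rejected and tallied.
#'
#' @param reads character vector or `DNAStringSet`.
#' @param umiLen UMI width (default 8; 0 is the identity transform).
#' @return list with `umi` (character), `rest` (character), `keep` (indices
#'   of retained reads) and `n_rejected`.
#' @export
extractUmi <- function(reads, umiLen = 8L) {
  reads <- as.character(reads)
  if (umiLen == 0L) {
    return(list(umi = rep("", length(reads)), rest = reads,
                keep = seq_along(reads), n_rejected = 0L))
  }
  keep <- which(nchar(reads) > umiLen)
  list(umi = substr(reads[keep], 1L, umiLen),
       rest = substr(reads[keep], umiLen + 1L, nchar(reads[keep])),
       keep = keep,
       n_rejected = length(reads) - length(keep))
}

#' Trim the constant regions flanking the reporter tag
#'
#' Native implementation of the two-step adapter trim: first a 5' adapter
#' (non-anchored `-g` semantics: a full-length occurrence -- the leftmost
#' exact one, else the leftmost with at most
#' `floor(errorRate * nchar(adapter))` mismatches -- is removed together
#' with everything 5' of it; if absent the read passes through untrimmed),
#' then a 3' adapter (`-a` semantics: the occurrence found by the same rule
#' and everything 3' of it are removed; absent means untrimmed at that end).
#' Products shorter than `minLen` are rejected. Partial adapter overlap
#' hanging off a read end is not searched; such reads stay untrimmed on that
#' end and are typically caught downstream by the length and assignment
#' gates.
#'
#' @param reads character vector (UMI already removed).
#' @param fiveAdapter,threeAdapter constant sequences (defaults are the
#'   reporter-tag flanks used by the simulator).
#' @param errorRate maximum error fraction of the adapter match
#'   (default 0.3).
#' @param minLen minimum retained product length (default 10).
#' @return list with `tag` (trimmed candidates), `keep` (indices into
#'   `reads`) and `n_rejected_length`.
#' @export
trimConstantRegions <- function(reads,
                                fiveAdapter = "CGCGGGATGCTAGCACGCGG",
                                threeAdapter = "ACATATAGGACCAG",
                                errorRate = 0.3, minLen = 10L) {
  stopifnot(nchar(fiveAdapter) > 0L, nchar(threeAdapter) > 0L)
  reads <- as.character(reads)
  mm5 <- floor(errorRate * nchar(fiveAdapter))
  mm3 <- floor(errorRate * nchar(threeAdapter))

  s5 <- findAnchor(reads, fiveAdapter, mm5)
  out <- reads
  hit5 <- !is.na(s5)
  out[hit5] <- substr(reads[hit5], s5[hit5] + nchar(fiveAdapter),
                      nchar(reads[hit5]))

  s3 <- findAnchor(out, threeAdapter, mm3)
  hit3 <- !is.na(s3)
  out[hit3] <- substr(out[hit3], 1L, s3[hit3] - 1L)

  keep <- which(nchar(out) >= minLen)
  list(tag = out[keep], keep = keep,
       n_rejected_length = length(reads) - length(keep))
}

#' Assign trimmed tag candidates to lookup-table tags
#'
#' Mismatch-tolerant demultiplexing: a candidate is assigned to the unique
#' lookup tag within Hamming distance `maxMismatch`; if two or more tags tie
#' at the minimum distance the read is ambiguous and left unassigned.
#' Candidates whose length differs from the tag length by more than 2 are
#' unassigned (`length`); candidates 1-2 nt short are compared against tag
#' prefixes of the candidate length, candidates 1-2 nt long by their own
#' prefix of tag length.
#'
#' @param candidates character vector of trimmed tag candidates.
#' @param lut a [LookupTable-class].
#' @param maxMismatch maximum Hamming distance (default 2).
#' @return list with `tag` (assigned lookup tag or NA per candidate) and
#'   `reason` (factor: `assigned`, `no_hit`, `ambiguous`, `length`).
#' @export
assignTag <- function(candidates, lut, maxMismatch = 2L) {
  tags <- lookupTags(lut)
  stopifnot(length(tags) > 0L)
  tagLen <- unique(nchar(tags))
  if (length(tagLen) != 1L) stop("lookup tags must have one common length")
  n <- length(candidates)
  assigned <- rep(NA_character_, n)
  reason <- rep("no_hit", n)

  lenOK <- abs(nchar(candidates) - tagLen) <= 2L
  reason[!lenOK] <- "length"

  ## compare at a common width: short candidates vs tag prefixes, long
  ## candidates truncated to tag length
  for (L in unique(nchar(candidates[lenOK]))) {
    idx <- which(lenOK & nchar(candidates) == L)
    cmpLen <- min(L, tagLen)
    cand <- substr(candidates[idx], 1L, cmpLen)
    tcmp <- substr(tags, 1L, cmpLen)
    ucand <- unique(cand)
    utag <- rep(NA_character_, length(ucand))
    ureason <- rep("no_hit", length(ucand))
    if (cmpLen == tagLen && !anyDuplicated(tcmp)) {
      ## exact fast path: full-length comparison, tags unique by invariant
      exact <- match(ucand, tcmp)
      hit <- !is.na(exact)
      utag[hit] <- tags[exact[hit]]
      ureason[hit] <- "assigned"
    } else {
      ## truncated comparison: prefixes may collide, go through distances
      hit <- rep(FALSE, length(ucand))
    }
    if (any(!hit) && maxMismatch > 0L) {
      d <- hammingMatrix(ucand[!hit], tcmp)
      dmin <- apply(d, 1L, min)
      nmin <- rowSums(d == dmin)
      ok <- dmin <= maxMismatch & nmin == 1L
      amb <- dmin <= maxMismatch & nmin > 1L
      sub <- which(!hit)
      utag[sub[ok]] <- tags[apply(d[ok, , drop = FALSE], 1L, which.min)]
      ureason[sub[ok]] <- "assigned"
      ureason[sub[amb]] <- "ambiguous"
    }
    m <- match(cand, ucand)
    assigned[idx] <- utag[m]
    reason[idx] <- ureason[m]
  }
  list(tag = assigned,
       reason = factor(reason,
                       levels = c("assigned", "no_hit", "ambiguous",
                                  "length")))
}

#' Count reads and distinct UMIs per tag
#'
#' Exact-sequence UMI deduplication: for every (tag, library, day) the read
#' count is the number of assigned reads and the UMI count the number of
#' distinct UMI sequences. Order-invariant. An optional Hamming-1 collapse
#' (`collapseUmis = TRUE`) additionally merges UMIs one mismatch apart
#' (greedily, by descending read support) to absorb sequencing errors in the
#' UMI itself; it is off by default.
#'
#' @param assignments data.frame with columns `tag`, `umi`, `library`, `day`
#'   (one row per assigned read).
#' @param lut a [LookupTable-class] used to annotate tags with their
#'   construct.
#' @param collapseUmis merge UMIs at Hamming distance 1 (default FALSE).
#' @return a [UmiCountTable-class].
#' @export
countUmis <- function(assignments, lut, collapseUmis = FALSE) {
  e <- lookupEntries(lut)
  dt <- data.table::as.data.table(assignments)
  if (collapseUmis) {
    cnt <- dt[, .(read_count = .N,
                  umi_count = collapsedUmiCount(umi)),
              by = .(tag, library, day)]
  } else {
    cnt <- dt[, .(read_count = .N,
                  umi_count = data.table::uniqueN(umi)),
              by = .(tag, library, day)]
  }
  cnt <- as.data.frame(cnt)
  m <- match(cnt$tag, e$tag)
  counts <- data.frame(enhancer_id = e$enhancer_id[m],
                       allele = e$allele[m], barcode = e$barcode[m],
                       tag = cnt$tag, library = cnt$library, day = cnt$day,
                       read_count = cnt$read_count,
                       umi_count = cnt$umi_count, stringsAsFactors = FALSE)
  counts <- counts[order(counts$enhancer_id, counts$allele, counts$tag,
                         counts$library, counts$day), , drop = FALSE]
  rownames(counts) <- NULL
  new("UmiCountTable", counts = counts)
}

## number of UMI clusters after greedy Hamming-1 absorption into more
## abundant UMIs
collapsedUmiCount <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  u <- names(tab)
  if (length(u) <= 1L) return(length(u))
  d <- hammingMatrix(u)
  absorbed <- rep(FALSE, length(u))
  for (i in seq_along(u)[-1L]) {
    if (any(!absorbed[seq_len(i - 1L)] & d[i, seq_len(i - 1L)] <= 1L))
      absorbed[i] <- TRUE
  }
  sum(!absorbed)
}

#' Count tags in a sequencing library end-to-end
#'
#' Runs the full per-library pipeline: UMI extraction, constant-region
#' trimming, mismatch-tolerant tag assignment and UMI deduplication, and
#' returns the count table together with a conservation-checked reject
#' summary (total reads = assigned + no-hit + ambiguous + length-unassigned +
#' trim-rejected + UMI-rejected).
#'
#' @param reads FASTQ path (optionally gzipped) or a character vector /
#'   `DNAStringSet` of reads.
#' @param lut a [LookupTable-class].
#' @param library "RNA" or "DNA".
#' @param day collection day label.
#' @param umiLen UMI width (default 8).
#' @param fiveAdapter,threeAdapter,errorRate,minLen see
#'   [trimConstantRegions()].
#' @param maxMismatch see [assignTag()].
#' @param collapseUmis see [countUmis()].
#' @return list with `counts` (a [UmiCountTable-class]) and `summary` (named
#'   integer tally).
#' @export
countTags <- function(reads, lut, library, day, umiLen = 8L,
                      fiveAdapter = "CGCGGGATGCTAGCACGCGG",
                      threeAdapter = "ACATATAGGACCAG", errorRate = 0.3,
                      minLen = 10L, maxMismatch = 2L, collapseUmis = FALSE) {
  stopifnot(library %in% c("RNA", "DNA"))
  if (is.character(reads) && length(reads) == 1L &&
      (file.exists(reads) || grepl("\\.(fq|fastq)(\\.gz)?$", reads))) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  reads <- as.character(reads)
  total <- length(reads)

  um <- extractUmi(reads, umiLen)
  tr <- trimConstantRegions(um$rest, fiveAdapter, threeAdapter, errorRate,
                            minLen)
  umi <- um$umi[tr$keep]
  asg <- assignTag(tr$tag, lut, maxMismatch)
  ok <- !is.na(asg$tag)

  summary <- c(total = total,
               rejected_umi = um$n_rejected,
               rejected_trim = tr$n_rejected_length,
               unassigned_no_hit = sum(asg$reason == "no_hit"),
               unassigned_ambiguous = sum(asg$reason == "ambiguous"),
               unassigned_length = sum(asg$reason == "length"),
               assigned = sum(ok))
  assignments <- data.frame(tag = asg$tag[ok], umi = umi[ok],
                            library = library, day = day,
                            stringsAsFactors = FALSE)
  counts <- countUmis(assignments, lut, collapseUmis = collapseUmis)
  list(counts = counts, summary = summary)
}

#' Write / read a UMI count table as TSV
#' @param x a [UmiCountTable-class].
#' @param path TSV path.
#' @return `path` invisibly; the reader returns a `UmiCountTable`.
#' @export
writeCountsTable <- function(x, path) {
  utils::write.table(umiCounts(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCountsTable
#' @export
readCountsTable <- function(path) {
  cc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(enhancer_id = "character",
                                         allele = "character",
                                         barcode = "character",
                                         tag = "character",
                                         library = "character"))
  new("UmiCountTable", counts = cc)
}
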