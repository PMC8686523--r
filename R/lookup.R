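#' Anchor structure of lookup-library reads
#'
#' The re-circularized lookup library juxtaposes the enhancer barcode and the
#' degenerate 20-mer tag; each read is `anchor1 + barcode + anchor2 + tag`
#' (possibly followed by vector sequence). The anchor sequences themselves
#' are library-chemistry constants and are configurable; the defaults are the
#' synthetic constants used by the package simulator.
#'
#' @param anchor1 constant sequence immediately 5' of the barcode.
#' @param anchor2 constant sequence between barcode and tag.
#' @param barcodeLen,tagLen fixed segment widths.
#' @param maxMismatch anchor mismatches tolerated when parsing.
#' @return named list describing the read structure.
#' @export
lookupStructure <- function(anchor1 = "ACGTCTGAACTCCAGTCAC",
                            anchor2 = "TCGGCATTCCTGCTGAACC",
                            barcodeLen = 8L, tagLen = 20L,
                            maxMismatch = 1L) {
  list(anchor1 = anchor1, anchor2 = anchor2,
       barcodeLen = as.integer(barcodeLen), tagLen = as.integer(tagLen),
       maxMismatch = as.integer(maxMismatch))
}

#' Parse lookup-library reads into (barcode, tag) pairs
#'
#' Locates both anchors (allowing up to `structure$maxMismatch` mismatches
#' each; leftmost match wins), checks that exactly `barcodeLen` bases
#' separate them, and excises the fixed-length barcode and tag. Reads failing
#' any step are rejected and tallied by reason.
#'
#' @param reads character vector or `DNAStringSet` of lookup reads.
#' @param structure read structure from [lookupStructure()].
#' @return list with `pairs` (data.frame `barcode`, `tag`) and `rejects`
#'   (named integer tally: `no_anchor1`, `no_anchor2`, `bad_spacing`,
#'   `too_short`).
#' @export
parseLookupReads <- function(reads, structure = lookupStructure()) {
  reads <- as.character(reads)
  n <- length(reads)
  rej <- c(no_anchor1 = 0L, no_anchor2 = 0L, bad_spacing = 0L,
           too_short = 0L)
  if (!n) {
    return(list(pairs = data.frame(barcode = character(0),
                                   tag = character(0)), rejects = rej))
  }
  a1 <- findAnchor(reads, structure$anchor1, structure$maxMismatch)
  ok1 <- !is.na(a1)
  rej["no_anchor1"] <- sum(!ok1)
  a2 <- rep(NA_integer_, n)
  a2[ok1] <- findAnchor(reads[ok1], structure$anchor2,
                        structure$maxMismatch,
                        from = a1[ok1] + nchar(structure$anchor1))
  ok2 <- ok1 & !is.na(a2)
  rej["no_anchor2"] <- sum(ok1 & !ok2)
  bcStart <- a1 + nchar(structure$anchor1)
  spacing <- ok2 & (a2 - bcStart == structure$barcodeLen)
  rej["bad_spacing"] <- sum(ok2 & !spacing)
  tagStart <- a2 + nchar(structure$anchor2)
  long <- spacing & (nchar(reads) >= tagStart + structure$tagLen - 1L)
  rej["too_short"] <- sum(spacing & !long)
  keep <- which(long)
  list(pairs = data.frame(
         barcode = substr(reads[keep], bcStart[keep],
                          bcStart[keep] + structure$barcodeLen - 1L),
         tag = substr(reads[keep], tagStart[keep],
                      tagStart[keep] + structure$tagLen - 1L),
         stringsAsFactors = FALSE),
       rejects = rej)
}

## start of `pattern` in each read, searching at or after `from` (1-based);
## NA if absent. Match priority: the leftmost exact occurrence, else the
## leftmost occurrence with <= maxMismatch mismatches. Exact matches are
## found with Boyer-Moore; reads without one first get a cheap tolerant
## check at position `from` (the leftmost possible, so semantics are
## preserved) and only the rest pay for the full mismatch-tolerant scan.
findAnchor <- function(reads, pattern, maxMismatch, from = 1L) {
  n <- length(reads)
  plen <- nchar(pattern)
  from <- rep_len(as.integer(from), n)
  tails <- substr(reads, from, nchar(reads))
  hit <- regexpr(pattern, tails, fixed = TRUE, useBytes = TRUE)
  hit <- ifelse(hit > 0L, as.integer(hit), NA_integer_)
  if (maxMismatch > 0L && anyNA(hit)) {
    miss <- which(is.na(hit) & nchar(tails) >= plen)
    if (length(miss)) {
      pre <- substr(tails[miss], 1L, plen)
      okPre <- as.vector(hammingMatrix(pre, pattern)) <= maxMismatch
      hit[miss[okPre]] <- 1L
      rest <- miss[!okPre]
      if (length(rest)) {
        mm <- Biostrings::vmatchPattern(
          pattern, Biostrings::DNAStringSet(tails[rest]),
          max.mismatch = maxMismatch)
        hit[rest] <- startOfFirst(mm)
      }
    }
  }
  hit + from - 1L
}

## first (leftmost) start per element of a match-index list; NA when no
## match. Vectorized over the concatenated matches: per-element S4
## subsetting is far too slow at FASTQ scale.
startOfFirst <- function(m) {
  nhit <- S4Vectors::elementNROWS(m)
  out <- rep(NA_integer_, length(m))
  has <- which(nhit > 0L)
  if (length(has)) {
    allStarts <- IRanges::start(unlist(m))
    firstIdx <- cumsum(nhit)[has] - nhit[has] + 1L
    out[has] <- allStarts[firstIdx]
  }
  out
}

#' Build the lookup table from counted barcode-tag pairs
#'
#' A (barcode, tag) pair is accepted iff it is listed in `expected`
#' (Sanger-anchored pairs are always true positives) or its read count is at
#' least `minFrac` times the largest tag count observed for that barcode
#' (empiric thresholding). A tag accepted for two or more barcodes is a
#' likely chimera and is dropped entirely; barcodes absent from the design
#' are dropped. Barcodes at Hamming distance 1 from a designed barcode are
#' corrected to it first (designed barcodes are >= 3 apart, so the correction
#' is unambiguous).
#'
#' @param pairs data.frame `barcode`, `tag` (one row per read, as from
#'   [parseLookupReads()]) or pre-counted with a `count` column.
#' @param design construct data.frame (from [buildAllelicSeries()] /
#'   [readConstructsFasta()]) giving the barcode -> construct mapping.
#' @param expected optional data.frame `barcode`, `tag` of known true pairs.
#' @param minFrac per-barcode count threshold as a fraction of that barcode's
#'   top tag (default 0.1).
#' @param correctBarcodes correct 1-mismatch barcodes to the design
#'   (default TRUE).
#' @return a [LookupTable-class]; constructs with no accepted tag are listed
#'   in `droppedConstructs()`.
#' @export
buildLookup <- function(pairs, design, expected = NULL, minFrac = 0.1,
                        correctBarcodes = TRUE) {
  stopifnot(minFrac > 0, minFrac <= 1)
  if (nrow(pairs) == 0L) {
    warning("no barcode-tag pairs supplied; lookup table is empty")
    return(new("LookupTable",
               entries = data.frame(tag = character(0),
                                    enhancer_id = character(0),
                                    allele = character(0),
                                    barcode = character(0),
                                    support = integer(0)),
               dropped = constructKey(design)))
  }
  if (!"count" %in% names(pairs)) {
    dt <- data.table::as.data.table(pairs)
    pairs <- as.data.frame(dt[, .(count = .N), by = .(barcode, tag)])
  }
  designBC <- unique(design$barcode)
  if (correctBarcodes) {
    unk <- !(pairs$barcode %in% designBC)
    if (any(unk)) {
      d <- hammingMatrix(pairs$barcode[unk], designBC)
      nearest <- apply(d, 1L, which.min)
      fix <- d[cbind(seq_len(sum(unk)), nearest)] <= 1L
      pairs$barcode[unk][fix] <- designBC[nearest[fix]]
      ## re-aggregate after correction
      dt <- data.table::as.data.table(pairs)
      pairs <- as.data.frame(dt[, .(count = sum(count)),
                                by = .(barcode, tag)])
    }
  }
  pairs <- pairs[pairs$barcode %in% designBC, , drop = FALSE]

  isExpected <- if (!is.null(expected) && nrow(expected)) {
    paste(pairs$barcode, pairs$tag) %in% paste(expected$barcode, expected$tag)
  } else rep(FALSE, nrow(pairs))
  topCount <- tapply(pairs$count, pairs$barcode, max)
  pass <- isExpected | pairs$count >= minFrac * topCount[pairs$barcode]
  acc <- pairs[pass, , drop = FALSE]

  ## chimera guard: a tag passing for >= 2 barcodes is removed entirely
  multi <- names(which(table(unique(acc[, c("tag", "barcode")])$tag) >= 2L))
  acc <- acc[!(acc$tag %in% multi), , drop = FALSE]

  di <- design[match(acc$barcode, design$barcode), , drop = FALSE]
  entries <- data.frame(tag = acc$tag, enhancer_id = di$enhancer_id,
                        allele = di$allele, barcode = acc$barcode,
                        support = acc$count, stringsAsFactors = FALSE)
  entries <- entries[order(entries$enhancer_id, entries$allele,
                           entries$tag), , drop = FALSE]
  rownames(entries) <- NULL
  dropped <- setdiff(constructKey(design), constructKey(entries))
  new("LookupTable", entries = entries, dropped = dropped)
}

#' Write the pseudo-genome FASTA for tag mapping
#'
#' One record per tag; the record id encodes the construct key and a
#' per-construct tag serial (`enhancerID|allele|barcode|tagN`), and the
#' sequence is the tag itself. Tag-counting aligns trimmed read candidates
#' against this index.
#'
#' @param lut a [LookupTable-class] (non-empty).
#' @param path FASTA output path.
#' @return `path`, invisibly.
#' @export
writePseudoGenome <- function(lut, path) {
  e <- lookupEntries(lut)
  if (!nrow(e)) stop("lookup table is empty")
  serial <- stats::ave(seq_len(nrow(e)), constructKey(e),
                       FUN = seq_along)
  x <- Biostrings::DNAStringSet(e$tag)
  names(x) <- paste0(constructKey(e), "|tag", serial)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Re-read a pseudo-genome FASTA into a lookup table
#' @param path FASTA written by [writePseudoGenome()].
#' @return a [LookupTable-class] (support is NA; it is not stored in FASTA).
#' @export
readPseudoGenome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  key <- do.call(rbind, strsplit(names(x), "|", fixed = TRUE))
  new("LookupTable",
      entries = data.frame(tag = as.character(x), enhancer_id = key[, 1],
                           allele = key[, 2], barcode = key[, 3],
                           support = NA_integer_, stringsAsFactors = FALSE),
      dropped = character(0))
}

#' Write / read the lookup table as TSV
#' @param lut a [LookupTable-class].
#' @param path TSV path.
#' @return `path` invisibly; the reader returns a `LookupTable`.
#' @export
writeLookupTable <- function(lut, path) {
  utils::write.table(lookupEntries(lut), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeLookupTable
#' @export
readLookupTable <- function(path) {
  e <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(enhancer_id = "character",
                                        allele = "character",
                                        barcode = "character",
                                        tag = "character"))
  new("LookupTable", entries = e, dropped = character(0))
}
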