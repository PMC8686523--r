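#' Design a minimal binding-site-destroying mutation
#'
#' Searches substitution sets of size 1, 2, ... `maxSubs` (exhaustively,
#' smallest size first) inside the site window for the edit that (a) drops
#' the window's log-likelihood ratio for the target PWM to `llrMin` or below
#' on both strands, (b) creates no new site of the target motif or of any
#' guard PWM with LLR > `llrMin` within motif-length - 1 of the window (an
#' edit can otherwise re-create the same motif at a shifted offset), and (c)
#' destroys no pre-existing guard site overlapping that region (pre-existing
#' sites of the target motif itself may be silenced by the same edit -- they
#' belong to the class being mutated). Ties at the smallest size
#' are broken by the largest LLR drop, then the leftmost edited positions,
#' then alphabetical replacement base.
#'
#' @param enhSeq the wildtype enhancer sequence (character).
#' @param site one row of a [scanPWM()] result for `enhSeq` and `targetPwm`.
#' @param targetPwm the [PWModel-class] whose site is being destroyed.
#' @param guardPwms list of PWMs whose sites must be neither created nor
#'   destroyed near the edit (overlapping-site guard).
#' @param llrMin the site-calling threshold in nats (default 6).
#' @param maxSubs largest substitution set considered (default 3).
#' @return data.frame with columns `pos` (1-based position in the enhancer),
#'   `ref`, `alt` -- the minimal edit.
#' @seealso [scanPWM()], [buildAllelicSeries()]
#' @export
designMutation <- function(enhSeq, site, targetPwm, guardPwms = list(),
                           llrMin = 6, maxSubs = 3L) {
  enhSeq <- as.character(enhSeq)
  L <- length(targetPwm)
  win <- site$start:site$end
  stopifnot(length(win) == L)
  chars <- strsplit(enhSeq, "", fixed = TRUE)[[1]]

  ## guard context: the widest motif can gain/lose sites within +/- (len-1)
  pad <- max(vapply(c(guardPwms, list(targetPwm)), length, integer(1))) - 1L
  lo <- max(1L, site$start - pad)
  hi <- min(nchar(enhSeq), site$end + pad)
  guardBefore <- guardSites(substr(enhSeq, lo, hi), guardPwms, llrMin)
  ## pre-existing sites of the target motif near the edit: the edit may
  ## silence them (same class) but must not create new ones
  targetBefore <- guardSites(substr(enhSeq, lo, hi), list(targetPwm), llrMin)

  targetLLR <- function(s) {
    w <- substr(s, site$start, site$end)
    max(windowLLR(w, targetPwm), windowLLR(w, revCompPWM(targetPwm)))
  }

  for (size in seq_len(maxSubs)) {
    combos <- utils::combn(win, size)
    ## collect every candidate that silences the target window, rank by the
    ## tie-break order, then pay for the guard re-scan only until the first
    ## candidate passes
    cands <- list()
    for (ci in seq_len(ncol(combos))) {
      pos <- combos[, ci]
      altSets <- altBaseGrid(chars[pos])
      for (ai in seq_len(nrow(altSets))) {
        alt <- unlist(altSets[ai, ], use.names = FALSE)
        mutChars <- chars
        mutChars[pos] <- alt
        mutSeq <- paste0(mutChars, collapse = "")
        llr <- targetLLR(mutSeq)
        if (llr > llrMin) next
        cands[[length(cands) + 1L]] <-
          list(pos = pos, ref = chars[pos], alt = alt, llr = llr,
               seq = mutSeq)
      }
    }
    if (length(cands)) {
      ord <- order(vapply(cands, function(cd)
        sprintf("%020.10f|%s|%s", cd$llr + 1e6,
                paste(sprintf("%06d", cd$pos), collapse = ","),
                paste(cd$alt, collapse = "")), character(1)))
      for (cd in cands[ord]) {
        region <- substr(cd$seq, lo, hi)
        tAfter <- guardSites(region, list(targetPwm), llrMin)
        if (!all(tAfter %in% targetBefore)) next  # shifted site re-created
        gAfter <- guardSites(region, guardPwms, llrMin)
        if (identical(gAfter, guardBefore)) {
          return(data.frame(pos = cd$pos, ref = cd$ref, alt = cd$alt,
                            stringsAsFactors = FALSE))
        }
      }
    }
  }
  stop("undisruptable site: ", targetPwm@name, " at ", site$start, "-",
       site$end, " cannot be destroyed within ", maxSubs, " substitutions",
       call. = FALSE)
}

## canonical string key set of guard sites in a region
guardSites <- function(regionSeq, guardPwms, llrMin) {
  if (!length(guardPwms)) return(character(0))
  keys <- character(0)
  for (g in guardPwms) {
    if (nchar(regionSeq) < length(g)) next
    s <- scanPWM(regionSeq, g, llrMin)
    if (nrow(s))
      keys <- c(keys, paste(s$motif, s$start, s$strand, sep = ":"))
  }
  sort(keys)
}

## all combinations of non-reference bases at the given positions
altBaseGrid <- function(refBases) {
  opts <- lapply(refBases, function(b) setdiff(DNA_BASES, b))
  do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
}

#' Apply substitutions to a sequence
#' @param seq DNA string.
#' @param edits data.frame with `pos`, `ref`, `alt` (as from
#'   [designMutation()]); `ref` is checked against the sequence.
#' @return the edited sequence.
#' @export
applyEdits <- function(seq, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars[edits$pos] == edits$ref))
    stop("edit reference bases do not match the sequence")
  chars[edits$pos] <- edits$alt
  paste0(chars, collapse = "")
}

#' Reporter construct flanking parts
#'
#' The fixed sequence parts a designed construct is assembled from:
#' recombination site (attB1), 5' primer binding site (SQ3), the restriction
#' site (BmtI, GCTAGC) separating barcode from enhancer, and the 3' primer
#' binding site (SQ5) and attB2, which enter reverse-complemented. attB1,
#' attB2 and the BmtI recognition site are the standard published sequences;
#' SQ3/SQ5 are synthetic stand-ins for unpublished primer sites and are
#' configurable.
#'
#' @param attB1,sq3,bmtI,sq5,attB2 part sequences (defaults provided).
#' @return named list of parts.
#' @export
constructParts <- function(attB1 = "GGGGACAAGTTTGTACAAAAAAGCAGGCT",
                           sq3 = "CTACACGACGCTCTTCC",
                           bmtI = "GCTAGC",
                           sq5 = "CAGACGTGTGCTCTTCC",
                           attB2 = "GGGGACCACTTTGTACAAGAAAGCTGGGT") {
  list(attB1 = attB1, sq3 = sq3, bmtI = bmtI, sq5 = sq5, attB2 = attB2)
}

#' Assemble the full construct sequence
#'
#' Layout: attB1 + SQ3 + barcode + BmtI site + enhancer + reverse complement
#' of the same barcode + rc(SQ5) + rc(attB2). The barcode therefore flanks
#' the enhancer in forward orientation 5' of it and reverse-complemented 3'
#' of it.
#'
#' @param barcode 8-mer barcode.
#' @param enhancerSeq enhancer (wildtype or mutant) sequence.
#' @param parts from [constructParts()].
#' @return the construct sequence (character).
#' @export
constructSequence <- function(barcode, enhancerSeq,
                              parts = constructParts()) {
  paste0(parts$attB1, parts$sq3, barcode, parts$bmtI, enhancerSeq,
         revComp(barcode), revComp(parts$sq5), revComp(parts$attB2))
}

#' Expand one enhancer into its combinatorial allelic series
#'
#' Builds the 2^3 = 8 constructs for an enhancer: wildtype, the three
#' single-motif-class mutants, the three pairwise mutants and the triple
#' mutant. Combinatorial alleles carry the union of the per-class edits, so
#' edits for different classes must not touch the same position. Each
#' construct receives the next unused barcode from `barcodes`.
#'
#' @param enhancerId enhancer name.
#' @param enhSeq wildtype enhancer sequence.
#' @param motifClasses character vector of exactly 3 motif class names.
#' @param siteMutations named list (one entry per class) of edit data.frames
#'   (`pos`, `ref`, `alt`), each the union of that class's per-site edits.
#' @param barcodes a [BarcodeSet-class] or character vector; must contain at
#'   least `offset + 8` barcodes.
#' @param offset number of barcodes already consumed (default 0).
#' @param parts construct flanking parts ([constructParts()]).
#' @return data.frame with one row per construct: `enhancer_id`, `allele`
#'   ("WT" or "+"-joined mutated classes), `barcode`, `enhancer_seq`,
#'   `construct_seq`, `n_subs`.
#' @export
buildAllelicSeries <- function(enhancerId, enhSeq, motifClasses,
                               siteMutations, barcodes, offset = 0L,
                               parts = constructParts()) {
  stopifnot(length(motifClasses) == 3L)
  if (!all(motifClasses %in% names(siteMutations)))
    stop("siteMutations must have an entry per motif class")
  allPos <- lapply(siteMutations[motifClasses], function(e) e$pos)
  if (anyDuplicated(unlist(allPos)))
    stop("edits for different motif classes overlap the same position")
  bc <- if (is(barcodes, "BarcodeSet")) as.character(barcodes) else barcodes
  if (length(bc) < offset + 8L)
    stop("barcode set exhausted: need ", offset + 8L, ", have ", length(bc))

  subsets <- lapply(0:7, function(mask) motifClasses[bitwAnd(mask, 2^(0:2)) > 0])
  rows <- lapply(seq_along(subsets), function(i) {
    classes <- subsets[[i]]
    edits <- do.call(rbind, c(siteMutations[classes],
                              list(data.frame(pos = integer(0),
                                              ref = character(0),
                                              alt = character(0)))))
    mutSeq <- applyEdits(enhSeq, edits)
    barcode <- bc[offset + i]
    data.frame(
      enhancer_id = enhancerId,
      allele = if (length(classes)) paste(sort(classes), collapse = "+")
               else "WT",
      barcode = barcode,
      enhancer_seq = mutSeq,
      construct_seq = constructSequence(barcode, mutSeq, parts),
      n_subs = nrow(edits),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary statistics of a designed construct library
#'
#' @param constructs data.frame of constructs (rows from
#'   [buildAllelicSeries()], possibly several enhancers).
#' @return list with `n_constructs`, `n_enhancers`, per-mutant substitution
#'   counts and their mean/min/max, the number of distinct barcodes, and the
#'   minimum pairwise barcode Hamming distance including reverse complements.
#' @export
designSummary <- function(constructs) {
  mut <- constructs[constructs$allele != "WT", , drop = FALSE]
  bcs <- unique(constructs$barcode)
  list(
    n_constructs = nrow(constructs),
    n_enhancers = length(unique(constructs$enhancer_id)),
    n_subs = mut$n_subs,
    mean_subs = mean(mut$n_subs),
    min_subs = if (nrow(mut)) min(mut$n_subs) else NA_integer_,
    max_subs = if (nrow(mut)) max(mut$n_subs) else NA_integer_,
    n_barcodes = length(bcs),
    barcode_min_hamming = barcodePairwiseMin(bcs))
}

#' Write / read designed constructs as FASTA
#'
#' Headers follow `enhancerID|allele|barcode`; sequences are the full
#' construct sequences. `readConstructsFasta()` inverts this, recovering the
#' enhancer sequence from the construct layout when `parts` are supplied.
#'
#' @param constructs construct data.frame.
#' @param path FASTA path.
#' @return `path` invisibly; the reader returns a construct data.frame.
#' @export
writeConstructsFasta <- function(constructs, path) {
  x <- Biostrings::DNAStringSet(constructs$construct_seq)
  names(x) <- constructKey(constructs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeConstructsFasta
#' @param parts construct flanking parts used at design time.
#' @export
readConstructsFasta <- function(path, parts = constructParts()) {
  x <- Biostrings::readDNAStringSet(path)
  key <- do.call(rbind, strsplit(names(x), "|", fixed = TRUE))
  seqs <- as.character(x)
  pre <- nchar(parts$attB1) + nchar(parts$sq3) + 8L + nchar(parts$bmtI)
  post <- 8L + nchar(parts$sq5) + nchar(parts$attB2)
  data.frame(enhancer_id = key[, 1], allele = key[, 2], barcode = key[, 3],
             enhancer_seq = substr(seqs, pre + 1L, nchar(seqs) - post),
             construct_seq = seqs, stringsAsFactors = FALSE)
}
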