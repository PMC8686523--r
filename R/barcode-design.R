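#' Read a PBM E-score table
#'
#' Two-column TSV (`kmer`, `escore`), one row per 8-mer; when the same 8-mer
#' (or its reverse complement) appears several times -- e.g. from several PBM
#' experiments -- the maximum E-score is kept. E-scores are rank statistics
#' in (-0.5, 0.5); a k-mer and its reverse complement are treated as the
#' same binding word.
#'
#' @param path TSV path (optional header `kmer<TAB>escore`; `#` comments
#'   allowed).
#' @return named numeric vector: canonical k-mer -> maximum E-score. The
#'   canonical orientation is the lexicographic minimum of the k-mer and its
#'   reverse complement.
#' @export
readEscoreTable <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (is.character(tab[[2]])) tab <- tab[-1L, , drop = FALSE]  # header row
  kmers <- toupper(tab[[1]])
  scores <- as.numeric(tab[[2]])
  assertKmers(kmers, k = unique(nchar(kmers))[1], what = "E-score k-mer")
  canon <- pmin(kmers, revComp(kmers))
  out <- tapply(scores, canon, max)
  setNames(as.numeric(out), names(out))
}

## max E-score of each kmer under orientation symmetry; NA if absent
escoreLookup <- function(kmers, table) {
  canon <- pmin(kmers, revComp(kmers))
  unname(table[canon])
}

#' Filter k-mers by PBM E-score
#'
#' Eliminates every k-mer whose maximum E-score across experiments -- looked
#' up under orientation symmetry (the k-mer or its reverse complement) --
#' exceeds `threshold`. K-mers absent from the table carry no binding
#' evidence and are retained. Input order is preserved.
#'
#' @param kmers character vector of 8-mers (A/C/G/T).
#' @param table named numeric vector from [readEscoreTable()] (may be
#'   empty).
#' @param threshold eliminate k-mers with E-score strictly greater than this
#'   (default 0.3).
#' @return the retained k-mers, in input order.
#' @export
filterByEscore <- function(kmers, table = numeric(0), threshold = 0.3) {
  assertKmers(kmers)
  stopifnot(threshold > -0.5, threshold < 0.5)
  if (!length(kmers) || !length(table)) return(kmers)
  sc <- escoreLookup(kmers, table)
  kmers[is.na(sc) | sc <= threshold]
}

#' Filter k-mers against a PWM panel
#'
#' A k-mer is eliminated if, for any PWM, the maximum log-likelihood-ratio
#' score over all offsets (both strands; the PWM must be no longer than the
#' k-mer, else that PWM is skipped with a warning) meets or exceeds that
#' PWM's threshold. Used to keep designed barcodes free of predicted TF
#' binding sites.
#'
#' @param kmers character vector of 8-mers.
#' @param pwms list of [PWModel-class] objects.
#' @param thresholds named numeric vector of per-PWM score thresholds (nats).
#'   Default: each PWM's consensus score minus 2 nats.
#' @return the retained k-mers, in input order.
#' @export
filterByPWM <- function(kmers, pwms,
                        thresholds = vapply(pwms, pwmMaxScore,
                                            numeric(1)) - 2) {
  assertKmers(kmers)
  if (!length(kmers) || !length(pwms)) return(kmers)
  if (is.null(names(thresholds)) && !is.null(names(pwms)))
    names(thresholds) <- names(pwms)
  keep <- rep(TRUE, length(kmers))
  k <- nchar(kmers[1])
  for (i in seq_along(pwms)) {
    pwm <- pwms[[i]]
    if (length(pwm) > k) {
      warning("PWM '", pwm@name, "' (length ", length(pwm),
              ") is longer than the k-mers and was skipped")
      next
    }
    thr <- if (!is.null(names(thresholds)) && pwm@name %in% names(thresholds))
      thresholds[[pwm@name]] else thresholds[[i]]
    sc <- kmerMaxLLR(kmers[keep], pwm)
    keep[keep] <- sc < thr
  }
  kmers[keep]
}

## max LLR of a PWM over all offsets and both strands, vectorized over kmers
kmerMaxLLR <- function(kmers, pwm) {
  if (!length(kmers)) return(numeric(0))
  k <- nchar(kmers[1])
  L <- length(pwm)
  idx <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE),
                             use.names = FALSE), DNA_BASES),
                nrow = length(kmers), byrow = TRUE)
  best <- rep(-Inf, length(kmers))
  for (m in list(llrMatrix(pwm), llrMatrix(revCompPWM(pwm)))) {
    for (off in 0:(k - L)) {
      s <- numeric(length(kmers))
      for (i in seq_len(L)) s <- s + m[cbind(idx[, off + i], i)]
      best <- pmax(best, s)
    }
  }
  best
}

#' Greedy selection of a mutually distant barcode set
#'
#' Scans the input in order and keeps a k-mer iff its Hamming distance to
#' every already-kept k-mer AND to every kept k-mer's reverse complement is
#' at least `minDist`. The greedy order is the input order, so the result is
#' deterministic and reproducible.
#'
#' @param kmers candidate k-mers (already filtered for binding sites).
#' @param minDist minimum pairwise Hamming distance (default 3).
#' @param nMax stop once this many barcodes are selected (default unlimited).
#' @return a [BarcodeSet-class].
#' @export
selectHammingSet <- function(kmers, minDist = 3L, nMax = Inf) {
  assertKmers(kmers)
  minDist <- as.integer(minDist)
  stopifnot(minDist >= 1L)
  if (!length(kmers))
    return(new("BarcodeSet", barcodes = character(0), minDist = minDist))
  k <- nchar(kmers[1])
  ## one-hot encode candidates and their reverse complements once; keep a
  ## growing matrix of accepted rows so each test is one matrix product
  H <- oneHot(kmers)
  Hrc <- oneHot(revComp(kmers))
  keptIdx <- integer(0)
  keptH <- matrix(0L, nrow = 0L, ncol = ncol(H))
  for (i in seq_along(kmers)) {
    if (length(keptIdx)) {
      d1 <- k - keptH %*% H[i, ]
      d2 <- k - keptH %*% Hrc[i, ]
      if (min(d1, d2) < minDist) next
    }
    keptIdx <- c(keptIdx, i)
    keptH <- rbind(keptH, H[i, , drop = FALSE])
    if (length(keptIdx) >= nMax) break
  }
  new("BarcodeSet", barcodes = kmers[keptIdx], minDist = minDist)
}

#' Design a neutral barcode set end-to-end
#'
#' Enumerates all 8-mers (lexicographic order), removes those with PBM
#' binding evidence ([filterByEscore()]), removes those matching any PWM in
#' the panel ([filterByPWM()]), then greedily enforces the minimum Hamming
#' separation ([selectHammingSet()]).
#'
#' @param n number of barcodes needed (selection stops early once reached).
#' @param pwms list of [PWModel-class] to exclude (may be empty).
#' @param escores E-score table from [readEscoreTable()] (may be empty).
#' @param escoreMax E-score elimination threshold (default 0.3).
#' @param minDist minimum Hamming separation (default 3).
#' @param thresholds per-PWM LLR thresholds passed to [filterByPWM()].
#' @param width barcode width (default 8).
#' @return a [BarcodeSet-class] of up to `n` barcodes (fewer only if the
#'   filters exhaust the universe, with a warning).
#' @export
designBarcodes <- function(n, pwms = list(), escores = numeric(0),
                           escoreMax = 0.3, minDist = 3L,
                           thresholds = NULL, width = 8L) {
  kmers <- allKmers(width)
  kmers <- filterByEscore(kmers, escores, escoreMax)
  if (length(pwms)) {
    kmers <- if (is.null(thresholds)) filterByPWM(kmers, pwms)
             else filterByPWM(kmers, pwms, thresholds)
  }
  bs <- selectHammingSet(kmers, minDist = minDist, nMax = n)
  if (length(bs) < n)
    warning("only ", length(bs), " of ", n, " requested barcodes available")
  bs
}

#' Write/read a barcode set (one barcode per line)
#' @param x a [BarcodeSet-class].
#' @param path output file.
#' @return `path` invisibly; `readBarcodeSet()` returns a `BarcodeSet`.
#' @export
writeBarcodeSet <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' @rdname writeBarcodeSet
#' @param minDist minimum distance recorded with the set.
#' @export
readBarcodeSet <- function(path, minDist = 3L) {
  new("BarcodeSet", barcodes = readLines(path),
      minDist = as.integer(minDist))
}
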