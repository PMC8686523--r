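#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of motif length on both strands with the
#' log-likelihood ratio relative to the PWM's background distribution and
#' reports all windows exceeding `llrMin`. Coordinates are 1-based and
#' inclusive on the plus strand; minus-strand sites are reported by the
#' plus-strand coordinates of the window they occupy. Windows containing
#' ambiguous bases (anything outside A/C/G/T) are skipped with a warning.
#'
#' @param seq a single DNA sequence (character or `DNAString`).
#' @param pwm a [PWModel-class].
#' @param llrMin report sites with LLR strictly greater than this (nats;
#'   default 6).
#' @return data.frame with columns `motif`, `start`, `end`, `strand`, `llr`,
#'   `occupancy`, `site_seq` (the matching sequence, motif orientation),
#'   sorted by `start` then strand.
#' @seealso [occupancyScore()], [designMutation()]
#' @export
#' @examples
#' pwm <- qefsToyPWMs()[[1]]
#' seq <- paste0("AAAAAA", consensusSequence(pwm), "TTTTTT")
#' scanPWM(seq, pwm, llrMin = 6)
scanPWM <- function(seq, pwm, llrMin = 6) {
  seq <- as.character(seq)
  L <- length(pwm)
  n <- nchar(seq)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      llr = numeric(0), occupancy = numeric(0),
                      site_seq = character(0), stringsAsFactors = FALSE)
  if (n < L) stop("sequence shorter than the PWM")
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  fwd <- slideScore(idx, llrMatrix(pwm))
  rev_ <- slideScore(idx, llrMatrix(revCompPWM(pwm)))
  if (anyNA(fwd) || anyNA(rev_)) {
    warning("windows containing ambiguous bases were skipped")
  }
  hits <- function(sc, strand) {
    keep <- which(!is.na(sc) & sc > llrMin)
    if (!length(keep)) return(empty)
    site <- substring(seq, keep, keep + L - 1L)
    oriented <- if (strand == "-") revComp(site) else site
    data.frame(motif = pwm@name, start = keep, end = keep + L - 1L,
               strand = strand, llr = sc[keep],
               occupancy = vapply(oriented, occupancyScore, numeric(1),
                                  pwm = pwm, USE.NAMES = FALSE),
               site_seq = oriented, stringsAsFactors = FALSE)
  }
  out <- rbind(hits(fwd, "+"), hits(rev_, "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

## vectorized sliding-window score; idx is match(bases) with NA for ambiguity
slideScore <- function(idx, m) {
  L <- ncol(m)
  nwin <- length(idx) - L + 1L
  if (nwin < 1L) return(numeric(0))
  s <- numeric(nwin)
  for (i in seq_len(L)) {
    s <- s + m[cbind(idx[i:(i + nwin - 1L)], i)]
  }
  s
}

## PWM scoring the reverse complement strand on plus-strand windows
revCompPWM <- function(pwm) {
  p <- pwm@prob[4:1, rev(seq_len(ncol(pwm@prob))), drop = FALSE]
  rownames(p) <- DNA_BASES
  bg <- pwm@background[4:1]
  names(bg) <- DNA_BASES
  new("PWModel", name = pwm@name, prob = p, background = bg,
      pseudocount = pwm@pseudocount)
}

#' Relative occupancy of a site under a PWM
#'
#' The product over positions of p_i(observed base) / p_i(most probable
#' base): the site's predicted affinity relative to the optimal site, equal
#' to 1 exactly at the consensus and independent of the background model.
#'
#' @param siteSeq DNA string of exactly the motif length, in motif
#'   orientation.
#' @param pwm a [PWModel-class].
#' @return occupancy in (0, 1].
#' @export
#' @examples
#' pwm <- qefsToyPWMs()[[1]]
#' occupancyScore(consensusSequence(pwm), pwm)  # 1
occupancyScore <- function(siteSeq, pwm) {
  b <- strsplit(siteSeq, "", fixed = TRUE)[[1]]
  if (length(b) != length(pwm)) stop("site length must equal the PWM length")
  p <- pwm@prob
  prod(p[cbind(match(b, DNA_BASES), seq_along(b))] / apply(p, 2L, max))
}

#' Filter motif sites by predicted occupancy
#'
#' Degenerate motifs (long zinc-finger or lipid-binding-protein PWMs) match
#' many weak sites above an LLR cutoff; a per-motif minimum occupancy removes
#' low-affinity matches before mutagenesis.
#'
#' @param sites data.frame from [scanPWM()].
#' @param minOccupancy drop sites with occupancy strictly below this.
#' @return the filtered site data.frame.
#' @export
filterSitesByOccupancy <- function(sites, minOccupancy) {
  sites[sites$occupancy >= minOccupancy, , drop = FALSE]
}
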