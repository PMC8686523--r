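DNA_BASES <- c("A", "C", "G", "T")

## data.table used via :: (not fully imported)
.datatable.aware <- TRUE

#' Reverse complement of DNA character strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revComp(c("ACGT", "AAAC"))
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  ## pure-R implementation: per-call Biostrings object construction dominates
  ## runtime when called once per construct
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  out <- vapply(strsplit(comp, "", fixed = TRUE),
                function(s) paste(rev(s), collapse = ""),
                character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

## stop unless every element is a fixed-width ACGT string
assertKmers <- function(kmers, k = 8L, what = "k-mer") {
  if (length(kmers) == 0L) return(invisible(TRUE))
  bad <- nchar(kmers) != k | grepl("[^ACGT]", kmers)
  if (any(bad)) {
    stop("malformed ", what, "(s): ",
         paste(utils::head(kmers[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "",
         " (must be length-", k, " over A/C/G/T)", call. = FALSE)
  }
  invisible(TRUE)
}

## split equal-length strings into an n x L character matrix
seqCharMatrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0L, ncol = 0L))
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("sequences must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = L, byrow = TRUE)
}

## one-hot encoding (n x 4L) of equal-length DNA strings; non-ACGT -> all-zero
oneHot <- function(x) {
  m <- seqCharMatrix(x)
  L <- ncol(m)
  out <- matrix(0L, nrow = nrow(m), ncol = 4L * L)
  for (b in seq_along(DNA_BASES)) {
    out[, (seq_len(L) - 1L) * 4L + b] <- (m == DNA_BASES[b]) + 0L
  }
  out
}

#' Pairwise Hamming distances between two sets of equal-length sequences
#'
#' Computed by one-hot matrix multiplication, so large barcode universes stay
#' fast. Sequences in `x` and `y` must share one common length.
#'
#' @param x,y character vectors of equal-length DNA strings (`y` defaults to
#'   `x`).
#' @return integer matrix of Hamming distances, `length(x)` by `length(y)`.
#' @export
hammingMatrix <- function(x, y = x) {
  if (length(x) == 0L || length(y) == 0L) {
    return(matrix(integer(0), nrow = length(x), ncol = length(y)))
  }
  L <- unique(c(nchar(x), nchar(y)))
  if (length(L) != 1L) stop("all sequences must have the same length")
  hx <- oneHot(x)
  hy <- oneHot(y)
  d <- L - tcrossprod(hx, hy)
  storage.mode(d) <- "integer"
  d
}

#' Hamming distance between two equal-length strings
#' @param a,b single equal-length strings.
#' @return integer distance.
#' @export
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## random DNA strings of fixed width
randomDNA <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## sample n integers uniformly from [lo, hi] (safe for lo == hi)
sampleRange <- function(range, n) {
  vals <- range[1]:range[2]
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

## all 4^k k-mers in lexicographic order (k small)
allKmers <- function(k) {
  stopifnot(k >= 1L, k <= 10L)
  g <- do.call(expand.grid,
               c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  ## expand.grid varies the first column fastest; reverse for lexicographic
  sort(do.call(paste0, g[rev(seq_len(k))]))
}
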