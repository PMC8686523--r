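#' Position weight matrix with background model
#'
#' A position probability matrix (4 rows: A, C, G, T; one column per motif
#' position) together with the background base distribution used for
#' log-likelihood-ratio scoring and the pseudocount applied at construction.
#' Sites are scored as sum over positions of log(p_i(b) / bg(b)) (nats);
#' relative occupancy is the product over positions of p_i(b) / p_i(b*),
#' which equals 1 at the consensus.
#'
#' @slot name motif name.
#' @slot prob 4 x L probability matrix, rows named A, C, G, T; every column
#'   sums to 1 and all entries are strictly positive (pseudocount applied).
#' @slot background length-4 background base frequencies summing to 1.
#' @slot pseudocount pseudocount per base that was added before
#'   renormalization.
#' @seealso [PWModel()], [scanPWM()], [occupancyScore()]
#' @export
setClass("PWModel",
  representation(name = "character", prob = "matrix",
                 background = "numeric", pseudocount = "numeric"))

setValidity("PWModel", function(object) {
  p <- object@prob
  msg <- character(0)
  if (!is.numeric(p) || nrow(p) != 4L)
    msg <- c(msg, "prob must be a numeric 4 x L matrix (rows A,C,G,T)")
  else {
    if (!identical(rownames(p), DNA_BASES))
      msg <- c(msg, "prob rows must be named A, C, G, T")
    if (any(p <= 0)) msg <- c(msg, "all probabilities must be > 0")
    if (any(abs(colSums(p) - 1) > 1e-9))
      msg <- c(msg, "each position's probabilities must sum to 1 (1e-9)")
  }
  bg <- object@background
  if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 positive frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PWModel
#'
#' @param prob 4 x L or L x 4 numeric matrix of base probabilities (or
#'   counts; columns/rows in A, C, G, T order). An L x 4 matrix is
#'   transposed automatically.
#' @param name motif name.
#' @param background background base frequencies (A, C, G, T); default
#'   uniform.
#' @param pseudocount value added to every entry before renormalization so
#'   log-ratios stay finite (default 1e-3).
#' @return a [PWModel-class] object.
#' @export
#' @examples
#' m <- rbind(c(.97,.01,.01,.01), c(.01,.01,.97,.01))  # consensus "AG"
#' pwm <- PWModel(m, name = "toy")
#' consensusSequence(pwm)
PWModel <- function(prob, name = "pwm", background = rep(0.25, 4),
                    pseudocount = 1e-3) {
  prob <- as.matrix(prob)
  if (ncol(prob) == 4L && nrow(prob) != 4L) prob <- t(prob)
  if (nrow(prob) != 4L) stop("prob must have 4 rows or 4 columns (A,C,G,T)")
  prob <- prob + pseudocount
  prob <- sweep(prob, 2L, colSums(prob), "/")
  dimnames(prob) <- list(DNA_BASES, NULL)
  background <- background / sum(background)
  names(background) <- DNA_BASES
  new("PWModel", name = name, prob = prob, background = background,
      pseudocount = pseudocount)
}

#' @describeIn PWModel-class motif length (number of positions)
#' @param x a `PWModel`.
#' @export
setMethod("length", "PWModel", function(x) ncol(x@prob))

#' @describeIn PWModel-class motif name
#' @export
setMethod("names", "PWModel", function(x) x@name)

setMethod("show", "PWModel", function(object) {
  cat("PWModel '", object@name, "': ", ncol(object@prob),
      " positions, consensus ", consensusSequence(object), "\n", sep = "")
})

#' Consensus sequence of a PWM
#' @param pwm a [PWModel-class].
#' @return the most probable base at each position, as one string.
#' @export
consensusSequence <- function(pwm) {
  paste0(DNA_BASES[apply(pwm@prob, 2L, which.max)], collapse = "")
}

#' A mutually distant set of neutral enhancer barcodes
#'
#' An ordered set of fixed-width barcodes in which every pair of members --
#' and every member against every member's reverse complement -- is separated
#' by at least `minDist` mismatches, so that single sequencing errors cannot
#' convert one barcode into another.
#'
#' @slot barcodes character vector of barcodes (default width 8).
#' @slot minDist minimum pairwise Hamming distance the set was built with.
#' @seealso [selectHammingSet()], [designBarcodes()]
#' @export
setClass("BarcodeSet",
  representation(barcodes = "character", minDist = "integer"))

setValidity("BarcodeSet", function(object) {
  bc <- object@barcodes
  if (length(bc) == 0L) return(TRUE)
  if (length(unique(nchar(bc))) != 1L) return("barcodes must share one width")
  if (any(grepl("[^ACGT]", bc))) return("barcodes must be A/C/G/T only")
  if (anyDuplicated(bc)) return("barcodes must be unique")
  d <- barcodePairwiseMin(bc)
  if (length(bc) > 1L && d < object@minDist)
    return(sprintf("pairwise Hamming (incl. reverse complements) %d < minDist %d",
                   d, object@minDist))
  TRUE
})

## minimum over all pairs of min(d(x,y), d(x, rc(y))); self-vs-own-rc excluded
barcodePairwiseMin <- function(bc) {
  if (length(bc) < 2L) return(NA_integer_)
  d1 <- hammingMatrix(bc)
  d2 <- hammingMatrix(bc, revComp(bc))
  diag(d1) <- NA_integer_
  diag(d2) <- NA_integer_
  min(pmin(d1, d2), na.rm = TRUE)
}

#' @describeIn BarcodeSet-class number of barcodes
#' @param x a `BarcodeSet`.
#' @export
setMethod("length", "BarcodeSet", function(x) length(x@barcodes))

#' @export
#' @describeIn BarcodeSet-class barcodes as a character vector
setMethod("as.character", "BarcodeSet", function(x) x@barcodes)

setMethod("show", "BarcodeSet", function(object) {
  cat("BarcodeSet: ", length(object@barcodes), " barcodes, min pairwise",
      " Hamming (incl. reverse complements) >= ", object@minDist, "\n",
      sep = "")
})

#' Tag-to-construct lookup table
#'
#' The validated association between degenerate reporter tags and barcoded
#' enhancer constructs, used as the demultiplexing key when counting
#' RNA-seq/DNA-seq reads. Each tag maps to exactly one construct; a construct
#' may carry several tags (internal replicates).
#'
#' @slot entries data.frame with columns `tag`, `enhancer_id`, `allele`,
#'   `barcode`, `support` (read support for the pair).
#' @slot dropped character vector of construct keys
#'   (`enhancer_id|allele|barcode`) for which no tag was validated.
#' @seealso [buildLookup()], [writePseudoGenome()]
#' @export
setClass("LookupTable",
  representation(entries = "data.frame", dropped = "character"))

setValidity("LookupTable", function(object) {
  e <- object@entries
  need <- c("tag", "enhancer_id", "allele", "barcode", "support")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$tag)) return("tags must be unique across the table")
  TRUE
})

#' @describeIn LookupTable-class number of tag entries
#' @param x a `LookupTable`.
#' @export
setMethod("length", "LookupTable", function(x) nrow(x@entries))

#' Accessors for LookupTable
#' @param x a [LookupTable-class].
#' @return `lookupTags()` the tag vector; `lookupEntries()` the entry
#'   data.frame; `droppedConstructs()` construct keys with no validated tag.
#' @export
lookupTags <- function(x) x@entries$tag

#' @rdname lookupTags
#' @export
lookupEntries <- function(x) x@entries

#' @rdname lookupTags
#' @export
droppedConstructs <- function(x) x@dropped

setMethod("show", "LookupTable", function(object) {
  cat("LookupTable: ", nrow(object@entries), " tags over ",
      length(unique(constructKey(object@entries))), " constructs",
      if (length(object@dropped))
        paste0(" (", length(object@dropped), " constructs without tags)"),
      "\n", sep = "")
})

## canonical construct key used throughout
constructKey <- function(df) {
  paste(df$enhancer_id, df$allele, df$barcode, sep = "|")
}

#' Per-tag UMI count table
#'
#' Distinct-UMI and raw read counts per (tag, library type, collection day).
#' Distinct UMIs, not reads, are the molecule-level readout of reporter
#' abundance; reads per tag include PCR duplicates.
#'
#' @slot counts data.frame with columns `enhancer_id`, `allele`, `barcode`,
#'   `tag`, `library` ("RNA" or "DNA"), `day`, `read_count`, `umi_count`.
#' @seealso [countUmis()], [countTags()], [normalizeExpression()]
#' @export
setClass("UmiCountTable", representation(counts = "data.frame"))

setValidity("UmiCountTable", function(object) {
  cc <- object@counts
  need <- c("enhancer_id", "allele", "barcode", "tag", "library", "day",
            "read_count", "umi_count")
  if (!all(need %in% names(cc)))
    return(paste("counts must have columns:", paste(need, collapse = ", ")))
  if (nrow(cc)) {
    if (!all(cc$library %in% c("RNA", "DNA")))
      return("library must be 'RNA' or 'DNA'")
    if (any(cc$umi_count > cc$read_count))
      return("umi_count must be <= read_count")
    if (any(cc$umi_count > 4^8))
      return("umi_count exceeds the 8-mer UMI space")
    if (anyDuplicated(cc[, c("tag", "library", "day")]))
      return("one row per (tag, library, day)")
  }
  TRUE
})

#' @describeIn UmiCountTable-class count rows as a data.frame
#' @param x a `UmiCountTable`.
#' @export
umiCounts <- function(x) x@counts

#' @describeIn UmiCountTable-class number of count rows
#' @export
setMethod("length", "UmiCountTable", function(x) nrow(x@counts))

setMethod("show", "UmiCountTable", function(object) {
  cc <- object@counts
  cat("UmiCountTable: ", nrow(cc), " (tag, library, day) rows; ",
      sum(cc$umi_count), " UMIs / ", sum(cc$read_count), " reads\n", sep = "")
})

#' Combine UMI count tables
#' @param x,... [UmiCountTable-class] objects (e.g. per library or day).
#' @return a single combined `UmiCountTable`.
#' @export
setMethod("rbind2", signature("UmiCountTable", "UmiCountTable"),
  function(x, y) new("UmiCountTable", counts = rbind(x@counts, y@counts)))

#' @rdname rbind2-UmiCountTable-UmiCountTable-method
#' @export
combineCounts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is(tabs[[1]], "UmiCountTable"))
    tabs <- tabs[[1]]
  new("UmiCountTable",
      counts = do.call(rbind, lapply(tabs, umiCounts)))
}
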