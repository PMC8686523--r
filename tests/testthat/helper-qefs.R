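## shared fixtures and independent oracle implementations for the test suite

toyPwms <- qefsToyPWMs()

## small shared design truth, built once per test run (seconds of compute)
sharedTruth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulateDesign(nEnhancers = 3L, enhLen = 600L,
                               tagsPerConstruct = c(4L, 4L), seed = 7L)
    }
    cache
  }
})

## ---- from-scratch statistical oracles (kept deliberately naive) ----------

## tie-corrected Kruskal-Wallis by the textbook formula
oracleKW <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  Ri <- tapply(r, rep(seq_along(groups), n), sum)
  Huncorr <- 12 / (N * (N + 1)) * sum(Ri^2 / n) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- Huncorr / C
  list(H = H, p = stats::pchisq(H, df = length(groups) - 1,
                                lower.tail = FALSE))
}

## Conover-Iman pairwise t statistics and p-values, straight from the formula
oracleConover <- function(groups) {
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- oracleKW(groups)$H
  pairs <- utils::combn(names(groups), 2L)
  res <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n[[i]] + 1 / n[[j]]))
    res$t[c] <- (rbar[[i]] - rbar[[j]]) / se
    res$p[c] <- 2 * stats::pt(-abs(res$t[c]), df = N - k)
  }
  res
}

## Benjamini-Hochberg step-up by hand
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## independent random DNA generator (does not use package internals)
randomDNAForTest <- function(n, width) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               nrow = n),
        1L, paste0, collapse = "")
}

## naive Hamming distance used to verify the matrix implementation
oracleHamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## single characters of a string at given positions
substrChars <- function(x, pos) {
  vapply(pos, function(p) substr(x, p, p), character(1))
}

## random sequence holding exactly one site of `pwm` and none of `others`
plantSingleSite <- function(pwm, others = list(), flank = 40L) {
  repeat {
    seq <- paste0(randomDNAForTest(1, flank), consensusSequence(pwm),
                  randomDNAForTest(1, flank))
    if (nrow(scanPWM(seq, pwm, 6)) != 1L) next
    spurious <- vapply(others, function(p) nrow(scanPWM(seq, p, 6)),
                       integer(1))
    if (!sum(spurious)) return(seq)
  }
}

## minimal UmiCountTable builder for quantify tests
makeCounts <- function(df) {
  df$enhancer_id <- as.character(df$enhancer_id)
  df$allele <- as.character(df$allele)
  df$barcode <- as.character(df$barcode)
  df$tag <- as.character(df$tag)
  if (is.null(df$read_count)) df$read_count <- df$umi_count * 10L
  new("UmiCountTable", counts = df)
}
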