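## hand-built count fixture: one enhancer, two alleles, two days
mkFixture <- function(rnaScale = 1L, dnaScale = 1L) {
  rows <- list()
  add <- function(tag, allele, lib, day, umi) {
    rows[[length(rows) + 1L]] <<- data.frame(
      enhancer_id = "E1", allele = allele, barcode = "AAAACCCC", tag = tag,
      library = lib, day = day, read_count = umi * 20L, umi_count = umi,
      stringsAsFactors = FALSE)
  }
  add("TAG1", "WT", "DNA", 1L, 100L * dnaScale)
  add("TAG2", "WT", "DNA", 1L, 300L * dnaScale)
  add("TAG1", "WT", "RNA", 1L, 80L * rnaScale)
  add("TAG2", "WT", "RNA", 1L, 120L * rnaScale)
  makeCounts(do.call(rbind, rows))
}

test_that("normalizeExpression reproduces hand-computed ratios exactly", {
  expr <- normalizeExpression(mkFixture())
  ## TAG1: (80/200) / (100/400) = 0.4 / 0.25 = 1.6
  ## TAG2: (120/200) / (300/400) = 0.6 / 0.75 = 0.8
  expect_identical(nrow(expr), 2L)
  expect_equal(expr$expression[expr$tag == "TAG1"], 1.6)
  expect_equal(expr$expression[expr$tag == "TAG2"], 0.8)
})

test_that("expression is invariant to scaling either library's depth", {
  base <- normalizeExpression(mkFixture())
  up <- normalizeExpression(mkFixture(rnaScale = 7L))
  expect_equal(up$expression, base$expression)
  up2 <- normalizeExpression(mkFixture(dnaScale = 13L))
  expect_equal(up2$expression, base$expression)
})

test_that("zero-DNA tags are skipped and RNA-absent tags get expression 0", {
  cc <- umiCounts(mkFixture())
  ## add an RNA-only tag and a DNA-only tag
  extra <- rbind(
    data.frame(enhancer_id = "E1", allele = "WT", barcode = "AAAACCCC",
               tag = "TAG3", library = "RNA", day = 1L, read_count = 100L,
               umi_count = 10L, stringsAsFactors = FALSE),
    data.frame(enhancer_id = "E1", allele = "WT", barcode = "AAAACCCC",
               tag = "TAG4", library = "DNA", day = 1L, read_count = 100L,
               umi_count = 50L, stringsAsFactors = FALSE))
  expr <- normalizeExpression(makeCounts(rbind(cc, extra)))
  expect_false("TAG3" %in% expr$tag)
  expect_identical(unname(attr(expr, "zero_dna")["1"]), 1L)
  expect_equal(expr$expression[expr$tag == "TAG4"], 0)
})

test_that("missing paired libraries are a hard error", {
  cc <- umiCounts(mkFixture())
  expect_error(normalizeExpression(makeCounts(cc[cc$library == "RNA", ])),
               "no paired DNA")
  expect_error(normalizeExpression(makeCounts(cc[cc$library == "DNA", ])),
               "no RNA")
})

## adversarial QC fixture builder: full control over umi_dna per tag/day
mkExpr <- function(df) {
  df$enhancer_id <- "E1"
  df$umi_rna <- 50L
  df$barcode <- "AAAACCCC"
  df$expression <- 1
  df[, c("enhancer_id", "allele", "barcode", "tag", "day", "umi_rna",
         "umi_dna", "expression")]
}

## brute-force oracle for the two gates in their fixed order
oracleQC <- function(expr, minDna = 65L, minTags = 4L) {
  keep1 <- expr$umi_dna >= minDna
  e1 <- expr[keep1, , drop = FALSE]
  key <- paste(e1$enhancer_id, e1$allele, e1$barcode, sep = "|")
  nt <- vapply(unique(key), function(k) length(unique(e1$tag[key == k])),
               integer(1))
  e2 <- e1[nt[key] >= minTags, , drop = FALSE]
  rownames(e2) <- NULL
  e2
}

test_that("qcFilter matches the brute-force oracle on adversarial fixtures", {
  ## construct C1: 5 tags, one of which dips below the DNA gate on day 2
  ## (survives: drops to 4 distinct tags -- exactly at the threshold);
  ## construct C2: 4 tags, one killed by the DNA gate -> whole construct
  ## dropped by the tag gate; construct C3: boundary DNA values 64/65
  df <- expand.grid(tag = paste0("t", 1:5), day = 1:2,
                    stringsAsFactors = FALSE)
  df$allele <- "C1"
  df$umi_dna <- 100L
  df$umi_dna[df$tag == "t5"] <- c(100L, 64L)  # below 65 on day 2 only
  c2 <- expand.grid(tag = paste0("u", 1:4), day = 1:2,
                    stringsAsFactors = FALSE)
  c2$allele <- "C2"
  c2$umi_dna <- ifelse(c2$tag == "u4", 10L, 100L)
  c3 <- data.frame(tag = paste0("v", 1:4), day = 1L, allele = "C3",
                   umi_dna = c(64L, 65L, 66L, 200L),
                   stringsAsFactors = FALSE)
  expr <- mkExpr(rbind(df, c2, c3))

  out <- qcFilter(expr)
  oracle <- oracleQC(expr)
  expect_identical(out$expr[order(out$expr$tag, out$expr$day), ]$tag,
                   oracle[order(oracle$tag, oracle$day), ]$tag)
  ## C1 keeps 5 tags with one (tag, day) cell removed
  expect_identical(sum(out$expr$allele == "C1"), 9L)
  ## C2 is gone entirely: the DNA gate reduced it to 3 distinct tags
  expect_identical(sum(out$expr$allele == "C2"), 0L)
  ## C3 is gone: only 3 tags survive the DNA gate (64 < 65 <= 65)
  expect_identical(sum(out$expr$allele == "C3"), 0L)
  ## drop log covers both rules
  expect_setequal(unique(out$dropLog$rule),
                  c("min_dna_per_tag_day", "min_tags_per_construct_week"))
  ## every input row is either kept or logged exactly once
  expect_identical(nrow(out$expr) + nrow(out$dropLog), nrow(expr))
})

test_that("qcFilter handles empty drop sets on either gate", {
  ## nothing dropped at all
  clean <- mkExpr(expand.grid(tag = paste0("t", 1:4), day = 1:2,
                              allele = "C1", umi_dna = 100L,
                              stringsAsFactors = FALSE))
  out <- qcFilter(clean)
  expect_identical(nrow(out$expr), 8L)
  expect_identical(nrow(out$dropLog), 0L)
  ## DNA drops only, no tag-gate drops (regression: mixed 0-length and
  ## scalar columns in the drop log must not error)
  one <- clean
  one$umi_dna[1] <- 10L
  out2 <- qcFilter(one)
  expect_identical(nrow(out2$dropLog), 1L)
  expect_identical(out2$dropLog$rule, "min_dna_per_tag_day")
  ## tag-gate drops only
  three <- mkExpr(expand.grid(tag = paste0("t", 1:3), day = 1:2,
                              allele = "C1", umi_dna = 100L,
                              stringsAsFactors = FALSE))
  out3 <- qcFilter(three)
  expect_identical(nrow(out3$expr), 0L)
  expect_identical(unique(out3$dropLog$rule), "min_tags_per_construct_week")
})

test_that("qcFilter can gate on raw DNA reads instead of UMIs", {
  cc <- umiCounts(mkFixture())
  ## TAG1: few distinct molecules (50 UMIs, below the gate) but deeply
  ## sequenced (1000 reads, above it) -- the two gate bases disagree
  sel <- cc$library == "DNA" & cc$tag == "TAG1"
  cc$read_count[sel] <- 1000L
  cc$umi_count[sel] <- 50L
  counts <- makeCounts(cc)
  expr <- normalizeExpression(counts)
  byUmi <- qcFilter(expr, minTagsPerConstructWeek = 1L)
  expect_false("TAG1" %in% byUmi$expr$tag)
  byReads <- qcFilter(expr, minTagsPerConstructWeek = 1L, gateOn = "reads",
                      counts = counts)
  expect_true("TAG1" %in% byReads$expr$tag)
  expect_error(qcFilter(expr, gateOn = "reads"), "requires")
})

test_that("aggregateReplicates pools tag-by-day cells (3 x 3 = 9)", {
  df <- expand.grid(tag = paste0("t", 1:3), day = 1:3,
                    stringsAsFactors = FALSE)
  df$allele <- "WT"
  df$umi_dna <- 100L
  expr <- mkExpr(df)
  expr$expression <- seq_len(nrow(expr))
  obs <- aggregateReplicates(expr, by = "allele")
  expect_identical(names(obs), "WT")
  expect_length(obs$WT, 9L)
  expect_setequal(obs$WT, 1:9)
})

test_that("foldChange propagates the standard error of the ratio", {
  wt <- c(2, 2.2, 1.8, 2.1)
  mut <- c(1, 1.1, 0.9)
  fc <- foldChange(mut, wt)
  expect_equal(fc$fold_change, mean(mut) / mean(wt))
  semW <- sd(wt) / sqrt(4)
  semM <- sd(mut) / sqrt(3)
  expect_equal(fc$sem, fc$fold_change *
                 sqrt((semM / mean(mut))^2 + (semW / mean(wt))^2))
  expect_identical(fc$n_obs, 3L)
  ## single observations contribute zero to the propagated error
  fc1 <- foldChange(1.5, wt)
  expect_equal(fc1$sem, fc1$fold_change * (semW / mean(wt)))
  expect_error(foldChange(mut, c(0, 0)), "positive")
})

test_that("seriesFoldChanges returns NULL with a warning when WT failed QC", {
  obs <- list(m1 = c(1, 2), m2 = c(2, 3))
  expect_warning(out <- seriesFoldChanges(obs, "E1"), "wildtype")
  expect_null(out)
  obs$WT <- c(2, 2)
  out <- seriesFoldChanges(obs, "E1")
  expect_identical(nrow(out), 3L)
  expect_equal(out$fold_change[out$allele == "WT"], 1)
  expect_equal(out$fold_change[out$allele == "m1"], 1.5 / 2)
})
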