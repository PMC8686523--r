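AD5 <- "CGCGGGATGCTAGCACGCGG"
AD3 <- "ACATATAGGACCAG"

mkLut <- function(tags) {
  new("LookupTable",
      entries = data.frame(tag = tags,
                           enhancer_id = "E1",
                           allele = paste0("a", seq_along(tags)),
                           barcode = strrep("A", 8),
                           support = 10L, stringsAsFactors = FALSE),
      dropped = character(0))
}

test_that("extractUmi splits the 8-base prefix", {
  reads <- c(paste0("ACGTACGT", "TTTTCCCC"), "SHORT")
  out <- extractUmi(reads)
  expect_identical(out$umi, "ACGTACGT")
  expect_identical(out$rest, "TTTTCCCC")
  expect_identical(out$keep, 1L)
  expect_identical(out$n_rejected, 1L)
  ident <- extractUmi(reads, umiLen = 0L)
  expect_identical(ident$rest, reads)
  expect_identical(ident$n_rejected, 0L)
})

test_that("trimConstantRegions removes both adapters exactly", {
  tag <- strrep("ACGGT", 4)
  out <- trimConstantRegions(paste0(AD5, tag, AD3))
  expect_identical(out$tag, tag)
  expect_identical(out$n_rejected_length, 0L)
})

test_that("trimConstantRegions tolerates mismatches within the error rate", {
  tag <- strrep("TGCAC", 4)
  a5 <- AD5
  ## floor(0.3 * 20) = 6 mismatches allowed in the 5' adapter
  for (p in c(2L, 5L, 8L, 11L, 14L, 17L)) {
    substr(a5, p, p) <- chartr("ACGT", "CGTA", substr(a5, p, p))
  }
  out <- trimConstantRegions(paste0(a5, tag, AD3))
  expect_identical(out$tag, tag)
  ## one mismatch beyond the allowance: adapter not found, read passes
  ## through untrimmed at the 5' end
  a5bad <- a5
  substr(a5bad, 20L, 20L) <- chartr("ACGT", "CGTA", substr(a5bad, 20L, 20L))
  out2 <- trimConstantRegions(paste0(a5bad, tag, AD3))
  expect_identical(out2$tag, paste0(a5bad, tag))
})

test_that("absent adapters pass reads through untrimmed", {
  tag <- strrep("GATCA", 4)
  out <- trimConstantRegions(paste0(tag, AD3))       # no 5' adapter
  expect_identical(out$tag, tag)
  out <- trimConstantRegions(paste0(AD5, tag))       # no 3' adapter
  expect_identical(out$tag, tag)
  out <- trimConstantRegions(tag)                    # neither
  expect_identical(out$tag, tag)
})

test_that("trimConstantRegions drops products shorter than minLen", {
  out <- trimConstantRegions(paste0(AD5, "ACGTACG", AD3), minLen = 10L)
  expect_length(out$tag, 0L)
  expect_identical(out$n_rejected_length, 1L)
})

test_that("assignTag demultiplexes with the unique-minimum rule", {
  set.seed(61)
  tags <- unique(randomDNAForTest(30, 20))
  lut <- mkLut(tags)
  ## exact
  out <- assignTag(tags[1:3], lut)
  expect_identical(out$tag, tags[1:3])
  expect_true(all(out$reason == "assigned"))
  ## 1 and 2 mismatches
  mm1 <- tags[4]; substr(mm1, 7, 7) <- chartr("ACGT", "CGTA", substr(mm1, 7, 7))
  mm2 <- mm1; substr(mm2, 15, 15) <- chartr("ACGT", "CGTA", substr(mm2, 15, 15))
  mm3 <- mm2; substr(mm3, 1, 1) <- chartr("ACGT", "CGTA", substr(mm3, 1, 1))
  out <- assignTag(c(mm1, mm2, mm3), lut)
  expect_identical(out$tag[1:2], rep(tags[4], 2))
  expect_identical(out$tag[3], NA_character_)   # 3 mismatches: no hit
  expect_identical(as.character(out$reason[3]), "no_hit")
})

test_that("assignTag flags ties as ambiguous", {
  t1 <- strrep("A", 20)
  t2 <- paste0(strrep("A", 18), "CC")
  lut <- mkLut(c(t1, t2))
  ## equidistant candidate: one mismatch from each
  cand <- paste0(strrep("A", 18), "CA")
  out <- assignTag(cand, lut)
  expect_identical(out$tag, NA_character_)
  expect_identical(as.character(out$reason), "ambiguous")
})

test_that("assignTag gates candidate length at +/- 2 with prefix comparison", {
  set.seed(62)
  tags <- unique(randomDNAForTest(10, 20))
  lut <- mkLut(tags)
  shortBy2 <- substr(tags[1], 1, 18)
  longBy2 <- paste0(tags[2], "GG")
  wayOff <- substr(tags[3], 1, 15)
  out <- assignTag(c(shortBy2, longBy2, wayOff), lut)
  expect_identical(out$tag[1], tags[1])
  expect_identical(out$tag[2], tags[2])
  expect_identical(as.character(out$reason[3]), "length")
})

test_that("countUmis deduplicates exact UMI sequences, order-invariantly", {
  tags <- c(strrep("A", 20), strrep("C", 20))
  lut <- mkLut(tags)
  asg <- data.frame(
    tag = c(rep(tags[1], 5), rep(tags[2], 2)),
    umi = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "CCCCCCCC",
            "TTTTTTTT", "TTTTTTTT"),
    library = "RNA", day = 1L, stringsAsFactors = FALSE)
  tab <- umiCounts(countUmis(asg, lut))
  expect_identical(tab$read_count[tab$tag == tags[1]], 5L)
  expect_identical(tab$umi_count[tab$tag == tags[1]], 3L)
  expect_identical(tab$umi_count[tab$tag == tags[2]], 1L)
  ## permuting the input rows changes nothing
  set.seed(63)
  tab2 <- umiCounts(countUmis(asg[sample(nrow(asg)), ], lut))
  expect_identical(tab2, tab)
})

test_that("optional Hamming-1 UMI collapse merges near-duplicates", {
  tags <- strrep("A", 20)
  lut <- mkLut(tags)
  asg <- data.frame(
    tag = tags,
    umi = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAT", "GGGGCCCC"),
    library = "DNA", day = 1L, stringsAsFactors = FALSE)[rep(1, 4), ]
  asg$umi <- c("AAAAAAAA", "AAAAAAAA", "AAAAAAAT", "GGGGCCCC")
  tab <- umiCounts(countUmis(asg, lut))
  expect_identical(tab$umi_count, 3L)
  tabC <- umiCounts(countUmis(asg, lut, collapseUmis = TRUE))
  expect_identical(tabC$umi_count, 2L)  # AAAAAAAT absorbed
})

test_that("countTags conserves reads across the reject categories", {
  truth <- sharedTruth()
  sim <- simulateReads(truth, depthPerTag = 30, days = 1L, seed = 64L)
  parsed <- parseLookupReads(sim$lookup)
  lut <- buildLookup(parsed$pairs, truth$constructs)
  res <- countTags(sim$rna[[1]], lut, library = "RNA", day = 1L)
  s <- res$summary
  expect_identical(unname(s["total"]),
                   unname(s["rejected_umi"] + s["rejected_trim"] +
                          s["unassigned_no_hit"] +
                          s["unassigned_ambiguous"] +
                          s["unassigned_length"] + s["assigned"]))
  expect_identical(unname(s["total"]), length(sim$rna[[1]]))
  expect_gt(s[["assigned"]] / s[["total"]], 0.9)
  cc <- umiCounts(res$counts)
  expect_true(all(cc$umi_count <= cc$read_count))
  expect_identical(sum(cc$read_count), s[["assigned"]])
})

test_that("countTags accepts FASTQ input identically to in-memory reads", {
  truth <- sharedTruth()
  sim <- simulateReads(truth, depthPerTag = 10, days = 1L, seed = 65L)
  parsed <- parseLookupReads(sim$lookup)
  lut <- buildLookup(parsed$pairs, truth$constructs)
  dir <- withr::local_tempdir()
  paths <- writeSimFastq(sim, dir)
  fromFile <- countTags(paths[["rna_day1"]], lut, library = "RNA", day = 1L)
  fromMem <- countTags(sim$rna[[1]], lut, library = "RNA", day = 1L)
  expect_identical(umiCounts(fromFile$counts), umiCounts(fromMem$counts))
})

test_that("count tables round-trip through TSV", {
  tags <- c(strrep("A", 20), strrep("C", 20))
  lut <- mkLut(tags)
  asg <- data.frame(tag = tags, umi = c("AAAAAAAA", "CCCCCCCC"),
                    library = "DNA", day = 2L, stringsAsFactors = FALSE)
  tab <- countUmis(asg, lut)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTable(tab, path)
  back <- readCountsTable(path)
  expect_identical(umiCounts(back), umiCounts(tab))
})
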