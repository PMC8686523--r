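#' Simulate a combinatorial motif-mutant reporter library design
#'
#' Generates `nEnhancers` random enhancers, plants near-consensus sites for
#' the three motif classes at non-overlapping positions, designs
#' site-destroying mutations with the package's own mutagenesis machinery
#' (guarding the other classes' sites), expands every enhancer into its 2^3
#' allelic series with designed barcodes, and assigns random unique 20-mer
#' tags to each construct. Per-construct population abundances (Dirichlet)
#' and true activities (exactly multiplicative over the planted log-scale
#' motif effects plus any pairwise interaction terms) complete the ground
#' truth.
#'
#' @param nEnhancers number of enhancers (default 12).
#' @param enhLen enhancer length in nt (default 1000).
#' @param pwms named list of >= 3 [PWModel-class]; the first 3 are the
#'   mutated classes (default [qefsToyPWMs()]).
#' @param sitesPerClass integer range, sites planted per class per enhancer
#'   (default c(1, 8)).
#' @param tagsPerConstruct integer range of tags per construct (default
#'   c(1, 6)).
#' @param motifEffectMeanlog,motifEffectSdlog distribution of per-enhancer,
#'   per-class log-scale activity effects of destroying that class's sites
#'   (default meanlog log(0.5), sdlog 0.3: mostly activity-reducing).
#' @param interactions optional data.frame `enhancer_id`, `class_a`,
#'   `class_b`, `effect` of planted pairwise log-scale interaction terms
#'   (default none: exactly multiplicative).
#' @param baselineSdlog sd of per-enhancer log baseline activity
#'   (default 0.5).
#' @param dirichletAlpha concentration of the per-construct abundance
#'   Dirichlet (default 5; smaller = more uneven representation).
#' @param llrMin site-calling threshold (default 6).
#' @param seed optional RNG seed (integer) for reproducibility.
#' @return a `qefs_truth` list: `constructs` (design data.frame with
#'   `activity`, `abundance` and tag list-column `tags`), `tags` (long
#'   data.frame tag -> construct), `enhancers`, `motifClasses`, `effects`,
#'   `interactions`, `baseline`, `pwms`, `params`.
#' @export
simulateDesign <- function(nEnhancers = 12L, enhLen = 1000L,
                           pwms = qefsToyPWMs(), sitesPerClass = c(1L, 8L),
                           tagsPerConstruct = c(1L, 6L),
                           motifEffectMeanlog = log(0.5),
                           motifEffectSdlog = 0.3,
                           interactions = NULL, baselineSdlog = 0.5,
                           dirichletAlpha = 5, llrMin = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nEnhancers >= 1L, length(pwms) >= 3L)
  classes <- vapply(pwms[1:3], function(p) p@name, character(1))
  classPwms <- setNames(pwms[1:3], classes)

  barcodes <- designBarcodes(nEnhancers * 8L, pwms = classPwms,
                             minDist = 3L)
  if (length(barcodes) < nEnhancers * 8L)
    stop("not enough barcodes for the requested library")

  enhIds <- sprintf("ENH%03d", seq_len(nEnhancers))
  enhancers <- character(nEnhancers)
  constructs <- list()
  effects <- list()
  for (e in seq_len(nEnhancers)) {
    ## spurious sites in the random background can occasionally make a
    ## mutation design infeasible; redraw the enhancer when that happens
    designed <- NULL
    for (attempt in seq_len(25L)) {
      planted <- plantSites(enhLen, classPwms, sitesPerClass, llrMin)
      designed <- tryCatch({
        edits <- lapply(setNames(classes, classes), function(cl) {
          sites <- scanPWM(planted$seq, classPwms[[cl]], llrMin)
          guards <- classPwms[setdiff(classes, cl)]
          ed <- lapply(seq_len(nrow(sites)), function(i)
            designMutation(planted$seq, sites[i, ], classPwms[[cl]], guards,
                           llrMin))
          ed <- unique(do.call(rbind, ed))
          ed[order(ed$pos), , drop = FALSE]
        })
        if (anyDuplicated(unlist(lapply(edits, `[[`, "pos"))))
          stop("edit collision between classes")
        series <- buildAllelicSeries(enhIds[e], planted$seq, classes, edits,
                                     barcodes, offset = (e - 1L) * 8L)
        ## scan-back: no allele may retain (or jointly re-create) a site of
        ## a class it mutates
        for (i in seq_len(nrow(series))) {
          if (series$allele[i] == "WT") next
          for (cl in strsplit(series$allele[i], "+", fixed = TRUE)[[1]]) {
            if (nrow(scanPWM(series$enhancer_seq[i], classPwms[[cl]],
                             llrMin)))
              stop("residual ", cl, " site in allele ", series$allele[i])
          }
        }
        series
      }, error = function(err) NULL)
      if (!is.null(designed)) break
    }
    if (is.null(designed))
      stop("could not design a feasible allelic series for ", enhIds[e])
    enhancers[e] <- planted$seq
    constructs[[e]] <- designed
    effects[[e]] <- data.frame(
      enhancer_id = enhIds[e], class = classes,
      effect = stats::rnorm(3L, motifEffectMeanlog, motifEffectSdlog),
      stringsAsFactors = FALSE)
  }
  constructs <- do.call(rbind, constructs)
  effects <- do.call(rbind, effects)
  if (is.null(interactions)) {
    interactions <- data.frame(enhancer_id = character(0),
                               class_a = character(0),
                               class_b = character(0), effect = numeric(0),
                               stringsAsFactors = FALSE)
  }
  baseline <- setNames(stats::rnorm(nEnhancers, 0, baselineSdlog), enhIds)
  constructs$activity <- trueActivity(constructs, effects, interactions,
                                      baseline)
  ab <- stats::rgamma(nrow(constructs), shape = dirichletAlpha)
  constructs$abundance <- ab / sum(ab)

  nTags <- sampleRange(tagsPerConstruct, nrow(constructs))
  tagPool <- unique(randomDNA(sum(nTags) * 2L, 20L))[seq_len(sum(nTags))]
  tags <- data.frame(
    tag = tagPool,
    enhancer_id = rep(constructs$enhancer_id, nTags),
    allele = rep(constructs$allele, nTags),
    barcode = rep(constructs$barcode, nTags), stringsAsFactors = FALSE)
  truth <- list(constructs = constructs, tags = tags,
                enhancers = setNames(enhancers, enhIds),
                motifClasses = classes, effects = effects,
                interactions = interactions, baseline = baseline,
                pwms = classPwms,
                params = list(nEnhancers = nEnhancers, enhLen = enhLen,
                              llrMin = llrMin, seed = seed))
  class(truth) <- "qefs_truth"
  truth
}

#' @export
print.qefs_truth <- function(x, ...) {
  cat("qefs simulation truth:", nrow(x$constructs), "constructs (",
      length(x$enhancers), "enhancers x 8 alleles ),",
      nrow(x$tags), "tags\n")
  invisible(x)
}

## random sequence with non-overlapping near-consensus sites per class;
## retries on collision
plantSites <- function(enhLen, classPwms, sitesPerClass, llrMin,
                       maxTries = 50L) {
  for (try in seq_len(maxTries)) {
    seq <- randomDNA(1L, enhLen)
    occupied <- integer(0)
    ok <- TRUE
    for (pwm in classPwms) {
      L <- length(pwm)
      nSites <- sampleRange(sitesPerClass, 1L)
      for (s in seq_len(nSites)) {
        placed <- FALSE
        for (att in seq_len(200L)) {
          st <- sample.int(enhLen - L + 1L, 1L)
          win <- st:(st + L - 1L)
          ## pad so edits near one site cannot create/destroy a neighbour
          pad <- max(vapply(classPwms, length, integer(1)))
          if (any((st - pad):(st + L - 1L + pad) %in% occupied)) next
          substr(seq, st, st + L - 1L) <- consensusSequence(pwm)
          occupied <- c(occupied, win)
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    ## verify: every class has >= 1 called site and no spurious overlaps
    ## broke another class's sites
    calls <- lapply(classPwms, function(p) scanPWM(seq, p, llrMin))
    if (all(vapply(calls, nrow, integer(1)) >= 1L)) {
      return(list(seq = seq, calls = calls))
    }
  }
  stop("failed to plant non-colliding sites after ", maxTries, " tries")
}

## exp(baseline + sum of mutated-class effects + interaction terms)
trueActivity <- function(constructs, effects, interactions, baseline) {
  vapply(seq_len(nrow(constructs)), function(i) {
    enh <- constructs$enhancer_id[i]
    mutated <- if (constructs$allele[i] == "WT") character(0)
               else strsplit(constructs$allele[i], "+", fixed = TRUE)[[1]]
    eff <- effects[effects$enhancer_id == enh &
                     effects$class %in% mutated, "effect"]
    intEff <- 0
    if (length(mutated) >= 2L && nrow(interactions)) {
      for (pr in utils::combn(sort(mutated), 2L, simplify = FALSE)) {
        hit <- interactions$enhancer_id == enh &
          interactions$class_a == pr[1] & interactions$class_b == pr[2]
        intEff <- intEff + sum(interactions$effect[hit])
      }
    }
    exp(baseline[[enh]] + sum(eff) + intEff)
  }, numeric(1))
}

#' Simulate lookup, RNA-seq and DNA-seq reads from a design truth
#'
#' DNA template molecules per tag and day are Poisson with mean
#' `depthPerTag` times the construct's (normalized) abundance weight; RNA
#' molecules additionally scale with the construct's true activity and a
#' per-(tag, day) lognormal biological noise term of coefficient of
#' variation `cv`. Every molecule receives a random 8-mer UMI and is
#' sequenced `1 + Geometric` times with mean `pcrDupMean` reads per molecule;
#' every read is `UMI + 5' constant + tag + 3' constant` with iid base errors
#' at `baseError`. Lookup reads pair each barcode with each of its tags per
#' the re-circularization structure, `poolDepth` reads per pair.
#'
#' @param truth a `qefs_truth` from [simulateDesign()].
#' @param depthPerTag expected DNA molecules per tag per day at unit
#'   abundance weight (default 200).
#' @param days number of collection days in the week (default 3).
#' @param pcrDupMean mean reads per molecule (default 1.3; 1 = no
#'   duplication).
#' @param baseError per-base sequencing error rate (default 0.005).
#' @param cv biological coefficient of variation of activity per (tag, day)
#'   (default 0.2).
#' @param poolDepth lookup reads per (barcode, tag) pair (default 50).
#' @param fiveAdapter,threeAdapter reporter-read constants (defaults match
#'   [countTags()]).
#' @param lutStructure lookup read structure ([lookupStructure()]).
#' @param seed optional RNG seed.
#' @return list with `lookup` (character reads), `rna` and `dna` (lists of
#'   character read vectors, one per day), and `molecules` (data.frame of
#'   true molecule counts per tag, library, day).
#' @export
simulateReads <- function(truth, depthPerTag = 200, days = 3L,
                          pcrDupMean = 1.3, baseError = 0.005, cv = 0.2,
                          poolDepth = 50,
                          fiveAdapter = "CGCGGGATGCTAGCACGCGG",
                          threeAdapter = "ACATATAGGACCAG",
                          lutStructure = lookupStructure(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depthPerTag >= 1, pcrDupMean >= 1)
  tags <- truth$tags
  con <- truth$constructs
  key <- constructKey(tags)
  ck <- constructKey(con)
  nTagsPer <- table(key)[ck]
  ## abundance weight per tag, normalized to mean 1 so depthPerTag is the
  ## average expected DNA molecule count per tag
  w <- (con$abundance[match(key, ck)] /
          as.integer(nTagsPer[match(key, ck)]))
  w <- w / mean(w)
  activity <- con$activity[match(key, ck)]

  molecules <- list()
  rna <- dna <- vector("list", days)
  sdlog <- sqrt(log(1 + cv^2))
  for (d in seq_len(days)) {
    nDna <- stats::rpois(length(w), depthPerTag * w)
    bio <- stats::rlnorm(length(w), -sdlog^2 / 2, sdlog)
    nRna <- stats::rpois(length(w), depthPerTag * w * activity * bio)
    molecules[[d]] <- data.frame(tag = rep(tags$tag, 2L),
                                 library = rep(c("DNA", "RNA"),
                                               each = length(w)),
                                 day = d, n_molecules = c(nDna, nRna),
                                 stringsAsFactors = FALSE)
    dna[[d]] <- reporterReads(tags$tag, nDna, pcrDupMean, baseError,
                              fiveAdapter, threeAdapter)
    rna[[d]] <- reporterReads(tags$tag, nRna, pcrDupMean, baseError,
                              fiveAdapter, threeAdapter)
  }
  nPair <- stats::rpois(nrow(tags), poolDepth)
  lookup <- paste0(lutStructure$anchor1,
                   rep(tags$barcode, nPair),
                   lutStructure$anchor2,
                   rep(tags$tag, nPair))
  lookup <- injectErrors(lookup, baseError)
  list(lookup = lookup, rna = rna, dna = dna,
       molecules = do.call(rbind, molecules))
}

## expand molecules into reads: UMI + const5 + tag + const3, PCR-duplicated
## geometrically, with iid base errors
reporterReads <- function(tagSeq, nMolecules, pcrDupMean, baseError,
                          fiveAdapter, threeAdapter) {
  total <- sum(nMolecules)
  if (total == 0L) return(character(0))
  tagOfMol <- rep(tagSeq, nMolecules)
  umi <- randomDNA(total, 8L)
  dup <- 1L + if (pcrDupMean > 1) {
    stats::rgeom(total, prob = 1 / pcrDupMean)
  } else rep(0L, total)
  reads <- paste0(rep(umi, dup), fiveAdapter, rep(tagOfMol, dup),
                  threeAdapter)
  injectErrors(reads, baseError)
}

## iid substitution errors at rate `rate` (error base drawn from the 3
## alternatives); vectorized over reads of equal length
injectErrors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads)
  nErr <- stats::rpois(length(reads), rate * len)  # ~Binomial(len, rate)
  mx <- max(nErr)
  if (mx == 0L) return(reads)
  for (k in seq_len(mx)) {
    sel <- which(nErr >= k)
    pos <- 1L + floor(stats::runif(length(sel)) * len[sel])
    cur <- substr(reads[sel], pos, pos)
    ## shift each base to one of the other three
    shift <- sample.int(3L, length(sel), replace = TRUE)
    alt <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
    substr(reads[sel], pos, pos) <- alt
  }
  reads
}

#' Write simulated reads as FASTQ
#'
#' Plain-text FASTQ with constant qualities ("I", Q40); one file for the
#' lookup library and one per (library type, day).
#'
#' @param sim result of [simulateReads()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimFastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFq <- function(reads, path, prefix) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("%s_%07d", prefix, seq_along(reads))
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
    path
  }
  paths <- c(lookup = writeFq(sim$lookup, file.path(dir, "lookup.fastq"),
                              "lut"))
  for (d in seq_along(sim$rna)) {
    paths[paste0("rna_day", d)] <-
      writeFq(sim$rna[[d]], file.path(dir, sprintf("rna_day%d.fastq", d)),
              sprintf("rna%d", d))
    paths[paste0("dna_day", d)] <-
      writeFq(sim$dna[[d]], file.path(dir, sprintf("dna_day%d.fastq", d)),
              sprintf("dna%d", d))
  }
  invisible(paths)
}

#' Write the simulation ground truth as TSVs
#'
#' Three files: `truth_constructs.tsv` (design, activity, abundance),
#' `truth_interactions.tsv`, and -- when a [simulateReads()] result is given
#' -- `truth_molecules.tsv` (true molecule counts per tag/library/day).
#' Round-trips losslessly through [readTruthTable()].
#'
#' @param truth a `qefs_truth`.
#' @param dir output directory.
#' @param sim optional [simulateReads()] result.
#' @return named vector of paths, invisibly.
#' @export
truthTable <- function(truth, dir, sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(
    constructs = w(truth$constructs[, c("enhancer_id", "allele", "barcode",
                                        "activity", "abundance", "n_subs")],
                   "truth_constructs.tsv"),
    tags = w(truth$tags, "truth_tags.tsv"),
    interactions = w(truth$interactions, "truth_interactions.tsv"))
  if (!is.null(sim)) {
    paths["molecules"] <- w(sim$molecules, "truth_molecules.tsv")
  }
  invisible(paths)
}

#' @rdname truthTable
#' @export
readTruthTable <- function(dir) {
  r <- function(name, classes = NA) {
    utils::read.table(file.path(dir, name), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = classes)
  }
  out <- list(constructs = r("truth_constructs.tsv"),
              tags = r("truth_tags.tsv"),
              interactions = r("truth_interactions.tsv"))
  mol <- file.path(dir, "truth_molecules.tsv")
  if (file.exists(mol)) {
    out$molecules <- utils::read.table(mol, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  }
  out
}
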