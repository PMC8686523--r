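#' Read PWMs from MEME minimal format or a tabular file
#'
#' `readPWM()` auto-detects the format: files containing a `MOTIF` line are
#' parsed as MEME minimal format (letter-probability matrices); otherwise the
#' file is read as a 4- or 5-column table (optional motif name column
#' followed by A, C, G, T probabilities, one row per position, `#` comments
#' allowed). All motifs in the file are returned.
#'
#' @param path file path.
#' @param background background base frequencies applied to every motif
#'   (default uniform; a MEME `Background letter frequencies` line overrides
#'   it).
#' @param pseudocount per-base pseudocount (default 1e-3).
#' @return named list of [PWModel-class] objects.
#' @export
readPWM <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MOTIF\\b", lines))) {
    readMemePWM(lines, background, pseudocount)
  } else {
    readTabularPWM(lines, background, pseudocount)
  }
}

readMemePWM <- function(lines, background, pseudocount) {
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bases <- toupper(toks[is.na(vals)])
    nums <- vals[!is.na(vals)]
    if (length(nums) == 4L && identical(bases, DNA_BASES)) background <- nums
  }
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    i <- s + 1L
    while (i <= length(lines) && !grepl("^letter-probability", lines[i])) i <- i + 1L
    if (i > length(lines)) stop("MEME motif '", name, "' has no matrix")
    rows <- list()
    j <- i + 1L
    while (j <= length(lines)) {
      toks <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) != 4L || any(is.na(vals))) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    mat <- t(do.call(rbind, rows))  # 4 x L
    pwms[[name]] <- PWModel(mat, name = name, background = background,
                            pseudocount = pseudocount)
  }
  pwms
}

readTabularPWM <- function(lines, background, pseudocount) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tab <- utils::read.table(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 5L) {
    split_tab <- split(tab[, 2:5], tab[, 1])
    lapply(setNames(names(split_tab), names(split_tab)), function(nm)
      PWModel(t(as.matrix(split_tab[[nm]])), name = nm,
              background = background, pseudocount = pseudocount))
  } else if (ncol(tab) == 4L) {
    list(pwm = PWModel(t(as.matrix(tab)), name = "pwm",
                       background = background, pseudocount = pseudocount))
  } else stop("tabular PWM file must have 4 or 5 columns")
}

#' Write PWMs in MEME minimal format
#' @param pwms list of [PWModel-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePWM <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies", paste(
                 rbind(DNA_BASES, format(pwms[[1]]@background, digits = 4)),
                 collapse = " "), ""), con)
  for (pwm in pwms) {
    writeLines(c(paste("MOTIF", pwm@name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         length(pwm))), con)
    writeLines(apply(pwm@prob, 2L, function(p)
      paste(format(p, digits = 6), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Bundled toy PWMs
#'
#' Three compact synthetic motifs (plus one degenerate one) shipped with the
#' package for examples, tests and the simulator. They are synthetic: chosen
#' for distinct consensus sequences and realistic information content, not
#' derived from any experimental PBM or ChIP data.
#'
#' @return named list of [PWModel-class] objects.
#' @export
qefsToyPWMs <- function() {
  readPWM(system.file("extdata", "toy_pwms.meme", package = "qefs"))
}

## per-position log(p/bg) matrix, 4 x L
llrMatrix <- function(pwm) {
  log(pwm@prob / pwm@background)
}

## LLR of a single window (character string, length == motif length)
windowLLR <- function(window, pwm) {
  b <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!b %in% DNA_BASES)) return(NA_real_)
  m <- llrMatrix(pwm)
  sum(m[cbind(match(b, DNA_BASES), seq_along(b))])
}

#' Maximum possible LLR score of a PWM (its consensus score)
#' @param pwm a [PWModel-class].
#' @return consensus log-likelihood-ratio score in nats.
#' @export
pwmMaxScore <- function(pwm) {
  sum(log(apply(pwm@prob, 2L, max) / pwm@background[
    apply(pwm@prob, 2L, which.max)]))
}
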