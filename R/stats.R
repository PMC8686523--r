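#' Kruskal-Wallis omnibus test over an allelic series
#'
#' Rank-based one-way analysis of variance on mid-ranks with tie correction;
#' the p-value comes from the chi-square distribution with k - 1 degrees of
#' freedom. Computed with [stats::kruskal.test()]. When all observations are
#' identical the statistic is 0 and p is 1.
#'
#' @param groups list of numeric observation vectors (>= 2 groups, each
#'   non-empty, total N >= 3).
#' @return list with `H` (tie-corrected statistic), `p`, `df`, `n` (total
#'   observations), `k` (groups).
#' @export
kruskalWallis <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  stopifnot(length(groups) >= 2L, sum(lengths(groups)) >= 3L)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x),
                k = length(groups)))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x), k = length(groups))
}

#' Conover-Iman post-hoc pairwise tests
#'
#' Rank-preserving pairwise comparisons within a series, valid only when the
#' Kruskal-Wallis omnibus null has been rejected. Using the mid-ranks shared
#' with the omnibus test,
#' t_ij = (Rbar_i - Rbar_j) / sqrt(S^2 * (N - 1 - H) / (N - k) * (1/n_i + 1/n_j)),
#' where S^2 = (sum r^2 - N (N+1)^2 / 4) / (N - 1) is the tie-adjusted rank
#' variance and H the tie-corrected Kruskal-Wallis statistic; two-sided
#' p-values come from Student's t with N - k degrees of freedom.
#'
#' @param groups named list of numeric observation vectors; empty groups are
#'   excluded with a warning.
#' @param omnibusRejected logical: did the Kruskal-Wallis test reject at the
#'   working alpha? If FALSE the results are still computed but flagged
#'   `valid = FALSE`, and they must not be used for significance calls.
#' @return data.frame with `group_i`, `group_j`, `t`, `p` (raw, two-sided)
#'   and the `valid` flag.
#' @export
conoverIman <- function(groups, omnibusRejected = TRUE) {
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  stopifnot(k >= 2L)
  if (is.null(names(groups))) names(groups) <- seq_len(k)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- lengths(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- if (S2 > 0) {
    (sum(tapply(r, g, sum)^2 / n) - N * (N + 1)^2 / 4) / S2
  } else 0
  pairs <- utils::combn(names(groups), 2L)
  tstat <- pval <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se2 <- S2 * ((N - 1 - H) / (N - k)) * (1 / n[[i]] + 1 / n[[j]])
    if (se2 <= 0) { tstat[c] <- 0; pval[c] <- 1; next }
    tstat[c] <- (rbar[[i]] - rbar[[j]]) / sqrt(se2)
    pval[c] <- 2 * stats::pt(-abs(tstat[c]), df = N - k)
  }
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ], t = tstat,
             p = pval, valid = omnibusRejected, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`: step-up
#' false-discovery-rate adjustment with monotonicity enforcement, capped at
#' 1, input order restored.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order and length.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Full allelic-series testing
#'
#' Kruskal-Wallis omnibus over the series; if it rejects at `alpha`, the
#' Conover-Iman post-hoc pairwise tests are run on the shared ranks and
#' BH-adjusted as one family. If the omnibus does not reject, no pairwise
#' significance is reported (the post-hoc test is only valid after omnibus
#' rejection).
#'
#' @param obsByAllele named list of observation vectors (one per allele).
#' @param enhancerId label for the output.
#' @param alpha working significance level (default 0.1, applied to both the
#'   omnibus gate and the BH-adjusted pairwise calls).
#' @return list with `enhancer_id`, `kw_H`, `kw_p`, `pairwise` (data.frame
#'   `group_i`, `group_j`, `t`, `p`, `adj_p`, `significant`, or NULL when the
#'   omnibus did not reject), `alpha`.
#' @export
runAllelicSeries <- function(obsByAllele, enhancerId = "enhancer",
                             alpha = 0.1) {
  kw <- kruskalWallis(obsByAllele)
  pairwise <- NULL
  if (kw$p < alpha) {
    pw <- conoverIman(obsByAllele, omnibusRejected = TRUE)
    pw$adj_p <- bhAdjust(pw$p)
    pw$significant <- pw$adj_p < alpha
    pw$valid <- NULL
    pairwise <- pw
  }
  list(enhancer_id = enhancerId, kw_H = kw$H, kw_p = kw$p,
       pairwise = pairwise, alpha = alpha)
}

#' Multiplicative-model epistasis test
#'
#' All replicate expression observations for the wildtype, the two single
#' mutants and the double mutant are log-transformed and fit by ordinary
#' least squares with indicator covariates for each mutation and their
#' product; the returned coefficient and two-sided p-value belong to the
#' interaction term. Under the multiplicative null the interaction
#' coefficient is 0; in the balanced case it equals mean log(AB) -
#' mean log(A) - mean log(B) + mean log(WT). Observations equal to 0 are
#' replaced by half the smallest positive observation across the four cells
#' before the log transform (tallied in `n_zero`).
#'
#' @param wt,mutA,mutB,mutAB numeric observation vectors (non-empty).
#' @return list with `coef` (interaction, log scale), `p` (NA when any cell
#'   has fewer than 2 observations), `n` (per-cell sizes), `n_zero` (zeros
#'   floored).
#' @export
epistasisTest <- function(wt, mutA, mutB, mutAB) {
  cells <- list(wt = wt, mutA = mutA, mutB = mutB, mutAB = mutAB)
  stopifnot(all(lengths(cells) >= 1L))
  y <- unlist(cells, use.names = FALSE)
  nZero <- sum(y == 0)
  if (nZero) {
    if (!any(y > 0)) stop("all observations are zero")
    y[y == 0] <- min(y[y > 0]) / 2
  }
  if (any(y < 0)) stop("expression observations must be >= 0")
  a <- rep(c(0, 1, 0, 1), lengths(cells))
  b <- rep(c(0, 0, 1, 1), lengths(cells))
  fit <- stats::lm(log(y) ~ a * b)
  est <- stats::coef(fit)[["a:b"]]
  p <- if (all(lengths(cells) >= 2L)) {
    stats::coef(summary(fit))["a:b", "Pr(>|t|)"]
  } else NA_real_
  list(coef = est, p = p, n = lengths(cells), n_zero = nZero)
}

#' Classify a significant interaction into an epistasis type
#'
#' Categories follow the standard taxonomy for pairwise motif epistasis:
#' \describe{
#'   \item{none}{the interaction term is not significant.}
#'   \item{synergistic}{the double mutant's effect exceeds the multiplicative
#'     prediction in the same direction as the single mutants.}
#'   \item{sign}{the direction of one motif's effect reverses in the context
#'     of the other mutation (e.g. a solo increase but an in-context
#'     decrease).}
#'   \item{alleviating-complementary}{weaker than predicted, and the double
#'     mutant's severity equals each single's (not significantly different
#'     from either single).}
#'   \item{alleviating-complete-suppression}{weaker than predicted; the
#'     double equals the milder single and both differ from the stronger
#'     single (AB = B < A).}
#'   \item{alleviating}{weaker than predicted but matching neither
#'     sub-pattern.}
#' }
#' "Severity equality" is operationalized as pairwise non-significance at
#' `alpha` (Conover-Iman adjusted calls). Direction is taken from the
#' log fold changes; a solo direction only counts as established when the
#' single differs significantly from wildtype.
#'
#' @param fcA,fcB,fcAB fold changes (vs wildtype) of the single and double
#'   mutants.
#' @param interactionP interaction-term p-value from [epistasisTest()].
#' @param sigAvsWT,sigBvsWT significance of each single vs wildtype.
#' @param sigABvsA,sigABvsB significance of the double vs each single.
#' @param alpha significance level (default 0.1).
#' @return one of "none", "synergistic", "sign",
#'   "alleviating-complementary", "alleviating-complete-suppression",
#'   "alleviating", or "undeterminable" when required inputs are missing
#'   (e.g. a construct failed QC).
#' @export
classifyEpistasis <- function(fcA, fcB, fcAB, interactionP,
                              sigAvsWT, sigBvsWT, sigABvsA, sigABvsB,
                              alpha = 0.1) {
  vals <- c(fcA, fcB, fcAB, interactionP)
  if (any(is.na(vals)) || any(is.na(c(sigAvsWT, sigBvsWT, sigABvsA,
                                      sigABvsB))))
    return("undeterminable")
  if (interactionP >= alpha) return("none")
  eA <- log(fcA); eB <- log(fcB); eAB <- log(fcAB)
  pred <- eA + eB

  ## synergistic: larger than the multiplicative prediction, same direction
  if (sign(eAB) == sign(pred) && abs(eAB) > abs(pred)) return("synergistic")

  ## sign: a motif's in-context direction opposes its established solo
  ## direction (in-context effect of A = eAB - eB, judged against AB vs B)
  soloDirA <- if (sigAvsWT) sign(eA) else 0
  soloDirB <- if (sigBvsWT) sign(eB) else 0
  ctxDirA <- if (sigABvsB) sign(eAB - eB) else 0
  ctxDirB <- if (sigABvsA) sign(eAB - eA) else 0
  if ((soloDirA != 0 && ctxDirA != 0 && soloDirA != ctxDirA) ||
      (soloDirB != 0 && ctxDirB != 0 && soloDirB != ctxDirB))
    return("sign")

  ## alleviating: weaker than predicted
  if (!sigABvsA && !sigABvsB) return("alleviating-complementary")
  strongerIsA <- abs(eA) >= abs(eB)
  sigVsMilder <- if (strongerIsA) sigABvsB else sigABvsA
  sigVsStronger <- if (strongerIsA) sigABvsA else sigABvsB
  if (!sigVsMilder && sigVsStronger)
    return("alleviating-complete-suppression")
  "alleviating"
}

#' Test and classify all motif-pair interactions in one allelic series
#'
#' For an enhancer's 2^3 allelic series this runs the omnibus and post-hoc
#' machinery once ([runAllelicSeries()]), then for every motif-class pair
#' (A, B) forms the four cells WT, A, B, A+B, runs [epistasisTest()] and
#' classifies the result with [classifyEpistasis()] using the Conover-Iman
#' adjusted significance calls.
#'
#' @param obsByAllele named list of observation vectors; allele names are
#'   "WT", single class names, and "+"-joined sorted combinations (as
#'   produced by [buildAllelicSeries()]).
#' @param motifClasses the 3 motif class names.
#' @param enhancerId label for the output.
#' @param alpha significance level (default 0.1).
#' @param adjustInteraction BH-adjust interaction p-values across the pairs
#'   tested here before classification (default FALSE: raw per-pair
#'   p-values).
#' @return data.frame with one row per pair: `enhancer_id`, `motif_a`,
#'   `motif_b`, `interaction_coef`, `interaction_p`, `category`.
#' @export
epistasisScan <- function(obsByAllele, motifClasses,
                          enhancerId = "enhancer", alpha = 0.1,
                          adjustInteraction = FALSE) {
  stopifnot(length(motifClasses) == 3L)
  series <- runAllelicSeries(obsByAllele, enhancerId, alpha)
  pairSig <- function(a, b) {
    pw <- series$pairwise
    if (is.null(pw)) return(FALSE)
    hit <- (pw$group_i == a & pw$group_j == b) |
           (pw$group_i == b & pw$group_j == a)
    if (!any(hit)) return(NA)
    any(pw$significant[hit])
  }
  fcs <- if ("WT" %in% names(obsByAllele)) {
    seriesFoldChanges(obsByAllele, enhancerId)
  } else NULL
  fcOf <- function(a) {
    if (is.null(fcs) || !a %in% fcs$allele) return(NA_real_)
    fcs$fold_change[fcs$allele == a]
  }
  pairs <- utils::combn(sort(motifClasses), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(ci) {
    A <- pairs[1L, ci]; B <- pairs[2L, ci]
    AB <- paste(sort(c(A, B)), collapse = "+")
    have <- c("WT", A, B, AB) %in% names(obsByAllele)
    if (!all(have)) {
      return(data.frame(enhancer_id = enhancerId, motif_a = A, motif_b = B,
                        interaction_coef = NA_real_,
                        interaction_p = NA_real_,
                        category = "undeterminable",
                        stringsAsFactors = FALSE))
    }
    et <- epistasisTest(obsByAllele[["WT"]], obsByAllele[[A]],
                        obsByAllele[[B]], obsByAllele[[AB]])
    data.frame(enhancer_id = enhancerId, motif_a = A, motif_b = B,
               interaction_coef = et$coef, interaction_p = et$p,
               category = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pClassify <- out$interaction_p
  if (adjustInteraction) {
    ok <- !is.na(pClassify)
    pClassify[ok] <- bhAdjust(pClassify[ok])
  }
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$category[i])) next  # already undeterminable
    A <- out$motif_a[i]; B <- out$motif_b[i]
    AB <- paste(sort(c(A, B)), collapse = "+")
    out$category[i] <- classifyEpistasis(
      fcA = fcOf(A), fcB = fcOf(B), fcAB = fcOf(AB),
      interactionP = pClassify[i],
      sigAvsWT = pairSig("WT", A), sigBvsWT = pairSig("WT", B),
      sigABvsA = pairSig(AB, A), sigABvsB = pairSig(AB, B),
      alpha = alpha)
  }
  out
}
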