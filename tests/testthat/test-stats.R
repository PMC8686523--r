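randomGroups <- function(k = NULL, tie = FALSE) {
  if (is.null(k)) k <- sample(2:5, 1)
  n <- sample(3:8, k, replace = TRUE)
  g <- lapply(n, function(ni) rnorm(ni))
  if (tie) g <- lapply(g, function(x) round(x, 1))  # force ties
  names(g) <- paste0("g", seq_len(k))
  g
}

test_that("kruskalWallis matches the tie-corrected textbook formula", {
  set.seed(71)
  for (i in 1:30) {
    g <- randomGroups(tie = i %% 2 == 0)
    got <- kruskalWallis(g)
    want <- oracleKW(g)
    expect_equal(got$H, want$H, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_identical(got$df, length(g) - 1L)
  }
})

test_that("kruskalWallis degenerate cases", {
  expect_equal(kruskalWallis(list(a = c(1, 1), b = c(1, 1, 1)))$H, 0)
  expect_equal(kruskalWallis(list(a = c(1, 1), b = c(1, 1, 1)))$p, 1)
  expect_error(kruskalWallis(list(a = 1:3)), "length")
  ## monotone-transform invariance: ranks see only the order
  set.seed(72)
  g <- randomGroups(3)
  gexp <- lapply(g, exp)
  expect_equal(kruskalWallis(g)$H, kruskalWallis(gexp)$H)
})

test_that("conoverIman matches the from-scratch oracle", {
  set.seed(73)
  for (i in 1:30) {
    g <- randomGroups(tie = i %% 3 == 0)
    got <- conoverIman(g)
    want <- oracleConover(g)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_identical(got$group_i, want$group_i)
  }
})

test_that("conoverIman flags validity and excludes empty groups", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = numeric(0))
  expect_warning(out <- conoverIman(g, omnibusRejected = FALSE), "empty")
  expect_identical(nrow(out), 1L)
  expect_false(any(out$valid))
})

test_that("bhAdjust equals the hand step-up on printed fixtures", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.2)
  ## by hand: sorted p = .005 .01 .03 .04 .2 ; p * 5/rank =
  ## .025 .025 .05 .05 .2 ; cummin from the right keeps them as-is
  expect_equal(bhAdjust(p), c(0.025, 0.05, 0.05, 0.025, 0.2))
  expect_equal(bhAdjust(p), oracleBH(p))
  set.seed(74)
  for (i in 1:20) {
    pr <- runif(sample(1:12, 1))
    expect_equal(bhAdjust(pr), oracleBH(pr))
  }
})

test_that("bhAdjust output is a fixed point of monotonicity enforcement", {
  set.seed(75)
  p <- runif(10)
  a1 <- bhAdjust(p)
  ## the step-up output is already monotone in the raw p order and capped at
  ## 1, so re-enforcing those constraints changes nothing (note that feeding
  ## adjusted values through the full BH procedure again is NOT the
  ## identity: the m/rank factors re-apply)
  enforce <- function(q, p) {
    o <- order(p)
    pmin(rev(cummin(rev(q[o]))), 1)[order(o)]
  }
  expect_equal(enforce(a1, p), a1)
  expect_true(all(a1 <= 1))
  expect_true(all(a1 >= p))
  expect_true(all(diff(a1[order(p)]) >= -1e-15)) # monotone in p
  o <- sample(10)
  expect_equal(bhAdjust(p[o]), a1[o])            # permutation-equivariant
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.5, 1.2)), "p")
})

test_that("runAllelicSeries gates the post-hoc on the omnibus", {
  set.seed(76)
  ## clearly separated groups: omnibus rejects, pairwise reported
  g <- list(WT = rnorm(9, 10, 0.1), m1 = rnorm(9, 5, 0.1),
            m2 = rnorm(9, 1, 0.1))
  out <- runAllelicSeries(g, "E1", alpha = 0.1)
  expect_lt(out$kw_p, 0.1)
  expect_identical(nrow(out$pairwise), 3L)
  expect_true(all(c("adj_p", "significant") %in% names(out$pairwise)))
  expect_equal(out$pairwise$adj_p, bhAdjust(out$pairwise$p))
  ## identical groups: omnibus cannot reject, no pairwise table
  g0 <- list(WT = rep(1, 5), m1 = rep(1, 5))
  out0 <- runAllelicSeries(g0, "E1")
  expect_null(out0$pairwise)
})

test_that("epistasisTest recovers the balanced log-scale contrast", {
  set.seed(77)
  wt <- exp(rnorm(9, 0, 0.1))
  a <- exp(rnorm(9, -0.5, 0.1))
  b <- exp(rnorm(9, -0.7, 0.1))
  ab <- exp(rnorm(9, -1.6, 0.1))
  et <- epistasisTest(wt, a, b, ab)
  manual <- mean(log(ab)) - mean(log(a)) - mean(log(b)) + mean(log(wt))
  expect_equal(et$coef, manual, tolerance = 1e-10)
  expect_true(et$p < 1 && et$p > 0)
  expect_identical(unname(et$n), rep(9L, 4))
  expect_identical(et$n_zero, 0L)
})

test_that("epistasisTest floors zeros and handles tiny cells", {
  et <- epistasisTest(c(1, 2), c(0, 1), c(1, 1.5), c(0.5, 0.6))
  expect_identical(et$n_zero, 1L)
  expect_true(is.finite(et$coef))
  ## a single-observation cell: estimate returned, p undefined
  et1 <- epistasisTest(c(1, 2), 1, c(1, 1.5), c(0.5, 0.6))
  expect_true(is.finite(et1$coef))
  expect_true(is.na(et1$p))
  expect_error(epistasisTest(0, 0, 0, 0), "zero")
})

test_that("classifyEpistasis reproduces the category taxonomy", {
  ## not significant
  expect_identical(classifyEpistasis(0.5, 0.5, 0.1, 0.5,
                                     TRUE, TRUE, TRUE, TRUE), "none")
  ## synergistic: |log fc(AB)| exceeds the additive prediction, same sign
  expect_identical(classifyEpistasis(0.5, 0.5, 0.1, 0.01,
                                     TRUE, TRUE, TRUE, TRUE), "synergistic")
  ## sign: solo decrease (A vs WT significant, fc < 1) but in context of B
  ## the A mutation increases expression (AB > B, significant)
  expect_identical(classifyEpistasis(0.5, 0.4, 0.8, 0.01,
                                     TRUE, TRUE, TRUE, TRUE), "sign")
  ## alleviating-complementary: AB indistinguishable from both singles
  expect_identical(classifyEpistasis(0.5, 0.45, 0.45, 0.01,
                                     TRUE, TRUE, FALSE, FALSE),
                   "alleviating-complementary")
  ## complete suppression: AB equals the milder single (B, itself not
  ## distinguishable from WT), differs from the stronger (A)
  expect_identical(classifyEpistasis(0.2, 0.6, 0.6, 0.01,
                                     TRUE, FALSE, TRUE, FALSE),
                   "alleviating-complete-suppression")
  ## alleviating residual: weaker than predicted, AB differs from both
  ## singles, no sign reversal established
  expect_identical(classifyEpistasis(0.2, 0.8, 0.3, 0.01,
                                     TRUE, FALSE, TRUE, TRUE), "alleviating")
  ## missing ingredients
  expect_identical(classifyEpistasis(NA, 0.5, 0.4, 0.01,
                                     TRUE, TRUE, TRUE, TRUE),
                   "undeterminable")
})

test_that("epistasisScan tests all three pairs and flags missing cells", {
  set.seed(78)
  classes <- c("mA", "mB", "mC")
  obs <- list(WT = exp(rnorm(9, 0, 0.1)))
  for (al in c("mA", "mB", "mC", "mA+mB", "mA+mC", "mB+mC", "mA+mB+mC")) {
    k <- length(strsplit(al, "+", fixed = TRUE)[[1]])
    obs[[al]] <- exp(rnorm(9, -0.5 * k, 0.1))
  }
  out <- epistasisScan(obs, classes, "E1")
  expect_identical(nrow(out), 3L)
  expect_setequal(paste(out$motif_a, out$motif_b),
                  c("mA mB", "mA mC", "mB mC"))
  ## exactly multiplicative data: no pair should look strongly epistatic
  expect_true(all(abs(out$interaction_coef) < 0.5))
  ## drop one double mutant: that pair becomes undeterminable
  out2 <- epistasisScan(obs[names(obs) != "mA+mB"], classes, "E1")
  expect_identical(out2$category[out2$motif_a == "mA" &
                                   out2$motif_b == "mB"], "undeterminable")
})
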