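# Toy scorers: cheap deterministic functions of the sequence, so beam
# behaviour can be checked against exhaustive enumeration.
countW <- function(seqs) vapply(strsplit(seqs, ""), function(x)
  sum(x == "W"), numeric(1))
hydScore <- function(seqs) vapply(strsplit(seqs, ""), function(x)
  sum(x %in% hydrophobicResidues()), numeric(1))
alphaScore <- function(seqs) vapply(strsplit(seqs, ""), function(x)
  sum(match(x, LETTERS)), numeric(1))

# All sequences within `maxSubs` substitutions of `seq` (20-AA alphabet).
allVariants <- function(seq, maxSubs) {
  ch <- strsplit(seq, "")[[1]]
  out <- seq
  if (maxSubs >= 1) {
    for (i in seq_along(ch)) for (a in setdiff(aminoAcids(), ch[i])) {
      v <- ch; v[i] <- a
      out <- c(out, paste(v, collapse = ""))
    }
  }
  if (maxSubs >= 2) {
    pairs <- utils::combn(seq_along(ch), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      for (a in setdiff(aminoAcids(), ch[i]))
        for (b in setdiff(aminoAcids(), ch[j])) {
          v <- ch; v[i] <- a; v[j] <- b
          out <- c(out, paste(v, collapse = ""))
        }
    }
  }
  unique(out)
}

test_that("substitution enumeration is complete and filterable", {
  s <- randomPrimary(40, seed = 30)
  cands <- enumerateSubstitutions(s)
  expect_identical(nrow(cands), 40L * 19L)
  expect_false(any(duplicated(cands$sequence)))
  noW <- enumerateSubstitutions(s, constraintRegime("no-W"))
  ch <- strsplit(s, "")[[1]]
  wIn <- sum(ch == "W")
  for (v in noW$sequence) {
    expect_lte(sum(strsplit(v, "")[[1]] == "W"), wIn)
  }
  expect_false("W" %in% noW$to)
  big <- enumerateSubstitutions(s, constraintRegime("no-AFILMVWY"))
  expect_false(any(big$to %in% hydrophobicResidues()))
})

test_that("the USM-nondecrease constraint filters what it must", {
  # model that scores adjacent-K pairs: removing a K from "KK" drops the
  # prediction, so such substitutions must be filtered out
  W <- matrix(0, 1, 23 * 2)
  W[1, match("K", primaryAlphabet())] <- 1
  W[1, 23 + match("K", primaryAlphabet())] <- 1
  mk <- USMModel(list(W = W, wh = 1, bh = 0), kernelWidth = 2)
  s <- "AKKAGA"
  cons <- refinementConstraints(usmNondecrease = TRUE)
  kept <- enumerateSubstitutions(s, cons, usmModel = mk)
  # no kept candidate may lower the adjacent-K count
  base <- usmPredict(mk, s, "trypsin")
  for (v in kept$sequence) {
    expect_gte(usmPredict(mk, v, "trypsin"), base)
  }
  # mutations destroying the KK pair are gone
  expect_false(any(kept$position %in% c(2L, 3L) & kept$to != "K"))
  expect_error(enumerateSubstitutions(s, cons), "requires a USM")
})

test_that("toy beam refinement follows the documented tie-breaks", {
  out1 <- beamRefine("AAA", countW, k = 1, rounds = 1)
  expect_identical(out1$sequence, "WAA")   # lowest position first
  out2 <- beamRefine("AAA", countW, k = 1, rounds = 2)
  expect_identical(out2$sequence[2], "WWA")
  expect_equal(out2$score, c(1, 2))
  expect_equal(out2$n_substitutions, c(1L, 2L))
})

test_that("unbounded beam equals brute force over <=2-substitution variants", {
  set.seed(31)
  for (scorer in list(countW, hydScore, alphaScore)) {
    s <- randomPrimary(6)
    out <- beamRefine(s, scorer, k = Inf, rounds = 2)
    pool <- allVariants(s, 2)
    sc <- scorer(pool)
    expect_equal(out$score[2], max(sc))
    # round-1 product likewise matches the 1-substitution optimum
    pool1 <- allVariants(s, 1)
    expect_equal(out$score[1], max(scorer(pool1)))
  }
})

test_that("per-round product scores never decrease", {
  set.seed(32)
  for (i in 1:3) {
    s <- randomPrimary(12)
    out <- beamRefine(s, alphaScore, k = 3, rounds = 4)
    expect_true(all(diff(out$score) >= 0))
    expect_true(all(out$n_substitutions <= out$round))
  }
})

test_that("constraints hold at every round of the beam", {
  s <- randomPrimary(15, seed = 33)
  out <- beamRefine(s, hydScore, k = 5, rounds = 3,
                    constraints = constraintRegime("no-W"))
  base <- sum(strsplit(s, "")[[1]] == "W")
  for (v in out$sequence) {
    expect_lte(sum(strsplit(v, "")[[1]] == "W"), base)
  }
})

test_that("random substitutions change one site per round, uniformly", {
  s <- randomPrimary(20, seed = 34)
  out <- randomSubstitutions(s, nRounds = 4, seed = 5)
  prev <- s
  for (r in seq_len(nrow(out))) {
    d <- sum(strsplit(out$sequence[r], "")[[1]] != strsplit(prev, "")[[1]])
    expect_identical(d, 1L)
    prev <- out$sequence[r]
  }
  # with 19 residues forbidden, only one replacement letter can appear
  cons <- refinementConstraints(forbidden = setdiff(aminoAcids(), "G"))
  res <- randomSubstitutions(s, nRounds = 2, constraints = cons, seed = 6)
  newCh <- mapply(function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    y[x != y]
  }, c(s, res$sequence[1]), res$sequence)
  expect_true(all(unlist(newCh) == "G"))
  # positions are uniform across seeds (chi-square at 3 sigma)
  pos <- vapply(1:2000, function(sd) {
    r1 <- randomSubstitutions(s, nRounds = 1, seed = sd)
    which(strsplit(r1$sequence, "")[[1]] != strsplit(s, "")[[1]])
  }, integer(1))
  tab <- tabulate(pos, 20)
  chisq <- sum((tab - 100)^2 / 100)
  # df = 19: mean 19, sd sqrt(38)
  expect_lt(chisq, 19 + 3 * sqrt(38))
})

test_that("substitution-effect matrix aggregates and tests correctly", {
  set.seed(35)
  null <- data.frame(from = "K", to = "W",
                     condition = rep(c("guided", "random"), each = 40),
                     delta = rnorm(80, 0.1, 0.05))
  outNull <- substitutionEffectMatrix(null)
  expect_lt(abs(outNull$cells$difference), 0.05)
  expect_gt(outNull$cells$p_value, 0.05)

  eff <- data.frame(from = "E", to = "W",
                    condition = rep(c("guided", "random"), each = 30),
                    delta = c(rnorm(30, 0.3, 0.05), rnorm(30, -0.1, 0.05)))
  outEff <- substitutionEffectMatrix(eff, fdr = TRUE)
  expect_equal(outEff$cells$difference, 0.4, tolerance = 0.06)
  expect_lt(outEff$cells$p_value, 0.001)
  expect_true("p_bh" %in% names(outEff$cells))

  # marginal means aggregate the raw records
  both <- rbind(null, eff)
  outBoth <- substitutionEffectMatrix(both)
  km <- outBoth$fromMarginal[outBoth$fromMarginal$residue == "K", ]
  expect_equal(km$mean_guided,
               mean(null$delta[null$condition == "guided"]))
  # cells with < 2 samples per condition are flagged undefined
  tiny <- data.frame(from = "A", to = "G",
                     condition = c("guided", "random"), delta = c(1, 0))
  expect_true(is.na(substitutionEffectMatrix(tiny)$cells$p_value))
})
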