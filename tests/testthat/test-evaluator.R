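tinyCfg <- function(...) {
  emConfig(convKernels = c(5L, 4L, 3L), convWidths = c(5L, 9L, 17L),
           dense = c(7L, 5L), dropout = 0, batchSize = 4L,
           optimizer = "adam", lr = 1e-3, ...)
}

test_that("the default architecture has the printed shapes", {
  m <- buildEM(emConfig(), seed = 1)
  p <- m@params
  expect_identical(dim(p$W1), c(400L, 23L * 5L))
  # first conv output is 171 positions x 400 kernels
  X <- protstab:::.encodeBatch(randomPrimary(40, seed = 1), 20L)
  Y <- protstab:::convForward(X, p$W1, p$b1, 5L)
  expect_identical(dim(Y), c(400L, 171L, 1L))
  expect_identical(dim(p$Ws), c(6L * 175L, 100L * 147L))
  expect_identical(nrow(p$Wd3), 2L)
})

test_that("forward pass appends an exact min unit and softmax head", {
  cfg <- tinyCfg()
  m <- buildEM(cfg, seed = 2)
  X <- protstab:::.encodeBatch(
    c(randomPrimary(30, seed = 3), randomPrimary(50, seed = 4)),
    c(20L, 40L))
  fw <- protstab:::.emForward(m@params, cfg, X)
  expect_identical(dim(fw$S), c(3L, 2L))
  expect_identical(fw$S["m", ], pmin(fw$S["c", ], fw$S["t", ]))
  sums <- apply(fw$Zhat, c(2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
})

test_that("analytic gradients match numerical ones through both heads", {
  cfg <- tinyCfg()
  m <- buildEM(cfg, seed = 5)
  params <- m@params
  kernels <- grammarKernels()
  set.seed(6)
  seqs <- vapply(1:3, function(i) randomPrimary(25), character(1))
  secs <- vapply(1:3, function(i) randomSecondary(25), character(1))
  offs <- vapply(seqs, deterministicOffset, integer(1))
  Xd <- protstab:::.encodeBatch(seqs, offs)
  Zt <- array(0, c(6, 175, 3))
  for (i in 1:3) Zt[, , i] <- encodeSecondary(secs[i], offs[i])
  Xtgt <- cbind(c = rnorm(3), t = rnorm(3), m = 0)
  Xtgt[, 3] <- pmin(Xtgt[, 1], Xtgt[, 2])
  natS <- vapply(1:3, function(i) randomPrimary(30), character(1))
  scrS <- vapply(natS, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  Xn <- protstab:::.encodeBatch(natS, rep(20L, 3))
  Xs <- protstab:::.encodeBatch(scrS, rep(20L, 3))
  Xb <- array(c(Xd, Xn, Xs), c(23, 175, 9))

  totalLoss <- function(prm) {
    fw <- protstab:::.emForward(prm, cfg, Xb)
    ls <- lossStability(Xtgt, t(fw$S[, 1:3]))
    lc <- lossComparator(t(fw$S[, 4:6]), t(fw$S[, 7:9]))
    ld <- mean(vapply(1:3, function(i)
      lossSecondary(Zt[, , i], fw$Zhat[, , i], kernels), numeric(1)))
    lossTotal(ls, lc, ld)
  }

  fw <- protstab:::.emForward(params, cfg, Xb, wantSecondary = TRUE,
                              wantCache = TRUE)
  dg <- protstab:::.designGrad(fw$S[, 1:3], fw$Zhat[, , 1:3], NULL,
                               Xtgt, Zt, kernels, 1e-12)
  cg <- protstab:::.comparatorGrad(fw$S[, 4:6], fw$S[, 7:9])
  dS2 <- matrix(0, 2, 9); dLogits <- matrix(0, 6 * 175, 9)
  dS2[, 1:3] <- 0.2 * dg$dS2
  dLogits[, 1:3] <- 2 * dg$dLogits
  dS2[, 4:6] <- 0.1 * cg$dNat
  dS2[, 7:9] <- 0.1 * cg$dScr
  g <- protstab:::.emBackward(params, cfg, fw, dS2, dLogits)

  eps <- 1e-5
  set.seed(7)
  for (nm in c("W1", "b2", "W3", "Wd1", "Wd3", "Ws", "bs", "bd3")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (k in idx) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (totalLoss(p2) - totalLoss(p3)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-3,
                   info = paste(nm, k))
    }
  }
})

test_that("fit metrics behave at their anchors", {
  obs <- c(1, 2, 3, 5)
  expect_equal(evaluateFit(obs, obs)$R2, 1)
  expect_equal(evaluateFit(obs, obs)$r2, 1)
  m <- evaluateFit(rep(mean(obs), 4), obs)
  expect_equal(m$R2, 0)
  anti <- evaluateFit(-(obs - mean(obs)) + mean(obs), obs)
  expect_lt(anti$R2, 0)
  expect_equal(anti$r2, 1)
  expect_warning(evaluateFit(obs, rep(2, 4)), "zero variance")
})

test_that("training improves validation loss and restores the best epoch", {
  cfg <- synthConfig(nDesigns = 220)
  corpus <- generateCorpus(cfg, seed = 9)
  scores <- stabilityScore(cbind(corpus$assayDesigns,
    usm_trypsin = corpus$truthDesigns$baseline_trypsin,
    usm_chymotrypsin = corpus$truthDesigns$baseline_chymotrypsin))
  em <- trainEM(corpus$designs, scores,
                naturals = corpus$naturals,
                naturalScrambles = corpus$naturalScrambles,
                config = emConfigSmall(maxEpochs = 6L,
                                       convKernels = c(8L, 6L, 4L),
                                       dense = c(16L, 8L)),
                seed = 10)
  log <- em@trainLog
  expect_lt(min(log$val), log$val[1])
  # restore-best contract: the kept weights correspond to the minimum
  # validation loss over epochs, not the last epoch
  expect_identical(which.min(log$val),
                   which(log$val == min(log$val))[1])
  # determinism
  em2 <- trainEM(corpus$designs, scores,
                 naturals = corpus$naturals,
                 naturalScrambles = corpus$naturalScrambles,
                 config = emConfigSmall(maxEpochs = 2L,
                                        convKernels = c(8L, 6L, 4L),
                                        dense = c(16L, 8L)),
                 seed = 11)
  em3 <- trainEM(corpus$designs, scores,
                 naturals = corpus$naturals,
                 naturalScrambles = corpus$naturalScrambles,
                 config = emConfigSmall(maxEpochs = 2L,
                                        convKernels = c(8L, 6L, 4L),
                                        dense = c(16L, 8L)),
                 seed = 11)
  expect_identical(em2@params$W1, em3@params$W1)
  expect_error(trainEM(corpus$designs[1:10], scores), "minibatch")
})

test_that("class holdout reports one row per class", {
  cfg <- synthConfig(nDesigns = 160, templates = c("HHH", "EHEE"))
  corpus <- generateCorpus(cfg, seed = 12)
  # collapse classes to the two templates for a compact check
  d <- corpus$designs
  d@designClass <- sub("_len.*$", "", d@designClass)
  scores <- stabilityScore(cbind(corpus$assayDesigns,
    usm_trypsin = corpus$truthDesigns$baseline_trypsin,
    usm_chymotrypsin = corpus$truthDesigns$baseline_chymotrypsin))
  res <- classHoldoutEval(d, scores,
                          config = emConfigSmall(maxEpochs = 3L,
                                                 convKernels = c(8L, 6L, 4L),
                                                 dense = c(16L, 8L),
                                                 batchSize = 32L),
                          nRepeats = 1L, seed = 13)
  expect_identical(sort(res$class), sort(unique(d@designClass)))
  expect_identical(nrow(res), 2L)
  expect_true(is.numeric(res$meanR2))
})
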