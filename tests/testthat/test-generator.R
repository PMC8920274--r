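# Toy deterministic secondary->primary grammar: each structured symbol
# maps to a residue determined by its within-segment phase. Gives the
# translator a fully learnable signal at small scale.
toyTranslate <- function(sec) {
  ch <- strsplit(sec, "")[[1]]
  phase <- protstab:::.segmentPhase(sec)
  paste(vapply(seq_along(ch), function(i) {
    switch(ch[i],
      H = c("A", "L", "E", "K")[1 + phase[i] %% 4],
      E = c("V", "T")[1 + phase[i] %% 2],
      L = "G")
  }, character(1)), collapse = "")
}

toyPairs <- function(n, seedBase = 0, lens = 30:45) {
  sec <- vapply(seq_len(n), function(i) {
    tpl <- c("HHH", "EHEE", "HEEH")[1 + (i %% 3)]
    unname(secondarySeq(generateDesign(tpl, lens[1 + (i %% length(lens))],
                                       seed = seedBase + i)))
  }, character(1))
  data.frame(secondary = sec,
             primary = vapply(sec, toyTranslate, character(1)),
             stringsAsFactors = FALSE)
}

test_that("perplexity calibration anchors hold exactly", {
  v <- setdiff(aminoAcids(), "C")
  s <- "MKVLATGREP"
  pUnif <- matrix(1 / 19, nchar(s), 19)
  expect_equal(perplexityFromProbs(pUnif, s, v), 19)
  pPerfect <- matrix(0, nchar(s), 19)
  pPerfect[cbind(seq_len(nchar(s)), match(strsplit(s, "")[[1]], v))] <- 1
  expect_equal(perplexityFromProbs(pPerfect, s, v), 1)
  pHalf <- pPerfect / 2 + 0.5 / 19 * 0
  pHalf[pHalf == 0.5] <- 0.5   # probability one half on the reference
  expect_equal(perplexityFromProbs(pPerfect * 0.5 + 1e-20, s, v,
                                   probFloor = 0), 2, tolerance = 1e-9)
  expect_message(
    perplexityFromProbs(matrix(c(1, 0), 1, 2), "B", c("A", "B")),
    "floored")
})

test_that("character error rate follows its definition", {
  expect_equal(cer("LLHH", "LLHE"), 0.25)
  expect_equal(cer("LLHH", "LLHH"), 0)
  expect_equal(cer("", "LLHH"), 1)
  expect_error(cer("LL", ""), "empty")
})

test_that("pairs with cysteine are rejected at load time", {
  bad <- data.frame(secondary = "LLL", primary = "ACL")
  expect_error(trainGM(bad, gmConfig(iterations = 1)), "cysteine")
})

test_that("a model memorises identical pairs to near-unit perplexity", {
  pairs <- toyPairs(8, seedBase = 100, lens = 30)
  cfg <- gmConfig(iterations = 250, lr = 0.8, batchSize = 8)
  m <- trainGM(pairs, cfg, seed = 2)
  expect_lt(perplexity(m, pairs), 1.35)
  expect_gte(perplexity(m, pairs), 1)
  # descent contract
  expect_lt(tail(m@trainLog$loss, 1), m@trainLog$loss[1])
})

test_that("the translator learns a toy grammar well below chance", {
  pairs <- toyPairs(1000, seedBase = 500)
  m <- trainGM(pairs, gmConfig(iterations = 8), seed = 1)
  pp <- perplexity(m, pairs[seq(1, 1000, by = 5), ])
  expect_lt(pp, 4)        # chance would be 19
  expect_gte(pp, 1)

  # beam outputs: right count, right length, ranked, clean vocabulary
  bd <- beamDecode(m, pairs$secondary[1], width = 5)
  expect_identical(nrow(bd), 5L)
  expect_true(all(nchar(bd$sequence) == nchar(pairs$secondary[1])))
  expect_true(all(diff(bd$logprob) <= 1e-12))
  expect_true(all(bd$logprob <= 0))
  emitted <- unique(unlist(strsplit(bd$sequence, "")))
  expect_false(any(emitted %in% c("C", "X", "J")))
  expect_false(any(emitted == "O"))   # stop token never emitted

})

test_that("an exhaustive beam equals brute-force enumeration", {
  sv <- c("L", "E", "H"); tv <- c("A", "G", "K", "O")
  cfg <- gmConfig(dEmb = 4, encKernels = c(6, 6), encWidths = c(3, 3),
                  dAtt = 4, dHidden = 8, iterations = 1)
  m <- buildGM(cfg, sv, tv, seed = 5)
  src <- "LH"
  # brute force: teacher-force every length-2 candidate
  cands <- expand.grid(a = c("A", "G", "K"), b = c("A", "G", "K"))
  bruteLp <- vapply(seq_len(nrow(cands)), function(i) {
    tgtSeq <- paste0(cands$a[i], cands$b[i])
    S <- protstab:::.gmSourceBatch(src, sv, 2L)
    tg <- protstab:::.gmTargets(tgtSeq, tv, 3L)
    fw <- protstab:::.gmForward(m@params, cfg, S, 2L, tg)
    sum(fw$logp[1:2, 1])
  }, numeric(1))
  bd <- beamDecode(m, src, width = 9)
  expect_identical(nrow(bd), 9L)
  ord <- order(-bruteLp)
  expect_equal(bd$logprob,
               bruteLp[ord], tolerance = 1e-10)
  expect_identical(bd$sequence,
                   paste0(cands$a, cands$b)[ord])

  # beam width 1 is the greedy decode: argmax of step 1, then the
  # argmax continuation given it (computed from the brute-force table)
  g1 <- beamDecode(m, src, width = 1)
  lp1 <- vapply(c("A", "G", "K"), function(a) {
    tg <- protstab:::.gmTargets(paste0(a, "A"), tv, 3L)
    S <- protstab:::.gmSourceBatch(src, sv, 2L)
    protstab:::.gmForward(m@params, cfg, S, 2L, tg)$logp[1, 1]
  }, numeric(1))
  aStar <- c("A", "G", "K")[which.max(lp1)]
  sel <- cands$a == aStar
  greedy <- paste0(cands$a, cands$b)[sel][
    which.max(bruteLp[sel] - max(lp1))]
  expect_identical(g1$sequence, greedy)
})

test_that("the reverse translator recovers secondary structure", {
  pairs <- toyPairs(400, seedBase = 900)
  rm <- trainReverseGM(pairs, gmConfig(iterations = 12), seed = 3)
  test <- toyPairs(30, seedBase = 5000)
  pred <- predictSecondary(rm, test$primary[1:15])
  cers <- mapply(cer, pred, test$secondary[1:15])
  expect_lt(mean(cers), 0.2)    # far below the ~0.66 all-wrong level

  # planted agreement: corrupt the requested secondary for some designs
  gen <- test[1:12, ]
  gen$id <- sprintf("g%02d", 1:12)
  bad <- c(2, 5, 9)
  gen$secondary[bad] <- chartr("HE", "EH", gen$secondary[bad])
  top <- selectBySecondaryAgreement(gen, rm, n = 6)
  expect_identical(nrow(top), 6L)
  expect_false(any(top$id %in% gen$id[bad]))
  expect_true(all(diff(top$cer) >= -1e-12))
  expect_warning(selectBySecondaryAgreement(gen, rm, n = 50), "set size")
})

test_that("stability-weighted subsets are proportional and enriching", {
  set.seed(6)
  ds <- Reduce(combineDesigns, lapply(1:2, function(i) {
    d <- generateDesign("HHH", 40, seed = i)
    d@id <- c("low", "high")[i]
    d
  }))
  sub <- stabilityWeightedSubset(ds, c(1, 3), size = 10000, seed = 7)
  ratio <- sum(sub$index == 2) / sum(sub$index == 1)
  expect_gt(ratio, 3 * 0.95)
  expect_lt(ratio, 3 * 1.05)
  expect_gt(sub$meanScoreOut, sub$meanScoreIn)

  # equal scores: uniform representation
  subEq <- stabilityWeightedSubset(ds, c(2, 2), size = 10000, seed = 8)
  expect_equal(sum(subEq$index == 1) / 10000, 0.5, tolerance = 0.03)
  expect_error(stabilityWeightedSubset(ds, c(-1, 0.05)), "degenerate")
})
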