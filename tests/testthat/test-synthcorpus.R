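test_that("template expansion and literal secondary strings work", {
  tpl <- paste0(strrep("H", 20), strrep("L", 5), strrep("H", 20))
  d <- generateDesign(tpl, 45, seed = 1)
  expect_identical(unname(secondarySeq(d)), tpl)
  e <- generateDesign("EHEE", 40, seed = 2)
  sec <- unname(secondarySeq(e))
  expect_identical(nchar(sec), 40L)
  # element order preserved: strand, helix, strand, strand
  runs <- rle(strsplit(sec, "")[[1]])
  expect_identical(runs$values[runs$values != "L"],
                   c("E", "H", "E", "E"))
})

test_that("design generation is deterministic and hydrophobically biased", {
  d1 <- generateDesign("HHH", 50, seed = 7)
  d2 <- generateDesign("HHH", 50, seed = 7)
  expect_identical(primarySeq(d1), primarySeq(d2))
  # helix-core positions are hydrophobic at roughly the drawn bias:
  # with bias 0.9, over many positions the hydrophobic fraction at core
  # phases must exceed chance (8/20) by a wide margin
  set.seed(8)
  hits <- 0L; total <- 0L
  for (i in 1:40) {
    d <- generateDesign("HHH", 60, seed = 100 + i, matchBias = 0.9)
    pr <- strsplit(unname(primarySeq(d)), "")[[1]]
    sc <- strsplit(unname(secondarySeq(d)), "")[[1]]
    phase <- protstab:::.segmentPhase(unname(secondarySeq(d)))
    core <- sc == "H" & phase %% 7 %in% c(0, 3)
    hits <- hits + sum(pr[core] %in% hydrophobicResidues())
    total <- total + sum(core)
  }
  expect_gt(total, 400)
  expect_gt(hits / total, 0.85)
  expect_lt(hits / total, 0.95)
})

test_that("scrambles preserve exactly what their mode dictates", {
  d <- generateDesign("EHEE", 45, seed = 9)
  multiset <- function(x) sort(strsplit(x, "")[[1]])
  full <- makeScramble(d, "full", seed = 1)
  expect_identical(multiset(unname(primarySeq(full))),
                   multiset(unname(primarySeq(d))))
  pat <- makeScramble(d, "patterned", seed = 2)
  chD <- strsplit(unname(primarySeq(d)), "")[[1]]
  chP <- strsplit(unname(primarySeq(pat)), "")[[1]]
  gp <- chD %in% c("G", "P")
  expect_identical(chP[gp], chD[gp])           # G/P fixed in place
  expect_identical(chP %in% hydrophobicResidues(),
                   chD %in% hydrophobicResidues())  # patterning kept
  expect_identical(multiset(unname(primarySeq(pat))), sort(chD))
  expect_identical(unname(provenance(full)), "scramble")
})

test_that("assay model is additive with protection recomputable", {
  cfg <- synthConfig(nDesigns = 10, noiseSd = 0, ceiling = NULL)
  d <- Reduce(combineDesigns,
              lapply(1:10, function(i) {
                x <- generateDesign("HHH", 40, seed = i)
                x@id <- sprintf("d%02d", i)
                x
              }))
  sim <- simulateAssay(d, cfg, seed = 1)
  expect_equal(sim$assay$ec50_trypsin - sim$truth$baseline_trypsin,
               sim$truth$protection, tolerance = 1e-12)
  expect_equal(sim$truth$protection,
               latentProtection(unname(primarySeq(d)),
                                unname(secondarySeq(d)), cfg),
               tolerance = 1e-12)
})

test_that("latent protection tracks match quality by construction", {
  set.seed(10)
  cfg <- synthConfig()
  prims <- character(60); secs <- character(60)
  for (i in 1:60) {
    d <- generateDesign("EHEE", 45, seed = 300 + i)
    prims[i] <- unname(primarySeq(d)); secs[i] <- unname(secondarySeq(d))
  }
  match <- vapply(1:60, function(i) patternMatchScore(prims[i], secs[i]),
                  numeric(1))
  prot <- latentProtection(prims, secs, cfg)
  expect_gte(cor(match, prot, method = "spearman"), 0.99)  # monotone map
  expect_gte(cor(match, prot)^2, 0.8)
})

test_that("scrambles sit near zero protection, designs separate", {
  cfg <- synthConfig(nDesigns = 40)
  corpus <- generateCorpus(cfg, seed = 3)
  scoreD <- stabilityScore(cbind(corpus$assayDesigns,
    usm_trypsin = corpus$truthDesigns$baseline_trypsin,
    usm_chymotrypsin = corpus$truthDesigns$baseline_chymotrypsin))
  scoreS <- stabilityScore(cbind(corpus$assayScrambles,
    usm_trypsin = corpus$truthScrambles$baseline_trypsin,
    usm_chymotrypsin = corpus$truthScrambles$baseline_chymotrypsin))
  # with the true baselines as the unfolded model, scramble scores are
  # essentially noise around zero while designs carry protection
  expect_lt(abs(mean(scoreS$score)), 0.3)
  expect_gt(mean(scoreD$score) - mean(scoreS$score), 0.3)
})

test_that("the corpus is reproducible bit for bit", {
  cfg <- synthConfig(nDesigns = 12)
  c1 <- generateCorpus(cfg, seed = 5)
  c2 <- generateCorpus(cfg, seed = 5)
  expect_identical(primarySeq(c1$designs), primarySeq(c2$designs))
  expect_identical(c1$assayDesigns, c2$assayDesigns)
  expect_identical(c1$assayScrambles, c2$assayScrambles)
})

test_that("ladder chips carry the injected distortion and span the range", {
  cfg <- synthConfig(nDesigns = 60, noiseSd = 0.05)
  corpus <- generateCorpus(cfg, seed = 6)
  chips <- makeLadderChips(corpus$assayDesigns, cfg, nLadder = 15,
                           seed = 7)
  expect_gte(length(chips$ladderIds), 10L)
  idx <- match(chips$ladderIds, chips$chipA$id)
  rngL <- range(chips$chipA$ec50_trypsin[idx])
  rngA <- range(chips$chipA$ec50_trypsin)
  expect_gte(diff(rngL) / diff(rngA), 0.9)
  m <- fitOrthogonal(chips$chipA$ec50_trypsin, chips$chipB$ec50_trypsin)
  expect_equal(m@slope, 1.2, tolerance = 0.1)
  expect_equal(m@intercept, -0.4, tolerance = 0.15)
  # zero distortion, zero noise: chips identical
  cfg0 <- synthConfig(nDesigns = 60, noiseSd = 0,
                      chipDistortion = c(slope = 1, intercept = 0))
  chips0 <- makeLadderChips(corpus$assayDesigns, cfg0, seed = 8)
  expect_equal(chips0$chipA$ec50_trypsin, chips0$chipB$ec50_trypsin)
})

test_that("ceiling compression caps high responses", {
  x <- c(1, 4, 6)
  expect_equal(protstab:::.ceilingCompress(x, c(c = 4, s = 0.5)),
               c(1, 4, 5))
  expect_equal(protstab:::.ceilingCompress(x, NULL), x)
})
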