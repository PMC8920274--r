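#' Synthetic corpus configuration
#'
#' Settings for the built-in fixture generator that emulates the data
#' structure of the designed-mini-protein stability assay: topology-
#' patterned designs of 25--65 residues with DSSP-style secondary
#' strings, full and patterned scrambles, per-protease EC50s composed of
#' an unfolded baseline plus folded protection plus noise, log-normally
#' distributed credible-interval widths, and cross-chip linear
#' distortions with an optional ceiling compression.
#'
#' The unfolded baselines are linear in cleavage-prone residue content
#' (K/R for trypsin, F/Y/W/L for chymotrypsin). Folded protection is a
#' smooth logistic function of the pattern-match quality between primary
#' and secondary sequence ([patternMatchScore()]), scaled to
#' `[0, protectionScale]` so stability scores occupy roughly -1 to 3;
#' scrambles sit near chance match quality and receive protection near 0.
#'
#' @param nDesigns number of designs to generate.
#' @param lengthRange inclusive residue-length range.
#' @param templates topology strings over H/E (expanded with loops).
#' @param baselineTrypsin,baselineChymotrypsin `c(intercept, slope)` of
#'   the unfolded baseline as a function of cleavage-prone residue
#'   fraction.
#' @param protectionScale,protectionMid,protectionWidth parameters of the
#'   logistic protection curve over match quality.
#' @param noiseSd assay noise standard deviation (EC50 log units).
#' @param ciMeanlog,ciSdlog log-normal parameters for credible-interval
#'   widths (defaults put ~10\% of widths above 2).
#' @param chipDistortion `c(slope, intercept)` of the cross-chip linear
#'   distortion used by [makeLadderChips()].
#' @param ceiling `c(c, s)` soft-ceiling compression applied to assayed
#'   EC50s (identity below `c`, slope `s` above), or `NULL` for none.
#' @return A named list of settings.
#' @export
synthConfig <- function(nDesigns = 2000L,
                        lengthRange = c(25L, 65L),
                        templates = c("HHH", "EHEE", "HEEH", "EEHEE", "HHHH"),
                        baselineTrypsin = c(3.0, -5.0),
                        baselineChymotrypsin = c(3.2, -4.0),
                        protectionScale = 2.5,
                        protectionMid = 0.70,
                        protectionWidth = 0.055,
                        noiseSd = 0.1,
                        ciMeanlog = log(0.8), ciSdlog = 0.75,
                        chipDistortion = c(slope = 1.2, intercept = -0.4),
                        ceiling = c(c = 4.5, s = 0.5)) {
  stopifnot(noiseSd >= 0, all(.splitSeq(paste(templates, collapse = ""))
                              %in% c("L", "E", "H")))
  as.list(environment())
}

# Position-wise preferred residue sets. Helix positions prefer
# hydrophobics at heptad-like within-segment phases {0,3}, strands at
# alternating phases; other structured positions prefer hydrophilics;
# loops prefer turn-formers (G/P-enriched).
.LOOP_SET <- c("G", "P", "D", "N", "S", "T")
.POLAR_SET <- setdiff(.AA20, .HYDROPHOBIC)

# Within-segment phase for each position of a secondary string.
.segmentPhase <- function(sec) {
  ch <- .splitSeq(sec)
  phase <- integer(length(ch))
  run <- 0L
  for (i in seq_along(ch)) {
    if (i > 1L && ch[i] == ch[i - 1L]) run <- run + 1L else run <- 0L
    phase[i] <- run
  }
  phase
}

.preferredSets <- function(secondary) {
  ch <- .splitSeq(secondary)
  phase <- .segmentPhase(secondary)
  lapply(seq_along(ch), function(i) {
    switch(ch[i],
      H = if (phase[i] %% 7L %in% c(0L, 3L)) .HYDROPHOBIC else .POLAR_SET,
      E = if (phase[i] %% 2L == 0L) .HYDROPHOBIC else .POLAR_SET,
      L = .LOOP_SET)
  })
}

#' Pattern-match quality between primary and secondary sequence
#'
#' Fraction of positions whose residue belongs to the preferred residue
#' class for its secondary context (hydrophobics at helix/strand core
#' phases, hydrophilics elsewhere in structured elements, turn-formers in
#' loops). This is the latent quantity that drives folded protection in
#' the synthetic assay; it is recomputable for any (primary, secondary)
#' pair, which makes refinement experiments scoreable against ground
#' truth.
#'
#' @param primary,secondary equal-length sequence strings.
#' @return A value in \[0, 1\].
#' @export
patternMatchScore <- function(primary, secondary) {
  stopifnot(nchar(primary) == nchar(secondary))
  ch <- .splitSeq(primary)
  pref <- .preferredSets(secondary)
  mean(vapply(seq_along(ch), function(i) ch[i] %in% pref[[i]], logical(1)))
}

#' @rdname patternMatchScore
#' @param config a [synthConfig()] list (protection parameters are read
#'   from it).
#' @return `latentProtection`: protection in EC50 log units,
#'   `protectionScale * plogis((match - mid) / width)`.
#' @export
latentProtection <- function(primary, secondary, config = synthConfig()) {
  m <- vapply(seq_along(primary),
              function(i) patternMatchScore(primary[i], secondary[i]),
              numeric(1))
  config$protectionScale *
    stats::plogis((m - config$protectionMid) / config$protectionWidth)
}

#' Generate one synthetic design
#'
#' Expands a topology template into a secondary string of the requested
#' length (loops of 2--4 residues between and around elements, remaining
#' length shared among helices/strands) and samples a primary sequence
#' with position-class-dependent residue distributions: each position
#' draws from its preferred set ([patternMatchScore()]) with a per-design
#' bias probability, otherwise from the complement. If `template` is
#' already a full secondary string of the right length it is used as is.
#'
#' @param template topology string over H/E (e.g. `"EHEE"`), or a full
#'   secondary string over L/E/H of length `length`.
#' @param length total design length in residues.
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @param matchBias probability of drawing from the preferred set; by
#'   default drawn per design from U(0.55, 0.95).
#' @return A [ProteinDesignSet-class] of length 1.
#' @export
generateDesign <- function(template, length, seed = 1L, matchBias = NULL) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sec <- if (nchar(template) == length) template
         else .expandTemplate(template, length)
  if (is.null(matchBias)) matchBias <- stats::runif(1, 0.55, 0.95)
  pref <- .preferredSets(sec)
  ch <- vapply(pref, function(s) {
    if (stats::runif(1) < matchBias) sample(s, 1L)
    else sample(setdiff(.AA20, s), 1L)
  }, character(1))
  ProteinDesignSet(id = sprintf("syn_%s_%d_s%d", template, length, seed),
                   primary = paste(ch, collapse = ""), secondary = sec,
                   designClass = sprintf("%s_len%d", template,
                                         5L * (length %/% 5L)),
                   provenance = "expert")
}

.expandTemplate <- function(template, length) {
  el <- .splitSeq(template)
  stopifnot(all(el %in% c("H", "E")))
  nEl <- length(el)
  nLoop <- nEl + 1L
  loopLen <- sample(2:4, nLoop, replace = TRUE)
  minEl <- ifelse(el == "H", 6L, 3L)
  rest <- length - sum(loopLen) - sum(minEl)
  if (rest < 0L) {
    loopLen <- rep(2L, nLoop)
    rest <- length - sum(loopLen) - sum(minEl)
    if (rest < 0L) stop("template does not fit length", call. = FALSE)
  }
  extra <- if (rest > 0L)
    tabulate(sample.int(nEl, rest, replace = TRUE), nEl) else integer(nEl)
  elLen <- minEl + extra
  parts <- character(2L * nEl + 1L)
  parts[seq(1L, 2L * nEl + 1L, by = 2L)] <- strrep("L", loopLen)
  parts[seq(2L, 2L * nEl, by = 2L)] <- strrep(el, elLen)
  paste(parts, collapse = "")
}

#' Scramble a design
#'
#' `full` mode permutes all residues uniformly. `patterned` mode permutes
#' residues only within the hydrophobic class and within the hydrophilic
#' class, keeping every glycine and proline at its original index, so the
#' hydrophobic/hydrophilic patterning and G/P positioning are preserved.
#'
#' @param design a [ProteinDesignSet-class] of length 1.
#' @param mode `"full"` or `"patterned"`.
#' @param seed integer seed for the permutation.
#' @return A [ProteinDesignSet-class] of length 1 with provenance
#'   `"scramble"` (secondary string dropped: it no longer describes the
#'   sequence).
#' @export
makeScramble <- function(design, mode = c("full", "patterned"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(design) == 1L)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- .splitSeq(design@primary)
  if (mode == "full") {
    ch <- sample(ch)
  } else {
    fixed <- ch %in% c("G", "P")
    hyd <- ch %in% .HYDROPHOBIC & !fixed
    pol <- !hyd & !fixed
    ch[hyd] <- sample(ch[hyd])
    ch[pol] <- sample(ch[pol])
  }
  ProteinDesignSet(id = paste0(design@id, "|scr_", mode, "_", seed),
                   primary = paste(ch, collapse = ""),
                   secondary = NA_character_,
                   designClass = design@designClass,
                   provenance = "scramble")
}

.ceilingCompress <- function(x, ceiling) {
  if (is.null(ceiling)) return(x)
  cc <- ceiling[[1L]]; ss <- ceiling[[2L]]
  ifelse(x <= cc, x, cc + ss * (x - cc))
}

.baseline <- function(seqs, coef, residues) {
  frac <- vapply(seqs, function(s) {
    ch <- .splitSeq(s)
    mean(ch %in% residues)
  }, numeric(1), USE.NAMES = FALSE)
  coef[1L] + coef[2L] * frac
}

#' Simulate the protease-resistance assay
#'
#' For each design, per protease: an unfolded baseline linear in
#' cleavage-prone residue fraction (K/R for trypsin, F/Y/W/L for
#' chymotrypsin), plus folded protection ([latentProtection()]; the
#' secondary used is the design's own, or the parent pattern for
#' scrambles where it is effectively absent and protection collapses to
#' near zero), passed through the configured ceiling compression, plus
#' Gaussian noise. Credible-interval widths are drawn log-normally.
#'
#' @param designs a [ProteinDesignSet-class]; designs without a secondary
#'   string (e.g. scrambles) receive protection from their chance-level
#'   match to a trivial all-loop pattern.
#' @param config a [synthConfig()] list.
#' @param seed integer seed (noise and CI widths).
#' @param secondaryFor optional named character vector supplying the
#'   secondary pattern against which match quality is computed (used for
#'   scrambles, whose parents' patterns they fail to match).
#' @return list with `assay` (data.frame: id, sequence, ec50_*, ci_*)
#'   and `truth` (data.frame: id, match, protection, baseline_*).
#' @export
simulateAssay <- function(designs, config = synthConfig(), seed = 1L,
                          secondaryFor = NULL) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seqs <- unname(primarySeq(designs))
  sec <- unname(secondarySeq(designs))
  if (!is.null(secondaryFor)) {
    m <- match(designId(designs), names(secondaryFor))
    sec[!is.na(m)] <- secondaryFor[m[!is.na(m)]]
  }
  # sequences with no usable secondary: score match against an all-loop
  # pattern, which sits at chance for any sequence
  sec[is.na(sec)] <- strrep("L", nchar(seqs[is.na(sec)]))
  prot <- latentProtection(seqs, sec, config)
  bT <- .baseline(seqs, config$baselineTrypsin, c("K", "R"))
  bC <- .baseline(seqs, config$baselineChymotrypsin, c("F", "Y", "W", "L"))
  n <- length(seqs)
  obsT <- .ceilingCompress(bT + prot, config$ceiling) +
    stats::rnorm(n, 0, config$noiseSd)
  obsC <- .ceilingCompress(bC + prot, config$ceiling) +
    stats::rnorm(n, 0, config$noiseSd)
  assay <- data.frame(
    id = designId(designs), sequence = seqs,
    ec50_trypsin = obsT, ec50_chymotrypsin = obsC,
    ci_trypsin = stats::rlnorm(n, config$ciMeanlog, config$ciSdlog),
    ci_chymotrypsin = stats::rlnorm(n, config$ciMeanlog, config$ciSdlog),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = designId(designs), match = NA_real_,
                      protection = prot, baseline_trypsin = bT,
                      baseline_chymotrypsin = bC, stringsAsFactors = FALSE)
  truth$match <- vapply(seq_len(n),
                        function(i) patternMatchScore(seqs[i], sec[i]),
                        numeric(1))
  list(assay = assay, truth = truth)
}

#' Generate a complete synthetic corpus
#'
#' Produces everything the pipeline needs: designs with secondary strings
#' and class labels, one full scramble per design (the unfolded-state
#' training set and negative controls), assay tables and latent truth for
#' both, and a set of unlabeled "natural-like" sequences with their
#' scrambles for the evaluator's comparator stream. Reproducible
#' bit-for-bit from (config, seed).
#'
#' @param config a [synthConfig()] list.
#' @param seed integer master seed.
#' @param nNaturals number of natural-like sequences (default
#'   `nDesigns / 4`).
#' @return A list with elements `designs`, `scrambles`, `naturals`,
#'   `naturalScrambles` ([ProteinDesignSet-class]s), `assayDesigns`,
#'   `assayScrambles`, `truthDesigns`, `truthScrambles` (data.frames).
#' @export
generateCorpus <- function(config = synthConfig(), seed = 1L,
                           nNaturals = NULL) {
  n <- config$nDesigns
  if (is.null(nNaturals)) nNaturals <- max(8L, n %/% 4L)
  lens <- config$lengthRange[1L]:config$lengthRange[2L]

  minLen <- function(tpl) {
    el <- .splitSeq(tpl)
    2L * (length(el) + 1L) + sum(ifelse(el == "H", 6L, 3L))
  }
  makeSet <- function(count, seedBase, prov) {
    sets <- vector("list", count)
    for (i in seq_len(count)) {
      tpl <- config$templates[1L + (seedBase + i) %% length(config$templates)]
      ok <- lens[lens >= minLen(tpl)]
      len <- ok[1L + (.stableHash(paste0(seedBase, ":", i)) %% length(ok))]
      d <- generateDesign(tpl, len, seed = seedBase + i)
      d@id <- sprintf("%s_%05d", prov, i)
      d@provenance <- prov
      sets[[i]] <- d
    }
    Reduce(combineDesigns, sets)
  }
  designs <- makeSet(n, seedBase = seed * 1000L, prov = "expert")
  naturals <- makeSet(nNaturals, seedBase = seed * 1000L + 500000L,
                      prov = "natural")

  scrOne <- function(set, k) {
    out <- vector("list", length(set))
    for (i in seq_along(set)) {
      out[[i]] <- makeScramble(set[i], "full", seed = k + i)
    }
    Reduce(combineDesigns, out)
  }
  scrambles <- scrOne(designs, seed * 2000L)
  natScrambles <- scrOne(naturals, seed * 3000L)

  # scrambles are judged against their parents' secondary patterns
  parentSec <- stats::setNames(unname(secondarySeq(designs)),
                               designId(scrambles))
  simD <- simulateAssay(designs, config, seed = seed + 11L)
  simS <- simulateAssay(scrambles, config, seed = seed + 13L,
                        secondaryFor = parentSec)
  list(designs = designs, scrambles = scrambles, naturals = naturals,
       naturalScrambles = natScrambles,
       assayDesigns = simD$assay, assayScrambles = simS$assay,
       truthDesigns = simD$truth, truthScrambles = simS$truth,
       config = config, seed = seed)
}

#' Simulate two assay chips sharing ladder designs
#'
#' Chip A carries the reference EC50 values; chip B carries the same
#' designs distorted by the configured linear map (per protease) plus
#' noise. A subset of designs spanning the EC50 range is flagged as the
#' ladder. Used to exercise [reconcileChip()] end to end.
#'
#' @param assay an assay data.frame from [simulateAssay()].
#' @param config a [synthConfig()] list (`chipDistortion`, `noiseSd`).
#' @param nLadder number of ladder designs (>= 10, spanning the range).
#' @param seed integer seed for the chip-B noise.
#' @return list with `chipA`, `chipB` (data.frames), `ladderIds`.
#' @export
makeLadderChips <- function(assay, config = synthConfig(), nLadder = 20L,
                            seed = 1L) {
  stopifnot(nLadder >= 10L, nrow(assay) >= nLadder)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sl <- config$chipDistortion[[1L]]; ic <- config$chipDistortion[[2L]]
  chipB <- assay
  for (p in .PROTEASES) {
    col <- paste0("ec50_", p)
    chipB[[col]] <- ic + sl * assay[[col]] +
      stats::rnorm(nrow(assay), 0, config$noiseSd)
  }
  # ladder: designs at evenly spaced quantiles of the trypsin EC50 range
  ord <- order(assay$ec50_trypsin)
  pickIdx <- ord[unique(round(seq(1L, nrow(assay), length.out = nLadder)))]
  list(chipA = assay, chipB = chipB, ladderIds = assay$id[pickIdx])
}
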