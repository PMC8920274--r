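#' Stamped TSV input and output
#'
#' All tabular artifacts travel as UTF-8 tab-separated files whose
#' header comment lines (prefixed `#`) carry the tool version, seed and
#' configuration hash, so every output records how it was made.
#' `readEC50Table` reads an assay table (columns `id`, `ec50_trypsin`,
#' `ec50_chymotrypsin` and optionally `ci_*`, `sequence`).
#'
#' @param df a data.frame.
#' @param path file path.
#' @param header named list written as `# key: value` lines.
#' @return `writeStampedTSV` returns `path` invisibly; `readEC50Table`
#'   returns a data.frame.
#' @export
writeStampedTSV <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(list(tool = paste0("protstab ",
                              as.character(utils::packageVersion("protstab")))),
           header)
  for (nm in names(hdr)) {
    writeLines(sprintf("# %s: %s", nm, hdr[[nm]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStampedTSV
#' @export
readEC50Table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("id", "ec50_trypsin", "ec50_chymotrypsin")
  if (!all(need %in% names(tab))) {
    stop("EC50 table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

# Stable short hash of a configuration list (for output stamping).
configHash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", .stableHash(s))
}

#' Filter assay records by credible-interval width
#'
#' Keeps records whose credible-interval widths for both measured
#' protease EC50 values are no greater than `maxWidth` (default 2, the
#' reference analysis threshold), and reports kept/dropped counts.
#'
#' @param records data.frame with `ci_trypsin` and `ci_chymotrypsin`
#'   columns.
#' @param maxWidth maximum admissible CI width.
#' @return The filtered data.frame, with attributes `nKept`/`nDropped`.
#' @examples
#' df <- data.frame(id = 1:2, ci_trypsin = c(1.5, 2.5),
#'                  ci_chymotrypsin = c(1.9, 1.0))
#' filterByCI(df)   # keeps only the first row
#' @export
filterByCI <- function(records, maxWidth = 2.0) {
  need <- c("ci_trypsin", "ci_chymotrypsin")
  if (!all(need %in% names(records))) {
    stop("records lack credible-interval columns ",
         paste(setdiff(need, names(records)), collapse = ", "),
         call. = FALSE)
  }
  keep <- records$ci_trypsin <= maxWidth &
    records$ci_chymotrypsin <= maxWidth
  out <- records[keep, , drop = FALSE]
  attr(out, "nKept") <- sum(keep)
  attr(out, "nDropped") <- sum(!keep)
  message(sprintf("CI filter (width <= %g): kept %d, dropped %d",
                  maxWidth, sum(keep), sum(!keep)))
  out
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order on a synthetic corpus:
#' corpus generation, unfolded-state model training, stability scoring,
#' CI filtering, evaluator training, generator training, beam decoding
#' of new designs from held-out secondary structures, evaluator-guided
#' refinement, and cross-chip calibration. Artifacts are returned as a
#' list and, when `outDir` is given, written as stamped TSV/FASTA files.
#' Reruns with the same config and seed produce identical outputs.
#'
#' This is a smoke-scale orchestration: model configurations default to
#' the reduced desk-scale settings.
#'
#' @param synthCfg a [synthConfig()] list.
#' @param emCfg an [emConfig()] list.
#' @param gmCfg a [gmConfig()] list.
#' @param usmCfg a [usmConfig()] list.
#' @param seed master seed; every stage derives its randomness from it.
#' @param outDir optional output directory (created; existing files are
#'   only overwritten with `force = TRUE`).
#' @param nRefine number of designs to refine.
#' @param refineRounds,refineK beam-refinement parameters.
#' @param force overwrite existing outputs.
#' @return Named list of artifacts: `corpus`, `usm`, `scores`,
#'   `filtered`, `em`, `gm`, `generated`, `refined`, `calibration`,
#'   `manifest`.
#' @export
runPipeline <- function(synthCfg = synthConfig(nDesigns = 500L),
                        emCfg = emConfigSmall(maxEpochs = 6L),
                        gmCfg = gmConfig(iterations = 4L),
                        usmCfg = usmConfig(epochs = 25L),
                        seed = 1L, outDir = NULL, nRefine = 5L,
                        refineRounds = 2L, refineK = 3L, force = FALSE) {
  manifest <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (completed: %s)", name,
                   conditionMessage(e),
                   paste(manifest, collapse = ", ")), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    manifest <<- c(manifest, name)
    res
  }

  corpus <- stage("synth", generateCorpus(synthCfg, seed = seed))

  usm <- stage("train-usm", {
    scr <- corpus$assayScrambles
    trainUSM(rbind(
      data.frame(sequence = scr$sequence, protease = "trypsin",
                 ec50 = scr$ec50_trypsin, stringsAsFactors = FALSE),
      data.frame(sequence = scr$sequence, protease = "chymotrypsin",
                 ec50 = scr$ec50_chymotrypsin, stringsAsFactors = FALSE)),
      usmCfg, seed = seed + 1L)
  })

  scores <- stage("score", stabilityScore(corpus$assayDesigns, usm))
  filtered <- stage("filter", suppressMessages(filterByCI(scores)))

  em <- stage("train-em", trainEM(
    corpus$designs[match(filtered$id, designId(corpus$designs))],
    data.frame(id = filtered$id,
               score_trypsin = filtered$score_trypsin,
               score_chymotrypsin = filtered$score_chymotrypsin),
    naturals = corpus$naturals,
    naturalScrambles = corpus$naturalScrambles,
    config = emCfg, seed = seed + 2L))

  gm <- stage("train-gm", {
    keep <- filtered$score > 0 | seq_len(nrow(filtered)) <= 64L
    ids <- filtered$id[keep]
    ds <- corpus$designs[match(ids, designId(corpus$designs))]
    prim <- chartr("C", "S", unname(primarySeq(ds)))  # GM vocab excludes C
    sw <- stabilityWeightedSubset(
      ProteinDesignSet(designId(ds), prim, unname(secondarySeq(ds))),
      pmax(filtered$score[keep], 0.05), seed = seed + 3L)
    pairs <- data.frame(secondary = unname(secondarySeq(sw$designs)),
                        primary = unname(primarySeq(sw$designs)),
                        stringsAsFactors = FALSE)
    trainGM(pairs, gmCfg, seed = seed + 3L)
  })

  generated <- stage("generate", {
    sec <- unname(secondarySeq(corpus$designs[1:3]))
    do.call(rbind, lapply(seq_along(sec), function(i) {
      out <- beamDecode(gm, sec[i], width = gmCfg$beamWidth)
      out$id <- sprintf("gen_%02d_%d", i, seq_len(nrow(out)))
      out$secondary <- sec[i]
      out
    }))
  })

  refined <- stage("refine", {
    scorer <- emScorer(em)
    ids <- utils::head(filtered$id, nRefine)
    do.call(rbind, lapply(ids, function(id) {
      s <- filtered$sequence[filtered$id == id]
      out <- beamRefine(s, scorer, k = refineK, rounds = refineRounds)
      out$id <- id
      out
    }))
  })

  calibration <- stage("calibrate", {
    chips <- makeLadderChips(corpus$assayDesigns, synthCfg,
                             seed = seed + 5L)
    ladder <- data.frame(
      id = chips$ladderIds,
      ref_trypsin = chips$chipA$ec50_trypsin[
        match(chips$ladderIds, chips$chipA$id)],
      ref_chymotrypsin = chips$chipA$ec50_chymotrypsin[
        match(chips$ladderIds, chips$chipA$id)])
    reconcileChip(chips$chipB, ladder)
  })

  artifacts <- list(corpus = corpus, usm = usm, scores = scores,
                    filtered = filtered, em = em, gm = gm,
                    generated = generated, refined = refined,
                    calibration = calibration, manifest = manifest,
                    seed = seed)
  if (!is.null(outDir)) {
    .writePipelineArtifacts(artifacts, outDir, synthCfg, seed, force)
  }
  artifacts
}

.writePipelineArtifacts <- function(artifacts, outDir, synthCfg, seed,
                                    force) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(seed = seed, config = configHash(synthCfg))
  paths <- file.path(outDir, c("designs.fasta", "designs_secondary.tsv",
                               "scores.tsv", "generated.tsv",
                               "refined.tsv"))
  if (!force && any(file.exists(paths))) {
    stop("output files exist; use force = TRUE to overwrite",
         call. = FALSE)
  }
  writeDesigns(artifacts$corpus$designs, paths[1L], paths[2L],
               header = hdr)
  writeStampedTSV(artifacts$scores, paths[3L], header = hdr)
  writeStampedTSV(artifacts$generated, paths[4L], header = hdr)
  writeStampedTSV(artifacts$refined, paths[5L], header = hdr)
  invisible(outDir)
}
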