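#' Refinement constraint regimes
#'
#' Constraints applied to candidate single-site substitutions during
#' beam-search refinement: a set of forbidden target residues (presets:
#' none; no tryptophan; none of the eight nonpolar residues
#' A,F,I,L,M,V,W,Y) and an optional rule that a substitution may not
#' decrease either protease's unfolded-state EC50 prediction relative to
#' a reference sequence (the immediate parent by default, or the
#' original round-0 sequence).
#'
#' @param forbidden character vector of amino acids that substitutions
#'   may not introduce.
#' @param usmNondecrease require USM predictions not to decrease.
#' @param usmReference `"parent"` or `"original"`.
#' @return A list of class settings used by the refinement functions.
#' @export
refinementConstraints <- function(forbidden = character(),
                                  usmNondecrease = FALSE,
                                  usmReference = c("parent", "original")) {
  usmReference <- match.arg(usmReference)
  stopifnot(all(forbidden %in% .AA20))
  list(forbidden = forbidden, usmNondecrease = usmNondecrease,
       usmReference = usmReference)
}

#' @rdname refinementConstraints
#' @param regime one of `"none"`, `"no-W"`, `"no-AFILMVWY"`.
#' @param ... passed on to `refinementConstraints`.
#' @export
constraintRegime <- function(regime = c("none", "no-W", "no-AFILMVWY"),
                             ...) {
  regime <- match.arg(regime)
  forbidden <- switch(regime, none = character(), `no-W` = "W",
                      `no-AFILMVWY` = .HYDROPHOBIC)
  refinementConstraints(forbidden = forbidden, ...)
}

#' Enumerate constrained single-site substitutions
#'
#' Generates all `len * 19` single-residue replacements of a sequence,
#' then removes those that introduce a forbidden target residue and --
#' when the USM-nondecrease rule is active -- those whose predicted
#' unfolded-state EC50 under either protease falls below the reference
#' sequence's prediction.
#'
#' @param sequence primary sequence.
#' @param constraints a [refinementConstraints()] list.
#' @param usmModel a [USMModel-class] (required when
#'   `constraints$usmNondecrease`).
#' @param referenceSeq sequence whose USM predictions set the floor
#'   (default: `sequence` itself).
#' @return data.frame with columns `position` (1-based), `from`, `to`,
#'   `sequence`.
#' @export
enumerateSubstitutions <- function(sequence, constraints =
                                     refinementConstraints(),
                                   usmModel = NULL,
                                   referenceSeq = sequence) {
  ch <- .splitSeq(sequence)
  len <- length(ch)
  targets <- lapply(seq_len(len), function(i)
    setdiff(.AA20, c(ch[i], constraints$forbidden)))
  pos <- rep(seq_len(len), lengths(targets))
  to <- unlist(targets)
  seqs <- vapply(seq_along(pos), function(k) {
    v <- ch; v[pos[k]] <- to[k]
    paste(v, collapse = "")
  }, character(1))
  out <- data.frame(position = pos, from = ch[pos], to = to,
                    sequence = seqs, stringsAsFactors = FALSE)
  if (isTRUE(constraints$usmNondecrease)) {
    if (is.null(usmModel)) {
      stop("usmNondecrease requires a USM model", call. = FALSE)
    }
    ref <- .usmPredictBoth(usmModel, referenceSeq)
    pred <- .usmPredictBoth(usmModel, out$sequence)
    keep <- pred[, 1L] >= ref[1L, 1L] - 1e-12 &
      pred[, 2L] >= ref[1L, 2L] - 1e-12
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Beam-search refinement of a sequence
#'
#' Five-round (by default) beam search over single-site substitutions:
#' each round pools all constrained substitutions of all current base
#' sequences (plus the previous round's product, so the per-round
#' product score is non-decreasing), deduplicates, ranks by the scorer,
#' records the top-1 as that round's product, and carries the top-`k`
#' forward as new bases. Ties are broken by lower mutation position,
#' then alphabetical replacement, which makes the search deterministic.
#'
#' @param sequence starting primary sequence.
#' @param scorer vectorised function: character vector of sequences ->
#'   numeric scores (typically [emScorer()]).
#' @param k beam width (the reference protocol used 50).
#' @param rounds number of refinement rounds (reference: 5).
#' @param constraints a [refinementConstraints()] list.
#' @param usmModel optional [USMModel-class] for the nondecrease rule.
#' @return data.frame with one row per completed round: `round`,
#'   `sequence`, `score`, `n_substitutions` (net Hamming distance from
#'   the origin).
#' @export
beamRefine <- function(sequence, scorer, k = 50L, rounds = 5L,
                       constraints = refinementConstraints(),
                       usmModel = NULL) {
  origin <- sequence
  originCh <- .splitSeq(origin)
  bases <- data.frame(sequence = sequence, score = scorer(sequence),
                      stringsAsFactors = FALSE)
  products <- vector("list", rounds)
  prevProduct <- NULL
  for (r in seq_len(rounds)) {
    refSeq <- if (constraints$usmReference == "original") origin else NULL
    cands <- unique(unlist(lapply(bases$sequence, function(s)
      enumerateSubstitutions(s, constraints, usmModel,
                             referenceSeq = refSeq %||% s)$sequence)))
    if (!is.null(prevProduct)) cands <- unique(c(cands, prevProduct))
    if (length(cands) == 0L) {
      warning("all candidates filtered out at round ", r,
              "; returning partial result")
      break
    }
    sc <- scorer(cands)
    # deterministic order: score desc, then the profile of mutated
    # positions (lexicographically, so lower positions win ties), then
    # alphabetical sequence
    diffKey <- vapply(cands, function(s) {
      d <- which(.splitSeq(s) != originCh)
      paste(sprintf("%03d", d), collapse = "")
    }, character(1))
    ord <- order(-sc, diffKey, cands)
    cands <- cands[ord]; sc <- sc[ord]
    products[[r]] <- data.frame(
      round = r, sequence = cands[1L], score = sc[1L],
      n_substitutions = sum(.splitSeq(cands[1L]) != originCh),
      stringsAsFactors = FALSE)
    prevProduct <- cands[1L]
    keep <- seq_len(min(k, length(cands)))
    bases <- data.frame(sequence = cands[keep], score = sc[keep],
                        stringsAsFactors = FALSE)
  }
  do.call(rbind, products[!vapply(products, is.null, logical(1))])
}

#' Random constrained substitutions (control arm)
#'
#' Applies one uniformly random constrained single-site substitution per
#' round -- the control against which guided refinement is compared.
#'
#' @param sequence starting primary sequence.
#' @param nRounds number of rounds.
#' @param constraints a [refinementConstraints()] list.
#' @param usmModel optional [USMModel-class].
#' @param seed integer seed.
#' @return data.frame with `round`, `sequence`, `n_substitutions`.
#' @export
randomSubstitutions <- function(sequence, nRounds = 5L,
                                constraints = refinementConstraints(),
                                usmModel = NULL, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  originCh <- .splitSeq(sequence)
  cur <- sequence
  rows <- vector("list", nRounds)
  for (r in seq_len(nRounds)) {
    nxt <- .drawRandomSubstitution(cur, constraints, usmModel)
    if (is.null(nxt)) {
      warning("no admissible substitution at round ", r)
      break
    }
    cur <- nxt
    rows[[r]] <- data.frame(
      round = r, sequence = cur,
      n_substitutions = sum(.splitSeq(cur) != originCh),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Uniform draw over admissible substitutions. Rejection sampling over
# (position, replacement) — uniform over the admissible set — with a
# full-enumeration fallback when acceptances are rare.
.drawRandomSubstitution <- function(sequence, constraints, usmModel) {
  ch <- .splitSeq(sequence)
  len <- length(ch)
  usmActive <- isTRUE(constraints$usmNondecrease)
  ref <- if (usmActive) .usmPredictBoth(usmModel, sequence) else NULL
  for (try in seq_len(100L)) {
    pos <- sample.int(len, 1L)
    to <- sample(setdiff(.AA20, ch[pos]), 1L)
    if (to %in% constraints$forbidden) next
    v <- ch; v[pos] <- to
    cand <- paste(v, collapse = "")
    if (usmActive) {
      p <- .usmPredictBoth(usmModel, cand)
      if (p[1L, 1L] < ref[1L, 1L] - 1e-12 ||
          p[1L, 2L] < ref[1L, 2L] - 1e-12) next
    }
    return(cand)
  }
  cands <- enumerateSubstitutions(sequence, constraints, usmModel)
  if (nrow(cands) == 0L) return(NULL)
  cands$sequence[sample.int(nrow(cands), 1L)]
}

#' Substitution-effect matrix with per-cell tests
#'
#' Aggregates observed stability-score changes of single-site
#' substitutions by (from, to) residue pair and condition (guided vs
#' random), reporting per-cell means, their difference, sample sizes, a
#' Welch two-sample two-tailed t-test p-value (uncorrected, with an
#' optional Benjamini-Hochberg column), and marginal means per from- and
#' per to-residue.
#'
#' @param records data.frame with columns `from`, `to`, `condition`
#'   (`"guided"` or `"random"`) and `delta` (stability-score change).
#' @param fdr append a BH-adjusted p-value column.
#' @return list with `cells` (one row per observed (from, to) pair),
#'   `fromMarginal`, `toMarginal`.
#' @export
substitutionEffectMatrix <- function(records, fdr = FALSE) {
  stopifnot(nrow(records) > 0L,
            all(c("from", "to", "condition", "delta") %in% names(records)))
  key <- interaction(records$from, records$to, drop = TRUE)
  cells <- do.call(rbind, lapply(split(records, key), function(d) {
    g <- d$delta[d$condition == "guided"]
    r <- d$delta[d$condition == "random"]
    p <- if (length(g) >= 2L && length(r) >= 2L) {
      stats::t.test(g, r)$p.value
    } else NA_real_
    data.frame(from = d$from[1L], to = d$to[1L],
               mean_guided = if (length(g)) mean(g) else NA_real_,
               mean_random = if (length(r)) mean(r) else NA_real_,
               difference = (if (length(g)) mean(g) else NA_real_) -
                 (if (length(r)) mean(r) else NA_real_),
               n_guided = length(g), n_random = length(r),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  if (fdr) cells$p_bh <- stats::p.adjust(cells$p_value, "BH")
  marg <- function(byCol) {
    agg <- split(records, records[[byCol]])
    do.call(rbind, lapply(agg, function(d) data.frame(
      residue = d[[byCol]][1L],
      mean_guided = mean(d$delta[d$condition == "guided"]),
      mean_random = mean(d$delta[d$condition == "random"]),
      n = nrow(d), stringsAsFactors = FALSE)))
  }
  list(cells = cells, fromMarginal = marg("from"), toMarginal = marg("to"))
}
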