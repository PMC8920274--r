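#' Generator model configuration
#'
#' Settings for the secondary-to-primary sequence generator (and its
#' reverse): a convolutional encoder over the one-hot source sequence, a
#' convolutional-feature attention mechanism with a Gaussian monotonic-
#' alignment prior (source and target have equal length), and a
#' single-layer LSTM decoder. The default sizes are desk-scale; the
#' parameter count is reported by the model's `show` method at build
#' time.
#'
#' @param dEmb target-token embedding dimension.
#' @param encKernels kernel counts of the two same-padded encoder conv
#'   layers.
#' @param encWidths kernel widths (odd) of the encoder conv layers.
#' @param dAtt attention key/query dimension.
#' @param dHidden LSTM hidden size.
#' @param beamWidth default beam width for decoding.
#' @param iterations training epochs (the reference run used 65).
#' @param lr SGD learning rate.
#' @param batchSize sequences per minibatch.
#' @param gradClip global gradient-norm clip.
#' @param priorSigma width (positions) of the Gaussian alignment prior.
#' @return A named list of settings.
#' @export
gmConfig <- function(dEmb = 12L, encKernels = c(24L, 24L),
                     encWidths = c(5L, 3L), dAtt = 16L, dHidden = 32L,
                     beamWidth = 5L, iterations = 65L, lr = 0.5,
                     batchSize = 64L, gradClip = 5, priorSigma = 2) {
  stopifnot(beamWidth >= 1L, all(encWidths %% 2L == 1L))
  as.list(environment())
}

#' GeneratorModel: sequence-to-sequence translator
#'
#' Translates aligned sequences between two vocabularies (secondary to
#' primary for the generator; primary to secondary for the reverse
#' model). Output sequences have the same length as the input; the stop
#' token appears only in training targets.
#'
#' @slot params named list of weights.
#' @slot config a [gmConfig()] list.
#' @slot sourceVocab,targetVocab character vectors of symbols; the last
#'   target symbol is the stop token.
#' @slot trainLog data.frame of per-epoch losses.
#' @export
setClass("GeneratorModel",
  representation(params = "list", config = "list",
                 sourceVocab = "character", targetVocab = "character",
                 trainLog = "data.frame"))

setValidity("GeneratorModel", function(object) {
  if (length(object@sourceVocab) < 2L || length(object@targetVocab) < 2L)
    return("vocabularies must have at least 2 symbols")
  if ("C" %in% utils::head(object@targetVocab, -1L) &&
      setequal(utils::head(object@targetVocab, -1L), .AA20))
    return("generator target vocabulary must exclude cysteine")
  TRUE
})

setMethod("show", "GeneratorModel", function(object) {
  nPar <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf(
    "GeneratorModel: %d -> %d symbols, %d parameters (conv encoder + attention + LSTM)\n",
    length(object@sourceVocab), length(object@targetVocab), nPar))
  if (nrow(object@trainLog) > 0L)
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                max(object@trainLog$epoch),
                object@trainLog$loss[nrow(object@trainLog)]))
})

#' Build an untrained generator
#'
#' @param config a [gmConfig()] list.
#' @param sourceVocab,targetVocab symbol vectors; the target's last
#'   element must be its stop token.
#' @param seed integer seed for initialisation.
#' @return A [GeneratorModel-class].
#' @export
buildGM <- function(config = gmConfig(),
                    sourceVocab = c("L", "E", "H"),
                    targetVocab = generatorAlphabet(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Vs <- length(sourceVocab); Vt <- length(targetVocab)
  ck <- config$encKernels; cw <- config$encWidths
  dE <- ck[2L]
  params <- list(
    Wc1 = glorot(ck[1L], Vs * cw[1L]), bc1 = numeric(ck[1L]),
    Wc2 = glorot(ck[2L], ck[1L] * cw[2L]), bc2 = numeric(ck[2L]),
    Wk = glorot(config$dAtt, dE), bk = numeric(config$dAtt),
    Wq = glorot(config$dAtt, config$dHidden), bq = numeric(config$dAtt),
    Wemb = glorot(config$dEmb, Vt), embStart = stats::rnorm(config$dEmb, 0, 0.1),
    Wl = glorot(4L * config$dHidden,
                config$dEmb + dE + config$dHidden),
    bl = c(numeric(config$dHidden), rep(1, config$dHidden),
           numeric(2L * config$dHidden)),  # forget-gate bias 1
    Wo = glorot(Vt, config$dHidden), bo = numeric(Vt))
  new("GeneratorModel", params = params, config = config,
      sourceVocab = sourceVocab, targetVocab = targetVocab,
      trainLog = data.frame())
}

# one-hot source batch: (Vs, Lmax, B); positions beyond len are zero
.gmSourceBatch <- function(seqs, vocab, Lmax) {
  B <- length(seqs)
  arr <- array(0, c(length(vocab), Lmax, B))
  for (i in seq_len(B)) {
    ch <- .splitSeq(seqs[i])
    arr[cbind(match(ch, vocab), seq_along(ch), i)] <- 1
  }
  arr
}

# same-padded conv: pad (w-1)/2 zeros each side, then valid conv
.convSame <- function(X, W, b, w) {
  p <- (w - 1L) %/% 2L
  d <- dim(X)
  Xp <- array(0, c(d[1L], d[2L] + 2L * p, d[3L]))
  Xp[, p + seq_len(d[2L]), ] <- X
  list(Y = convForward(Xp, W, b, w), Xp = Xp, pad = p)
}

.convSameBwd <- function(Xp, W, dY, w, pad, Lorig) {
  cb <- convBackward(Xp, W, dY, w)
  list(dX = cb$dX[, pad + seq_len(Lorig), , drop = FALSE],
       dW = cb$dW, db = cb$db)
}

# Encoder forward: returns enc (dE, Lmax, B), K (dAtt, Lmax, B), caches.
.gmEncode <- function(params, cfg, S) {
  c1 <- .convSame(S, params$Wc1, params$bc1, cfg$encWidths[1L])
  H1 <- relu(c1$Y)
  c2 <- .convSame(H1, params$Wc2, params$bc2, cfg$encWidths[2L])
  enc <- relu(c2$Y)
  d <- dim(enc)
  Kf <- params$Wk %*% matrix(enc, nrow = d[1L]) + params$bk
  K <- array(Kf, c(cfg$dAtt, d[2L], d[3L]))
  list(enc = enc, K = K, c1 = c1, H1 = H1, c2 = c2, S = S)
}

# attention score prior: Gaussian band around the diagonal
.alignPrior <- function(Lmax, t, sigma) {
  -(seq_len(Lmax) - t)^2 / (2 * sigma^2)
}

# Full teacher-forced forward (and optional caches for backward).
# tgt: integer matrix (Tmax, B), NA beyond len+1; row len+1 is stop.
.gmForward <- function(params, cfg, S, lens, tgt = NULL, wantCache = FALSE) {
  dA <- cfg$dAtt; dH <- cfg$dHidden; dEmb <- cfg$dEmb
  enc <- .gmEncode(params, cfg, S)
  dE <- dim(enc$enc)[1L]
  Lmax <- dim(S)[2L]; B <- dim(S)[3L]
  Tmax <- if (!is.null(tgt)) nrow(tgt) else Lmax
  active <- function(t) t <= (lens + 1L)
  maskArr <- matrix(-1e30, Lmax, B)
  for (i in seq_len(B)) maskArr[seq_len(lens[i]), i] <- 0

  H <- matrix(0, dH, B); C <- matrix(0, dH, B)
  logp <- matrix(NA_real_, Tmax, B)
  steps <- if (wantCache) vector("list", Tmax) else NULL
  nll <- 0; nTok <- 0L
  for (t in seq_len(Tmax)) {
    act <- which(if (!is.null(tgt)) !is.na(tgt[t, ]) else rep(TRUE, B))
    if (length(act) == 0L) break
    q <- params$Wq %*% H + params$bq            # dA x B
    scores <- matrix(0, Lmax, B)
    for (d in seq_len(dA)) {
      scores <- scores + enc$K[d, , ] * rep(q[d, ], each = Lmax)
    }
    scores <- scores + .alignPrior(Lmax, t, cfg$priorSigma) + maskArr
    alpha <- softmaxCols(scores)                # Lmax x B
    ctx <- matrix(0, dE, B)
    for (d in seq_len(dE)) ctx[d, ] <- colSums(enc$enc[d, , ] * alpha)
    embPrev <- if (t == 1L) matrix(params$embStart, dEmb, B) else {
      prev <- tgt[t - 1L, ]
      out <- matrix(0, dEmb, B)
      ok <- !is.na(prev)
      out[, ok] <- params$Wemb[, prev[ok], drop = FALSE]
      out
    }
    x <- rbind(embPrev, ctx, H)                  # (dEmb+dE+dH) x B
    z <- params$Wl %*% x + params$bl             # 4dH x B
    ig <- sigmoid(z[seq_len(dH), , drop = FALSE])
    fg <- sigmoid(z[dH + seq_len(dH), , drop = FALSE])
    og <- sigmoid(z[2L * dH + seq_len(dH), , drop = FALSE])
    gg <- tanh(z[3L * dH + seq_len(dH), , drop = FALSE])
    Cnew <- fg * C + ig * gg
    Hnew <- og * tanh(Cnew)
    # freeze state for finished samples
    upd <- if (!is.null(tgt)) !is.na(tgt[t, ]) else rep(TRUE, B)
    Cn <- C; Hn <- H
    Cn[, upd] <- Cnew[, upd]; Hn[, upd] <- Hnew[, upd]
    logits <- params$Wo %*% Hn + params$bo
    P <- softmaxCols(logits)
    if (!is.null(tgt)) {
      for (i in which(upd)) {
        p <- max(P[tgt[t, i], i], 1e-12)
        logp[t, i] <- log(p)
        nll <- nll - log(p)
        nTok <- nTok + 1L
      }
    }
    if (wantCache) {
      steps[[t]] <- list(q = q, alpha = alpha, ctx = ctx, x = x,
                         ig = ig, fg = fg, og = og, gg = gg,
                         Cprev = C, Cnew = Cn, Hprev = H, Hnew = Hn,
                         P = P, upd = upd)
    }
    H <- Hn; C <- Cn
  }
  list(nll = nll, nTok = nTok, logp = logp, enc = enc, steps = steps,
       maskArr = maskArr)
}

# Backward through the decoder, attention and encoder. Returns gradients
# for all params. fw must come from .gmForward(wantCache = TRUE).
.gmBackward <- function(params, cfg, S, lens, tgt, fw, lossScale = 1) {
  dA <- cfg$dAtt; dH <- cfg$dHidden; dEmb <- cfg$dEmb
  enc <- fw$enc
  dE <- dim(enc$enc)[1L]
  Lmax <- dim(S)[2L]; B <- dim(S)[3L]
  Tmax <- nrow(tgt)
  g <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  dEnc <- array(0, dim(enc$enc))
  dK <- array(0, dim(enc$K))
  dHn <- matrix(0, dH, B); dCn <- matrix(0, dH, B)
  for (t in rev(seq_len(Tmax))) {
    st <- fw$steps[[t]]
    if (is.null(st)) next
    upd <- st$upd
    # output layer: softmax CE gradient on active samples
    dLogits <- st$P
    for (i in which(upd)) dLogits[tgt[t, i], i] <- dLogits[tgt[t, i], i] - 1
    dLogits[, !upd] <- 0
    dLogits <- dLogits * lossScale
    g$Wo <- g$Wo + tcrossprod(dLogits, st$Hnew)
    g$bo <- g$bo + rowSums(dLogits)
    dH_t <- crossprod(params$Wo, dLogits) + dHn
    dH_t[, !upd] <- 0
    dC_t <- dCn
    dC_t[, !upd] <- 0
    # LSTM cell backward
    tC <- tanh(st$Cnew)
    dOg <- dH_t * tC
    dCc <- dC_t + dH_t * st$og * (1 - tC^2)
    dIg <- dCc * st$gg
    dFg <- dCc * st$Cprev
    dGg <- dCc * st$ig
    dz <- rbind(dIg * st$ig * (1 - st$ig),
                dFg * st$fg * (1 - st$fg),
                dOg * st$og * (1 - st$og),
                dGg * (1 - st$gg^2))
    g$Wl <- g$Wl + tcrossprod(dz, st$x)
    g$bl <- g$bl + rowSums(dz)
    dx <- crossprod(params$Wl, dz)
    dEmbPrev <- dx[seq_len(dEmb), , drop = FALSE]
    dCtx <- dx[dEmb + seq_len(dE), , drop = FALSE]
    dHprev <- dx[dEmb + dE + seq_len(dH), , drop = FALSE]
    # frozen samples pass their state gradient straight through
    dHprev[, !upd] <- dHn[, !upd]
    dCprev <- dCc * st$fg
    dCprev[, !upd] <- dCn[, !upd]
    # embeddings
    if (t == 1L) {
      g$embStart <- g$embStart + rowSums(dEmbPrev)
    } else {
      prev <- tgt[t - 1L, ]
      for (i in which(!is.na(prev) & upd)) {
        g$Wemb[, prev[i]] <- g$Wemb[, prev[i]] + dEmbPrev[, i]
      }
    }
    # attention backward
    dAlpha <- matrix(0, Lmax, B)
    for (d in seq_len(dE)) {
      dAlpha <- dAlpha + enc$enc[d, , ] * rep(dCtx[d, ], each = Lmax)
      dEnc[d, , ] <- dEnc[d, , ] + st$alpha * rep(dCtx[d, ], each = Lmax)
    }
    dAlpha[, !upd] <- 0
    sAd <- colSums(st$alpha * dAlpha)
    dScores <- st$alpha * (dAlpha - rep(sAd, each = Lmax))
    dq <- matrix(0, dA, B)
    for (d in seq_len(dA)) {
      dq[d, ] <- colSums(enc$K[d, , ] * dScores)
      dK[d, , ] <- dK[d, , ] + dScores * rep(st$q[d, ], each = Lmax)
    }
    g$Wq <- g$Wq + tcrossprod(dq, st$Hprev)
    g$bq <- g$bq + rowSums(dq)
    dHprev <- dHprev + crossprod(params$Wq, dq)
    dHn <- dHprev; dCn <- dCprev
  }
  # keys -> encoder
  encMat <- matrix(enc$enc, nrow = dE)
  dKmat <- matrix(dK, nrow = dA)
  g$Wk <- g$Wk + tcrossprod(dKmat, encMat)
  g$bk <- g$bk + rowSums(dKmat)
  dEnc <- dEnc + array(crossprod(params$Wk, dKmat), dim(dEnc))
  # encoder conv stack backward
  dC2out <- reluGrad(enc$enc, dEnc)
  cb2 <- .convSameBwd(enc$c2$Xp, params$Wc2, dC2out, cfg$encWidths[2L],
                      enc$c2$pad, Lmax)
  g$Wc2 <- g$Wc2 + cb2$dW; g$bc2 <- g$bc2 + cb2$db
  dH1 <- reluGrad(enc$H1, cb2$dX)
  cb1 <- .convSameBwd(enc$c1$Xp, params$Wc1, dH1, cfg$encWidths[1L],
                      enc$c1$pad, Lmax)
  g$Wc1 <- g$Wc1 + cb1$dW; g$bc1 <- g$bc1 + cb1$db
  g
}

.gmTargets <- function(seqs, vocab, Tmax) {
  B <- length(seqs)
  tgt <- matrix(NA_integer_, Tmax, B)
  stopIdx <- length(vocab)
  for (i in seq_len(B)) {
    ch <- .splitSeq(seqs[i])
    idx <- match(ch, vocab)
    tgt[seq_along(idx), i] <- idx
    tgt[length(idx) + 1L, i] <- stopIdx
  }
  tgt
}

.checkPairs <- function(pairs, sourceVocab, targetVocab) {
  stopifnot(all(c("secondary", "primary") %in% names(pairs)))
  if (any(nchar(pairs$secondary) != nchar(pairs$primary))) {
    stop("secondary and primary must have equal lengths", call. = FALSE)
  }
  tv <- utils::head(targetVocab, -1L)
  bad <- vapply(pairs$primary, function(p)
    any(!.splitSeq(p) %in% tv), logical(1))
  if (identical(sort(tv), sort(setdiff(.AA20, "C"))) && any(bad)) {
    off <- unique(unlist(lapply(pairs$primary[bad], function(p)
      setdiff(.splitSeq(p), tv))))
    stop("primary sequences contain symbols outside the generator ",
         "vocabulary (cysteine is excluded): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (any(bad)) stop("sequences outside the target vocabulary",
                     call. = FALSE)
  invisible(TRUE)
}

#' Train the generator (secondary to primary)
#'
#' Fits the sequence-to-sequence model by minimising the cross-entropy of
#' the predicted primary sequence against the reference, with plain
#' stochastic gradient descent for `config$iterations` epochs.
#' Deterministic given `seed`. Pairs containing cysteine are rejected at
#' load time.
#'
#' @param pairs data.frame with columns `secondary`, `primary` (equal
#'   lengths per row).
#' @param config a [gmConfig()] list.
#' @param seed integer seed.
#' @return A trained [GeneratorModel-class].
#' @export
trainGM <- function(pairs, config = gmConfig(), seed = 1L) {
  .trainSeq2Seq(pairs$secondary, pairs$primary, c("L", "E", "H"),
                generatorAlphabet(), config, seed,
                checkCys = TRUE)
}

#' @rdname trainGM
#' @details `trainReverseGM` trains the same architecture with primary as
#'   source and secondary as target (the "Reverse GM" used for
#'   secondary-structure agreement checks); its source vocabulary is the
#'   full 20-amino-acid alphabet and its target is \{L,E,H\} plus stop.
#' @export
trainReverseGM <- function(pairs, config = gmConfig(), seed = 1L) {
  .trainSeq2Seq(pairs$primary, pairs$secondary, .AA20,
                c("L", "E", "H", "O"), config, seed, checkCys = FALSE)
}

.trainSeq2Seq <- function(src, tgtSeqs, sourceVocab, targetVocab, config,
                          seed, checkCys = FALSE) {
  if (length(src) == 0L) stop("empty pair set", call. = FALSE)
  if (checkCys) {
    .checkPairs(data.frame(secondary = src, primary = tgtSeqs),
                sourceVocab, targetVocab)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  model <- buildGM(config, sourceVocab, targetVocab, seed = seed)
  params <- model@params
  n <- length(src)
  lens <- nchar(src)
  log <- data.frame(epoch = integer(), loss = numeric())
  for (epoch in seq_len(config$iterations)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    tot <- 0; totTok <- 0L
    for (bt in batches) {
      Lmax <- max(lens[bt])
      S <- .gmSourceBatch(src[bt], sourceVocab, Lmax)
      tgt <- .gmTargets(tgtSeqs[bt], targetVocab, Lmax + 1L)
      fw <- .gmForward(params, config, S, lens[bt], tgt, wantCache = TRUE)
      grads <- .gmBackward(params, config, S, lens[bt], tgt, fw,
                           lossScale = 1 / fw$nTok)
      nrm <- sqrt(sum(vapply(grads, function(x) sum(x * x), numeric(1))))
      sc <- if (nrm > config$gradClip) config$gradClip / nrm else 1
      for (nm in names(params)) {
        params[[nm]] <- params[[nm]] - config$lr * sc * grads[[nm]]
      }
      tot <- tot + fw$nll; totTok <- totTok + fw$nTok
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = tot / totTok))
  }
  new("GeneratorModel", params = params, config = config,
      sourceVocab = sourceVocab, targetVocab = targetVocab, trainLog = log)
}

#' Beam-search decoding of primary sequences
#'
#' Iteratively builds primary sequences one residue at a time: at each
#' step the per-token distribution is computed for every hypothesis, and
#' the `width` likeliest extended sequences (by total log probability)
#' are kept for the next step. Output sequences have exactly the length
#' of the input secondary string; the stop token is never emitted.
#'
#' @param model a trained [GeneratorModel-class].
#' @param secondary source string over the model's source vocabulary.
#' @param width beam width (default from the model's config).
#' @return data.frame with columns `sequence` and `logprob`, ranked by
#'   descending total log probability, `width` rows.
#' @export
beamDecode <- function(model, secondary, width = NULL) {
  if (nchar(secondary) == 0L) stop("empty input sequence", call. = FALSE)
  cfg <- model@config
  if (is.null(width)) width <- cfg$beamWidth
  params <- model@params
  vocab <- model@targetVocab
  Vt <- length(vocab)
  nEmit <- Vt - 1L   # stop token masked during constrained decoding
  L <- nchar(secondary)
  S <- .gmSourceBatch(secondary, model@sourceVocab, L)
  enc <- .gmEncode(params, cfg, S[, , 1L, drop = FALSE])
  dH <- cfg$dHidden; dE <- dim(enc$enc)[1L]

  stepProbs <- function(H, C, prevTok, t) {
    B <- ncol(H)
    q <- params$Wq %*% H + params$bq
    scores <- matrix(0, L, B)
    for (d in seq_len(cfg$dAtt)) {
      scores <- scores + matrix(enc$K[d, , 1L], L, B) *
        rep(q[d, ], each = L)
    }
    scores <- scores + .alignPrior(L, t, cfg$priorSigma)
    alpha <- softmaxCols(scores)
    ctx <- matrix(0, dE, B)
    for (d in seq_len(dE)) {
      ctx[d, ] <- colSums(matrix(enc$enc[d, , 1L], L, B) * alpha)
    }
    embPrev <- matrix(0, cfg$dEmb, B)
    for (i in seq_len(B)) {
      embPrev[, i] <- if (is.na(prevTok[i])) params$embStart
                      else params$Wemb[, prevTok[i]]
    }
    x <- rbind(embPrev, ctx, H)
    z <- params$Wl %*% x + params$bl
    ig <- sigmoid(z[seq_len(dH), , drop = FALSE])
    fg <- sigmoid(z[dH + seq_len(dH), , drop = FALSE])
    og <- sigmoid(z[2L * dH + seq_len(dH), , drop = FALSE])
    gg <- tanh(z[3L * dH + seq_len(dH), , drop = FALSE])
    Cn <- fg * C + ig * gg
    Hn <- og * tanh(Cn)
    P <- softmaxCols(params$Wo %*% Hn + params$bo)
    list(P = P, H = Hn, C = Cn)
  }

  beams <- list(list(toks = integer(0), logprob = 0,
                     H = matrix(0, dH, 1L), C = matrix(0, dH, 1L)))
  for (t in seq_len(L)) {
    H <- do.call(cbind, lapply(beams, `[[`, "H"))
    C <- do.call(cbind, lapply(beams, `[[`, "C"))
    prevTok <- vapply(beams, function(b)
      if (length(b$toks) == 0L) NA_integer_ else b$toks[length(b$toks)],
      integer(1))
    sp <- stepProbs(H, C, prevTok, t)
    cand <- do.call(rbind, lapply(seq_along(beams), function(i) {
      lp <- log(pmax(sp$P[seq_len(nEmit), i], 1e-300))
      data.frame(parent = i, tok = seq_len(nEmit),
                 logprob = beams[[i]]$logprob + lp)
    }))
    # rank by log probability; deterministic tie-break by token index
    cand <- cand[order(-cand$logprob, cand$parent, cand$tok), ]
    keep <- utils::head(cand, width)
    beams <- lapply(seq_len(nrow(keep)), function(r) {
      i <- keep$parent[r]
      list(toks = c(beams[[i]]$toks, keep$tok[r]),
           logprob = keep$logprob[r],
           H = sp$H[, i, drop = FALSE], C = sp$C[, i, drop = FALSE])
    })
  }
  data.frame(
    sequence = vapply(beams, function(b)
      paste(vocab[b$toks], collapse = ""), character(1)),
    logprob = vapply(beams, `[[`, numeric(1), "logprob"),
    stringsAsFactors = FALSE)
}

#' Perplexity of primary-sequence predictions
#'
#' Perplexity is the antilog of the average per-residue cross-entropy of
#' the model's predictions: 1 for a perfect predictor, the vocabulary
#' size (19 for the cysteine-free generator vocabulary) for chance.
#' `perplexity` evaluates a trained model teacher-forced on reference
#' pairs (the stop position is excluded: the metric is per residue);
#' `perplexityFromProbs` evaluates an explicit per-position probability
#' matrix, which is convenient for calibration checks.
#'
#' @param model a [GeneratorModel-class].
#' @param pairs data.frame with `secondary` and `primary` columns.
#' @param probFloor floor for zero-probability reference tokens (capped
#'   and reported via a message).
#' @return A single numeric perplexity, >= 1.
#' @export
perplexity <- function(model, pairs, probFloor = 1e-12) {
  stopifnot(nrow(pairs) > 0L)
  cfg <- model@config
  lens <- nchar(pairs$secondary)
  nll <- 0; nTok <- 0L
  ord <- order(lens)
  for (bt in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
    Lmax <- max(lens[bt])
    S <- .gmSourceBatch(pairs$secondary[bt], model@sourceVocab, Lmax)
    tgt <- .gmTargets(pairs$primary[bt], model@targetVocab, Lmax + 1L)
    fw <- .gmForward(model@params, cfg, S, lens[bt], tgt)
    # drop the stop rows: per-residue metric
    for (i in seq_along(bt)) {
      lp <- fw$logp[seq_len(lens[bt[i]]), i]
      nll <- nll - sum(lp)
      nTok <- nTok + lens[bt[i]]
    }
  }
  exp(nll / nTok)
}

#' @rdname perplexity
#' @param probs an L x V matrix of per-position probabilities over the
#'   vocabulary (rows sum to 1).
#' @param reference the reference sequence (length L).
#' @param vocab the vocabulary the columns refer to.
#' @return `perplexityFromProbs`: a single numeric perplexity.
#' @examples
#' v <- setdiff(aminoAcids(), "C")
#' p <- matrix(1 / 19, nchar("MKVLAT"), 19)
#' perplexityFromProbs(p, "MKVLAT", v)   # exactly 19
#' @export
perplexityFromProbs <- function(probs, reference, vocab,
                                probFloor = 1e-12) {
  ch <- .splitSeq(reference)
  stopifnot(nrow(probs) == length(ch), ncol(probs) == length(vocab))
  idx <- match(ch, vocab)
  if (anyNA(idx)) stop("reference contains out-of-vocabulary symbols",
                       call. = FALSE)
  p <- probs[cbind(seq_along(idx), idx)]
  if (any(p < probFloor)) {
    message("zero-probability reference tokens floored at ", probFloor)
    p <- pmax(p, probFloor)
  }
  exp(mean(-log(p)))
}

#' Character error rate between two sequences
#'
#' Levenshtein edit distance between the predicted and reference strings
#' divided by the reference length.
#'
#' @param predicted,reference character scalars (reference nonempty).
#' @return Numeric error rate (0 = identical).
#' @examples
#' cer("LLHH", "LLHE")   # 0.25
#' @export
cer <- function(predicted, reference) {
  if (nchar(reference) == 0L) stop("empty reference", call. = FALSE)
  as.numeric(utils::adist(predicted, reference)) / nchar(reference)
}

#' Greedy secondary-structure prediction with the reverse model
#'
#' @param model a reverse [GeneratorModel-class] (primary source,
#'   secondary target).
#' @param primary primary sequence(s).
#' @return Character vector of predicted secondary strings.
#' @export
predictSecondary <- function(model, primary) {
  vapply(primary, function(p) beamDecode(model, p, width = 1L)$sequence,
         character(1), USE.NAMES = FALSE)
}

#' Rank generated designs by secondary-structure agreement
#'
#' Scores each generated design by the character error rate between the
#' requested secondary structure and the reverse model's prediction from
#' the generated primary sequence, and returns the `n` best (lowest CER;
#' ties broken by id).
#'
#' @param generated data.frame with columns `id`, `secondary` (requested)
#'   and `primary`.
#' @param reverseModel a reverse [GeneratorModel-class].
#' @param n how many designs to keep.
#' @return The top-`n` rows with a `cer` column appended, sorted.
#' @export
selectBySecondaryAgreement <- function(generated, reverseModel, n) {
  if (n > nrow(generated)) {
    warning("n exceeds the set size; returning all designs")
    n <- nrow(generated)
  }
  pred <- predictSecondary(reverseModel, generated$primary)
  generated$cer <- mapply(cer, pred, generated$secondary)
  ord <- order(generated$cer, generated$id)
  utils::head(generated[ord, , drop = FALSE], n)
}

#' Stability-weighted training subset
#'
#' Resamples a design corpus (with replacement) so that each design's
#' expected multiplicity is proportional to its stability score, clamped
#' below at `floor` (negative and near-zero scores still get a small
#' weight). The resampled set's mean stability is at least the input's.
#'
#' @param designs a [ProteinDesignSet-class].
#' @param scores numeric vector of combined stability scores aligned
#'   with `designs` (or a data.frame with `id` and `score` columns).
#' @param size output multiset size (default: the input size).
#' @param floor lower clamp on weights.
#' @param seed integer seed.
#' @return list with `index` (sampled positions), `designs` (resampled
#'   set with uniquified ids), `nUnique`, `meanScoreIn`, `meanScoreOut`.
#' @export
stabilityWeightedSubset <- function(designs, scores, size = NULL,
                                    floor = 0.05, seed = 1L) {
  if (is.data.frame(scores)) {
    scores <- scores$score[match(designId(designs), scores$id)]
  }
  stopifnot(length(scores) == length(designs))
  w <- pmax(scores, floor)
  if (all(scores <= floor)) {
    stop("all scores at or below the floor: weighting is degenerate",
         call. = FALSE)
  }
  if (is.null(size)) size <- length(designs)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(length(designs), size, replace = TRUE, prob = w)
  out <- new("ProteinDesignSet",
             id = sprintf("%s#%d", designs@id[idx], seq_along(idx)),
             primary = designs@primary[idx],
             secondary = designs@secondary[idx],
             designClass = designs@designClass[idx],
             provenance = designs@provenance[idx])
  list(index = idx, designs = out, nUnique = length(unique(idx)),
       meanScoreIn = mean(scores), meanScoreOut = mean(scores[idx]))
}
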