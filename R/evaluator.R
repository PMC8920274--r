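#' Evaluator model configuration
#'
#' Architecture and training settings for the multi-task convolutional
#' evaluator. The defaults reproduce the reference architecture: three
#' valid-convolution layers (400 kernels of 23 x 5, giving a 171 x 400
#' first layer; 200 of 1 x 9; 100 of 1 x 17), ReLU activations with 20\%
#' dropout on all conv layers, a stability path of dense 80 and 40 ReLU
#' units into a 2-unit linear output (chymotrypsin, trypsin) with an
#' appended third unit equal to their minimum, and a secondary-structure
#' path: a dense 6 x 175 softmax layer over the full input window.
#' `emConfigSmall()` is a reduced configuration of the same shape for
#' desk-scale training runs.
#'
#' @param convKernels kernel counts for the three conv layers.
#' @param convWidths kernel widths for the three conv layers.
#' @param dense sizes of the two hidden dense layers.
#' @param dropout dropout probability on conv layers during training.
#' @param batchSize designed proteins per minibatch (each minibatch also
#'   carries the same number of naturals and scrambled naturals).
#' @param patience early-stopping patience in epochs.
#' @param maxEpochs hard cap on training epochs.
#' @param optimizer `"adadelta"` (default) or `"adam"`.
#' @param lr optimizer learning rate (1 for adadelta).
#' @param lrDecayEvery decay the learning rate every this many epochs
#'   (default `Inf`: constant).
#' @param lrDecayFactor multiplicative decay factor.
#' @param restoreBest return the weights of the best validation epoch
#'   (the reference protocol). With `FALSE`, training runs the full
#'   `maxEpochs` budget and the final weights are returned — the more
#'   reliable choice at desk scale, where the stability head keeps
#'   generalising after the composite validation loss has bottomed out.
#' @param monitor which validation quantity drives early stopping:
#'   `"total"` (the composite loss, the reference behaviour) or
#'   `"stability"` (the stability component only — useful at desk scale,
#'   where the two heads converge at different epochs and the composite
#'   optimum can miss the stability optimum).
#' @param naturalStream include the natural/scramble comparator stream.
#' @param lcAsPrinted comparator exponent sign switch (see
#'   [lossComparator()]).
#' @param permissiveStart grammar-kernel start rule (see
#'   [grammarKernels()]).
#' @param valFraction validation fraction when the corpus is smaller than
#'   50,000 designs (otherwise 10,000 samples are held out).
#' @param globalSeed seed for the deterministic per-sequence placement.
#' @return A named list of settings.
#' @export
emConfig <- function(convKernels = c(400L, 200L, 100L),
                     convWidths = c(5L, 9L, 17L),
                     dense = c(80L, 40L),
                     dropout = 0.2,
                     batchSize = 64L,
                     patience = 5L,
                     maxEpochs = 100L,
                     optimizer = c("adadelta", "adam"),
                     lr = 1.0,
                     lrDecayEvery = Inf,
                     lrDecayFactor = 0.3,
                     restoreBest = TRUE,
                     monitor = c("total", "stability"),
                     naturalStream = TRUE,
                     lcAsPrinted = FALSE,
                     permissiveStart = FALSE,
                     valFraction = 0.1,
                     globalSeed = 0L) {
  optimizer <- match.arg(optimizer)
  monitor <- match.arg(monitor)
  stopifnot(length(convKernels) == 3L, all(convKernels > 0L),
            all(convWidths > 0L), all(dense > 0L))
  as.list(environment())
}

#' @rdname emConfig
#' @param ... overrides passed to [emConfig()].
#' @export
emConfigSmall <- function(...) {
  args <- utils::modifyList(
    list(convKernels = c(16L, 12L, 8L), convWidths = c(5L, 9L, 17L),
         dense = c(48L, 24L), maxEpochs = 30L,
         optimizer = "adam", lr = 1e-3),
    list(...))
  do.call(emConfig, args)
}

#' EvaluatorModel: multi-task stability and secondary-structure predictor
#'
#' Holds the weights, configuration and training log of the evaluator.
#' Outputs for a sequence are the two per-protease stability scores, the
#' architectural minimum of the two, and a column-stochastic 6 x 175
#' secondary-structure prediction.
#'
#' @slot params named list of weight matrices/vectors.
#' @slot config an [emConfig()] list.
#' @slot trainLog data.frame of per-epoch losses.
#' @export
setClass("EvaluatorModel",
  representation(params = "list", config = "list", trainLog = "data.frame"))

setValidity("EvaluatorModel", function(object) {
  need <- c("W1", "b1", "W2", "b2", "W3", "b3", "Wd1", "bd1",
            "Wd2", "bd2", "Wd3", "bd3", "Ws", "bs")
  if (!all(need %in% names(object@params))) {
    return(paste("missing parameter(s):",
                 paste(setdiff(need, names(object@params)), collapse = ", ")))
  }
  cfg <- object@config
  if (nrow(object@params$W1) != cfg$convKernels[1L] ||
      ncol(object@params$W1) != 23L * cfg$convWidths[1L])
    return("first conv layer dimensions disagree with config")
  if (nrow(object@params$Ws) != 6L * 175L)
    return("secondary head must emit 6 x 175 units")
  TRUE
})

setMethod("show", "EvaluatorModel", function(object) {
  cfg <- object@config
  nPar <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf(
    "EvaluatorModel: conv %s (widths %s), dense %s+2(+min), %.3g params\n",
    paste(cfg$convKernels, collapse = "/"),
    paste(cfg$convWidths, collapse = "/"),
    paste(cfg$dense, collapse = "/"), nPar))
  if (nrow(object@trainLog) > 0L)
    cat(sprintf("  trained %d epochs, best val loss %.4f at epoch %d\n",
                max(object@trainLog$epoch), min(object@trainLog$val),
                object@trainLog$epoch[which.min(object@trainLog$val)]))
})

.emOutLens <- function(cfg) {
  L1 <- 175L - cfg$convWidths[1L] + 1L
  L2 <- L1 - cfg$convWidths[2L] + 1L
  L3 <- L2 - cfg$convWidths[3L] + 1L
  c(L1, L2, L3)
}

#' Build an untrained evaluator
#'
#' Initialises all weights (Glorot-uniform, deterministic given `seed`)
#' for the architecture described by `config`. With the default
#' configuration the first convolutional layer output has shape
#' 171 x 400.
#'
#' @param config an [emConfig()] list.
#' @param seed integer seed for weight initialisation.
#' @return An [EvaluatorModel-class].
#' @export
buildEM <- function(config = emConfig(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nk <- config$convKernels; w <- config$convWidths
  Ls <- .emOutLens(config)
  flat <- nk[3L] * Ls[3L]
  d <- config$dense
  params <- list(
    W1 = glorot(nk[1L], 23L * w[1L]), b1 = numeric(nk[1L]),
    W2 = glorot(nk[2L], nk[1L] * w[2L]), b2 = numeric(nk[2L]),
    W3 = glorot(nk[3L], nk[2L] * w[3L]), b3 = numeric(nk[3L]),
    Wd1 = glorot(d[1L], flat), bd1 = numeric(d[1L]),
    Wd2 = glorot(d[2L], d[1L]), bd2 = numeric(d[2L]),
    Wd3 = glorot(2L, d[2L]), bd3 = numeric(2L),
    Ws = glorot(6L * 175L, flat), bs = numeric(6L * 175L))
  new("EvaluatorModel", params = params, config = config,
      trainLog = data.frame())
}

# Forward pass. X: 23 x 175 x B. Returns stability predictions (3 x B,
# rows c/t/m), secondary softmax (6 x 175 x B when wanted) and caches.
.emForward <- function(params, cfg, X, masks = NULL, wantSecondary = TRUE,
                       wantCache = FALSE) {
  w <- cfg$convWidths
  A1 <- convForward(X, params$W1, params$b1, w[1L])
  C1 <- relu(A1); if (!is.null(masks)) C1 <- C1 * masks[[1L]]
  A2 <- convForward(C1, params$W2, params$b2, w[2L])
  C2 <- relu(A2); if (!is.null(masks)) C2 <- C2 * masks[[2L]]
  A3 <- convForward(C2, params$W3, params$b3, w[3L])
  C3 <- relu(A3); if (!is.null(masks)) C3 <- C3 * masks[[3L]]
  B <- dim(X)[3L]
  Fmat <- matrix(C3, ncol = B)
  H1 <- relu(denseForward(Fmat, params$Wd1, params$bd1))
  H2 <- relu(denseForward(H1, params$Wd2, params$bd2))
  S2 <- denseForward(H2, params$Wd3, params$bd3)      # 2 x B: (c, t)
  S <- rbind(S2, pmin(S2[1L, ], S2[2L, ]))            # append min unit
  rownames(S) <- c("c", "t", "m")
  out <- list(S = S)
  if (wantSecondary) {
    logits <- denseForward(Fmat, params$Ws, params$bs) # 1050 x B
    # per-column softmax over the 6 rows, all samples at once
    Zhat <- array(softmaxCols(matrix(logits, nrow = 6L)), c(6L, 175L, B))
    out$Zhat <- Zhat
    if (wantCache) out$logits <- logits
  }
  if (wantCache) out$cache <- list(X = X, C1 = C1, C2 = C2, C3 = C3,
                                   Fmat = Fmat, H1 = H1, H2 = H2)
  out
}

# Backward pass: dS2 is the gradient on the two linear stability units
# (min-unit gradients must already be routed by the caller);
# dLogits the gradient on the secondary logits (1050 x B or NULL).
.emBackward <- function(params, cfg, fw, dS2, dLogits) {
  cc <- fw$cache
  w <- cfg$convWidths
  g <- list()
  d3 <- denseBackward(cc$H2, params$Wd3, dS2)
  g$Wd3 <- d3$dW; g$bd3 <- d3$db
  dH2 <- reluGrad(cc$H2, d3$dX)
  d2 <- denseBackward(cc$H1, params$Wd2, dH2)
  g$Wd2 <- d2$dW; g$bd2 <- d2$db
  dH1 <- reluGrad(cc$H1, d2$dX)
  d1 <- denseBackward(cc$Fmat, params$Wd1, dH1)
  g$Wd1 <- d1$dW; g$bd1 <- d1$db
  dF <- d1$dX
  if (!is.null(dLogits)) {
    ds <- denseBackward(cc$Fmat, params$Ws, dLogits)
    g$Ws <- ds$dW; g$bs <- ds$db
    dF <- dF + ds$dX
  } else {
    g$Ws <- array(0, dim(params$Ws)); g$bs <- numeric(length(params$bs))
  }
  dC3 <- reluGrad(cc$C3, array(dF, dim(cc$C3)))
  cb3 <- convBackward(cc$C2, params$W3, dC3, w[3L])
  g$W3 <- cb3$dW; g$b3 <- cb3$db
  dC2 <- reluGrad(cc$C2, cb3$dX)
  cb2 <- convBackward(cc$C1, params$W2, dC2, w[2L])
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dC1 <- reluGrad(cc$C1, cb2$dX)
  cb1 <- convBackward(cc$X, params$W1, dC1, w[1L])
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  g
}

#' Predict stability scores and secondary structure
#'
#' Runs the evaluator on sequences at their deterministic placements.
#' Returns per-protease stability scores, the architectural minimum, and
#' (optionally) the decoded secondary-structure prediction for the
#' residue window.
#'
#' @param model an [EvaluatorModel-class].
#' @param x a [ProteinDesignSet-class] or character vector of sequences.
#' @param secondary return decoded secondary predictions (slower; the
#'   secondary head is the largest matrix in the model).
#' @param chunkSize sequences per forward chunk.
#' @return data.frame with columns `id`, `score_chymotrypsin`,
#'   `score_trypsin`, `score_min` and, if requested, `secondary_pred`.
#' @export
predictEM <- function(model, x, secondary = FALSE, chunkSize = 256L) {
  seqs <- if (is(x, "ProteinDesignSet")) unname(primarySeq(x)) else
    as.character(x)
  ids <- if (is(x, "ProteinDesignSet")) designId(x) else
    as.character(seq_along(seqs))
  cfg <- model@config
  n <- length(seqs)
  offs <- vapply(seqs, deterministicOffset, integer(1),
                 globalSeed = cfg$globalSeed)
  scoreC <- numeric(n); scoreT <- numeric(n)
  secPred <- if (secondary) character(n) else NULL
  for (st in seq(1L, n, by = chunkSize)) {
    en <- min(n, st + chunkSize - 1L)
    idx <- st:en
    X <- .encodeBatch(seqs[idx], offs[idx])
    fw <- .emForward(model@params, cfg, X, wantSecondary = secondary)
    scoreC[idx] <- fw$S["c", ]
    scoreT[idx] <- fw$S["t", ]
    if (secondary) {
      for (j in seq_along(idx)) {
        len <- nchar(seqs[idx[j]])
        cols <- (offs[idx[j]] + 1L):(offs[idx[j]] + len)
        sub <- fw$Zhat[1:3, cols, j, drop = TRUE]
        secPred[idx[j]] <- paste(c("L", "E", "H")[
          max.col(t(matrix(sub, nrow = 3L)), ties.method = "first")],
          collapse = "")
      }
    }
  }
  out <- data.frame(id = ids, score_chymotrypsin = scoreC,
                    score_trypsin = scoreT,
                    score_min = pmin(scoreC, scoreT),
                    stringsAsFactors = FALSE)
  if (secondary) out$secondary_pred <- secPred
  out
}

#' Evaluator scorer for refinement
#'
#' Returns a vectorised function mapping sequences to the evaluator's
#' combined (minimum) stability score, suitable as the `scorer` argument
#' of [beamRefine()].
#'
#' @param model an [EvaluatorModel-class].
#' @return function(character vector) -> numeric vector.
#' @export
emScorer <- function(model) {
  force(model)
  function(seqs) predictEM(model, seqs)$score_min
}

# Gradient of the total loss with respect to the stability outputs and
# secondary logits of a designed-protein batch; see lossStability /
# lossSecondary for the corresponding values.
.designGrad <- function(S, Zhat, logits, Xtgt, Ztgt, kernels, probFloor) {
  B <- ncol(S)
  Xhat <- t(S)                        # B x 3 (c, t, m)
  mse <- 2 * (Xhat - Xtgt) / (3 * B)
  dXhat <- mse
  Dm <- mean((Xtgt[, 3L] - mean(Xtgt[, 3L]))^2)
  if (Dm > .Machine$double.eps) {
    dXhat[, 3L] <- dXhat[, 3L] + 10 * (Xhat[, 3L] - Xtgt[, 3L]) / (B * Dm)
  }
  ct <- c(Xtgt[, 1L], Xtgt[, 2L])
  Dct <- mean((ct - mean(ct))^2)
  if (Dct > .Machine$double.eps) {
    dXhat[, 1L] <- dXhat[, 1L] + (Xhat[, 1L] - Xtgt[, 1L]) / (B * Dct)
    dXhat[, 2L] <- dXhat[, 2L] + (Xhat[, 2L] - Xtgt[, 2L]) / (B * Dct)
  }
  # route the min unit's gradient into whichever output attains it
  dS2 <- matrix(0, 2L, B)
  minIsC <- S["c", ] <= S["t", ]
  dS2[1L, ] <- dXhat[, 1L] + ifelse(minIsC, dXhat[, 3L], 0)
  dS2[2L, ] <- dXhat[, 2L] + ifelse(!minIsC, dXhat[, 3L], 0)

  # secondary head: cross-entropy + differentiable grammar terms.
  # The argmax-binarized terms carry no gradient.
  dLogits <- matrix(Zhat - Ztgt, 6L * 175L, B) / B
  for (i in seq_len(B)) {
    Zh <- Zhat[, , i]
    dZsoft <- .violationGrad(Zh, kernels)
    if (is.null(dZsoft)) next
    # softmax backward per column for the grammar part
    dLog <- Zh * (dZsoft - rep(colSums(Zh * dZsoft), each = 6L))
    dLogits[, i] <- dLogits[, i] + as.vector(dLog) / B
  }
  list(dS2 = dS2, dLogits = dLogits)
}

# Gradient of 0.1*mean + 0.05*max of clipped grammar convolutions with
# respect to the softmax output Zh (6 x 175).
.violationGrad <- function(Zh, kernels) {
  L <- ncol(Zh)
  K1 <- vapply(kernels, function(k) k[, 1L], numeric(6L))  # 6 x 6
  K2 <- vapply(kernels, function(k) k[, 2L], numeric(6L))
  convs <- crossprod(K1, Zh[, -L, drop = FALSE]) +
    crossprod(K2, Zh[, -1L, drop = FALSE])                 # 6k x (L-1)
  clipped <- pmin(pmax(convs, 0), 1)
  kStar <- max.col(t(clipped), ties.method = "first")
  vals <- clipped[cbind(kStar, seq_len(L - 1L))]
  act <- convs[cbind(kStar, seq_len(L - 1L))]
  inside <- act > 0 & act < 1
  if (!any(inside)) return(NULL)
  jMax <- which.max(vals)
  wts <- 0.1 / (L - 1L) + 0.05 * (seq_len(L - 1L) == jMax)
  dZ <- matrix(0, 6L, L)
  for (j in which(inside)) {
    dZ[, j] <- dZ[, j] + wts[j] * K1[, kStar[j]]
    dZ[, j + 1L] <- dZ[, j + 1L] + wts[j] * K2[, kStar[j]]
  }
  dZ
}

#' Train the evaluator
#'
#' Optimises the total loss `0.2 Ls + 0.1 Lc + 2 Ld` with Adadelta (or
#' Adam) over minibatches of triplets: designed proteins with stability
#' and secondary targets, natural sequences, and scrambles of those
#' naturals. Training stops when validation loss has not improved for
#' `patience` epochs and the best-epoch weights are restored.
#' Deterministic given `seed`.
#'
#' @param designs [ProteinDesignSet-class] with secondary strings.
#' @param scores data.frame with `id`, `score_trypsin`,
#'   `score_chymotrypsin` (e.g. from [stabilityScore()]).
#' @param naturals,naturalScrambles optional [ProteinDesignSet-class]s
#'   for the comparator stream (required when
#'   `config$naturalStream = TRUE`).
#' @param config an [emConfig()] list.
#' @param seed integer seed.
#' @return A trained [EvaluatorModel-class].
#' @export
trainEM <- function(designs, scores, naturals = NULL,
                    naturalScrambles = NULL, config = emConfigSmall(),
                    seed = 1L) {
  n <- length(designs)
  if (n < config$batchSize) stop("corpus smaller than one minibatch",
                                 call. = FALSE)
  useNat <- isTRUE(config$naturalStream) && !is.null(naturals)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  model <- buildEM(config, seed = seed)
  params <- model@params
  kernels <- grammarKernels(config$permissiveStart)
  cfg <- config

  seqs <- unname(primarySeq(designs))
  secs <- unname(secondarySeq(designs))
  if (anyNA(secs)) stop("all designs need secondary strings", call. = FALSE)
  m <- match(designId(designs), scores$id)
  if (anyNA(m)) stop("scores missing for some designs", call. = FALSE)
  xc <- scores$score_chymotrypsin[m]
  xt <- scores$score_trypsin[m]
  Xtgt <- cbind(c = xc, t = xt, m = pmin(xc, xt))
  offs <- vapply(seqs, deterministicOffset, integer(1),
                 globalSeed = cfg$globalSeed)
  Xall <- .encodeBatch(seqs, offs)
  Zall <- array(0, c(6L, 175L, n))
  for (i in seq_len(n)) Zall[, , i] <- encodeSecondary(secs[i], offs[i])

  if (useNat) {
    natSeqs <- unname(primarySeq(naturals))
    scrSeqs <- unname(primarySeq(naturalScrambles))
    stopifnot(length(natSeqs) == length(scrSeqs))
    natOffs <- vapply(natSeqs, deterministicOffset, integer(1),
                      globalSeed = cfg$globalSeed)
    scrOffs <- vapply(scrSeqs, deterministicOffset, integer(1),
                      globalSeed = cfg$globalSeed)
    Xnat <- .encodeBatch(natSeqs, natOffs)
    Xscr <- .encodeBatch(scrSeqs, scrOffs)
    nNat <- length(natSeqs)
  }

  nVal <- if (n >= 50000L) 10000L else max(2L, round(cfg$valFraction * n))
  idxVal <- sample.int(n, nVal)
  idxTr <- setdiff(seq_len(n), idxVal)

  valLoss <- function(prm) {
    totLs <- 0; totLd <- 0
    for (st in seq(1L, length(idxVal), by = 256L)) {
      sub <- idxVal[st:min(length(idxVal), st + 255L)]
      fw <- .emForward(prm, cfg, Xall[, , sub, drop = FALSE],
                       wantSecondary = TRUE)
      totLs <- totLs + lossStability(Xtgt[sub, , drop = FALSE],
                                     t(fw$S)) * length(sub)
      totLd <- totLd + .lossSecondaryBatch(Zall[, , sub, drop = FALSE],
                                           fw$Zhat, kernels) * length(sub)
    }
    c(ls = totLs / length(idxVal), ld = totLd / length(idxVal))
  }

  opt <- optimInit(params, cfg$optimizer, lr = cfg$lr)
  best <- list(val = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  for (epoch in seq_len(cfg$maxEpochs)) {
    opt$lr <- cfg$lr * cfg$lrDecayFactor^((epoch - 1) %/% cfg$lrDecayEvery)
    ord <- sample(idxTr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    batches <- batches[lengths(batches) >= 2L]  # Ls needs spread
    epochLoss <- 0
    for (bt in batches) {
      B <- length(bt)
      Xd <- Xall[, , bt, drop = FALSE]
      if (useNat) {
        nb <- (sample.int(nNat, B, replace = nNat < B))
        Xb <- array(c(Xd, Xnat[, , nb, drop = FALSE],
                      Xscr[, , nb, drop = FALSE]), c(23L, 175L, 3L * B))
      } else Xb <- Xd
      Btot <- dim(Xb)[3L]
      Lens <- .emOutLens(cfg)
      masks <- if (cfg$dropout > 0) list(
        dropoutMask(c(cfg$convKernels[1L], Lens[1L], Btot), cfg$dropout),
        dropoutMask(c(cfg$convKernels[2L], Lens[2L], Btot), cfg$dropout),
        dropoutMask(c(cfg$convKernels[3L], Lens[3L], Btot), cfg$dropout))
      fw <- .emForward(params, cfg, Xb, masks = masks,
                       wantSecondary = TRUE, wantCache = TRUE)
      di <- seq_len(B)
      dg <- .designGrad(fw$S[, di, drop = FALSE],
                        fw$Zhat[, , di, drop = FALSE], NULL,
                        Xtgt[bt, , drop = FALSE], Zall[, , bt, drop = FALSE],
                        kernels, 1e-12)
      dS2 <- matrix(0, 2L, Btot)
      dLogits <- matrix(0, 6L * 175L, Btot)
      dS2[, di] <- 0.2 * dg$dS2
      dLogits[, di] <- 2 * dg$dLogits
      if (useNat) {
        ni <- B + seq_len(B); si <- 2L * B + seq_len(B)
        cg <- .comparatorGrad(fw$S[, ni, drop = FALSE],
                              fw$S[, si, drop = FALSE], cfg$lcAsPrinted)
        dS2[, ni] <- dS2[, ni] + 0.1 * cg$dNat
        dS2[, si] <- dS2[, si] + 0.1 * cg$dScr
      }
      grads <- .emBackward(params, cfg, fw, dS2, dLogits)
      st <- optimStep(params, grads, opt)
      params <- st$params; opt <- st$state

      ls <- lossStability(Xtgt[bt, , drop = FALSE], t(fw$S[, di]))
      lc <- if (useNat)
        lossComparator(t(fw$S[, ni]), t(fw$S[, si]), cfg$lcAsPrinted) else 0
      ld <- .lossSecondaryBatch(Zall[, , bt, drop = FALSE],
                                fw$Zhat[, , di, drop = FALSE], kernels)
      epochLoss <- epochLoss + lossTotal(ls, lc, ld)
    }
    vparts <- valLoss(params)
    vl <- 0.2 * vparts[["ls"]] + 2 * vparts[["ld"]]
    log <- rbind(log, data.frame(epoch = epoch,
                                 train = epochLoss / length(batches),
                                 val = vl,
                                 val_stability = vparts[["ls"]],
                                 val_secondary = vparts[["ld"]]))
    vMon <- if (identical(cfg$monitor, "stability")) vparts[["ls"]] else vl
    if (vMon < best$val - 1e-8) {
      best <- list(val = vMon, params = params, epoch = epoch)
    } else if (isTRUE(cfg$restoreBest) &&
               epoch - best$epoch >= cfg$patience) break
  }
  finalParams <- if (isTRUE(cfg$restoreBest)) best$params else params
  new("EvaluatorModel", params = finalParams, config = cfg, trainLog = log)
}

# Gradient of the comparator loss wrt the two stability outputs of the
# natural (dNat) and scrambled (dScr) streams.
.comparatorGrad <- function(Snat, Sscr, asPrinted = FALSE) {
  B <- ncol(Snat)
  d <- Sscr["m", ] - Snat["m", ]
  if (asPrinted) d <- -d
  sg <- sigmoid(d)
  dd <- 2.5 * sg * (1 - sg) / B
  if (asPrinted) dd <- -dd
  dNat <- matrix(0, 2L, B); dScr <- matrix(0, 2L, B)
  natMinC <- Snat["c", ] <= Snat["t", ]
  scrMinC <- Sscr["c", ] <= Sscr["t", ]
  dNat[1L, ] <- ifelse(natMinC, -dd, 0)
  dNat[2L, ] <- ifelse(!natMinC, -dd, 0)
  dScr[1L, ] <- ifelse(scrMinC, dd, 0)
  dScr[2L, ] <- ifelse(!scrMinC, dd, 0)
  diff <- Snat["c", ] - Snat["t", ]
  dNat[1L, ] <- dNat[1L, ] + 0.002 * diff / B
  dNat[2L, ] <- dNat[2L, ] - 0.002 * diff / B
  list(dNat = dNat, dScr = dScr)
}

#' Goodness-of-fit metrics for predictions
#'
#' Returns the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (which can be negative when the
#' model does worse than predicting the mean), the squared Pearson
#' correlation \eqn{r^2}, and Spearman's \eqn{\rho}.
#'
#' @param predictions,observations paired numeric vectors (n >= 2).
#' @return list with `R2`, `r2`, `spearman`.
#' @export
evaluateFit <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(predictions) >= 2L)
  sstot <- sum((observations - mean(observations))^2)
  if (sstot < .Machine$double.eps) {
    warning("zero variance in observations: metrics undefined")
    return(list(R2 = NA_real_, r2 = NA_real_, spearman = NA_real_))
  }
  R2 <- 1 - sum((observations - predictions)^2) / sstot
  if (stats::var(predictions) < .Machine$double.eps) {
    # constant predictions: R2 is defined, the correlations are not
    return(list(R2 = R2, r2 = NA_real_, spearman = NA_real_))
  }
  r2 <- stats::cor(predictions, observations)^2
  rho <- stats::cor(predictions, observations, method = "spearman")
  list(R2 = R2, r2 = r2, spearman = rho)
}

#' Held-out-class generalisation
#'
#' For each design class, trains fresh evaluators on all other classes
#' (`nRepeats` times with different seeds) and reports the mean
#' \eqn{R^2} of combined-score predictions on the held-out class --
#' a guard against the model memorising class-specific signatures
#' instead of stability.
#'
#' @param designs [ProteinDesignSet-class] with class labels.
#' @param scores score table as in [trainEM()].
#' @param config an [emConfig()] list.
#' @param nRepeats models trained per class.
#' @param seed integer base seed.
#' @return data.frame with one row per class: `class`, `n`, `meanR2`.
#' @export
classHoldoutEval <- function(designs, scores, config = emConfigSmall(),
                             nRepeats = 3L, seed = 1L) {
  cls <- unname(designClass(designs))
  classes <- unique(cls)
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  rows <- list()
  for (cl in classes) {
    inCl <- cls == cl
    if (sum(inCl) < 2L) {
      warning("skipping singleton class ", cl)
      next
    }
    r2s <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      mdl <- trainEM(designs[!inCl], scores, config = config,
                     seed = seed + 97L * r)
      held <- designs[inCl]
      pred <- predictEM(mdl, held)$score_min
      mm <- match(designId(held), scores$id)
      obs <- pmin(scores$score_chymotrypsin[mm], scores$score_trypsin[mm])
      r2s[r] <- evaluateFit(pred, obs)$R2
    }
    rows[[cl]] <- data.frame(class = cl, n = sum(inCl), meanR2 = mean(r2s),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
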