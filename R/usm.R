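#' USMModel: per-protease unfolded-state model
#'
#' A sequence-only convolutional predictor of unfolded-state proteolytic
#' resistance (EC50, log-concentration units), trained on scrambled
#' sequences that are very unlikely to fold. One fully separate model is
#' kept per protease (trypsin, chymotrypsin). Each model holds `nKernels`
#' convolutional kernels of shape 23 x `kernelWidth`; a sequence's
#' prediction is a learned linear combination of each kernel's maximum
#' activation over the valid convolution positions of its one-hot
#' encoding, so predictions depend only on the residues, never on the
#' padding.
#'
#' @slot models named list (`trypsin`, `chymotrypsin`), each with elements
#'   `W` (`nKernels` x `23*kernelWidth` kernel matrix, column-major
#'   vectorised windows), `b` (conv bias), `wh` (head weights), `bh`
#'   (head bias).
#' @slot kernelWidth integer kernel width (default 5).
#' @slot nKernels integer kernel count per protease (default 100).
#' @slot trainLog data.frame of per-epoch losses (may be empty).
#' @export
setClass("USMModel",
  representation(models = "list", kernelWidth = "integer",
                 nKernels = "integer", trainLog = "data.frame"))

.PROTEASES <- c("trypsin", "chymotrypsin")

setValidity("USMModel", function(object) {
  if (!all(.PROTEASES %in% names(object@models)))
    return("models must contain both 'trypsin' and 'chymotrypsin'")
  for (p in .PROTEASES) {
    m <- object@models[[p]]
    if (!all(c("W", "b", "wh", "bh") %in% names(m)))
      return("each protease model needs W, b, wh, bh")
    if (nrow(m$W) != object@nKernels)
      return(sprintf("%s: expected exactly %d kernels", p, object@nKernels))
    if (ncol(m$W) != 23L * object@kernelWidth)
      return(sprintf("%s: kernel matrix must be nKernels x 23*width", p))
    if (length(m$wh) != object@nKernels)
      return(sprintf("%s: head dimension must match kernel count", p))
  }
  TRUE
})

#' Construct a USMModel from explicit weights
#'
#' Mainly useful for tests and for loading checkpoints; [trainUSM()] is
#' the usual way to obtain a model.
#'
#' @param trypsin,chymotrypsin lists with `W`, `b`, `wh`, `bh` (see
#'   [USMModel-class]); `b`/`wh`/`bh` default to zeros.
#' @param kernelWidth kernel width shared by both models.
#' @return A [USMModel-class] object.
#' @export
USMModel <- function(trypsin, chymotrypsin = trypsin, kernelWidth = 5L) {
  fill <- function(m) {
    nk <- nrow(m[["W"]])
    list(W = m[["W"]], b = m[["b"]] %||% numeric(nk),
         wh = m[["wh"]] %||% numeric(nk), bh = m[["bh"]] %||% 0)
  }
  new("USMModel", models = list(trypsin = fill(trypsin),
                                chymotrypsin = fill(chymotrypsin)),
      kernelWidth = as.integer(kernelWidth),
      nKernels = nrow(trypsin$W), trainLog = data.frame())
}

setMethod("show", "USMModel", function(object) {
  cat(sprintf("USMModel: %d kernels of width %d per protease\n",
              object@nKernels, object@kernelWidth))
  if (nrow(object@trainLog) > 0L)
    cat(sprintf("  trained for %d epochs (final val MSE %.4g / %.4g)\n",
                max(object@trainLog$epoch),
                min(object@trainLog$val_trypsin, na.rm = TRUE),
                min(object@trainLog$val_chymotrypsin, na.rm = TRUE)))
})

# Forward pass for a batch of sequences under one protease model.
# Returns list(pred, pooled max M, argmax A, conv cache) for training.
.usmForward <- function(m, w, seqs, wantCache = FALSE) {
  lens <- nchar(seqs)
  if (any(lens < w)) {
    stop("sequence shorter than kernel width", call. = FALSE)
  }
  offsets <- rep(15L, length(seqs))
  X <- .encodeBatch(seqs, offsets)
  Y <- convForward(X, m$W, m$b, w)
  # valid output positions: kernel windows fully inside the residue span
  start <- offsets
  end <- offsets + lens - w
  mp <- .maxPoolFwd(Y, as.integer(start), as.integer(end))
  pred <- drop(crossprod(mp$max, m$wh)) + m$bh
  if (!wantCache) return(pred)
  list(pred = pred, M = mp$max, A = mp$argmax, X = X, Y = Y)
}

#' Predict unfolded-state EC50 for sequences
#'
#' Runs one protease's unfolded-state model on primary sequences: the
#' linear-head combination of each kernel's maximum activation over the
#' valid convolution positions. Deterministic (fixed placement).
#'
#' @param model a [USMModel-class].
#' @param primary character vector of primary sequences.
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @return Numeric vector of predicted unfolded-state EC50 values.
#' @export
usmPredict <- function(model, primary, protease = .PROTEASES) {
  protease <- match.arg(protease)
  .usmForward(model@models[[protease]], model@kernelWidth, primary)
}

# Predictions for both proteases sharing a single batch encoding (the
# refinement constraint needs both and the encoding dominates the cost).
.usmPredictBoth <- function(model, primary) {
  w <- model@kernelWidth
  lens <- nchar(primary)
  if (any(lens < w)) stop("sequence shorter than kernel width", call. = FALSE)
  offsets <- rep(15L, length(primary))
  X <- .encodeBatch(primary, offsets)
  out <- matrix(0, length(primary), 2L,
                dimnames = list(NULL, .PROTEASES))
  for (p in .PROTEASES) {
    m <- model@models[[p]]
    Y <- convForward(X, m$W, m$b, w)
    mp <- .maxPoolFwd(Y, as.integer(offsets), as.integer(offsets + lens - w))
    out[, p] <- drop(crossprod(mp$max, m$wh)) + m$bh
  }
  out
}

#' Default unfolded-state model training configuration
#'
#' @param nKernels kernels per protease (100).
#' @param kernelWidth kernel width in residues (5).
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param valFraction fraction of scrambles held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @return A named list of settings for [trainUSM()].
#' @export
usmConfig <- function(nKernels = 100L, kernelWidth = 5L, epochs = 150L,
                      batchSize = 64L, lr = 0.003, valFraction = 0.1,
                      patience = 15L) {
  list(nKernels = as.integer(nKernels), kernelWidth = as.integer(kernelWidth),
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       lr = lr, valFraction = valFraction, patience = as.integer(patience))
}

#' Train the unfolded-state models on scrambled sequences
#'
#' Fits one model per protease by minimising mean squared EC50 error with
#' Adam, using a random held-out fraction of the scrambles for early
#' stopping (best-epoch weights are restored). Training is deterministic
#' given `seed`.
#'
#' @param scrambles data.frame with columns `sequence`, `protease`
#'   (values `trypsin`/`chymotrypsin`) and `ec50`.
#' @param config a [usmConfig()] list.
#' @param seed integer seed controlling initialisation, shuffling and the
#'   validation split.
#' @return A trained [USMModel-class] with a populated training log.
#' @export
trainUSM <- function(scrambles, config = usmConfig(), seed = 1L) {
  stopifnot(all(c("sequence", "protease", "ec50") %in% names(scrambles)))
  models <- list()
  logs <- list()
  for (p in .PROTEASES) {
    dat <- scrambles[scrambles$protease == p, , drop = FALSE]
    if (nrow(dat) == 0L) {
      stop("no training scrambles for protease ", p, call. = FALSE)
    }
    if (nrow(dat) < 100L) {
      stop("need at least 100 training scrambles per protease", call. = FALSE)
    }
    fit <- .trainUSMOne(dat$sequence, dat$ec50, config, seed)
    models[[p]] <- fit$params
    logs[[p]] <- fit$log
  }
  nEp <- max(nrow(logs$trypsin), nrow(logs$chymotrypsin))
  pad <- function(v) c(v, rep(NA_real_, nEp - length(v)))
  log <- data.frame(epoch = seq_len(nEp),
                    train_trypsin = pad(logs$trypsin$train),
                    val_trypsin = pad(logs$trypsin$val),
                    train_chymotrypsin = pad(logs$chymotrypsin$train),
                    val_chymotrypsin = pad(logs$chymotrypsin$val))
  new("USMModel", models = models, kernelWidth = config$kernelWidth,
      nKernels = config$nKernels, trainLog = log)
}

.trainUSMOne <- function(seqs, y, config, seed) {
  w <- config$kernelWidth
  nk <- config$nKernels
  n <- length(seqs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  params <- list(W = glorot(nk, 23L * w) * 0.5, b = numeric(nk),
                 wh = stats::rnorm(nk, 0, 0.05), bh = mean(y))
  opt <- optimInit(params, "adam", lr = config$lr)

  nVal <- max(1L, round(config$valFraction * n))
  idxVal <- sample.int(n, nVal)
  idxTr <- setdiff(seq_len(n), idxVal)
  Xval <- seqs[idxVal]; yval <- y[idxVal]

  lens <- nchar(seqs)
  offsets <- rep(15L, n)
  Xall <- .encodeBatch(seqs, offsets)

  evalMSE <- function(prm, idx) {
    pr <- .usmForward(prm, w, seqs[idx])
    mean((pr - y[idx])^2)
  }

  best <- list(val = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(idxTr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    trLoss <- 0
    for (bt in batches) {
      Xb <- Xall[, , bt, drop = FALSE]
      Yb <- convForward(Xb, params$W, params$b, w)
      mp <- .maxPoolFwd(Yb, as.integer(offsets[bt]),
                        as.integer(offsets[bt] + lens[bt] - w))
      pred <- drop(crossprod(mp$max, params$wh)) + params$bh
      resid <- pred - y[bt]
      trLoss <- trLoss + sum(resid^2)
      B <- length(bt)
      dpred <- 2 * resid / B
      grads <- list(
        W = NULL, b = NULL,
        wh = drop(mp$max %*% dpred),
        bh = sum(dpred))
      # route head gradient through the max positions
      dY <- array(0, dim = dim(Yb))
      dM <- outer(params$wh, dpred)           # nk x B
      ib <- rep(seq_len(B), each = nk)
      ik <- rep(seq_len(nk), times = B)
      dY[cbind(ik, as.vector(mp$argmax), ib)] <- as.vector(dM)
      cb <- convBackward(Xb, params$W, dY, w)
      grads$W <- cb$dW; grads$b <- cb$db
      st <- optimStep(params, grads, opt)
      params <- st$params; opt <- st$state
    }
    valMSE <- evalMSE(params, idxVal)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train = trLoss / length(idxTr),
                                 val = valMSE))
    if (valMSE < best$val - 1e-8) {
      best <- list(val = valMSE, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) break
  }
  list(params = best$params, log = log)
}

#' Stability scores from observed and model-predicted EC50
#'
#' The stability score of a design under one protease is its observed
#' EC50 minus the unfolded-state model's predicted EC50 for its sequence;
#' the combined score is the minimum over the two proteases (both on the
#' assay's log scale, one unit is roughly ten-fold resistance). Input
#' rows must carry both proteases' observations.
#'
#' @param assays data.frame with columns `id`, `ec50_trypsin`,
#'   `ec50_chymotrypsin` and either a `sequence` column (predictions are
#'   computed with `model`) or precomputed `usm_trypsin` /
#'   `usm_chymotrypsin` columns.
#' @param model a [USMModel-class]; may be `NULL` when predictions are
#'   supplied as columns.
#' @return The input data.frame with `usm_*`, `score_trypsin`,
#'   `score_chymotrypsin` and combined `score` columns appended.
#' @examples
#' tab <- data.frame(id = "d", ec50_trypsin = 3, ec50_chymotrypsin = 2.5,
#'                   usm_trypsin = 2, usm_chymotrypsin = 1.7)
#' stabilityScore(tab)$score   # min(1.0, 0.8) = 0.8
#' @export
stabilityScore <- function(assays, model = NULL) {
  need <- c("ec50_trypsin", "ec50_chymotrypsin")
  if (!all(need %in% names(assays))) {
    stop("assay table must contain observations for both proteases",
         call. = FALSE)
  }
  if (!is.null(model)) {
    assays$usm_trypsin <- usmPredict(model, assays$sequence, "trypsin")
    assays$usm_chymotrypsin <- usmPredict(model, assays$sequence,
                                          "chymotrypsin")
  }
  if (!all(c("usm_trypsin", "usm_chymotrypsin") %in% names(assays))) {
    stop("supply a model or precomputed usm_* columns", call. = FALSE)
  }
  assays$score_trypsin <- assays$ec50_trypsin - assays$usm_trypsin
  assays$score_chymotrypsin <- assays$ec50_chymotrypsin -
    assays$usm_chymotrypsin
  assays$score <- pmin(assays$score_trypsin, assays$score_chymotrypsin)
  assays
}

#' Median prediction gap between designs and scrambles
#'
#' A diagnostic for unfolded-state model bias: the difference between the
#' median predicted EC50 of designed sequences and that of scrambles. An
#' unbiased model (one that has learned only unfolded-state chemistry)
#' shows a small magnitude; the sign flips when the two sets are swapped.
#'
#' @param model a [USMModel-class].
#' @param designs,scrambles character vectors of sequences (or
#'   [ProteinDesignSet-class] objects).
#' @param protease which protease model to interrogate.
#' @return A single numeric: median(designs) - median(scrambles).
#' @export
compareUsmBias <- function(model, designs, scrambles,
                           protease = .PROTEASES) {
  protease <- match.arg(protease)
  if (is(designs, "ProteinDesignSet")) designs <- unname(primarySeq(designs))
  if (is(scrambles, "ProteinDesignSet")) scrambles <- unname(primarySeq(scrambles))
  if (length(designs) == 0L || length(scrambles) == 0L) {
    stop("both sequence sets must be nonempty", call. = FALSE)
  }
  stats::median(usmPredict(model, designs, protease)) -
    stats::median(usmPredict(model, scrambles, protease))
}
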