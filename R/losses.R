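#' Evaluator loss terms
#'
#' The three bespoke loss components of the evaluator, combined by
#' [lossTotal()]. All are pure functions of predictions and targets so
#' they can be inspected and tested independently of training.
#'
#' `lossStability` scores the stability head on a minibatch:
#' \deqn{L_s = \overline{(X-\hat X)^2} - 5\,R^2(x_m,\hat x_m)
#'       - R^2(x_{c,t},\hat x_{c,t})}
#' where the first term is the mean squared error over all three outputs
#' (chymotrypsin, trypsin, minimum), and the two coefficient-of-
#' determination terms (computed with minibatch means, the second pooled
#' over the two per-protease columns) reward rank-faithful fits. A perfect
#' fit on a non-constant batch yields exactly \eqn{0 - 5 - 1 = -6}. When a
#' batch has zero target variance the corresponding \eqn{R^2} term is set
#' to 0 (guard against division by zero) and a message is emitted.
#'
#' @param X,Xhat n x 3 matrices of observed and predicted stability score
#'   vectors, columns ordered (chymotrypsin, trypsin, minimum).
#' @return A single finite numeric loss value.
#' @examples
#' X <- cbind(c = c(1, 2, 0), t = c(0, 1, 2), m = c(0, 1, 0))
#' lossStability(X, X)   # -6
#' @export
lossStability <- function(X, Xhat) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  stopifnot(ncol(X) == 3L, all(dim(X) == dim(Xhat)))
  mse <- mean((X - Xhat)^2)
  mse - 5 * .r2Term(X[, 3L], Xhat[, 3L]) -
    .r2Term(c(X[, 1L], X[, 2L]), c(Xhat[, 1L], Xhat[, 2L]))
}

.r2Term <- function(obs, pred) {
  sstot <- mean((obs - mean(obs))^2)
  if (sstot < .Machine$double.eps) {
    message("zero-variance minibatch: R-squared term set to 0")
    return(0)
  }
  1 - mean((obs - pred)^2) / sstot
}

#' @describeIn lossStability comparator loss for natural/scramble pairs:
#'   \eqn{L_c = \overline{2.5\,\sigma(\tilde y_m - \hat y_m)} +
#'   0.001\,\overline{(\hat y_c - \hat y_t)^2}}. The bounded sigmoid term
#'   penalises scrambles predicted as stable as their natural parents
#'   (capped in (0, 2.5)); the second term mildly encourages the two
#'   per-protease predictions for naturals to agree. `asPrinted = TRUE`
#'   flips the sign in the exponent for fidelity experiments.
#' @param Yhat,Ytilde n x 3 prediction matrices for natural proteins and
#'   their scrambles.
#' @param asPrinted use the opposite exponent sign.
#' @export
lossComparator <- function(Yhat, Ytilde, asPrinted = FALSE) {
  Yhat <- as.matrix(Yhat); Ytilde <- as.matrix(Ytilde)
  d <- Ytilde[, 3L] - Yhat[, 3L]
  if (asPrinted) d <- -d
  mean(2.5 * sigmoid(d)) + 0.001 * mean((Yhat[, 1L] - Yhat[, 2L])^2)
}

#' @describeIn lossStability secondary-structure loss for one design:
#'   categorical cross-entropy of the softmax output against the one-hot
#'   target plus four grammar-invalidity estimates,
#'   \eqn{L_d = -\sum Z\log\hat Z + 0.8\,\overline{L^*(\hat Z_{01})} +
#'   0.4\,\max L^*(\hat Z_{01}) + 0.1\,\overline{L^*(\hat Z)} +
#'   0.05\,\max L^*(\hat Z)}, where \eqn{\hat Z_{01}} is the per-column
#'   argmax binarization and \eqn{L^*} is [grammarViolations()].
#' @param Z 6 x L binary target matrix.
#' @param Zhat 6 x L column-stochastic prediction matrix.
#' @param kernels grammar kernel bank.
#' @param probFloor floor applied inside the log for numerical safety.
#' @export
lossSecondary <- function(Z, Zhat, kernels = grammarKernels(),
                          probFloor = 1e-12) {
  if (!all(dim(Z) == dim(Zhat))) stop("shape mismatch", call. = FALSE)
  ce <- -sum(Z * log(pmax(Zhat, probFloor)))
  vBin <- grammarViolations(binarizeSecondary(Zhat), kernels)
  vSoft <- grammarViolations(Zhat, kernels)
  ce + 0.8 * mean(vBin) + 0.4 * max(vBin) +
    0.1 * mean(vSoft) + 0.05 * max(vSoft)
}

# Vectorised batch version of lossSecondary over (6, L, B) arrays;
# returns the per-sample mean. Identical in value to looping
# lossSecondary over slices (asserted in the tests).
.lossSecondaryBatch <- function(Zarr, ZhatArr, kernels = grammarKernels(),
                                probFloor = 1e-12) {
  d <- dim(Zarr)
  B <- d[3L]; L <- d[2L]
  ce <- colSums(matrix(Zarr * log(pmax(ZhatArr, probFloor)), ncol = B))
  K1 <- vapply(kernels, function(k) k[, 1L], numeric(6L))
  K2 <- vapply(kernels, function(k) k[, 2L], numeric(6L))
  viol <- function(arr) {
    Zmat <- matrix(arr, nrow = 6L)
    M1 <- array(crossprod(K1, Zmat), c(6L, L, B))
    M2 <- array(crossprod(K2, Zmat), c(6L, L, B))
    convs <- M1[, -L, , drop = FALSE] + M2[, -1L, , drop = FALSE]
    convs <- pmin(pmax(convs, 0), 1)
    v <- convs[1L, , , drop = TRUE]
    for (k in 2:6) v <- pmax(v, convs[k, , , drop = TRUE])
    matrix(v, ncol = B)      # (L-1) x B
  }
  idx <- max.col(t(matrix(ZhatArr, nrow = 6L)), ties.method = "first")
  Zbin <- array(0, d)
  Zbin[cbind(idx, rep(seq_len(L), times = B) + 0L,
             rep(seq_len(B), each = L))] <- 1
  vB <- viol(Zbin); vS <- viol(ZhatArr)
  ld <- -ce + 0.8 * colMeans(vB) + 0.4 * apply(vB, 2L, max) +
    0.1 * colMeans(vS) + 0.05 * apply(vS, 2L, max)
  mean(ld)
}

#' @describeIn lossStability total training loss
#'   \eqn{L = 0.2 L_s + 0.1 L_c + 2 L_d}.
#' @param Ls,Lc,Ld the three component losses.
#' @export
lossTotal <- function(Ls, Lc, Ld) 0.2 * Ls + 0.1 * Lc + 2 * Ld
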