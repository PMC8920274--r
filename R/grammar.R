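#' Grammar kernels for secondary-structure validity
#'
#' The bank of six 6 x 2 convolutional kernels that encode which
#' secondary-structure symbols may follow which. Each kernel corresponds
#' to one symbol of [secondaryAlphabet()]: its first column holds a single
#' `+1` marking the focal symbol, and its second column holds `-1` at
#' every symbol permitted to follow it. The successor table is:
#' `L -> {L,E,H,O}`, `E -> {L,E}`, `H -> {L,H}`, `X -> {X,J}`, `J -> {L}`,
#' `O -> {X}`. Convolving a kernel across a one-hot secondary matrix gives,
#' at each adjacent pair, `1` exactly when the focal symbol is followed by
#' a disallowed symbol.
#'
#' Note that as specified, only `L` may follow `J`: a chain cannot open
#' directly into a strand or helix. `permissiveStart = TRUE` relaxes the
#' `J` kernel to allow `{L,E,H}`.
#'
#' @param permissiveStart allow E/H directly after the start symbol.
#' @return A named list of six 6 x 2 matrices, rows ordered `L,E,H,X,J,O`.
#' @examples
#' grammarKernels()$E   # strand may be followed only by L or E
#' @export
grammarKernels <- function(permissiveStart = FALSE) {
  succ <- list(L = c("L", "E", "H", "O"), E = c("L", "E"), H = c("L", "H"),
               X = c("X", "J"), J = "L", O = "X")
  if (permissiveStart) succ$J <- c("L", "E", "H")
  lapply(stats::setNames(nm = .SECONDARY), function(sym) {
    k <- matrix(0, nrow = 6L, ncol = 2L,
                dimnames = list(.SECONDARY, c("focal", "successor")))
    k[sym, 1L] <- 1
    k[succ[[sym]], 2L] <- -1
    k
  })
}

#' Per-position grammar-violation signal
#'
#' Convolves the six grammar kernels across a 6 x L secondary matrix
#' (binary one-hot or column-stochastic softmax output) and returns, at
#' each of the L-1 adjacent-pair positions, the maximum over kernels of
#' the convolution value clamped to \[0, 1\]. For a binary matrix this is
#' exactly the indicator that the symbol pair violates the successor
#' table; for a softmax matrix it is a differentiable surrogate whose
#' gradient points toward legal predictions.
#'
#' @param zhat a 6 x L matrix whose columns each sum to 1 (tolerance 1e-6).
#' @param kernels a kernel bank from [grammarKernels()].
#' @return Numeric vector of length L-1 of violation values in \[0, 1\].
#' @examples
#' z <- secondaryToMatrix("XJLLHOX")
#' grammarViolations(z)   # all zero: fully legal
#' @export
grammarViolations <- function(zhat, kernels = grammarKernels()) {
  if (nrow(zhat) != 6L) stop("zhat must have 6 rows", call. = FALSE)
  cs <- colSums(zhat)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("zhat columns must sum to 1", call. = FALSE)
  }
  L <- ncol(zhat)
  vals <- vapply(kernels, function(k) {
    crossprod(zhat[, -L, drop = FALSE], k[, 1L])[, 1L] +
      crossprod(zhat[, -1L, drop = FALSE], k[, 2L])[, 1L]
  }, numeric(L - 1L))
  v <- apply(matrix(pmin(pmax(vals, 0), 1), nrow = L - 1L), 1L, max)
  unname(v)
}

#' Full secondary matrix utilities
#'
#' `secondaryToMatrix` one-hot encodes a string over the full 6-symbol
#' alphabet (including X/J/O flanks) into a 6 x L matrix;
#' `matrixToSecondary` inverts it via per-column argmax;
#' `binarizeSecondary` argmax-binarizes a column-stochastic matrix, with
#' ties broken toward the lowest row index (L first) for determinism.
#'
#' @param secondary a string over `L,E,H,X,J,O`.
#' @return `secondaryToMatrix`: a 6 x L binary matrix.
#' @export
secondaryToMatrix <- function(secondary) {
  .checkSymbols(secondary, .SECONDARY, "secondary")
  ch <- .splitSeq(secondary)
  mat <- matrix(0, nrow = 6L, ncol = length(ch),
                dimnames = list(.SECONDARY, NULL))
  mat[cbind(match(ch, .SECONDARY), seq_along(ch))] <- 1
  mat
}

#' @rdname secondaryToMatrix
#' @param zhat a 6 x L numeric matrix.
#' @export
matrixToSecondary <- function(zhat) {
  paste(.SECONDARY[max.col(t(zhat), ties.method = "first")], collapse = "")
}

#' @rdname secondaryToMatrix
#' @export
binarizeSecondary <- function(zhat) {
  idx <- max.col(t(zhat), ties.method = "first")
  out <- matrix(0, nrow = nrow(zhat), ncol = ncol(zhat),
                dimnames = dimnames(zhat))
  out[cbind(idx, seq_along(idx))] <- 1
  out
}
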