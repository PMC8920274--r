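# Internal neural-network primitives. Shapes follow the convention:
# activations for conv stages are arrays (channels, positions, batch);
# dense stages use matrices (units, batch). Kernels for the valid 1-D
# convolution are stored as nk x (channels*width) with column-major
# vectorised windows (see src/conv.cpp).

convForward <- function(X, W, b, w) .conv1dFwd(X, W, b, as.integer(w))

convBackward <- function(X, W, dY, w) {
  out <- .conv1dBwd(X, W, dY, as.integer(w))
  out$db <- as.numeric(out$db)
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

reluGrad <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

# Inverted dropout: scales kept units by 1/(1-p) so inference needs no
# rescaling. Mask drawn from the supplied RNG stream (caller seeds).
dropoutMask <- function(dim, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dim)) >= p) / (1 - p), dim = dim)
}

denseForward <- function(X, W, b) W %*% X + b

denseBackward <- function(X, W, dY) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

# Column-wise softmax of a matrix of logits.
softmaxCols <- function(z) {
  mx <- z[1L, ]
  for (i in seq_len(nrow(z))[-1L]) mx <- pmax(mx, z[i, ])
  e <- exp(z - rep(mx, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

glorot <- function(nOut, nIn, fan = c(nIn, nOut)) {
  lim <- sqrt(6 / (fan[1L] + fan[2L]))
  matrix(stats::runif(nOut * nIn, -lim, lim), nrow = nOut)
}

# --- Optimizers -----------------------------------------------------------
# Parameters and gradients are flat named lists of numeric arrays.

optimInit <- function(params, method = c("adadelta", "adam"),
                      lr = 1, rho = 0.95, eps = 1e-6,
                      beta1 = 0.9, beta2 = 0.999) {
  method <- match.arg(method)
  zeros <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  list(method = method, lr = lr, rho = rho, eps = eps,
       beta1 = beta1, beta2 = beta2, t = 0L,
       m = zeros, v = zeros)
}

optimStep <- function(params, grads, state, clip = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(clip) && nrm > clip) {
    grads <- lapply(grads, function(g) g * (clip / nrm))
  }
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (state$method == "adadelta") {
      state$m[[nm]] <- state$rho * state$m[[nm]] + (1 - state$rho) * g * g
      upd <- -sqrt(state$v[[nm]] + state$eps) /
        sqrt(state$m[[nm]] + state$eps) * g
      state$v[[nm]] <- state$rho * state$v[[nm]] + (1 - state$rho) * upd * upd
      params[[nm]] <- params[[nm]] + state$lr * upd
    } else {
      state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
      state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
      mhat <- state$m[[nm]] / (1 - state$beta1^state$t)
      vhat <- state$v[[nm]] / (1 - state$beta2^state$t)
      params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
    }
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))
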