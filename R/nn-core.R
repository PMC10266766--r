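## Minimal seeded neural-network primitives shared by the representation
## CNN and the downstream regressor: batch normalization, leaky ReLU and
## Adam. All randomness goes through R's RNG so a seed fully determines
## initialization and optimization.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

lrelu_grad <- function(dy, x, slope) {
  dy[x < 0] <- dy[x < 0] * slope
  dy
}

## Batchnorm over rows: X is (features x M), statistics per row.
## A priming pass with momentum = 1 initializes the running statistics from
## the first batch, so eval-mode metrics are meaningful from epoch 1.
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = BN_MOMENTUM) {
  if (training) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- X - mu
    new_mean <- run_mean
    new_var <- run_var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * ivar
  list(y = gamma * xhat + beta, xhat = xhat, ivar = ivar,
       run_mean = new_mean, run_var = new_var)
}

bn_backward <- function(dY, cache, gamma) {
  M <- ncol(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * gamma
  dX <- (cache$ivar / M) *
    (M * dXhat - rowSums(dXhat) - cache$xhat * rowSums(dXhat * cache$xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)  # keeps each parameter's shape
  list(m = zeros, v = zeros, t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
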