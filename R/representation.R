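## The self-supervised representation model: a 3D CNN that predicts the
## masked wild-type amino acid from the voxelized local environment. Each
## block is conv(3^3, "same") -> batchnorm -> leaky ReLU -> maxpool(2^3);
## the classifier head is FC(100) -> leaky ReLU -> FC(20), and the 100-node
## post-activation layer is the residue representation used downstream.

#' Representation-model configuration
#'
#' Defaults follow the reference architecture: three convolutional layers
#' with 16, 32 and 64 filters of edge 3 voxels, fully-connected layers of
#' 100 and 20 nodes, Adam with learning rate 3e-4 and batches of 100
#' residues. \code{convFilters} can be reduced for desk-scale experiments;
#' the 100/20 head is fixed because the 100-d embedding is the downstream
#' feature contract and 20 is the number of amino-acid classes.
#'
#' @param convFilters integer vector of three filter counts
#' @param kernelEdge convolution kernel edge, voxels
#' @param fcSizes sizes of the two fully-connected layers; second must be 20
#' @param learningRate Adam learning rate
#' @param batchSize residues per batch
#' @param leakySlope negative slope of the leaky ReLU
#' @param poolEdge max-pool window edge, voxels
#' @param maxEpochs maximum training epochs
#' @param patience early-stopping patience (epochs without validation
#'   accuracy improvement)
#' @param seed RNG seed controlling initialization and batching
#' @return a named list
#' @export
representationConfig <- function(convFilters = c(16L, 32L, 64L),
                                 kernelEdge = 3L, fcSizes = c(100L, 20L),
                                 learningRate = 3e-4, batchSize = 100L,
                                 leakySlope = 0.01, poolEdge = 2L,
                                 maxEpochs = 100L, patience = 10L,
                                 seed = 0L) {
  stopifnot(length(convFilters) == 3, all(convFilters >= 1),
            length(fcSizes) == 2, fcSizes[2] == 20L,
            kernelEdge %% 2 == 1, learningRate > 0, batchSize >= 1)
  list(conv_filters = as.integer(convFilters),
       kernel_edge = as.integer(kernelEdge),
       fc_sizes = as.integer(fcSizes),
       learning_rate = learningRate, batch_size = as.integer(batchSize),
       leaky_slope = leakySlope, pool_edge = as.integer(poolEdge),
       max_epochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed))
}

repr_flat_dim <- function(config, spec) {
  s <- sideVoxels(spec)
  for (i in 1:3) s <- s %/% config$pool_edge
  as.integer(config$conv_filters[3] * s^3)
}

#' Initialize a representation model
#'
#' Parameter initialization (He-scaled Gaussians) is fully determined by
#' \code{seed}; the architecture itself is seed-independent.
#'
#' @param config from \code{\link{representationConfig}}
#' @param spec the \linkS4class{GridSpec} the model will consume
#' @param seed RNG seed (default: \code{config$seed})
#' @return an untrained \linkS4class{RepresentationModel}
#' @export
initRepresentation <- function(config = representationConfig(),
                               spec = gridSpec(), seed = config$seed) {
  set.seed(seed)
  K <- config$kernel_edge
  f <- config$conv_filters
  cin <- c(6L, f[1], f[2])
  params <- list()
  for (l in 1:3) {
    fan_in <- cin[l] * K^3
    params[[paste0("conv", l, "_W")]] <-
      matrix(rnorm(f[l] * fan_in, sd = sqrt(2 / fan_in)), f[l], fan_in)
    params[[paste0("conv", l, "_b")]] <- numeric(f[l])
    params[[paste0("bn", l, "_gamma")]] <- rep(1, f[l])
    params[[paste0("bn", l, "_beta")]] <- numeric(f[l])
    params[[paste0("bn", l, "_mean")]] <- numeric(f[l])
    params[[paste0("bn", l, "_var")]] <- rep(1, f[l])
  }
  flat <- repr_flat_dim(config, spec)
  params$fc1_W <- he_init(flat, config$fc_sizes[1])
  params$fc1_b <- numeric(config$fc_sizes[1])
  params$fc2_W <- he_init(config$fc_sizes[1], config$fc_sizes[2])
  params$fc2_b <- numeric(config$fc_sizes[2])
  new("RepresentationModel", config = config, gridSpec = spec,
      params = params, history = data.frame(), trained = FALSE)
}

as_grid_batch <- function(grid, spec) {
  S <- sideVoxels(spec)
  d <- dim(grid)
  if (is.null(d) || !(length(d) %in% c(4, 5)))
    stop("grid must be a (6, S, S, S[, N]) array")
  if (!identical(d[1:4], c(6L, S, S, S)) &&
      !identical(as.integer(d[1:4]), c(6L, S, S, S)))
    stop("grid shape mismatch: model expects side ", S, " voxels")
  if (length(d) == 4) dim(grid) <- c(d, 1L)
  grid
}

repr_forward <- function(params, config, x, training = FALSE,
                         keep_cache = FALSE, bn_momentum = BN_MOMENTUM) {
  K <- config$kernel_edge
  slope <- config$leaky_slope
  cache <- list(x0 = if (keep_cache) x else NULL)
  for (l in 1:3) {
    z <- conv3d_forward(x, dim(x), params[[paste0("conv", l, "_W")]],
                        params[[paste0("conv", l, "_b")]], K)
    Fl <- config$conv_filters[l]
    zm <- matrix(z, nrow = Fl)
    bn <- bn_forward(zm, params[[paste0("bn", l, "_gamma")]],
                     params[[paste0("bn", l, "_beta")]],
                     params[[paste0("bn", l, "_mean")]],
                     params[[paste0("bn", l, "_var")]], training,
                     bn_momentum)
    a <- bn$y
    dim(a) <- dim(z)
    act <- lrelu(a, slope)
    pooled <- maxpool3d_forward(act, dim(act), config$pool_edge)
    if (keep_cache) {
      cache[[paste0("conv_in", l)]] <- x
      cache[[paste0("conv_out", l)]] <- z
      cache[[paste0("bn", l)]] <- bn[c("xhat", "ivar")]
      cache[[paste0("preact", l)]] <- a
      cache[[paste0("pool", l)]] <- pooled$argmax
      cache[[paste0("actdim", l)]] <- dim(act)
    }
    cache[[paste0("bn_run", l)]] <- bn[c("run_mean", "run_var")]
    x <- pooled$out
  }
  N <- dim(x)[5]
  flat <- prod(dim(x)[1:4])
  Xf <- t(matrix(x, flat, N))
  H <- sweep(Xf %*% params$fc1_W, 2, params$fc1_b, "+")
  E <- lrelu(H, slope)
  logits <- sweep(E %*% params$fc2_W, 2, params$fc2_b, "+")
  if (keep_cache) {
    cache$Xf <- Xf
    cache$H <- H
    cache$E <- E
    cache$pooled_dim <- dim(x)
  }
  list(logits = logits, embedding = E, cache = cache)
}

repr_backward <- function(params, config, cache, dlogits) {
  slope <- config$leaky_slope
  grads <- list()
  grads$fc2_W <- t(cache$E) %*% dlogits
  grads$fc2_b <- colSums(dlogits)
  dE <- dlogits %*% t(params$fc2_W)
  dH <- lrelu_grad(dE, cache$H, slope)
  grads$fc1_W <- t(cache$Xf) %*% dH
  grads$fc1_b <- colSums(dH)
  dXf <- dH %*% t(params$fc1_W)
  dx <- t(dXf)
  dim(dx) <- cache$pooled_dim
  for (l in 3:1) {
    actdim <- cache[[paste0("actdim", l)]]
    dact <- maxpool3d_backward(dx, cache[[paste0("pool", l)]],
                               prod(actdim), actdim)
    da <- lrelu_grad(dact, cache[[paste0("preact", l)]], slope)
    Fl <- config$conv_filters[l]
    dbn <- bn_backward(matrix(da, nrow = Fl), cache[[paste0("bn", l)]],
                       params[[paste0("bn", l, "_gamma")]])
    grads[[paste0("bn", l, "_gamma")]] <- dbn$dgamma
    grads[[paste0("bn", l, "_beta")]] <- dbn$dbeta
    dz <- dbn$dX
    dim(dz) <- dim(cache[[paste0("conv_out", l)]])
    cb <- conv3d_backward(cache[[paste0("conv_in", l)]],
                          dim(cache[[paste0("conv_in", l)]]),
                          params[[paste0("conv", l, "_W")]], dz,
                          config$kernel_edge)
    grads[[paste0("conv", l, "_W")]] <- cb$dW
    grads[[paste0("conv", l, "_b")]] <- as.numeric(cb$db)
    dx <- cb$dx
  }
  grads
}

#' Classify the masked wild-type amino acid of voxelized environments
#'
#' @param model a \linkS4class{RepresentationModel}
#' @param grid a \code{(6, S, S, S)} array or \code{(6, S, S, S, N)} batch
#'   of blurred voxel grids matching the model's \linkS4class{GridSpec}
#' @return matrix (\code{N} x 20) of class probabilities, columns in
#'   alphabetical one-letter amino-acid order; rows sum to 1
#' @export
classifyWt <- function(model, grid) {
  x <- as_grid_batch(grid, model@gridSpec)
  fw <- repr_forward(model@params, model@config, x, training = FALSE)
  p <- softmax_rows(fw$logits)
  colnames(p) <- AA_ALPHABET
  p
}

#' Embed voxelized environments into the 100-d latent space
#'
#' Returns the post-activation values of the 100-node fully-connected
#' layer, i.e. the prefix of the classifier computation that the downstream
#' ddG model consumes as features.
#'
#' @inheritParams classifyWt
#' @return matrix (\code{N} x 100) of finite reals
#' @export
embedResidue <- function(model, grid) {
  x <- as_grid_batch(grid, model@gridSpec)
  repr_forward(model@params, model@config, x, training = FALSE)$embedding
}

#' Train the representation model
#'
#' Self-supervised training: cross-entropy between predicted and true
#' (masked) wild-type labels, Adam optimization, early stopping on
#' validation accuracy. The train/validation split is by protein; a protein
#' appearing in both partitions is a hard error (leakage guard). Returns
#' the best-validation checkpoint with a per-epoch accuracy history.
#'
#' @param grids \code{(6, S, S, S, N)} array of blurred voxel grids
#' @param labels length-N character vector of wild-type one-letter codes
#' @param proteins length-N character vector of protein identifiers
#' @param config from \code{\link{representationConfig}}
#' @param spec the \linkS4class{GridSpec} used to build \code{grids}
#' @param valProteins protein ids held out for validation; default: a
#'   seeded 20\% sample of unique proteins
#' @param verbose print per-epoch metrics
#' @return a trained \linkS4class{RepresentationModel}
#' @export
trainRepresentation <- function(grids, labels, proteins,
                                config = representationConfig(),
                                spec = gridSpec(), valProteins = NULL,
                                verbose = FALSE) {
  N <- dim(grids)[5]
  stopifnot(length(labels) == N, length(proteins) == N, N >= 2)
  y <- match(labels, AA_ALPHABET)
  if (any(is.na(y))) stop("labels must be canonical one-letter amino acids")
  set.seed(config$seed)
  uniq <- unique(proteins)
  if (is.null(valProteins)) {
    n_val <- max(1L, floor(0.2 * length(uniq)))
    if (length(uniq) < 2) stop("need >= 2 proteins to split by protein")
    valProteins <- sample(uniq, n_val)
  }
  train_idx <- which(!(proteins %in% valProteins))
  val_idx <- which(proteins %in% valProteins)
  if (length(train_idx) == 0 || length(val_idx) == 0)
    stop("empty train or validation split")
  if (length(intersect(unique(proteins[train_idx]),
                       unique(proteins[val_idx]))) > 0)
    stop("protein leakage: a protein appears in both train and validation")

  model <- initRepresentation(config, spec, seed = config$seed)
  params <- model@params
  opt_names <- grep("_mean$|_var$", names(params), invert = TRUE,
                    value = TRUE)
  state <- adam_init(params[opt_names])
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- list()
  Yhot <- diag(20)[y, , drop = FALSE]

  ## prime the batchnorm running statistics from one batch so that
  ## eval-mode validation accuracy is meaningful from the first epoch
  prime_idx <- train_idx[seq_len(min(config$batch_size, length(train_idx)))]
  fw0 <- repr_forward(params, config,
                      grids[, , , , prime_idx, drop = FALSE],
                      training = TRUE, bn_momentum = 1)
  for (l in 1:3) {
    run <- fw0$cache[[paste0("bn_run", l)]]
    params[[paste0("bn", l, "_mean")]] <- run$run_mean
    params[[paste0("bn", l, "_var")]] <- run$run_var
  }

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(train_idx)
    nb <- ceiling(length(idx) / config$batch_size)
    ep_loss <- 0
    ep_hits <- 0
    for (b in seq_len(nb)) {
      bi <- idx[((b - 1) * config$batch_size + 1):
                min(b * config$batch_size, length(idx))]
      xb <- grids[, , , , bi, drop = FALSE]
      fw <- repr_forward(params, config, xb, training = TRUE,
                         keep_cache = TRUE)
      for (l in 1:3) {
        run <- fw$cache[[paste0("bn_run", l)]]
        params[[paste0("bn", l, "_mean")]] <- run$run_mean
        params[[paste0("bn", l, "_var")]] <- run$run_var
      }
      P <- softmax_rows(fw$logits)
      yb <- y[bi]
      ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_along(bi), yb)], 1e-12)))
      ep_hits <- ep_hits + sum(max.col(P, ties.method = "first") == yb)
      dlogits <- (P - Yhot[bi, , drop = FALSE]) / length(bi)
      grads <- repr_backward(params, config, fw$cache, dlogits)
      upd <- adam_step(params[opt_names], grads[opt_names], state,
                       config$learning_rate)
      params[opt_names] <- upd$params
      state <- upd$state
    }
    val_acc <- repr_accuracy(params, config, grids, y, val_idx,
                             config$batch_size)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / length(idx),
      train_acc = ep_hits / length(idx), val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %.3f",
                      epoch, ep_loss / length(idx), ep_hits / length(idx),
                      val_acc))
    if (val_acc > best$acc)
      best <- list(acc = val_acc, params = params, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  new("RepresentationModel", config = config, gridSpec = spec,
      params = best$params, history = do.call(rbind, hist), trained = TRUE)
}

repr_accuracy <- function(params, config, grids, y, idx, batch_size) {
  hits <- 0
  nb <- ceiling(length(idx) / batch_size)
  for (b in seq_len(nb)) {
    bi <- idx[((b - 1) * batch_size + 1):min(b * batch_size, length(idx))]
    fw <- repr_forward(params, config, grids[, , , , bi, drop = FALSE],
                       training = FALSE)
    hits <- hits + sum(max.col(softmax_rows(fw$logits), ties.method = "first") == y[bi])
  }
  hits / length(idx)
}

#' Training history of a fitted model
#'
#' @param model a trained \linkS4class{RepresentationModel}
#' @return data.frame of per-epoch metrics
#' @export
trainingHistory <- function(model) model@history
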