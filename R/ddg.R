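## The supervised downstream regressor: feature construction, the Fermi
## target transform, MAE training in Fermi space, and ensemble-median
## prediction in kcal/mol.

#' Fermi (switching) transform of a stability change
#'
#' \eqn{F(\Delta\Delta G) = 1 / (1 + e^{-\beta(\Delta\Delta G - \alpha)})}
#' with defaults \eqn{\beta = 0.4} (1/(kcal/mol)) and \eqn{\alpha = 3.0}
#' kcal/mol. The transform compresses targets into (0, 1) and focuses
#' training on the ddG range from roughly -1 to 7 kcal/mol, where
#' physics-based reference calculations are most reliable and where many
#' disease-relevant loss-of-function variants lie. Strictly increasing in
#' \code{ddg}.
#'
#' @param ddg stability change(s), kcal/mol
#' @param beta steepness, 1/(kcal/mol); must be positive
#' @param alpha midpoint, kcal/mol
#' @return value(s) in (0, 1)
#' @examples
#' fermiTransform(3.0)    # exactly 0.5 at the midpoint
#' @export
fermiTransform <- function(ddg, beta = 0.4, alpha = 3.0) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (ddg - alpha)))
}

#' Invert the Fermi transform back to kcal/mol
#'
#' Algebraic inverse of \code{\link{fermiTransform}}. Scores are clamped to
#' \code{[clamp, 1 - clamp]} before inversion because the transform is not
#' invertible at 0/1; with the default clamp of 1e-4 the reportable range
#' saturates at roughly [-20, +26] kcal/mol. Clamping events are reported
#' with a warning.
#'
#' @param score Fermi-space score(s) in (0, 1)
#' @param beta,alpha as in \code{\link{fermiTransform}}
#' @param clamp clamping bound applied before inversion
#' @return stability change(s), kcal/mol
#' @export
inverseFermi <- function(score, beta = 0.4, alpha = 3.0, clamp = 1e-4) {
  stopifnot(beta > 0, clamp > 0, clamp < 0.5)
  n_clamped <- sum(score < clamp | score > 1 - clamp)
  if (n_clamped > 0)
    warning(n_clamped, " score(s) clamped to [", clamp, ", ", 1 - clamp,
            "] before inversion")
  s <- pmin(pmax(score, clamp), 1 - clamp)
  alpha - log(1 / s - 1) / beta
}

#' Convert raw Rosetta-style scores to kcal/mol
#'
#' Reference cartesian ddG scores are divided by 2.9 to land on a scale
#' corresponding to kcal/mol.
#'
#' @param raw raw score(s)
#' @param scale divisor (default 2.9)
#' @return scores in kcal/mol
#' @export
convertRosettaUnits <- function(raw, scale = 2.9) raw / scale

#' Background amino-acid frequencies of a structure set
#'
#' Empirical frequency of each canonical amino acid over all residue sites
#' of the given structures. The two frequency entries of the downstream
#' feature vector come from this table, so it is persisted inside any
#' trained \linkS4class{DdgEnsemble}.
#'
#' @param structures a \linkS4class{ProteinStructure} or list of them
#' @return named length-20 numeric vector summing to 1
#' @export
aaFrequencies <- function(structures) {
  if (is(structures, "ProteinStructure")) structures <- list(structures)
  if (length(structures) == 0) stop("empty structure set")
  aa <- unlist(lapply(structures, function(s) residueSites(s)$wt_aa))
  if (length(aa) == 0) stop("no resolvable residues in structure set")
  counts <- table(factor(aa, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / sum(counts)
  names(freq) <- AA_ALPHABET
  freq
}

one_hot_aa <- function(aa) {
  i <- match(aa, AA_ALPHABET)
  if (any(is.na(i))) stop("non-canonical amino acid: ",
                          paste(unique(aa[is.na(i)]), collapse = ", "))
  m <- matrix(0, length(aa), 20)
  m[cbind(seq_along(i), i)] <- 1
  m
}

#' Build downstream feature vectors
#'
#' Concatenates, in fixed block order: the 100-d environment embedding, the
#' wild-type one-hot (20), the mutant one-hot (20), and the background
#' frequencies of the wild-type and mutant amino acid (2), for a 142-d
#' feature vector per variant.
#'
#' @param embedding matrix (n x 100) or length-100 vector
#' @param wt_aa,mut_aa character vectors of one-letter codes (length n)
#' @param frequencies named length-20 frequency vector from
#'   \code{\link{aaFrequencies}}
#' @return matrix (n x 142)
#' @export
buildFeatures <- function(embedding, wt_aa, mut_aa, frequencies) {
  if (is.null(dim(embedding))) embedding <- matrix(embedding, nrow = 1)
  if (ncol(embedding) != 100)
    stop("embedding must have 100 columns, got ", ncol(embedding))
  stopifnot(length(wt_aa) == nrow(embedding),
            length(mut_aa) == nrow(embedding),
            identical(names(frequencies), AA_ALPHABET))
  cbind(embedding, one_hot_aa(wt_aa), one_hot_aa(mut_aa),
        wt_freq = frequencies[wt_aa], mut_freq = frequencies[mut_aa])
}

#' Annotate disulfide-bonded cysteines
#'
#' Cystines are detected geometrically: sulfur atoms of two different
#' cysteine residues closer than \code{maxDist} Angstrom (default 2.5) are
#' taken to be disulfide-bonded. Free cysteines are not flagged.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param maxDist S-S distance cutoff, Angstrom
#' @return integer vector of residue indices participating in a disulfide
#' @export
annotateDisulfides <- function(structure, maxDist = 2.5) {
  a <- structure@atoms
  s <- a[a$element == "S" & a$resid3 == "CYS", , drop = FALSE]
  if (nrow(s) < 2) return(integer())
  xyz <- as.matrix(s[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  bonded <- which(d < maxDist & d > 0, arr.ind = TRUE)
  bonded <- bonded[s$resno[bonded[, 1]] != s$resno[bonded[, 2]], ,
                   drop = FALSE]
  sort(unique(s$resno[as.vector(bonded)]))
}

#' Remove training variants at disulfide-bonded cystine positions
#'
#' Stability changes at cystine positions are unreliable under the
#' reference protocol and are excluded from training, validation and test
#' data. Free (non-bonded) cysteines are retained. The number of removed
#' rows is reported with a message.
#'
#' @param records data.frame with at least \code{source_id} and
#'   \code{residue_index} columns
#' @param structures named list of \linkS4class{ProteinStructure} objects
#'   (names matching \code{source_id}), or a single structure
#' @param maxDist S-S distance cutoff, Angstrom
#' @return filtered records
#' @export
filterTrainingVariants <- function(records, structures, maxDist = 2.5) {
  if (is(structures, "ProteinStructure")) {
    structures <- setNames(list(structures), structures@sourceId)
  }
  drop <- rep(FALSE, nrow(records))
  for (sid in unique(records$source_id)) {
    st <- structures[[sid]]
    if (is.null(st)) next
    cystines <- annotateDisulfides(st, maxDist)
    drop <- drop | (records$source_id == sid &
                    records$residue_index %in% cystines)
  }
  if (any(drop))
    message("removed ", sum(drop), " variant(s) at disulfide-bonded ",
            "cystine positions")
  records[!drop, , drop = FALSE]
}

#' Downstream-model configuration
#'
#' Defaults follow the reference setup: fully-connected layers of 128, 64
#' and 16 nodes ending in a scalar passed through a sigmoid, mean absolute
#' error on Fermi-transformed targets, Adam with learning rate 5e-4 and
#' batches of 40 variants, and an ensemble of 10 differently-seeded models
#' whose median is the prediction.
#'
#' @param fcSizes hidden layer sizes
#' @param learningRate Adam learning rate
#' @param batchSize variants per batch
#' @param seeds one seed per ensemble member (default 0..9)
#' @param fermiBeta,fermiAlpha Fermi transform parameters
#' @param rosettaScale raw-score divisor for unit conversion
#' @param maxEpochs maximum epochs per member
#' @param patience early-stopping patience on validation MAE (Fermi space)
#' @param leakySlope negative slope of the leaky ReLU
#' @return a named list with \code{ensemble_size = length(seeds)}
#' @export
downstreamConfig <- function(fcSizes = c(128L, 64L, 16L),
                             learningRate = 5e-4, batchSize = 40L,
                             seeds = 0:9, fermiBeta = 0.4,
                             fermiAlpha = 3.0, rosettaScale = 2.9,
                             maxEpochs = 300L, patience = 25L,
                             leakySlope = 0.01) {
  stopifnot(length(fcSizes) == 3, all(fcSizes >= 1), learningRate > 0,
            batchSize >= 1, length(seeds) >= 1, fermiBeta > 0)
  list(fc_sizes = as.integer(fcSizes), learning_rate = learningRate,
       batch_size = as.integer(batchSize), ensemble_size = length(seeds),
       seeds = as.integer(seeds),
       fermi = list(beta = fermiBeta, alpha = fermiAlpha),
       rosetta_scale = rosettaScale, max_epochs = as.integer(maxEpochs),
       patience = as.integer(patience), leaky_slope = leakySlope)
}

mlp_init <- function(seed, in_dim, fc_sizes) {
  set.seed(seed)
  sizes <- c(in_dim, fc_sizes, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    params[[paste0("W", l)]] <- he_init(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  for (l in seq_along(fc_sizes)) {
    params[[paste0("g", l)]] <- rep(1, fc_sizes[l])
    params[[paste0("be", l)]] <- numeric(fc_sizes[l])
    params[[paste0("rm", l)]] <- numeric(fc_sizes[l])
    params[[paste0("rv", l)]] <- rep(1, fc_sizes[l])
  }
  params
}

mlp_forward <- function(params, X, slope, training = FALSE,
                        keep_cache = FALSE, bn_momentum = BN_MOMENTUM) {
  nh <- sum(grepl("^g", names(params)))
  cache <- list(X = X)
  A <- X
  for (l in seq_len(nh)) {
    Z <- sweep(A %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]],
               "+")
    bn <- bn_forward(t(Z), params[[paste0("g", l)]],
                     params[[paste0("be", l)]], params[[paste0("rm", l)]],
                     params[[paste0("rv", l)]], training, bn_momentum)
    Hpre <- t(bn$y)
    Anew <- lrelu(Hpre, slope)
    if (keep_cache) {
      cache[[paste0("A", l - 1)]] <- A
      cache[[paste0("bn", l)]] <- bn[c("xhat", "ivar")]
      cache[[paste0("pre", l)]] <- Hpre
    }
    cache[[paste0("run", l)]] <- bn[c("run_mean", "run_var")]
    A <- Anew
  }
  lout <- nh + 1
  z <- sweep(A %*% params[[paste0("W", lout)]], 2,
             params[[paste0("b", lout)]], "+")
  p <- 1 / (1 + exp(-z))
  if (keep_cache) {
    cache[[paste0("A", nh)]] <- A
    cache$z <- z
    cache$p <- p
  }
  list(p = as.numeric(p), cache = cache)
}

mlp_backward <- function(params, cache, dz, slope) {
  nh <- sum(grepl("^g", names(params)))
  grads <- list()
  lout <- nh + 1
  A <- cache[[paste0("A", nh)]]
  grads[[paste0("W", lout)]] <- t(A) %*% dz
  grads[[paste0("b", lout)]] <- colSums(dz)
  dA <- dz %*% t(params[[paste0("W", lout)]])
  for (l in nh:1) {
    dpre <- lrelu_grad(dA, cache[[paste0("pre", l)]], slope)
    dbn <- bn_backward(t(dpre), cache[[paste0("bn", l)]],
                       params[[paste0("g", l)]])
    grads[[paste0("g", l)]] <- dbn$dgamma
    grads[[paste0("be", l)]] <- dbn$dbeta
    dZ <- t(dbn$dX)
    Aprev <- cache[[paste0("A", l - 1)]]
    grads[[paste0("W", l)]] <- t(Aprev) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[paste0("W", l)]])
  }
  grads
}

mlp_mae_fermi <- function(params, X, target_f, slope) {
  mean(abs(mlp_forward(params, X, slope, training = FALSE)$p - target_f))
}

train_one_downstream <- function(X, target_f, train_idx, val_idx, config,
                                 seed, verbose = FALSE) {
  params <- mlp_init(seed, ncol(X), config$fc_sizes)
  opt_names <- grep("^rm|^rv", names(params), invert = TRUE, value = TRUE)
  state <- adam_init(params[opt_names])
  best <- list(mae = Inf, params = params, epoch = 0L)
  set.seed(seed + 1L)
  ## prime batchnorm running statistics from one batch (see bn_forward)
  prime_idx <- train_idx[seq_len(min(config$batch_size, length(train_idx)))]
  fw0 <- mlp_forward(params, X[prime_idx, , drop = FALSE],
                     config$leaky_slope, training = TRUE, bn_momentum = 1)
  for (l in seq_along(config$fc_sizes)) {
    run <- fw0$cache[[paste0("run", l)]]
    params[[paste0("rm", l)]] <- run$run_mean
    params[[paste0("rv", l)]] <- run$run_var
  }
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(train_idx)
    nb <- ceiling(length(idx) / config$batch_size)
    for (b in seq_len(nb)) {
      bi <- idx[((b - 1) * config$batch_size + 1):
                min(b * config$batch_size, length(idx))]
      fw <- mlp_forward(params, X[bi, , drop = FALSE], config$leaky_slope,
                        training = TRUE, keep_cache = TRUE)
      nh <- length(config$fc_sizes)
      for (l in seq_len(nh)) {
        run <- fw$cache[[paste0("run", l)]]
        params[[paste0("rm", l)]] <- run$run_mean
        params[[paste0("rv", l)]] <- run$run_var
      }
      p <- fw$p
      dz <- matrix(sign(p - target_f[bi]) * p * (1 - p) / length(bi),
                   ncol = 1)
      grads <- mlp_backward(params, fw$cache, dz, config$leaky_slope)
      upd <- adam_step(params[opt_names], grads[opt_names], state,
                       config$learning_rate)
      params[opt_names] <- upd$params
      state <- upd$state
    }
    val_mae <- mlp_mae_fermi(params, X[val_idx, , drop = FALSE],
                             target_f[val_idx], config$leaky_slope)
    if (verbose && epoch %% 10 == 0)
      message(sprintf("  seed %d epoch %3d val MAE_F %.4f", seed, epoch,
                      val_mae))
    if (val_mae < best$mae)
      best <- list(mae = val_mae, params = params, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  best$params
}

#' Train the downstream ddG ensemble
#'
#' Targets are supplied as ddG in kcal/mol, transformed with the Fermi
#' function, and fit by minimizing the mean absolute error in Fermi space
#' (MAE_F). One model is trained per seed; predictions later use the
#' ensemble median. The train/validation split is by protein and protein
#' leakage is a hard error. Targets outside [-20, 30] kcal/mol are rejected
#' as likely unit errors.
#'
#' @param features matrix (n x 142) from \code{\link{buildFeatures}}
#' @param ddg length-n numeric targets, kcal/mol
#' @param proteins length-n protein identifiers
#' @param config from \code{\link{downstreamConfig}}
#' @param aaFreq frequency vector stored with the ensemble (from
#'   \code{\link{aaFrequencies}})
#' @param spec the \linkS4class{GridSpec} of the representation model whose
#'   embeddings were used
#' @param valProteins proteins held out for validation; default: a seeded
#'   20\% sample of unique proteins
#' @param verbose print progress
#' @return a \linkS4class{DdgEnsemble}
#' @export
trainDownstream <- function(features, ddg, proteins,
                            config = downstreamConfig(), aaFreq,
                            spec = gridSpec(), valProteins = NULL,
                            verbose = FALSE) {
  n <- nrow(features)
  stopifnot(length(ddg) == n, length(proteins) == n, n >= 2)
  if (any(!is.finite(ddg)) || any(ddg < -20 | ddg > 30))
    stop("targets outside [-20, 30] kcal/mol: suspected unit error")
  set.seed(config$seeds[1])
  uniq <- unique(proteins)
  if (is.null(valProteins)) {
    if (length(uniq) < 2) stop("need >= 2 proteins to split by protein")
    valProteins <- sample(uniq, max(1L, floor(0.2 * length(uniq))))
  }
  train_idx <- which(!(proteins %in% valProteins))
  val_idx <- which(proteins %in% valProteins)
  if (length(train_idx) == 0 || length(val_idx) == 0)
    stop("empty train or validation split")
  if (length(intersect(unique(proteins[train_idx]),
                       unique(proteins[val_idx]))) > 0)
    stop("protein leakage: a protein appears in both train and validation")

  target_f <- fermiTransform(ddg, config$fermi$beta, config$fermi$alpha)
  models <- lapply(config$seeds, function(s) {
    if (verbose) message("training ensemble member, seed ", s)
    train_one_downstream(features, target_f, train_idx, val_idx, config, s,
                         verbose)
  })
  new("DdgEnsemble", models = models, config = config,
      fermi = config$fermi, aaFreq = aaFreq, gridSpec = spec)
}

#' Predict stability changes with an ensemble
#'
#' Each member model produces a sigmoid output in Fermi space; the
#' prediction is the member median, mapped to kcal/mol with
#' \code{\link{inverseFermi}}. Per-model scores are retained in the result.
#'
#' @param ensemble a \linkS4class{DdgEnsemble}
#' @param features matrix (n x 142) from \code{\link{buildFeatures}}
#' @return data.frame with \code{score_fermi} and \code{ddg_kcal_per_mol};
#'   the per-member score matrix is attached as attribute
#'   \code{"per_model_scores"}
#' @export
predictDdg <- function(ensemble, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (length(ensemble@models) == 0) stop("empty ensemble")
  in_dim <- nrow(ensemble@models[[1]]$W1)
  if (ncol(features) != in_dim)
    stop("feature-length mismatch: ensemble expects ", in_dim, " columns")
  slope <- ensemble@config$leaky_slope %||% 0.01
  per <- vapply(ensemble@models, function(m)
    mlp_forward(m, features, slope, training = FALSE)$p,
    numeric(nrow(features)))
  per <- matrix(per, nrow = nrow(features))
  score <- apply(per, 1, median)
  ddg <- suppressWarnings(
    inverseFermi(score, ensemble@config$fermi$beta,
                 ensemble@config$fermi$alpha))
  out <- data.frame(score_fermi = score, ddg_kcal_per_mol = ddg)
  attr(out, "per_model_scores") <- per
  out
}
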