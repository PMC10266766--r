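test_that("fermi transform has exact midpoint, monotonicity and round trip", {
  expect_identical(fermiTransform(3.0), 0.5)
  ## independent evaluation of the logistic at ddg = -1
  expect_equal(fermiTransform(-1), 1 / (1 + exp(1.6)), tolerance = 1e-12)
  expect_true(fermiTransform(7) > fermiTransform(3))
  expect_true(fermiTransform(3) > fermiTransform(-1))
  ## strict monotonicity on a dense grid
  x <- seq(-10, 17, length.out = 1000)
  expect_true(all(diff(fermiTransform(x)) > 0))
  ## algebraic inverse round trip
  expect_lt(max(abs(inverseFermi(fermiTransform(x)) - x)), 1e-9)
  expect_equal(inverseFermi(0.5), 3.0)
})

test_that("inverse fermi clamps extreme scores with a warning", {
  expect_warning(v <- inverseFermi(1e-6), "clamped")
  expect_equal(v, suppressWarnings(inverseFermi(1e-4)))
  expect_warning(inverseFermi(1 - 1e-9), "clamped")
  expect_silent(inverseFermi(0.3))
})

test_that("rosetta unit conversion is a plain division by 2.9", {
  expect_equal(convertRosettaUnits(2.9), 1)
  expect_equal(convertRosettaUnits(0), 0)
  expect_equal(convertRosettaUnits(-5.8), -2)
  expect_equal(convertRosettaUnits(c(2.9, 29)), c(1, 10))
})

test_that("amino-acid frequencies count residue sites and normalise", {
  st <- helix30()
  freq <- aaFrequencies(st)
  expect_equal(sum(freq), 1, tolerance = 1e-12)
  ## matches direct counting
  counts <- table(factor(residueSites(st)$wt_aa,
                         levels = names(freq)))
  expect_equal(as.numeric(freq), as.numeric(counts / sum(counts)))
  ## all-alanine structure concentrates on A
  ala <- makeToyStructure(10, "ideal_helix",
                          sequence = strrep("A", 10), seed = 2)
  fa <- aaFrequencies(ala)
  expect_equal(unname(fa["A"]), 1)
  expect_equal(sum(fa[names(fa) != "A"]), 0)
  expect_error(aaFrequencies(list()), "empty")
})

test_that("feature vectors have the fixed 100+20+20+2 block layout", {
  set.seed(3)
  emb <- matrix(rnorm(200), 2, 100)
  freq <- rep(1 / 20, 20)
  names(freq) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  X <- buildFeatures(emb, c("A", "W"), c("C", "A"), freq)
  expect_equal(dim(X), c(2, 142))
  expect_equal(X[1, 1:100], emb[1, ], ignore_attr = TRUE)
  expect_equal(sum(X[1, 101:120]), 1)   # one-hot wt
  expect_equal(sum(X[1, 121:140]), 1)   # one-hot mut
  expect_equal(X[1, 101], 1)            # wt A is first of the alphabet
  expect_equal(X[1, 122], 1)            # mut C is second
  ## swapping wt and mut swaps the one-hot blocks and frequency entries
  Y <- buildFeatures(emb, c("C", "A"), c("A", "W"), freq)
  expect_equal(Y[1, 101:120], X[1, 121:140], ignore_attr = TRUE)
  expect_equal(Y[1, 121:140], X[1, 101:120], ignore_attr = TRUE)
  expect_equal(Y[1, 141:142], X[1, c(142, 141)], ignore_attr = TRUE)
  ## self-substitution has identical one-hot blocks
  Z <- buildFeatures(emb[1, ], "A", "A", freq)
  expect_equal(Z[1, 101:120], Z[1, 121:140], ignore_attr = TRUE)
  expect_error(buildFeatures(emb, c("A", "B"), c("C", "A"), freq),
               "non-canonical")
})

test_that("disulfide detection flags S-S pairs under 2.5 A and spares free cysteines", {
  st <- makeToyStructure(12, "extended", sequence = "ACAAAAAACAAA",
                         seed = 5, sourceId = "ss")
  expect_identical(annotateDisulfides(st), integer())  # extended: far apart
  ## move the two cysteine sulfurs within bonding distance
  a <- atoms(st)
  s_rows <- which(a$element == "S")
  expect_length(s_rows, 2)
  a[s_rows[2], c("x", "y", "z")] <-
    a[s_rows[1], c("x", "y", "z")] + c(2.0, 0, 0)
  st2 <- new("ProteinStructure", sourceId = "ss", chain = "A", atoms = a)
  expect_identical(annotateDisulfides(st2), c(2L, 9L))

  ## filtering removes exactly the 2 x 19 cystine variants
  ddg <- makeSyntheticDdg(st2, seed = 1, noiseSd = 0)
  kept <- suppressMessages(filterTrainingVariants(ddg, st2))
  expect_equal(nrow(ddg) - nrow(kept), 2 * 19)
  expect_false(any(kept$residue_index %in% c(2, 9)))
  ## a single free cysteine is retained
  st3 <- makeToyStructure(8, "ideal_helix", sequence = "AAACAAAA",
                          seed = 6, sourceId = "freec")
  ddg3 <- makeSyntheticDdg(st3, seed = 1, noiseSd = 0)
  expect_equal(nrow(suppressMessages(filterTrainingVariants(ddg3, st3))),
               nrow(ddg3))
})

test_that("target range guard rejects unit-error ddG values", {
  X <- matrix(rnorm(10 * 142), 10, 142)
  freq <- aaFrequencies(helix30())
  expect_error(
    trainDownstream(X, c(rep(1, 9), 55), rep(c("a", "b"), 5),
                    downstreamConfig(seeds = 0L), freq),
    "unit error")
})

test_that("protein leakage between downstream splits is a hard error", {
  X <- matrix(rnorm(20 * 142), 20, 142)
  freq <- aaFrequencies(helix30())
  expect_error(
    trainDownstream(X, rep(1, 20), rep(c("a", "b"), 10),
                    downstreamConfig(seeds = 0L), freq,
                    valProteins = c("a", "b")),
    "empty train|leakage")
})

test_that("downstream overfits a small memorizable variant set", {
  set.seed(21)
  n <- 200
  wt <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  mut <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  emb <- matrix(rnorm(n * 100), n, 100)
  freq <- rep(1 / 20, 20)
  names(freq) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  X <- buildFeatures(emb, wt, mut, freq)
  ddg <- rnorm(n, 2, 1.5)
  cfg <- downstreamConfig(seeds = 0L, maxEpochs = 250L, patience = 250L,
                          learningRate = 2e-3)
  ## a token held-out protein keeps the by-protein split machinery honest
  prot <- c(rep("p2", 20), rep("p1", n - 20))
  ens <- trainDownstream(X, ddg, prot, cfg, freq, valProteins = "p2")
  pred <- predictDdg(ens, X[21:n, ])
  tf <- fermiTransform(ddg[21:n])
  expect_lt(mean(abs(pred$score_fermi - tf)), 0.02)
})

test_that("same seed reproduces identical downstream parameters; different seeds differ", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 142), n, 142)
  ddg <- rnorm(n, 2, 1)
  prot <- rep(c("p1", "p2", "p3"), each = 20)
  freq <- rep(1 / 20, 20)
  names(freq) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cfg <- downstreamConfig(seeds = c(0L, 1L, 2L), maxEpochs = 5L)
  e1 <- trainDownstream(X, ddg, prot, cfg, freq, valProteins = "p3")
  e2 <- trainDownstream(X, ddg, prot, cfg, freq, valProteins = "p3")
  expect_identical(e1@models[[1]], e2@models[[1]])
  expect_identical(e1@models[[3]], e2@models[[3]])
  ## ensemble members with different seeds have distinct parameters
  expect_false(identical(e1@models[[1]]$W1, e1@models[[2]]$W1))
  expect_length(e1@models, 3)
})

test_that("ensemble median respects the stated contracts", {
  set.seed(8)
  n <- 5
  X <- matrix(rnorm(n * 142), n, 142)
  freq <- rep(1 / 20, 20)
  names(freq) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cfg <- downstreamConfig(seeds = 0L, maxEpochs = 1L)
  prot <- c("a", "a", "a", "b", "b")
  ens1 <- trainDownstream(X, rep(1, n), prot, cfg, freq,
                          valProteins = "b")
  m <- ens1@models[[1]]
  ## identical-member ensemble equals the single model exactly
  ens3 <- ens1
  ens3@models <- list(m, m, m)
  expect_identical(predictDdg(ens3, X)$score_fermi,
                   predictDdg(ens1, X)$score_fermi)
  ## order invariance
  ens_mix <- ens1
  ens_mix@models <- list(m, ens1@models[[1]], m)
  p1 <- predictDdg(ens_mix, X)
  ens_mix@models <- rev(ens_mix@models)
  expect_identical(predictDdg(ens_mix, X)$score_fermi, p1$score_fermi)
  ## feature-length mismatch errors
  expect_error(predictDdg(ens1, X[, 1:100]), "mismatch")
})

test_that("median of fixed member scores {0.2, 0.5, 0.9} inverts to 3 kcal/mol", {
  ## contract check on the median + inverse composition
  score <- median(c(0.2, 0.5, 0.9))
  expect_equal(score, 0.5)
  expect_equal(inverseFermi(score), 3.0)
})
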