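# Shared desk-scale training pipelines for the acceptance properties.
# Built once per test run and cached: several properties probe different
# aspects of the same trained artifacts.

# Representation learnability study: ~1,000 environments from 24 toy
# helices, reduced filter counts, held out by protein.
helix_learnability <- function() cached("helix_learnability", function() {
  spec <- gridSpec()
  structures <- lapply(1:24, function(s)
    makeToyStructure(42, "ideal_helix", seed = s,
                     sourceId = sprintf("hel%02d", s)))
  dat <- voxelizeStructureSet(structures, spec)
  cfg <- representationConfig(convFilters = c(6L, 12L, 24L),
                              maxEpochs = 12L, patience = 12L, seed = 0L)
  model <- trainRepresentation(dat$grids, dat$labels, dat$proteins, cfg,
                               spec,
                               valProteins = sprintf("hel%02d", 21:24))
  list(model = model, data = dat,
       heldout_accuracy = max(trainingHistory(model)$val_acc))
})

# Two-stage recovery study on the synthetic ddG rule: the representation
# model is trained on its own structure set (disjoint from the ddG
# proteins, as in the real two-stage setup), then a 3-seed downstream
# ensemble is trained on 13 proteins, validated on 1 and tested on 2.
toy_study <- function() cached("toy_study", function() {
  spec <- gridSpec()
  repr_structs <- lapply(1:8, function(i)
    makeToyStructure(42, "compact_bundle", seed = 900 + i,
                     sourceId = sprintf("rep%02d", i)))
  rset <- voxelizeStructureSet(repr_structs, spec)
  cfg_r <- representationConfig(convFilters = c(6L, 12L, 24L),
                                maxEpochs = 15L, patience = 15L, seed = 0L)
  repr <- trainRepresentation(rset$grids, rset$labels, rset$proteins,
                              cfg_r, spec,
                              valProteins = c("rep07", "rep08"))

  structures <- lapply(1:16, function(i)
    makeToyStructure(42, "compact_bundle", seed = i,
                     sourceId = sprintf("fix%02d", i)))
  names(structures) <- vapply(structures, function(s) s@sourceId,
                              character(1))
  ddg <- do.call(rbind, lapply(seq_along(structures), function(i)
    makeSyntheticDdg(structures[[i]], seed = 100 + i, noiseSd = 0.2)))
  dset <- voxelizeStructureSet(structures, spec)
  emb <- embedResidue(repr, dset$grids)
  freqs <- aaFrequencies(unname(structures))
  key <- paste(dset$proteins, dset$residue_index)
  feats <- buildFeatures(
    emb[match(paste(ddg$source_id, ddg$residue_index), key), ,
        drop = FALSE],
    ddg$wt_aa, ddg$mut_aa, freqs)

  train_p <- sprintf("fix%02d", 1:13)
  val_p <- "fix14"
  test_p <- c("fix15", "fix16")
  in_ds <- ddg$source_id %in% c(train_p, val_p)
  ens <- trainDownstream(feats[in_ds, ], ddg$ddg_kcal_per_mol[in_ds],
                         ddg$source_id[in_ds],
                         downstreamConfig(seeds = 0:2, maxEpochs = 200L,
                                          patience = 40L),
                         freqs, spec, valProteins = val_p)
  te <- ddg$source_id %in% test_p
  pred <- predictDdg(ens, feats[te, ])
  list(repr = repr, ensemble = ens, structures = structures, ddg = ddg,
       features = feats, test_idx = te, pred = pred,
       heldout_pearson = cor(pred$ddg_kcal_per_mol, ddg$ddg_true[te]),
       heldout_mae = mean(abs(pred$ddg_kcal_per_mol - ddg$ddg_true[te])))
})
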