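test_that("toy structures are seeded, complete and geometry-faithful", {
  st <- makeToyStructure(30, "ideal_helix", seed = 1)
  expect_equal(nrow(residueSites(st)), 30)
  ## same seed -> identical PDB bytes
  f1 <- tempfile(); f2 <- tempfile()
  writeStructure(makeToyStructure(20, "ideal_helix", seed = 5), f1)
  writeStructure(makeToyStructure(20, "ideal_helix", seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  ## different seed -> different sequence
  s1 <- residueSites(makeToyStructure(25, "ideal_helix", seed = 1))$wt_aa
  s2 <- residueSites(makeToyStructure(25, "ideal_helix", seed = 2))$wt_aa
  expect_false(identical(s1, s2))
  ## helix is compact along its axis, extended strand is not
  span <- function(st) {
    ca <- atoms(st)[atoms(st)$atom_name == "CA", c("x", "y", "z")]
    max(dist(as.matrix(ca)))
  }
  expect_lt(span(makeToyStructure(20, "ideal_helix", sequence =
                                    strrep("A", 20), seed = 1)),
            span(makeToyStructure(20, "extended", sequence =
                                    strrep("A", 20), seed = 1)))
  ## explicit sequence is respected
  st_seq <- makeToyStructure(5, "ideal_helix", sequence = "MKLVW", seed = 1)
  expect_identical(residueSites(st_seq)$wt_aa,
                   c("M", "K", "L", "V", "W"))
  expect_error(makeToyStructure(5, "ideal_helix", sequence = "MK", seed = 1),
               "length")
  expect_error(makeToyStructure(2, "ideal_helix", sequence = "XZ", seed = 1),
               "non-canonical")
})

test_that("generated PDB files re-read cleanly without warnings", {
  f <- tempfile(fileext = ".pdb")
  makeToyStructure(25, "compact_bundle", seed = 3, path = f)
  expect_warning(st <- readStructure(f, chain = "A"), NA)
  expect_equal(nrow(residueSites(st)), 25)
})

test_that("pseudo side-chain elements encode residue class", {
  st <- makeToyStructure(8, "extended", sequence = "CMSKAWDV", seed = 2)
  a <- atoms(st)
  cb <- a[a$atom_name == "CB", ]
  expect_identical(cb$element, c("S", "S", "O", "N", "C", "N", "O", "C"))
})

test_that("compact bundles contain buried sites", {
  sa <- computeRelativeSasa(bundle45())
  expect_true(any(classifyBurial(sa$relative_sasa) == "buried"))
})

test_that("synthetic ddG landscapes follow the deterministic rule plus noise", {
  st <- bundle45()
  ## noise-free: exact deterministic function of (wt, mut, burial)
  d1 <- makeSyntheticDdg(st, seed = 1, noiseSd = 0)
  d2 <- makeSyntheticDdg(st, seed = 99, noiseSd = 0)
  expect_equal(d1$ddg_kcal_per_mol, d2$ddg_kcal_per_mol)
  expect_equal(nrow(d1), 45 * 19)
  ## same seed with noise -> identical; different seed -> different
  n1 <- makeSyntheticDdg(st, seed = 4, noiseSd = 0.2)
  n2 <- makeSyntheticDdg(st, seed = 4, noiseSd = 0.2)
  n3 <- makeSyntheticDdg(st, seed = 5, noiseSd = 0.2)
  expect_identical(n1, n2)
  expect_false(identical(n1$ddg_kcal_per_mol, n3$ddg_kcal_per_mol))
  ## self-substitutions are exactly zero when requested
  ds <- makeSyntheticDdg(st, seed = 1, noiseSd = 0.2, includeSelf = TRUE)
  expect_equal(nrow(ds), 45 * 20)
  expect_true(all(ds$ddg_kcal_per_mol[ds$wt_aa == ds$mut_aa] == 0))
  ## burial amplifies: buried sites have larger mean |ddg| for same wt
  agg <- tapply(abs(d1$ddg_kcal_per_mol), d1$buried, mean)
  if (length(agg) == 2) expect_gt(agg["1"], agg["0"])
})

test_that("generated ddG values concentrate in the -1..7 kcal/mol window", {
  vals <- unlist(lapply(1:4, function(i) {
    st <- makeToyStructure(40, "compact_bundle", seed = i)
    makeSyntheticDdg(st, seed = 100 + i, noiseSd = 0.2)$ddg_kcal_per_mol
  }))
  expect_gte(mean(vals >= -1 & vals <= 7), 0.9)
})

test_that("variant tables are seeded, class-skewed and decoy-bearing", {
  st <- bundle45()
  ddg <- makeSyntheticDdg(st, seed = 1, noiseSd = 0.2)
  v1 <- makeVariantTable(ddg, seed = 2, n = 100, decoyRate = 0.1)
  v2 <- makeVariantTable(ddg, seed = 2, n = 100, decoyRate = 0.1)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 100)
  expect_true(all(v1$allele_frequency > 0 & v1$allele_frequency <= 0.1))
  ## pathogenic variants sit at higher true ddG than benign ones
  key <- paste(ddg$residue_index, ddg$mut_aa)
  truth <- ddg$ddg_kcal_per_mol[match(paste(v1$residue_index, v1$mut_aa),
                                      key)]
  expect_gt(median(truth[v1$class == "pathogenic"]),
            median(truth[v1$class == "benign"]))
  ## decoys: close to the binomial expectation, and rejected by the join
  scan_like <- data.frame(source_id = ddg$source_id, chain = ddg$chain,
                          residue_index = ddg$residue_index,
                          wt_aa = ddg$wt_aa, mut_aa = ddg$mut_aa,
                          score_fermi = 0.5,
                          ddg_kcal_per_mol = ddg$ddg_kcal_per_mol,
                          wt_is_cysteine = ddg$wt_aa == "C",
                          self_substitution = FALSE)
  ann <- suppressMessages(annotateVariants(scan_like, v1))
  n_rej <- unname(attr(ann, "join_stats")["wt_mismatch"])
  expect_gte(n_rej, 3)
  expect_lte(n_rej, 20)
  expect_error(makeVariantTable(ddg[0, ], seed = 1), "empty")
})
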