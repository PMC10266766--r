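# An untrained model pair is enough for the scan-structure contracts:
# determinism, completeness and serialization do not depend on fit quality.
tiny_models <- function() cached("tiny_models", function() {
  spec <- gridSpec()
  repr <- initRepresentation(
    representationConfig(convFilters = c(2L, 4L, 8L)), spec, seed = 1)
  freq <- aaFrequencies(helix30())
  cfg <- downstreamConfig(seeds = c(0L, 1L, 2L), maxEpochs = 1L)
  set.seed(1)
  X <- matrix(rnorm(60 * 142), 60, 142)
  ens <- trainDownstream(X, rep(1.5, 60), rep(c("p1", "p2"), 30), cfg,
                         freq, spec, valProteins = "p2")
  list(repr = repr, ens = ens)
})

test_that("saturation scan emits 20 ordered rows per site with flagged self rows", {
  m <- tiny_models()
  st <- helix30()
  tab <- saturationScan(st, m$repr, m$ens)
  r <- scanRecords(tab)
  expect_equal(nrow(r), 30 * 20)
  ## per-site mutant multiset is exactly the canonical alphabet, in order
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in unique(r$residue_index))
    expect_identical(r$mut_aa[r$residue_index == i], aa)
  ## residues in scan order
  expect_identical(unique(r$residue_index), 1:30)
  ## one self substitution per site, ddg exactly 0
  expect_equal(sum(r$self_substitution), 30)
  expect_true(all(r$ddg_kcal_per_mol[r$self_substitution] == 0))
  expect_identical(r$wt_aa[r$self_substitution],
                   residueSites(st)$wt_aa)
  ## cysteine flag tracks the wild type
  expect_identical(r$wt_is_cysteine, r$wt_aa == "C")
  ## per-model scores retained, one column per member
  expect_equal(dim(tab@perModel), c(600, 3))
})

test_that("scan skips incomplete residues and logs them", {
  m <- tiny_models()
  st <- helix30()
  a <- atoms(st)
  a <- a[!(a$resno == 7 & a$atom_name == "N"), ]
  st2 <- new("ProteinStructure", sourceId = "gap", chain = "A", atoms = a)
  tab <- suppressMessages(saturationScan(st2, m$repr, m$ens))
  expect_equal(nrow(scanRecords(tab)), 29 * 20)
  expect_false(7 %in% scanRecords(tab)$residue_index)
})

test_that("scans are deterministic and refuse mismatched grid specs", {
  m <- tiny_models()
  st <- helix30()
  t1 <- saturationScan(st, m$repr, m$ens)
  t2 <- saturationScan(st, m$repr, m$ens)
  expect_identical(scanRecords(t1), scanRecords(t2))
  ## byte-identical serialization
  f1 <- tempfile(); f2 <- tempfile()
  writeScanCsv(t1, f1); writeScanCsv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## GridSpec mismatch is an error
  ens_bad <- m$ens
  ens_bad@gridSpec <- gridSpec(blurSigma = 2)
  expect_error(saturationScan(st, m$repr, ens_bad), "GridSpec mismatch")
})

test_that("scan CSV round-trips at serialized precision", {
  m <- tiny_models()
  tab <- saturationScan(helix30(), m$repr, m$ens)
  f <- tempfile(fileext = ".csv")
  writeScanCsv(tab, f)
  expect_true(any(grepl("^# units: ddg kcal/mol", readLines(f))))
  tab2 <- readScanCsv(f)
  r1 <- scanRecords(tab)
  r2 <- scanRecords(tab2)
  expect_equal(r2$ddg_kcal_per_mol, round(r1$ddg_kcal_per_mol, 4))
  expect_identical(r2$mut_aa, r1$mut_aa)
  expect_identical(r2$self_substitution, r1$self_substitution)
  ## second round trip is lossless
  f2 <- tempfile(fileext = ".csv")
  writeScanCsv(tab2, f2)
  expect_identical(scanRecords(readScanCsv(f2)), scanRecords(tab2))

  ## missing units header -> warning, assumed kcal/mol
  lines <- readLines(f)
  f3 <- tempfile(fileext = ".csv")
  writeLines(lines[!grepl("^# units", lines)], f3)
  expect_warning(readScanCsv(f3), "kcal/mol")

  ## malformed line is reported with its line number
  broken <- lines
  broken[10] <- paste0(broken[10], ",stray,fields")
  f4 <- tempfile(fileext = ".csv")
  writeLines(broken, f4)
  expect_error(readScanCsv(f4), "line 10")
})

test_that("relative SASA separates exposed surface from a buried core", {
  ## isolated residue: nothing occludes it
  one <- makeToyStructure(1, "extended", sequence = "L", seed = 9)
  s1 <- computeRelativeSasa(one)
  expect_gte(s1$relative_sasa, 0.8)
  ## compact bundle contains sites under the 0.2 burial cutoff
  sa <- computeRelativeSasa(bundle45())
  expect_true(any(sa$relative_sasa < 0.2))
  expect_equal(nrow(sa), 45)
  ## empty structure -> empty annotation
  st0 <- new("ProteinStructure", sourceId = "e", chain = "A",
             atoms = atoms(helix30())[0, ])
  expect_equal(nrow(computeRelativeSasa(st0)), 0)
})

test_that("burial classification uses >= 0.2 as exposed, boundary inclusive", {
  expect_identical(as.character(classifyBurial(c(0.25, 0.15, 0.2, 0))),
                   c("exposed", "buried", "exposed", "buried"))
  expect_error(classifyBurial(-0.1), "negative")
})
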