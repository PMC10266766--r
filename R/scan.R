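## Saturation-mutagenesis scanning and solvent-accessibility annotation.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue relative solvent-accessible surface area
#'
#' Rolling-probe (Shrake-Rupley) SASA with a 1.4 Angstrom probe over the
#' heavy atoms of the chain, summed per residue and divided by the Sander &
#' Rost maximum for the residue type. Values may slightly exceed 1 for
#' terminal or fully exposed residues and are deliberately not clipped.
#' SASA is computed on the stored chain only; other chains of the source
#' file were already excluded at parse time.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param probe probe radius, Angstrom
#' @param nPoints test points per atom sphere
#' @return data.frame with \code{residue_index}, \code{wt_aa},
#'   \code{abs_sasa} (A^2), \code{relative_sasa}; residue types without a
#'   reference maximum get \code{NA} relative SASA
#' @export
computeRelativeSasa <- function(structure, probe = 1.4, nPoints = 256) {
  a <- structure@atoms
  heavy <- a[a$element != "H", , drop = FALSE]
  if (nrow(heavy) == 0)
    return(data.frame(residue_index = integer(), wt_aa = character(),
                      abs_sasa = numeric(), relative_sasa = numeric()))
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  rad <- VDW_RADII[heavy$element]
  rad[is.na(rad)] <- 1.70
  er <- rad + probe
  pts <- fibonacci_sphere(nPoints)
  n <- nrow(xyz)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (er[i] + er)^2 & seq_len(n) != i)
    sp <- pts * er[i] + rep(xyz[i, ], each = nPoints)
    if (length(nb) == 0) {
      acc <- nPoints
    } else {
      buried <- rep(FALSE, nPoints)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < er[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    asa[i] <- 4 * pi * er[i]^2 * acc / nPoints
  }
  per_res <- tapply(asa, heavy$resno, sum)
  resno <- as.integer(names(per_res))
  ord <- match(unique(heavy$resno), resno)
  resno <- resno[ord]
  per_res <- as.numeric(per_res)[ord]
  aa <- suppressWarnings(
    bio3d::aa321(heavy$resid3[match(resno, heavy$resno)]))
  maxasa <- SANDER_ROST_MAX_ASA[aa]
  data.frame(residue_index = resno, wt_aa = aa, abs_sasa = per_res,
             relative_sasa = per_res / maxasa, stringsAsFactors = FALSE)
}

#' Classify burial from relative SASA
#'
#' A residue is exposed iff its relative SASA is at least \code{cutoff}
#' (default 0.2); the boundary value itself is exposed.
#'
#' @param relativeSasa numeric vector of relative SASA values (>= 0)
#' @param cutoff exposed/buried threshold
#' @return factor with levels \code{buried}, \code{exposed}
#' @export
classifyBurial <- function(relativeSasa, cutoff = 0.2) {
  if (any(relativeSasa < 0, na.rm = TRUE))
    stop("relative SASA cannot be negative")
  factor(ifelse(relativeSasa >= cutoff, "exposed", "buried"),
         levels = c("buried", "exposed"))
}

params_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  sprintf("%.8e", sum(v * v) + sum(v))
}

#' Saturation-mutagenesis scan of a structure
#'
#' For every scannable residue site: extract the masked local environment,
#' voxelize and blur it, embed it with the representation model, then build
#' features and predict the stability change for each of the 20 amino
#' acids. Rows are ordered by residue and then amino-acid alphabet; the
#' self-substitution row of each site is emitted with ddG fixed at 0 and
#' flagged, and wild-type cysteines are flagged (their predictions are
#' unreliable at disulfide positions but they are never dropped at
#' prediction time). The scan refuses to run when the representation model
#' and ensemble disagree on the grid specification.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param reprModel a \linkS4class{RepresentationModel}
#' @param ensemble a \linkS4class{DdgEnsemble}
#' @return a \linkS4class{ScanTable}
#' @export
saturationScan <- function(structure, reprModel, ensemble) {
  gs1 <- reprModel@gridSpec
  gs2 <- ensemble@gridSpec
  if (abs(gs1@radius - gs2@radius) > 1e-9 ||
      abs(gs1@voxelEdge - gs2@voxelEdge) > 1e-9 ||
      abs(gs1@blurSigma - gs2@blurSigma) > 1e-9)
    stop("GridSpec mismatch between representation model and ensemble")
  sites <- residueSites(structure)
  if (nrow(sites) == 0) stop("zero scannable sites")
  grids <- voxelizeSites(structure, sites, gs1, blur = TRUE)
  emb <- embedResidue(reprModel, grids)
  fermi <- ensemble@fermi
  self_score <- fermiTransform(0, fermi$beta, fermi$alpha)
  recs <- vector("list", nrow(sites))
  per_all <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    wt <- sites$wt_aa[i]
    feats <- buildFeatures(
      matrix(rep(emb[i, ], each = 20), nrow = 20, byrow = FALSE),
      rep(wt, 20), AA_ALPHABET, ensemble@aaFreq)
    pred <- predictDdg(ensemble, feats)
    is_self <- AA_ALPHABET == wt
    pred$score_fermi[is_self] <- self_score
    pred$ddg_kcal_per_mol[is_self] <- 0.0
    recs[[i]] <- data.frame(
      source_id = structure@sourceId, chain = sites$chain_id[i],
      residue_index = sites$residue_index[i], wt_aa = wt,
      mut_aa = AA_ALPHABET, score_fermi = pred$score_fermi,
      ddg_kcal_per_mol = pred$ddg_kcal_per_mol,
      wt_is_cysteine = wt == "C", self_substitution = is_self,
      stringsAsFactors = FALSE)
    per_all[[i]] <- attr(pred, "per_model_scores")
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  new("ScanTable", records = records, perModel = do.call(rbind, per_all),
      provenance = list(
        source_id = structure@sourceId, chain = structure@chain,
        n_sites = nrow(sites),
        grid = list(radius = gs1@radius, voxel_edge = gs1@voxelEdge,
                    blur_sigma = gs1@blurSigma),
        repr_checksum = params_checksum(reprModel@params),
        ensemble_checksum = params_checksum(ensemble@models)))
}

SCAN_CSV_COLUMNS <- c("source_id", "chain", "residue_index", "wt_aa",
                      "mut_aa", "score_fermi", "ddg_kcal_per_mol",
                      "wt_is_cysteine", "self_substitution")

#' Write a scan table to CSV
#'
#' Fixed column order with a comment header documenting the ddG units
#' (kcal/mol). ddG values are serialized with 4 decimals; Fermi scores with
#' 10 significant digits.
#'
#' @param table a \linkS4class{ScanTable}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeScanCsv <- function(table, path) {
  r <- table@records[, SCAN_CSV_COLUMNS]
  r$ddg_kcal_per_mol <- sprintf("%.4f", r$ddg_kcal_per_mol)
  r$score_fermi <- sprintf("%.10g", r$score_fermi)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# stabscan saturation scan",
               "# units: ddg kcal/mol",
               sprintf("# source_id: %s", table@provenance$source_id %||%
                         "NA")), con)
  write.csv(r, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scan table from CSV
#'
#' Round-trips the output of \code{\link{writeScanCsv}} (ddG at the
#' serialized 4-decimal precision). A file without the units header line is
#' accepted with a warning and assumed to be in kcal/mol. Malformed rows
#' raise an error naming the first offending line.
#'
#' @param path path to a scan CSV
#' @return a \linkS4class{ScanTable} (provenance holds the source id only)
#' @export
readScanCsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^# units:", lines)))
    warning("no units header found; assuming ddg in kcal/mol")
  body <- which(!grepl("^#", lines))
  if (length(body) == 0) stop("no CSV content in ", path)
  nf <- count.fields(textConnection(lines[body]), sep = ",")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("malformed scan CSV at line ", body[bad[1]], " of ", path)
  r <- read.csv(textConnection(lines[body]), stringsAsFactors = FALSE)
  miss <- setdiff(SCAN_CSV_COLUMNS, names(r))
  if (length(miss))
    stop("scan CSV missing columns: ", paste(miss, collapse = ", "))
  sid <- sub("^# source_id: ", "", grep("^# source_id:", lines,
                                        value = TRUE)[1])
  new("ScanTable", records = r[, SCAN_CSV_COLUMNS],
      perModel = matrix(numeric(), nrow = 0, ncol = 0),
      provenance = list(source_id = if (is.na(sid)) NULL else sid))
}
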