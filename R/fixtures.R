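## Seeded generators for toy structures, synthetic ddG landscapes and
## variant tables. These stand in for curated structure sets and
## physics-based reference calculations so that every other module is
## testable without external data. They are deliberately not physically
## realistic energetics: the ddG rule is a fixed deterministic function of
## residue identity and burial, which is exactly what makes recovery
## testable.

## Element of the single pseudo side-chain atom placed at the C-beta
## position. Residue identity is recoverable from environment composition
## because the element class is a function of residue type.
CB_ELEMENT <- c(
  A = "C", C = "S", D = "O", E = "O", F = "C", G = "C", H = "N", I = "C",
  K = "N", L = "C", M = "S", N = "O", P = "C", Q = "O", R = "N", S = "O",
  T = "O", V = "C", W = "N", Y = "O")

AA3 <- setNames(c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                  "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                  "THR", "VAL", "TRP", "TYR"), AA_ALPHABET)

## Kyte-Doolittle hydropathy and mean residue volumes (A^3); the synthetic
## ddG rule is built from these standard per-residue constants.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
AA_VOLUME <- c(
  A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
  H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
  P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6)

## Natural extension reference frame: place atom D given A, B, C with
## bond |C-D|, angle B-C-D and torsion A-B-C-D (degrees).
nerf_place <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  M <- cbind(bc, cross3(n, bc), n)
  C + as.numeric(M %*% (bond * c(-cos(th), sin(th) * cos(chi),
                                 sin(th) * sin(chi))))
}

## Backbone of one segment from ideal internal coordinates.
build_backbone <- function(n_res, phi, psi) {
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)[-1]) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  list(N = N, CA = CA, C = C)
}

## Run-structured random sequence: runs of a single residue type with
## geometric lengths (mean ~4), element class uniform, member within class
## weighted 2^-k. Local environments are therefore informative about the
## masked residue, which gives the representation model signal to learn at
## toy scale.
random_sequence <- function(n_res) {
  classes <- split(AA_ALPHABET, CB_ELEMENT[AA_ALPHABET])
  seqv <- character(0)
  while (length(seqv) < n_res) {
    cls <- classes[[sample.int(length(classes), 1)]]
    w <- 2^-(seq_along(cls) - 1)
    aa <- sample(cls, 1, prob = w / sum(w))
    len <- rgeom(1, 1 / 4) + 1
    seqv <- c(seqv, rep(aa, len))
  }
  seqv[seq_len(n_res)]
}

principal_axis_align <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc), symmetric = TRUE)
  R <- ev$vectors[, c(2, 3, 1)]  # principal axis -> z
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, ctr = ctr)
}

segment_atoms <- function(seqv, bb, resno_offset) {
  n_res <- length(seqv)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    aa <- seqv[i]
    Ni <- bb$N[i, ]; CAi <- bb$CA[i, ]; Ci <- bb$C[i, ]
    ## carbonyl O in the peptide plane, trans to the next amide N; the
    ## C-terminal residue reuses the ideal psi of the geometry
    psi_i <- if (i < n_res) dihedral4(Ni, CAi, Ci, bb$N[i + 1, ]) else -47
    O <- nerf_place(Ni, CAi, Ci, 1.231, 120.8, psi_i + 180)
    CB <- nerf_place(Ci, Ni, CAi, 1.530, 110.5, 122.6)
    at <- data.frame(
      atom_name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", CB_ELEMENT[[aa]]),
      x = c(Ni[1], CAi[1], Ci[1], O[1], CB[1]),
      y = c(Ni[2], CAi[2], Ci[2], O[2], CB[2]),
      z = c(Ni[3], CAi[3], Ci[3], O[3], CB[3]),
      stringsAsFactors = FALSE)
    if (i > 1) {
      H <- Ni + 1.01 * unitv(unitv(Ni - CAi) + unitv(Ni - bb$C[i - 1, ]))
      at <- rbind(at, data.frame(atom_name = "H", element = "H",
                                 x = H[1], y = H[2], z = H[3]))
    }
    at$resid3 <- AA3[[aa]]
    at$resno <- resno_offset + i
    rows[[i]] <- at
  }
  do.call(rbind, rows)
}

dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Generate a toy protein structure
#'
#' Builds a small protein with realistic backbone geometry from ideal
#' internal coordinates: \code{ideal_helix} (phi = -57, psi = -47),
#' \code{extended} (phi = psi = 180) or \code{compact_bundle} (three or
#' more packed antiparallel helices whose interior residues have relative
#' SASA below 0.2). Each residue carries backbone N/CA/C/O, an amide
#' hydrogen (except the N-terminus) and a single pseudo side-chain atom at
#' the C-beta position whose element depends on the residue type (S for
#' Cys/Met, O for Ser/Thr/Asp/Glu/Asn/Gln/Tyr, N for Lys/Arg/His/Trp, C
#' otherwise), so residue identity is recoverable from local environment
#' composition. Output is deterministic given \code{seed}.
#'
#' @param nResidues number of residues (>= 1)
#' @param geometry one of \code{"ideal_helix"}, \code{"extended"},
#'   \code{"compact_bundle"}
#' @param sequence a string of one-letter codes of length \code{nResidues},
#'   or \code{"random"} for a seeded run-structured random sequence
#' @param seed RNG seed
#' @param sourceId identifier stored with the structure
#' @param path optional path; when given, the structure is also written as
#'   a PDB file
#' @return a \linkS4class{ProteinStructure}
#' @export
makeToyStructure <- function(nResidues, geometry = c("ideal_helix",
                                                     "extended",
                                                     "compact_bundle"),
                             sequence = "random", seed = 1L,
                             sourceId = NULL, path = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(nResidues >= 1)
  set.seed(seed)
  seqv <- if (identical(sequence, "random")) random_sequence(nResidues)
          else strsplit(sequence, "")[[1]]
  if (length(seqv) != nResidues)
    stop("sequence length does not match nResidues")
  if (!all(seqv %in% AA_ALPHABET))
    stop("sequence contains non-canonical letters")

  if (geometry != "compact_bundle") {
    ang <- if (geometry == "ideal_helix") c(-57, -47) else c(180, 180)
    bb <- build_backbone(nResidues, ang[1], ang[2])
    atoms <- segment_atoms(seqv, bb, 0L)
  } else {
    n_helix <- max(3L, ceiling(nResidues / 18))
    sizes <- rep(nResidues %/% n_helix, n_helix)
    extra <- nResidues - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    if (any(sizes < 4)) stop("too few residues for a compact bundle")
    spacing <- 8.2
    angles <- 2 * pi * (seq_len(n_helix) - 1) / n_helix
    ring_r <- spacing / (2 * sin(pi / n_helix))
    parts <- vector("list", n_helix)
    off <- 0L
    for (h in seq_len(n_helix)) {
      bb <- build_backbone(sizes[h], -57, -47)
      al <- principal_axis_align(bb$CA)
      rot <- function(m) sweep(m, 2, al$ctr) %*% al$R
      bbh <- list(N = rot(bb$N), CA = rot(bb$CA), C = rot(bb$C))
      if (h %% 2 == 0) {       # antiparallel: flip about the x axis
        flip <- diag(c(1, -1, -1))
        bbh <- lapply(bbh, function(m) m %*% flip)
      }
      shift <- c(ring_r * cos(angles[h]), ring_r * sin(angles[h]), 0)
      bbh <- lapply(bbh, function(m) sweep(m, 2, shift, "+"))
      parts[[h]] <- segment_atoms(seqv[(off + 1):(off + sizes[h])], bbh,
                                  off)
      off <- off + sizes[h]
    }
    atoms <- do.call(rbind, parts)
  }
  atoms$chain_id <- "A"
  atoms$channel <- elementChannel(atoms$element)
  atoms <- atoms[, c("atom_name", "element", "channel", "resid3", "resno",
                     "chain_id", "x", "y", "z")]
  rownames(atoms) <- NULL
  st <- new("ProteinStructure",
            sourceId = sourceId %||% paste0("toy_", geometry, "_", seed),
            chain = "A", atoms = atoms)
  if (!is.null(path)) writeStructure(st, path)
  st
}

## The fixed deterministic ddG rule. Substitution severity d grows with
## hydropathy and volume differences; the wild-type scale s grows with
## wild-type volume; burial amplifies by (1 + b). A small negative offset
## leaves a tail of mildly stabilizing substitutions. Values concentrate in
## the [-1, 7] kcal/mol range that the downstream training focuses on.
DDG_RULE <- list(b_buried = 0.8, offset = 0.3,
                 w_hydro = 0.9, w_vol = 1.3)

synthetic_ddg_rule <- function(wt, mut, buried) {
  s <- 0.6 + AA_VOLUME[wt] / 228
  d <- ifelse(wt == mut, 0,
              DDG_RULE$w_hydro * abs(KD_HYDROPATHY[wt] - KD_HYDROPATHY[mut]) / 9 +
              DDG_RULE$w_vol * abs(AA_VOLUME[wt] - AA_VOLUME[mut]) / 167.7 +
              0.25)
  ifelse(wt == mut, 0,
         as.numeric(s * d * (1 + DDG_RULE$b_buried * buried) -
                    DDG_RULE$offset))
}

#' Generate a synthetic ddG training table for a structure
#'
#' Emits one row per (site, mutant) pair with
#' \code{ddg = s(wt) * d(wt, mut) * (1 + b * buried) - offset + noise},
#' where \code{s}, \code{d} and \code{b} are fixed tables published in the
#' package source (hydropathy/volume based), \code{buried} comes from the
#' structure's relative SASA (cutoff 0.2), and the noise is Gaussian with
#' standard deviation \code{noiseSd}. Self-substitutions, when requested,
#' are exactly 0. Deterministic given \code{seed}.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param seed RNG seed
#' @param noiseSd Gaussian noise standard deviation, kcal/mol
#' @param includeSelf also emit wt -> wt rows with ddg = 0
#' @param burial optional data.frame from \code{\link{computeRelativeSasa}}
#'   (computed from the structure when missing)
#' @return data.frame with columns \code{source_id}, \code{chain},
#'   \code{residue_index}, \code{wt_aa}, \code{mut_aa},
#'   \code{ddg_kcal_per_mol}, \code{ddg_true} (the noiseless value of the
#'   rule, the recovery target for parameter-recovery checks) and
#'   \code{buried}
#' @export
makeSyntheticDdg <- function(structure, seed = 1L, noiseSd = 0.2,
                             includeSelf = FALSE, burial = NULL) {
  sites <- residueSites(structure)
  if (nrow(sites) == 0) stop("structure has no scannable sites")
  if (is.null(burial)) burial <- computeRelativeSasa(structure)
  bur <- burial$relative_sasa[match(sites$residue_index,
                                    burial$residue_index)]
  if (any(is.na(bur))) stop("missing burial annotation for some sites")
  is_buried <- as.integer(classifyBurial(bur) == "buried")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    wt <- sites$wt_aa[i]
    muts <- if (includeSelf) AA_ALPHABET else setdiff(AA_ALPHABET, wt)
    data.frame(source_id = structure@sourceId, chain = sites$chain_id[i],
               residue_index = sites$residue_index[i], wt_aa = wt,
               mut_aa = muts, buried = is_buried[i],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  base <- synthetic_ddg_rule(tab$wt_aa, tab$mut_aa, tab$buried)
  noise <- rnorm(nrow(tab), 0, noiseSd)
  noise[tab$wt_aa == tab$mut_aa] <- 0
  tab$ddg_true <- base
  tab$ddg_kcal_per_mol <- base + noise
  tab[, c("source_id", "chain", "residue_index", "wt_aa", "mut_aa",
          "ddg_kcal_per_mol", "ddg_true", "buried")]
}

#' Generate a synthetic variant annotation table
#'
#' Samples variants from a ddG table and assigns a clinical class
#' (pathogenic with probability increasing in the true ddG) and an allele
#' frequency (log-uniform in [1e-6, 1e-1]). A stated fraction of rows are
#' emitted as decoys whose wild type is deliberately wrong, to exercise
#' join rejection downstream. Deterministic given \code{seed}.
#'
#' @param ddgTable data.frame from \code{\link{makeSyntheticDdg}}
#' @param seed RNG seed
#' @param n number of variants to sample (default: min(200, rows))
#' @param decoyRate fraction of rows with a mismatched wild type
#' @return data.frame with columns \code{protein_id}, \code{residue_index},
#'   \code{wt_aa}, \code{mut_aa}, \code{class}, \code{allele_frequency}
#' @export
makeVariantTable <- function(ddgTable, seed = 1L, n = NULL,
                             decoyRate = 0.1) {
  if (nrow(ddgTable) == 0) stop("empty ddG table")
  set.seed(seed)
  n <- n %||% min(200L, nrow(ddgTable))
  pick <- sample.int(nrow(ddgTable), n)
  v <- ddgTable[pick, , drop = FALSE]
  p_path <- stats::plogis(1.5 * (v$ddg_kcal_per_mol - 1.5))
  klass <- ifelse(runif(n) < p_path, "pathogenic", "benign")
  af <- 10^runif(n, -6, -1)
  wt <- v$wt_aa
  decoy <- runif(n) < decoyRate
  wt[decoy] <- vapply(wt[decoy], function(a)
    sample(setdiff(AA_ALPHABET, a), 1), character(1))
  data.frame(protein_id = v$source_id, residue_index = v$residue_index,
             wt_aa = wt, mut_aa = v$mut_aa, class = klass,
             allele_frequency = af, stringsAsFactors = FALSE)
}
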