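## Structure parsing and the atom-typing/cleaning contract.
##
## Protonation is deliberately NOT performed here: inputs are expected to be
## pre-processed externally (e.g. Reduce / PDBFixer). This module validates
## (warning when a file looks un-protonated) rather than fixing.

#' Map element symbols to input channels
#'
#' The voxel grids carry one occupancy channel per element, in the fixed
#' order C, N, O, H, S, P. The mapping is total: elements outside the
#' alphabet (metals, selenium, ...) map to \code{NA} ("no channel") rather
#' than erroring; such atoms are dropped during featurization.
#'
#' @param element character vector of element symbols (case-insensitive)
#' @return integer vector of 0-based channel indices, \code{NA} for elements
#'   outside the six-channel alphabet
#' @examples
#' elementChannel(c("C", "P", "FE"))   # 0, 5, NA
#' @export
elementChannel <- function(element) {
  idx <- match(toupper(trimws(element)), ELEMENT_ORDER)
  as.integer(idx - 1L)
}

guess_element <- function(atom_name) {
  ## PDB atom-name heuristic fallback when the element column is absent:
  ## strip digits/primes, take the first letter. Adequate for protein atoms.
  nm <- gsub("[^A-Za-z]", "", atom_name)
  toupper(substr(nm, 1, 1))
}

#' Read a single-chain protein structure from a PDB file
#'
#' Parses a PDB file (via bio3d), selects one chain and applies the cleaning
#' contract: waters and hetero-atoms are excluded, alternate locations other
#' than A are dropped, only model 1 of multi-model (NMR) files is used, and
#' residues without a canonical amino-acid mapping are skipped with a
#' warning. Atoms are typed into the six element channels; atoms of other
#' elements are kept in the table with \code{channel = NA} and a warning.
#' Residue numbering is the author numbering as deposited, never re-indexed,
#' so predictions can be joined against variant tables keyed by reference
#' numbering. A warning is emitted when fewer than 5\% of atoms are
#' hydrogens, a proxy for an un-protonated input.
#'
#' @param path path to a PDB file
#' @param chain chain identifier to extract (default: first chain in file)
#' @param sourceId identifier stored with the structure (default: file stem)
#' @return a \linkS4class{ProteinStructure}
#' @seealso \code{\link{residueSites}}, \code{\link{writeStructure}}
#' @export
readStructure <- function(path, chain = NULL, sourceId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_models <- length(grep("^MODEL ", readLines(path, warn = FALSE)))
  if (n_models > 1)
    warning("multi-model file: using model 1 of ", n_models)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("unknown chain '", chain, "' in ", path)
  at <- at[at$type == "ATOM", , drop = FALSE]

  if (nrow(at) > 0) {
    aa1 <- suppressWarnings(bio3d::aa321(at$resid))
    bad <- is.na(aa1) | aa1 == "X" | !(aa1 %in% AA_ALPHABET)
    if (any(bad)) {
      skipped <- unique(at$resid[bad])
      warning("skipping residues without canonical mapping: ",
              paste(skipped, collapse = ", "))
      at <- at[!bad, , drop = FALSE]
    }
  }
  if (nrow(at) == 0) stop("zero resolvable residues in chain '", chain, "'")

  element <- toupper(trimws(at$elesy))
  noelem <- is.na(element) | element == ""
  element[noelem] <- guess_element(at$elety[noelem])
  channel <- elementChannel(element)
  if (any(is.na(channel)))
    warning("atoms with elements outside the C/N/O/H/S/P alphabet kept with ",
            "no channel: ", paste(unique(element[is.na(channel)]),
                                  collapse = ", "))
  h_frac <- mean(element == "H")
  if (h_frac < 0.05)
    warning(sprintf(
      "only %.1f%% of atoms are hydrogens; structure may be un-protonated",
      100 * h_frac))

  atoms <- data.frame(
    atom_name = trimws(at$elety), element = element, channel = channel,
    resid3 = at$resid, resno = at$resno, chain_id = at$chain,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  new("ProteinStructure",
      sourceId = sourceId %||% sub("\\.pdb$", "", basename(path)),
      chain = chain, atoms = atoms)
}

#' Write a ProteinStructure back to PDB
#'
#' Coordinates are serialized at PDB precision (3 decimals); a write/read
#' round trip therefore reproduces coordinates to 1e-3 Angstrom.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid3, chain = a$chain_id,
    eleno = seq_len(nrow(a)), elety = a$atom_name, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Enumerate scannable residue sites
#'
#' One site per canonical residue with a complete N/C-alpha/C backbone, in
#' file order. Residues with an incomplete backbone are skipped with a
#' message. Sites carry the author residue numbering and the backbone
#' coordinates needed to build the local frame.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @return data.frame with columns \code{chain_id}, \code{residue_index},
#'   \code{wt_aa} and backbone coordinates \code{n_x..c_z} (Angstrom)
#' @export
residueSites <- function(structure) {
  a <- structure@atoms
  empty <- data.frame(chain_id = character(), residue_index = integer(),
                      wt_aa = character(),
                      n_x = numeric(), n_y = numeric(), n_z = numeric(),
                      ca_x = numeric(), ca_y = numeric(), ca_z = numeric(),
                      c_x = numeric(), c_y = numeric(), c_z = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0) return(empty)
  keys <- unique(a$resno)  # file order within the single chain
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    res <- a[a$resno == keys[i], , drop = FALSE]
    aa <- suppressWarnings(bio3d::aa321(res$resid3[1]))
    bb <- lapply(c("N", "CA", "C"), function(nm) {
      j <- which(res$atom_name == nm)
      if (length(j) == 0) NULL else as.numeric(res[j[1], c("x", "y", "z")])
    })
    if (any(vapply(bb, is.null, logical(1))) || !(aa %in% AA_ALPHABET)) {
      message("skipping residue ", keys[i], " (incomplete backbone or ",
              "non-canonical)")
      next
    }
    rows[[i]] <- data.frame(
      chain_id = res$chain_id[1], residue_index = keys[i], wt_aa = aa,
      n_x = bb[[1]][1], n_y = bb[[1]][2], n_z = bb[[1]][3],
      ca_x = bb[[2]][1], ca_y = bb[[2]][2], ca_z = bb[[2]][3],
      c_x = bb[[3]][1], c_y = bb[[3]][2], c_z = bb[[3]][3],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
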