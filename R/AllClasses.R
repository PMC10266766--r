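#' Voxel grid specification
#'
#' Geometry of the cubic occupancy grid used to featurize a residue's local
#' atomic environment: a sphere of \code{radius} Angstrom around the target
#' C-alpha is binned into cubic voxels of edge \code{voxelEdge} Angstrom, one
#' occupancy channel per element (C, N, O, H, S, P), then smoothed with an
#' isotropic Gaussian of width \code{blurSigma}. The cube is the minimal cube
#' circumscribing the sphere, so the side length in voxels is
#' \code{2 * radius / voxelEdge}.
#'
#' @slot radius sphere radius in Angstrom (default 9)
#' @slot voxelEdge voxel edge length in Angstrom (default 1)
#' @slot blurSigma Gaussian blur standard deviation in Angstrom (default 1)
#' @slot channels number of element channels (fixed at 6)
#' @exportClass GridSpec
setClass("GridSpec",
  representation(radius = "numeric", voxelEdge = "numeric",
                 blurSigma = "numeric", channels = "integer"),
  prototype(radius = 9, voxelEdge = 1, blurSigma = 1, channels = 6L))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@radius) != 1 || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(object@voxelEdge) != 1 || !is.finite(object@voxelEdge) ||
      object@voxelEdge <= 0)
    msg <- c(msg, "voxelEdge must be a single positive number")
  if (length(object@blurSigma) != 1 || !is.finite(object@blurSigma) ||
      object@blurSigma <= 0)
    msg <- c(msg, "blurSigma must be a single positive number")
  if (object@channels != 6L)
    msg <- c(msg, "channels is fixed at 6 (C, N, O, H, S, P)")
  if (length(msg) == 0) {
    side <- 2 * object@radius / object@voxelEdge
    if (abs(side - round(side)) > 1e-9)
      msg <- c(msg, "2 * radius / voxelEdge must be an integer voxel count")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param radius sphere radius, Angstrom
#' @param voxelEdge voxel edge, Angstrom
#' @param blurSigma Gaussian blur sigma, Angstrom
#' @return a \linkS4class{GridSpec}
#' @examples
#' gridSpec()            # the default 9 A / 1 A / sigma 1 A grid
#' sideVoxels(gridSpec())
#' @export
gridSpec <- function(radius = 9, voxelEdge = 1, blurSigma = 1) {
  new("GridSpec", radius = as.numeric(radius),
      voxelEdge = as.numeric(voxelEdge),
      blurSigma = as.numeric(blurSigma), channels = 6L)
}

#' @describeIn gridSpec number of voxels along one cube edge
#' @param spec a \linkS4class{GridSpec}
#' @export
sideVoxels <- function(spec) as.integer(round(2 * spec@radius / spec@voxelEdge))

#' Parsed protein structure
#'
#' A single chain of a protein structure with typed atoms. Atoms carry an
#' element channel index (0-based, order C, N, O, H, S, P; \code{NA} for
#' elements outside that alphabet), coordinates in Angstrom and residue
#' membership under the author numbering of the source file. Hetero-atoms,
#' waters and alternate locations other than A are dropped at parse time.
#'
#' @slot sourceId identifier of the source structure (file stem by default)
#' @slot chain the selected chain identifier
#' @slot atoms data.frame with columns \code{atom_name}, \code{element},
#'   \code{channel}, \code{resid3}, \code{resno}, \code{chain_id},
#'   \code{x}, \code{y}, \code{z}
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(sourceId = "character", chain = "character",
                 atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  need <- c("atom_name", "element", "channel", "resid3", "resno",
            "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    return("atom coordinates must all be finite")
  ch <- object@atoms$channel
  if (any(!is.na(ch) & (ch < 0L | ch > 5L)))
    return("element channels must be in 0..5 or NA")
  TRUE
})

#' Self-supervised residue-environment representation model
#'
#' A 3D convolutional network trained to classify the masked wild-type amino
#' acid of a residue from the voxelized local environment. The 100-node
#' fully-connected layer provides the latent residue representation consumed
#' by the downstream ddG regressor. The \linkS4class{GridSpec} the model was
#' trained with is stored alongside the parameters so that inference can
#' never silently mismatch featurization.
#'
#' @slot config architecture/training configuration (see
#'   \code{\link{representationConfig}})
#' @slot gridSpec the \linkS4class{GridSpec} the model expects
#' @slot params named list of parameter arrays
#' @slot history per-epoch training/validation metrics
#' @slot trained whether the parameters have been fit
#' @exportClass RepresentationModel
setClass("RepresentationModel",
  representation(config = "list", gridSpec = "GridSpec", params = "list",
                 history = "data.frame", trained = "logical"))

#' Downstream ddG ensemble
#'
#' An ensemble of fully-connected regressors predicting Fermi-transformed
#' stability changes from concatenated features (100-d environment
#' representation, wild-type and mutant one-hot encodings, and background
#' amino-acid frequencies). Predictions are the ensemble median in Fermi
#' space, mapped back to kcal/mol with the inverse Fermi transform.
#'
#' @slot models list of member parameter sets (one per seed)
#' @slot config training configuration (see \code{\link{downstreamConfig}})
#' @slot fermi list with elements \code{beta} and \code{alpha}
#' @slot aaFreq length-20 named amino-acid frequency vector
#' @slot gridSpec the \linkS4class{GridSpec} of the representation model the
#'   ensemble was trained against
#' @exportClass DdgEnsemble
setClass("DdgEnsemble",
  representation(models = "list", config = "list", fermi = "list",
                 aaFreq = "numeric", gridSpec = "GridSpec"))

setValidity("DdgEnsemble", function(object) {
  if (length(object@models) < 1) return("ensemble must contain >= 1 model")
  if (!all(c("beta", "alpha") %in% names(object@fermi)))
    return("fermi must carry beta and alpha")
  if (object@fermi$beta <= 0) return("fermi beta must be positive")
  if (length(object@aaFreq) != 20 ||
      !identical(names(object@aaFreq), AA_ALPHABET))
    return("aaFreq must be a length-20 vector named by the amino-acid alphabet")
  TRUE
})

#' Saturation-scan result table
#'
#' One row per (residue site, mutant amino acid): 20 rows per scanned site,
#' including a flagged self-substitution row with ddG fixed at 0. Per-model
#' Fermi-space scores are retained alongside the records, and a provenance
#' block records the structure, model checksums and grid configuration.
#'
#' @slot records data.frame with columns \code{source_id}, \code{chain},
#'   \code{residue_index}, \code{wt_aa}, \code{mut_aa}, \code{score_fermi},
#'   \code{ddg_kcal_per_mol}, \code{wt_is_cysteine}, \code{self_substitution}
#' @slot perModel matrix of per-member Fermi scores, rows aligned to records
#' @slot provenance list describing structure, models and configuration
#' @exportClass ScanTable
setClass("ScanTable",
  representation(records = "data.frame", perModel = "matrix",
                 provenance = "list"))

setValidity("ScanTable", function(object) {
  need <- c("source_id", "chain", "residue_index", "wt_aa", "mut_aa",
            "score_fermi", "ddg_kcal_per_mol", "wt_is_cysteine",
            "self_substitution")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  r <- object@records
  if (nrow(r) > 0) {
    per_site <- table(paste(r$source_id, r$chain, r$residue_index))
    if (any(per_site != 20))
      return("every scanned site must contribute exactly 20 rows")
    selfs <- tapply(r$self_substitution,
                    paste(r$source_id, r$chain, r$residue_index), sum)
    if (any(selfs != 1))
      return("every site must have exactly one self-substitution row")
    if (any(r$ddg_kcal_per_mol[r$self_substitution] != 0))
      return("self-substitution rows must have ddg exactly 0")
  }
  TRUE
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: radius %g A, voxel %g A (%d^3 voxels), 6 channels, blur sigma %g A\n",
    object@radius, object@voxelEdge, sideVoxels(object), object@blurSigma))
})

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s' chain %s: %d atoms, %d residues\n",
              object@sourceId, object@chain, nrow(object@atoms),
              length(unique(object@atoms$resno))))
})

setMethod("show", "RepresentationModel", function(object) {
  cat(sprintf(
    "RepresentationModel: conv filters (%s), fc (%s), %s\n",
    paste(object@config$conv_filters, collapse = ", "),
    paste(object@config$fc_sizes, collapse = ", "),
    if (object@trained) sprintf("trained (%d epochs recorded)",
                                nrow(object@history)) else "untrained"))
  show(object@gridSpec)
})

setMethod("show", "DdgEnsemble", function(object) {
  cat(sprintf(
    "DdgEnsemble: %d member model(s), fermi beta %g alpha %g kcal/mol\n",
    length(object@models), object@fermi$beta, object@fermi$alpha))
})

setMethod("show", "ScanTable", function(object) {
  r <- object@records
  cat(sprintf("ScanTable: %d rows (%d sites x 20 substitutions) for '%s'\n",
              nrow(r), nrow(r) %/% 20,
              object@provenance$source_id %||% "?"))
})

#' Accessors for stabscan objects
#'
#' @param x a \linkS4class{ProteinStructure} or \linkS4class{ScanTable}
#' @return \code{atoms} returns the atom table of a structure;
#'   \code{scanRecords} the record data.frame of a scan; \code{provenance}
#'   the provenance list of a scan.
#' @export
atoms <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  x@atoms
}

#' @rdname atoms
#' @export
scanRecords <- function(x) {
  stopifnot(is(x, "ScanTable"))
  x@records
}

#' @rdname atoms
#' @export
provenance <- function(x) {
  stopifnot(is(x, "ScanTable"))
  x@provenance
}
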