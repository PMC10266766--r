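## Checkpoint bundles. A representation checkpoint stores architecture,
## parameters and the GridSpec it was trained with; an ensemble checkpoint
## stores all member models plus the Fermi parameters, the frequency vector
## and the GridSpec. Keeping featurization config inside the checkpoint is
## what lets inference refuse a silent featurization mismatch.

#' Save / load model checkpoints
#'
#' @param object a \linkS4class{RepresentationModel} or
#'   \linkS4class{DdgEnsemble}
#' @param path checkpoint file path
#' @return \code{loadCheckpoint} returns the restored object;
#'   \code{saveCheckpoint} returns \code{path} invisibly
#' @export
saveCheckpoint <- function(object, path) {
  if (!is(object, "RepresentationModel") && !is(object, "DdgEnsemble"))
    stop("only RepresentationModel and DdgEnsemble checkpoints are supported")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "RepresentationModel") && !is(obj, "DdgEnsemble"))
    stop("not a stabscan checkpoint: ", path)
  validObject(obj)
  obj
}
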