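## Masked local-environment extraction and voxelization.
##
## All coordinates are expressed in a backbone local frame before binning,
## which is what makes the grids invariant to rigid motion of the input
## structure.

#' Backbone local frame of a residue site
#'
#' Orthonormal right-handed frame from the N/C-alpha/C backbone by
#' Gram-Schmidt: origin at C-alpha, first axis along N - CA, second the
#' component of C - CA orthogonal to it, third their cross product.
#'
#' @param site a single-row site as returned by \code{\link{residueSites}}
#' @return list with \code{origin} (length-3) and \code{axes} (3x3 matrix,
#'   rows are the axes)
#' @export
localFrame <- function(site) {
  stopifnot(nrow(site) == 1)
  n  <- as.numeric(site[1, c("n_x", "n_y", "n_z")])
  ca <- as.numeric(site[1, c("ca_x", "ca_y", "ca_z")])
  cc <- as.numeric(site[1, c("c_x", "c_y", "c_z")])
  a1 <- unitv(n - ca)
  v <- cc - ca
  rej <- v - sum(v * a1) * a1
  if (sqrt(sum(rej^2)) < 1e-6)
    stop("degenerate (collinear) backbone geometry at residue ",
         site$residue_index[1], " chain ", site$chain_id[1])
  a2 <- unitv(rej)
  a3 <- cross3(a1, a2)
  list(origin = ca, axes = rbind(a1, a2, a3, deparse.level = 0))
}

#' Extract the masked local atomic environment of a residue
#'
#' Returns every atom within \code{spec@radius} Angstrom of the site's
#' C-alpha, excluding all atoms of the target residue itself (masking) and
#' atoms without an element channel. Coordinates are expressed in the
#' backbone local frame of the site. An empty environment is legal.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param site a single-row site from \code{\link{residueSites}}
#' @param spec a \linkS4class{GridSpec}
#' @return data.frame with columns \code{channel} (0-based) and local
#'   coordinates \code{x}, \code{y}, \code{z} (Angstrom)
#' @export
extractEnvironment <- function(structure, site, spec = gridSpec()) {
  a <- structure@atoms
  frame <- localFrame(site)
  keep <- !is.na(a$channel) &
    !(a$chain_id == site$chain_id[1] & a$resno == site$residue_index[1])
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(channel = integer(), x = numeric(), y = numeric(),
                      z = numeric()))
  rel <- t(as.matrix(a[, c("x", "y", "z")])) - frame$origin
  d <- sqrt(colSums(rel^2))
  inside <- d <= spec@radius
  loc <- frame$axes %*% rel[, inside, drop = FALSE]
  data.frame(channel = a$channel[inside],
             x = loc[1, ], y = loc[2, ], z = loc[3, ])
}

#' Voxelize a local environment
#'
#' Each atom increments the voxel whose center is nearest its local
#' coordinates, in its element's channel (nearest-center binning; smoothing
#' is applied separately by \code{\link{gaussianBlur}}). The grid spans
#' \code{[-radius, radius]^3} with voxel centers at half-integer multiples
#' of the voxel edge.
#'
#' @param env environment data.frame from \code{\link{extractEnvironment}}
#' @param spec a \linkS4class{GridSpec}
#' @return numeric array of dim \code{c(6, S, S, S)} with
#'   \code{S = sideVoxels(spec)}
#' @export
voxelize <- function(env, spec = gridSpec()) {
  S <- sideVoxels(spec)
  grid <- array(0, dim = c(6L, S, S, S))
  if (nrow(env) == 0) return(grid)
  bin <- function(u) pmin(pmax(floor((u + spec@radius) / spec@voxelEdge) + 1,
                               1), S)
  ii <- cbind(env$channel + 1L, bin(env$x), bin(env$y), bin(env$z))
  for (k in seq_len(nrow(ii)))
    grid[ii[k, 1], ii[k, 2], ii[k, 3], ii[k, 4]] <-
      grid[ii[k, 1], ii[k, 2], ii[k, 3], ii[k, 4]] + 1
  grid
}

blur_kernel_1d <- function(sigma, edge) {
  r <- max(1L, as.integer(ceiling(2 * sigma / edge)))
  d <- (-r:r) * edge
  w <- exp(-d^2 / (2 * sigma^2))
  list(r = r, w = w / sum(w))
}

#' Gaussian blur of a voxel grid
#'
#' Separable per-channel convolution with an isotropic Gaussian kernel
#' truncated at 2 sigma and normalised to unit sum, so total per-channel
#' mass is conserved in the grid interior; mass blurred past the cube
#' boundary is lost.
#'
#' @param grid array of dim \code{c(6, S, S, S)} from \code{\link{voxelize}}
#' @param sigma Gaussian standard deviation, Angstrom; must be positive
#' @param spec the \linkS4class{GridSpec} of the grid
#' @return blurred array, same dim
#' @export
gaussianBlur <- function(grid, sigma, spec = gridSpec()) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  S <- dim(grid)[2]
  k <- blur_kernel_1d(sigma, spec@voxelEdge)
  K <- matrix(0, S, S)
  for (i in seq_len(S)) {
    j <- max(1, i - k$r):min(S, i + k$r)
    K[i, j] <- k$w[j - i + k$r + 1]
  }
  out <- grid
  for (ch in seq_len(dim(grid)[1])) {
    a <- grid[ch, , , ]
    a <- array(K %*% matrix(a, S, S * S), dim = c(S, S, S))          # x
    a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), S, S * S),
                     dim = c(S, S, S)), c(2, 1, 3))                  # y
    a <- aperm(array(K %*% matrix(aperm(a, c(3, 1, 2)), S, S * S),
                     dim = c(S, S, S)), c(2, 3, 1))                  # z
    out[ch, , , ] <- a
  }
  out
}

#' Featurize every site of a structure into blurred voxel grids
#'
#' Convenience wrapper: extracts, voxelizes and blurs the masked local
#' environment of each site.
#'
#' @param structure a \linkS4class{ProteinStructure}
#' @param sites data.frame from \code{\link{residueSites}} (default: all)
#' @param spec a \linkS4class{GridSpec}
#' @param blur apply Gaussian blurring with \code{spec@blurSigma}
#' @return array of dim \code{c(6, S, S, S, nrow(sites))}
#' @export
voxelizeSites <- function(structure, sites = residueSites(structure),
                          spec = gridSpec(), blur = TRUE) {
  S <- sideVoxels(spec)
  out <- array(0, dim = c(6L, S, S, S, nrow(sites)))
  for (i in seq_len(nrow(sites))) {
    g <- voxelize(extractEnvironment(structure, sites[i, , drop = FALSE],
                                     spec), spec)
    if (blur) g <- gaussianBlur(g, spec@blurSigma, spec)
    out[, , , , i] <- g
  }
  out
}

#' Featurize a set of structures into one stacked grid batch
#'
#' Runs \code{\link{voxelizeSites}} over every structure and concatenates
#' the results, keeping per-site bookkeeping needed for training and for
#' joining features back to variant tables.
#'
#' @param structures list of \linkS4class{ProteinStructure} objects
#' @param spec a \linkS4class{GridSpec}
#' @param blur apply Gaussian blurring
#' @return list with \code{grids} (\code{(6, S, S, S, N)} array),
#'   \code{labels} (wild-type one-letter codes), \code{proteins} (source
#'   ids) and \code{residue_index}
#' @export
voxelizeStructureSet <- function(structures, spec = gridSpec(),
                                 blur = TRUE) {
  stopifnot(length(structures) >= 1)
  sites_list <- lapply(structures, residueSites)
  n_each <- vapply(sites_list, nrow, integer(1))
  S <- sideVoxels(spec)
  grids <- array(0, dim = c(6L, S, S, S, sum(n_each)))
  off <- 0L
  for (i in seq_along(structures)) {
    if (n_each[i] == 0) next
    grids[, , , , (off + 1):(off + n_each[i])] <-
      voxelizeSites(structures[[i]], sites_list[[i]], spec, blur)
    off <- off + n_each[i]
  }
  list(grids = grids,
       labels = unlist(lapply(sites_list, `[[`, "wt_aa"),
                       use.names = FALSE),
       proteins = rep(vapply(structures, function(s) s@sourceId,
                             character(1)), n_each),
       residue_index = unlist(lapply(sites_list, `[[`, "residue_index"),
                              use.names = FALSE))
}
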