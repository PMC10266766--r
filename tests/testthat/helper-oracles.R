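# Independent brute-force oracle for voxelization: for every atom, scan all
# voxel centers and take the nearest. Shares no code with voxelize().

brute_force_voxelize <- function(env, spec = gridSpec()) {
  S <- sideVoxels(spec)
  centers <- -spec@radius + (seq_len(S) - 0.5) * spec@voxelEdge
  cgrid <- as.matrix(expand.grid(x = centers, y = centers, z = centers))
  grid <- array(0, dim = c(6L, S, S, S))
  idx <- as.matrix(expand.grid(i = seq_len(S), j = seq_len(S),
                               k = seq_len(S)))
  for (a in seq_len(nrow(env))) {
    d2 <- (cgrid[, 1] - env$x[a])^2 + (cgrid[, 2] - env$y[a])^2 +
      (cgrid[, 3] - env$z[a])^2
    best <- idx[which.min(d2), ]
    ch <- env$channel[a] + 1L
    grid[ch, best[1], best[2], best[3]] <-
      grid[ch, best[1], best[2], best[3]] + 1
  }
  grid
}
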