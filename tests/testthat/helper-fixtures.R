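# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

helix30 <- function() cached("helix30", function()
  makeToyStructure(30, "ideal_helix", seed = 11, sourceId = "helix30"))

bundle45 <- function() cached("bundle45", function()
  makeToyStructure(45, "compact_bundle", seed = 7, sourceId = "bundle45"))

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(st, R, shift) {
  a <- atoms(st)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("ProteinStructure", sourceId = st@sourceId, chain = st@chain,
      atoms = a)
}

## seeded random environment: n atoms uniform in the 9 A sphere
random_environment <- function(n, spec = gridSpec()) {
  r <- spec@radius * runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  data.frame(channel = sample(0:5, n, replace = TRUE),
             x = r * u[, 1], y = r * u[, 2], z = r * u[, 3])
}
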