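test_that("local frame is orthonormal, right-handed and equivariant", {
  st <- helix30()
  sites <- residueSites(st)
  fr <- localFrame(sites[10, , drop = FALSE])
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-8)
  expect_equal(fr$origin,
               as.numeric(sites[10, c("ca_x", "ca_y", "ca_z")]))

  ## translation moves the origin, not the axes
  sh <- sites[10, , drop = FALSE]
  for (cc in c("n_x", "ca_x", "c_x")) sh[[cc]] <- sh[[cc]] + 10
  fr_t <- localFrame(sh)
  expect_equal(fr_t$axes, fr$axes, tolerance = 1e-10)
  expect_equal(fr_t$origin, fr$origin + c(10, 0, 0), tolerance = 1e-10)

  ## rotation rotates the axes by the same rotation
  set.seed(4)
  R <- random_rotation()
  sr <- sites[10, , drop = FALSE]
  for (at in c("n", "ca", "c")) {
    v <- as.numeric(sr[, paste0(at, c("_x", "_y", "_z"))])
    sr[, paste0(at, c("_x", "_y", "_z"))] <- as.numeric(R %*% v)
  }
  fr_r <- localFrame(sr)
  expect_equal(fr_r$axes, fr$axes %*% t(R), tolerance = 1e-8)
})

test_that("collinear backbone raises an error naming the residue", {
  st <- helix30()
  s <- residueSites(st)[5, , drop = FALSE]
  ## place C on the N-CA line
  d <- as.numeric(s[, c("n_x", "n_y", "n_z")]) -
    as.numeric(s[, c("ca_x", "ca_y", "ca_z")])
  cc <- as.numeric(s[, c("ca_x", "ca_y", "ca_z")]) + 2 * d
  s[, c("c_x", "c_y", "c_z")] <- as.list(cc)
  expect_error(localFrame(s), "residue 5")
})

test_that("environment extraction masks the target residue and respects the radius", {
  st <- helix30()
  sites <- residueSites(st)
  spec <- gridSpec()
  env <- extractEnvironment(st, sites[15, , drop = FALSE], spec)
  expect_true(all(sqrt(env$x^2 + env$y^2 + env$z^2) <= spec@radius + 1e-12))

  ## brute-force recount: atoms within 9 A of CA minus the residue's own
  a <- atoms(st)
  ca <- as.numeric(sites[15, c("ca_x", "ca_y", "ca_z")])
  d <- sqrt((a$x - ca[1])^2 + (a$y - ca[2])^2 + (a$z - ca[3])^2)
  expected <- sum(d <= spec@radius & a$resno != 15 & !is.na(a$channel))
  expect_equal(nrow(env), expected)
  ## no atom of the target residue contributes
  own <- a[a$resno == 15, ]
  expect_true(nrow(env) < sum(d <= spec@radius & !is.na(a$channel)))

  ## single-residue structure: everything is the target's -> empty
  one <- makeToyStructure(1, "extended", sequence = "A", seed = 3)
  s1 <- residueSites(one)
  expect_equal(nrow(extractEnvironment(one, s1[1, , drop = FALSE], spec)),
               0)
})

test_that("an atom just outside the sphere is excluded, just inside included", {
  spec <- gridSpec()
  st <- helix30()
  sites <- residueSites(st)
  site <- sites[1, , drop = FALSE]
  ca <- as.numeric(site[, c("ca_x", "ca_y", "ca_z")])
  base <- atoms(st)[1, ]
  mk <- function(dist) {
    a <- base
    a$resno <- 999L
    a$x <- ca[1] + dist; a$y <- ca[2]; a$z <- ca[3]
    st2 <- new("ProteinStructure", sourceId = "probe", chain = "A",
               atoms = rbind(atoms(st)[atoms(st)$resno == 1, ], a))
    nrow(extractEnvironment(st2, site, spec))
  }
  expect_equal(mk(9.5), 0)   # outside 9 A
  expect_equal(mk(8.9), 1)   # inside
})

test_that("voxelize bins to the nearest half-integer center", {
  spec <- gridSpec()
  env <- data.frame(channel = 0L, x = 0.2, y = 0.2, z = 0.2)
  g <- voxelize(env, spec)
  expect_equal(sum(g), 1)
  ## voxel centered at (0.5, 0.5, 0.5): index 10 along each axis
  expect_equal(g[1, 10, 10, 10], 1)
  ## empty environment -> all zeros
  e0 <- data.frame(channel = integer(), x = numeric(), y = numeric(),
                   z = numeric())
  expect_equal(sum(voxelize(e0, spec)), 0)
  expect_equal(dim(voxelize(e0, spec)), c(6, 18, 18, 18))
})

test_that("voxelize equals the brute-force oracle on 100 random environments", {
  spec <- gridSpec()
  set.seed(101)
  for (i in 1:100) {
    env <- random_environment(sample(5:60, 1), spec)
    expect_identical(voxelize(env, spec), brute_force_voxelize(env, spec))
  }
})

test_that("per-channel sums equal in-sphere atom counts without blur", {
  spec <- gridSpec()
  set.seed(7)
  env <- random_environment(40, spec)
  g <- voxelize(env, spec)
  for (ch in 0:5)
    expect_equal(sum(g[ch + 1, , , ]), sum(env$channel == ch))
})

test_that("gaussian blur conserves interior mass and has a delta limit", {
  spec <- gridSpec()
  ## all-zero grid stays zero
  z <- array(0, dim = c(6, 18, 18, 18))
  expect_equal(gaussianBlur(z, 1, spec), z)
  ## unit mass at the cube center survives blurring
  g <- z
  g[3, 9, 9, 9] <- 1
  gb <- gaussianBlur(g, 1, spec)
  expect_equal(sum(gb[3, , , ]), 1, tolerance = 1e-6)
  expect_equal(sum(gb[-3, , , ]), 0)
  ## sigma -> 0 limit reproduces the input
  expect_equal(gaussianBlur(g, 1e-3, spec), g, tolerance = 1e-6)
  ## non-positive sigma is an error
  expect_error(gaussianBlur(g, 0, spec), "positive")
  expect_error(gaussianBlur(g, -1, spec), "positive")
})

test_that("blurred voxel grids are invariant under rigid motion", {
  st <- helix30()
  spec <- gridSpec()
  sites <- residueSites(st)
  pick <- c(1, 8, 15, 22, 30)
  g0 <- voxelizeSites(st, sites[pick, ], spec, blur = TRUE)
  set.seed(12)
  R <- random_rotation()
  st2 <- transform_structure(st, R, c(11.3, -4.2, 7.9))
  sites2 <- residueSites(st2)
  g1 <- voxelizeSites(st2, sites2[pick, ], spec, blur = TRUE)
  expect_lt(max(abs(g0 - g1)), 1e-6)
})
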