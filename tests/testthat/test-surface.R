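test_that("signed distance field calibrates the half-voxel boundary offset", {
  a <- array(0L, c(7, 7, 7)); a[4, 4, 4] <- 1L
  v <- label_volume(a, spacing = c(0.1, 0.1, 0.1))
  phi <- mask_to_levelset(v)
  expect_equal(min(phi$values), -0.05, tolerance = 1e-9)
  expect_equal(which.min(phi$values), which(a == 1L))
  # digital ball of radius 1 mm: centre value close to -1 mm
  g <- seq(-1.4, 1.4, by = 0.1)
  ball <- array(as.integer(outer(outer(g^2, g^2, `+`), g^2, `+`) <= 1), rep(length(g), 3))
  phib <- mask_to_levelset(label_volume(ball, spacing = rep(0.1, 3), origin = rep(-1.4, 3)))
  expect_lt(abs(min(phib$values) + 1), 0.1 + 1e-9)
  expect_error(mask_to_levelset(label_volume(array(1L, c(3, 3, 3)))), "whole grid")
  expect_error(mask_to_levelset(label_volume(array(0L, c(3, 3, 3)))), "empty")
})

test_that("refinement is the identity at zero iterations and preserves planes", {
  g <- seq(-1, 1, by = 0.1)
  n <- length(g)
  plane <- structure(list(values = array(rep(g, each = 1, times = n * n), c(n, n, n)),
                          spacing = rep(0.1, 3), origin = rep(-1, 3)),
                     class = "levelset_field")
  expect_identical(refine_levelset(plane, 0), plane)
  ref <- refine_levelset(plane, 5)
  # a flat interface has zero curvature everywhere: nothing moves
  expect_lt(max(abs(ref$values - plane$values)), 1e-10)
  expect_error(refine_levelset(plane, -1), "non-negative")
})

test_that("refinement reduces boundary roughness within the fidelity band", {
  set.seed(3)
  g <- seq(-1.4, 1.4, by = 0.1)
  n <- length(g)
  pts <- as.matrix(expand.grid(g, g, g))
  r <- sqrt(rowSums(pts^2))
  ball <- array(as.integer(r <= 1), c(n, n, n))
  # checkerboard flips on the boundary shell
  shell <- abs(r - 1) < 0.08
  parity <- (rowSums(round(pts / 0.1)) %% 2) == 0
  noisy <- ball
  noisy[shell & parity] <- 1L - noisy[shell & parity]
  v <- label_volume(noisy, spacing = rep(0.1, 3), origin = rep(-1.4, 3))
  phi <- mask_to_levelset(v)
  band <- 0.5 * 0.1
  ref <- refine_levelset(phi, iterations = 2, smooth_weight = 0.5, fidelity_band = band)
  expect_lte(max(abs(ref$values - phi$values)), band + 1e-12)
  rms_sphere <- function(ls) {
    m <- marching_cubes(ls)
    sqrt(mean((sqrt(rowSums(m$vertices^2)) - 1)^2))
  }
  expect_lt(rms_sphere(ref), rms_sphere(phi))
})

test_that("iso-surfacing yields watertight meshes with accurate volume", {
  phi <- sdf_field(sphere_sdf(1), lim = 1.3, h = 0.05)
  m <- marching_cubes(phi)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 4 * pi / 3, tolerance = 0.02)
  expect_error(marching_cubes(sdf_field(function(p) rep(1, nrow(p)), lim = 0.2, h = 0.1)),
               "empty surface")
})

test_that("a single voxel meshes to a closed genus-0 surface of sane volume", {
  a <- array(0L, c(7, 7, 7)); a[4, 4, 4] <- 1L
  v <- label_volume(a, spacing = rep(0.1, 3))
  m <- marching_cubes(mask_to_levelset(v))
  expect_true(is_watertight(m))
  # Euler characteristic 2 for genus 0
  ne <- nrow(m$faces) * 3 / 2
  expect_equal(nrow(m$vertices) - ne + nrow(m$faces), 2)
  vol <- mesh_volume(m)
  # mid-edge crossings around an isolated voxel bound the enclosed solid
  # below by the dual octahedron (1/6 of the voxel) and above by the voxel
  expect_gt(vol, (1 / 6) * 0.1^3)
  expect_lt(vol, 1.5 * 0.1^3)
})

test_that("windowed-sinc smoothing attenuates noise with little shrinkage", {
  mesh <- icosphere(1, 4)
  expect_identical(windowed_sinc_smooth(mesh, 0), mesh)
  sm <- windowed_sinc_smooth(mesh, 20, 0.1)
  expect_identical(sm$faces, mesh$faces)
  expect_lt(abs(mesh_volume(sm) - mesh_volume(mesh)) / mesh_volume(mesh), 0.01)
  set.seed(8)
  noisy <- mesh
  jitter <- 1 + stats::rnorm(nrow(mesh$vertices), sd = 0.05)
  noisy$vertices <- mesh$vertices * jitter
  rms <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) - 1)^2))
  expect_lt(rms(windowed_sinc_smooth(noisy, 20, 0.1)), rms(noisy))
  expect_error(windowed_sinc_smooth(mesh, 10, 2.5), "passband")
})

test_that("mesh volume is exact on the unit cube and sign-aware", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  expect_equal(mesh_volume(icosphere(1, 4)), 4 * pi / 3, tolerance = 0.005)
  inward <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(inward), 1, tolerance = 1e-12)        # auto-fix
  expect_error(mesh_volume(inward, fix_orientation = FALSE), "inward")
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "watertight")
})

test_that("end-to-end reconstruction conserves phantom volume within 3%", {
  ph <- cached_chain()
  for (lab in c(malleus = 1L, incus = 2L)) {
    mask <- extract_label_mask(ph$volume, lab)
    rs <- reconstruct_surface(mask)
    nm <- names(which(c(malleus = 1L, incus = 2L) == lab))
    expect_lt(abs(rs$qc$mesh_volume_mm3 - rs$qc$voxel_volume_mm3) /
                ph$truth$volumes[[nm]], 0.03)
  }
})
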