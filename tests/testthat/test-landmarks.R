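# Landmark recovery on phantoms with analytic ground truth.

d3 <- function(p, q) sqrt(sum((p - q)^2))

test_that("malleus landmarks recover within two voxels in any pose", {
  ph <- cached_chain()
  tr <- ph$truth
  res <- cached_chain_measured()
  f <- res$landmarks$malleus
  for (nm in c("A", "B", "C"))
    expect_point_close(f$points[[nm]], tr$landmarks[[nm]], 0.2)
  expect_lt(abs(d3(f$points$A, f$points$C) -
                  tr$parameters[["malleus_total_height_AC"]]), 0.2)
  expect_lt(abs(d3(f$points$B, f$points$C) -
                  tr$parameters[["malleus_manubrium_BC"]]), 0.2)
  expect_lt(abs(d3(f$points$A, f$points$B) -
                  tr$parameters[["malleus_head_neck_AB"]]), 0.2)
})

test_that("landmark distances are rigid-invariant", {
  # the same phantom in two poses yields the same distances within a voxel
  pose <- rigid_pose(rotation_about(c(1, 2, 0.5), 65), c(0.03, -0.02, 0.04))
  ph2 <- generate_chain_phantom(spacing = 0.1, pose = pose)
  r2 <- measure_chain(ph2$volume)
  r1 <- cached_chain_measured()
  for (nm in ossimetry:::measurement_names[1:8]) {
    expect_lt(abs(r1$measurements[[nm]] - r2$measurements[[nm]]), 0.1)
  }
  expect_lt(abs(r1$measurements$incudostapedial_angle_DGI -
                  r2$measurements$incudostapedial_angle_DGI), 2.5)
})

test_that("incus landmarks recover and D/G orientation follows the stapes", {
  ph <- cached_chain()
  tr <- ph$truth
  f <- cached_chain_measured()$landmarks$incus
  for (nm in c("D", "E", "F", "G"))
    expect_point_close(f$points[[nm]], tr$landmarks[[nm]], 0.2)
})

test_that("stapes landmarks recover; tilt and perforation barely move HJ", {
  cfg <- measure_config()
  base <- generate_stapes_phantom(stapes_spec(), spacing = 0.1)
  run <- function(ph) {
    mask <- ph$volume
    rs <- reconstruct_surface(mask, cfg)
    locate_stapes_landmarks(rs$mesh, config = cfg)
  }
  f0 <- run(base)
  expect_point_close(f0$points$I, base$truth$landmarks$I, 0.2)
  hj0 <- d3(f0$points$H, f0$points$J)
  expect_lt(abs(hj0 - base$truth$parameters[["stapes_footplate_HJ"]]), 0.15)
  gi0 <- d3(f0$points$G_s, f0$points$I)
  expect_lt(abs(gi0 - base$truth$parameters[["stapes_total_height_GI"]]), 0.2)

  perf <- generate_stapes_phantom(stapes_spec(perforation_radius = 0.3), spacing = 0.1)
  fp <- run(perf)
  expect_lt(abs(d3(fp$points$H, fp$points$J) - hj0) / hj0, 0.01)

  tilt <- generate_stapes_phantom(stapes_spec(footplate_tilt_deg = 20), spacing = 0.1)
  ft <- run(tilt)
  expect_lt(abs(d3(ft$points$H, ft$points$J) - hj0) / hj0, 0.01)
  expect_lt(abs(d3(ft$points$G_s, ft$points$I) -
                  tilt$truth$parameters[["stapes_total_height_GI"]]), 0.2)
})

test_that("missing anatomy produces the documented hard errors", {
  # malleus without a lateral process: detectable B is gone
  ph <- generate_chain_phantom(spacing = 0.1)
  mask <- extract_label_mask(ph$volume, 1L)
  rs <- reconstruct_surface(mask)
  cm <- compute_vertex_curvatures(rs$mesh)
  # fake spec-level absence by measuring a bump-free solid
  sp <- malleus_spec(lateral_bump_radius = 0)
  b <- ossimetry:::build_malleus(sp)
  ras <- ossimetry:::rasterize_solids(list(b$prims), 1L, 0.1)
  rs2 <- reconstruct_surface(ras$volume)
  expect_error(locate_malleus_landmarks(rs2$mesh), "landmark-B-not-found")

  # stapes without its footplate: no planar cluster
  nofp <- generate_stapes_phantom(stapes_spec(), spacing = 0.1, footplate = FALSE)
  rs3 <- reconstruct_surface(nofp$volume)
  expect_error(locate_stapes_landmarks(rs3$mesh), "footplate-not-found")
})
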