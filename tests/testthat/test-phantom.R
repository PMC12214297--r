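d3 <- function(p, q) sqrt(sum((p - q)^2))

test_that("ground-truth landmark distances equal the stored parameters", {
  tr <- cached_chain()$truth
  lm <- tr$landmarks
  pairs <- list(
    malleus_total_height_AC = c("A", "C"), malleus_manubrium_BC = c("B", "C"),
    malleus_head_neck_AB = c("A", "B"), incus_total_height_DG = c("D", "G"),
    incus_total_width_EF = c("E", "F"), incus_process_distance_FG = c("F", "G"),
    stapes_total_height_GI = c("G_s", "I"), stapes_footplate_HJ = c("H", "J"))
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    expect_equal(d3(lm[[p[1]]], lm[[p[2]]]), unname(tr$parameters[nm]),
                 tolerance = 1e-9, info = nm)
  }
  expect_equal(unname(tr$parameters["incudostapedial_angle_DGI"]),
               joint_angle(lm$D, lm$G, lm$I), tolerance = 1e-9)
})

test_that("defaults are sized to the cohort's automated means", {
  tr <- cached_chain()$truth
  expect_equal(unname(tr$parameters["malleus_total_height_AC"]), 7.91)
  expect_equal(unname(tr$parameters["incus_total_height_DG"]), 6.56)
  expect_equal(unname(tr$parameters["stapes_total_height_GI"]), 3.25)
  expect_equal(unname(tr$parameters["stapes_footplate_HJ"]), 2.63)
  expect_equal(unname(tr$parameters["incudostapedial_angle_DGI"]), 96.83)
})

test_that("rigid poses move landmarks but not parameters", {
  set.seed(11)
  for (rep in 1:3) {
    pose <- random_pose(2)
    base <- generate_malleus_phantom(malleus_spec(), spacing = 0.1)
    posed <- generate_malleus_phantom(malleus_spec(pose = pose), spacing = 0.1)
    expect_equal(posed$truth$parameters, base$truth$parameters, tolerance = 1e-9)
    expect_gt(d3(posed$truth$landmarks$A, base$truth$landmarks$A), 1e-3)
    for (nm in c("A", "B", "C"))
      expect_point_close(posed$truth$landmarks[[nm]],
                         as.numeric(pose$R %*% base$truth$landmarks[[nm]] + pose$t), 1e-9)
  }
})

test_that("voxel volume converges to the analytic volume as spacing shrinks", {
  # generic pose: axis-aligned solids alias against the grid and make the
  # error non-monotone at coarse spacings
  pose <- rigid_pose(rotation_about(c(1, 0.6, 0.3), 28), c(0.013, 0.007, 0.011))
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    ph <- generate_malleus_phantom(malleus_spec(pose = pose), spacing = h)
    abs(ph$truth$voxel_counts[["malleus"]] * h^3 - ph$truth$volumes[["malleus"]]) /
      ph$truth$volumes[["malleus"]]
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12 + 0))   # monotone non-increasing
  expect_lt(errs[3], 0.02)                    # within 2% at 0.05 mm
})

test_that("closed-form union volumes agree with fine quadrature", {
  bm <- ossimetry:::build_malleus(malleus_spec())
  expect_equal(ossimetry:::solid_volume_quadrature(bm$prims, h = 0.025),
               bm$volume, tolerance = 0.005)
  bi <- ossimetry:::build_incus(incus_spec())
  expect_equal(ossimetry:::solid_volume_quadrature(bi$prims, h = 0.025),
               bi$volume, tolerance = 0.005)
})

test_that("incus right-angle construction gives FG = L * sqrt(2)", {
  # equal junction-to-tip lengths L and a 90 degree inter-process angle;
  # DG is not the maximal extent of this synthetic solid, which the
  # constructor flags
  r_b <- 1.1; L <- 4
  expect_warning(
    sp <- incus_spec(total_height_DG = L + r_b, total_width_EF = L + r_b,
                     process_distance_FG = L * sqrt(2), body_radius = r_b),
    "maximum incus extent")
  expect_equal(sp$theta, pi / 2, tolerance = 1e-12)
  b <- ossimetry:::build_incus(sp)
  expect_equal(d3(b$landmarks$F, b$landmarks$G), L * sqrt(2), tolerance = 1e-12)
})

test_that("bump-free malleus refuses with the missing landmark named", {
  expect_error(generate_malleus_phantom(malleus_spec(lateral_bump_radius = 0)),
               "landmark B")
})

test_that("stapes perforation and tilt leave the ground-truth HJ unchanged", {
  base <- ossimetry:::build_stapes(stapes_spec())
  perf <- ossimetry:::build_stapes(stapes_spec(perforation_radius = 0.3))
  tilt <- ossimetry:::build_stapes(stapes_spec(footplate_tilt_deg = 20))
  expect_equal(d3(perf$landmarks$H, perf$landmarks$J),
               d3(base$landmarks$H, base$landmarks$J), tolerance = 1e-12)
  expect_equal(d3(tilt$landmarks$H, tilt$landmarks$J),
               d3(base$landmarks$H, base$landmarks$J), tolerance = 1e-12)
  # tilt rotates H and J
  expect_gt(d3(tilt$landmarks$H, base$landmarks$H), 0.01)
  # perforation leaves a through-hole: fewer voxels than the intact plate
  vi <- generate_stapes_phantom(stapes_spec(), spacing = 0.1)
  vp <- generate_stapes_phantom(stapes_spec(perforation_radius = 0.3), spacing = 0.1)
  expect_lt(vp$truth$voxel_counts[["stapes"]], vi$truth$voxel_counts[["stapes"]])
})

test_that("chain placement honours the requested joint angle", {
  for (ang in c(90, 96.83, 110)) {
    ch <- generate_chain_phantom(joint_angle_deg = ang, spacing = 0.1)
    lm <- ch$truth$landmarks
    expect_equal(joint_angle(lm$D, lm$G, lm$I), ang, tolerance = 1e-9)
  }
  expect_error(generate_chain_phantom(joint_angle_deg = 180), "collinear")
  expect_error(generate_chain_phantom(joint_angle_deg = 0), "collinear")
})

test_that("too-coarse rasterization is refused", {
  expect_error(generate_stapes_phantom(spacing = 0.2), "resolution")
})

test_that("perturb_volume flips only boundary voxels, reproducibly", {
  ph <- cached_chain()
  expect_identical(perturb_volume(ph$volume, 0)$data, ph$volume$data)
  p1 <- perturb_volume(ph$volume, 0.2, seed = 5)
  p2 <- perturb_volume(ph$volume, 0.2, seed = 5)
  expect_identical(p1$data, p2$data)
  changed <- which(p1$data != ph$volume$data)
  expect_gt(length(changed), 0)
  # independent boundary recomputation: a changed voxel must have both
  # foreground and background in its 6-neighbourhood
  a <- ph$volume$data
  dm <- dim(a)
  for (ix in changed[seq_len(min(200, length(changed)))]) {
    idx <- arrayInd(ix, dm)
    nb <- c()
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      j <- idx; j[ax] <- j[ax] + dd
      if (all(j >= 1L) && all(j <= dm)) nb <- c(nb, a[j[1], j[2], j[3]])
    }
    expect_true(any(nb == 0L) && any(c(nb, a[idx[1], idx[2], idx[3]]) != 0L))
  }
  expect_error(perturb_volume(ph$volume, 0.7), "0.5")
})
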