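test_that("curvature maps match analytic values on spheres and planes", {
  m <- icosphere(2, 3)
  curv <- compute_vertex_curvatures(m)
  expect_equal(mean(curv$gaussian), 0.25, tolerance = 0.05 * 0.25)
  expect_true(all(curv$mean > 0))      # convex
  expect_equal(mean(curv$mean), 0.5, tolerance = 0.05)
  # Gauss-Bonnet on closed genus-0 meshes: total angle deficit = 4*pi
  for (mesh in list(m, icosphere(0.7, 2), unit_cube_mesh())) {
    cv <- compute_vertex_curvatures(mesh)
    expect_equal(sum(cv$angle_deficit), 4 * pi, tolerance = 1e-6)
  }
})

test_that("flat interior vertices have zero Gaussian curvature", {
  # a cube mesh's face-interior subdivision: use a flat triangulated patch
  # folded into a closed box via the unit cube refined once
  g <- seq(0, 1, by = 0.25)
  # subdivide the top face of a box: build a closed surface from two grids
  nx <- length(g)
  idx <- function(i, j, top) (top * nx * nx) + (j - 1) * nx + i
  V <- rbind(as.matrix(expand.grid(g, g)), as.matrix(expand.grid(g, g)))
  V <- cbind(V, rep(c(0, 0.5), each = nx * nx))
  F <- NULL
  for (i in seq_len(nx - 1)) for (j in seq_len(nx - 1)) {
    a <- idx(i, j, 0); b <- idx(i + 1, j, 0); c <- idx(i, j + 1, 0); d <- idx(i + 1, j + 1, 0)
    F <- rbind(F, c(a, c, b), c(b, c, d))       # bottom (outward -z)
    a <- idx(i, j, 1); b <- idx(i + 1, j, 1); c <- idx(i, j + 1, 1); d <- idx(i + 1, j + 1, 1)
    F <- rbind(F, c(a, b, c), c(b, d, c))       # top (outward +z)
  }
  # side walls
  for (i in seq_len(nx - 1)) {
    F <- rbind(F,
      c(idx(i, 1, 0), idx(i + 1, 1, 0), idx(i, 1, 1)),
      c(idx(i + 1, 1, 0), idx(i + 1, 1, 1), idx(i, 1, 1)),
      c(idx(i, nx, 0), idx(i, nx, 1), idx(i + 1, nx, 0)),
      c(idx(i + 1, nx, 0), idx(i, nx, 1), idx(i + 1, nx, 1)),
      c(idx(1, i, 0), idx(1, i, 1), idx(1, i + 1, 0)),
      c(idx(1, i + 1, 0), idx(1, i, 1), idx(1, i + 1, 1)),
      c(idx(nx, i, 0), idx(nx, i + 1, 0), idx(nx, i, 1)),
      c(idx(nx, i + 1, 0), idx(nx, i + 1, 1), idx(nx, i, 1)))
  }
  box <- triangle_mesh(V, F)
  expect_true(is_watertight(box))
  # raw estimates: map smoothing would bleed edge curvature inward
  curv <- compute_vertex_curvatures(box, smooth_iters = 0)
  interior <- which(V[, 1] > 0.2 & V[, 1] < 0.8 & V[, 2] > 0.2 & V[, 2] < 0.8)
  expect_lt(max(abs(curv$gaussian[interior])), 1e-8)
})

test_that("oriented bounding box recovers box extents in any pose", {
  V <- as.matrix(expand.grid(c(0, 2), c(0, 1), c(0, 0.5)))
  set.seed(2)
  V <- V[sample(nrow(V)), ] + 0    # order must not matter
  obb <- compute_obb(rbind(V, colMeans(V)))   # add interior point (non-coplanar safe)
  expect_equal(sort(obb$extents, decreasing = TRUE), c(2, 1, 0.5), tolerance = 1e-9)
  expect_equal(obb$volume, 1, tolerance = 1e-9)
  R <- rotation_about(c(0, 0, 1), 30)
  obb_rot <- compute_obb(sweep(rbind(V, colMeans(V)) %*% t(R), 2, c(1, -2, 0.5), `+`))
  expect_equal(obb_rot$extents, c(2, 1, 0.5), tolerance = 1e-6)
  expect_equal(obb_rot$volume, 1, tolerance = 1e-6)
  expect_equal(max(abs(crossprod(obb_rot$axes) - diag(3))), 0, tolerance = 1e-9)
  expect_error(compute_obb(cbind(1:5, 2 * (1:5), 0)), "degenerate")
})

test_that("refined box is never worse than PCA and matches a dense grid search", {
  # tetrahedron: PCA box is suboptimal; compare against a 0.5-degree grid oracle
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  pca_box_volume <- function(P) {
    ctr <- colMeans(P)
    R <- svd(sweep(P, 2, ctr), nu = 0)$v
    prod(apply(sweep(P, 2, ctr) %*% R, 2, function(cl) diff(range(cl))))
  }
  obb <- compute_obb(tet)
  expect_lte(obb$volume, pca_box_volume(tet) + 1e-12)

  grid_oracle <- function(P, step = 0.5) {
    best <- Inf
    ctr <- colMeans(P); Pc <- sweep(P, 2, ctr)
    for (a in seq(0, 90 - step, by = step)) for (b in seq(0, 90 - step, by = step)) {
      R <- rotation_about(c(0, 0, 1), a) %*% rotation_about(c(0, 1, 0), b)
      Q <- Pc %*% R
      v <- prod(apply(Q, 2, function(cl) diff(range(cl))))
      if (v < best) best <- v
    }
    best
  }
  box <- as.matrix(expand.grid(c(0, 2), c(0, 1), c(0, 0.5)))
  R0 <- rotation_about(c(0, 0, 1), 17)
  rbox <- rbind(box, colMeans(box)) %*% t(R0)
  oracle <- grid_oracle(rbox)       # in-plane rotation: 2-angle grid suffices
  got <- compute_obb(rbox)$volume
  expect_lt(abs(got - oracle) / oracle, 0.01)
  expect_lte(got, pca_box_volume(rbox) + 1e-12)
})

test_that("farthest point pair is exact against the quadratic oracle", {
  cube <- unit_cube_mesh()
  expect_equal(farthest_point_pair(cube)$dist, sqrt(3), tolerance = 1e-12)
  sp <- icosphere(1, 3)
  expect_equal(farthest_point_pair(sp)$dist, 2, tolerance = 0.01 * 2)
  set.seed(9)
  for (rep in 1:5) {
    P <- matrix(stats::rnorm(3 * 500), ncol = 3)
    m <- triangle_mesh(P, matrix(1:3, 1))   # faces irrelevant to the search
    fp <- farthest_point_pair(m)
    D <- as.matrix(stats::dist(P))
    expect_equal(fp$dist, max(D), tolerance = 1e-12)
    expect_setequal(c(fp$i, fp$j), which(D == max(D), arr.ind = TRUE)[1, ])
  }
  expect_error(farthest_point_pair(cube, integer(0), 1:2), "empty")
})

test_that("protrusion tips appear one per capsule cap and nowhere on spheres", {
  # a hemispherical cap has uniform curvature, so the detector's contract is
  # one tip per protrusion, on the cap (suppression radius covering the
  # cap); apex-exact localization is the job of the downstream geometric
  # refinement, which the landmark tests cover
  phi <- sdf_field(capsule_sdf(c(-0.7, 0, 0), c(0.7, 0, 0), 0.4), lim = 1.6, h = 0.05)
  caps <- marching_cubes(phi)
  curv <- compute_vertex_curvatures(caps)
  tips <- detect_protrusion_tips(caps, curv, min_gauss = 2, nms_radius = 0.9)
  expect_equal(nrow(tips), 2)
  got <- tips[order(tips$x), ]
  # one tip on each cap, on the capsule surface, within the cap's extent of
  # its apex
  expect_lt(got$x[1], -0.7)
  expect_gt(got$x[2], 0.7)
  expect_point_close(as.numeric(unlist(got[1, c("x", "y", "z")])), c(-1.1, 0, 0), 0.55)
  expect_point_close(as.numeric(unlist(got[2, c("x", "y", "z")])), c(1.1, 0, 0), 0.55)
  for (r in 1:2) {
    cap_ctr <- c(sign(got$x[r]) * 0.7, 0, 0)
    d <- sqrt(sum((as.numeric(unlist(got[r, c("x", "y", "z")])) - cap_ctr)^2))
    expect_lt(abs(d - 0.4), 0.05)   # on the spherical cap
  }
  sp <- icosphere(1, 3)
  cs <- compute_vertex_curvatures(sp)
  expect_equal(nrow(detect_protrusion_tips(sp, cs, min_gauss = 2, nms_radius = 0.2)), 0)
  expect_error(detect_protrusion_tips(sp, cs, nms_radius = 0), "positive")
})

test_that("footplate major axis is exact on analytic ellipse rims", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  rim2 <- cbind(1.3 * cos(th), 0.7 * sin(th), 0)
  Rt <- rotation_about(c(1, 1, 0), 25)
  rim <- rim2 %*% t(Rt)
  fit <- footplate_major_axis(rim)
  true_axis <- as.numeric(Rt %*% c(1, 0, 0))
  ang <- acos(min(abs(sum(fit$axis * true_axis)), 1)) * 180 / pi
  expect_lt(ang, 2)
  expect_equal(fit$HJ, 2.6, tolerance = 0.01 * 2.6)
  circ <- cbind(cos(th), sin(th), 0)
  expect_warning(footplate_major_axis(circ), "ambiguous")
  expect_error(footplate_major_axis(rim[1:5, ]), "at least 10")
})
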