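#' @importFrom stats integrate
NULL

# ---------------------------------------------------------------------------
# Rigid poses and implicit solid primitives.
#
# Phantom ossicles are unions of spheres, capsules and elliptical plates,
# chosen so that every reported parameter (and, for malleus/incus, the solid
# volume) has a closed-form ground truth. Solids are evaluated implicitly at
# voxel centres (a voxel is "on" iff its centre lies inside the union).

#' Rigid pose (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation in mm.
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("R must be a proper rotation matrix", call. = FALSE)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_pose")
}

#' Rotation matrix about an axis
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniformly random rigid pose
#'
#' Random rotation from a normalized Gaussian quaternion plus a uniform
#' translation; draws from the current RNG stream.
#' @param max_shift_mm maximum absolute translation per axis.
#' @export
random_pose <- function(max_shift_mm = 1) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y + w*z),     2*(x*z - w*y),
    2*(x*y - w*z),     1 - 2*(x^2 + z^2), 2*(y*z + w*x),
    2*(x*z + w*y),     2*(y*z - w*x),     1 - 2*(x^2 + y^2)), 3, 3)
  rigid_pose(R, stats::runif(3, -max_shift_mm, max_shift_mm))
}

apply_pose <- function(pose, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(pose$R), 2, pose$t, `+`)
}

pose_pt <- function(pose, p) as.numeric(pose$R %*% p + pose$t)

# primitives -----------------------------------------------------------------

prim_sphere <- function(center, r) list(type = "sphere", c = center, r = r)
prim_capsule <- function(p1, p2, r) list(type = "capsule", p1 = p1, p2 = p2, r = r)
# elliptical plate: centre, orthonormal in-plane axes u (major), v (minor),
# normal n; semi-axes a > b, thickness t, optional through-hole of radius
# hole_r along n.
prim_plate <- function(center, u, v, n, a, b, t, hole_r = 0)
  list(type = "plate", c = center, u = u, v = v, n = n, a = a, b = b, t = t,
       hole = hole_r)

prim_contains <- function(prim, pts) {
  switch(prim$type,
    sphere = {
      d <- sweep(pts, 2, prim$c)
      rowSums(d * d) <= prim$r^2
    },
    capsule = {
      ax <- prim$p2 - prim$p1
      L2 <- sum(ax * ax)
      d <- sweep(pts, 2, prim$p1)
      tt <- pmin(pmax((d %*% ax) / L2, 0), 1)
      dd <- d - tcrossprod(tt[, 1], ax)
      rowSums(dd * dd) <= prim$r^2
    },
    plate = {
      d <- sweep(pts, 2, prim$c)
      du <- d %*% prim$u; dv <- d %*% prim$v; dn <- d %*% prim$n
      inside <- abs(dn) <= prim$t / 2 &
        (du / prim$a)^2 + (dv / prim$b)^2 <= 1
      if (prim$hole > 0) inside <- inside & (du^2 + dv^2 > prim$hole^2)
      inside[, 1]
    },
    stop("unknown primitive"))
}

prim_bbox <- function(prim) {
  switch(prim$type,
    sphere = rbind(prim$c - prim$r, prim$c + prim$r),
    capsule = rbind(pmin(prim$p1, prim$p2) - prim$r, pmax(prim$p1, prim$p2) + prim$r),
    plate = {
      ext <- abs(prim$u) * prim$a + abs(prim$v) * prim$b + abs(prim$n) * prim$t / 2
      rbind(prim$c - ext, prim$c + ext)
    })
}

prim_transform <- function(prim, pose) {
  switch(prim$type,
    sphere = prim_sphere(pose_pt(pose, prim$c), prim$r),
    capsule = prim_capsule(pose_pt(pose, prim$p1), pose_pt(pose, prim$p2), prim$r),
    plate = prim_plate(pose_pt(pose, prim$c),
                       as.numeric(pose$R %*% prim$u), as.numeric(pose$R %*% prim$v),
                       as.numeric(pose$R %*% prim$n), prim$a, prim$b, prim$t, prim$hole))
}

solid_contains <- function(prims, pts) {
  inside <- rep(FALSE, nrow(pts))
  for (p in prims) inside <- inside | prim_contains(p, pts)
  inside
}

solid_bbox <- function(prims) {
  bb <- vapply(prims, prim_bbox, matrix(0, 2, 3))
  rbind(apply(bb[1, , , drop = FALSE], 2, min), apply(bb[2, , , drop = FALSE], 2, max))
}

# closed-form overlap of a sphere (radius R) with a capsule of radius r whose
# segment starts at the sphere centre and exits it: half the classic
# napkin-ring cylinder-through-centre intersection plus the buried start cap.
overlap_sphere_centre_capsule <- function(R, r) {
  stopifnot(r < R)
  (2 / 3) * pi * r^3 + 0.5 * (4 * pi / 3) * (R^3 - (R^2 - r^2)^(3 / 2))
}

capsule_volume <- function(len, r) pi * r^2 * len + (4 / 3) * pi * r^3

# solid volume of an ossicle by quadrature of the implicit union on a fine
# grid (used where the union has no closed form; also serves as a
# cross-check of the closed forms in the test suite)
solid_volume_quadrature <- function(prims, h = 0.02) {
  bb <- solid_bbox(prims)
  n <- ceiling((bb[2, ] - bb[1, ]) / h) + 1L
  ax <- lapply(1:3, function(a) bb[1, a] + (seq_len(n[a]) - 1) * h)
  # slab-wise to bound memory
  tot <- 0
  g12 <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]]))
  for (z in ax[[3]]) {
    pts <- cbind(g12, z)
    tot <- tot + sum(solid_contains(prims, pts))
  }
  tot * h^3
}

# ---------------------------------------------------------------------------
# Phantom specifications. Defaults are sized to the automated population
# means of the study cohort (total heights 7.91 / 6.56 / 3.25 mm etc.), so
# phantoms live in the anatomically plausible regime.

#' Malleus phantom specification
#'
#' The malleus is modelled as a head sphere, a neck+manubrium capsule
#' anchored at the head centre, and a lateral-process stalk capsule whose
#' hemispherical cap apex is the landmark B. Landmarks: A = head apex
#' (farthest head point from the manubrium tip), B = lateral-process apex,
#' C = manubrium tip. The three defining distances AC, BC, AB are exact by
#' construction.
#'
#' @param total_height_AC,manubrium_BC,head_neck_AB target distances in mm.
#' @param head_radius,manubrium_radius,lateral_bump_radius solid radii (mm);
#'   setting `lateral_bump_radius = 0` removes the lateral process (and with
#'   it landmark B).
#' @param manubrium_tilt_deg tilt of the head-to-manubrium axis from the
#'   vertical, degrees.
#' @param pose a [rigid_pose] applied to the whole solid.
#' @export
malleus_spec <- function(total_height_AC = 7.91, manubrium_BC = 4.36,
                         head_neck_AB = 4.89, head_radius = 1.1,
                         manubrium_radius = 0.4, lateral_bump_radius = 0.4,
                         manubrium_tilt_deg = 10, pose = rigid_pose()) {
  s <- list(AC = total_height_AC, BC = manubrium_BC, AB = head_neck_AB,
            r_head = head_radius, r_man = manubrium_radius,
            r_bump = lateral_bump_radius, tilt = manubrium_tilt_deg, pose = pose)
  if (s$AC <= 0 || s$BC <= 0 || s$AB <= 0 || s$r_head <= 0 || s$r_man <= 0)
    stop("malleus dimensions must be positive", call. = FALSE)
  if (s$AC <= s$AB || s$AC <= s$BC)
    stop("total height AC must exceed AB and BC", call. = FALSE)
  structure(s, class = c("malleus_spec", "phantom_spec"))
}

build_malleus <- function(spec) {
  phi <- spec$tilt * pi / 180
  d <- c(0, sin(phi), -cos(phi))
  ch <- c(0, 0, 0)
  A <- ch - spec$r_head * d
  C <- ch + (spec$AC - spec$r_head) * d
  P2 <- C - spec$r_man * d
  if (sqrt(sum((P2 - ch)^2)) < spec$r_head + spec$r_man)
    stop("manubrium too short for this head radius", call. = FALSE)
  tB <- (spec$AB^2 - spec$BC^2 + spec$AC^2) / (2 * spec$AC)
  disc <- spec$AB^2 - tB^2
  if (disc <= 0)
    stop("AC, BC, AB do not form a valid triangle for landmark B", call. = FALSE)
  rho <- sqrt(disc)
  B <- A + tB * d + rho * c(1, 0, 0)
  prims <- list(prim_sphere(ch, spec$r_head),
                prim_capsule(ch, P2, spec$r_man))
  vol <- (4 / 3) * pi * spec$r_head^3 +
    capsule_volume(sqrt(sum((P2 - ch)^2)), spec$r_man) -
    overlap_sphere_centre_capsule(spec$r_head, spec$r_man)
  landmarks <- list(A = A, C = C)
  if (spec$r_bump > 0) {
    rb <- spec$r_bump
    if (rho - rb <= spec$r_man)
      stop("lateral process does not protrude beyond the manubrium", call. = FALSE)
    Q <- A + tB * d
    Bc <- B - rb * c(1, 0, 0)
    prims <- c(prims, list(prim_capsule(Q, Bc, rb)))
    # stalk volume minus its overlap with the manubrium capsule:
    # buried start hemisphere + perpendicular cylinder-cylinder core
    core <- integrate(function(z) 2 * sqrt(pmax(rb^2 - z^2, 0)) * sqrt(spec$r_man^2 - z^2),
                      -rb, rb, rel.tol = 1e-10)$value
    vol <- vol + capsule_volume(rho - rb, rb) - ((2 / 3) * pi * rb^3 + core)
    landmarks$B <- B
  }
  # pose
  landmarks <- lapply(landmarks, function(p) pose_pt(spec$pose, p))
  prims <- lapply(prims, prim_transform, pose = spec$pose)
  params <- c(malleus_total_height_AC = spec$AC,
              malleus_manubrium_BC = spec$BC,
              malleus_head_neck_AB = spec$AB)
  if (is.null(landmarks$B)) params <- params["malleus_total_height_AC"]
  list(prims = prims, landmarks = landmarks, params = params,
       volume = vol, min_feature = min(spec$r_man, if (spec$r_bump > 0) spec$r_bump else Inf))
}

#' Incus phantom specification
#'
#' Body sphere plus long- and short-process capsules radiating from the body
#' centre. Landmarks: D = body point farthest from the long-process tip G,
#' E = body point farthest from the short-process tip F. The inter-process
#' angle is solved from the three target distances DG, EF, FG and the body
#' radius, so all three are exact by construction.
#'
#' @param total_height_DG,total_width_EF,process_distance_FG targets in mm.
#' @param body_radius,process_radius solid radii in mm.
#' @param pose a [rigid_pose].
#' @export
incus_spec <- function(total_height_DG = 6.56, total_width_EF = 4.97,
                       process_distance_FG = 5.55, body_radius = 1.3,
                       process_radius = 0.4, pose = rigid_pose()) {
  s <- list(DG = total_height_DG, EF = total_width_EF, FG = process_distance_FG,
            r_body = body_radius, r_proc = process_radius, pose = pose)
  g <- s$DG - s$r_body; f <- s$EF - s$r_body
  if (g <= 0 || f <= 0) stop("body radius too large for DG/EF", call. = FALSE)
  if (s$FG >= s$DG || s$EF >= s$DG)
    warning("total height DG is not the maximum incus extent (DG <= EF or FG); ",
            "farthest-pair landmark detection will not identify D and G on this solid",
            call. = FALSE)
  cth <- (g^2 + f^2 - s$FG^2) / (2 * g * f)
  if (abs(cth) >= 1)
    stop("DG, EF, FG are geometrically inconsistent with this body radius", call. = FALSE)
  s$theta <- acos(cth)
  structure(s, class = c("incus_spec", "phantom_spec"))
}

build_incus <- function(spec) {
  g <- spec$DG - spec$r_body; f <- spec$EF - spec$r_body
  gh <- c(0, 0, -1)
  fh <- c(0, sin(spec$theta), -cos(spec$theta))
  cb <- c(0, 0, 0)
  G <- cb + g * gh
  F <- cb + f * fh
  D <- cb - spec$r_body * gh
  E <- cb - spec$r_body * fh
  rp <- spec$r_proc
  if (g - rp < spec$r_body + rp || f - rp < spec$r_body + rp)
    stop("processes too short for this body radius", call. = FALSE)
  # both capsule-capsule shared regions must sit inside the body sphere so
  # inclusion-exclusion collapses to per-capsule napkin-ring overlaps
  reach <- sqrt(2 * rp^2 + 2 * rp^2 * abs(cos(spec$theta))) / sin(spec$theta)
  if (reach > spec$r_body)
    stop("process geometry violates the closed-form volume precondition", call. = FALSE)
  prims <- list(prim_sphere(cb, spec$r_body),
                prim_capsule(cb, G - rp * gh, rp),
                prim_capsule(cb, F - rp * fh, rp))
  vol <- (4 / 3) * pi * spec$r_body^3 +
    capsule_volume(g - rp, rp) + capsule_volume(f - rp, rp) -
    2 * overlap_sphere_centre_capsule(spec$r_body, rp)
  landmarks <- lapply(list(D = D, E = E, F = F, G = G),
                      function(p) pose_pt(spec$pose, p))
  prims <- lapply(prims, prim_transform, pose = spec$pose)
  list(prims = prims, landmarks = landmarks,
       params = c(incus_total_height_DG = spec$DG,
                  incus_total_width_EF = spec$EF,
                  incus_process_distance_FG = spec$FG),
       volume = vol, min_feature = rp)
}

#' Stapes phantom specification
#'
#' Head sphere, two straight crura capsules from the head centre to the
#' footplate top face, and an elliptical footplate plate (optionally
#' perforated and/or tilted). Landmarks: G = head point farthest from the
#' footplate (apex toward the incus), H/J = major-axis extremes of the
#' bottom footplate face, I = the footplate point farthest from the head
#' (the J-side bottom rim corner in this idealized flat plate). GI and
#' HJ (= 2a) are exact by construction.
#'
#' @param total_height_GI,footplate_HJ targets in mm.
#' @param head_radius,crura_radius solid radii (mm).
#' @param footplate_minor minor semi-axis b of the footplate (mm); the major
#'   semi-axis is `footplate_HJ / 2`.
#' @param footplate_thickness plate thickness (mm).
#' @param footplate_tilt_deg obliquity of the plate relative to the head
#'   axis, degrees (rotation about the minor axis).
#' @param perforation_radius through-hole radius at the plate centre
#'   (0 = intact); must be strictly smaller than `footplate_minor`.
#' @param head_offset_mm in-plane offset of the head along the major axis;
#'   a non-zero value makes the farthest bottom corner (landmark I) unique.
#' @param crura_spread fraction of the major semi-axis at which the crura
#'   meet the plate.
#' @param pose a [rigid_pose].
#' @export
stapes_spec <- function(total_height_GI = 3.25, footplate_HJ = 2.63,
                        head_radius = 0.45, crura_radius = 0.2,
                        footplate_minor = 0.65, footplate_thickness = 0.25,
                        footplate_tilt_deg = 0, perforation_radius = 0,
                        head_offset_mm = -0.12, crura_spread = 0.55,
                        pose = rigid_pose()) {
  s <- list(GI = total_height_GI, HJ = footplate_HJ, r_head = head_radius,
            r_crus = crura_radius, b = footplate_minor, t = footplate_thickness,
            tilt = footplate_tilt_deg, r_perf = perforation_radius,
            s_off = head_offset_mm, chi = crura_spread, pose = pose)
  a <- s$HJ / 2
  if (a <= s$b) stop("footplate major semi-axis must exceed the minor one", call. = FALSE)
  if (s$r_perf > 0 && s$r_perf >= s$b)
    stop("perforation must lie strictly inside the footplate", call. = FALSE)
  if (s$s_off >= 0) stop("head_offset_mm must be negative (toward H) so landmark I is unique",
                         call. = FALSE)
  structure(s, class = c("stapes_spec", "phantom_spec"))
}

build_stapes <- function(spec, footplate = TRUE) {
  a <- spec$HJ / 2
  tau <- spec$tilt * pi / 180
  ah <- c(cos(tau), 0, sin(tau))   # plate major axis
  bh <- c(0, 1, 0)                 # plate minor axis
  nh <- c(-sin(tau), 0, cos(tau))  # plate normal
  cf <- c(0, 0, 0)
  Pp <- cf + a * ah - (spec$t / 2) * nh   # bottom corners: one of them is landmark I
  Pm <- cf - a * ah - (spec$t / 2) * nh
  s <- spec$s_off
  # place the head apex GI away from whichever bottom corner ends up farthest;
  # solve against each corner and keep the self-consistent choice
  ch <- NULL; I_pt <- NULL
  for (X in list(Pp, Pm)) {
    rr <- (spec$GI - spec$r_head)^2 - (s - X[1])^2 - X[2]^2
    if (rr <= 0) next
    ch_try <- c(s, 0, X[3] + sqrt(rr))
    other <- if (identical(X, Pp)) Pm else Pp
    if (sum((ch_try - X)^2) > sum((ch_try - other)^2) + 1e-12) {
      ch <- ch_try; I_pt <- X
      break
    }
  }
  if (is.null(ch))
    stop("stapes geometry is degenerate: no unique farthest footplate corner",
         call. = FALSE)
  Gs <- ch + spec$r_head * (ch - I_pt) / sqrt(sum((ch - I_pt)^2))
  Ept <- lapply(c(-1, 1), function(sg) cf + sg * spec$chi * a * ah + (spec$t / 2) * nh)
  prims <- list(prim_sphere(ch, spec$r_head),
                prim_capsule(ch, Ept[[1]], spec$r_crus),
                prim_capsule(ch, Ept[[2]], spec$r_crus))
  landmarks <- list(G = Gs)
  params <- NULL
  if (footplate) {
    prims <- c(prims, list(prim_plate(cf, ah, bh, nh, a, spec$b, spec$t, spec$r_perf)))
    landmarks$H <- Pm
    landmarks$J <- Pp
    landmarks$I <- I_pt
    params <- c(stapes_total_height_GI = spec$GI, stapes_footplate_HJ = spec$HJ)
  }
  landmarks <- lapply(landmarks, function(p) pose_pt(spec$pose, p))
  prims <- lapply(prims, prim_transform, pose = spec$pose)
  list(prims = prims, landmarks = landmarks, params = params,
       volume = NA_real_,  # no closed form; filled by quadrature on demand
       min_feature = min(spec$r_crus, spec$t),  # a plate needs 2 voxels across its thickness
       head_centre = pose_pt(spec$pose, ch))
}

# ---------------------------------------------------------------------------
# Rasterization and ground truth containers.

phantom_ground_truth <- function(landmarks, parameters, volumes, voxel_counts = NULL) {
  structure(list(landmarks = landmarks, parameters = parameters,
                 volumes = volumes, voxel_counts = voxel_counts),
            class = "phantom_ground_truth")
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat("<phantom_ground_truth> ", length(x$landmarks), " landmarks, ",
      length(x$parameters), " parameters\n", sep = "")
  print(round(x$parameters, 4))
  invisible(x)
}

rasterize_solids <- function(solids, labels, spacing, margin = 0.5) {
  bbs <- lapply(solids, solid_bbox)
  lo <- apply(do.call(rbind, lapply(bbs, function(b) b[1, ])), 2, min) - margin
  hi <- apply(do.call(rbind, lapply(bbs, function(b) b[2, ])), 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  n <- ceiling((hi - origin) / spacing) + 1L
  grid <- array(0L, n)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * spacing)
  overlap <- 0L
  counts <- integer(length(solids))
  for (si in seq_along(solids)) {
    bb <- bbs[[si]]
    ir <- lapply(1:3, function(a) which(ax[[a]] >= bb[1, a] - spacing & ax[[a]] <= bb[2, a] + spacing))
    pts <- as.matrix(expand.grid(x = ax[[1]][ir[[1]]], y = ax[[2]][ir[[2]]], z = ax[[3]][ir[[3]]]))
    inside <- solid_contains(solids[[si]], pts)
    sub <- grid[ir[[1]], ir[[2]], ir[[3]]]
    ins <- array(inside, dim = lengths(ir))
    overlap <- overlap + sum(ins & sub != 0L)
    sub[ins & sub == 0L] <- labels[si]   # earlier ossicles take precedence
    grid[ir[[1]], ir[[2]], ir[[3]]] <- sub
    counts[si] <- sum(ins)
  }
  list(volume = label_volume(grid, spacing = rep(spacing, 3), origin = origin),
       overlap_voxels = overlap, raw_counts = counts)
}

check_spacing <- function(spacing, min_feature) {
  if (spacing > min_feature / 2)
    stop("resolution error: spacing ", spacing, " mm exceeds half the smallest feature radius (",
         format(min_feature / 2, digits = 3), " mm)", call. = FALSE)
}

#' Generate a malleus phantom
#'
#' Rasterizes the malleus solid at the requested voxel spacing and returns
#' the binary label volume together with its analytic ground truth
#' (landmarks A, B, C; the distances AC, BC, AB; the closed-form solid
#' volume).
#'
#' @param spec a [malleus_spec].
#' @param spacing isotropic voxel size, mm.
#' @param label integer label for the on-voxels.
#' @return list with elements `volume` ([label_volume]) and `truth`
#'   ([phantom_ground_truth]).
#' @export
generate_malleus_phantom <- function(spec = malleus_spec(), spacing = 0.1, label = 1L) {
  b <- build_malleus(spec)
  if (is.null(b$landmarks$B))
    stop("landmark B is unavailable: the spec has no lateral process (lateral_bump_radius = 0)",
         call. = FALSE)
  check_spacing(spacing, b$min_feature)
  ras <- rasterize_solids(list(b$prims), label, spacing)
  list(volume = ras$volume,
       truth = phantom_ground_truth(b$landmarks, b$params,
                                    c(malleus = b$volume),
                                    c(malleus = ras$raw_counts[1])))
}

#' Generate an incus phantom
#' @inheritParams generate_malleus_phantom
#' @param spec an [incus_spec].
#' @export
generate_incus_phantom <- function(spec = incus_spec(), spacing = 0.1, label = 2L) {
  b <- build_incus(spec)
  check_spacing(spacing, b$min_feature)
  ras <- rasterize_solids(list(b$prims), label, spacing)
  list(volume = ras$volume,
       truth = phantom_ground_truth(b$landmarks, b$params,
                                    c(incus = b$volume),
                                    c(incus = ras$raw_counts[1])))
}

#' Generate a stapes phantom
#' @inheritParams generate_malleus_phantom
#' @param spec a [stapes_spec].
#' @param footplate set FALSE to emulate the clinically common incomplete
#'   segmentation in which the footplate is missing.
#' @param volume_oracle_spacing grid step (mm) of the quadrature used for the
#'   reference solid volume (the crura/plate junction has no closed form).
#' @export
generate_stapes_phantom <- function(spec = stapes_spec(), spacing = 0.1, label = 3L,
                                    footplate = TRUE, volume_oracle_spacing = 0.02) {
  b <- build_stapes(spec, footplate = footplate)
  check_spacing(spacing, b$min_feature)
  ras <- rasterize_solids(list(b$prims), label, spacing)
  vol <- solid_volume_quadrature(b$prims, h = volume_oracle_spacing)
  list(volume = ras$volume,
       truth = phantom_ground_truth(b$landmarks, b$params, c(stapes = vol),
                                    c(stapes = ras$raw_counts[1])))
}

#' Generate a full ossicular-chain phantom
#'
#' Builds malleus, incus and stapes in one labeled volume. The stapes head is
#' articulated at the incus long-process tip G with a small joint gap, and
#' oriented so that the incudostapedial angle (at vertex G, between the rays
#' G->D and G->I) equals `joint_angle_deg` exactly in the ground truth. The
#' malleus is placed laterally to the incus with a clearance gap.
#'
#' @param malleus,incus,stapes phantom specs (poses inside these specs are
#'   ignored; use `pose` to move the whole chain).
#' @param joint_angle_deg incudostapedial joint angle, degrees, in (0, 180).
#' @param joint_gap_mm articular gap between the stapes head apex and the
#'   incus long-process tip.
#' @param spacing isotropic voxel size, mm.
#' @param pose optional [rigid_pose] applied to the whole chain.
#' @param labels an [ossicle_label_map].
#' @param collision_tol_mm3 maximum tolerated label-overlap volume.
#' @param stapes_footplate FALSE drops the footplate (incomplete stapes case).
#' @export
generate_chain_phantom <- function(malleus = malleus_spec(), incus = incus_spec(),
                                   stapes = stapes_spec(), joint_angle_deg = 96.83,
                                   joint_gap_mm = 0.12, spacing = 0.1,
                                   pose = rigid_pose(), labels = ossicle_label_map(),
                                   collision_tol_mm3 = 0.1, stapes_footplate = TRUE) {
  if (!(joint_angle_deg > 0 && joint_angle_deg < 180))
    stop("degenerate-collinear joint angle: must be strictly inside (0, 180) degrees",
         call. = FALSE)
  binc <- build_incus(incus)
  D <- binc$landmarks$D; G <- binc$landmarks$G
  dDG <- (D - G) / sqrt(sum((D - G)^2))
  # joint plane: processes live in the y-z plane; the stapes goes to +y
  p_perp <- c(0, 1, 0) - sum(c(0, 1, 0) * dDG) * dDG
  p_perp <- p_perp / sqrt(sum(p_perp^2))
  th <- joint_angle_deg * pi / 180
  w <- cos(th) * dDG + sin(th) * p_perp

  bsta0 <- build_stapes(stapes, footplate = stapes_footplate)
  apex <- bsta0$landmarks$G
  Ican <- if (stapes_footplate) bsta0$landmarks$I else {
    # aim the head-to-plate axis even without a plate
    2 * bsta0$head_centre - apex
  }
  u1 <- (Ican - apex) / sqrt(sum((Ican - apex)^2))
  bcan <- c(0, 1, 0)
  u2 <- bcan - sum(bcan * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  u3 <- pracma_cross(u1, u2)
  v1 <- w
  xh <- c(1, 0, 0)
  v2 <- xh - sum(xh * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  v3 <- pracma_cross(v1, v2)
  Rst <- cbind(v1, v2, v3) %*% t(cbind(u1, u2, u3))
  t_st <- G + joint_gap_mm * w - as.numeric(Rst %*% apex)
  st_pose <- rigid_pose(Rst, t_st)
  bsta <- build_stapes(modifyList(stapes, list(pose = st_pose)), footplate = stapes_footplate)
  class(bsta) <- class(bsta0)

  # malleus: offset laterally (+x) from the incus body, clearance 0.4 mm
  bmal0 <- build_malleus(malleus)
  mal_shift <- c(incus$r_body + malleus$r_head + 0.4, 0, 0)
  bmal <- build_malleus(modifyList(malleus, list(pose = rigid_pose(diag(3), mal_shift))))

  # whole-chain pose
  reposed <- lapply(list(malleus = bmal, incus = binc, stapes = bsta), function(b) {
    b$landmarks <- lapply(b$landmarks, function(p) pose_pt(pose, p))
    b$prims <- lapply(b$prims, prim_transform, pose = pose)
    b
  })
  st_lm <- reposed$stapes$landmarks
  names(st_lm)[names(st_lm) == "G"] <- "G_s"
  lm <- c(reposed$malleus$landmarks, reposed$incus$landmarks, st_lm)
  angle_true <- joint_angle_deg
  params <- c(reposed$malleus$params, reposed$incus$params, reposed$stapes$params)
  if (stapes_footplate) params <- c(params, incudostapedial_angle_DGI = angle_true)

  ras <- rasterize_solids(list(reposed$malleus$prims, reposed$incus$prims, reposed$stapes$prims),
                          c(labels$malleus, labels$incus, labels$stapes), spacing)
  if (ras$overlap_voxels * spacing^3 > collision_tol_mm3)
    stop("placement error: ossicle labels overlap by ",
         format(ras$overlap_voxels * spacing^3, digits = 3), " mm^3", call. = FALSE)
  st_vol <- solid_volume_quadrature(reposed$stapes$prims, h = 0.02)
  vols <- c(malleus = reposed$malleus$volume, incus = reposed$incus$volume, stapes = st_vol)
  counts <- stats::setNames(ras$raw_counts, c("malleus", "incus", "stapes"))
  list(volume = ras$volume,
       truth = phantom_ground_truth(lm, params, vols, counts),
       joint_angle_deg = angle_true)
}

pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

#' Flip boundary voxels at random (segmentation-noise harness)
#'
#' Only voxels whose 6-neighbourhood contains both foreground and background
#' are eligible: foreground boundary voxels may be cleared and background
#' boundary voxels may adopt the smallest adjacent label. Interior voxels are
#' never touched. Reproducible for a fixed seed.
#'
#' @param vol a [label_volume].
#' @param boundary_flip_prob flip probability in `[0, 0.5]`.
#' @param seed integer seed for the flip draw.
#' @export
perturb_volume <- function(vol, boundary_flip_prob, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"))
  if (boundary_flip_prob < 0 || boundary_flip_prob > 0.5)
    stop("boundary_flip_prob must be in [0, 0.5]", call. = FALSE)
  if (boundary_flip_prob == 0) return(vol)
  a <- vol$data
  d <- dim(a)
  shift <- function(arr, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- if (by > 0) c(1L, seq_len(n - 1L)) else c(seq_len(n - 1L) + 1L, n)
    idx[[ax]] <- src
    do.call(`[`, c(list(arr), idx))
  }
  nb <- list(shift(a, 1, 1), shift(a, 1, -1), shift(a, 2, 1),
             shift(a, 2, -1), shift(a, 3, 1), shift(a, 3, -1))
  any_bg <- Reduce(`|`, lapply(nb, function(x) x == 0L))
  any_fg <- Reduce(`|`, lapply(nb, function(x) x != 0L))
  boundary <- (a != 0L & any_bg) | (a == 0L & any_fg)
  # smallest adjacent non-zero label for background adopters
  minlab <- Reduce(function(x, y) pmin(x, y),
                   lapply(nb, function(x) ifelse(x == 0L, .Machine$integer.max, x)))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  flip <- boundary & array(stats::runif(length(a)) < boundary_flip_prob, d)
  out <- a
  out[flip & a != 0L] <- 0L
  adopt <- flip & a == 0L
  out[adopt] <- minlab[adopt]
  label_volume(out, spacing = vol$spacing, origin = vol$origin,
               axis_orientation = vol$axis_orientation)
}
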