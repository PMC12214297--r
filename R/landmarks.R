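#' Landmark detection on ossicle meshes
#'
#' The measurement pipeline names ten anatomical landmarks (Fig.-style
#' letters): malleus A (head apex), B (lateral-process apex), C (manubrium
#' tip); incus D (body top), E (body point farthest from the short process
#' tip), F (short-process tip), G (long-process tip); stapes G (head apex,
#' held as `G_s`), H/J (footplate major-axis extremes), I (footplate point
#' farthest from the head). Each locator records the rule that produced each
#' point (provenance) plus any warnings.
#'
#' @name landmarks
NULL

feature_point_set <- function(points, provenance, warnings = character()) {
  structure(list(points = points, provenance = provenance, warnings = warnings),
            class = "feature_point_set")
}

#' @export
print.feature_point_set <- function(x, ...) {
  for (nm in names(x$points))
    cat(sprintf("  %-3s (%8.4f, %8.4f, %8.4f)  [%s]\n", nm,
                x$points[[nm]][1], x$points[[nm]][2], x$points[[nm]][3],
                x$provenance[[nm]]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Exact farthest point pair between two vertex regions
#'
#' Maximizes the Euclidean distance over all pairs (a, b) with `a` in
#' `region_a` and `b` in `region_b`, exactly, using bounding-box pruning in
#' a PCA-aligned frame; ties are broken lexicographically on (x, y, z).
#'
#' @param mesh a [triangle_mesh].
#' @param region_a,region_b integer vertex index vectors (default: all).
#' @return list with `p`, `q` (mm coordinates), `i`, `j` (vertex indices
#'   into the mesh) and `dist` (mm).
#' @export
farthest_point_pair <- function(mesh, region_a = NULL, region_b = NULL) {
  V <- mesh$vertices
  ia <- if (is.null(region_a)) seq_len(nrow(V)) else as.integer(region_a)
  ib <- if (is.null(region_b)) seq_len(nrow(V)) else as.integer(region_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("farthest_point_pair: empty vertex region", call. = FALSE)
  A <- V[ia, , drop = FALSE]; B <- V[ib, , drop = FALSE]
  ctr <- colMeans(rbind(A, B))
  R <- svd(sweep(rbind(A, B), 2, ctr), nu = 0)$v
  res <- cpp_farthest_pair(sweep(A, 2, ctr) %*% R, sweep(B, 2, ctr) %*% R)
  list(p = as.numeric(A[res$i, ]), q = as.numeric(B[res$j, ]),
       i = ia[res$i], j = ib[res$j], dist = res$dist)
}

vertex_adjacency_list <- function(mesh) {
  F <- mesh$faces
  i <- c(F[, 1], F[, 2], F[, 2], F[, 3], F[, 3], F[, 1])
  j <- c(F[, 2], F[, 1], F[, 3], F[, 2], F[, 1], F[, 3])
  split(j, factor(i, levels = seq_len(nrow(mesh$vertices))))
}

#' Detect convex protrusion tips
#'
#' Vertices that are strict local maxima of Gaussian curvature with
#' `K >= min_gauss` and convex mean curvature (`H > 0`), then
#' non-maximum-suppressed within `nms_radius` mm; returned sorted by K
#' descending. A uniformly curved surface (sphere) yields no strict maxima
#' above a threshold of twice its curvature, hence no tips.
#'
#' @param mesh a [triangle_mesh].
#' @param curv its [compute_vertex_curvatures()] map.
#' @param min_gauss Gaussian-curvature threshold, 1/mm^2.
#' @param nms_radius suppression radius, mm (> 0).
#' @param min_area_frac reliability gate: vertices whose barycentric support
#'   area falls below this fraction of the median are excluded — discrete
#'   curvature on micro-triangle clusters (grid nodes grazing the surface)
#'   is unbounded noise, not geometry.
#' @return tibble with columns `vertex`, `x`, `y`, `z`, `gaussian`, `mean`.
#' @export
detect_protrusion_tips <- function(mesh, curv, min_gauss = 4, nms_radius = 0.4,
                                   min_area_frac = 0.1) {
  if (nms_radius <= 0) stop("nms_radius must be positive", call. = FALSE)
  K <- curv$gaussian; H <- curv$mean
  adj <- vertex_adjacency_list(mesh)
  reliable <- curv$area >= min_area_frac * stats::median(curv$area)
  is_max <- vapply(seq_along(K), function(v) {
    nb <- unique(adj[[v]])
    length(nb) > 0 && all(K[v] > K[nb])
  }, logical(1))
  cand <- which(is_max & reliable & K >= min_gauss & H > 0)
  if (length(cand) == 0) return(empty_tips())
  V <- mesh$vertices
  ord <- order(-K[cand], V[cand, 1], V[cand, 2], V[cand, 3])
  cand <- cand[ord]
  kept <- integer(0)
  for (v in cand) {
    if (length(kept) == 0 ||
        min(sqrt(colSums((t(V[kept, , drop = FALSE]) - V[v, ])^2))) > nms_radius)
      kept <- c(kept, v)
  }
  tibble::tibble(vertex = kept, x = V[kept, 1], y = V[kept, 2], z = V[kept, 3],
                 gaussian = K[kept], mean = H[kept])
}

empty_tips <- function() {
  tibble::tibble(vertex = integer(), x = numeric(), y = numeric(), z = numeric(),
                 gaussian = numeric(), mean = numeric())
}

#' Footplate major axis by planar PCA
#'
#' Total-least-squares plane fit of the footplate vertex region, projection
#' into the plane, 2D PCA; the major axis is the first component and H, J
#' are the extreme vertices along it (ties broken lexicographically). The
#' extremes lie on the rim, so interior holes (perforations) do not move
#' them. A near-isotropic projection (eigenvalue ratio below `ratio_warn`)
#' raises an ambiguous-axis warning but still returns deterministically.
#'
#' @param points `n x 3` matrix of footplate vertices (n >= 10).
#' @param ratio_warn eigenvalue-ratio threshold for the ambiguity warning.
#' @return list with `axis` (unit 3-vector), `centroid`, `H`, `J`, `HJ`
#'   (mm), `normal` (plane normal), `rms` (plane-fit RMS, mm),
#'   `ambiguous` (logical).
#' @export
footplate_major_axis <- function(points, ratio_warn = 1.05) {
  P <- as.matrix(points)
  if (nrow(P) < 10) stop("footplate region needs at least 10 vertices", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0)
  normal <- sv$v[, 3]
  rms <- sqrt(mean((Pc %*% normal)^2))
  basis <- sv$v[, 1:2, drop = FALSE]
  Q <- Pc %*% basis                     # 2D projection
  sv2 <- svd(Q, nu = 0)
  lam <- sv2$d^2
  ambiguous <- (lam[1] / max(lam[2], 1e-300)) < ratio_warn
  if (ambiguous)
    warning("ambiguous footplate axis: in-plane spread is nearly isotropic", call. = FALSE)
  major2 <- sv2$v[, 1]
  axis <- as.numeric(basis %*% major2)
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.numeric(Pc %*% axis)
  iH <- pick_extreme(proj, P, min)
  iJ <- pick_extreme(proj, P, max)
  H <- as.numeric(P[iH, ]); J <- as.numeric(P[iJ, ])
  list(axis = axis, centroid = ctr, H = H, J = J,
       HJ = sqrt(sum((H - J)^2)), normal = normal, rms = rms,
       ambiguous = ambiguous, iH = iH, iJ = iJ)
}

# index of min/max of proj with lexicographic (x, y, z) tie-break
pick_extreme <- function(proj, P, fn) {
  target <- fn(proj)
  cand <- which(abs(proj - target) < 1e-12)
  if (length(cand) > 1)
    cand <- cand[order(P[cand, 1], P[cand, 2], P[cand, 3])]
  cand[1]
}

point_line_distance <- function(p, a, b) {
  d <- b - a; d <- d / sqrt(sum(d^2))
  v <- p - a
  w <- v - sum(v * d) * d
  sqrt(sum(w * w))
}

# robust local thickness proxy: 0.9 quantile of radial distance from the
# principal axis, over vertices within `band` mm of the end's projection
end_thickness <- function(V, axis, proj, end_proj, band = 0.75) {
  sel <- abs(proj - end_proj) <= band
  rel <- sweep(V[sel, , drop = FALSE], 2, colMeans(V[sel, , drop = FALSE]))
  t <- as.numeric(rel %*% axis)
  rad <- sqrt(rowSums((rel - outer(t, axis))^2))
  stats::quantile(rad, 0.9, names = FALSE)
}

#' Locate malleus landmarks A, B, C
#'
#' (A, C) is the farthest vertex pair of the mesh; A is the end whose local
#' cross-section (radial thickness near the end along the principal box
#' axis) is larger — the head. B is the highest-Gaussian-curvature
#' protrusion tip in the central half of the principal-axis extent (the
#' lateral process); its absence is a hard error mirroring the clinical
#' exclusion of incomplete segmentations.
#'
#' @param mesh malleus [triangle_mesh].
#' @param curv its curvature map (computed if NULL).
#' @param obb its [compute_obb()] box (computed if NULL).
#' @param config a [measure_config()] list.
#' @return A `feature_point_set` with points A, B, C.
#' @export
locate_malleus_landmarks <- function(mesh, curv = NULL, obb = NULL,
                                     config = measure_config()) {
  if (is.null(curv)) curv <- compute_vertex_curvatures(mesh)
  if (is.null(obb)) obb <- compute_obb(mesh)
  V <- mesh$vertices
  fp <- farthest_point_pair(mesh)
  axis <- obb$axes[, 1]
  proj <- as.numeric(sweep(V, 2, obb$center) %*% axis)
  th_p <- end_thickness(V, axis, proj, proj[fp$i])
  th_q <- end_thickness(V, axis, proj, proj[fp$j])
  if (th_p >= th_q) { A <- fp$p; C <- fp$q } else { A <- fp$q; C <- fp$p }
  tips <- detect_protrusion_tips(mesh, curv, config$landmarks$min_gauss,
                                 config$landmarks$nms_radius)
  lo <- min(proj) + 0.25 * diff(range(proj))
  hi <- min(proj) + 0.75 * diff(range(proj))
  if (nrow(tips) > 0) {
    tp <- as.numeric(as.matrix(tips[, c("x", "y", "z")]) %*% axis) -
      sum(obb$center * axis)
    tips <- tips[tp >= lo & tp <= hi, , drop = FALSE]
  }
  if (nrow(tips) == 0)
    stop("landmark-B-not-found: no protrusion tip in the mid-band of the malleus ",
         "(incomplete lateral process?)", call. = FALSE)
  # the lateral process is the tip that protrudes farthest from the
  # head-manubrium chord AC; surface-noise curvature spikes hug the axis
  dprot <- vapply(seq_len(nrow(tips)), function(r)
    point_line_distance(as.numeric(unlist(tips[r, c("x", "y", "z")])), A, C), numeric(1))
  if (max(dprot) < config$landmarks$min_protrusion)
    stop("landmark-B-not-found: no tip protrudes more than ",
         config$landmarks$min_protrusion, " mm from the AC chord", call. = FALSE)
  B <- as.numeric(unlist(tips[which.max(dprot), c("x", "y", "z")]))
  # refine to the true protrusion apex: the vertex near the tip farthest
  # from the head-manubrium chord AC
  near <- which(sqrt(rowSums(sweep(V, 2, B)^2)) <= config$landmarks$tip_refine_radius)
  dAC <- vapply(near, function(vv) point_line_distance(V[vv, ], A, C), numeric(1))
  B <- as.numeric(V[near[which.max(dAC)], ])
  feature_point_set(
    list(A = A, B = B, C = C),
    list(A = "farthest-pair end with larger cross-section (head)",
         B = "max-Gaussian-curvature protrusion tip in central 50% band",
         C = "farthest-pair end with smaller cross-section (manubrium tip)"))
}

#' Locate incus landmarks D, E, F, G
#'
#' (D, G) is the farthest pair; G (long-process tip) is the end nearer the
#' stapes head when one is supplied, otherwise the thinner end. F is the
#' protrusion tip farthest from the line DG (short-process tip); E is the
#' body-region vertex (projections nearer D than the DG midpoint) farthest
#' from F.
#'
#' @inheritParams locate_malleus_landmarks
#' @param stapes_head optional stapes head centre (mm) used to orient D/G.
#' @export
locate_incus_landmarks <- function(mesh, curv = NULL, obb = NULL,
                                   stapes_head = NULL, config = measure_config()) {
  if (is.null(curv)) curv <- compute_vertex_curvatures(mesh)
  if (is.null(obb)) obb <- compute_obb(mesh)
  V <- mesh$vertices
  warnings <- character()
  fp <- farthest_point_pair(mesh)
  axis <- obb$axes[, 1]
  proj <- as.numeric(sweep(V, 2, obb$center) %*% axis)
  if (!is.null(stapes_head)) {
    dp <- sqrt(sum((fp$p - stapes_head)^2)); dq <- sqrt(sum((fp$q - stapes_head)^2))
    if (dp <= dq) { G <- fp$p; D <- fp$q } else { G <- fp$q; D <- fp$p }
  } else {
    th_p <- end_thickness(V, axis, proj, proj[fp$i])
    th_q <- end_thickness(V, axis, proj, proj[fp$j])
    if (abs(th_p - th_q) < 0.05 * max(th_p, th_q)) {
      warnings <- c(warnings, "ambiguous D/G assignment (equal end cross-sections); lexicographic order used")
      ends <- list(fp$p, fp$q)
      ords <- order(c(fp$p[1], fp$q[1]), c(fp$p[2], fp$q[2]), c(fp$p[3], fp$q[3]))
      D <- ends[[ords[1]]]; G <- ends[[ords[2]]]
    } else if (th_p >= th_q) { D <- fp$p; G <- fp$q } else { D <- fp$q; G <- fp$p }
  }
  tips <- detect_protrusion_tips(mesh, curv, config$landmarks$min_gauss,
                                 config$landmarks$nms_radius)
  if (nrow(tips) < 2)
    stop("landmark error: fewer than two protrusion tips on the incus", call. = FALSE)
  dline <- vapply(seq_len(nrow(tips)), function(r)
    point_line_distance(as.numeric(unlist(tips[r, c("x", "y", "z")])), D, G), numeric(1))
  F_pt <- as.numeric(unlist(tips[which.max(dline), c("x", "y", "z")]))
  # body region: projections (along the dominant D-G chord) nearer to D
  # than to the DG midpoint
  u <- (D - G) / sqrt(sum((D - G)^2))
  tv <- as.numeric(sweep(V, 2, G) %*% u)
  cut <- (sqrt(sum((D - G)^2)) + sqrt(sum((D - G)^2)) / 2) / 2
  body <- which(tv >= cut)
  # refine F to the short-process apex: the vertex near the detected tip
  # farthest from the body centroid
  cB <- colMeans(V[body, , drop = FALSE])
  near <- which(sqrt(rowSums(sweep(V, 2, F_pt)^2)) <= config$landmarks$tip_refine_radius)
  F_pt <- as.numeric(V[near[which.max(rowSums(sweep(V[near, , drop = FALSE], 2, cB)^2))], ])
  dF <- sqrt(rowSums(sweep(V[body, , drop = FALSE], 2, F_pt)^2))
  E <- as.numeric(V[body[which.max(dF)], ])
  feature_point_set(
    list(D = D, E = E, F = F_pt, G = G),
    list(D = "farthest-pair end at the body", E = "body vertex farthest from F",
         F = "protrusion tip farthest from line DG",
         G = if (!is.null(stapes_head)) "farthest-pair end nearer stapes head"
             else "farthest-pair end with smaller cross-section"),
    warnings)
}

#' Locate stapes landmarks G_s, H, I, J
#'
#' The footplate is found as the largest connected near-planar vertex
#' cluster (|mean curvature| below `planar_h`, plane-fit RMS below
#' `planar_rms`). The head landmark G_s and the footplate landmark I are the
#' farthest pair between the head-side region and the footplate (the
#' literal "maximum distance from the head to the footplate's bottom");
#' when the incus long-process tip is supplied, G_s snaps to the stapes
#' vertex nearest to it (the articular contact point) and I maximizes
#' distance from there. H and J come from [footplate_major_axis()], which is
#' robust to perforations and obliquity.
#'
#' @inheritParams locate_malleus_landmarks
#' @param incus_G optional incus long-process tip (mm).
#' @export
locate_stapes_landmarks <- function(mesh, curv = NULL, obb = NULL, incus_G = NULL,
                                    config = measure_config()) {
  if (is.null(curv)) curv <- compute_vertex_curvatures(mesh)
  if (is.null(obb)) obb <- compute_obb(mesh)
  V <- mesh$vertices
  warnings <- character()
  flat <- which(abs(curv$mean) < config$landmarks$planar_h)
  clusters <- vertex_clusters(mesh, flat)
  if (length(clusters) == 0)
    stop("footplate-not-found: no planar vertex cluster (incomplete stapes segmentation?)",
         call. = FALSE)
  # try candidate clusters largest-first; the validity rules (flat,
  # bounding, millimetre-scale, contiguous plate) pick out the true
  # footplate even when surface noise fragments it below other flat patches
  found <- NULL
  reason <- "no candidate cluster"
  for (cluster in clusters) {
    fit <- suppressWarnings(
      footplate_major_axis(V[cluster, , drop = FALSE],
                           ratio_warn = config$landmarks$axis_ratio_warn))
    if (fit$rms > config$landmarks$planar_rms) {
      reason <- paste0("planar cluster plane-fit RMS ", format(fit$rms, digits = 3),
                       " mm exceeds tolerance")
      next
    }
    # head side: orient the plate normal towards the far side of the mesh
    sd_all <- as.numeric(sweep(V, 2, fit$centroid) %*% fit$normal)
    if (abs(min(sd_all)) > max(sd_all)) { fit$normal <- -fit$normal; sd_all <- -sd_all }
    # the footplate caps the solid: essentially everything lies on one side
    # of its plane; flat patches elsewhere split the mesh and fail this
    if (-min(sd_all) > 0.4) {
      reason <- "planar cluster does not bound the solid"
      next
    }
    # full plate region: the detected flat face (or arc of one, if a
    # perforation fragments it) plus the rounded rim, as a thin slab around
    # the cluster plane; the rim carries the true major-axis extremes
    plate <- union(which(abs(sd_all) <= config$landmarks$plate_slab), cluster)
    fit2 <- suppressWarnings(
      footplate_major_axis(V[plate, , drop = FALSE],
                           ratio_warn = config$landmarks$axis_ratio_warn))
    proj2 <- as.numeric(V[plate, , drop = FALSE] %*% fit2$axis)
    if (diff(range(proj2)) < config$landmarks$min_plate_extent) {
      reason <- "planar region extent below the minimum plate size"
      next
    }
    if (acos(min(1, abs(sum(fit$normal * fit2$normal)))) > 30 * pi / 180) {
      reason <- "no plane-consistent plate region"
      next
    }
    # a plate fills its major axis continuously; disconnected co-planar
    # patches (e.g. the exposed crura end caps of an incomplete stapes)
    # project bimodally with an empty middle
    bins <- table(cut(proj2, breaks = seq(min(proj2), max(proj2), length.out = 11)))
    if (mean(bins > 0) < 0.8) {
      reason <- "planar region is not a contiguous plate"
      next
    }
    found <- list(fit = fit, fit2 = fit2, plate = plate, sd_all = sd_all)
    break
  }
  if (is.null(found))
    stop("footplate-not-found: ", reason, call. = FALSE)
  fit <- found$fit; fit2 <- found$fit2; plate <- found$plate; sd_all <- found$sd_all
  if (fit$ambiguous || fit2$ambiguous)
    warnings <- c(warnings, "ambiguous footplate major axis")
  fit$H <- fit2$H; fit$J <- fit2$J
  head_side <- which(sd_all > config$landmarks$head_margin)
  head_side <- setdiff(head_side, plate)
  if (length(head_side) == 0)
    stop("footplate-not-found: no vertices on the head side of the footplate", call. = FALSE)
  if (!is.null(incus_G)) {
    iG <- which.min(rowSums(sweep(V, 2, incus_G)^2))
    Gs <- as.numeric(V[iG, ])
    dI <- sqrt(rowSums(sweep(V[plate, , drop = FALSE], 2, Gs)^2))
    I_pt <- as.numeric(V[plate[which.max(dI)], ])
    prov_g <- "stapes vertex nearest the incus long-process tip"
  } else {
    fp <- farthest_point_pair(mesh, head_side, plate)
    Gs <- fp$p; I_pt <- fp$q
    prov_g <- "head-side end of the maximal head-to-footplate distance"
  }
  feature_point_set(
    list(G_s = Gs, H = fit$H, I = I_pt, J = fit$J),
    list(G_s = prov_g,
         H = "footplate major-axis extreme (min projection)",
         I = "footplate vertex farthest from the head",
         J = "footplate major-axis extreme (max projection)"),
    warnings)
}

# 1-ring-connected components within a vertex subset, largest first
vertex_clusters <- function(mesh, subset, min_size = 10L, max_clusters = 5L) {
  if (length(subset) == 0) return(list())
  comp <- cluster_labels(mesh, subset)
  sizes <- tabulate(comp[subset])
  ord <- order(sizes, decreasing = TRUE)
  ord <- ord[sizes[ord] >= min_size]
  lapply(utils::head(ord, max_clusters), function(k) which(comp == k))
}

# largest 1-ring-connected component within a vertex subset
largest_vertex_cluster <- function(mesh, subset) {
  cl <- vertex_clusters(mesh, subset, min_size = 1L, max_clusters = 1L)
  if (length(cl) == 0) integer(0) else cl[[1]]
}

cluster_labels <- function(mesh, subset) {
  if (length(subset) == 0) return(integer(0))
  adj <- vertex_adjacency_list(mesh)
  inset <- logical(nrow(mesh$vertices))
  inset[subset] <- TRUE
  comp <- integer(nrow(mesh$vertices))
  cur <- 0L
  for (s in subset) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- adj[[v]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      if (length(nb)) stack <- c(stack, nb)
    }
  }
  comp
}
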