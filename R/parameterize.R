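#' Pipeline configuration
#'
#' Tunable parameters of the measurement pipeline with their defaults:
#' level-set refinement (`refine$iterations`, `refine$smooth_weight`,
#' `refine$fidelity_band_voxels` — the hard containment band in voxels),
#' windowed-sinc smoothing (`smooth$iterations`, `smooth$passband`), and
#' landmark detection thresholds (`landmarks$min_gauss` 1/mm^2,
#' `landmarks$nms_radius` mm, `landmarks$planar_h` 1/mm,
#' `landmarks$planar_rms` mm, `landmarks$head_margin` mm,
#' `landmarks$axis_ratio_warn`).
#'
#' @param ... named overrides, e.g. `measure_config(smooth = list(iterations = 10))`;
#'   unknown keys are rejected.
#' @export
measure_config <- function(...) {
  cfg <- list(
    refine = list(iterations = 2L, smooth_weight = 0.5, fidelity_band_voxels = 0.5),
    smooth = list(iterations = 20L, passband = 0.1),
    landmarks = list(min_gauss = 2.5, nms_radius = 0.4, planar_h = 0.5,
                     planar_rms = 0.15, head_margin = 0.3, axis_ratio_warn = 1.05,
                     plate_slab = 0.25, tip_refine_radius = 0.6,
                     min_protrusion = 1.2, min_plate_extent = 1.0))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config key: '", nm, "'", call. = FALSE)
    for (k in names(over[[nm]])) {
      if (!k %in% names(cfg[[nm]]))
        stop("unknown config key: '", nm, "$", k, "'", call. = FALSE)
      cfg[[nm]][[k]] <- over[[nm]][[k]]
    }
  }
  cfg
}

#' Euclidean distance between two points
#' @param p,q length-3 mm coordinates.
#' @export
distance3 <- function(p, q) {
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("distance3: non-finite coordinates", call. = FALSE)
  sqrt(sum((p - q)^2))
}

#' Incudostapedial joint angle
#'
#' Angle at vertex G between the rays G->D and G->I, degrees, computed with
#' the numerically stable two-argument arctangent of the cross and dot
#' products.
#'
#' @param D,G,I length-3 mm coordinates; D and I must differ from G.
#' @export
joint_angle <- function(D, G, I) {
  u <- D - G; v <- I - G
  if (sqrt(sum(u * u)) < 1e-12 || sqrt(sum(v * v)) < 1e-12)
    stop("degenerate joint angle: coincident points", call. = FALSE)
  cr <- pracma_cross(u, v)
  atan2(sqrt(sum(cr * cr)), sum(u * v)) * 180 / pi
}

stapes_centre <- function(mesh) colMeans(mesh$vertices)

measurement_names <- c(
  "malleus_total_height_AC", "malleus_manubrium_BC", "malleus_head_neck_AB",
  "incus_total_height_DG", "incus_total_width_EF", "incus_process_distance_FG",
  "stapes_total_height_GI", "stapes_footplate_HJ", "incudostapedial_angle_DGI",
  "malleus_volume", "incus_volume", "stapes_volume")

stapes_dependent <- c("stapes_total_height_GI", "stapes_footplate_HJ",
                      "incudostapedial_angle_DGI", "stapes_volume")

#' Measure the twelve ossicular-chain parameters from a label volume
#'
#' Runs the full pipeline per ossicle — surface reconstruction, curvature /
#' bounding-box analysis, landmark detection — and maps the landmarks to the
#' twelve reported parameters: eight distances (mm), the incudostapedial
#' joint angle (degrees) and three mesh volumes (mm^3). Malleus and incus
#' labels are required; a stapes whose landmarks cannot be detected (the
#' clinically common incomplete segmentation) yields a flagged partial
#' result, not a failure.
#'
#' @param vol a [label_volume] with the three ossicle labels.
#' @param labels an [ossicle_label_map].
#' @param config a [measure_config()].
#' @param ear_id identifier copied into the output row.
#' @return An object of class `ossicle_measurements`: list with
#'   `measurements` (one-row tibble: ear_id, the 12 parameters, logical
#'   `*_available` flags), `landmarks` (per-ossicle `feature_point_set`s),
#'   and `qc` (per-ossicle reconstruction statistics and warnings).
#' @export
measure_chain <- function(vol, labels = ossicle_label_map(),
                          config = measure_config(), ear_id = "ear") {
  stopifnot(inherits(vol, "label_volume"))
  present <- function(l) any(vol$data == l)
  if (!present(labels$malleus) || !present(labels$incus))
    stop("input error: malleus and incus labels must both be present", call. = FALSE)

  qc <- list(warnings = character())
  out <- stats::setNames(rep(NA_real_, length(measurement_names)), measurement_names)
  lms <- list()

  recon <- function(lab) {
    mask <- suppressWarnings(extract_label_mask(vol, lab))
    reconstruct_surface(mask, config)
  }

  # malleus
  rm_ <- recon(labels$malleus)
  cm <- compute_vertex_curvatures(rm_$mesh)
  om <- compute_obb(rm_$mesh)
  fm <- locate_malleus_landmarks(rm_$mesh, cm, om, config)
  lms$malleus <- fm
  out["malleus_total_height_AC"] <- distance3(fm$points$A, fm$points$C)
  out["malleus_manubrium_BC"] <- distance3(fm$points$B, fm$points$C)
  out["malleus_head_neck_AB"] <- distance3(fm$points$A, fm$points$B)
  out["malleus_volume"] <- rm_$qc$mesh_volume_mm3
  qc$malleus <- rm_$qc

  # incus (stapes head passed in afterwards if the stapes succeeds; the
  # thinner-end rule is used here and cross-checked below)
  ri <- recon(labels$incus)
  ci <- compute_vertex_curvatures(ri$mesh)
  oi <- compute_obb(ri$mesh)
  fi <- locate_incus_landmarks(ri$mesh, ci, oi, stapes_head = NULL, config = config)
  lms$incus <- fi
  out["incus_total_height_DG"] <- distance3(fi$points$D, fi$points$G)
  out["incus_total_width_EF"] <- distance3(fi$points$E, fi$points$F)
  out["incus_process_distance_FG"] <- distance3(fi$points$F, fi$points$G)
  out["incus_volume"] <- ri$qc$mesh_volume_mm3
  qc$incus <- ri$qc
  qc$warnings <- c(qc$warnings, fm$warnings, fi$warnings)

  # stapes: optional, failure is a flagged partial result
  stapes_ok <- FALSE
  if (present(labels$stapes)) {
    st <- tryCatch({
      rs <- recon(labels$stapes)
      cs <- compute_vertex_curvatures(rs$mesh)
      os <- compute_obb(rs$mesh)
      fs <- locate_stapes_landmarks(rs$mesh, cs, os, incus_G = fi$points$G,
                                    config = config)
      list(rs = rs, cs = cs, os = os, fs = fs)
    }, error = function(e) e)
    if (!inherits(st, "error")) {
      fs <- st$fs
      # re-orient incus D/G with the stapes now known: the long-process tip
      # is the end nearer the stapes; if the initial thickness rule had them
      # reversed, the articular snap used the wrong point, so redo it
      ctr <- stapes_centre(st$rs$mesh)
      if (distance3(fi$points$D, ctr) < distance3(fi$points$G, ctr)) {
        # the thickness rule had D/G reversed: re-detect the incus with the
        # stapes position known (E and F depend on the body-region cut),
        # then redo the articular snap with the corrected G
        fi <- locate_incus_landmarks(ri$mesh, ci, oi, stapes_head = ctr,
                                     config = config)
        out["incus_total_height_DG"] <- distance3(fi$points$D, fi$points$G)
        out["incus_total_width_EF"] <- distance3(fi$points$E, fi$points$F)
        out["incus_process_distance_FG"] <- distance3(fi$points$F, fi$points$G)
        qc$warnings <- c(qc$warnings, "incus D/G re-oriented to match stapes position")
        lms$incus <- fi
        fs <- locate_stapes_landmarks(st$rs$mesh, st$cs, st$os,
                                      incus_G = fi$points$G, config = config)
      }
      lms$stapes <- fs
      out["stapes_total_height_GI"] <- distance3(fs$points$G_s, fs$points$I)
      out["stapes_footplate_HJ"] <- distance3(fs$points$H, fs$points$J)
      out["incudostapedial_angle_DGI"] <-
        joint_angle(fi$points$D, fi$points$G, fs$points$I)
      out["stapes_volume"] <- st$rs$qc$mesh_volume_mm3
      qc$stapes <- st$rs$qc
      qc$warnings <- c(qc$warnings, fs$warnings)
      stapes_ok <- TRUE
    } else {
      qc$warnings <- c(qc$warnings, paste("stapes unavailable:", conditionMessage(st)))
    }
  } else {
    qc$warnings <- c(qc$warnings, "stapes label absent")
  }

  avail <- stats::setNames(!is.na(out), paste0(measurement_names, "_available"))
  row <- tibble::as_tibble(c(list(ear_id = ear_id), as.list(out), as.list(avail)))
  structure(list(measurements = row, landmarks = lms, qc = qc,
                 stapes_available = stapes_ok),
            class = "ossicle_measurements")
}

#' @export
print.ossicle_measurements <- function(x, ...) {
  cat("<ossicle_measurements> ear '", x$measurements$ear_id[1], "'\n", sep = "")
  m <- x$measurements
  for (nm in measurement_names) {
    v <- m[[nm]]
    unit <- if (grepl("angle", nm)) "deg" else if (grepl("volume", nm)) "mm^3" else "mm"
    cat(sprintf("  %-28s %s\n", nm,
                if (is.na(v)) "unavailable" else paste(format(round(v, 3)), unit)))
  }
  if (length(x$qc$warnings)) cat("  warnings:", paste(x$qc$warnings, collapse = "; "), "\n")
  invisible(x)
}
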