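#' Phantom recovery evaluation
#'
#' Generates a seeded suite of randomized chain phantoms (dimensions drawn
#' around the cohort's automated population means with their reported
#' standard deviations, fully random rigid pose), optionally degrades the
#' label volumes with boundary-flip noise, runs the measurement pipeline on
#' each, and reports recovery errors against the analytic ground truth.
#'
#' @param n_phantoms number of phantoms (>= 1).
#' @param noise_levels boundary flip probabilities to evaluate (0 = clean).
#' @param seed integer seed; the whole suite is reproducible.
#' @param spacing voxel size, mm.
#' @param config a [measure_config()].
#' @return A `recovery_report`: tibble with columns `phantom`, `noise`,
#'   `parameter`, `truth`, `measured`, `error` (`measured - truth`; NA with
#'   a failure note when the pipeline declined the case).
#' @export
evaluate_recovery <- function(n_phantoms = 50L, noise_levels = 0, seed = 1L,
                              spacing = 0.1, config = measure_config()) {
  if (n_phantoms < 1) stop("n_phantoms must be >= 1", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_phantoms)) {
    ph <- random_chain_phantom(spacing = spacing)
    tr <- ph$truth
    truth <- c(tr$parameters,
               malleus_volume = unname(tr$volumes["malleus"]),
               incus_volume = unname(tr$volumes["incus"]),
               stapes_volume = unname(tr$volumes["stapes"]))
    for (nz in noise_levels) {
      vol <- if (nz > 0) perturb_volume(ph$volume, nz, seed = seed + 7919L * i) else ph$volume
      meas <- tryCatch(measure_chain(vol, config = config, ear_id = paste0("phantom_", i)),
                       error = function(e) e)
      for (nm in names(truth)) {
        got <- if (inherits(meas, "error")) NA_real_ else meas$measurements[[nm]]
        tru <- unname(truth[nm])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phantom = i, noise = nz, parameter = nm,
          truth = tru, measured = got, error = got - tru,
          note = if (inherits(meas, "error")) conditionMessage(meas) else NA_character_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_report", class(out))
  out
}

# one randomized phantom around the population means; resamples until the
# drawn dimensions are geometrically consistent
random_chain_phantom <- function(spacing = 0.1, max_tries = 50L) {
  draw <- function(mu, sd, lim = 1.5) mu + sd * max(min(stats::rnorm(1), lim), -lim)
  for (try in seq_len(max_tries)) {
    specs <- tryCatch({
      ac <- draw(7.91, 0.36); bc <- draw(4.36, 0.28); ab <- draw(4.89, 0.31)
      # the lateral process must stand clear of the head-manubrium chord;
      # a near-collinear A-B-C triangle is anatomically degenerate and
      # indistinguishable from surface noise at mesh scale
      tb <- (ab^2 - bc^2 + ac^2) / (2 * ac)
      if (ab^2 - tb^2 < 1.5^2) stop("degenerate malleus draw")
      mal <- malleus_spec(total_height_AC = ac, manubrium_BC = bc,
                          head_neck_AB = ab)
      dg <- draw(6.56, 0.38); ef <- draw(4.97, 0.33); fg <- draw(5.55, 0.39)
      # the total height must dominate the other extents by a clear margin,
      # or the farthest-pair definition of D/G is ambiguous at mesh scale
      if (dg < fg + 0.3 || dg < ef + 0.3) stop("inconsistent incus draw")
      inc <- incus_spec(total_height_DG = dg, total_width_EF = ef,
                        process_distance_FG = fg)
      sta <- stapes_spec(total_height_GI = draw(3.25, 0.22),
                         footplate_HJ = draw(2.63, 0.15))
      ang <- draw(96.83, 6.03)
      pose <- random_pose(0.05)
      generate_chain_phantom(mal, inc, sta, joint_angle_deg = ang,
                             spacing = spacing, pose = pose)
    }, error = function(e) e)
    if (!inherits(specs, "error")) return(specs)
  }
  stop("could not draw a consistent phantom in ", max_tries, " tries", call. = FALSE)
}

#' Summarize a recovery report
#'
#' Per noise level and parameter: bias (mean error), MAE, maximum absolute
#' error, the relative MAE (for volumes), and the failure count.
#'
#' @param report a `recovery_report` from [evaluate_recovery()].
#' @export
recovery_summary <- function(report) {
  report |>
    dplyr::group_by(.data$noise, .data$parameter) |>
    dplyr::summarize(
      n = dplyr::n(),
      n_failed = sum(is.na(.data$measured)),
      bias = mean(.data$error, na.rm = TRUE),
      mae = mean(abs(.data$error), na.rm = TRUE),
      max_abs_error = max(abs(.data$error), na.rm = TRUE),
      rel_mae = mean(abs(.data$error) / .data$truth, na.rm = TRUE),
      .groups = "drop")
}
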