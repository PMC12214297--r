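#' Oriented (near-)minimum bounding box
#'
#' PCA-initialized box refined by deterministic coordinate-descent rotation
#' search over the support vertices (extreme points in a fixed set of
#' directions), minimizing box volume. The result is near-minimal: the test
#' suite checks it is never worse than the plain PCA box and matches a dense
#' 0.5-degree rotation-grid search on box fixtures to within 1%.
#'
#' @param x a [triangle_mesh] or an `n x 3` point matrix.
#' @return An `oriented_bbox`: list with `center` (mm), `axes` (3x3
#'   orthonormal, columns sorted by decreasing extent), `extents` (full side
#'   lengths, mm, sorted decreasing) and `volume` (mm^3).
#' @export
compute_obb <- function(x) {
  P <- if (inherits(x, "triangle_mesh")) x$vertices else as.matrix(x)
  stopifnot(ncol(P) == 3)
  if (nrow(P) < 4) stop("degenerate geometry: need at least 4 vertices", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0)
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: vertices are (nearly) coplanar or collinear", call. = FALSE)
  R0 <- sv$v
  if (det(R0) < 0) R0[, 3] <- -R0[, 3]

  cand <- support_points(Pc)
  vol_of <- function(R) {
    Q <- cand %*% R
    prod(apply(Q, 2, function(col) diff(range(col))))
  }
  box_extent <- function(R) {
    Q <- Pc %*% R
    apply(Q, 2, range)
  }
  R <- R0
  best <- vol_of(R)
  planes <- list(c(1, 2), c(1, 3), c(2, 3))
  for (sweep_i in 1:3) {
    for (pl in planes) {
      best_ang <- 0
      for (stage in 1:2) {
        angs <- if (stage == 1) seq(-45, 45, by = 1) else seq(best_ang - 1, best_ang + 1, by = 0.1)
        for (ang in angs) {
          Rrot <- plane_rotation(pl, ang)
          v <- vol_of(R %*% Rrot)
          if (v < best - 1e-12) { best <- v; best_ang <- ang }
        }
      }
      if (best_ang != 0) R <- R %*% plane_rotation(pl, best_ang)
    }
  }
  rng <- box_extent(R)
  ext <- rng[2, ] - rng[1, ]
  ord <- order(ext, decreasing = TRUE)
  axes <- R[, ord, drop = FALSE]
  ext <- ext[ord]
  # deterministic sign convention: largest-magnitude component positive
  for (cc in 1:3) {
    lead <- which.max(abs(axes[, cc]))
    if (axes[lead, cc] < 0) axes[, cc] <- -axes[, cc]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  Q <- Pc %*% axes
  rng2 <- apply(Q, 2, range)
  center <- ctr + as.numeric(axes %*% ((rng2[1, ] + rng2[2, ]) / 2))
  structure(list(center = center, axes = axes,
                 extents = rng2[2, ] - rng2[1, ],
                 volume = prod(rng2[2, ] - rng2[1, ])),
            class = "oriented_bbox")
}

plane_rotation <- function(pl, ang_deg) {
  th <- ang_deg * pi / 180
  R <- diag(3)
  i <- pl[1]; j <- pl[2]
  R[i, i] <- cos(th); R[j, j] <- cos(th)
  R[i, j] <- -sin(th); R[j, i] <- sin(th)
  R
}

# extreme points of a centred cloud in a deterministic set of directions
# (spherical Fibonacci lattice); a compact superset of the support set that
# the rotation search needs
support_points <- function(Pc, n_dir = 128L) {
  if (nrow(Pc) <= 256L) return(Pc)
  i <- seq_len(n_dir) - 0.5
  phi <- acos(1 - 2 * i / n_dir)
  theta <- pi * (1 + sqrt(5)) * i
  D <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  proj <- Pc %*% t(D)
  idx <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  Pc[idx, , drop = FALSE]
}

#' @export
print.oriented_bbox <- function(x, ...) {
  cat("<oriented_bbox> extents ", paste(format(x$extents, digits = 4), collapse = " x "),
      " mm, volume ", format(x$volume, digits = 5), " mm^3\n", sep = "")
  invisible(x)
}
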