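#' Euler-curve-energy active-contour loss
#'
#' Standalone implementation of the segmentation loss used to improve stapes
#' segmentation completeness: a weighted sum of soft Dice loss, pixel-wise
#' binary cross-entropy, and an active-contour energy that penalizes the
#' length and squared curvature of the predicted 0.5-level contour,
#'
#' \deqn{loss = w_{dice} Dice + w_{ce} CE + w_{ace} \int_\ell (\alpha + \beta \kappa^2) d\ell}
#'
#' with printed weights 0.5 / 0.5 / 1e-5 and penalty coefficients
#' \eqn{\alpha = \beta = 0.1}. The curvature is the graph curvature of the
#' probability field computed by central finite differences,
#' \deqn{\kappa = \frac{(1+u_x^2)u_{yy} + (1+u_y^2)u_{xx} - 2 u_x u_y u_{xy}}{(1+u_x^2+u_y^2)^{3/2}}.}
#'
#' @name contour_energy
NULL

#' Active-contour loss parameters
#'
#' @param alpha contour-length penalty (default 0.1).
#' @param beta squared-curvature penalty (default 0.1).
#' @param w_dice,w_ce,w_ace weights of the three loss terms
#'   (defaults 0.5, 0.5, 1e-5).
#' @export
contour_energy_params <- function(alpha = 0.1, beta = 0.1,
                                  w_dice = 0.5, w_ce = 0.5, w_ace = 1e-5) {
  p <- list(alpha = alpha, beta = beta, w_dice = w_dice, w_ce = w_ce, w_ace = w_ace)
  if (any(unlist(p) < 0)) stop("all loss weights must be non-negative", call. = FALSE)
  p
}

#' Graph-curvature field of a 2D scalar field
#'
#' All five derivatives (`ux, uy, uxx, uyy, uxy`) use central finite
#' differences on interior points; the one-pixel boundary ring uses
#' one-sided differences and is flagged in the `boundary` attribute.
#'
#' @param u numeric matrix (at least 3x3), e.g. a foreground probability.
#' @param h grid spacing in pixels.
#' @return Matrix of curvature values with attribute `boundary` (logical
#'   matrix marking the one-sided ring).
#' @export
curvature_field <- function(u, h = 1) {
  u <- as.matrix(u)
  if (nrow(u) < 3 || ncol(u) < 3)
    stop("curvature_field needs a grid of at least 3x3", call. = FALSE)
  sh <- function(m, dr, dc) {
    n <- nrow(m); p <- ncol(m)
    r <- pmin(pmax(seq_len(n) + dr, 1L), n)
    c <- pmin(pmax(seq_len(p) + dc, 1L), p)
    m[r, c, drop = FALSE]
  }
  # central differences with replicated edges give one-sided differences on
  # the boundary ring automatically (with halved denominator there; we use
  # true one-sided forms instead)
  ux <- (sh(u, 1, 0) - sh(u, -1, 0)) / (2 * h)
  uy <- (sh(u, 0, 1) - sh(u, 0, -1)) / (2 * h)
  uxx <- (sh(u, 1, 0) - 2 * u + sh(u, -1, 0)) / h^2
  uyy <- (sh(u, 0, 1) - 2 * u + sh(u, 0, -1)) / h^2
  uxy <- (sh(u, 1, 1) - sh(u, 1, -1) - sh(u, -1, 1) + sh(u, -1, -1)) / (4 * h^2)
  # fix the boundary ring to one-sided first derivatives
  n <- nrow(u); p <- ncol(u)
  ux[1, ] <- (u[2, ] - u[1, ]) / h
  ux[n, ] <- (u[n, ] - u[n - 1, ]) / h
  uy[, 1] <- (u[, 2] - u[, 1]) / h
  uy[, p] <- (u[, p] - u[, p - 1]) / h
  kap <- ((1 + ux^2) * uyy + (1 + uy^2) * uxx - 2 * ux * uy * uxy) /
    (1 + ux^2 + uy^2)^(3 / 2)
  boundary <- matrix(FALSE, n, p)
  boundary[c(1, n), ] <- TRUE
  boundary[, c(1, p)] <- TRUE
  attr(kap, "boundary") <- boundary
  kap
}

#' Active-contour (Euler curve) energy of a probability field
#'
#' Extracts the 0.5-level contour of `u` by 2D marching squares
#' ([grDevices::contourLines()]), samples the curvature field at segment
#' midpoints by bilinear interpolation, and accumulates
#' \eqn{\sum (\alpha + \beta \kappa^2) \Delta\ell}. A field with no
#' 0.5-crossing has zero energy.
#'
#' @param u numeric matrix in `[0, 1]`.
#' @param params a [contour_energy_params()] list.
#' @param level contour level (default 0.5).
#' @export
ace_loss <- function(u, params = contour_energy_params(), level = 0.5) {
  u <- as.matrix(u)
  if (min(u) > level || max(u) < level) return(0)
  kap <- curvature_field(u)
  xs <- seq_len(nrow(u)); ys <- seq_len(ncol(u))
  cl <- grDevices::contourLines(x = xs, y = ys, z = u, levels = level)
  if (length(cl) == 0) return(0)
  total <- 0
  for (cc in cl) {
    px <- cc$x; py <- cc$y
    dx <- diff(px); dy <- diff(py)
    len <- sqrt(dx^2 + dy^2)
    mx <- (px[-1] + px[-length(px)]) / 2
    my <- (py[-1] + py[-length(py)]) / 2
    k <- bilinear_at(kap, mx, my)
    total <- total + sum((params$alpha + params$beta * k^2) * len)
  }
  total
}

bilinear_at <- function(m, x, y) {
  n <- nrow(m); p <- ncol(m)
  x0 <- pmin(pmax(floor(x), 1L), n - 1L); x1 <- x0 + 1L
  y0 <- pmin(pmax(floor(y), 1L), p - 1L); y1 <- y0 + 1L
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) + m[cbind(x1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y1)] * (1 - fx) * fy + m[cbind(x1, y1)] * fx * fy
}

#' Soft Dice loss
#'
#' `1 - 2|P.T| / (|P| + |T|)` with a smoothing epsilon so that two empty
#' masks have zero loss.
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param target binary matrix of the same shape.
#' @param eps smoothing constant.
#' @export
dice_loss <- function(pred, target, eps = 1e-7) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target)))
    stop("dice_loss: shape mismatch", call. = FALSE)
  inter <- sum(pred * target)
  1 - (2 * inter + eps) / (sum(pred) + sum(target) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean pixel-wise cross-entropy with probabilities clipped to
#' `[eps, 1 - eps]` to avoid log(0).
#'
#' @inheritParams dice_loss
#' @export
ce_loss <- function(pred, target, eps = 1e-7) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!all(dim(pred) == dim(target)))
    stop("ce_loss: shape mismatch", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Combined segmentation loss
#'
#' The weighted total `w_dice * Dice + w_ce * CE + w_ace * ACE`, returned
#' together with its components.
#'
#' @inheritParams dice_loss
#' @param params a [contour_energy_params()].
#' @return list with `total`, `dice`, `ce`, `ace`.
#' @export
combined_loss <- function(pred, target, params = contour_energy_params()) {
  d <- dice_loss(pred, target)
  ce <- ce_loss(pred, target)
  ace <- ace_loss(pred, params)
  list(total = params$w_dice * d + params$w_ce * ce + params$w_ace * ace,
       dice = d, ce = ce, ace = ace)
}

#' Smoothed disk probability field (loss-check fixture)
#'
#' An analytically convenient test image: a disk of radius `r` whose
#' indicator is softened over `width` pixels, so the 0.5-level contour is a
#' circle of radius `r` with curvature `1/r` and length `2*pi*r`.
#'
#' @param n image side, pixels.
#' @param r disk radius, pixels.
#' @param center disk centre (defaults to the image centre).
#' @param width transition width, pixels.
#' @export
disk_field <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2), width = 3) {
  g <- seq_len(n)
  d <- sqrt(outer((g - center[1])^2, (g - center[2])^2, `+`))
  1 / (1 + exp((d - r) / (width / 4)))
}
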