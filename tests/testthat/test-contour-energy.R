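test_that("curvature field matches closed forms on polynomial fields", {
  n <- 41; g <- seq(-2, 2, length.out = n); h <- g[2] - g[1]
  # linear field: zero curvature at interior points
  kl <- curvature_field(outer(g, rep(1, n)), h = h)
  expect_lt(max(abs(kl[2:(n - 1), 2:(n - 1)])), 1e-8)
  # constant field
  kc <- curvature_field(matrix(0.3, n, n), h = h)
  expect_equal(max(abs(kc)), 0)
  # paraboloid u = x^2 + y^2 at (1, 0): kappa = 12 / 5^(3/2)
  kq <- curvature_field(outer(g^2, g^2, `+`), h = h)
  i <- which.min(abs(g - 1)); j <- which.min(abs(g))
  expect_equal(kq[i, j], 12 / 5^1.5, tolerance = 1e-6)
  expect_error(curvature_field(matrix(0, 2, 5)), "3x3")
})

test_that("curvature discretization converges at second order", {
  # a non-polynomial field (central differences are exact on quadratics)
  kap_err <- function(n) {
    g <- seq(-2, 2, length.out = n); h <- g[2] - g[1]
    u <- outer(sin(g), cos(g))
    k <- curvature_field(u, h = h)
    x <- g[which.min(abs(g - 0.7))]; y <- g[which.min(abs(g - 0.3))]
    ux <- cos(x) * cos(y); uy <- -sin(x) * sin(y)
    uxx <- -sin(x) * cos(y); uyy <- -sin(x) * cos(y); uxy <- -cos(x) * sin(y)
    truth <- ((1 + ux^2) * uyy + (1 + uy^2) * uxx - 2 * ux * uy * uxy) /
      (1 + ux^2 + uy^2)^1.5
    abs(k[which.min(abs(g - 0.7)), which.min(abs(g - 0.3))] - truth)
  }
  e1 <- kap_err(41)   # h = 0.1
  e2 <- kap_err(81)   # h = 0.05
  expect_gt(e1 / max(e2, 1e-15), 3)
})

test_that("active-contour energy matches the analytic circle integral", {
  expect_equal(ace_loss(matrix(0, 32, 32)), 0)
  u <- disk_field(64, 10)
  expect_equal(ace_loss(u), (0.1 + 0.1 / 100) * 2 * pi * 10, tolerance = 0.03)
  # scale behaviour: length term grows with r, curvature term shrinks
  vals <- vapply(c(5, 10, 20, 40), function(r)
    ace_loss(disk_field(2 * r + 24, r)), numeric(1))
  expected <- vapply(c(5, 10, 20, 40), function(r)
    (0.1 + 0.1 / r^2) * 2 * pi * r, numeric(1))
  expect_true(all(abs(vals / expected - 1) < 0.05))
  # the printed ratio check between r = 20 and r = 10
  expect_equal(vals[3] / vals[2], expected[3] / expected[2], tolerance = 0.03)
})

test_that("dice and cross-entropy behave on canonical mask pairs", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_loss(a, a), 0, tolerance = 1e-6)
  expect_equal(dice_loss(a, 1 - a), 1, tolerance = 1e-6)
  expect_equal(dice_loss(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2)), 0.5,
               tolerance = 1e-6)
  expect_equal(dice_loss(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_lt(ce_loss(a, a), 1e-5)
  expect_gt(ce_loss(1 - a, a), 10)
})

test_that("combined loss recomposes from its parts with the printed weights", {
  set.seed(4)
  target <- matrix(0, 48, 48)
  target[outer((1:48 - 20)^2, (1:48 - 24)^2, `+`) <= 100] <- 1
  pred <- disk_field(48, 10, center = c(24, 24))
  p <- contour_energy_params()
  expect_equal(p$w_dice, 0.5)
  expect_equal(p$w_ce, 0.5)
  expect_equal(p$w_ace, 1e-5)
  got <- combined_loss(pred, target, p)
  expect_equal(got$total,
               0.5 * dice_loss(pred, target) + 0.5 * ce_loss(pred, target) +
                 1e-5 * ace_loss(pred, p),
               tolerance = 1e-12)
  # weights (1, 0, 0) reduce to the dice loss exactly
  p100 <- contour_energy_params(w_dice = 1, w_ce = 0, w_ace = 0)
  expect_equal(combined_loss(pred, target, p100)$total, dice_loss(pred, target),
               tolerance = 1e-12)
  # near-perfect prediction of an empty target
  empty <- combined_loss(matrix(0, 16, 16), matrix(0, 16, 16), p)
  expect_lt(empty$total, 1e-5)
  expect_error(contour_energy_params(alpha = -1), "non-negative")
})
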