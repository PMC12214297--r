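# Shared geometric fixtures, all generated in code.

# icosphere: subdivided icosahedron projected onto a sphere of radius r
icosphere <- function(r = 1, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env()
    nv <- nrow(V)
    newF <- matrix(0L, nrow(F) * 4, 3)
    Vlist <- list(V)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- get0(key, envir = edge_mid)
      if (!is.null(got)) return(got)
      m <- (Vlist[[1]][a, ] + Vlist[[1]][b, ]) / 2
      Vlist[[1]] <<- rbind(Vlist[[1]], m)
      id <- nrow(Vlist[[1]])
      assign(key, id, envir = edge_mid)
      id
    }
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- Vlist[[1]]
    F <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * r
  triangle_mesh(V, F)
}

# 12-triangle axis-aligned unit cube mesh with outward orientation
unit_cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  triangle_mesh(V, F)
}

# level-set field of an analytic signed-distance function on a cube grid
sdf_field <- function(fn, lim = 1.5, h = 0.05) {
  g <- seq(-lim, lim, by = h)
  n <- length(g)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  vals <- fn(pts)
  structure(list(values = array(vals, c(n, n, n)), spacing = rep(h, 3),
                 origin = rep(-lim, 3)),
            class = "levelset_field")
}

sphere_sdf <- function(r) function(p) sqrt(rowSums(p^2)) - r

capsule_sdf <- function(a, b, r) function(p) {
  ab <- b - a
  t <- pmin(pmax(sweep(p, 2, a) %*% ab / sum(ab^2), 0), 1)
  d <- sweep(p, 2, a) - tcrossprod(t[, 1], ab)
  sqrt(rowSums(d^2)) - r
}

# default chain phantom, generated once per test run
cached_chain <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_chain_phantom(spacing = 0.1)
    val
  }
})

cached_chain_measured <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- measure_chain(cached_chain()$volume)
    val
  }
})

expect_point_close <- function(p, q, tol) {
  expect_lt(sqrt(sum((p - q)^2)), tol)
}
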