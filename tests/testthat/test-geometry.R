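test_that("triangle areas match hand-evaluated cross products", {
  expect_equal(triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(triangle_area(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1)), sqrt(2) / 2)
  expect_error(triangle_area(c(0, 0), c(1, 0, 0), c(0, 1, 0)), "length 3")
})

test_that("quad area depends on the diagonal only for non-planar quads", {
  sq <- list(a = c(0, 0, 0), b = c(1, 0, 0), c = c(1, 1, 0), d = c(0, 1, 0))
  expect_equal(quad_area(sq$a, sq$b, sq$c, sq$d, "A"), 1)
  expect_equal(quad_area(sq$a, sq$b, sq$c, sq$d, "B"), 1)
  # warped quad: hand-evaluated cross products
  a <- c(0, 0, 0); b <- c(1, 0, 0); cc <- c(1, 1, 1); d <- c(0, 1, 0)
  expect_equal(quad_area(a, b, cc, d, "A"), sqrt(2))
  expect_equal(quad_area(a, b, cc, d, "B"), 0.5 + sqrt(3) / 2)
  # planar quads agree between diagonals on randomized inputs
  set.seed(42)
  for (k in 1:20) {
    p <- matrix(rnorm(6), 2, 3)   # basis of a random plane
    o <- rnorm(3)
    phi <- sort(runif(4, 0, 2 * pi))       # points on an ellipse: convex order
    uv <- cbind(runif(1, 0.5, 2) * cos(phi), runif(1, 0.5, 2) * sin(phi))
    q <- sweep(uv %*% p, 2, o, `+`)  # convex planar quad
    expect_equal(quad_area(q[1, ], q[2, ], q[3, ], q[4, ], "A"),
                 quad_area(q[1, ], q[2, ], q[3, ], q[4, ], "B"),
                 tolerance = 1e-9)
  }
})

test_that("areas are invariant under rigid motions", {
  set.seed(7)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- c(10, -3, 2)
  for (k in 1:20) {
    P <- matrix(rnorm(12), 4, 3)
    Q <- sweep(P %*% t(R), 2, tr, `+`)
    expect_equal(triangle_area(P[1, ], P[2, ], P[3, ]),
                 triangle_area(Q[1, ], Q[2, ], Q[3, ]), tolerance = 1e-9)
    expect_equal(quad_area(P[1, ], P[2, ], P[3, ], P[4, ], "B"),
                 quad_area(Q[1, ], Q[2, ], Q[3, ], Q[4, ], "B"),
                 tolerance = 1e-9)
  }
})

test_that("ILM interpolation is piecewise-linear in arclength", {
  cv <- ilm_curve(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(interpolate_ilm(cv, 1)[1, ], c(1, 0, 0))
  expect_equal(interpolate_ilm(cv, 0)[1, ], c(0, 0, 0))
  cv2 <- ilm_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(interpolate_ilm(cv2, 1.5)[1, ], c(1, 0.5, 0))
  expect_equal(interpolate_ilm(cv2, 2)[1, ], c(1, 1, 0))
  expect_error(interpolate_ilm(cv2, 2.5), "arclength")
  expect_error(interpolate_ilm(cv2, -0.1), "arclength")
  # continuity: |f(t+eps) - f(t)| <= eps for arclength parametrization
  set.seed(3)
  v <- cbind(cumsum(runif(10, 0.05, 0.2)), rnorm(10, sd = 0.05), rnorm(10, sd = 0.05))
  cv3 <- ilm_curve(v)
  L <- cv3$s[length(cv3$s)]
  t0 <- runif(50, 0, L - 1e-3)
  eps <- 1e-3
  d <- sqrt(rowSums((interpolate_ilm(cv3, t0 + eps) - interpolate_ilm(cv3, t0))^2))
  expect_true(all(d <= eps + 1e-12))
})

test_that("ILM curve constructor validates its invariants", {
  expect_error(ilm_curve(matrix(0, 1, 3)), "at least 2")
  expect_error(ilm_curve(rbind(c(0, 0, 0), c(0, 0, 0))), "zero-length")
  expect_error(ilm_curve(rbind(c(0, 0, NA), c(1, 0, 0))), "finite")
  cv <- ilm_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0)))
  expect_equal(cv$s, c(0, 1, 3))
})

test_that("BMO polygon area matches closed forms and is rigid-invariant", {
  sc <- cylinder_scan(48)
  expect_equal(bmo_polygon_area(sc), 48 / 2 * sin(2 * pi / 48), tolerance = 1e-12)
  # rigidly rotated copy has identical area
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(bmo_polygon_area(rigid_transform(sc, R, c(5, -2, 1))),
               bmo_polygon_area(sc), tolerance = 1e-9)
  # ellipse sampled at 48 angles is within 0.5% of pi*a*b
  ang <- (0:47) * 360 / 48
  rad <- ang * pi / 180
  a <- 0.9; b <- 0.6
  rho <- a * b / sqrt((b * cos(rad))^2 + (a * sin(rad))^2)
  bmo <- cbind(rho * cos(rad), rho * sin(rad), 0)
  ilm <- lapply(seq_len(48), function(i) rbind(bmo[i, ], bmo[i, ] + c(0, 0, 0.3)))
  sc2 <- star_scan("OD", ang, bmo, ilm)
  expect_equal(bmo_polygon_area(sc2), pi * a * b, tolerance = 0.005)
  expect_error(bmo_polygon_area(star_scan("OD", c(0, 180), matrix(rnorm(6), 2, 3),
                                          list(rbind(c(0, 0, 0), c(1, 0, 0)),
                                               rbind(c(0, 0, 0), c(-1, 0, 0))))),
               "3 spokes")
})

test_that("rigid_transform rejects improper rotations and preserves geometry", {
  sc <- cylinder_scan(12)
  expect_error(rigid_transform(sc, diag(c(1, 1, -1))), "proper orthogonal")
  expect_error(rigid_transform(sc, matrix(1, 3, 3)), "proper orthogonal")
  id <- rigid_transform(sc, diag(3), c(0, 0, 0))
  expect_identical(bmo_points(id), bmo_points(sc))
  tr <- rigid_transform(sc, diag(3), c(10, -3, 2))
  expect_equal(bmo_polygon_area(tr), bmo_polygon_area(sc), tolerance = 1e-9)
})

test_that("star_scan validation names the offending spoke", {
  ang <- c(0, 120, 240)
  bmo <- diag(3)
  good <- lapply(1:3, function(i) rbind(c(0, 0, 0), c(1, 1, 1)))
  bad <- good
  bad[[2]] <- matrix(c(0, 0, 0), 1, 3)
  expect_error(star_scan("OD", ang, bmo, bad), "spoke 2")
  expect_error(star_scan("OD", c(0, 240, 120), bmo, good), "strictly increasing")
  expect_error(star_scan("OD", c(0, 120, 360), bmo, good), "\\[0, 360\\)")
})
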