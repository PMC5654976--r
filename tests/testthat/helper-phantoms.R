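# Analytic phantom scans and brute-force oracles shared across tests.

# regular-n-gon BMO ring of given radius at z = 0, ILM a vertical segment
# above each BMO point spanning z in [z_lo, z_hi]; minimal rim = perimeter
# times z_lo, attained at the bottom vertex of every segment
cylinder_scan <- function(n = 48L, radius = 1, z_lo = 0.1, z_hi = 0.5) {
  th <- (seq_len(n) - 1) * 360 / n
  rad <- th * pi / 180
  bmo <- cbind(radius * cos(rad), radius * sin(rad), 0)
  ilm <- lapply(seq_len(n), function(i)
    cbind(rep(bmo[i, 1L], 3), rep(bmo[i, 2L], 3),
          c(z_lo, (z_lo + z_hi) / 2, z_hi)))
  star_scan("OD", th, bmo, ilm)
}

cylinder_total <- function(n = 48L, radius = 1, z_lo = 0.1) {
  n * 2 * radius * sin(pi / n) * z_lo
}

# ILM lies in the BMO plane and passes through the BMO points: rim area 0
flat_scan <- function(n = 48L, radius = 1) {
  th <- (seq_len(n) - 1) * 360 / n
  rad <- th * pi / 180
  bmo <- cbind(radius * cos(rad), radius * sin(rad), 0)
  ilm <- lapply(seq_len(n), function(i) {
    r <- c(0.5, radius, 1.4)
    cbind(r * cos(rad[i]), r * sin(rad[i]), 0)
  })
  star_scan("OD", th, bmo, ilm)
}

# rotationally symmetric: BMO circle radius 1 at z = 0, ILM radial segments
# in the plane z = z_ilm with r in [r_lo, r_hi]
frustum_scan <- function(n = 48L, z_ilm = 0.2, r_lo = 0.2, r_hi = 1.4,
                         n_vert = 61L) {
  th <- (seq_len(n) - 1) * 360 / n
  rad <- th * pi / 180
  bmo <- cbind(cos(rad), sin(rad), 0)
  r <- seq(r_lo, r_hi, length.out = n_vert)
  ilm <- lapply(seq_len(n), function(i)
    cbind(r * cos(rad[i]), r * sin(rad[i]), z_ilm))
  star_scan("OD", th, bmo, ilm)
}

# 1-dof brute force for the frustum: by symmetry every spoke uses the same
# radius; scan it densely and return the minimal total
frustum_oracle <- function(n = 48L, z_ilm = 0.2, r_lo = 0.2, r_hi = 1.4,
                           step = 1e-4) {
  rad1 <- 0
  rad2 <- 2 * pi / n
  a <- c(cos(rad1), sin(rad1), 0)
  b <- c(cos(rad2), sin(rad2), 0)
  rs <- seq(r_lo, r_hi, by = step)
  tot <- vapply(rs, function(r) {
    cc <- c(r * cos(rad2), r * sin(rad2), z_ilm)
    d <- c(r * cos(rad1), r * sin(rad1), z_ilm)
    n * quad_area(a, b, cc, d, "A")
  }, numeric(1))
  min(tot)
}

# small randomized phantom for property tests (fast sizes)
random_phantom_scan <- function(seed, n_spokes = 12L, eye = "OD") {
  set.seed(seed)
  spec <- phantom_spec(
    n_spokes = n_spokes,
    bmo_semi_axes = c(runif(1, 0.7, 1.0), runif(1, 0.55, 0.85)),
    bmo_tilt_deg = runif(1, 0, 6),
    rim_height = runif(1, 0.4, 1.0),
    cup_depth = runif(1, 0.05, 0.3),
    rim_slope_width = runif(1, 0.15, 0.3),
    axial_noise_sd = runif(1, 0, 0.01),
    radial_samples = 20L,
    r_max = 1.3,
    eye = eye,
    seed = seed + 1L)
  generate_phantom(spec)$scan
}

# fast search options for property tests
opts_grid <- function(step = 0.03) search_options(step = step, refine = FALSE)

# exhaustive enumeration oracle for the cyclic assignment problem
enumerate_cyclic_min <- function(tables) {
  n <- length(tables)
  m <- vapply(tables, nrow, integer(1))
  idx <- as.matrix(expand.grid(lapply(m, seq_len)))
  tot <- rowSums(vapply(seq_len(n), function(k) {
    nxt <- if (k == n) 1L else k + 1L
    tables[[k]][cbind(idx[, k], idx[, nxt])]
  }, numeric(nrow(idx))))
  best <- min(tot)
  sel <- idx[which(tot == best)[1L], ]
  list(total = best, indices = as.integer(sel))
}

# full 2-D grid-search oracle for a single trapezoid over vertex candidates
trapezoid_grid_oracle <- function(bmo_i, bmo_j, vi, vj, diag = "A") {
  best <- Inf
  for (k in seq_len(nrow(vi))) {
    for (l in seq_len(nrow(vj))) {
      ar <- quad_area(bmo_i, bmo_j, vj[l, ], vi[k, ], diag)
      if (ar < best) best <- ar
    }
  }
  best
}

# paired sign-flip permutation oracle for the AUC difference
permutation_delong_oracle <- function(s1, s2, labels, B = 20000L, seed = 1L) {
  set.seed(seed)
  obs <- roc_auc(s1, labels, direction = "higher_is_case") -
    roc_auc(s2, labels, direction = "higher_is_case")
  n <- length(s1)
  d <- vapply(seq_len(B), function(b) {
    flip <- runif(n) < 0.5
    a1 <- ifelse(flip, s2, s1)
    a2 <- ifelse(flip, s1, s2)
    roc_auc(a1, labels, direction = "higher_is_case") -
      roc_auc(a2, labels, direction = "higher_is_case")
  }, numeric(1))
  mean(abs(d) >= abs(obs) - 1e-12)
}
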