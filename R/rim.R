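# Minimum rim area of the optic nerve head.
#
# Both optimization strategies search the same space: on each spoke, one
# BMO-ILM connection point sliding along the ILM polyline (arclength
# parameter). Between consecutive spokes i and i+1 the rim surface is a
# quad (bmo_i, bmo_{i+1}, ilm_{i+1}, ilm_i) split into two triangles along
# a fixed diagonal (chirality).
#
#   * sequential (BMO-MRA): each quad's area is minimized independently
#     over both of its endpoint parameters and the minima are summed.
#   * global (BMO-gMRA): all connection points are optimized
#     simultaneously so that the total triangulated area is minimal under
#     the constraint that adjacent quads share each spoke's connection
#     point (a continuous surface). On the discretized candidate set this
#     is solved exactly by cyclic dynamic programming.
#
# Because the sequential problem is the global problem with the coupling
# constraint dropped, the sequential total can never exceed the global
# total on a matched candidate set (relaxation bound).

#' Default chirality from eye laterality
#'
#' The orientation of the shared triangle edge is reversed between right
#' (OD) and left (OS) eyes to avoid a systematic discretization bias:
#' OD maps to `"A"`, OS to `"B"`. An explicit override wins.
#'
#' @param eye `"OD"` or `"OS"`.
#' @param override optional `"A"` or `"B"` (or `"auto"`/`NULL` for the
#'   laterality default).
#' @return `"A"` or `"B"`.
#' @export
resolve_chirality <- function(eye = c("OD", "OS"), override = NULL) {
  eye <- match.arg(eye)
  if (!is.null(override) && !identical(override, "auto")) {
    return(match.arg(override, c("A", "B")))
  }
  if (eye == "OD") "A" else "B"
}

#' Search options for the rim-area optimizers
#'
#' @param step candidate spacing for uniform arclength densification of the
#'   ILM polyline, in mm (default 0.010 mm = 10 micrometres). Candidates are
#'   the polyline vertices plus this uniform grid.
#' @param refine logical: after the grid optimum, refine the continuous
#'   arclength parameters by golden-section coordinate descent.
#' @param refine_tol stop refinement sweeps when the total area improves by
#'   less than this (mm², default 1e-7).
#' @param max_sweeps maximum refinement sweeps over all spokes.
#' @return A list of class `search_options`.
#' @export
search_options <- function(step = 0.010, refine = TRUE,
                           refine_tol = 1e-7, max_sweeps = 100L) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0,
            is.logical(refine), length(refine) == 1L,
            is.numeric(refine_tol), refine_tol > 0,
            max_sweeps >= 1L)
  structure(list(step = as.double(step), refine = isTRUE(refine),
                 refine_tol = as.double(refine_tol),
                 max_sweeps = as.integer(max_sweeps)),
            class = "search_options")
}

# candidate arclength positions: polyline vertices plus a uniform grid
.candidates <- function(curve, step) {
  L <- curve$s[length(curve$s)]
  t <- sort(c(curve$s, seq(0, L, by = step)))
  t[c(TRUE, diff(t) > 1e-9)]
}

# Cost tables: table i is an m_i x m_{i+1} matrix of quad areas between
# every candidate pair on spokes i and i+1 (cyclic). Vectorized over all
# pairs via outer cross products (see .pair_table).
.cost_tables <- function(scan, cand_pts, diag) {
  n <- scan$n_spokes
  B <- bmo_points(scan)
  lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    .pair_table(B[i, ], B[j, ], cand_pts[[i]], cand_pts[[j]], diag)
  })
}

#' Exact cyclic dynamic program over candidate-pair cost tables
#'
#' Minimizes the total of `tables[[k]][j_k, j_{k+1}]` over all cyclic
#' candidate assignments (spoke `n+1` is spoke 1). The returned selection is
#' the exact global minimum on the candidate grid; ties resolve to the
#' lexicographically smallest index vector.
#'
#' @param tables list of n numeric matrices; matrix `k` has one row per
#'   candidate on spoke `k` and one column per candidate on spoke `k+1`.
#' @return List with `indices` (1-based selected candidate per spoke) and
#'   `total` (the minimal total cost).
#' @export
dp_cyclic_min <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("tables must be a list of at least 2 cost matrices", call. = FALSE)
  tables <- lapply(seq_along(tables), function(k) {
    Tk <- tables[[k]]
    if (is.null(dim(Tk))) stop("cost tables must be matrices", call. = FALSE)
    if (any(dim(Tk) == 0L))
      stop(sprintf("empty candidate set in cost table %d", k), call. = FALSE)
    storage.mode(Tk) <- "double"
    Tk
  })
  dp_cyclic_core(tables)
}

# golden-section search on [lo, hi]; returns list(x, fx)
.gss <- function(f, lo, hi, xtol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > xtol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  if (f1 <= f2) list(x = x1, fx = f1) else list(x = x2, fx = f2)
}

# continuous refinement of a single quad (sequential strategy):
# alternating golden-section descent on the two endpoint parameters within
# +/- one grid step of the current optimum.
.refine_pair <- function(a, b, curve_i, curve_j, diag, ti, tj, area, opts) {
  Li <- curve_i$s[length(curve_i$s)]
  Lj <- curve_j$s[length(curve_j$s)]
  d <- opts$step
  for (it in seq_len(50L)) {
    prev <- area
    fi <- function(t) .quad(a, b, .interp1(curve_j, tj), .interp1(curve_i, t), diag)
    r <- .gss(fi, max(0, ti - d), min(Li, ti + d))
    if (r$fx < area) { ti <- r$x; area <- r$fx }
    fj <- function(t) .quad(a, b, .interp1(curve_j, t), .interp1(curve_i, ti), diag)
    r <- .gss(fj, max(0, tj - d), min(Lj, tj + d))
    if (r$fx < area) { tj <- r$x; area <- r$fx }
    if (prev - area < opts$refine_tol) break
  }
  list(ti = ti, tj = tj, area = area)
}

# continuous refinement of the global solution: cyclic coordinate descent,
# one golden-section line search per spoke and sweep. Monotone by
# construction (only improvements are accepted).
.refine_global <- function(scan, diag, t, opts) {
  n <- scan$n_spokes
  B <- bmo_points(scan)
  curves <- lapply(scan$spokes, `[[`, "ilm")
  Ls <- vapply(curves, function(cv) cv$s[length(cv$s)], numeric(1))
  pts <- do.call(rbind, lapply(seq_len(n), function(i) .interp1(curves[[i]], t[i])))
  quad_k <- function(k, pk, pk1) {
    j <- if (k == n) 1L else k + 1L
    .quad(B[k, ], B[j, ], pk1, pk, diag)
  }
  areas <- vapply(seq_len(n), function(k) {
    j <- if (k == n) 1L else k + 1L
    quad_k(k, pts[k, ], pts[j, ])
  }, numeric(1))
  total <- sum(areas)
  trace <- total
  d <- opts$step
  for (sweep_i in seq_len(opts$max_sweeps)) {
    before <- total
    for (k in seq_len(n)) {
      km1 <- if (k == 1L) n else k - 1L
      kp1 <- if (k == n) 1L else k + 1L
      f <- function(tk) {
        p <- .interp1(curves[[k]], tk)
        quad_k(km1, pts[km1, ], p) + quad_k(k, p, pts[kp1, ])
      }
      cur <- areas[km1] + areas[k]
      r <- .gss(f, max(0, t[k] - d), min(Ls[k], t[k] + d))
      if (r$fx < cur) {
        t[k] <- r$x
        pts[k, ] <- .interp1(curves[[k]], t[k])
        areas[km1] <- quad_k(km1, pts[km1, ], pts[k, ])
        areas[k] <- quad_k(k, pts[k, ], pts[kp1, ])
        total <- total - (cur - r$fx)
      }
    }
    total <- sum(areas)  # re-sum to avoid drift
    trace <- c(trace, total)
    if (before - total < opts$refine_tol) break
  }
  list(t = t, pts = pts, total = total, trace = trace)
}

#' Minimize one inter-spoke rim trapezoid
#'
#' Joint 2-D minimization of the quad area over both endpoint arclength
#' parameters: exhaustive search on the candidate grid (polyline vertices
#' densified at `opts$step`), optionally followed by golden-section
#' coordinate refinement of the continuous parameters. Ties on the grid
#' resolve to the smallest `(t_i, t_j)` pair.
#'
#' @param bmo_i,bmo_j BMO points of the two neighbouring spokes (mm).
#' @param curve_i,curve_j their ILM polylines ([ilm_curve()]).
#' @param diag chirality, `"A"` or `"B"`.
#' @param opts a [search_options()].
#' @return List with `t_i`, `t_j` (arclength mm) and `area` (mm²).
#' @export
minimize_trapezoid <- function(bmo_i, bmo_j, curve_i, curve_j,
                               diag = "A", opts = search_options()) {
  stopifnot(inherits(curve_i, "ilm_curve"), inherits(curve_j, "ilm_curve"))
  diag <- match.arg(diag, c("A", "B"))
  a <- .check_point(bmo_i, "bmo_i")
  b <- .check_point(bmo_j, "bmo_j")
  ti_c <- .candidates(curve_i, opts$step)
  tj_c <- .candidates(curve_j, opts$step)
  if (length(ti_c) == 0L || length(tj_c) == 0L)
    stop("empty candidate set", call. = FALSE)
  Pi <- interpolate_ilm(curve_i, ti_c)
  Pj <- interpolate_ilm(curve_j, tj_c)
  Tm <- .pair_table(a, b, Pi, Pj, diag)
  w <- which(Tm == min(Tm), arr.ind = TRUE)
  w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
  ti <- ti_c[w[1L]]
  tj <- tj_c[w[2L]]
  area <- Tm[w[1L], w[2L]]
  if (opts$refine) {
    r <- .refine_pair(a, b, curve_i, curve_j, diag, ti, tj, area, opts)
    ti <- r$ti; tj <- r$tj; area <- r$area
  }
  list(t_i = ti, t_j = tj, area = area)
}

# single-pair cost table (rows: candidates on curve_i, cols: curve_j)
.pair_table <- function(a, b, Pi, Pj, diag) {
  mi <- nrow(Pi); mj <- nrow(Pj)
  if (diag == "A") {
    C <- sweep(Pj, 2L, a); D <- sweep(Pi, 2L, a); u <- b - a
    t1 <- 0.5 * sqrt((u[2L] * C[, 3L] - u[3L] * C[, 2L])^2 +
                     (u[3L] * C[, 1L] - u[1L] * C[, 3L])^2 +
                     (u[1L] * C[, 2L] - u[2L] * C[, 1L])^2)
    X <- outer(C[, 2L], D[, 3L]) - outer(C[, 3L], D[, 2L])
    Y <- outer(C[, 3L], D[, 1L]) - outer(C[, 1L], D[, 3L])
    Z <- outer(C[, 1L], D[, 2L]) - outer(C[, 2L], D[, 1L])
    t(0.5 * sqrt(X * X + Y * Y + Z * Z)) + matrix(t1, mi, mj, byrow = TRUE)
  } else {
    D <- sweep(Pi, 2L, a); u <- b - a
    t1 <- 0.5 * sqrt((u[2L] * D[, 3L] - u[3L] * D[, 2L])^2 +
                     (u[3L] * D[, 1L] - u[1L] * D[, 3L])^2 +
                     (u[1L] * D[, 2L] - u[2L] * D[, 1L])^2)
    Cb <- sweep(Pj, 2L, b); Db <- sweep(Pi, 2L, b)
    X <- outer(Cb[, 2L], Db[, 3L]) - outer(Cb[, 3L], Db[, 2L])
    Y <- outer(Cb[, 3L], Db[, 1L]) - outer(Cb[, 1L], Db[, 3L])
    Z <- outer(Cb[, 1L], Db[, 2L]) - outer(Cb[, 2L], Db[, 1L])
    t(0.5 * sqrt(X * X + Y * Y + Z * Z)) + matrix(t1, mi, mj)
  }
}

#' Compute the minimum rim area of a star scan
#'
#' The central fitting function. For `method = "sequential"` (BMO-MRA) each
#' inter-spoke trapezoid is minimized independently over both endpoint
#' parameters and the minima are summed; for `method = "global"` (BMO-gMRA)
#' all BMO-ILM connection points are optimized simultaneously under the
#' shared-vertex continuity constraint, solved exactly on the candidate grid
#' by cyclic dynamic programming. Both methods optionally refine the
#' continuous arclength parameters by golden-section coordinate descent.
#'
#' @param scan a [star_scan()] with at least 3 spokes.
#' @param method `"global"` or `"sequential"`.
#' @param chirality `"auto"` (from eye laterality: OD is `"A"`, OS `"B"`),
#'   `"A"`, or `"B"`.
#' @param opts a [search_options()].
#' @param scheme a [sector_scheme()] for sector aggregation.
#' @return An object of class `rim_area`: list with elements `method`,
#'   `eye`, `chirality`, `total` (mm²), `sector_sums` (named vector, mm²),
#'   `quads` (data frame with one row per inter-spoke quad: endpoint
#'   parameters `t_i`/`t_j`, triangle areas `delta1`/`delta2`, quad `area`,
#'   angular midpoint and sector), `selection` (for the global method, the
#'   per-spoke arclength vector and 3-D connection points), `grid_total`
#'   (the exact optimum on the candidate grid, before refinement),
#'   `refine_trace` (total after each refinement sweep), `bmo_area` (mm²),
#'   `settings` and `settings_hash`.
#' @seealso [summary.rim_area()], [coef.rim_area()], [plot.rim_area()]
#' @export
rim_area <- function(scan, method = c("global", "sequential"),
                     chirality = c("auto", "A", "B"),
                     opts = search_options(),
                     scheme = garway_heath_scheme()) {
  stopifnot(inherits(scan, "star_scan"))
  method <- match.arg(method)
  chirality <- match.arg(chirality)
  if (scan$n_spokes < 3L)
    stop("rim area needs at least 3 spokes", call. = FALSE)
  diag <- resolve_chirality(scan$eye, if (chirality == "auto") NULL else chirality)

  n <- scan$n_spokes
  B <- bmo_points(scan)
  ang <- spoke_angles(scan)
  curves <- lapply(scan$spokes, `[[`, "ilm")
  for (i in seq_len(n)) {
    if (!inherits(curves[[i]], "ilm_curve"))
      stop(sprintf("spoke %d: invalid ILM curve", i), call. = FALSE)
  }
  cand_t <- lapply(curves, .candidates, step = opts$step)
  cand_pts <- lapply(seq_len(n), function(i) interpolate_ilm(curves[[i]], cand_t[[i]]))
  tables <- .cost_tables(scan, cand_pts, diag)

  jnext <- c(seq_len(n)[-1L], 1L)
  mid <- mapply(.mid_angle, ang, ang[jnext])

  if (method == "sequential") {
    sols <- lapply(seq_len(n), function(i) {
      Tm <- tables[[i]]
      w <- which(Tm == min(Tm), arr.ind = TRUE)
      w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
      list(ti = cand_t[[i]][w[1L]], tj = cand_t[[jnext[i]]][w[2L]],
           area = Tm[w[1L], w[2L]])
    })
    grid_total <- sum(vapply(sols, `[[`, numeric(1), "area"))
    if (opts$refine) {
      sols <- lapply(seq_len(n), function(i) {
        r <- .refine_pair(B[i, ], B[jnext[i], ], curves[[i]], curves[[jnext[i]]],
                          diag, sols[[i]]$ti, sols[[i]]$tj, sols[[i]]$area, opts)
        list(ti = r$ti, tj = r$tj, area = r$area)
      })
    }
    ti <- vapply(sols, `[[`, numeric(1), "ti")
    tj <- vapply(sols, `[[`, numeric(1), "tj")
    split2 <- t(vapply(seq_len(n), function(i) {
      .quad_split(B[i, ], B[jnext[i], ],
                  .interp1(curves[[jnext[i]]], tj[i]),
                  .interp1(curves[[i]], ti[i]), diag)
    }, numeric(2)))
    areas <- split2[, 1L] + split2[, 2L]
    selection <- NULL
    trace <- c(grid_total, sum(areas))
  } else {
    dp <- dp_cyclic_min(tables)
    grid_total <- dp$total
    t_sel <- vapply(seq_len(n), function(i) cand_t[[i]][dp$indices[i]], numeric(1))
    if (opts$refine) {
      r <- .refine_global(scan, diag, t_sel, opts)
      t_sel <- r$t
      pts <- r$pts
      trace <- r$trace
    } else {
      pts <- do.call(rbind, lapply(seq_len(n), function(i)
        .interp1(curves[[i]], t_sel[i])))
      trace <- grid_total
    }
    split2 <- t(vapply(seq_len(n), function(i) {
      .quad_split(B[i, ], B[jnext[i], ], pts[jnext[i], ], pts[i, ], diag)
    }, numeric(2)))
    areas <- split2[, 1L] + split2[, 2L]
    ti <- t_sel
    tj <- t_sel[jnext]
    selection <- list(t = t_sel, points = pts)
  }

  quads <- data.frame(
    sector_index = seq_len(n),
    spoke_i = seq_len(n),
    spoke_j = jnext,
    mid_angle_deg = mid,
    sector = assign_sector(scheme, mid, scan$axis_deg),
    t_i = ti, t_j = tj,
    delta1 = split2[, 1L], delta2 = split2[, 2L],
    area = areas,
    stringsAsFactors = FALSE)

  sector_sums <- aggregate_sectors(scheme, areas, mid, scan$axis_deg)
  settings <- list(method = method, step = opts$step, refine = opts$refine,
                   refine_tol = opts$refine_tol, max_sweeps = opts$max_sweeps,
                   chirality = diag, axis_deg = scan$axis_deg,
                   scheme = paste(scheme$name, scheme$start, scheme$end,
                                  collapse = ";"))
  structure(list(method = method, eye = scan$eye, n_spokes = n,
                 chirality = diag,
                 total = sum(areas),
                 sector_sums = sector_sums[setdiff(names(sector_sums), "global")],
                 quads = quads,
                 selection = selection,
                 grid_total = grid_total,
                 refine_trace = trace,
                 bmo_area = bmo_polygon_area(scan),
                 settings = settings,
                 settings_hash = settings_hash(settings)),
            class = "rim_area")
}

# S3 methods ---------------------------------------------------------------

#' @export
print.rim_area <- function(x, ...) {
  lab <- if (x$method == "sequential") "BMO-MRA (sequential)" else "BMO-gMRA (global)"
  cat(sprintf("%s minimum rim area\n", lab))
  cat(sprintf("  eye: %s   spokes: %d   chirality: %s\n",
              x$eye, x$n_spokes, x$chirality))
  cat(sprintf("  BMO area: %.4f mm^2\n", x$bmo_area))
  cat(sprintf("  total rim area: %.4f mm^2\n", x$total))
  invisible(x)
}

#' Summarize a rim-area fit
#'
#' @param object a [rim_area()] result.
#' @param ... unused.
#' @return An object of class `summary.rim_area` with the sector breakdown.
#' @export
summary.rim_area <- function(object, ...) {
  structure(list(fit = object,
                 sectors = data.frame(sector = names(object$sector_sums),
                                      area_mm2 = as.numeric(object$sector_sums),
                                      row.names = NULL)),
            class = "summary.rim_area")
}

#' @export
print.summary.rim_area <- function(x, ...) {
  print(x$fit)
  cat("  sector breakdown (mm^2):\n")
  s <- x$sectors
  for (k in seq_len(nrow(s)))
    cat(sprintf("    %-18s %.4f\n", s$sector[k], s$area_mm2[k]))
  cat(sprintf("  grid optimum: %.6f mm^2; refined: %.6f mm^2 (%d sweep(s))\n",
              x$fit$grid_total, x$fit$total, length(x$fit$refine_trace) - 1L))
  invisible(x)
}

#' Extract rim-area coefficients
#'
#' @param object a [rim_area()] result.
#' @param ... unused.
#' @return Named numeric vector: `global` total followed by sector sums (mm²).
#' @export
coef.rim_area <- function(object, ...) {
  c(global = object$total, object$sector_sums)
}

#' Plot the en-face view of a rim-area solution
#'
#' Shows the BMO polygon and, for the global method, the optimized BMO-ILM
#' connection points joined into the continuous rim boundary.
#'
#' @param x a [rim_area()] result; requires the originating scan.
#' @param scan the [star_scan()] the fit was computed from.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rim_area <- function(x, scan, ...) {
  stopifnot(inherits(scan, "star_scan"))
  B <- bmo_points(scan)
  rng <- range(c(B[, 1L], B[, 2L])) * 1.3
  plot(NA, xlim = rng, ylim = rng, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
       main = sprintf("%s rim area: %.3f mm^2", x$method, x$total), ...)
  polygon(B[, 1L], B[, 2L], border = "grey40", lwd = 1.5)
  if (!is.null(x$selection)) {
    P <- x$selection$points
    polygon(P[, 1L], P[, 2L], border = "firebrick", lwd = 1.5)
    segments(B[, 1L], B[, 2L], P[, 1L], P[, 2L],
             col = adjustcolor("steelblue", 0.6))
  }
  points(B[, 1L], B[, 2L], pch = 16, cex = 0.5, col = "grey30")
  invisible(x)
}
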