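# Star-scan data model: one eye's reconstructed 3-D geometry from radial
# SD-OCT B-scans centred on the BMO. Each radial B-scan contributes two
# spokes (24 scans at 15 degrees -> 48 spokes at 7.5 degrees), each spoke
# carrying one BMO point and one ILM segmentation polyline.
#
# Internal convention: all processing happens in the right-eye (OD)
# orientation with spoke angles measured counterclockwise from the temporal
# horizontal axis. Left-eye (OS) scans are mirrored about the vertical
# en-face axis on load; the laterality label is retained because it decides
# the default chirality of the triangulated rim surface.

#' Construct a star scan
#'
#' @param eye `"OD"` (right) or `"OS"` (left). Geometry passed here is taken
#'   to be already in the internal OD orientation; use [read_star_scan()] to
#'   load device-native OS geometry (mirrored on load).
#' @param angles_deg strictly increasing spoke angles in `[0, 360)` degrees,
#'   counterclockwise from the temporal horizontal axis.
#' @param bmo n-by-3 matrix of BMO points (mm), one row per spoke.
#' @param ilm list of n ILM polylines ([ilm_curve()] objects or n-by-3
#'   matrices, coerced).
#' @param axis_deg optional rotation of the temporal reference axis applied
#'   before sector assignment (degrees, default 0).
#' @return An object of class `star_scan`.
#' @export
star_scan <- function(eye = c("OD", "OS"), angles_deg, bmo, ilm, axis_deg = 0) {
  eye <- match.arg(eye)
  angles_deg <- as.double(angles_deg)
  n <- length(angles_deg)
  if (n < 1L) stop("a star scan needs at least one spoke", call. = FALSE)
  if (any(!is.finite(angles_deg)) || any(angles_deg < 0) || any(angles_deg >= 360))
    stop("spoke angles must be finite and in [0, 360) degrees", call. = FALSE)
  if (n > 1L && any(diff(angles_deg) <= 0))
    stop("spoke angles must be strictly increasing", call. = FALSE)
  bmo <- as.matrix(bmo)
  storage.mode(bmo) <- "double"
  if (nrow(bmo) != n || ncol(bmo) != 3L)
    stop("bmo must be an n-by-3 matrix matching the number of spokes", call. = FALSE)
  if (!all(is.finite(bmo))) stop("BMO coordinates must be finite", call. = FALSE)
  if (!is.list(ilm) || length(ilm) != n)
    stop("ilm must be a list with one curve per spoke", call. = FALSE)
  if (!is.numeric(axis_deg) || length(axis_deg) != 1L || !is.finite(axis_deg))
    stop("axis_deg must be a finite scalar", call. = FALSE)

  spokes <- vector("list", n)
  for (i in seq_len(n)) {
    curve <- ilm[[i]]
    if (!inherits(curve, "ilm_curve")) {
      curve <- tryCatch(ilm_curve(curve), error = function(e)
        stop(sprintf("spoke %d: %s", i, conditionMessage(e)), call. = FALSE))
    }
    spokes[[i]] <- list(index = i, angle_deg = angles_deg[i],
                        bmo = bmo[i, ], ilm = curve)
  }
  structure(list(eye = eye, axis_deg = as.double(axis_deg) %% 360,
                 n_spokes = n, spokes = spokes),
            class = "star_scan")
}

#' @export
print.star_scan <- function(x, ...) {
  cat(sprintf("<star_scan: %s eye, %d spokes, axis %.1f deg>\n",
              x$eye, x$n_spokes, x$axis_deg))
  invisible(x)
}

#' Extract the BMO points of a star scan
#'
#' @param scan a [star_scan()].
#' @return n-by-3 matrix of BMO points (mm), one row per spoke.
#' @export
bmo_points <- function(scan) {
  stopifnot(inherits(scan, "star_scan"))
  do.call(rbind, lapply(scan$spokes, `[[`, "bmo"))
}

#' Spoke angles of a star scan
#' @param scan a [star_scan()].
#' @return numeric vector of spoke angles in degrees.
#' @export
spoke_angles <- function(scan) {
  stopifnot(inherits(scan, "star_scan"))
  vapply(scan$spokes, `[[`, numeric(1), "angle_deg")
}

#' Projected BMO polygon area
#'
#' Area of the polygon of BMO points projected onto its least-squares
#' best-fit plane. This is the package's definition of "BMO area"; it is
#' invariant under rigid motions of the scan.
#'
#' @param scan a [star_scan()] with at least 3 spokes.
#' @return Area in mm².
#' @export
bmo_polygon_area <- function(scan) {
  P <- bmo_points(scan)
  if (nrow(P) < 3L) stop("BMO polygon area needs at least 3 spokes", call. = FALSE)
  C <- sweep(P, 2L, colMeans(P))
  sv <- svd(C, nu = 0L, nv = 2L)
  uv <- C %*% sv$v
  x <- uv[, 1L]
  y <- uv[, 2L]
  0.5 * abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y))
}

#' Apply a rigid motion to a star scan
#'
#' All rim and BMO areas are invariant under this transform (tested
#' property of the optimizers).
#'
#' @param scan a [star_scan()].
#' @param rotation 3-by-3 proper orthogonal matrix.
#' @param translation numeric length-3 vector (mm).
#' @return The transformed `star_scan`.
#' @export
rigid_transform <- function(scan, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(scan, "star_scan"))
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 ||
      abs(det(R) - 1) > 1e-8)
    stop("rotation must be a proper orthogonal 3-by-3 matrix", call. = FALSE)
  tr <- .check_point(translation, "translation")
  ang <- spoke_angles(scan)
  bmo <- bmo_points(scan) %*% t(R)
  bmo <- sweep(bmo, 2L, tr, `+`)
  ilm <- lapply(scan$spokes, function(sp) {
    v <- sp$ilm$v %*% t(R)
    ilm_curve(sweep(v, 2L, tr, `+`))
  })
  star_scan(scan$eye, ang, bmo, ilm, axis_deg = scan$axis_deg)
}

#' Mirror a star scan about the vertical en-face axis
#'
#' Produces the fellow-eye mirror image: x coordinates are negated, spoke
#' angles map to `(180 - angle) mod 360`, spokes are re-sorted, and the
#' laterality label is toggled. Mirroring plus a chirality flip leaves all
#' rim areas unchanged (tested property).
#'
#' @param scan a [star_scan()].
#' @return The mirrored `star_scan` with opposite laterality.
#' @export
mirror_scan <- function(scan) {
  stopifnot(inherits(scan, "star_scan"))
  ang <- (180 - spoke_angles(scan)) %% 360
  ord <- order(ang)
  bmo <- bmo_points(scan)
  bmo[, 1L] <- -bmo[, 1L]
  ilm <- lapply(scan$spokes, function(sp) {
    v <- sp$ilm$v
    v[, 1L] <- -v[, 1L]
    ilm_curve(v)
  })
  star_scan(if (scan$eye == "OD") "OS" else "OD",
            ang[ord], bmo[ord, , drop = FALSE], ilm[ord],
            axis_deg = (180 - scan$axis_deg) %% 360)
}

# uniform coordinate scaling (lambda^2 law for areas); internal test helper
.scale_scan <- function(scan, lambda) {
  star_scan(scan$eye, spoke_angles(scan), bmo_points(scan) * lambda,
            lapply(scan$spokes, function(sp) ilm_curve(sp$ilm$v * lambda)),
            axis_deg = scan$axis_deg)
}
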