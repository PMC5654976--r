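# Low-level 3-D primitives. All coordinates are in millimetres, in a
# right-handed frame with z the axial (depth) direction and x-y the
# en-face plane.

# unchecked kernels used in hot paths -------------------------------------

.tri <- function(p, q, r) {
  u <- q - p
  v <- r - p
  cx <- u[2L] * v[3L] - u[3L] * v[2L]
  cy <- u[3L] * v[1L] - u[1L] * v[3L]
  cz <- u[1L] * v[2L] - u[2L] * v[1L]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

# quad (a, b, c, d) = (bmo_i, bmo_j, ilm_j, ilm_i); chirality selects the
# shared diagonal: "A" = a-c, "B" = b-d.
.quad <- function(a, b, c, d, diag) {
  if (diag == "A") .tri(a, b, c) + .tri(a, c, d) else .tri(a, b, d) + .tri(b, c, d)
}

.quad_split <- function(a, b, c, d, diag) {
  if (diag == "A") c(.tri(a, b, c), .tri(a, c, d)) else c(.tri(a, b, d), .tri(b, c, d))
}

.check_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p)))
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  as.double(p)
}

# exported surface ---------------------------------------------------------

#' Area of a triangle in 3-D
#'
#' Half the magnitude of the cross product of two edge vectors. Degenerate
#' (collinear) triangles return 0.
#'
#' @param p,q,r numeric length-3 vertices, in mm.
#' @return Triangle area in mm² (non-negative scalar).
#' @examples
#' triangle_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) # 0.5
#' @export
triangle_area <- function(p, q, r) {
  .tri(.check_point(p, "p"), .check_point(q, "q"), .check_point(r, "r"))
}

#' Area of a (possibly non-planar) quadrilateral split into two triangles
#'
#' The quad is given in the fixed vertex order `(bmo_i, bmo_j, ilm_j, ilm_i)`
#' around its boundary. It is split into two triangles along one diagonal;
#' `diag = "A"` uses the diagonal `a`-`c` (triangles `a b c` and `a c d`),
#' `diag = "B"` uses `b`-`d` (triangles `a b d` and `b c d`). For planar
#' quads the two choices agree; for warped quads they do not, which is the
#' chirality effect that the global rim-surface optimization reverses
#' between right and left eyes.
#'
#' @param a,b,c,d numeric length-3 vertices, in mm.
#' @param diag `"A"` or `"B"`, the shared diagonal.
#' @return Quad area in mm² (sum of the two triangle areas).
#' @export
quad_area <- function(a, b, c, d, diag = c("A", "B")) {
  diag <- match.arg(diag)
  .quad(.check_point(a, "a"), .check_point(b, "b"),
        .check_point(c, "c"), .check_point(d, "d"), diag)
}

#' Construct an ILM segmentation polyline
#'
#' Stores the ordered polyline vertices together with their cumulative
#' arclength, which is the parametrization used by all rim-area
#' optimizations (invariant to vertex resampling density).
#'
#' @param vertices numeric n-by-3 matrix (n >= 2) of polyline vertices in mm.
#' @return An object of class `ilm_curve`: list with elements `v` (vertex
#'   matrix) and `s` (cumulative arclength, starting at 0, strictly
#'   increasing).
#' @export
ilm_curve <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 3L) stop("ILM vertices must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(v) < 2L) stop("ILM polyline needs at least 2 vertices", call. = FALSE)
  if (!all(is.finite(v))) stop("ILM vertices must be finite", call. = FALSE)
  seg <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(seg <= 0))
    stop("ILM polyline has a zero-length segment (duplicate consecutive vertices)",
         call. = FALSE)
  structure(list(v = v, s = c(0, cumsum(seg))), class = "ilm_curve")
}

#' @export
print.ilm_curve <- function(x, ...) {
  cat(sprintf("<ilm_curve: %d vertices, arclength %.4f mm>\n",
              nrow(x$v), x$s[length(x$s)]))
  invisible(x)
}

#' Evaluate an ILM polyline at given arclength positions
#'
#' Linear interpolation between the bounding vertices; `t = 0` returns the
#' first vertex exactly and `t = total arclength` the last.
#'
#' @param curve an [ilm_curve()].
#' @param t numeric vector of arclength positions in mm, each within
#'   `[0, total arclength]`.
#' @return A `length(t)`-by-3 matrix of interpolated points.
#' @export
interpolate_ilm <- function(curve, t) {
  stopifnot(inherits(curve, "ilm_curve"))
  s <- curve$s
  L <- s[length(s)]
  if (!is.numeric(t) || anyNA(t))
    stop("arclength parameter must be numeric and non-missing", call. = FALSE)
  if (any(t < -1e-12) || any(t > L + 1e-12))
    stop(sprintf("arclength parameter outside [0, %.6g]", L), call. = FALSE)
  t <- pmin(pmax(t, 0), L)
  k <- findInterval(t, s, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(s) - 1L)
  w <- (t - s[k]) / (s[k + 1L] - s[k])
  curve$v[k, , drop = FALSE] * (1 - w) + curve$v[k + 1L, , drop = FALSE] * w
}

# scalar fast path (no validation) used inside optimizers
.interp1 <- function(curve, t) {
  s <- curve$s
  n <- length(s)
  if (t <= 0) return(curve$v[1L, ])
  if (t >= s[n]) return(curve$v[n, ])
  k <- findInterval(t, s)
  w <- (t - s[k]) / (s[k + 1L] - s[k])
  curve$v[k, ] * (1 - w) + curve$v[k + 1L, ] * w
}
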