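# Angular sector schemes for the optic nerve head, in the right-eye (OD)
# frame with 0 degrees at the temporal horizontal axis, counterclockwise.
# The default is the Garway-Heath layout used by clinical ONH reports:
# temporal, temporal superior, nasal superior, nasal, nasal inferior,
# temporal inferior.

#' Construct a sector scheme
#'
#' A sector scheme is a set of half-open angular intervals
#' `[start, end)` (degrees, OD frame, counterclockwise from the temporal
#' axis) that partition the circle. Intervals may wrap across 0.
#'
#' @param names character vector of unique sector labels.
#' @param start,end numeric vectors of interval boundaries in `[0, 360)`.
#' @return An object of class `sector_scheme` (a data frame with columns
#'   `name`, `start`, `end`).
#' @export
sector_scheme <- function(names, start, end) {
  if (length(names) != length(start) || length(start) != length(end))
    stop("names, start and end must have equal length", call. = FALSE)
  if (anyDuplicated(names)) stop("sector labels must be unique", call. = FALSE)
  start <- as.double(start) %% 360
  end <- as.double(end) %% 360
  width <- (end - start) %% 360
  width[width == 0] <- 360  # a single full-circle sector
  if (abs(sum(width) - 360) > 1e-9)
    stop("sector intervals must partition [0, 360)", call. = FALSE)
  structure(data.frame(name = as.character(names), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("sector_scheme", "data.frame"))
}

#' Garway-Heath sector scheme
#'
#' The six-sector layout reported in clinical BMO-based ONH analyses, in the
#' OD frame: temporal `[315, 45)`, temporal superior `[45, 85)`, nasal
#' superior `[85, 125)`, nasal `[125, 235)`, nasal inferior `[235, 275)`,
#' temporal inferior `[275, 315)`.
#'
#' @return A [sector_scheme()].
#' @export
garway_heath_scheme <- function() {
  sector_scheme(
    names = c("temporal", "temporal_superior", "nasal_superior",
              "nasal", "nasal_inferior", "temporal_inferior"),
    start = c(315, 45, 85, 125, 235, 275),
    end   = c(45, 85, 125, 235, 275, 315))
}

#' Assign angles to sectors
#'
#' @param scheme a [sector_scheme()].
#' @param angle_deg numeric vector of angles in degrees (any real; reduced
#'   modulo 360).
#' @param axis_deg optional rotation of the reference axis subtracted before
#'   assignment (default 0).
#' @return Character vector of sector labels.
#' @export
assign_sector <- function(scheme, angle_deg, axis_deg = 0) {
  stopifnot(inherits(scheme, "sector_scheme"))
  a <- (as.double(angle_deg) - axis_deg) %% 360
  out <- character(length(a))
  for (k in seq_len(nrow(scheme))) {
    s <- scheme$start[k]
    e <- scheme$end[k]
    inside <- if (s < e) (a >= s & a < e) else (a >= s | a < e)
    out[inside] <- scheme$name[k]
  }
  if (any(out == "")) stop("internal error: sector intervals do not cover the circle")
  out
}

#' Aggregate per-quad areas into sector sums
#'
#' Sums quad areas by the sector containing each quad's angular midpoint and
#' appends the global total. The sector sums are exactly additive: they sum
#' to the global value.
#'
#' @param scheme a [sector_scheme()].
#' @param areas numeric vector of quad areas (mm²).
#' @param mid_angles_deg numeric vector of quad angular midpoints (degrees),
#'   same length as `areas`.
#' @param axis_deg optional reference-axis rotation (degrees).
#' @return Named numeric vector: one entry per scheme sector (0 for empty
#'   sectors) plus `"global"`.
#' @export
aggregate_sectors <- function(scheme, areas, mid_angles_deg, axis_deg = 0) {
  stopifnot(inherits(scheme, "sector_scheme"))
  if (length(areas) != length(mid_angles_deg))
    stop("areas and mid_angles_deg must have equal length", call. = FALSE)
  lab <- assign_sector(scheme, mid_angles_deg, axis_deg)
  sums <- vapply(scheme$name, function(nm) sum(areas[lab == nm]), numeric(1))
  c(sums, global = sum(areas))
}

# circular midpoint of two spoke angles, walking counterclockwise from a to b
.mid_angle <- function(a, b) {
  (a + ((b - a) %% 360) / 2) %% 360
}
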