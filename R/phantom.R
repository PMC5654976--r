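# Synthetic optic-nerve-head phantoms and cohorts.
#
# The phantom emulates the geometry the rim-area pipeline consumes: an
# elliptical BMO ring of realistic area (~1.6-2.6 mm^2) sampled at the
# radial star-scan spoke angles (48 spokes at 7.5 degrees by default), and
# per-spoke ILM profiles following a logistic ramp from the cup floor to
# the rim plateau, with sector-specific glaucomatous thinning, optic-disc
# tilt, and additive Gaussian axial segmentation noise. It makes no claim
# of anatomical fidelity beyond these controlled features; it exists so
# every pipeline stage is testable against known ground truth.

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic ONH phantom
#'
#' @param n_spokes number of spokes (default 48, i.e. 24 radial B-scans at
#'   15 degrees).
#' @param bmo_semi_axes BMO ellipse semi-axes `(a, b)` in mm; the defaults
#'   give a BMO area near 1.9 mm².
#' @param bmo_tilt_deg rigid tilt of the whole phantom about the horizontal
#'   en-face axis, degrees.
#' @param rim_height peak ILM height above the BMO plane (rim plateau), mm.
#' @param cup_depth cup floor depth below the BMO plane, mm.
#' @param rim_slope_width radial width of the logistic cup-to-rim ramp, mm.
#' @param sector_thinning named multiplicative factors in `(0, 1]` applied
#'   to `rim_height` per Garway-Heath sector (missing sectors default to 1).
#' @param axial_noise_sd standard deviation of independent Gaussian axial
#'   noise added to every ILM sample, mm (default 5 micrometres).
#' @param radial_samples ILM samples per spoke from the scan centre to
#'   `r_max` (the BMO crossing radius is always included as a sample).
#' @param r_max radial extent of each ILM profile, mm.
#' @param eye laterality label, `"OD"` or `"OS"`.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_spokes = 48L,
                         bmo_semi_axes = c(0.85, 0.71),
                         bmo_tilt_deg = 2,
                         rim_height = 0.90,
                         cup_depth = 0.10,
                         rim_slope_width = 0.25,
                         sector_thinning = NULL,
                         axial_noise_sd = 0.005,
                         radial_samples = 48L,
                         r_max = 1.5,
                         eye = c("OD", "OS"),
                         seed = 1L) {
  eye <- match.arg(eye)
  if (n_spokes < 3L) stop("need at least 3 spokes", call. = FALSE)
  if (any(bmo_semi_axes <= 0)) stop("BMO semi-axes must be positive", call. = FALSE)
  if (axial_noise_sd < 0) stop("axial_noise_sd must be >= 0", call. = FALSE)
  if (rim_slope_width <= 0) stop("rim_slope_width must be positive", call. = FALSE)
  if (rim_height < 0 || cup_depth < 0)
    stop("rim_height and cup_depth must be >= 0", call. = FALSE)
  if (radial_samples < 4L) stop("radial_samples must be >= 4", call. = FALSE)
  if (r_max <= max(bmo_semi_axes))
    stop("r_max must exceed the BMO semi-axes", call. = FALSE)
  scheme <- garway_heath_scheme()
  thin <- setNames(rep(1, nrow(scheme)), scheme$name)
  if (!is.null(sector_thinning)) {
    if (is.null(names(sector_thinning)) ||
        !all(names(sector_thinning) %in% scheme$name))
      stop("sector_thinning must be named by Garway-Heath sector", call. = FALSE)
    if (any(sector_thinning <= 0) || any(sector_thinning > 1))
      stop("sector_thinning factors must be in (0, 1]", call. = FALSE)
    thin[names(sector_thinning)] <- sector_thinning
  }
  structure(list(n_spokes = as.integer(n_spokes),
                 bmo_semi_axes = as.double(bmo_semi_axes),
                 bmo_tilt_deg = as.double(bmo_tilt_deg),
                 rim_height = as.double(rim_height),
                 cup_depth = as.double(cup_depth),
                 rim_slope_width = as.double(rim_slope_width),
                 sector_thinning = thin,
                 axial_noise_sd = as.double(axial_noise_sd),
                 radial_samples = as.integer(radial_samples),
                 r_max = as.double(r_max),
                 eye = eye,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic star scan from a phantom spec
#'
#' The BMO ring is the spec's ellipse sampled at the spoke angles; the ILM
#' profile on the spoke at angle `theta` is
#' `z(r) = -cup_depth + (h + cup_depth) * plogis((r - rho) / rim_slope_width)`
#' with `rho` the BMO radius and `h = rim_height * thinning(sector(theta))`,
#' plus Gaussian axial noise. The whole phantom is then rigidly tilted by
#' `bmo_tilt_deg` (areas are unaffected by the tilt).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `simulated_eye` with elements `scan`
#'   ([star_scan()]), `diagnosis` (`"control"` placeholder), `md_db` (`NA`
#'   until set by [generate_cohort()]), `true_rim_area` (analytic, only for
#'   the degenerate flat phantom), `rim_proxy` (analytic noise-free rim-area
#'   proxy used for the visual-field link) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_spokes
    theta <- (seq_len(n) - 1L) * 360 / n
    th <- theta * pi / 180
    A <- spec$bmo_semi_axes[1L]
    Bx <- spec$bmo_semi_axes[2L]
    rho <- A * Bx / sqrt((Bx * cos(th))^2 + (A * sin(th))^2)
    bmo <- cbind(rho * cos(th), rho * sin(th), 0)
    sect <- assign_sector(garway_heath_scheme(), theta)
    h <- spec$rim_height * spec$sector_thinning[sect]

    ilm <- vector("list", n)
    for (i in seq_len(n)) {
      r <- sort(unique(c(seq(0, spec$r_max, length.out = spec$radial_samples),
                         rho[i])))
      z <- -spec$cup_depth +
        (h[i] + spec$cup_depth) * plogis((r - rho[i]) / spec$rim_slope_width)
      if (spec$axial_noise_sd > 0)
        z <- z + rnorm(length(z), sd = spec$axial_noise_sd)
      ilm[[i]] <- ilm_curve(cbind(r * cos(th[i]), r * sin(th[i]), z))
    }
    scan <- star_scan(spec$eye, theta, bmo, ilm)
    if (spec$bmo_tilt_deg != 0) {
      phi <- spec$bmo_tilt_deg * pi / 180
      R <- rbind(c(1, 0, 0),
                 c(0, cos(phi), -sin(phi)),
                 c(0, sin(phi), cos(phi)))
      scan <- rigid_transform(scan, R)
    }

    # analytic noise-free proxy of the rim area: BMO chord lengths times
    # the mean local rim height (a cylinder-band approximation)
    jn <- c(seq_len(n)[-1L], 1L)
    chord <- sqrt(rowSums((bmo[jn, ] - bmo)^2))
    proxy <- sum(chord * (h + h[jn]) / 2)

    true_area <- if (spec$rim_height == 0 && spec$cup_depth == 0 &&
                     spec$axial_noise_sd == 0) 0 else NA_real_
    structure(list(eye_id = NA_character_, scan = scan, diagnosis = "control",
                   md_db = NA_real_, true_rim_area = true_area,
                   rim_proxy = proxy, spec = spec),
              class = "simulated_eye")
  })
}

#' @export
print.simulated_eye <- function(x, ...) {
  cat(sprintf("<simulated_eye %s: %s, %s, %d spokes, MD %.2f dB>\n",
              if (is.na(x$eye_id)) "" else x$eye_id, x$diagnosis,
              x$scan$eye, x$scan$n_spokes, x$md_db))
  invisible(x)
}

#' Specify a synthetic study cohort
#'
#' Per-group parameter distributions for [phantom_spec()] fields, plus a
#' linear link from the analytic rim-area proxy to a visual-field mean
#' deviation (MD, dB) with additive Gaussian noise. The defaults are
#' calibrated so that measured control global rim areas fall near 1.2 mm²
#' and glaucoma near 0.8 mm², with glaucomatous thinning concentrated
#' temporally-inferiorly.
#'
#' @param n_per_group named integer counts for `glaucoma`, `control`, `OHT`.
#' @param groups named list (per diagnosis) of lists with elements
#'   `rim_height` (c(mean, sd), mm), `cup_depth` (c(mean, sd), mm),
#'   `bmo_scale_sd` (sd of the multiplicative BMO-size factor) and
#'   `sector_thinning` (named factors, see [phantom_spec()]).
#' @param md_link numeric `c(intercept, slope, sd)`: MD (dB) = intercept +
#'   slope * rim proxy (mm²) + Gaussian noise.
#' @param seed master integer seed; per-eye substreams are derived from it
#'   by an eye-index counter, so cohorts are reproducible and
#'   order-independent.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(glaucoma = 100L, control = 100L, OHT = 0L),
                        groups = NULL,
                        md_link = c(intercept = -22, slope = 4.5, sd = 5.5),
                        seed = 1L) {
  grp_names <- c("glaucoma", "control", "OHT")
  n <- setNames(rep(0L, 3L), grp_names)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% grp_names))
    stop("n_per_group must be named with glaucoma/control/OHT", call. = FALSE)
  n[names(n_per_group)] <- as.integer(n_per_group)
  if (any(n < 0L)) stop("group counts must be >= 0", call. = FALSE)
  if (sum(n) == 0L) stop("cohort must contain at least one eye", call. = FALSE)
  default_groups <- list(
    glaucoma = list(rim_height = c(0.72, 0.28), cup_depth = c(0.20, 0.05),
                    bmo_scale_sd = 0.08,
                    sector_thinning = c(temporal_inferior = 0.72,
                                        temporal_superior = 0.82,
                                        nasal_inferior = 0.90,
                                        nasal_superior = 0.95)),
    control = list(rim_height = c(0.90, 0.28), cup_depth = c(0.10, 0.05),
                   bmo_scale_sd = 0.08, sector_thinning = NULL),
    OHT = list(rim_height = c(0.88, 0.28), cup_depth = c(0.12, 0.05),
               bmo_scale_sd = 0.08, sector_thinning = NULL))
  if (!is.null(groups)) {
    for (g in names(groups)) {
      if (!g %in% grp_names) stop("unknown group: ", g, call. = FALSE)
      default_groups[[g]] <- utils::modifyList(default_groups[[g]], groups[[g]],
                                               keep.null = TRUE)
    }
  }
  if (length(md_link) != 3L || any(!is.finite(md_link)) || md_link[3L] < 0)
    stop("md_link must be c(intercept, slope, sd) with sd >= 0", call. = FALSE)
  structure(list(n_per_group = n, groups = default_groups,
                 md_link = setNames(as.double(md_link),
                                    c("intercept", "slope", "sd")),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of simulated eyes
#'
#' Each eye draws its phantom parameters from its diagnostic group's
#' distributions under a per-eye RNG substream derived from the master seed
#' by the eye-index counter; its MD value is the linear link applied to the
#' eye's analytic rim proxy plus Gaussian noise. Laterality is drawn
#' OD/OS with equal probability.
#'
#' @param spec a [cohort_spec()].
#' @return List of `simulated_eye` objects (class `simulated_cohort`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  idx <- 0L
  for (g in c("glaucoma", "control", "OHT")) {
    ng <- spec$n_per_group[[g]]
    if (ng == 0L) next
    gp <- spec$groups[[g]]
    for (k in seq_len(ng)) {
      idx <- idx + 1L
      eye_seed <- as.integer((as.double(spec$seed) + 104729 * idx) %% 2147483647)
      eye <- .with_seed(eye_seed, {
        rh <- max(0.03, rnorm(1, gp$rim_height[1L], gp$rim_height[2L]))
        cd <- max(0.02, rnorm(1, gp$cup_depth[1L], gp$cup_depth[2L]))
        sc <- max(0.6, rnorm(1, 1, gp$bmo_scale_sd))
        lat <- sample(c("OD", "OS"), 1L)
        md_noise <- rnorm(1, 0, spec$md_link[["sd"]])
        ps <- phantom_spec(rim_height = rh, cup_depth = cd,
                           bmo_semi_axes = c(0.85, 0.71) * sc,
                           sector_thinning = gp$sector_thinning,
                           eye = lat,
                           seed = (eye_seed + 1L) %% 2147483647L)
        e <- generate_phantom(ps)
        e$eye_id <- sprintf("eye_%04d", idx)
        e$diagnosis <- g
        e$md_db <- spec$md_link[["intercept"]] +
          spec$md_link[["slope"]] * e$rim_proxy + md_noise
        e
      })
      out[[idx]] <- eye
    }
  }
  structure(out, class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  dx <- table(vapply(x, `[[`, character(1), "diagnosis"))
  cat(sprintf("<simulated_cohort: %d eyes (%s)>\n", length(x),
              paste(names(dx), dx, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one star-scan JSON file per eye plus a cohort manifest CSV with
#' columns `eye_id`, `file`, `diagnosis`, `md_db`, `seed`.
#'
#' @param cohort a `simulated_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(e) {
    f <- paste0(e$eye_id, ".json")
    write_star_scan(e$scan, file.path(dir, f))
    data.frame(eye_id = e$eye_id, file = f, diagnosis = e$diagnosis,
               md_db = e$md_db, seed = e$spec$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
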