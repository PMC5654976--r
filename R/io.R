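# File formats: versioned star-scan JSON (one eye per file), results CSV
# (one row per eye and method), cohort manifest CSV, and the evaluation
# table. JSON is used for geometry because it is diff-able and free of
# proprietary dependencies; numbers are serialized with 9 significant
# digits. Scans may be stored in device-native orientation: OS eyes are
# mirrored into the internal OD frame on load (and mirrored back on write),
# with the laterality label retained for chirality resolution.

.SCHEMA_VERSION <- "1.0"

#' Write a star scan to JSON
#'
#' @param scan a [star_scan()] (internal OD orientation). OS eyes are
#'   mirrored back to their device-native orientation on disk.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_star_scan <- function(scan, path) {
  stopifnot(inherits(scan, "star_scan"))
  out <- scan
  if (scan$eye == "OS") {
    out <- mirror_scan(scan)   # back to device-native frame
    out$eye <- "OS"
  }
  spokes <- lapply(out$spokes, function(sp) {
    list(angle_deg = signif(sp$angle_deg, 9),
         bmo = signif(unname(sp$bmo), 9),
         ilm = unname(signif(sp$ilm$v, 9)))
  })
  doc <- list(schema_version = .SCHEMA_VERSION,
              eye = out$eye,
              axis_deg = signif(out$axis_deg, 9),
              n_spokes = out$n_spokes,
              spokes = spokes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.scan_schema_fail <- function(msg, spoke = NULL) {
  where <- if (is.null(spoke)) "" else sprintf(" (spoke %d)", spoke)
  stop("invalid star-scan file: ", msg, where, call. = FALSE)
}

#' Read a star scan from JSON
#'
#' Validates the versioned schema (failures name the offending field and
#' spoke index) and returns the scan in the internal OD orientation: OS
#' eyes are mirrored about the vertical en-face axis on load, keeping the
#' laterality label so the chirality convention can be resolved.
#'
#' @param path path to a star-scan JSON file.
#' @return A [star_scan()].
#' @export
read_star_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, .SCHEMA_VERSION))
    .scan_schema_fail(sprintf("schema_version must be \"%s\"", .SCHEMA_VERSION))
  if (is.null(doc$eye) || !doc$eye %in% c("OD", "OS"))
    .scan_schema_fail("field 'eye' must be \"OD\" or \"OS\"")
  axis <- if (is.null(doc$axis_deg)) 0 else doc$axis_deg
  if (!is.numeric(axis)) .scan_schema_fail("field 'axis_deg' must be numeric")
  if (is.null(doc$spokes) || length(doc$spokes) == 0L)
    .scan_schema_fail("field 'spokes' must be a non-empty array")
  n <- length(doc$spokes)
  if (!is.null(doc$n_spokes) && doc$n_spokes != n)
    .scan_schema_fail(sprintf("field 'n_spokes' (%s) does not match the %d spokes present",
                              doc$n_spokes, n))
  ang <- numeric(n)
  bmo <- matrix(0, n, 3L)
  ilm <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- doc$spokes[[i]]
    if (is.null(sp$angle_deg) || !is.numeric(sp$angle_deg))
      .scan_schema_fail("field 'angle_deg' missing or non-numeric", i)
    ang[i] <- sp$angle_deg
    b <- unlist(sp$bmo)
    if (length(b) != 3L || !is.numeric(b) || !all(is.finite(b)))
      .scan_schema_fail("field 'bmo' must be a finite [x, y, z] triple", i)
    bmo[i, ] <- b
    if (is.null(sp$ilm) || length(sp$ilm) < 2L)
      .scan_schema_fail("field 'ilm' must contain at least 2 points", i)
    v <- try(do.call(rbind, lapply(sp$ilm, function(p) {
      p <- unlist(p)
      if (length(p) != 3L || !is.numeric(p)) stop("bad point")
      p
    })), silent = TRUE)
    if (inherits(v, "try-error") || !all(is.finite(v)))
      .scan_schema_fail("field 'ilm' must be an array of finite [x, y, z] points", i)
    ilm[[i]] <- v
  }
  if (n > 1L && any(diff(ang) <= 0))
    .scan_schema_fail("spoke angles must be strictly increasing")
  scan <- tryCatch(star_scan(doc$eye, ang, bmo, ilm, axis_deg = axis),
                   error = function(e)
                     .scan_schema_fail(conditionMessage(e)))
  if (scan$eye == "OS") {
    scan <- mirror_scan(scan)  # into the internal OD frame
    scan$eye <- "OS"
  }
  scan
}

#' Deterministic hash of analysis settings
#'
#' A short provenance tag attached to every result row; it changes whenever
#' the candidate step, refinement settings, chirality, axis or sector
#' scheme change. Polynomial rolling hash over the canonical settings
#' string (not cryptographic).
#'
#' @param settings a named list of settings.
#' @return An 8-character hexadecimal string.
#' @export
settings_hash <- function(settings) {
  s <- paste(names(settings),
             vapply(settings, function(v) paste(format(v, digits = 15), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Collect rim-area fits into a results table
#'
#' One row per fit, mirroring the global-plus-sector layout of clinical ONH
#' reports: `eye_id`, `method`, `global`, the six Garway-Heath sector
#' columns, `bmo_area` and `settings_hash`. Sector columns sum to `global`.
#'
#' @param fits list of [rim_area()] results.
#' @param eye_ids character vector of eye identifiers, one per fit.
#' @return A data frame.
#' @export
results_table <- function(fits, eye_ids) {
  if (length(fits) != length(eye_ids))
    stop("fits and eye_ids must have equal length", call. = FALSE)
  sector_cols <- c("nasal", "nasal_superior", "nasal_inferior",
                   "temporal", "temporal_superior", "temporal_inferior")
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    stopifnot(inherits(f, "rim_area"))
    s <- f$sector_sums
    missing <- setdiff(sector_cols, names(s))
    if (length(missing))
      stop("fit uses a sector scheme without the standard columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    cbind(data.frame(eye_id = eye_ids[k], method = f$method,
                     global = f$total, stringsAsFactors = FALSE),
          as.data.frame(as.list(s[sector_cols])),
          data.frame(bmo_area = f$bmo_area, settings_hash = f$settings_hash,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Diagnostic evaluation of paired rim-area parameters
#'
#' Reproduces the structure of a paired ROC comparison table: for the
#' global value and each sector, the AUC of the sequential (MRA) and global
#' (gMRA) parameters, the DeLong p-value for the paired AUC difference, the
#' unnormalized partial AUCs over specificity 0.9-1.0 with a stratified
#' paired bootstrap p-value, and sensitivities at 90% and 95% specificity.
#' Rim areas are scored with the lower-is-case direction.
#'
#' @param results results data frame from [results_table()] (methods
#'   `"sequential"` and `"global"` for the same eyes).
#' @param manifest cohort manifest data frame with `eye_id` and `diagnosis`.
#' @param positive,negative diagnosis labels treated as cases and controls.
#' @param B bootstrap resamples for the pAUC comparison.
#' @param seed integer seed for the bootstrap.
#' @return Data frame with one row per sector (including `"global"`).
#' @export
evaluate_diagnostics <- function(results, manifest,
                                 positive = "glaucoma", negative = "control",
                                 B = 2000L, seed = 1L) {
  need <- c("eye_id", "method", "global")
  if (!all(need %in% names(results)))
    stop("results must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("eye_id", "diagnosis") %in% names(manifest)))
    stop("manifest must contain columns eye_id and diagnosis", call. = FALSE)
  manifest <- manifest[manifest$diagnosis %in% c(positive, negative), ,
                       drop = FALSE]
  if (!any(manifest$diagnosis == positive))
    stop("no eyes with the positive diagnosis '", positive, "' in the manifest",
         call. = FALSE)
  if (!any(manifest$diagnosis == negative))
    stop("no eyes with the negative diagnosis '", negative, "' in the manifest",
         call. = FALSE)
  seqr <- results[results$method == "sequential", , drop = FALSE]
  glor <- results[results$method == "global", , drop = FALSE]
  ids <- intersect(intersect(seqr$eye_id, glor$eye_id), manifest$eye_id)
  if (length(ids) < 2L)
    stop("need both methods computed for at least 2 manifest eyes", call. = FALSE)
  seqr <- seqr[match(ids, seqr$eye_id), , drop = FALSE]
  glor <- glor[match(ids, glor$eye_id), , drop = FALSE]
  dx <- manifest$diagnosis[match(ids, manifest$eye_id)]
  labels <- dx == positive
  if (!any(labels) || !any(!labels))
    stop("evaluation needs at least one case and one control after matching",
         call. = FALSE)

  params <- c("global", intersect(c("nasal", "nasal_superior", "nasal_inferior",
                                    "temporal", "temporal_superior",
                                    "temporal_inferior"), names(results)))
  rows <- lapply(seq_along(params), function(k) {
    pc <- params[k]
    s1 <- seqr[[pc]]
    s2 <- glor[[pc]]
    dl <- delong_paired_test(s1, s2, labels)
    bp <- bootstrap_pauc_test(s1, s2, labels, B = B,
                              seed = (seed + k) %% 2147483647)
    data.frame(sector = pc,
               auc_mra = dl$auc1, auc_gmra = dl$auc2, delong_p = dl$p,
               pauc_mra = bp$pauc1, pauc_gmra = bp$pauc2, pauc_p = bp$p,
               sens90_mra = sensitivity_at_specificity(s1, labels, 0.90),
               sens90_gmra = sensitivity_at_specificity(s2, labels, 0.90),
               sens95_mra = sensitivity_at_specificity(s1, labels, 0.95),
               sens95_gmra = sensitivity_at_specificity(s2, labels, 0.95),
               n_case = sum(labels), n_control = sum(!labels),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a sector-scheme configuration file
#'
#' JSON object with parallel arrays `names`, `start_deg`, `end_deg`
#' (degrees, OD frame); see [sector_scheme()].
#'
#' @param path JSON config path.
#' @return A [sector_scheme()].
#' @export
read_sector_config <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$names) || is.null(doc$start_deg) || is.null(doc$end_deg))
    stop("sector config needs fields names, start_deg, end_deg", call. = FALSE)
  sector_scheme(doc$names, doc$start_deg, doc$end_deg)
}
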