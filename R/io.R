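#' Read a triangular surface mesh
#'
#' Supported formats: `off` (Object File Format), `ply` (ascii PLY),
#' `fs_ascii` (FreeSurfer ASCII .asc surfaces). Coordinates are taken as
#' stored; orientation is preserved.
#'
#' @param path file path.
#' @param format one of "off", "ply", "fs_ascii"; guessed from the
#'   extension when missing.
#' @return A [tri_mesh()].
#' @export
load_surface <- function(path, format = c("auto", "off", "ply", "fs_ascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("surface file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply", asc = "fs_ascii",
                     stop(sprintf("cannot guess surface format from '.%s'", ext)))
  }
  lines <- readLines(path, warn = FALSE)
  switch(format,
    off = .parse_off(lines, path),
    ply = .parse_ply(lines, path),
    fs_ascii = .parse_fs_ascii(lines, path))
}

.tokens <- function(line) strsplit(trimws(line), "\\s+")[[1L]]

.strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

.parse_off <- function(lines, path) {
  lines <- .strip_comments(lines)
  if (length(lines) < 2L || toupper(trimws(lines[1L])) != "OFF")
    stop(sprintf("%s: malformed OFF header at line 1", path))
  counts <- suppressWarnings(as.integer(.tokens(lines[2L])))
  if (length(counts) < 2L || any(is.na(counts[1:2])))
    stop(sprintf("%s: malformed OFF count line at line 2", path))
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf)
    stop(sprintf("%s: truncated OFF file", path))
  v <- matrix(as.numeric(unlist(lapply(lines[3:(2L + nv)], .tokens))),
              nv, 3L, byrow = TRUE)
  f <- t(vapply(lines[(3L + nv):(2L + nv + nf)], function(l) {
    tk <- as.integer(.tokens(l))
    if (tk[1L] != 3L) stop(sprintf("%s: only triangular faces supported", path))
    tk[2:4]
  }, integer(3L)))
  tri_mesh(v, f + 1L)
}

.parse_ply <- function(lines, path) {
  if (toupper(trimws(lines[1L])) != "PLY")
    stop(sprintf("%s: malformed PLY header at line 1", path))
  hend <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hend)) stop(sprintf("%s: PLY missing end_header", path))
  hdr <- lines[seq_len(hend)]
  if (!any(grepl("^format\\s+ascii", trimws(hdr))))
    stop(sprintf("%s: only ascii PLY supported", path))
  ev <- grep("^element\\s+vertex", trimws(hdr), value = TRUE)
  ef <- grep("^element\\s+face", trimws(hdr), value = TRUE)
  if (!length(ev) || !length(ef))
    stop(sprintf("%s: PLY header missing vertex/face elements", path))
  nv <- as.integer(.tokens(ev)[3L]); nf <- as.integer(.tokens(ef)[3L])
  body <- lines[(hend + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  v <- matrix(as.numeric(unlist(lapply(body[seq_len(nv)], function(l)
    .tokens(l)[1:3]))), nv, 3L, byrow = TRUE)
  f <- t(vapply(body[(nv + 1L):(nv + nf)], function(l) {
    tk <- as.integer(.tokens(l))
    if (tk[1L] != 3L) stop(sprintf("%s: only triangular faces supported", path))
    tk[2:4]
  }, integer(3L)))
  tri_mesh(v, f + 1L)
}

.parse_fs_ascii <- function(lines, path) {
  lines <- .strip_comments(lines)
  counts <- suppressWarnings(as.integer(.tokens(lines[1L])))
  if (length(counts) != 2L || any(is.na(counts)))
    stop(sprintf("%s: malformed FreeSurfer ASCII count line", path))
  nv <- counts[1L]; nf <- counts[2L]
  v <- matrix(as.numeric(unlist(lapply(lines[2:(1L + nv)], function(l)
    .tokens(l)[1:3]))), nv, 3L, byrow = TRUE)
  f <- matrix(as.integer(unlist(lapply(lines[(2L + nv):(1L + nv + nf)],
    function(l) .tokens(l)[1:3]))), nf, 3L, byrow = TRUE)
  tri_mesh(v, f + 1L)
}

#' Write a triangular surface mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format "off", "ply" (ascii) or "fs_ascii".
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
save_surface <- function(mesh, path, format = c("off", "ply", "fs_ascii"),
                         digits = 17L) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (nrow(mesh$triangles) == 0L) stop("refusing to write a mesh with no faces")
  v <- mesh$vertices; f <- mesh$triangles - 1L
  fmtv <- apply(v, 1L, function(r) paste(formatC(r, digits = digits,
                                                 format = "g"), collapse = " "))
  con <- file(path, "w"); on.exit(close(con))
  if (format == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)), fmtv,
                 sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L])), con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header",
                 fmtv, sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L])), con)
  } else {
    writeLines(c(sprintf("%d %d", nrow(v), nrow(f)),
                 paste(fmtv, "0"),
                 sprintf("%d %d %d 0", f[, 1L], f[, 2L], f[, 3L])), con)
  }
  invisible(path)
}

#' Read a sensor layout (SFP/ELC dialect)
#'
#' One `label x y z` row per sensor. Coordinates are interpreted as
#' meters; if any coordinate magnitude exceeds 1.5 the file is assumed to
#' be in millimeters and converted, with a warning.
#'
#' @param path file path.
#' @param type sensor type for the resulting array.
#' @return A [sensor_array()].
#' @export
load_sensor_layout <- function(path, type = "eeg") {
  if (!file.exists(path)) stop(sprintf("layout file not found: %s", path))
  lines <- .strip_comments(readLines(path, warn = FALSE))
  if (!length(lines)) stop(sprintf("%s: empty sensor layout", path))
  rows <- lapply(lines, .tokens)
  if (any(vapply(rows, length, 1L) < 4L))
    stop(sprintf("%s: each row must be 'label x y z'", path))
  labels <- vapply(rows, `[`, "", 1L)
  xyz <- t(vapply(rows, function(r) {
    val <- suppressWarnings(as.numeric(r[2:4]))
    if (any(is.na(val)))
      stop(sprintf("%s: non-numeric coordinate for sensor '%s'", path, r[1L]))
    val
  }, numeric(3L)))
  if (max(abs(xyz)) > 1.5) {
    warning(sprintf("%s: coordinates look like millimeters; converting to meters",
                    path))
    xyz <- xyz / 1000
  }
  sensor_array(labels, xyz, type = type)
}

#' Write a sensor layout
#' @param sensors a [sensor_array()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_sensor_layout <- function(sensors, path) {
  writeLines(sprintf("%s %.17g %.17g %.17g", sensors$labels,
                     sensors$positions[, 1L], sensors$positions[, 2L],
                     sensors$positions[, 3L]), path)
  invisible(path)
}

#' Save a lead field (portable binary array + JSON sidecar)
#'
#' The matrix is stored row-major as little-endian float64 in `<path>`,
#' with metadata (shape, sensor labels, source count, orientation mode,
#' units, reference, provenance) in `<path>.json`. Round trips are
#' bit-exact.
#'
#' @param lf a [lead_field()].
#' @param path data-file path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
save_leadfield <- function(lf, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.vector(t(lf$matrix)), con, size = 8L, endian = "little")
  meta <- list(
    n_sensors = nrow(lf$matrix), n_columns = ncol(lf$matrix),
    n_sources = if (lf$orientation_mode == "free") ncol(lf$matrix) / 3L
                else ncol(lf$matrix),
    orientation_mode = lf$orientation_mode, units = lf$units,
    reference = lf$reference, provenance = lf$provenance,
    labels = lf$labels, order = "row_major", dtype = "float64_le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a lead field saved by [save_leadfield()]
#' @param path data-file path.
#' @return A [lead_field()].
#' @export
load_leadfield <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("lead-field data or sidecar file missing")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_sensors * meta$n_columns
  con <- file(path, "rb"); on.exit(close(con))
  x <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  if (length(x) != n)
    stop(sprintf("lead-field array has %d values but sidecar declares %d",
                 length(x), n))
  if (meta$orientation_mode == "free" && meta$n_columns %% 3L != 0L)
    stop("free-orientation lead field with column count not divisible by 3")
  if (meta$n_columns != (if (meta$orientation_mode == "free") 3L else 1L) *
        meta$n_sources)
    stop("sidecar source count inconsistent with array shape")
  M <- matrix(x, meta$n_sensors, meta$n_columns, byrow = TRUE)
  lead_field(M, meta$orientation_mode, units = meta$units,
             reference = meta$reference, provenance = meta$provenance,
             labels = meta$labels)
}

# ---- configuration ----------------------------------------------------

#' Default toolkit configuration
#'
#' Full nested defaults for forward modeling, quality control, spectral
#' estimation, inverse solving, priors and the comparison analysis. Any
#' JSON configuration file overrides a subset of these keys; unknown keys
#' are errors.
#'
#' @return Nested list of class `esi_config`.
#' @export
default_config <- function() {
  structure(list(
    forward = list(
      model = "three_shell_sphere",
      conductivities = c(0.33, 0.0042, 0.33),
      radii = c(0.079, 0.082, 0.088, 0.092),
      n_terms = 60,
      reference = "average"
    ),
    qc = list(
      sensor_corr_threshold = 0.7,
      source_corr_threshold = 0.33,
      min_distance_m = 0.002,
      max_iterations = 5,
      flag_mode = "any"
    ),
    spectral = list(
      fmax = 50, df = 0.5, bandwidth = 1,
      bands = list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                   beta = c(14, 30), gamma = c(30, NA)),
      segment_length = 256
    ),
    inverse = list(
      method = "sssbl", type2 = "hglasso",
      alpha1 = 0.1, alpha2 = 0.01, alpha_graph = 0.1,
      noise_variance = NA, max_iter = 200, tolerance = 1e-6,
      support_threshold = 0.95
    ),
    priors = list(
      field = FALSE, curvature = FALSE, laplacian = FALSE,
      parcellation = FALSE,
      slope_gyri = 0.5, intercept_gyri = 1.0,
      slope_sulci = 0.5, intercept_sulci = 1.0,
      deformation = 1e-3
    ),
    comparison = list(n_permutations = 500, alpha = 0.01,
                      statistic = "mean_diff", use_residuals = TRUE),
    seed = 1
  ), class = "esi_config")
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a JSON configuration, filling missing keys from defaults
#'
#' @param path JSON file, or NULL for pure defaults.
#' @return `esi_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- structure(.merge_config(unclass(cfg), user), class = "esi_config")
  }
  validate_config(cfg)
}

#' Validate configuration invariants
#' @param cfg an `esi_config`.
#' @return The config, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  qc <- cfg$qc
  if (qc$sensor_corr_threshold <= 0 || qc$sensor_corr_threshold > 1 ||
      qc$source_corr_threshold <= 0 || qc$source_corr_threshold > 1)
    stop("correlation thresholds must lie in (0, 1]")
  if (qc$max_iterations < 1) stop("qc.max_iterations must be >= 1")
  if (cfg$spectral$fmax <= 0 || cfg$spectral$df <= 0)
    stop("spectral.fmax and spectral.df must be > 0")
  edges <- unlist(lapply(cfg$spectral$bands, function(b) b[1L]))
  if (any(diff(edges) <= 0)) stop("band lower edges must be strictly increasing")
  invisible(cfg)
}

# ---- reports ----------------------------------------------------------

#' Stage report
#'
#' Bookkeeping record for a pipeline stage: status is one of `pass`,
#' `flagged`, `corrected`, `incorrigible`; every flagged entry names the
#' violated threshold; history holds ordered correction records.
#'
#' @param stage stage name.
#' @param status initial status.
#' @param metrics named list of scalar/array summaries.
#' @return Object of class `esi_report`.
#' @export
new_report <- function(stage, status = "pass", metrics = list()) {
  structure(list(stage = stage, status = status, metrics = metrics,
                 history = list(), figures = character(0)),
            class = "esi_report")
}

report_flag <- function(report, threshold_name, threshold_value, detail) {
  if (!report$status %in% c("pass", "flagged"))
    stop("invalid status transition")
  report$status <- "flagged"
  report$history <- c(report$history, list(list(
    event = "flag", threshold = threshold_name, value = threshold_value,
    detail = detail)))
  report
}
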