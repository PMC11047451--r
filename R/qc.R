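#' Lead-field QC thresholds
#'
#' Default flagging rules: a sensor is artifactual
#' when its source-wide correlation with the homogeneous lead field falls
#' strictly below 0.7, a source when its sensor-wide correlation falls
#' strictly below 0.33.
#'
#' @param sensor_corr_threshold flag sensors strictly below this (0, 1].
#' @param source_corr_threshold flag sources strictly below this (0, 1].
#' @param min_distance_m minimum source to inner-skull distance, meters.
#' @param max_iterations correction-loop cap.
#' @param flag_mode "any" (either rule flags) or "all" (both required).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sensor_corr_threshold = 0.7,
                          source_corr_threshold = 0.33,
                          min_distance_m = 0.002,
                          max_iterations = 5L,
                          flag_mode = c("any", "all")) {
  flag_mode <- match.arg(flag_mode)
  if (sensor_corr_threshold <= 0 || sensor_corr_threshold > 1 ||
      source_corr_threshold <= 0 || source_corr_threshold > 1)
    stop("correlation thresholds must lie in (0, 1]")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  structure(list(sensor_corr_threshold = sensor_corr_threshold,
                 source_corr_threshold = source_corr_threshold,
                 min_distance_m = min_distance_m,
                 max_iterations = as.integer(max_iterations),
                 flag_mode = flag_mode),
            class = "qc_thresholds")
}

.pearson_rows <- function(A, B) {
  a <- A - rowMeans(A); b <- B - rowMeans(B)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Sensor-wide and source-wide lead-field correlations
#'
#' The QC index: for each sensor (lead-field row) the Pearson correlation
#' across sources between the tested and the homogeneous lead field, and
#' for each source (column) the Pearson correlation across sensors. Both
#' lead fields must be orientation-constrained and of identical shape.
#' Zero-variance rows/columns yield NA with a reason, to be flagged
#' downstream rather than silently passed.
#'
#' @param L_test,L_hom [lead_field()]s or plain matrices of equal shape.
#' @return List: `per_sensor_corr` (N), `per_source_corr` (S),
#'   `undefined_sensors`, `undefined_sources` (indices with zero variance).
#' @export
leadfield_correlations <- function(L_test, L_hom) {
  A <- if (inherits(L_test, "lead_field")) L_test$matrix else as.matrix(L_test)
  B <- if (inherits(L_hom, "lead_field")) L_hom$matrix else as.matrix(L_hom)
  if (inherits(L_test, "lead_field") && L_test$orientation_mode == "free")
    stop("QC correlations need orientation-constrained lead fields")
  if (!all(dim(A) == dim(B))) stop("lead-field shape mismatch")
  per_sensor <- .pearson_rows(A, B)
  per_source <- .pearson_rows(t(A), t(B))
  list(per_sensor_corr = per_sensor, per_source_corr = per_source,
       undefined_sensors = which(is.na(per_sensor)),
       undefined_sources = which(is.na(per_source)))
}

#' Global linear fit between two lead fields
#'
#' Ordinary least squares of the vectorized tested lead field on the
#' vectorized homogeneous one, the goodness-of-fit diagnostic shown in
#' the QC report scatter panels.
#'
#' @param L_test,L_hom matrices or [lead_field()]s of equal shape.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
leadfield_linear_fit <- function(L_test, L_hom) {
  y <- as.vector(if (inherits(L_test, "lead_field")) L_test$matrix else L_test)
  x <- as.vector(if (inherits(L_hom, "lead_field")) L_hom$matrix else L_hom)
  if (length(x) != length(y)) stop("lead-field shape mismatch")
  vx <- stats::var(x)
  if (vx == 0) stop("homogeneous lead field is constant; fit undefined")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Apply the strict-below flagging rules to QC correlations
#'
#' Sensor i is flagged iff its correlation is strictly below the sensor
#' threshold, source j iff strictly below the source threshold (boundary
#' values pass). Undefined (zero-variance) entries are always flagged.
#'
#' @param qc output of [leadfield_correlations()].
#' @param thr a [qc_thresholds()].
#' @return List of class `qc_result` adding `sensor_flags`,
#'   `source_flags`, `status` ("pass"/"flagged"), `violated` (names of
#'   violated thresholds with values).
#' @export
flag_leadfield <- function(qc, thr) {
  sflag <- qc$per_sensor_corr < thr$sensor_corr_threshold
  sflag[is.na(sflag)] <- TRUE
  jflag <- qc$per_source_corr < thr$source_corr_threshold
  jflag[is.na(jflag)] <- TRUE
  any_flag <- if (thr$flag_mode == "any") any(sflag) || any(jflag)
              else any(sflag) && any(jflag)
  violated <- c(
    if (any(sflag)) sprintf("sensor_corr_threshold=%g", thr$sensor_corr_threshold),
    if (any(jflag)) sprintf("source_corr_threshold=%g", thr$source_corr_threshold))
  structure(c(qc, list(sensor_flags = sflag, source_flags = jflag,
                       status = if (any_flag) "flagged" else "pass",
                       violated = violated, thresholds = thr)),
            class = "qc_result")
}

#' Distance flags for sources too close to the inner skull
#'
#' @param src a [source_space()].
#' @param inner_skull [tri_mesh()].
#' @param min_distance_m threshold, meters.
#' @return As [surface_surface_distances()].
#' @export
distance_flag_sources <- function(src, inner_skull, min_distance_m = 0.002) {
  surface_surface_distances(src$positions, inner_skull, min_distance_m)
}

#' Lead-field quality-control and correction loop
#'
#' Iterates: compute the tested lead field (from `lf_provider`) and the
#' homogeneous baseline, their correlation indices, threshold flags, and
#' the source-to-inner-skull distance flags; while distance violations
#' remain, warp the inner skull outward and recompute. Stops at `pass` or
#' after `max_iterations`, in which case status is `incorrigible` and the
#' full iteration history is returned. The loop is automatic: cases an
#' interactive workflow would hand to visual inspection are labeled
#' incorrigible instead of pausing.
#'
#' @param head a `head_model` (see [make_nested_head()]).
#' @param src a constrained [source_space()].
#' @param sensors a [sensor_array()].
#' @param lf_provider function(head, src, sensors) -> [lead_field()]
#'   (orientation-constrained or free; free is constrained with the
#'   source normals).
#' @param thr a [qc_thresholds()].
#' @return List: `head`, `leadfield`, `qc` (final `qc_result` with
#'   `status` in pass/corrected/incorrigible), `history` (per-iteration
#'   metrics).
#' @export
qc_control_loop <- function(head, src, sensors, lf_provider, thr) {
  history <- list()
  corrected <- FALSE
  incorrigible <- FALSE
  for (it in seq_len(thr$max_iterations)) {
    L_test <- lf_provider(head, src, sensors)
    if (inherits(L_test, "lead_field") && L_test$orientation_mode == "free")
      L_test <- apply_orientation_constraint(L_test, src$orientations)
    L_hom <- homogeneous_leadfield_eeg(src, sensors,
                                       sigma = head$conductivities[[1L]],
                                       reference = L_test$reference)
    qc <- leadfield_correlations(L_test, L_hom)
    qc <- flag_leadfield(qc, thr)
    fit <- leadfield_linear_fit(L_test, L_hom)
    dd <- distance_flag_sources(src, head$inner_skull, thr$min_distance_m)
    qc$distance_flags <- dd$flags
    qc$distances <- dd$distances
    qc$fit <- fit
    history[[it]] <- list(
      iteration = it,
      min_sensor_corr = suppressWarnings(min(qc$per_sensor_corr, na.rm = TRUE)),
      min_source_corr = suppressWarnings(min(qc$per_source_corr, na.rm = TRUE)),
      n_sensor_flags = sum(qc$sensor_flags),
      n_source_flags = sum(qc$source_flags),
      n_distance_flags = sum(dd$flags),
      r_squared = fit$r_squared,
      corrected = corrected)
    if (qc$status == "pass" && !any(dd$flags)) {
      qc$status <- if (corrected) "corrected" else "pass"
      return(list(head = head, leadfield = L_test, qc = qc, history = history))
    }
    if (it == thr$max_iterations) break
    if (any(dd$flags)) {
      w <- warp_surface_outward(head$inner_skull,
                                src$positions[dd$flags, , drop = FALSE],
                                thr$min_distance_m,
                                outer_limit = head$outer_skull)
      head$inner_skull <- w$mesh
      corrected <- TRUE
      if (w$incorrigible) { incorrigible <- TRUE; break }
    } else {
      # correlation flags with no distance cause: nothing the geometric
      # loop can fix automatically
      incorrigible <- TRUE
      break
    }
  }
  qc$status <- "incorrigible"
  list(head = head, leadfield = L_test, qc = qc, history = history)
}

#' Template fallback head model
#'
#' Substitutes the individual head/source model with the packaged
#' template fixture (nested-sphere surfaces) when the QC loop declares a
#' case incorrigible; provenance is recorded as "template".
#'
#' @param config an `esi_config` (radii/subdivisions come from
#'   `config$forward`).
#' @param subdivisions icosphere subdivision level.
#' @return List: `head` (provenance "template"), `src` (constrained
#'   [source_space()] on the template cortex).
#' @export
template_fallback <- function(config = default_config(), subdivisions = 3L) {
  radii <- config$forward$radii
  if (is.null(radii) || length(radii) != 4L)
    stop("template fallback needs 4 forward.radii in the configuration")
  head <- make_nested_head(radii = radii, subdivisions = subdivisions)
  head$provenance <- "template"
  nrm <- vertex_normals(head$cortex)
  src <- source_space(head$cortex$vertices, nrm)
  list(head = head, src = src)
}

#' Write the QC report (JSON + optional figures)
#'
#' Serializes all QC metrics (correlations, flags, thresholds, fit,
#' distances, history) to `qc_report.json` in `out_dir`, and optionally
#' renders static figure panels (correlation bars, linear-fit scatter).
#'
#' @param qc a `qc_result` (optionally with `history` attached).
#' @param out_dir output directory (created if missing).
#' @param history optional loop history to embed.
#' @param figures render PNG panels.
#' @return Path of the JSON report, invisibly.
#' @export
generate_qc_report <- function(qc, out_dir, history = NULL, figures = FALSE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  payload <- list(
    schema = "esikit-qc-report/1",
    status = qc$status,
    per_sensor_corr = qc$per_sensor_corr,
    per_source_corr = qc$per_source_corr,
    sensor_flags = qc$sensor_flags,
    source_flags = qc$source_flags,
    distance_flags = qc$distance_flags,
    distances = qc$distances,
    violated = if (length(qc$violated)) qc$violated else character(0),
    thresholds = unclass(qc$thresholds),
    fit = qc$fit,
    history = history)
  path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (figures) {
    fp <- file.path(out_dir, "qc_correlations.png")
    grDevices::png(fp, width = 900, height = 400)
    graphics::par(mfrow = c(1, 2))
    graphics::barplot(qc$per_sensor_corr, main = "sensor-wide correlation",
                      ylim = c(-1, 1))
    graphics::abline(h = qc$thresholds$sensor_corr_threshold, col = "red")
    graphics::barplot(qc$per_source_corr, main = "source-wide correlation",
                      ylim = c(-1, 1))
    graphics::abline(h = qc$thresholds$source_corr_threshold, col = "red")
    grDevices::dev.off()
  }
  invisible(path)
}

#' Re-load a QC report written by [generate_qc_report()]
#' @param path JSON report path.
#' @return Parsed report list.
#' @export
load_qc_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
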