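#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: 10*4^s + 2 vertices,
#' consistently outward-oriented, closed, genus 0. The standard synthetic
#' cortex/head surface used throughout the toolkit's fixtures.
#'
#' @param subdivisions integer in 0..6.
#' @param radius sphere radius in meters.
#' @return A [tri_mesh()].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 6L)
    stop("subdivisions must be in [0, 6]")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- new.env(hash = TRUE, parent = emptyenv())
    verts <- vector("list", 3L * nrow(f))
    nnew <- 0L
    midpoint <- function(a, b) {
      key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
      id <- edge_key[[key]]
      if (!is.null(id)) return(id)
      nnew <<- nnew + 1L
      verts[[nnew]] <<- (v[a, ] + v[b, ]) / 2
      id <- nv + nnew
      edge_key[[key]] <- id
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c3, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, verts[seq_len(nnew)]))
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  tri_mesh(v * radius, f)
}

#' Nested-sphere head model
#'
#' Four concentric icospheres (cortex, inner skull, outer skull, scalp)
#' with piecewise-homogeneous isotropic conductivities; the spherical
#' idealization of a BEM head model used as the built-in fixture.
#'
#' @param radii ascending numeric(4), meters; defaults 0.079, 0.082,
#'   0.088, 0.092.
#' @param subdivisions icosphere subdivision level for every surface.
#' @param conductivities named numeric(3) S/m for brain, skull, scalp;
#'   defaults 0.33, 0.0042, 0.33.
#' @return List of class `head_model`: surfaces `cortex`, `inner_skull`,
#'   `outer_skull`, `scalp`, plus `conductivities`, `radii`, `model_type`.
#' @export
make_nested_head <- function(radii = c(0.079, 0.082, 0.088, 0.092),
                             subdivisions = 3L,
                             conductivities = c(brain = 0.33, skull = 0.0042,
                                                scalp = 0.33)) {
  if (length(radii) != 4L || any(diff(radii) <= 0))
    stop("radii must be 4 strictly ascending values")
  if (any(conductivities <= 0)) stop("conductivities must be > 0")
  structure(list(
    cortex = make_icosphere(subdivisions, radii[1L]),
    inner_skull = make_icosphere(subdivisions, radii[2L]),
    outer_skull = make_icosphere(subdivisions, radii[3L]),
    scalp = make_icosphere(subdivisions, radii[4L]),
    conductivities = conductivities,
    radii = radii,
    model_type = "three_shell_sphere",
    provenance = "synthetic"
  ), class = "head_model")
}

# standard 10-20 angular positions (azimuth deg from +x nasion axis,
# inclination deg from +z apex); conventional spherical-cap placement
.ten20_angles <- function() {
  rbind(
    Fp1 = c(108, 72), Fp2 = c(72, 72),
    F7 = c(144, 72), F3 = c(129, 48), Fz = c(90, 36), F4 = c(51, 48), F8 = c(36, 72),
    T3 = c(180, 72), C3 = c(180, 36), Cz = c(0, 0), C4 = c(0, 36), T4 = c(0, 72),
    T5 = c(216, 72), P3 = c(231, 48), Pz = c(270, 36), P4 = c(309, 48), T6 = c(324, 72),
    O1 = c(252, 72), O2 = c(288, 72))
}

#' Synthetic 19-channel 10-20 EEG layout on a scalp surface
#'
#' Places the 19 standard 10-20 electrodes at conventional angular
#' coordinates on the bounding sphere and projects each onto the scalp
#' mesh.
#'
#' @param scalp scalp [tri_mesh()] (spherical fixture).
#' @return A `sensor_array` (see [sensor_array()]).
#' @export
make_1020_layout <- function(scalp) {
  ang <- .ten20_angles()
  r <- max(sqrt(rowSums(scalp$vertices^2)))
  incl <- ang[, 2L] * pi / 180
  az <- ang[, 1L] * pi / 180
  pos <- cbind(r * sin(incl) * cos(az),
               r * sin(incl) * sin(az),
               r * cos(incl))
  sa <- sensor_array(labels = rownames(ang), positions = pos, type = "eeg")
  project_sensors_to_scalp(sa, scalp)
}

#' Standard quality-control fixture scene
#'
#' Nested-sphere head model, 19-channel 10-20 layout, and a constrained
#' source space restricted to cortex vertices beneath the montage
#' (z > `cap_z`). Restricting sources to the sensor-covered cap mirrors
#' real anatomy, where the cortex lies under the electrode array; sources
#' on the far side of a full sphere are unobservable to a 10-20 montage
#' and carry no quality-control information.
#'
#' @param subdivisions icosphere subdivision level (default 2: 162
#'   vertices per surface).
#' @param cap_z lower z-bound (meters) for included cortex vertices.
#' @param radii passed to [make_nested_head()].
#' @return List: `head`, `sensors`, `src`, `source_vertices` (indices
#'   into the cortex mesh).
#' @export
make_qc_scene <- function(subdivisions = 2L, cap_z = 0.01,
                          radii = c(0.079, 0.082, 0.088, 0.092)) {
  head <- make_nested_head(radii = radii, subdivisions = subdivisions)
  sensors <- make_1020_layout(head$scalp)
  keep <- which(head$cortex$vertices[, 3L] > cap_z)
  nrm <- vertex_normals(head$cortex)
  src <- source_space(head$cortex$vertices[keep, , drop = FALSE],
                      nrm[keep, , drop = FALSE])
  list(head = head, sensors = sensors, src = src, source_vertices = keep)
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model (%s, %s): 4 nested surfaces, radii %s m\n",
              x$model_type, x$provenance,
              paste(x$radii, collapse = "/")))
  cat(sprintf("  conductivities (S/m): %s\n",
              paste(sprintf("%s=%g", names(x$conductivities),
                            x$conductivities), collapse = ", ")))
  invisible(x)
}
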