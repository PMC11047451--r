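# closest point on each triangle to a single point p (Ericson's method,
# vectorized over triangles); returns squared distances and closest points
.closest_on_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(A)
  out <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  set_rows <- function(idx, pts) {
    if (any(idx)) { out[idx, ] <<- pts[idx, , drop = FALSE]; done[idx] <<- TRUE }
  }
  set_rows(!done & d1 <= 0 & d2 <= 0, A)
  set_rows(!done & d3 >= 0 & d4 <= d3, B)
  set_rows(!done & d6 >= 0 & d5 <= d6, C)
  vdenom <- d1 / (d1 - d3)
  set_rows(!done & vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * vdenom)
  wdenom <- d2 / (d2 - d6)
  set_rows(!done & vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * wdenom)
  udenom <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_rows(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * udenom)
  denom <- 1 / (va + vb + vc)
  vcoef <- vb * denom; wcoef <- vc * denom
  set_rows(!done, A + ab * vcoef + ac * wcoef)
  d2q <- rowSums(sweep(out, 2L, p, "-")^2)
  list(dist2 = d2q, points = out)
}

#' Unsigned distances from points to a surface
#'
#' Nearest point-to-triangle distance from each query point (or each
#' vertex of an inner mesh) to an outer triangulated surface, with flags
#' for points closer than a minimum-distance criterion. This is the
#' surface-surface distance indicator the lead-field quality control uses
#' to detect sources sitting too close to the inner skull.
#'
#' @param inner a [tri_mesh()] or an n x 3 matrix of points (meters).
#' @param outer a [tri_mesh()].
#' @param min_distance_m flagging threshold in meters (default 0.002).
#' @return List: `distances` (n), `closest` (n x 3 nearest surface points),
#'   `flags` (distance < min_distance_m).
#' @export
surface_surface_distances <- function(inner, outer, min_distance_m = 0.002) {
  pts <- if (inherits(inner, "tri_mesh")) inner$vertices else as.matrix(inner)
  if (!inherits(outer, "tri_mesh") || nrow(outer$triangles) == 0L)
    stop("outer surface must be a non-empty tri_mesh")
  if (nrow(pts) == 0L) stop("no query points supplied")
  A <- outer$vertices[outer$triangles[, 1L], , drop = FALSE]
  B <- outer$vertices[outer$triangles[, 2L], , drop = FALSE]
  C <- outer$vertices[outer$triangles[, 3L], , drop = FALSE]
  n <- nrow(pts)
  d <- numeric(n); cl <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    r <- .closest_on_triangles(pts[i, ], A, B, C)
    j <- which.min(r$dist2)
    d[i] <- sqrt(r$dist2[j]); cl[i, ] <- r$points[j, ]
  }
  list(distances = d, closest = cl, flags = d < min_distance_m)
}

#' Warp a surface outward away from too-close points
#'
#' Forces the local inner-skull triangle mesh outwards until every
#' offending point reaches a minimum distance to the surface. Vertices
#' within `smoothing_radius_m` of an offending point's nearest surface
#' point are displaced along the direction away from the point with a
#' smooth quartic falloff; vertices beyond the radius are untouched. The
#' correction is recomputed from current distances, so applying it twice
#' equals applying it once. If an `outer_limit` surface is supplied and
#' the warp would push vertices through it, those vertices are clamped and
#' the result is flagged incorrigible.
#'
#' @param inner_skull closed [tri_mesh()] to deform.
#' @param offending_points m x 3 matrix of source positions needing
#'   clearance.
#' @param min_distance_m required clearance (meters).
#' @param smoothing_radius_m spatial extent of the local deformation.
#' @param outer_limit optional [tri_mesh()] the warp must not cross.
#' @param max_passes internal refinement passes.
#' @return List: `mesh` (warped [tri_mesh()]), `achieved` (logical),
#'   `incorrigible` (logical), `moved` (indices of displaced vertices).
#' @export
warp_surface_outward <- function(inner_skull, offending_points, min_distance_m,
                                 smoothing_radius_m = 0.015,
                                 outer_limit = NULL, max_passes = 10L) {
  pts <- as.matrix(offending_points)
  if (nrow(pts) == 0L)
    return(list(mesh = inner_skull, achieved = TRUE, incorrigible = FALSE,
                moved = integer(0)))
  v <- inner_skull$vertices
  moved <- logical(nrow(v))
  incorrigible <- FALSE
  for (pass in seq_len(max_passes)) {
    ss <- surface_surface_distances(pts, tri_mesh(v, inner_skull$triangles,
                                                  validate = FALSE),
                                    min_distance_m)
    need <- pmax(0, min_distance_m - ss$distances)
    if (all(need <= 1e-12)) break
    # one displacement per vertex: from the offending point demanding the
    # largest move there (later passes mop up any remaining deficit)
    disp_amt <- numeric(nrow(v))
    disp_dir <- matrix(0, nrow(v), 3L)
    for (j in which(need > 1e-12)) {
      q <- ss$closest[j, ]
      dir <- q - pts[j, ]
      nd <- sqrt(sum(dir^2))
      if (nd <= 1e-12) {   # point exactly on the surface: push along centroid ray
        dir <- q - colMeans(v)
        nd <- sqrt(sum(dir^2))
      }
      dir <- dir / nd
      r2 <- rowSums(sweep(v, 2L, q, "-")^2)
      w <- pmax(0, 1 - r2 / smoothing_radius_m^2)^2
      amt <- (need[j] * 1.05) * w
      take <- amt > disp_amt
      if (any(take)) {
        disp_amt[take] <- amt[take]
        disp_dir[take, ] <- matrix(dir, sum(take), 3L, byrow = TRUE)
        moved <- moved | take
      }
    }
    v <- v + disp_dir * disp_amt
    if (!is.null(outer_limit)) {
      chk <- surface_surface_distances(v[moved, , drop = FALSE], outer_limit,
                                       min_distance_m = 0)
      ctr <- colMeans(outer_limit$vertices)
      rad_pt <- sqrt(rowSums(sweep(v[moved, , drop = FALSE], 2L, ctr, "-")^2))
      rad_cl <- sqrt(rowSums(sweep(chk$closest, 2L, ctr, "-")^2))
      outside <- rad_pt > rad_cl
      if (any(outside)) {
        idx <- which(moved)[outside]
        # clamp crossing vertices back onto the limiting surface
        v[idx, ] <- chk$closest[outside, , drop = FALSE]
        incorrigible <- TRUE
      }
    }
  }
  ss <- surface_surface_distances(pts, tri_mesh(v, inner_skull$triangles,
                                                validate = FALSE),
                                  min_distance_m)
  achieved <- all(ss$distances >= min_distance_m - 1e-9)
  if (!achieved && !is.null(outer_limit)) incorrigible <- TRUE
  list(mesh = tri_mesh(v, inner_skull$triangles),
       achieved = achieved, incorrigible = incorrigible,
       moved = which(moved))
}
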