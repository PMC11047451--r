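#' Resample (decimate) a mesh to a target vertex count
#'
#' Iterative edge collapse driven by quadric error (sum of squared
#' distances to the planes of the original incident faces). Collapses are
#' accepted only when they preserve the closed-manifold link condition, so
#' sphere-like fixtures keep closedness, orientability and genus. The new
#' vertex position is the best (lowest quadric cost) of the two endpoints
#' and the midpoint, which keeps vertices on or within one edge length of
#' the input surface.
#'
#' @param mesh a closed [tri_mesh()].
#' @param target_vertices desired vertex count, in [12, V].
#' @return A [tri_mesh()] with vertex count within 2\% of the target
#'   (exactly the target unless no further valid collapse exists).
#' @export
resample_mesh <- function(mesh, target_vertices) {
  validate_mesh(mesh)
  target_vertices <- as.integer(target_vertices)
  nv <- nrow(mesh$vertices)
  if (target_vertices > nv) stop("target vertex count exceeds current count")
  if (target_vertices < 12L) stop("target vertex count must be at least 12")
  if (target_vertices == nv) return(mesh)

  v <- mesh$vertices
  tr <- mesh$triangles
  fa <- face_normals_areas(mesh)
  # per-vertex quadrics from area-weighted incident face planes, kept as
  # flattened 4x4 matrices in a nv x 16 array for cheap accumulation
  Q <- matrix(0, nv, 16L)
  for (i in seq_len(nrow(tr))) {
    n <- fa$normals[i, ]
    p <- c(n, -sum(n * v[tr[i, 1L], ]))
    K <- as.vector(fa$areas[i] * (p %o% p))
    Q[tr[i, 1L], ] <- Q[tr[i, 1L], ] + K
    Q[tr[i, 2L], ] <- Q[tr[i, 2L], ] + K
    Q[tr[i, 3L], ] <- Q[tr[i, 3L], ] + K
  }

  e0 <- mesh_edges(mesh)
  nbr <- vector("list", nv)
  for (i in seq_len(nrow(e0))) {
    a <- e0[i, 1L]; b <- e0[i, 2L]
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }

  best_collapse <- function(a, b) {
    Qs <- matrix(Q[a, ] + Q[b, ], 4L, 4L)
    cand <- rbind(v[a, ], v[b, ], (v[a, ] + v[b, ]) / 2)
    ch <- cbind(cand, 1)
    costs <- rowSums((ch %*% Qs) * ch)
    j <- which.min(costs)
    list(cost = costs[j], pos = cand[j, ])
  }

  # lazy-deletion queue keyed by per-vertex stamps
  qa <- e0[, 1L]; qb <- e0[, 2L]
  qcost <- numeric(length(qa))
  qpos <- matrix(0, length(qa), 3L)
  for (i in seq_along(qa)) {
    bc <- best_collapse(qa[i], qb[i])
    qcost[i] <- bc$cost; qpos[i, ] <- bc$pos
  }
  alive <- rep(TRUE, nv)
  stamp <- integer(nv)
  qsa <- integer(length(qa)); qsb <- integer(length(qa))
  parent <- seq_len(nv)     # collapse map: b merged into a

  n_alive <- nv
  while (n_alive > target_vertices) {
    i <- which.min(qcost)
    if (!is.finite(qcost[i])) break
    a <- qa[i]; b <- qb[i]
    stale <- !alive[a] || !alive[b] || qsa[i] != stamp[a] || qsb[i] != stamp[b]
    qcost[i] <- Inf
    if (stale) next
    common <- intersect(nbr[[a]], nbr[[b]])
    if (length(common) != 2L) next       # link condition
    v[a, ] <- qpos[i, ]
    Q[a, ] <- Q[a, ] + Q[b, ]
    alive[b] <- FALSE
    parent[b] <- a
    nb <- setdiff(unique(c(nbr[[a]], nbr[[b]])), c(a, b))
    nbr[[a]] <- nb
    for (x in nb) {
      s <- setdiff(nbr[[x]], b)
      if (!(a %in% s)) s <- c(s, a)
      nbr[[x]] <- s
      stamp[x] <- stamp[x] + 1L
    }
    nbr[[b]] <- integer(0)
    stamp[a] <- stamp[a] + 1L
    n_alive <- n_alive - 1L
    m <- length(nb)
    if (m > 0L) {
      costs <- numeric(m); poss <- matrix(0, m, 3L)
      for (j in seq_len(m)) {
        bc <- best_collapse(a, nb[j])
        costs[j] <- bc$cost; poss[j, ] <- bc$pos
      }
      qa <- c(qa, rep(a, m)); qb <- c(qb, nb)
      qcost <- c(qcost, costs); qpos <- rbind(qpos, poss)
      qsa <- c(qsa, rep(stamp[a], m)); qsb <- c(qsb, stamp[nb])
    }
  }

  # resolve collapse chains with path compression
  root <- seq_len(nv)
  for (i in seq_len(nv)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    root[i] <- r
  }
  keep <- which(alive)
  newid <- integer(nv)
  newid[keep] <- seq_along(keep)
  f2 <- matrix(newid[root[tr]], ncol = 3L)
  degen <- f2[, 1L] == f2[, 2L] | f2[, 2L] == f2[, 3L] | f2[, 1L] == f2[, 3L]
  f2 <- f2[!degen, , drop = FALSE]
  tri_mesh(v[keep, , drop = FALSE], f2)
}
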