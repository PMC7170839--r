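# Incremental 3D convex hull (quickhull-style beneath-beyond) returning the
# hull as supporting halfspaces. Written in-package because no installed
# package offers a 3D hull; faces live in preallocated matrices with alive
# flags (no per-insertion list copying) so lesion-sized inputs (a few
# thousand candidate points) run in tens of milliseconds.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Drop points that are strictly inside the 2D convex hull of their z-slice:
# such points cannot be vertices of the 3D hull.
prefilter_slice_hulls <- function(P) {
  keep <- unlist(lapply(split(seq_len(nrow(P)), P[, 3]), function(idx) {
    if (length(idx) < 4L) return(idx)
    idx[grDevices::chull(P[idx, 1], P[idx, 2])]
  }))
  P[sort(keep), , drop = FALSE]
}

# P: n x 3 matrix of points. Returns list(normals = m x 3, offsets = m) with
# outward unit normals (x inside hull iff normals %*% x <= offsets + eps), or
# NULL when the points are degenerate (rank < 3).
convex_hull3 <- function(P) {
  P <- unique(prefilter_slice_hulls(P))
  n <- nrow(P)
  if (n < 4L) return(NULL)
  scale <- max(apply(P, 2, function(x) diff(range(x))), 1)
  eps <- 1e-9 * scale

  # initial tetrahedron from extremes
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (max(abs(P[i1, ] - P[i2, ])) < eps) return(NULL)
  ab <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
              rel[, 3] * ab[1] - rel[, 1] * ab[3],
              rel[, 1] * ab[2] - rel[, 2] * ab[1])
  d_line <- sqrt(rowSums(cr^2))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps) return(NULL)
  nrm <- cross3(ab, P[i3, ] - P[i1, ])
  d_plane <- rel %*% nrm
  i4 <- which.max(abs(d_plane))
  if (abs(d_plane[i4]) < eps * sqrt(sum(nrm^2))) return(NULL)
  interior <- colMeans(P[c(i1, i2, i3, i4), ])

  max_faces <- 8L * n + 64L
  FV <- matrix(NA_integer_, max_faces, 3)   # face vertex indices
  FN <- matrix(NA_real_, max_faces, 3)      # outward unit normals
  FD <- rep(NA_real_, max_faces)            # plane offsets
  alive <- logical(max_faces)
  outside <- vector("list", max_faces)      # conflict sets
  n_face <- 0L

  plane_of <- function(tri) {
    nn <- cross3(P[tri[2], ] - P[tri[1], ], P[tri[3], ] - P[tri[1], ])
    nl <- sqrt(sum(nn^2))
    if (nl < 1e-300) return(NULL)
    nn <- nn / nl
    dd <- sum(nn * P[tri[1], ])
    if (sum(nn * interior) > dd + 1e-300) { nn <- -nn; dd <- -dd }
    list(n = nn, d = dd)
  }
  add_face <- function(tri, pool) {
    pl <- plane_of(tri)
    if (is.null(pl)) return(invisible(NULL))
    n_face <<- n_face + 1L
    f <- n_face
    FV[f, ] <<- tri
    FN[f, ] <<- pl$n
    FD[f] <<- pl$d
    alive[f] <<- TRUE
    if (length(pool) > 0L) {
      h <- P[pool, , drop = FALSE] %*% pl$n - pl$d
      outside[[f]] <<- pool[h > eps]
    } else {
      outside[[f]] <<- integer(0)
    }
    invisible(NULL)
  }

  seed_pool <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  add_face(c(i1, i2, i3), seed_pool)
  add_face(c(i1, i2, i4), seed_pool)
  add_face(c(i1, i3, i4), seed_pool)
  add_face(c(i2, i3, i4), seed_pool)

  repeat {
    pending <- which(alive & lengths(outside) > 0L)
    if (length(pending) == 0L) break
    k <- pending[1]
    cand <- outside[[k]]
    h <- P[cand, , drop = FALSE] %*% FN[k, ] - FD[k]
    p_idx <- cand[which.max(h)]
    pt <- P[p_idx, ]
    act <- which(alive)
    vis <- act[(FN[act, , drop = FALSE] %*% pt - FD[act]) > eps]
    # horizon = edges appearing exactly once among visible faces
    tris <- FV[vis, , drop = FALSE]
    e1 <- rbind(tris[, c(1, 2), drop = FALSE],
                tris[, c(2, 3), drop = FALSE],
                tris[, c(1, 3), drop = FALSE])
    ek <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
    single <- ek %in% names(which(table(ek) == 1L))
    horizon <- e1[single, , drop = FALSE]
    pool <- setdiff(unique(unlist(outside[vis])), p_idx)
    alive[vis] <- FALSE
    outside[vis] <- list(integer(0))
    for (e in seq_len(nrow(horizon))) {
      add_face(c(horizon[e, 1], horizon[e, 2], p_idx), pool)
    }
  }
  keep <- which(alive)
  list(normals = FN[keep, , drop = FALSE], offsets = FD[keep])
}

# TRUE for each row of Q inside (or on) the hull.
points_in_hull <- function(hull, Q, eps = 1e-7) {
  inside <- rep(TRUE, nrow(Q))
  for (f in seq_along(hull$offsets)) {
    idx <- which(inside)
    if (length(idx) == 0L) break
    inside[idx] <- Q[idx, , drop = FALSE] %*% hull$normals[f, ] <=
      hull$offsets[f] + eps
  }
  inside
}

# Convex volume of a voxel mask: voxelization of the convex hull of the
# foreground voxel centers (count of grid voxel centers inside the hull times
# the voxel volume), the voxelized-convex-image convention, so a digital
# cube has solidity exactly 1. For
# rank-deficient (flat) masks the hull has no 3D volume; the mask volume is
# returned with a warning.
convex_volume_mask <- function(mask, spacing) {
  w <- which(mask, arr.ind = TRUE)
  vox_vol <- prod(spacing)
  bnd <- boundary_voxels(mask, w)   # boundary voxels suffice for the hull
  pts <- sweep(bnd, 2, spacing, `*`)
  hull <- convex_hull3(pts)
  if (is.null(hull)) {
    warn("Mask is flat (rank < 3); convex volume set to the mask volume.")
    return(nrow(w) * vox_vol)
  }
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  grid_phys <- sweep(grid, 2, spacing, `*`)
  sum(points_in_hull(hull, grid_phys)) * vox_vol
}

# Voxels of a mask with at least one of the 6 face-neighbours outside.
boundary_voxels <- function(mask, w = NULL) {
  if (is.null(w)) w <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  keep <- logical(nrow(w))
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  wp <- w + 1L
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(wp, 2, shifts[s, ], `+`)
    keep <- keep | !pad[nb]
  }
  w[keep, , drop = FALSE]
}
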