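# 3D convex hull of lattice points and lattice-point-in-hull counting.
#
# Solidity is defined as a ratio of lattice-point counts: voxels in the
# object over lattice points inside (or on) the convex hull of the object's
# voxel centers. The hull is built by incremental insertion (quickhull-style
# visibility/horizon updates); membership uses facet half-space tests with a
# small tolerance so boundary points count as inside, honouring the hull
# definition "the smallest region that is convex and contains the object".

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Keep, within every (y, x) column, only the voxels with extreme z. Every
# dropped voxel is a convex combination of the two kept endpoints of its
# column, so the convex hull is unchanged. Cuts hull-building cost sharply
# for filled objects.
.prune_z_extremes <- function(P) {
  key <- paste(P[, 2], P[, 3])
  ord <- order(key, P[, 1])
  Ps <- P[ord, , drop = FALSE]
  ks <- key[ord]
  first <- !duplicated(ks)
  last <- rev(!duplicated(rev(ks)))
  unique(Ps[first | last, , drop = FALSE])
}

# Numeric rank of the point set's affine span (0 = single point, 1 = line,
# 2 = plane, 3 = full 3D), with basis vectors of the span.
.affine_rank <- function(P) {
  ctr <- colMeans(P)
  M <- sweep(P, 2L, ctr)
  sv <- svd(M, nu = 0)
  tol <- max(dim(M)) * max(sv$d, 0) * 1e-10
  rank <- sum(sv$d > max(tol, 1e-12))
  list(rank = rank, center = ctr, basis = sv$v)
}

# Incremental 3D convex hull. P: m x 3 matrix of full-rank points (m >= 4).
# Returns unit outward facet normals (F x 3) and offsets d with the hull
# interior satisfying n . x <= d.
.hull3d_facets <- function(P) {
  m <- nrow(P)
  scale <- max(1, max(abs(P)))
  eps <- 1e-7 * scale

  # initial tetrahedron from axis extremes + farthest-point picks
  cand <- unique(c(apply(P, 2L, which.min), apply(P, 2L, which.max)))
  D2 <- as.matrix(stats::dist(P[cand, , drop = FALSE]))^2
  ij <- which(D2 == max(D2), arr.ind = TRUE)[1L, ]
  i1 <- cand[ij[1L]]; i2 <- cand[ij[2L]]
  a <- P[i1, ]; b <- P[i2, ]
  ab <- b - a
  rel <- sweep(P, 2L, a)
  tt <- as.vector(rel %*% ab) / sum(ab * ab)
  perp2 <- rowSums((rel - outer(tt, ab))^2)
  i3 <- which.max(perp2)
  n0 <- .cross3(ab, P[i3, ] - a)
  off <- abs(as.vector(rel %*% n0))
  i4 <- which.max(off)
  if (off[i4] <= eps * sqrt(sum(n0^2))) {
    stop("internal: hull3d called on a degenerate (non-3D) point set")
  }
  tet <- c(i1, i2, i3, i4)
  interior <- colMeans(P[tet, , drop = FALSE])

  maxf <- 8L * m + 16L
  Fidx <- matrix(0L, maxf, 3L)
  N <- matrix(0, maxf, 3L)
  Dv <- numeric(maxf)
  alive <- logical(maxf)
  nf <- 0L
  add_facet <- function(u, v, w) {
    nrm <- .cross3(P[v, ] - P[u, ], P[w, ] - P[u, ])
    nl <- sqrt(sum(nrm^2))
    if (nl <= 1e-14 * scale^2) return(invisible(NULL))
    nrm <- nrm / nl
    d <- sum(nrm * P[u, ])
    if (sum(nrm * interior) > d) { nrm <- -nrm; d <- -d }
    nf <<- nf + 1L
    if (nf > nrow(N)) stop("internal: hull facet storage exhausted")
    Fidx[nf, ] <<- c(u, v, w)
    N[nf, ] <<- nrm
    Dv[nf] <<- d
    alive[nf] <<- TRUE
    invisible(NULL)
  }
  combs <- utils::combn(4L, 3L)
  for (j in seq_len(ncol(combs))) {
    add_facet(tet[combs[1, j]], tet[combs[2, j]], tet[combs[3, j]])
  }

  # insert remaining points, farthest from the interior first
  rest <- setdiff(seq_len(m), tet)
  if (length(rest)) {
    ord <- rest[order(-rowSums(sweep(P[rest, , drop = FALSE], 2L, interior)^2))]
    for (p in ord) {
      idx_alive <- which(alive[seq_len(nf)])
      vis_val <- as.vector(N[idx_alive, , drop = FALSE] %*% P[p, ]) - Dv[idx_alive]
      vis <- idx_alive[vis_val > eps]
      if (!length(vis)) next
      # horizon = edges bounding the visible region exactly once
      e1 <- Fidx[vis, c(1L, 2L), drop = FALSE]
      e2 <- Fidx[vis, c(2L, 3L), drop = FALSE]
      e3 <- Fidx[vis, c(3L, 1L), drop = FALSE]
      E <- rbind(e1, e2, e3)
      Es <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
      ekey <- paste(Es[, 1], Es[, 2])
      once <- ekey %in% names(which(table(ekey) == 1L))
      horizon <- E[once, , drop = FALSE]
      alive[vis] <- FALSE
      for (h in seq_len(nrow(horizon))) {
        add_facet(horizon[h, 1L], horizon[h, 2L], p)
      }
    }
  }
  keep <- which(alive[seq_len(nf)])
  res <- list(normals = N[keep, , drop = FALSE], offsets = Dv[keep],
              vertices = sort(unique(as.vector(Fidx[keep, ]))))
  # closure sanity check: no input point may lie outside the final hull
  viol <- max(P %*% t(res$normals) -
                matrix(res$offsets, m, length(res$offsets), byrow = TRUE))
  if (viol > 1e-6 * scale) stop("internal: hull construction failed")
  res
}

# Count lattice points satisfying all half-space constraints, chunked to
# bound memory. Boundary tolerance per the package convention: 1e-9 on
# unit-normalized facet inequalities (boundary points are inside).
.count_lattice_halfspaces <- function(rng, normals, offsets, tol = 1e-9) {
  zs <- rng[1, 1]:rng[2, 1]
  ys <- rng[1, 2]:rng[2, 2]
  xs <- rng[1, 3]:rng[2, 3]
  total <- 0L
  plane <- as.matrix(expand.grid(z = zs, y = ys))
  for (x in xs) {
    C <- cbind(plane, x)
    M <- C %*% t(normals)
    ok <- rowSums(M > matrix(offsets + tol, nrow(C), length(offsets),
                             byrow = TRUE)) == 0L
    total <- total + sum(ok)
  }
  total
}

.count_lattice_segment <- function(P, tol = 1e-9) {
  ctr <- colMeans(P)
  M <- sweep(P, 2L, ctr)
  dvec <- svd(M, nu = 0)$v[, 1L]
  tvals <- as.vector(M %*% dvec)
  rng <- apply(P, 2L, range)
  cand <- as.matrix(expand.grid(z = rng[1, 1]:rng[2, 1],
                                y = rng[1, 2]:rng[2, 2],
                                x = rng[1, 3]:rng[2, 3]))
  rel <- sweep(cand, 2L, ctr)
  t2 <- as.vector(rel %*% dvec)
  perp <- rel - outer(t2, dvec)
  on_line <- sqrt(rowSums(perp^2)) <= 1e-7
  in_range <- t2 >= min(tvals) - tol & t2 <= max(tvals) + tol
  sum(on_line & in_range)
}

.count_lattice_planar <- function(P, basis, center, tol = 1e-9) {
  nrm <- basis[, 3L]
  u <- basis[, 1L]; v <- basis[, 2L]
  rng <- apply(P, 2L, range)
  cand <- as.matrix(expand.grid(z = rng[1, 1]:rng[2, 1],
                                y = rng[1, 2]:rng[2, 2],
                                x = rng[1, 3]:rng[2, 3]))
  rel <- sweep(cand, 2L, center)
  inplane <- abs(as.vector(rel %*% nrm)) <= 1e-7
  cand <- cand[inplane, , drop = FALSE]
  rel <- rel[inplane, , drop = FALSE]
  uv <- cbind(as.vector(rel %*% u), as.vector(rel %*% v))
  Prel <- sweep(P, 2L, center)
  Puv <- cbind(as.vector(Prel %*% u), as.vector(Prel %*% v))
  hullidx <- chull(Puv)
  H <- Puv[hullidx, , drop = FALSE]
  if (nrow(H) < 3L) {  # numerically collinear in-plane: fall back to segment
    return(.count_lattice_segment(P, tol))
  }
  ctr2 <- colMeans(H)
  inside <- rep(TRUE, nrow(uv))
  nh <- nrow(H)
  for (i in seq_len(nh)) {
    a <- H[i, ]; b <- H[if (i == nh) 1L else i + 1L, ]
    edge <- b - a
    nrm2 <- c(edge[2L], -edge[1L])
    nrm2 <- nrm2 / sqrt(sum(nrm2^2))
    d <- sum(nrm2 * a)
    if (sum(nrm2 * ctr2) > d) { nrm2 <- -nrm2; d <- -d }
    inside <- inside & (uv %*% nrm2 <= d + tol)
  }
  sum(inside)
}

.as_voxel_matrix <- function(cell_voxels) {
  if (is.data.frame(cell_voxels)) cell_voxels <- as.matrix(cell_voxels)
  if (!is.matrix(cell_voxels) || ncol(cell_voxels) != 3L) {
    stop("`cell_voxels` must be an n x 3 matrix of (z, y, x) voxel indices",
         call. = FALSE)
  }
  if (nrow(cell_voxels) < 1L) stop("cell has no voxels", call. = FALSE)
  storage.mode(cell_voxels) <- "double"
  if (anyNA(cell_voxels) || any(cell_voxels != round(cell_voxels))) {
    stop("voxel coordinates must be integral lattice points", call. = FALSE)
  }
  unique(cell_voxels)
}

#' Lattice-point count of a cell's convex hull
#'
#' Number of lattice points lying inside or on the convex hull of the cell's
#' voxel centers. Degenerate cells are handled by hulls in their affine span:
#' a single voxel counts 1, collinear cells count lattice points on the
#' segment, coplanar cells count lattice points in the 2D hull polygon.
#' Because lattice membership is preserved by axis-aligned translations,
#' permutations and reflections, the count (and hence solidity) does not
#' depend on the physical voxel spacing.
#'
#' @param cell_voxels n x 3 matrix of integer (z, y, x) voxel coordinates.
#' @param spacing A [voxel_spacing()]; accepted for interface symmetry, the
#'   lattice count is spacing-invariant.
#' @return Integer count, always >= the number of distinct voxels.
#' @examples
#' cube <- as.matrix(expand.grid(z = 1:5, y = 1:5, x = 1:5))
#' convex_voxel_count(cube, voxel_spacing(1, 1, 1))  # 125: its own hull
#' @export
convex_voxel_count <- function(cell_voxels, spacing = voxel_spacing(1, 1, 1)) {
  P <- .as_voxel_matrix(cell_voxels)
  if (nrow(P) == 1L) return(1L)
  ar <- .affine_rank(P)
  if (ar$rank == 0L) return(1L)
  if (ar$rank == 1L) return(as.integer(.count_lattice_segment(P)))
  if (ar$rank == 2L) {
    return(as.integer(.count_lattice_planar(P, ar$basis, ar$center)))
  }
  Pp <- .prune_z_extremes(P)
  hull <- .hull3d_facets(Pp)
  rng <- apply(P, 2L, range)
  as.integer(.count_lattice_halfspaces(rng, hull$normals, hull$offsets))
}

#' Tridimensional solidity of a cell
#'
#' Ratio of the cell's volume to its convex volume, both measured as lattice
#' counts: distinct voxels in the cell divided by lattice points inside its
#' convex hull. A digitally convex object (filled cuboid, digital ball)
#' scores exactly 1; ramified cells with thin processes score much lower
#' because the hull spans the processes' reach.
#'
#' @inheritParams convex_voxel_count
#' @return A value in (0, 1].
#' @examples
#' cub <- as.matrix(expand.grid(z = 1:11, y = 1:21, x = 1:21))
#' solidity(cub)  # exactly 1
#' @export
solidity <- function(cell_voxels, spacing = voxel_spacing(1, 1, 1)) {
  P <- .as_voxel_matrix(cell_voxels)
  nrow(P) / convex_voxel_count(P, spacing)
}
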