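# Independent brute-force oracles and small fixture builders. These
# deliberately recompute quantities by the most direct definition available
# (exhaustive enumeration, sliding windows, half-space tests over all point
# triples) and share no code path with the package implementation.

iso_spacing <- function() voxel_spacing(1, 1, 1)

make_stack <- function(arr, spacing = iso_spacing(), name = "fixture") {
  image_stack(arr, spacing, name = name)
}

make_mask <- function(arr, spacing = iso_spacing()) {
  binary_mask(arr, spacing)
}

# digital ball: lattice points within radius r of the origin
digital_ball <- function(r) {
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

filled_cuboid <- function(nz, ny, nx) {
  as.matrix(expand.grid(z = seq_len(nz), y = seq_len(ny), x = seq_len(nx)))
}

# random 26-connected lattice blob of about n voxels (full 3D rank w.h.p.)
random_blob <- function(n, seed) {
  set.seed(seed)
  steps <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  steps <- steps[rowSums(abs(steps)) > 0, ]
  pos <- c(0, 0, 0)
  pts <- matrix(pos, 1, 3)
  while (nrow(unique(pts)) < n) {
    pos <- pos + steps[sample(nrow(steps), 1), ]
    pts <- rbind(pts, pos)
  }
  P <- unique(pts)
  colnames(P) <- c("z", "y", "x")
  P
}

# Exhaustive hull-membership oracle: every triple of points defines a
# candidate plane; planes with all points on one side are facet half-spaces;
# a lattice point of the bounding box is inside iff it violates none.
oracle_hull_count <- function(P, tol = 1e-9) {
  P <- unique(P)
  n <- nrow(P)
  stopifnot(n >= 4)
  combs <- utils::combn(n, 3)
  normals <- matrix(0, 0, 3)
  offsets <- numeric(0)
  chunk <- 20000L
  for (s in seq(1L, ncol(combs), by = chunk)) {
    e <- min(ncol(combs), s + chunk - 1L)
    ii <- combs[1, s:e]; jj <- combs[2, s:e]; kk <- combs[3, s:e]
    u <- P[jj, , drop = FALSE] - P[ii, , drop = FALSE]
    v <- P[kk, , drop = FALSE] - P[ii, , drop = FALSE]
    nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
    len <- sqrt(rowSums(nrm^2))
    ok <- len > 1e-9
    nrm <- nrm[ok, , drop = FALSE] / len[ok]
    d0 <- rowSums(nrm * P[ii[ok], , drop = FALSE])
    S <- P %*% t(nrm)
    D <- matrix(d0, n, length(d0), byrow = TRUE)
    below <- colSums(S > D + 1e-7) == 0L
    above <- colSums(S < D - 1e-7) == 0L
    normals <- rbind(normals, nrm[below, , drop = FALSE],
                     -nrm[above, , drop = FALSE])
    offsets <- c(offsets, d0[below], -d0[above])
  }
  # deduplicate by rounded key but keep exact coefficients, and use a
  # boundary tolerance generous against floating-point plane error yet far
  # below the minimum separation of integer lattice points from any plane
  # through lattice points of this size
  keep <- !duplicated(round(cbind(normals, offsets), 7))
  normals <- normals[keep, , drop = FALSE]
  offsets <- offsets[keep]
  rng <- apply(P, 2, range)
  cand <- as.matrix(expand.grid(z = rng[1, 1]:rng[2, 1],
                                y = rng[1, 2]:rng[2, 2],
                                x = rng[1, 3]:rng[2, 3]))
  M <- cand %*% t(normals)
  inside <- rowSums(M > matrix(offsets + 1e-6, nrow(cand), length(offsets),
                               byrow = TRUE)) == 0L
  sum(inside)
}

# Direct two-pass Otsu scan: for every bin-edge cut compute class weights
# and means from the counts and maximize w0*w1*(mu0-mu1)^2.
oracle_otsu_threshold <- function(values, bins) {
  breaks <- seq(min(values), max(values), length.out = bins + 1)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- as.double(tabulate(idx, nbins = bins))
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts[(k + 1):bins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (is.na(best_k) || bcv > best) {
      best <- bcv
      best_k <- k
    }
  }
  breaks[best_k + 1]
}

# Exhaustive clipped-neighbourhood majority vote.
oracle_majority_filter <- function(v, r) {
  d <- dim(v)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- max(1, z - r):min(d[1], z + r)
    yy <- max(1, y - r):min(d[2], y + r)
    xx <- max(1, x - r):min(d[3], x + r)
    nb <- v[zz, yy, xx]
    out[z, y, x] <- 2 * sum(nb) > length(nb)
  }
  out
}

# Sliding min-then-max with a flat digital disk (clipped windows): the
# definition of grayscale opening.
oracle_opening_2d <- function(m, r) {
  offs <- as.matrix(expand.grid(-r:r, -r:r))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= r^2, , drop = FALSE]
  mm_filter <- function(img, f) {
    out <- img
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      keep <- ii >= 1 & ii <= nrow(img) & jj >= 1 & jj <= ncol(img)
      out[i, j] <- f(img[cbind(ii[keep], jj[keep])])
    }
    out
  }
  mm_filter(mm_filter(m, min), max)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no-ties case; the null U distribution is symmetric).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  uobs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mid <- na * length(b) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(us - mid) >= abs(uobs - mid) - 1e-9)
}

# Linear index helper for (z, y, x) arrays.
lin_index <- function(v, d) {
  v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1)
}

# Best IoU of each true cell against any measured label.
best_iou_per_cell <- function(truth, labels) {
  d <- dim(labels$labels)
  pos <- which(labels$labels > 0L)
  bylab <- split(pos, labels$labels[pos])
  vapply(truth$cells, function(ci) {
    ti <- lin_index(ci$voxels, d)
    if (!length(bylab)) return(0)
    max(vapply(bylab, function(li) {
      length(intersect(ti, li)) / length(union(ti, li))
    }, numeric(1)))
  }, numeric(1))
}

# Small test scene shared by segmentation tests: same lateral sampling class
# as the full-size default, scaled field.
test_scene <- function(seed, n_cells = 10, side = 256, field = 320) {
  scene_params(field_size_um = field, side_px = side, depth_um = 25,
               n_cells = n_cells, min_centroid_separation_um = 60,
               seed = seed)
}
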