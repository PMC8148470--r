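test_that("object detection follows 26-connectivity with deterministic labels", {
  v <- array(FALSE, c(10, 10, 20))
  v[2:4, 2:4, 2:4] <- TRUE
  v[2:4, 2:4, 10:12] <- TRUE
  lab <- detect_objects(make_mask(v))
  expect_equal(lab$n_labels, 2L)
  expect_equal(as.vector(table(lab$labels[lab$labels > 0])), c(27L, 27L))

  # corner-touching cubes join under 26-connectivity
  w <- array(FALSE, c(8, 8, 8))
  w[2:3, 2:3, 2:3] <- TRUE
  w[4:5, 4:5, 4:5] <- TRUE
  expect_equal(detect_objects(make_mask(w))$n_labels, 1L)

  expect_equal(detect_objects(make_mask(array(FALSE, c(3, 3, 3))))$n_labels, 0L)
})

test_that("size gate keeps only objects within [min, max]", {
  v <- array(FALSE, c(6, 40, 80))
  v[2, 2, 2:6] <- TRUE                      # 5 voxels
  v[2:6, 10:19, 10:19] <- TRUE              # 500 voxels
  v[1:6, 21:40, 21:70] <- TRUE              # 6000 voxels
  lab <- detect_objects(make_mask(v))
  expect_equal(lab$n_labels, 3L)
  out <- filter_by_size(lab, segmentation_params(min_object_voxels = 100,
                                                 max_object_voxels = 5000))
  expect_equal(out$n_labels, 1L)
  expect_equal(sum(out$labels > 0), 500L)
  # open gates: identity up to relabelling
  all_kept <- filter_by_size(lab, segmentation_params(min_object_voxels = 1,
                                                      max_object_voxels = 10^7))
  expect_identical(all_kept$labels, lab$labels)
})

test_that("bright-center detection finds one seed per soma", {
  sp <- voxel_spacing(1.25, 1.25, 2.5)
  sc <- scene_params(field_size_um = 120, side_px = 96, depth_um = 25,
                     n_cells = 1, min_centroid_separation_um = 10, seed = 3)
  gen <- generate_scene(sc, amoeboid_phenotype())
  res <- segment_stack(gen$stack)
  seeds <- res$seeds
  expect_equal(nrow(seeds$points), 1L)
  truec <- gen$truth$cells[[1]]$center_um
  got_um <- c((seeds$points[1, 2] - 1) * sp$dy, (seeds$points[1, 3] - 1) * sp$dx)
  expect_lt(sqrt(sum((got_um - truec[2:3])^2)), 2 * 1.25)  # within 2 px of soma

  # two somata 20 px apart -> two seeds at min distance 8
  v <- array(0, c(3, 48, 48))
  blob <- function(cy, cx) {
    for (y in -4:4) for (x in -4:4) {
      if (y^2 + x^2 <= 16) v[2, cy + y, cx + x] <<- 150 * exp(-(y^2 + x^2) / 12)
    }
  }
  blob(24, 14); blob(24, 34)
  st <- make_stack(round(v))
  lab <- detect_objects(binary_mask(st$voxels > 10, st$spacing))
  s2 <- detect_bright_centers(st, lab, segmentation_params(seed_min_distance_px = 8))
  expect_equal(nrow(s2$points), 2L)

  # uniform-intensity object still yields exactly one deterministic seed
  u <- array(0, c(3, 20, 20)); u[2, 5:15, 5:15] <- 50
  stu <- make_stack(u)
  labu <- detect_objects(binary_mask(stu$voxels > 0, stu$spacing))
  su <- detect_bright_centers(stu, labu, segmentation_params())
  expect_equal(nrow(su$points), 1L)
})

test_that("watershed splitting partitions a dumbbell at the bridge", {
  d <- c(11, 24, 44)
  v <- array(0, d)
  sphere <- function(cz, cy, cx, r, val) {
    for (z in -r:r) for (y in -r:r) for (x in -r:r) {
      if (z^2 + y^2 + x^2 <= r^2) {
        v[cz + z, cy + y, cx + x] <<-
          max(v[cz + z, cy + y, cx + x], val * exp(-(z^2 + y^2 + x^2) / (2 * (r / 1.5)^2)))
      }
    }
  }
  sphere(6, 12, 10, 5, 200)
  sphere(6, 12, 34, 5, 200)
  v[6:7, 12:13, 15:29] <- 40  # thin dim bridge
  st <- make_stack(round(v))
  mask <- binary_mask(st$voxels > 5, st$spacing)
  lab <- detect_objects(mask)
  expect_equal(lab$n_labels, 1L)
  seeds <- detect_bright_centers(st, lab, segmentation_params())
  expect_equal(nrow(seeds$points), 2L)
  split <- split_cells(lab, seeds, st)
  expect_equal(split$n_labels, 2L)
  counts <- as.vector(table(split$labels[split$labels > 0]))
  single <- sum(v[, , 1:22] > 5)  # one blob + half bridge
  expect_true(all(abs(counts - single) / single < 0.1))
  # partition property: labelled voxels conserved exactly
  expect_identical(split$labels > 0, lab$labels > 0)
})

test_that("single-seed objects pass through splitting unchanged", {
  v <- array(FALSE, c(5, 12, 12)); v[2:4, 3:9, 3:9] <- TRUE
  st <- make_stack(array(as.double(v) * 80, dim(v)))
  lab <- detect_objects(make_mask(v))
  seeds <- detect_bright_centers(st, lab, segmentation_params())
  out <- split_cells(lab, seeds, st)
  expect_identical(out$labels, lab$labels)
})

test_that("shape filter decisions match an independent recomputation", {
  sp <- voxel_spacing(1, 1, 1)
  v <- array(FALSE, c(46, 46, 46))
  v[2:10, 2:10, 2:10] <- TRUE                         # compact cube: keep
  v[20, 20, 2:42] <- TRUE                             # 1x1x40 fiber: elongation
  v[30:31, 30:31, 2:45] <- TRUE                       # thicker fiber
  v[40:44, 2:6, 40:44] <- TRUE                        # small cube: size gate
  v[12:14, 30:44, 30:44] <- TRUE                      # slab
  lab <- detect_objects(binary_mask(v, sp))
  expect_equal(lab$n_labels, 5L)
  params <- segmentation_params(min_cell_voxels = 200, max_cell_voxels = 20000,
                                max_elongation = 10, min_extent = 0.02)
  out <- filter_by_shape(lab, params)

  # independent recomputation of all three criteria per object
  keep_expected <- logical(5)
  for (l in 1:5) {
    pts <- arrayInd(which(lab$labels == l), dim(lab$labels))
    n <- nrow(pts)
    cv <- cov(pts) * (n - 1) / n + diag(3) / 12
    ev <- eigen(cv, only.values = TRUE)$values
    elong <- sqrt(max(ev) / min(ev))
    extent <- n / prod(apply(pts, 2, function(q) diff(range(q)) + 1))
    keep_expected[l] <- n >= 200 && n <= 20000 && elong <= 10 &&
      extent >= 0.02
  }
  expect_equal(out$n_labels, sum(keep_expected))
  # surviving voxels are exactly the union of kept objects
  expect_identical(out$labels > 0,
                   array(lab$labels %in% which(keep_expected), dim(lab$labels)))
  # spec examples: fiber removed, compact cube retained
  expect_false(any((out$labels > 0)[20, 20, ]))
  expect_true(all((out$labels > 0)[2:10, 2:10, 2:10]))
})

test_that("border flags mark exactly the volume-touching cells", {
  v <- array(FALSE, c(6, 12, 12))
  v[1:2, 1:3, 1:3] <- TRUE    # touches z = 1 and y/x = 1
  v[3:4, 6:8, 6:8] <- TRUE    # interior
  lab <- detect_objects(make_mask(v))
  fl <- flag_border_cells(lab)
  expect_equal(fl$border_touching, c(TRUE, FALSE))
  expect_equal(nrow(flag_border_cells(
    label_volume(array(0L, c(2, 2, 2)), iso_spacing()))), 0L)
})

test_that("the full chain is deterministic and monotone", {
  sc <- test_scene(5, n_cells = 4, side = 128, field = 160)
  gen <- generate_scene(sc, list(ramified_phenotype(), amoeboid_phenotype()))
  r1 <- segment_stack(gen$stack)
  r2 <- segment_stack(gen$stack)
  expect_identical(r1$labels$labels, r2$labels$labels)
  # monotonicity: every finally-labelled voxel was detected initially
  mask0 <- median_denoise(otsu_threshold(
    subtract_background(gen$stack, estimate_background(gen$stack)))$mask)
  expect_true(all(mask0$voxels[r1$labels$labels > 0]))
})
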