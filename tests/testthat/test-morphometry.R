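test_that("convex objects are their own hulls", {
  cube <- filled_cuboid(5, 5, 5)
  expect_identical(convex_voxel_count(cube), 125L)
  expect_equal(solidity(filled_cuboid(11, 21, 21)), 1)
  expect_equal(solidity(digital_ball(5)), 1)
  expect_identical(convex_voxel_count(matrix(c(3, 4, 5), 1)), 1L)
})

test_that("degenerate geometries use hulls in their affine span", {
  # collinear: lattice points on the segment
  expect_identical(convex_voxel_count(cbind(0, 0, c(0, 4))), 5L)
  expect_identical(convex_voxel_count(cbind(0:3, 0:3, 0:3)), 4L)
  # planar L-shape gains the lattice point (0,1,1) on the hull boundary
  L <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0), c(0, 2, 1), c(0, 2, 2))
  expect_identical(convex_voxel_count(L), 6L)
  expect_equal(solidity(L), 5 / 6)
})

test_that("hull counts equal the exhaustive half-space oracle", {
  # 3D axis cross: hull is the octahedron |z|+|y|+|x| <= 4
  arm <- -4:4
  cr <- unique(rbind(cbind(z = arm, y = 0, x = 0),
                     cbind(z = 0, y = arm, x = 0),
                     cbind(z = 0, y = 0, x = arm)))
  expect_identical(convex_voxel_count(cr), oracle_hull_count(cr))

  for (seed in 1:10) {
    P <- random_blob(sample(30:90, 1), seed = 100 + seed)
    expect_identical(convex_voxel_count(P), oracle_hull_count(P),
                     label = sprintf("blob seed %d", 100 + seed))
  }
})

test_that("solidity is invariant to translation, rotation, permutation, spacing", {
  set.seed(31)
  for (k in 1:20) {
    P <- random_blob(sample(25:70, 1), seed = 200 + k)
    s0 <- solidity(P)
    expect_equal(solidity(sweep(P, 2, c(7, -11, 23), `+`)), s0)
    expect_equal(solidity(P[, c(2, 3, 1)]), s0)          # axis permutation
    R <- P; R[, 2] <- -P[, 3]; R[, 3] <- P[, 2]          # 90-degree rotation
    expect_equal(solidity(R), s0)
    expect_equal(solidity(P, voxel_spacing(0.4, 1.3, 2.5)), s0)
  }
})

test_that("appending arms to a convex core strictly lowers solidity", {
  sp <- voxel_spacing(1.25, 1.25, 2.5)
  for (k in 1:20) {
    core <- cell_phenotype(soma_radius_um = 6, n_branches = 0, label = "core")
    ram <- cell_phenotype(soma_radius_um = 6,
                          n_branches = sample(3:7, 1),
                          branch_length_um = runif(1, 10, 22),
                          branch_width_um = 5,
                          branch_tortuosity = runif(1, 0, 0.5),
                          label = "ram")
    ctr <- c(11.25, 60, 60)
    s_core <- solidity(generate_cell_mask(core, sp, ctr, seed = 400 + k)$voxels, sp)
    s_ram <- solidity(generate_cell_mask(ram, sp, ctr, seed = 400 + k)$voxels, sp)
    expect_lt(s_ram, s_core)
  }
})

test_that("per-cell records satisfy their invariants on a synthetic stack", {
  sc <- test_scene(9, n_cells = 6, side = 192, field = 240)
  gen <- generate_scene(sc, list(ramified_phenotype(), amoeboid_phenotype()))
  res <- segment_stack(gen$stack)
  cells <- measure_cells(res$labels, res$labels$spacing,
                         lesion_id = "les1", eye_id = "eyeA")
  expect_equal(nrow(cells), res$labels$n_labels)
  expect_true(all(cells$voxel_count >= 1))
  expect_true(all(cells$voxel_count <= cells$convex_voxel_count))
  expect_true(all(cells$solidity > 0 & cells$solidity <= 1))
  expect_equal(cells$solidity, cells$voxel_count / cells$convex_voxel_count)
  sp <- res$labels$spacing
  expect_equal(cells$volume_um3, cells$voxel_count * sp$dx * sp$dy * sp$dz)
  expect_identical(cells$cell_id, seq_len(nrow(cells)))

  empty <- label_volume(array(0L, c(2, 4, 4)), iso_spacing())
  expect_equal(nrow(measure_cells(empty, iso_spacing())), 0L)
})

test_that("per-eye means pool cells and respect border exclusion", {
  cells <- data.frame(cell_id = 1:6,
                      lesion_id = rep(c("l1", "l2"), 3),
                      eye_id = c("A", "A", "A", "B", "B", "B"),
                      solidity = c(0.4, 0.6, 0.8, 0.2, 0.4, 0.9),
                      border_touching = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  eyes <- mean_solidity_per_eye(cells, exclude_border = FALSE)
  expect_equal(eyes$mean_solidity[eyes$eye_id == "A"], 0.6)
  expect_equal(eyes$mean_solidity[eyes$eye_id == "B"], 0.5)
  eyes2 <- mean_solidity_per_eye(cells, exclude_border = TRUE)
  expect_equal(eyes2$n_cells[eyes2$eye_id == "B"], 2L)
  expect_equal(eyes2$mean_solidity[eyes2$eye_id == "B"], 0.3)
  # an eye losing all its cells is reported missing, not NaN
  cells$border_touching <- cells$eye_id == "B"
  eyes3 <- mean_solidity_per_eye(cells, exclude_border = TRUE)
  expect_identical(eyes3$eye_id, "A")
  expect_false(anyNA(eyes3$mean_solidity))
})

test_that("lesion-mean aggregation differs from pooling when lesions are unbalanced", {
  cells <- data.frame(cell_id = 1:3, lesion_id = c("l1", "l1", "l2"),
                      eye_id = "A", solidity = c(0.2, 0.4, 0.9),
                      border_touching = FALSE)
  pool <- mean_solidity_per_eye(cells, exclude_border = FALSE)$mean_solidity
  les <- mean_solidity_per_eye(cells, exclude_border = FALSE,
                               aggregate = "lesion-mean")$mean_solidity
  expect_equal(pool, 0.5)
  expect_equal(les, mean(c(0.3, 0.9)))
})
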