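test_that("a branchless soma rasterizes as the exact digital ball", {
  sp <- voxel_spacing(1, 1, 1)
  ph <- cell_phenotype(soma_radius_um = 5, n_branches = 0)
  cm <- generate_cell_mask(ph, sp, center_um = c(10, 10, 10), seed = 1)
  # exhaustive enumeration: lattice points within 5 um of the center
  g <- as.matrix(expand.grid(z = 1:21, y = 1:21, x = 1:21))
  phys <- g - 1
  truth <- sum(rowSums(sweep(phys, 2, c(10, 10, 10))^2) <= 25)
  expect_identical(nrow(cm$voxels), as.integer(truth))
  expect_equal(solidity(cm$voxels, sp), 1)
})

test_that("branches lower solidity below the branchless value", {
  sp <- voxel_spacing(1.25, 1.25, 2.5)
  ph0 <- cell_phenotype(soma_radius_um = 6, n_branches = 0)
  ph6 <- cell_phenotype(soma_radius_um = 6, n_branches = 6,
                        branch_length_um = 15)
  ctr <- c(11.25, 50, 50)
  s0 <- solidity(generate_cell_mask(ph0, sp, ctr, seed = 2)$voxels, sp)
  s6 <- solidity(generate_cell_mask(ph6, sp, ctr, seed = 2)$voxels, sp)
  expect_lt(s6, s0)
})

test_that("generators are pure functions of their seed", {
  sp <- voxel_spacing(1.25, 1.25, 2.5)
  ph <- ramified_phenotype()
  a <- generate_cell_mask(ph, sp, c(10, 40, 40), seed = 9)
  b <- generate_cell_mask(ph, sp, c(10, 40, 40), seed = 9)
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$intensity, b$intensity)

  sc <- test_scene(4, n_cells = 3, side = 96, field = 120)
  sc$min_centroid_separation_um <- 30
  g1 <- generate_scene(sc, amoeboid_phenotype())
  g2 <- generate_scene(sc, amoeboid_phenotype())
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  # and the caller's RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_scene(sc, amoeboid_phenotype()))
  expect_identical(rnorm(1), before)
})

test_that("scenes honour separation, disjointness and noise-free composition", {
  sc <- test_scene(6, n_cells = 5, side = 160, field = 200)
  gen <- generate_scene(sc, list(ramified_phenotype(), amoeboid_phenotype()))
  centers <- t(sapply(gen$truth$cells, function(c) c$center_um))
  d <- as.matrix(dist(centers[, 2:3]))
  diag(d) <- Inf
  expect_true(all(d >= sc$min_centroid_separation_um))
  ids <- lapply(gen$truth$cells, function(c) lin_index(c$voxels, dim(gen$stack$voxels)))
  expect_equal(length(unlist(ids)), length(unique(unlist(ids))))  # disjoint

  sc0 <- sc
  sc0$noise_sd <- 0; sc0$background_offset <- 0; sc0$background_ramp <- 0
  g0 <- generate_scene(sc0, list(ramified_phenotype(), amoeboid_phenotype()))
  inside <- unique(unlist(lapply(g0$truth$cells, function(c)
    lin_index(c$voxels, dim(g0$stack$voxels)))))
  expect_true(all(g0$stack$voxels[-inside] == 0))
  expect_true(all(g0$stack$voxels[inside] > 0))

  # infeasible placement fails loudly
  cramped <- scene_params(field_size_um = 100, side_px = 64, n_cells = 12,
                          min_centroid_separation_um = 60, seed = 1)
  expect_error(generate_scene(cramped, amoeboid_phenotype()), "placement|field")
})

test_that("amoeboid-parameter cells beat matched ramified cells in true solidity", {
  sp <- voxel_spacing(1.25, 1.25, 2.5)
  for (k in 1:20) {
    soma <- runif(1, 5, 8)
    ram <- cell_phenotype(soma_radius_um = soma, n_branches = 6,
                          branch_length_um = 20, branch_width_um = 6,
                          label = "ram")
    amo <- cell_phenotype(soma_radius_um = soma, n_branches = 1,
                          branch_length_um = 5, branch_width_um = 5,
                          label = "amo")
    ctr <- c(11.25, 60, 60)
    expect_gt(solidity(generate_cell_mask(amo, sp, ctr, seed = 600 + k)$voxels, sp),
              solidity(generate_cell_mask(ram, sp, ctr, seed = 600 + k)$voxels, sp))
  }
})

test_that("flat-mount generator hits the requested stained fraction", {
  sc <- scene_params(side_px = 256, noise_sd = 0, seed = 5)
  fm <- generate_flatmount(sc, 0.25)
  expect_lt(abs(fm$true_fraction - 0.25), 0.005)
  got <- stained_area_fraction(fm$image, threshold = 100)$area_fraction
  expect_equal(got, fm$true_fraction)
  expect_equal(generate_flatmount(sc, 0)$true_fraction, 0)
  expect_identical(generate_flatmount(sc, 0.1)$image,
                   generate_flatmount(sc, 0.1)$image)
})

test_that("cohorts are written complete, reproducible, and well separated by arm", {
  dir <- withr::local_tempdir()
  sc <- test_scene(21, n_cells = 2, side = 96, field = 120)
  sc$min_centroid_separation_um <- 40
  coh <- generate_cohort(dir, n_eyes_per_group = 2, n_lesions_per_eye = 2,
                         scene = sc, seed = 21)
  expect_equal(nrow(coh$manifest), 8L)  # 2 groups x 2 eyes x 2 lesions
  expect_true(all(file.exists(coh$manifest$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  gt <- coh$ground_truth
  expect_equal(nrow(gt), 8L * 2L)
  margin <- aggregate(gt$true_solidity, list(gt$group), mean)
  expect_gt(margin$x[margin$Group.1 == "mimic-like"],
            margin$x[margin$Group.1 == "inhibitor-like"] + 0.2)
  # determinism of the whole cohort
  dir2 <- withr::local_tempdir()
  coh2 <- generate_cohort(dir2, n_eyes_per_group = 2, n_lesions_per_eye = 2,
                          scene = sc, seed = 21)
  expect_identical(unname(tools::md5sum(coh$manifest$path)),
                   unname(tools::md5sum(coh2$manifest$path)))
})
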