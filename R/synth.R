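# Synthetic Iba1-like fluorescence data with voxel-level ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# bright ellipsoidal somata with a smooth intensity peak, dimmer ramified
# processes drawn as random-walk tubes, a smooth additive background ramp,
# and Gaussian noise, sampled on an anisotropic voxel lattice (coarse
# z-step, as in confocal stacks of flat-mounted tissue).

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fixed seed-splitting rule so any sub-object of a cohort is reproducible
# from the single global seed. Kept below 2^31 - 1.
.derive_seed <- function(seed, k) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(k) * 7919) %% 2147483647
}

#' Cell phenotype parameters
#'
#' Morphological model of a microglia cell: an ellipsoidal soma (spherical
#' in physical um) with a bright intensity peak, and `n_branches` dimmer
#' random-walk processes of given length, width and waviness. Resting
#' (ramified) cells have many long processes; activated (amoeboid) cells
#' have none or short ones.
#'
#' Branch widths default to 5 um: narrower processes are not resolvable at
#' the coarse axial sampling the scene generator emulates and would vanish
#' under the pipeline's denoising, which would make the phenotypes
#' untestable rather than more realistic.
#'
#' @param soma_radius_um Soma radius (um).
#' @param n_branches Number of processes (>= 0).
#' @param branch_length_um,branch_width_um Process length and width (um).
#' @param branch_tortuosity Waviness in \[0, 1\]; 0 gives straight rays.
#' @param soma_peak_intensity,branch_intensity Fluorescence levels; the
#'   branch level may not exceed the soma peak (somata are the bright
#'   centers).
#' @param label Phenotype tag carried into ground truth.
#' @return An object of class `cell_phenotype`.
#' @export
cell_phenotype <- function(soma_radius_um = 6, n_branches = 5,
                           branch_length_um = 18, branch_width_um = 5,
                           branch_tortuosity = 0.3,
                           soma_peak_intensity = 200,
                           branch_intensity = 120,
                           label = "cell") {
  stopifnot(soma_radius_um > 0, n_branches >= 0, branch_length_um > 0,
            branch_width_um > 0, branch_tortuosity >= 0,
            branch_tortuosity <= 1, soma_peak_intensity > 0,
            branch_intensity > 0,
            branch_intensity <= soma_peak_intensity)
  structure(list(soma_radius_um = soma_radius_um,
                 n_branches = as.integer(n_branches),
                 branch_length_um = branch_length_um,
                 branch_width_um = branch_width_um,
                 branch_tortuosity = branch_tortuosity,
                 soma_peak_intensity = soma_peak_intensity,
                 branch_intensity = branch_intensity,
                 label = label),
            class = "cell_phenotype")
}

#' @rdname cell_phenotype
#' @export
ramified_phenotype <- function() {
  cell_phenotype(soma_radius_um = 6, n_branches = 6, branch_length_um = 20,
                 branch_width_um = 6, branch_tortuosity = 0.3,
                 label = "ramified")
}

#' @rdname cell_phenotype
#' @export
amoeboid_phenotype <- function() {
  cell_phenotype(soma_radius_um = 7.5, n_branches = 1, branch_length_um = 5,
                 branch_width_um = 5, branch_tortuosity = 0.3,
                 label = "amoeboid")
}

#' Scene parameters
#'
#' Acquisition geometry and nuisance structure of a synthetic field of view.
#' Defaults reproduce the acquisition the pipeline targets: a 780 um square
#' imaged at 20X (512 px across, so dx = dy = 780/512 um) with an axial
#' z-path of 2.5 um.
#'
#' @param field_size_um Side of the square field (um); default 780.
#' @param side_px Lateral pixels per side; dx = dy = field_size_um/side_px.
#' @param dz Axial step (um); default 2.5.
#' @param depth_um Axial extent (um); planes at 0, dz, ..., default 25.
#' @param n_cells Cells per scene.
#' @param min_centroid_separation_um Minimum pairwise xy distance between
#'   cell centers (um).
#' @param background_offset,background_ramp Additive background: constant
#'   offset plus a linear ramp of the given amplitude across the field.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_params` (includes derived `spacing`).
#' @export
scene_params <- function(field_size_um = 780, side_px = 512L, dz = 2.5,
                         depth_um = 25, n_cells = 10L,
                         min_centroid_separation_um = 60,
                         background_offset = 20, background_ramp = 15,
                         noise_sd = 8, seed = 1L) {
  stopifnot(field_size_um > 0, side_px >= 4, dz > 0, depth_um >= 0,
            n_cells >= 0, min_centroid_separation_um >= 0, noise_sd >= 0,
            background_offset >= 0, background_ramp >= 0)
  structure(list(field_size_um = field_size_um, side_px = as.integer(side_px),
                 dz = dz, depth_um = depth_um, n_cells = as.integer(n_cells),
                 min_centroid_separation_um = min_centroid_separation_um,
                 background_offset = background_offset,
                 background_ramp = background_ramp, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 spacing = voxel_spacing(field_size_um / side_px,
                                         field_size_um / side_px, dz)),
            class = "scene_params")
}

# Physical coordinate of voxel index i along an axis: (i - 1) * step.
.phys_to_idx <- function(p, step) p / step + 1

#' Generate one cell's voxel mask and intensities
#'
#' Rasterizes the soma (all lattice points within `soma_radius_um` of the
#' center, in physical um) and `n_branches` random-walk tubes emanating from
#' the soma. Branches walk within the cell's focal plane (flat-mounted cells
#' spread laterally), with per-step angular jitter set by the tortuosity.
#' The result is 26-connected by construction. Soma voxels carry a Gaussian
#' intensity peak; branch voxels carry the branch level.
#'
#' @param phenotype A [cell_phenotype()].
#' @param spacing A [voxel_spacing()].
#' @param center_um Cell center in physical (z, y, x) um.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param dim Optional (nz, ny, nx) bounds; out-of-volume voxels are
#'   dropped.
#' @return List with `voxels` (n x 3 integer (z, y, x) matrix), `intensity`
#'   (per voxel), `center_um`, and `phenotype`.
#' @export
generate_cell_mask <- function(phenotype, spacing, center_um = c(0, 0, 0),
                               seed = 1L, dim = NULL) {
  stopifnot(inherits(phenotype, "cell_phenotype"))
  spacing <- .check_spacing(spacing)
  .with_seed(seed, {
    steps <- c(spacing$dz, spacing$dy, spacing$dx)
    rs <- phenotype$soma_radius_um
    # soma: lattice points within rs of the center
    lo <- floor(.phys_to_idx(center_um - rs, steps))
    hi <- ceiling(.phys_to_idx(center_um + rs, steps))
    g <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                               x = lo[3]:hi[3]))
    phys <- sweep(sweep(g, 2L, c(1, 1, 1)), 2L, steps, `*`)
    d2 <- rowSums(sweep(phys, 2L, center_um)^2)
    soma <- g[d2 <= rs^2, , drop = FALSE]
    sigma <- rs / 1.5
    soma_int <- phenotype$branch_intensity +
      (phenotype$soma_peak_intensity - phenotype$branch_intensity) *
      exp(-d2[d2 <= rs^2] / (2 * sigma^2))
    pts <- soma
    ints <- soma_int
    # branches: planar random-walk tubes from the soma surface
    if (phenotype$n_branches > 0L) {
      wr <- phenotype$branch_width_um / 2
      step_um <- 1
      nsteps <- max(1L, ceiling(phenotype$branch_length_um / step_um))
      for (jb in seq_len(phenotype$n_branches)) {
        theta <- 2 * pi * (jb - 1) / phenotype$n_branches +
          runif(1, -0.4, 0.4)
        pos <- center_um + 0.8 * rs * c(0, sin(theta), cos(theta))
        samples <- matrix(0, nsteps + 1L, 3L)
        samples[1L, ] <- pos
        for (s in seq_len(nsteps)) {
          theta <- theta + rnorm(1, sd = phenotype$branch_tortuosity * 0.5)
          pos <- pos + step_um * c(0, sin(theta), cos(theta))
          samples[s + 1L, ] <- pos
        }
        for (s in seq_len(nrow(samples))) {
          p <- samples[s, ]
          blo <- floor(.phys_to_idx(p - wr, steps))
          bhi <- ceiling(.phys_to_idx(p + wr, steps))
          bg <- as.matrix(expand.grid(z = blo[1]:bhi[1], y = blo[2]:bhi[2],
                                      x = blo[3]:bhi[3]))
          bphys <- sweep(sweep(bg, 2L, c(1, 1, 1)), 2L, steps, `*`)
          bd2 <- rowSums(sweep(bphys, 2L, p)^2)
          inb <- bd2 <= wr^2
          if (any(inb)) {
            pts <- rbind(pts, bg[inb, , drop = FALSE])
            ints <- c(ints, rep(phenotype$branch_intensity, sum(inb)))
          }
        }
      }
    }
    # deduplicate, keeping the brightest assignment per voxel
    ord <- order(pts[, 1], pts[, 2], pts[, 3], -ints)
    pts <- pts[ord, , drop = FALSE]
    ints <- ints[ord]
    dup <- duplicated(pts)
    pts <- pts[!dup, , drop = FALSE]
    ints <- ints[!dup]
    if (!is.null(dim)) {
      inside <- pts[, 1] >= 1 & pts[, 1] <= dim[1] &
        pts[, 2] >= 1 & pts[, 2] <= dim[2] &
        pts[, 3] >= 1 & pts[, 3] <= dim[3]
      pts <- pts[inside, , drop = FALSE]
      ints <- ints[inside]
    }
    if (nrow(pts) == 0L) stop("phenotype parameters yield an empty mask",
                              call. = FALSE)
    storage.mode(pts) <- "integer"
    list(voxels = pts, intensity = ints, center_um = center_um,
         phenotype = phenotype)
  })
}

.place_centers <- function(scene, margin_um, seed) {
  .with_seed(seed, {
    lo <- margin_um
    hi <- scene$field_size_um - margin_um
    if (hi <= lo) stop("field too small for the requested cells", call. = FALSE)
    for (attempt in seq_len(20L)) {
      ys <- numeric(0); xs <- numeric(0)
      tries <- 0L
      while (length(ys) < scene$n_cells && tries < 5000L) {
        tries <- tries + 1L
        y <- runif(1, lo, hi); x <- runif(1, lo, hi)
        if (!length(ys) ||
            all((ys - y)^2 + (xs - x)^2 >=
                  scene$min_centroid_separation_um^2)) {
          ys <- c(ys, y); xs <- c(xs, x)
        }
      }
      if (length(ys) == scene$n_cells) return(cbind(y = ys, x = xs))
    }
    stop("cell placement failed: field cannot fit the requested cells at the given separation",
         call. = FALSE)
  })
}

#' Generate a synthetic confocal-like scene with ground truth
#'
#' Places `n_cells` cells at pairwise xy separation of at least
#' `min_centroid_separation_um` by rejection sampling, composes their
#' intensities over a linear background ramp, adds Gaussian noise (clipped
#' at zero) and rounds to integer gray levels. Cell centers sit midway
#' between the two central z-planes, as flat-mounted cells concentrate near
#' one focal depth. Identical seeds give bit-identical scenes.
#'
#' @param scene A [scene_params()].
#' @param phenotypes A single [cell_phenotype()] or list (recycled across
#'   cells).
#' @return List with `stack` (an [image_stack()]) and `truth`: per-cell true
#'   voxel sets, phenotype labels, true solidity (computed on the true
#'   masks), centers, and the seed used.
#' @export
generate_scene <- function(scene, phenotypes = cell_phenotype()) {
  stopifnot(inherits(scene, "scene_params"))
  if (inherits(phenotypes, "cell_phenotype")) phenotypes <- list(phenotypes)
  phenotypes <- rep(phenotypes, length.out = max(scene$n_cells, 1L))
  nz <- as.integer(round(scene$depth_um / scene$dz)) + 1L
  dims <- c(nz, scene$side_px, scene$side_px)
  sp <- scene$spacing
  margin <- if (scene$n_cells > 0L) {
    max(vapply(phenotypes, function(p) {
      p$soma_radius_um + p$branch_length_um + p$branch_width_um
    }, numeric(1)))
  } else 0
  zc <- (floor(nz / 2) - 0.5) * scene$dz  # midway between two planes
  centers <- if (scene$n_cells > 0L) {
    .place_centers(scene, margin, .derive_seed(scene$seed, 1L))
  } else matrix(0, 0, 2)
  # background ramp
  ramp_y <- if (dims[2] > 1) (seq_len(dims[2]) - 1) / (dims[2] - 1) else 0
  ramp_x <- if (dims[3] > 1) (seq_len(dims[3]) - 1) / (dims[3] - 1) else 0
  plane <- scene$background_offset +
    scene$background_ramp * outer(ramp_y, ramp_x, `+`) / 2
  vox <- aperm(array(plane, c(dims[2], dims[3], dims[1])), c(3L, 1L, 2L))
  cells <- vector("list", scene$n_cells)
  for (i in seq_len(scene$n_cells)) {
    cm <- generate_cell_mask(phenotypes[[i]], sp,
                             center_um = c(zc, centers[i, 1], centers[i, 2]),
                             seed = .derive_seed(scene$seed, 100L + i),
                             dim = dims)
    idx <- cm$voxels[, 1] + dims[1] * (cm$voxels[, 2] - 1L) +
      dims[1] * dims[2] * (cm$voxels[, 3] - 1L)
    vox[idx] <- pmax(vox[idx], cm$intensity)
    cells[[i]] <- list(voxels = cm$voxels,
                       phenotype = phenotypes[[i]]$label,
                       params = phenotypes[[i]],
                       true_solidity = solidity(cm$voxels, sp),
                       center_um = cm$center_um)
  }
  if (scene$noise_sd > 0) {
    noise <- .with_seed(.derive_seed(scene$seed, 2L),
                        rnorm(length(vox), sd = scene$noise_sd))
    vox <- vox + noise
  }
  vox <- round(pmax(vox, 0))
  list(stack = image_stack(vox, sp, name = sprintf("scene_seed%d", scene$seed)),
       truth = list(cells = cells, spacing = sp, seed = scene$seed))
}

#' Generate a flat-mount-like 2D image with a known stained fraction
#'
#' A bright disk-shaped "lesion" over a noisy background. The disk radius is
#' chosen so the disk covers as close as possible to the requested pixel
#' fraction; the realized fraction is recorded as ground truth.
#'
#' @param scene A [scene_params()] (supplies side_px, background and noise).
#' @param lesion_fraction Requested stained pixel fraction in \[0, 1\].
#' @param seed Integer seed (defaults to the scene's).
#' @param lesion_intensity Gray level of the lesion (default 200).
#' @return List with `image` (2D matrix), `true_fraction` (realized),
#'   `requested_fraction`, and `seed`.
#' @export
generate_flatmount <- function(scene, lesion_fraction, seed = scene$seed,
                               lesion_intensity = 200) {
  stopifnot(inherits(scene, "scene_params"),
            lesion_fraction >= 0, lesion_fraction <= 1)
  n <- scene$side_px
  img <- .with_seed(.derive_seed(seed, 3L), {
    m <- matrix(scene$background_offset, n, n)
    if (scene$noise_sd > 0) m <- m + rnorm(n * n, sd = scene$noise_sd)
    m
  })
  lesion <- matrix(FALSE, n, n)
  target <- round(lesion_fraction * n * n)
  if (target > 0) {
    ctr <- (n + 1) / 2
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
    r2 <- sort(d2)[target]
    lesion <- d2 <= r2
  }
  img[lesion] <- lesion_intensity
  img <- round(pmax(img, 0))
  list(image = img, true_fraction = mean(lesion),
       requested_fraction = lesion_fraction, seed = seed)
}

#' Generate a reproducible two-arm cohort of synthetic stacks
#'
#' Writes one multi-page TIFF per lesion image, `n_eyes_per_group` eyes and
#' `n_lesions_per_eye` lesion images per eye and per group, together with a
#' `manifest.csv` (image_id, eye_id, lesion_id, group, path) consumable by
#' the pipeline commands and a `ground_truth.csv` of true per-cell
#' solidities. Per-cell phenotypes are jittered around each group's base
#' phenotype (branch count +/- 1, lengths and soma radius within +/- 20% and
#' +/- 10%) so that solidity varies within arms. All randomness derives from
#' the single seed by a fixed splitting rule.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_eyes_per_group,n_lesions_per_eye Cohort layout.
#' @param group_phenotypes Named list mapping group name to its base
#'   [cell_phenotype()].
#' @param scene A [scene_params()] shared by all images.
#' @param seed Integer master seed (defaults to the scene's).
#' @return Invisibly, a list with `manifest` and `ground_truth` data.frames
#'   and the paths written.
#' @export
generate_cohort <- function(out_dir, n_eyes_per_group = 5L,
                            n_lesions_per_eye = 4L,
                            group_phenotypes = list(
                              "inhibitor-like" = ramified_phenotype(),
                              "mimic-like" = amoeboid_phenotype()),
                            scene = scene_params(),
                            seed = scene$seed) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("input error: cannot create directory '%s'", out_dir),
                  call. = FALSE)
  }
  stopifnot(length(names(group_phenotypes)) == length(group_phenotypes))
  manifest <- list()
  truth <- list()
  k <- 0L
  for (g in seq_along(group_phenotypes)) {
    gname <- names(group_phenotypes)[g]
    base <- group_phenotypes[[g]]
    for (e in seq_len(n_eyes_per_group)) {
      eye_id <- sprintf("%s_eye%02d", gname, e)
      for (l in seq_len(n_lesions_per_eye)) {
        k <- k + 1L
        image_id <- sprintf("%s_lesion%02d", eye_id, l)
        phen <- .with_seed(.derive_seed(seed, 500000L + k), {
          lapply(seq_len(scene$n_cells), function(i) {
            cell_phenotype(
              soma_radius_um = base$soma_radius_um * runif(1, 0.9, 1.1),
              n_branches = max(0L, base$n_branches + sample(-1L:1L, 1)),
              branch_length_um = base$branch_length_um * runif(1, 0.8, 1.2),
              branch_width_um = base$branch_width_um,
              branch_tortuosity = base$branch_tortuosity,
              soma_peak_intensity = base$soma_peak_intensity,
              branch_intensity = base$branch_intensity,
              label = base$label)
          })
        })
        sc <- scene
        sc$seed <- as.integer(.derive_seed(seed, k) %% 2147483647)
        gen <- generate_scene(sc, phen)
        path <- file.path(out_dir, paste0(image_id, ".tif"))
        write_stack(gen$stack, path)
        manifest[[k]] <- data.frame(image_id = image_id, eye_id = eye_id,
                                    lesion_id = sprintf("lesion%02d", l),
                                    group = gname, path = path,
                                    dx_um = scene$spacing$dx,
                                    dz_um = scene$dz,
                                    stringsAsFactors = FALSE)
        truth[[k]] <- do.call(rbind, lapply(seq_along(gen$truth$cells),
                                            function(i) {
          ci <- gen$truth$cells[[i]]
          ctr <- colMeans(ci$voxels)
          data.frame(image_id = image_id, eye_id = eye_id,
                     lesion_id = sprintf("lesion%02d", l), group = gname,
                     cell_id = i, phenotype = ci$phenotype,
                     true_solidity = ci$true_solidity,
                     voxel_count = nrow(ci$voxels),
                     centroid_z = ctr[1], centroid_y = ctr[2],
                     centroid_x = ctr[3], stringsAsFactors = FALSE)
        }))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, ground_truth = truth, dir = out_dir,
                 seed = seed))
}
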