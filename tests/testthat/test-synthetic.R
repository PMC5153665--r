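test_that("phantom_spec validates geometry and contrast invariants", {
  expect_error(phantom_spec(grid_shape = c(0, 4, 4)), "positive")
  expect_error(phantom_spec(voxel_size = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(label_mean = 120, background_mean = 100,
                            background_sd = 10), "4\\*background_sd")
  sp <- phantom_preset("neurite-sbem")
  expect_equal(sp$voxel_size, c(25, 10.5, 10.5))
  expect_equal(phantom_preset("fibsem")$voxel_size, c(10, 10, 10))
})

test_that("mitochondria phantom: catalogue, disjointness, determinism", {
  sp <- small_mito_phantom(seed = 1)
  ph <- sp$phantom
  cat_mito <- subset(ph$truth$catalogue, class == "mitochondria")
  expect_equal(nrow(cat_mito), 5L)
  # catalogue count equals connected-object count of the class mask
  for (cl in names(ph$truth$masks)) {
    lab <- connected_components(ph$truth$masks[[cl]] > 0L, 26L)
    expect_equal(lab$n_objects,
                 sum(ph$truth$catalogue$class == cl))
    # distinct objects are voxel-disjoint by construction of the label
    # array; check ids match the catalogue
    expect_equal(sort(unique(as.integer(ph$truth$masks[[cl]][
      ph$truth$masks[[cl]] > 0L]))),
      subset(ph$truth$catalogue, class == cl)$id)
  }
  # masks of different classes never overlap
  expect_equal(max((ph$truth$masks$mitochondria > 0L) +
                   (ph$truth$masks$speckle > 0L) +
                   (ph$truth$masks$membrane_fragment > 0L)), 1L)

  # identical seed => bit-identical phantom
  ph2 <- small_mito_phantom(seed = 1)$phantom
  expect_identical(ph$volume$values, ph2$volume$values)
  expect_identical(ph$truth$masks, ph2$truth$masks)
})

test_that("labelled voxel intensities match the clamped Gaussian model", {
  sp <- small_mito_phantom(seed = 2)
  spec <- sp$spec
  ph <- sp$phantom
  mask <- truth_mask(ph$truth, "mitochondria")
  n <- sum(mask)
  mu <- mean(ph$volume$values[mask])
  # sample mean within 3 sd / sqrt(N) of the label mean (clamping at
  # -2 sd shifts the mean by only ~0.0085 sd)
  expect_lt(abs(mu - spec$label_mean), 3 * spec$label_sd / sqrt(n) + 0.1)
})

test_that("the separating range splits label from background by construction", {
  sp <- small_mito_phantom(seed = 3)
  ph <- sp$phantom
  rng <- separating_range(sp$spec)
  lab_mask <- truth_mask(ph$truth, "mitochondria") |
    truth_mask(ph$truth, "speckle")
  in_range <- ph$volume$values >= rng$lo & ph$volume$values <= rng$hi
  expect_gte(mean(in_range[lab_mask]), 0.99)
  bg <- !(lab_mask | truth_mask(ph$truth, "membrane_fragment"))
  expect_lte(mean(in_range[bg]), 0.001)
})

test_that("every speckle is below 10 voxels; mitochondria stay above the
           cutoff even after 3x3x1 binning", {
  # SBEM preset with default semi-axes: the paper's regime
  spec <- phantom_spec(grid_shape = c(64L, 256L, 256L), rng_seed = 6)
  ph <- make_mitochondria_phantom(spec, n_objects = 6, n_speckle = 25,
                                  n_membrane_fragments = 0)
  spk <- subset(ph$truth$catalogue, class == "speckle")
  expect_true(all(spk$n_voxels < 10))
  mito <- subset(ph$truth$catalogue, class == "mitochondria")
  binned_voxel <- prod(spec$voxel_size * c(1, 3, 3)) / 1e9
  expect_true(all(mito$n_voxels * voxel_volume_um3(spec$voxel_size) /
                    binned_voxel >= 10))
})

test_that("placement failure raises a class-named error; bad counts error", {
  spec <- phantom_preset("fibsem", grid_shape = c(16L, 16L, 16L),
                         rng_seed = 1)
  expect_error(
    make_mitochondria_phantom(spec, n_objects = 80,
                              semi_axis_range = c(40, 60), n_speckle = 0,
                              n_membrane_fragments = 0, max_attempts = 25),
    "mitochondria")
  expect_error(make_mitochondria_phantom(spec, n_objects = 0), "positive")
  expect_error(make_mitochondria_phantom(spec, n_objects = 2,
                                         n_speckle = -1), "non-negative")
})

test_that("background texture: identity at amplitude 0, reproducible,
           raises variance of a constant field", {
  g <- volume_grid(array(100, c(16, 16, 16)), voxel_size = c(10, 10, 10))
  t0 <- add_background_texture(g, amplitude = 0, rng_seed = 9)
  expect_identical(t0$values, g$values)
  t1 <- add_background_texture(g, granularity_nm = 30, amplitude = 10,
                               rng_seed = 9)
  t2 <- add_background_texture(g, granularity_nm = 30, amplitude = 10,
                               rng_seed = 9)
  expect_identical(t1$values, t2$values)
  expect_gt(var(as.numeric(t1$values)), 0)
  expect_gte(min(t1$values), 0)
  expect_lte(max(t1$values), 255)
})

test_that("neurite phantom: zero-depth tree is a single soma object", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(48L, 64L, 64L),
                         rng_seed = 5)
  ph <- make_neurite_phantom(spec, tree = list(depth = 0L,
                                               soma_radius_nm = 250))
  expect_equal(names(ph$truth$masks), "cell_1")
  lab <- connected_components(truth_mask(ph$truth, "cell_1"), 26L)
  expect_equal(lab$n_objects, 1L)
})

test_that("without drop-off, seeded growth at the separating range recovers
           the whole cell exactly", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(64L, 128L, 128L),
                         rng_seed = 7)
  ph <- make_neurite_phantom(spec, dropoff = 0)
  seed <- round(ph$soma_centre_nm / spec$voxel_size + 0.5)
  t1 <- grow_from_seed(ph$volume, seed, separating_range(spec))
  expect_identical(t1$roi, truth_mask(ph$truth, "cell_1"))
})

test_that("with drop-off at branch points, growth at the undropped range
           stops at the first branch point", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(64L, 128L, 128L),
                         rng_seed = 8)
  ph <- make_neurite_phantom(spec, tree = list(depth = 3L), dropoff = 0.3)
  seed <- round(ph$soma_centre_nm / spec$voxel_size + 0.5)
  t1 <- grow_from_seed(ph$volume, seed, separating_range(spec))
  truth <- truth_mask(ph$truth, "cell_1")
  expect_true(all(!t1$roi | truth))        # roi strictly inside the cell
  expect_lt(sum(t1$roi), sum(truth))       # distal branches excluded
  # the recovered region is the soma plus the primary (generation-0)
  # neurite: it must be much more than the bare soma
  soma_vox <- 4 / 3 * pi * 400^3 / prod(spec$voxel_size)
  expect_gt(sum(t1$roi), soma_vox)
})

test_that("crossover cells touch the primary cell and keep per-cell masks
           connected and disjoint", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(64L, 144L, 144L),
                         rng_seed = 9)
  ph <- make_neurite_phantom(spec, n_crossover_cells = 2)
  expect_setequal(names(ph$truth$masks), c("cell_1", "cell_2", "cell_3"))
  overlap <- (ph$truth$masks$cell_1 > 0L) + (ph$truth$masks$cell_2 > 0L) +
    (ph$truth$masks$cell_3 > 0L)
  expect_lte(max(overlap), 1L)
  for (cl in names(ph$truth$masks))
    expect_equal(connected_components(ph$truth$masks[[cl]] > 0L,
                                      26L)$n_objects, 1L)
  # all cells fall in one 26-connected component at the separating range
  m <- threshold_range(ph$volume, separating_range(spec))
  cc <- connected_components(m, 26L)
  seeds_lab <- vapply(names(ph$truth$masks), function(cl) {
    idx <- which(ph$truth$masks[[cl]] > 0L)[1]
    cc$labels[idx]
  }, 1L)
  expect_equal(length(unique(seeds_lab)), 1L)
})
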