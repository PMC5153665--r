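test_that("seeded growth on a constant volume fills the whole grid", {
  g <- tiny_volume(array(100, c(6, 6, 6)))
  t1 <- grow_from_seed(g, c(3, 3, 3), intensity_range(90, 110))
  expect_true(all(t1$roi))
  expect_equal(t1$voxel_count, 216L)
  expect_equal(t1$volume_um3, 216 * 1e3 / 1e9)
})

test_that("seed errors: outside the grid, intensity outside the range", {
  g <- tiny_volume(array(100, c(6, 6, 6)))
  expect_error(grow_from_seed(g, c(7, 1, 1), intensity_range(0, 255)),
               "outside the grid")
  expect_error(grow_from_seed(g, c(1, 1, 1), intensity_range(150, 255)),
               "seed intensity 100")
})

test_that("seeded growth equals threshold -> components -> seed component", {
  set.seed(21)
  for (i in 1:30) {
    g <- tiny_volume(array(sample(0:255, 8^3, TRUE), c(8, 8, 8)))
    lo <- sample(0:200, 1); hi <- lo + sample(20:55, 1)
    in_range <- which(g$values >= lo & g$values <= hi)
    if (!length(in_range)) next
    seed <- arrayInd(sample(in_range, 1), dim(g$values))[1, ]
    for (conn in c(6L, 18L, 26L)) {
      roi <- grow_from_seed(g, seed, intensity_range(lo, hi), conn)$roi
      lab <- connected_components(threshold_range(g, intensity_range(lo, hi)),
                                  conn)
      want <- lab$labels == lab$labels[seed[1], seed[2], seed[3]]
      expect_identical(roi, want)
    }
  }
})

test_that("a one-trial series equals a single seeded growth; step
           arithmetic follows the true-range width", {
  g <- tiny_volume(array(100, c(6, 6, 6)))
  g$values[1, 1, 1] <- 0; g$values[6, 6, 6] <- 255   # true range width 255
  ser <- trial_series_spec(hi = 255, lo_start = 90, step_fraction = 0.004,
                           n_trials = 1)
  tr <- run_trial_series(g, c(3, 3, 3), ser)
  expect_length(tr, 1L)
  expect_identical(tr[[1]]$roi,
                   grow_from_seed(g, c(3, 3, 3),
                                  intensity_range(90, 255))$roi)
  # 0.4% of a width-255 true range is 1.02 intensity units per step
  expect_equal(attr(tr, "step"), 1.02)
  ser2 <- trial_series_spec(hi = 255, lo_start = 90, step_fraction = 0.004,
                            n_trials = 4)
  tr2 <- run_trial_series(g, c(3, 3, 3), ser2)
  expect_equal(attr(tr2, "growth")$lo, 90 - 1.02 * (0:3))
})

test_that("trial series: nested ROIs and non-decreasing voxel counts", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(48L, 96L, 96L),
                         rng_seed = 31)
  ph <- make_neurite_phantom(spec, tree = list(depth = 2L), dropoff = 0.05)
  seed <- round(ph$soma_centre_nm / spec$voxel_size + 0.5)
  sep <- separating_range(spec)
  tr <- run_trial_series(ph$volume, seed,
                         trial_series_spec(hi = sep$hi, lo_start = sep$lo,
                                           step_fraction = 0.004,
                                           n_trials = 10))
  counts <- attr(tr, "growth")$voxels
  expect_true(all(diff(counts) >= 0))
  for (k in 2:length(tr))
    expect_true(all(tr[[k]]$roi[tr[[k - 1]]$roi]))
})

test_that("a trial whose range excludes the seed is recorded, not fatal", {
  g <- tiny_volume(array(100, c(4, 4, 4)))
  g$values[1, 1, 1] <- 0; g$values[4, 4, 4] <- 255
  # lo_start above the seed value: trial 1 errors, later trials include it
  ser <- trial_series_spec(hi = 255, lo_start = 120, step_fraction = 0.05,
                           n_trials = 3)
  tr <- run_trial_series(g, c(2, 2, 2), ser)
  expect_false(is.null(tr[[1]]$error))
  expect_equal(tr[[1]]$voxel_count, 0L)
  expect_null(tr[[3]]$error)     # lo = 120 - 2*12.75 = 94.5 <= 100
  expect_gt(tr[[3]]$voxel_count, 0L)
})

test_that("multi-seed tracing: disjoint components get distinct ids, seeds
           in one component merge with a logged merge", {
  v <- array(0, c(8, 4, 4))
  v[1:2, , ] <- 200
  v[6:8, , ] <- 200
  g <- tiny_volume(v)
  rng <- intensity_range(150, 255)
  out <- multi_seed_trace(g, list(c(1, 1, 1), c(7, 1, 1)), rng)
  expect_equal(out$n_objects, 2L)
  expect_equal(nrow(attr(out, "merges")), 0L)

  out2 <- multi_seed_trace(g, list(c(1, 1, 1), c(2, 4, 4), c(7, 1, 1)), rng)
  expect_equal(out2$n_objects, 2L)
  expect_equal(attr(out2, "seed_object"), c(1L, 1L, 2L))
  expect_equal(attr(out2, "merges")$seed, 2L)
  # only seeded components are labelled
  expect_equal(sort(unique(as.integer(out2$labels))), 0:2)
  expect_error(multi_seed_trace(g, list(c(1, 1, 1), c(1, 1, 1)), rng),
               "distinct")
})

test_that("multi-seed traces of touching labelled cells reproduce the
           union of the per-cell truth masks", {
  spec <- phantom_preset("neurite-sbem", grid_shape = c(64L, 144L, 144L),
                         rng_seed = 33)
  ph <- make_neurite_phantom(spec, n_crossover_cells = 4, dropoff = 0)
  seeds <- lapply(names(ph$truth$masks), function(cl) {
    arrayInd(which(ph$truth$masks[[cl]] > 0L)[1], dim(ph$volume$values))[1, ]
  })
  out <- multi_seed_trace(ph$volume, seeds, separating_range(spec))
  union_truth <- Reduce(`|`, lapply(names(ph$truth$masks), truth_mask,
                                    truth = ph$truth))
  expect_identical(out$labels > 0L, union_truth)
})
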