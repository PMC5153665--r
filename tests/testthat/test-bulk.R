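test_that("range thresholding uses inclusive bounds", {
  v <- array(5, c(2, 2, 2))
  v[1, 1, 1] <- 10; v[2, 1, 1] <- 15; v[1, 2, 1] <- 20
  g <- tiny_volume(v)
  m <- threshold_range(g, intensity_range(10, 15))
  expect_equal(which(m), c(1L, 2L))      # exactly the 10 and 15 voxels
  expect_true(all(threshold_range(g, true_range(g))))
  expect_error(threshold_range(g, intensity_range(0, 300)), "domain")
})

test_that("connected components: hand-checked cases", {
  m <- mask_at(c(3, 3, 3), rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(connected_components(m, 26L)$n_objects, 1L)
  expect_equal(connected_components(m, 6L)$n_objects, 2L)
  expect_equal(connected_components(m, 18L)$n_objects, 2L)
  # edge-adjacency joins under 18 but not 6
  m2 <- mask_at(c(3, 3, 3), rbind(c(1, 1, 1), c(2, 2, 1)))
  expect_equal(connected_components(m2, 6L)$n_objects, 2L)
  expect_equal(connected_components(m2, 18L)$n_objects, 1L)

  expect_equal(connected_components(array(FALSE, c(3, 3, 3)))$n_objects, 0L)
  all3 <- connected_components(array(TRUE, c(3, 3, 3)))
  expect_equal(all3$n_objects, 1L)
  expect_equal(sum(all3$labels == 1L), 27L)
})

test_that("connected components agree with the brute-force BFS oracle", {
  set.seed(101)
  for (i in 1:300) {
    m <- array(runif(27) < 0.5, c(3, 3, 3))
    for (conn in c(6L, 18L, 26L)) {
      ours <- connected_components(m, conn)
      oracle <- bfs_label_oracle(m, conn)
      expect_identical(ours$labels,
                       array(as.integer(oracle), dim(oracle)))
      expect_identical(ours$n_objects, attr(oracle, "n_objects"))
    }
  }
})

test_that("partition property: every thresholded voxel gets exactly one id", {
  set.seed(12)
  g <- tiny_volume(array(sample(0:255, 8^3, TRUE), c(8, 8, 8)))
  m <- threshold_range(g, intensity_range(100, 200))
  lab <- connected_components(m, 26L)
  expect_identical(lab$labels > 0L, m)
  expect_equal(sort(unique(as.integer(lab$labels[m]))),
               seq_len(lab$n_objects))
})

test_that("widening the range never shrinks the thresholded voxel set", {
  set.seed(13)
  g <- tiny_volume(array(sample(0:255, 8^3, TRUE), c(8, 8, 8)))
  prev <- 0L
  for (lo in c(200, 150, 100, 50, 0)) {
    n <- sum(threshold_range(g, intensity_range(lo, 255)))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("minimum-size filter: strict cutoff, physical criterion,
           idempotence", {
  # three objects of sizes 3, 10, 250 along separated z-bands
  v <- array(0, c(30, 8, 8))
  v[1:3, 1, 1] <- 200                               # 3 voxels
  v[6:10, 1:2, 1] <- 200                            # 10 voxels
  v[13:22, 1:5, 1:5] <- 200                         # 250 voxels
  g <- volume_grid(v, voxel_size = c(50, 18.9, 18.9))
  lab <- connected_components(threshold_range(g, intensity_range(150, 255)),
                              26L, voxel_size = g$voxel_size)
  expect_equal(lab$n_objects, 3L)
  st <- filter_min_size(lab, min_voxels = 10)
  sizes <- tabulate(st$labels$labels[st$labels$labels > 0L])
  expect_setequal(sizes, c(10L, 250L))    # "< 10" removed, 10 kept

  # physical cutoff at the binned SBEM voxel: 0.0002 um^3 ~ 11.2 voxels,
  # so objects of <= 11 voxels go
  st2 <- filter_min_size(lab, min_voxels = NULL, min_volume_um3 = 2e-4)
  sizes2 <- tabulate(st2$labels$labels[st2$labels$labels > 0L])
  expect_equal(sizes2, 250L)
  expect_equal(sort(filter_log_table(st2$log)$object_id), c(1L, 2L))

  # idempotence
  st3 <- filter_min_size(st$labels, min_voxels = 10)
  expect_identical(st3$labels$labels, st$labels$labels)

  # empty input, empty log
  empty <- connected_components(array(FALSE, c(2, 2, 2)), 26L,
                                voxel_size = c(10, 10, 10))
  st4 <- filter_min_size(empty, min_voxels = 10)
  expect_equal(st4$labels$n_objects, 0L)
  expect_equal(nrow(filter_log_table(st4$log)), 0L)
  expect_error(filter_min_size(lab, NULL, NULL), "at least one")
})

test_that("intensity-variance filter removes bimodal objects and keeps
           constant ones; population variance is used", {
  v <- array(0, c(12, 4, 4))
  v[1:4, 1, 1] <- 128                       # constant object: variance 0
  v[7:11, 1:2, 1] <- rep(c(0, 255), each = 5)  # 10 voxels, half 0 half 255
  g <- tiny_volume(v)
  mask <- array(FALSE, c(12, 4, 4))
  mask[1:4, 1, 1] <- TRUE
  mask[7:11, 1:2, 1] <- TRUE                # mask includes the 0 voxels
  lab <- connected_components(mask, 26L)
  expect_equal(lab$n_objects, 2L)
  # direct population-variance check on the bimodal object
  feats <- compute_features(lab, g)
  expect_equal(max(feats$intensity_var), 16256.25)
  st <- filter_intensity_variance(lab, g, max_variance = 1000)
  expect_equal(st$labels$n_objects, 1L)
  expect_equal(unique(g$values[st$labels$labels == 1L]), 128)
  # kept for any threshold >= 0 when constant
  st2 <- filter_intensity_variance(st$labels, g, max_variance = 0)
  expect_equal(st2$labels$n_objects, 1L)
  # idempotence
  st3 <- filter_intensity_variance(st$labels, g, max_variance = 1000)
  expect_identical(st3$labels$labels, st$labels$labels)
})

test_that("single-voxel objects have variance zero and survive the
           variance filter", {
  v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 200
  g <- tiny_volume(v)
  lab <- connected_components(v > 0, 26L)
  st <- filter_intensity_variance(lab, g, max_variance = 0)
  expect_equal(st$labels$n_objects, 1L)
})

test_that("bulk_segment composes threshold, components and both filters in
           order and recovers exactly the phantom mitochondria", {
  sp <- small_mito_phantom(seed = 7)
  ph <- sp$phantom
  rng <- separating_range(sp$spec)
  seg <- bulk_segment(ph$volume, rng, min_voxels = 10,
                      max_variance = (4 * sp$spec$label_sd)^2)
  expect_equal(seg$labels$n_objects, 5L)
  rep <- evaluate_against_truth(seg$labels, ph$truth, "mitochondria", 0.5)
  expect_equal(rep$object_precision, 1)
  expect_equal(rep$object_recall, 1)
  # log records the full parameter set and the removed distractors
  expect_equal(seg$log$header$min_voxels, 10)
  tab <- filter_log_table(seg$log)
  expect_equal(sum(tab$filter == "min_size"), 10L)          # speckles
  expect_equal(sum(tab$filter == "intensity_variance"), 3L) # fragments

  # a range covering nothing
  seg0 <- bulk_segment(ph$volume, intensity_range(0, 0))
  expect_equal(seg0$labels$n_objects, 0L)

  # filters disabled: raw component count
  seg_raw <- bulk_segment(ph$volume, rng, min_voxels = NULL,
                          min_volume_um3 = NULL, max_variance = NULL)
  raw <- connected_components(threshold_range(ph$volume, rng), 26L)
  expect_equal(seg_raw$labels$n_objects, raw$n_objects)
})
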