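test_that("planted nuclei are recovered with accurate centroids", {
  scene <- generate_nucleus_scene(scene_params(n_nuclei = 3, markers = c()),
                                  seed = 2)
  nuclei <- segment_nuclei(scene$channels$DAPI)
  expect_length(nuclei, 3)
  truth <- as.matrix(scene$truth$nuclei[, c("z_nm", "y_nm", "x_nm")])
  for (nuc in nuclei) {
    d <- sqrt(colSums((t(truth) - nuc$centroid)^2))
    expect_lt(min(d), 200)
  }
  # sorted by volume, descending
  vols <- vapply(nuclei, `[[`, numeric(1), "volume")
  expect_true(all(diff(vols) <= 0))
})

test_that("an all-zero stack yields no nuclei", {
  empty <- image_stack(array(0, c(6, 16, 16)), c(125, 40, 40))
  expect_identical(segment_nuclei(empty), list())
})

test_that("sub-minimum speckles are dropped", {
  v <- array(0, c(16, 48, 48))
  v[6:11, 10:25, 10:25] <- 100     # nucleus-sized block
  v[8, 40, 40] <- 100              # single-voxel speckle
  s <- image_stack(v, c(125, 40, 40), "DAPI")
  nuclei <- segment_nuclei(s, d = 0)
  expect_length(nuclei, 1)
  expect_equal(length(nuclei[[1]]$voxels), 6 * 16 * 16)
})

test_that("nucleus count is exact over repeated default 5-nucleus scenes", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    scene <- generate_nucleus_scene(scene_params(n_nuclei = 5, markers = c()),
                                    seed = 1000 + s)
    nuclei <- segment_nuclei(scene$channels$DAPI)
    if (length(nuclei) == 5) hits <- hits + 1
  }
  expect_equal(hits, n_seeds)  # recall and precision both 100%
})

test_that("objects group to nuclei by edge-to-edge physical distance", {
  dims <- c(20, 60, 60)
  vs <- c(125, 40, 40)
  v <- array(0, dims); v[8:12, 20:35, 20:35] <- 100
  nuclei <- segment_nuclei(image_stack(v, vs, "DAPI"), d = 0, min_volume = 0)
  lab <- array(0L, dims)
  lab[10, 28, 39:40] <- 1L  # 160-200 nm from the mask edge
  lab[10, 28, 48:49] <- 2L  # > 500 nm away
  lab[10, 28, 30] <- 3L     # inside the mask
  grouped <- group_channels(nuclei, list(GFP = lab), max_dist = 200)
  members <- grouped[[1]]$members$GFP
  expect_setequal(vapply(members, `[[`, numeric(1), "object"), c(1, 3))
  expect_equal(members[[which(vapply(members, `[[`, numeric(1),
                                     "object") == 3)]]$distance, 0)
  expect_length(grouped[[1]]$unassigned, 1)
  expect_equal(grouped[[1]]$unassigned[[1]]$object, 2)
})

test_that("objects within range of two nuclei go to both, flagged ambiguous", {
  dims <- c(12, 40, 80)
  vs <- c(125, 40, 40)
  v <- array(0, dims)
  v[4:8, 10:30, 10:30] <- 100
  v[4:8, 10:30, 48:68] <- 100
  nuclei <- segment_nuclei(image_stack(v, vs, "DAPI"), d = 0, min_volume = 0)
  expect_length(nuclei, 2)
  lab <- array(0L, dims)
  lab[6, 20, 38:40] <- 1L  # between the two nuclei
  grouped <- group_channels(nuclei, list(GFP = lab), max_dist = 400)
  expect_length(grouped[[1]]$members$GFP, 1)
  expect_length(grouped[[2]]$members$GFP, 1)
  expect_true(grouped[[1]]$members$GFP[[1]]$ambiguous)
  expect_true(grouped[[2]]$members$GFP[[1]]$ambiguous)
})

test_that("per-nucleus masks stay within the global above-threshold region", {
  scene <- generate_nucleus_scene(scene_params(n_nuclei = 2, markers = c()),
                                  seed = 5)
  dapi <- scene$channels$DAPI
  nuclei <- segment_nuclei(dapi)
  thr <- flexible_threshold(dapi, analysis_config()$threshold_d)
  global <- sum(threshold_mask(dapi, thr))
  expect_lte(sum(vapply(nuclei, function(n) length(n$voxels), numeric(1))),
             global)
})

test_that("crops restore the original voxels when re-embedded", {
  scene <- generate_nucleus_scene(scene_params(markers = c()), seed = 3)
  dapi <- scene$channels$DAPI
  nuclei <- segment_nuclei(dapi)
  crop <- crop_nucleus(list(DAPI = dapi), nuclei[[1]], margin = 120)
  lo <- crop$offset
  hi <- lo + dim(crop$channels$DAPI$voxels) - 1L
  expect_identical(crop$channels$DAPI$voxels,
                   dapi$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                               drop = FALSE])
  # margin 0 gives exactly the mask bounding box
  crop0 <- crop_nucleus(list(DAPI = dapi), nuclei[[1]], margin = 0)
  zyx <- knobtools:::linear_to_zyx(nuclei[[1]]$voxels, nuclei[[1]]$dims)
  expect_equal(unname(crop0$bbox["lo", ]), unname(apply(zyx, 2, min)))
  expect_equal(unname(crop0$bbox["hi", ]), unname(apply(zyx, 2, max)))
})

test_that("crops of different nuclei hold disjoint masks", {
  scene <- generate_nucleus_scene(scene_params(n_nuclei = 2, markers = c()),
                                  seed = 7)
  dapi <- scene$channels$DAPI
  nuclei <- segment_nuclei(dapi)
  crops <- lapply(nuclei, function(n)
    crop_nucleus(list(DAPI = dapi), n, margin = 0))
  # map each crop mask back to global linear indices
  to_global <- function(crop, nuc) {
    zyx <- which(crop$mask, arr.ind = TRUE)
    zyx <- sweep(zyx, 2, crop$offset - 1L, `+`)
    zyx[, 1] + (zyx[, 2] - 1) * nuc$dims[1] +
      (zyx[, 3] - 1) * nuc$dims[1] * nuc$dims[2]
  }
  g1 <- to_global(crops[[1]], nuclei[[1]])
  g2 <- to_global(crops[[2]], nuclei[[2]])
  expect_length(intersect(g1, g2), 0)
})
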