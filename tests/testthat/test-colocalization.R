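test_that("normalization follows the max3 formula", {
  n0 <- normalize_image(c(0, 5, 10, 10, 10), t = 0)
  expect_equal(as.numeric(n0$values), c(0, 0.5, 1, 1, 1))
  expect_equal(n0$max3, 10)
  n5 <- normalize_image(c(0, 5, 10, 10, 10), t = 5)
  expect_equal(as.numeric(n5$values), c(0, 0, 1, 1, 1))
  # averaging the top three lets the single brightest voxel exceed 1
  ntop <- normalize_image(c(8, 10, 12), t = 0)
  expect_equal(ntop$max3, 10)
  expect_equal(max(ntop$values), 1.2)
  expect_error(normalize_image(c(1, 2, 3), t = 5), "degenerate")
})

test_that("max3 is taken over the nucleus object when a mask is given", {
  v <- array(c(100, rep(1, 7)), c(2, 2, 2))  # bright voxel outside the mask
  mask <- array(c(FALSE, rep(TRUE, 7)), c(2, 2, 2))
  n <- normalize_image(v, t = 0, object_mask = mask)
  expect_equal(n$max3, 1)
})

test_that("identical images give overlap exactly 1", {
  cs <- make_cropped_scene(seed = 1)
  b <- cs$crop$channels$DAPI
  for (mode in c("thresholded", "unthresholded")) {
    ov <- overlap(b, b, mode = mode, object_mask = cs$crop$mask)
    expect_equal(ov$n, 1)
  }
})

test_that("disjoint supports give overlap near 0", {
  g <- c(5, 8, 10, 0, 0, 0, rep(0, 6))
  b <- c(0, 0, 0, 9, 10, 7, rep(0, 6))
  ov <- overlap(g, b, mode = "unthresholded")
  expect_lte(ov$n, 0.005)
})

test_that("the 4-voxel toy matches the direct padded-formula oracle", {
  g <- c(1, 1, 0, 0)
  b <- c(1, 0, 1, 0)
  ov <- overlap(g, b, mode = "unthresholded", padding_factor = 250)
  oracle <- overlap_padded_oracle(g / 1, b / 1, 250)  # max3 = 2/3 cancels
  # normalization scales both images; the statistic is scale-free, so the
  # oracle on raw arrays applies
  expect_equal(ov$n, oracle, tolerance = 1e-12)
})

test_that("closed-form padded moments equal the materialized computation", {
  set.seed(31)
  g <- runif(40); b <- runif(40)
  gn <- normalize_image(g)$values
  bn <- normalize_image(b)$values
  ov <- overlap(g, b, mode = "unthresholded", padding_factor = 250)
  expect_equal(ov$n, overlap_padded_oracle(gn, bn, 250), tolerance = 1e-12)
})

test_that("overlap is scale-invariant and symmetric", {
  cs <- make_cropped_scene(seed = 4,
                           params = scene_params(markers = c(M = 0.6)))
  g <- cs$crop$channels$M
  b <- cs$crop$channels$DAPI
  ov <- overlap(g, b, object_mask = cs$crop$mask)
  g3 <- g; g3$voxels <- g$voxels * 3.7
  ov_scaled <- overlap(g3, b, object_mask = cs$crop$mask)
  expect_equal(ov_scaled$n, ov$n, tolerance = 1e-9)
  ov_swap <- overlap(b, g, object_mask = cs$crop$mask)
  expect_equal(ov_swap$n, ov$n, tolerance = 1e-9)
})

test_that("overlap decays as a focus is moved off its reference", {
  dims <- c(8, 24, 24)
  base <- array(0, dims); base[4, 12, 8] <- 100
  vs <- c(125, 40, 40)
  b <- gaussian_blur(base, c(150, 80, 80), vs)
  ns <- numeric(0)
  for (shift in 0:8) {  # 40 nm steps in x
    g0 <- array(0, dims); g0[4, 12, 8 + shift] <- 100
    g <- gaussian_blur(g0, c(150, 80, 80), vs)
    ns <- c(ns, overlap(g, b, mode = "unthresholded")$n)
  }
  expect_true(all(diff(ns) <= 1e-9))
  expect_equal(ns[1], 1)
})

test_that("overlap tables order markers by colocalization weight", {
  scene <- generate_nucleus_scene(
    scene_params(n_nuclei = 2, markers = c(hi = 0.9, lo = 0.3)), seed = 8)
  nuclei <- segment_nuclei(scene$channels$DAPI)
  tab <- overlap_table(scene$channels, nuclei)
  for (mode in c("thresholded", "unthresholded")) {
    sub <- tab[tab$mode == mode, ]
    expect_gt(sub$mean_n[sub$marker == "hi"], sub$mean_n[sub$marker == "lo"])
  }
  # weak-background effect: unthresholded differences are smaller
  d_thr <- diff(rev(tab$mean_n[tab$mode == "thresholded"]))
  d_unt <- diff(rev(tab$mean_n[tab$mode == "unthresholded"]))
  expect_lt(abs(d_unt), abs(d_thr))
})

test_that("a single nucleus reports s.d. 0 with a flag, DAPI overlap 1", {
  scene <- generate_nucleus_scene(scene_params(markers = c(M = 0.5)), seed = 9)
  nuclei <- segment_nuclei(scene$channels$DAPI)[1]
  stacks <- scene$channels
  stacks$DAPI2 <- stacks$DAPI
  tab <- overlap_table(stacks, nuclei, markers = c("M", "DAPI2"))
  expect_true(all(tab$single_nucleus))
  expect_true(all(tab$sd_n == 0))
  expect_equal(tab$mean_n[tab$marker == "DAPI2"], c(1, 1))
})
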