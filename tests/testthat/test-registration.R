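test_that("identity transform reproduces the input exactly", {
  s <- make_smooth_stack(seed = 1)
  out <- apply_transform(s, transform_params())
  expect_identical(out$voxels, s$voxels)
})

test_that("whole-voxel translation shifts the lattice by one index", {
  s <- make_smooth_stack(seed = 2)
  out <- apply_transform(s, transform_params(tx = s$voxel_size[3]))
  d <- dim(s$voxels)
  expect_equal(out$voxels[, , 1:(d[3] - 1)], s$voxels[, , 2:d[3]])
})

test_that("applying a transform then its analytic inverse restores the image", {
  s <- make_smooth_stack(seed = 3)
  p <- transform_params(tz = 60, ty = -35, tx = 45, theta_z = 0.4,
                        mz = 1.002, my = 0.999, mx = 1.001)
  fwd <- apply_transform(s, p)
  back <- apply_inverse_transform(fwd, invert_transform(p, s))
  interior <- abs(back$voxels - s$voxels)[4:13, 6:27, 6:27]
  expect_lt(mean(interior), 0.01 * diff(range(s$voxels)))
})

test_that("transforms that keep mass in frame preserve total intensity", {
  s <- make_smooth_stack(seed = 4)
  p <- transform_params(tz = 30, ty = 20, tx = -25, theta_z = 0.3)
  out <- apply_transform(s, p)
  expect_lt(abs(sum(out$voxels) - sum(s$voxels)) / sum(s$voxels), 0.02)
})

test_that("non-positive magnifications are rejected", {
  expect_error(transform_params(mx = 0), "> 0")
  expect_error(transform_params(mz = -1), "> 0")
})

test_that("transform parameters round-trip through JSON", {
  p <- transform_params(tz = 1.25, ty = -3, tx = 0.5, theta_z = 0.21,
                        mz = 1.0021, my = 0.9987, mx = 1.0004)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(p, f)
  expect_equal(read_transform(f), p)
})

test_that("estimating against itself returns the identity", {
  bf <- generate_bead_field(transform_params(), n_beads = 50, seed = 21,
                            shape = c(16, 64, 64))
  est <- estimate_transform(bf$reference, bf$reference)
  expect_lt(max(abs(c(est$tz, est$ty, est$tx))), 5)
  expect_lt(abs(est$theta_z), 0.02)
  expect_lt(max(abs(c(est$mz, est$my, est$mx) - 1)), 5e-4)
  expect_gte(attr(est, "correlation"), 0.999)
})

test_that("a pure translation is recovered within a quarter voxel", {
  p <- transform_params(tz = 125, ty = -80, tx = 120)
  bf <- generate_bead_field(p, n_beads = 60, seed = 22, shape = c(16, 64, 64))
  est <- estimate_transform(bf$reference, bf$moving)
  expect_lt(abs(est$tz - 125), 0.25 * 125)
  expect_lt(abs(est$ty + 80), 0.25 * 40)
  expect_lt(abs(est$tx - 120), 0.25 * 40)
})

test_that("pull-back of a transformed stack recovers the parameters", {
  # apply_transform(A, p) is the mis-registered observation of A, so the
  # estimate with reference = transformed, moving = original returns p
  s <- make_smooth_stack(seed = 6, shape = c(16, 48, 48))
  p <- transform_params(tz = 50, ty = -45, tx = 70)
  obs <- apply_transform(s, p)
  est <- estimate_transform(obs, s)
  expect_lt(abs(est$tz - p$tz), 0.25 * 125)
  expect_lt(abs(est$ty - p$ty), 0.25 * 40)
  expect_lt(abs(est$tx - p$tx), 0.25 * 40)
})

test_that("correlation at the estimate is at least that of the initial guess", {
  p <- transform_params(ty = 55, tx = -45)
  bf <- generate_bead_field(p, n_beads = 50, seed = 23, shape = c(16, 64, 64))
  est <- estimate_transform(bf$reference, bf$moving)
  cor_init <- knobtools:::transform_correlation(bf$reference, bf$moving,
                                                transform_params())
  expect_gte(attr(est, "correlation"), cor_init)
})

test_that("translation refinement re-optimizes only the translations", {
  s <- make_smooth_stack(seed = 8, shape = c(20, 64, 64), n_blobs = 8)
  calib <- transform_params(tz = 40, ty = 30, tx = -25, theta_z = 0.2,
                            mz = 1.001, my = 0.999, mx = 1.002)
  total <- calib
  total$tz <- calib$tz + 250  # extra sample-dependent z shift
  mov <- apply_inverse_transform(s, invert_transform(total, s))
  ref <- refine_translation(s, mov, calib)
  expect_identical(c(ref$theta_z, ref$mz, ref$my, ref$mx),
                   c(calib$theta_z, calib$mz, calib$my, calib$mx))
  expect_lt(abs((ref$tz - calib$tz) - 250), 0.25 * 125)
})

test_that("aligned inputs leave the calibration translations unchanged", {
  s <- make_smooth_stack(seed = 9, shape = c(16, 48, 48), n_blobs = 6)
  calib <- transform_params(ty = 40, tx = -40)
  mov <- apply_inverse_transform(s, invert_transform(calib, s))
  ref <- refine_translation(s, mov, calib)
  expect_lt(abs(ref$ty - calib$ty), 10)
  expect_lt(abs(ref$tx - calib$tx), 10)
})

test_that("degenerate registration inputs are rejected", {
  flat <- image_stack(array(1, c(8, 16, 16)), c(125, 40, 40))
  s <- make_smooth_stack(seed = 10, shape = c(8, 16, 16))
  expect_error(estimate_transform(flat, s), "flat image")
  small <- make_smooth_stack(seed = 10, shape = c(8, 16, 17))
  expect_error(estimate_transform(s, small), "grid shape")
  far <- transform_params(tx = 1e4)
  expect_error(estimate_transform(s, s, initial = far), "outside search bounds")
})
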