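test_that("scene generation is a pure function of parameters and seed", {
  a <- generate_nucleus_scene(scene_params(), seed = 4)
  b <- generate_nucleus_scene(scene_params(), seed = 4)
  expect_identical(a$channels$DAPI$voxels, b$channels$DAPI$voxels)
  expect_identical(a$channels$GFP$voxels, b$channels$GFP$voxels)
  expect_identical(a$truth$knobs, b$truth$knobs)
  c <- generate_nucleus_scene(scene_params(), seed = 5)
  expect_false(identical(a$channels$DAPI$voxels, c$channels$DAPI$voxels))
})

test_that("the generator does not disturb the caller's random stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_nucleus_scene(scene_params(), seed = 3))
  expect_identical(runif(1), before)
})

test_that("ground truth lists exactly the requested knobs", {
  scene <- generate_nucleus_scene(scene_params(knob_count = 2, markers = c()),
                                  seed = 6)
  expect_equal(nrow(scene$truth$knobs), 2)
  none <- generate_nucleus_scene(scene_params(knob_count = 0, markers = c()),
                                 seed = 6)
  expect_null(none$truth$knobs)
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(markers = c(M = 1.2)), "\\[0, 1\\]")
  expect_error(scene_params(nucleus_diameter_nm = -5))
  expect_error(scene_params(knob_count = -1))
})

test_that("planted knobs stay brighter than the nuclear median after blur", {
  for (s in 11:16) {
    scene <- generate_nucleus_scene(scene_params(markers = c()), seed = s)
    dapi <- scene$channels$DAPI$voxels
    vs <- scene$truth$voxel_size
    kc <- unlist(scene$truth$knobs[1, c("z_nm", "y_nm", "x_nm")])
    nc <- unlist(scene$truth$nuclei[1, c("z_nm", "y_nm", "x_nm")])
    kreg <- knobtools:::dist2_to_point(dim(dapi), vs, kc) <=
      scene$truth$knobs$radius_nm[1]^2
    nreg <- knobtools:::dist2_to_point(dim(dapi), vs, nc) <=
      scene$truth$nuclei$radius_nm[1]^2
    expect_gt(mean(dapi[kreg]), median(dapi[nreg]))
  }
})

test_that("a fully colocalized noise-free marker overlaps DAPI at >= 0.99", {
  scene <- generate_nucleus_scene(
    scene_params(markers = c(M = 1), noise_gain = 0, noise_read_sd = 0),
    seed = 3)
  nuclei <- segment_nuclei(scene$channels$DAPI)
  crop <- crop_nucleus(scene$channels, nuclei[[1]], margin = 200)
  ov <- overlap(crop$channels$M, crop$channels$DAPI,
                mode = "thresholded", object_mask = crop$mask)
  expect_gte(ov$n, 0.99)
})

test_that("bead fields: identity transform and zero noise give equal stacks", {
  bf <- generate_bead_field(transform_params(), n_beads = 20, seed = 9,
                            shape = c(12, 48, 48))
  expect_identical(bf$reference$voxels, bf$moving$voxels)
  bf2 <- generate_bead_field(transform_params(), n_beads = 20, seed = 9,
                             shape = c(12, 48, 48))
  expect_identical(bf$moving$voxels, bf2$moving$voxels)  # seeded determinism
})

test_that("transforms that expel the beads raise an error", {
  expect_error(
    generate_bead_field(transform_params(tx = 5e5), n_beads = 5, seed = 1,
                        shape = c(12, 48, 48)),
    "out of frame")
})

test_that("probe tables are deterministic and collapse correctly at alpha 0", {
  a <- generate_probe_table(array_params(), seed = 2)
  b <- generate_probe_table(array_params(), seed = 2)
  expect_identical(a$spots$strain[[1]], b$spots$strain[[1]])
  expect_identical(a$truth$fold, b$truth$fold)

  z <- generate_probe_table(array_params(noise_cv = 0, alpha = 0), seed = 3)
  spots <- z$spots$control[[1]]
  pm <- spots[spots$probe_id %in% paste0("P_", names(z$truth$abundance_control)), ]
  probe_vals <- tapply(pm$gProcessedSignal, pm$probe_id, median)
  genes <- sub("^P_", "", names(probe_vals))
  cn <- z$annotation$copy_number[match(genes, z$annotation$gene)]
  expected <- z$truth$abundance_control[genes] * cn *
    z$truth$scale_control[1]
  expect_equal(as.numeric(probe_vals), unname(expected), tolerance = 1e-12)
})

test_that("array parameter validation enforces the attenuation domain", {
  expect_error(array_params(alpha = 1))
  expect_error(array_params(down_fold = 1.5))
})
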