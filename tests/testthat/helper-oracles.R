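# Independent oracles and small fixture builders used across the suite.

# Brute-force isodata threshold on a binned histogram: iterate the
# intermeans rule on bin midpoints/counts. Independent of the package's
# raw-value iteration.
isodata_hist_oracle <- function(values, n_bins = 1000) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  t <- sum(mids * counts) / sum(counts)
  for (i in 1:500) {
    lo <- mids <= t
    m_lo <- sum(mids[lo] * counts[lo]) / sum(counts[lo])
    m_hi <- sum(mids[!lo] * counts[!lo]) / sum(counts[!lo])
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t) < 1e-9 * diff(rng)) break
    t <- t_new
  }
  t_new
}

# Direct-formula overlap oracle: materializes the zero-padded arrays and
# evaluates Cov/sqrt(V*V) with population moments.
overlap_padded_oracle <- function(g, b, padding_factor) {
  m <- padding_factor * length(g)
  gp <- c(g, rep(0, m - length(g)))
  bp <- c(b, rep(0, m - length(b)))
  cv <- mean(gp * bp) - mean(gp) * mean(bp)
  cv / sqrt((mean(gp^2) - mean(gp)^2) * (mean(bp^2) - mean(bp)^2))
}

# Smooth test stack: a few blurred blobs, margins clear of the border.
make_smooth_stack <- function(seed = 1, shape = c(16, 32, 32),
                              voxel_size = c(125, 40, 40), n_blobs = 4) {
  set.seed(seed)
  a <- array(0, shape)
  for (i in seq_len(n_blobs)) {
    # central placement keeps >= 98% of blurred mass in frame under the
    # small transforms used in the tests
    pos <- sapply(shape, function(n)
      sample(seq(ceiling(n * 0.35), floor(n * 0.65)), 1))
    a[pos[1], pos[2], pos[3]] <- runif(1, 50, 100)
  }
  image_stack(pmax(gaussian_blur(a, c(250, 150, 150), voxel_size), 0),
              voxel_size, "test")
}

# One-nucleus scene cropped for overlap work: returns list(crop, truth).
make_cropped_scene <- function(seed = 1, params = scene_params(markers = c())) {
  scene <- generate_nucleus_scene(params, seed = seed)
  nuclei <- segment_nuclei(scene$channels$DAPI)
  stopifnot(length(nuclei) >= 1)
  list(crop = crop_nucleus(scene$channels, nuclei[[1]], margin = 200),
       nuclei = nuclei, scene = scene)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("%s within rel tol %g of %s",
                              deparse(substitute(object)), tol,
                              deparse(substitute(expected))))
}
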