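test_that("probe summarization takes spot medians and detection means", {
  spots <- data.frame(
    probe_id = c("a", "a", "a", "b", "b", "c", "c", "c", "c"),
    gProcessedSignal = c(100, 200, 300, 100, 300, 5, 5, 5, 5),
    gIsWellAboveBG = c(1, 1, 1, 1, 0, 1, 1, 0, 0))
  pr <- summarize_probes(spots)
  expect_equal(pr$intensity[pr$probe_id == "a"], 200)
  expect_equal(pr$intensity[pr$probe_id == "b"], 200)  # mean of middle two
  expect_false(pr$detected[pr$probe_id == "b"])        # mean flag 0.5
  expect_false(pr$detected[pr$probe_id == "c"])
  spots6 <- data.frame(probe_id = rep("d", 5),
                       gProcessedSignal = 1:5,
                       gIsWellAboveBG = c(1, 1, 1, 0, 0))
  expect_true(summarize_probes(spots6)$detected)       # mean flag 0.6
  expect_error(summarize_probes(spots[0, ]), "no spots")
})

test_that("the 75th percentile is pinned to 2,500 and ratios are preserved", {
  set.seed(41)
  v <- rlnorm(500, 6, 1)
  nv <- percentile_normalize(v)
  expect_equal(unname(quantile(nv, 0.75, type = 7)), 2500)
  expect_equal(nv[2] / nv[5], v[2] / v[5])
  expect_equal(as.numeric(percentile_normalize(rep(7, 10))), rep(2500, 10))
  # idempotence
  expect_equal(as.numeric(percentile_normalize(nv)), as.numeric(nv),
               tolerance = 1e-12)
  expect_error(percentile_normalize(numeric(0)))
})

test_that("paralog correction inverts its forward model exactly", {
  for (alpha in c(0, 0.05, 0.2, 0.5)) {
    for (m in 1:5) {
      s_a <- 1000; s_b <- 500
      am <- alpha^m
      pm_a <- s_a + am * s_b
      pm_b <- s_b + am * s_a
      fit <- paralog_correct(pm_a, pm_b,
                             corr_a = rep(alpha * pm_a, 2),
                             corr_b = rep(alpha * pm_b, 2),
                             mismatches = m)
      expect_equal(fit$s_a, s_a, tolerance = 1e-9)
      expect_equal(fit$s_b, s_b, tolerance = 1e-9)
      expect_equal(fit$alpha, alpha, tolerance = 1e-9)
    }
  }
})

test_that("paralog correction handles its degenerate cases", {
  # alpha = 0: no cross-hybridization, pass-through
  fit <- paralog_correct(800, 300, mismatches = 3, alpha = 0)
  expect_equal(fit$s_a, 800)
  expect_equal(fit$s_b, 300)
  expect_error(paralog_correct(800, 300, mismatches = 0, alpha = 0.1),
               "singular")
  expect_error(paralog_correct(800, 300, mismatches = 2, alpha = 1.2),
               "outside \\[0, 1\\)")
  # negative solutions are floored and flagged
  fit2 <- paralog_correct(100, 1000, mismatches = 1, alpha = 0.5)
  expect_true(fit2$flagged)
  expect_gte(fit2$s_a, 0)
})

test_that("copy-number adjustment divides and validates", {
  expect_equal(copy_number_adjust(c(3000, 500), c(2, 1)), c(1500, 500))
  expect_error(copy_number_adjust(100, 0), ">= 1")
  expect_error(copy_number_adjust(100, 1.5), "integers")
})

test_that("replicates combine by geometric mean and ratio to control", {
  s <- matrix(c(100, 400, 200, 200), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  ctl <- matrix(c(200, 200, 200, 200), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), NULL))
  res <- differential_ratios(s, ctl)
  expect_equal(res$strain_combined, c(200, 200))
  expect_equal(res$ratio, c(1, 1))
  expect_equal(res$log2_ratio, c(0, 0))
  # scaling both replicates scales the combined value (equivariance)
  res2 <- differential_ratios(s * 3, ctl)
  expect_equal(res2$strain_combined, 3 * res$strain_combined)
  # zero control flags the ratio undefined
  ctl0 <- ctl; ctl0["g2", ] <- 0
  res3 <- differential_ratios(s, ctl0)
  expect_false(res3$ratio_defined[2])
  expect_true(is.na(res3$ratio[2]))
})

test_that("fold-change sets use strict inequalities across all strains", {
  ratios <- data.frame(gene = c("a", "b", "c", "d", "e"),
                       s1 = c(2.1, 2.1, 2.0, 0.4, 0.6),
                       s2 = c(2.5, 1.9, 2.4, 0.3, 0.4),
                       s3 = c(3.0, 2.2, 2.2, 0.49, 0.3))
  sets <- fold_change_sets(ratios, c("s1", "s2", "s3"))
  expect_identical(sets$up, "a")       # b fails in s2, c is exactly 2 in s1
  expect_identical(sets$down, "d")     # e is 0.6 in s1
})

test_that("category fractions and the chi-squared test match hand values", {
  cats <- rep(c("coding", "ncRNA", "pseudogene"), c(89, 44, 9))
  res <- category_analysis(cats, c(coding = 0.8, ncRNA = 0.15,
                                   pseudogene = 0.05))
  expect_equal(res$table$percent, c(63, 31, 6))
  expect_equal(res$df, 2)
  # observed proportional to expected gives statistic 0
  res0 <- category_analysis(rep(c("x", "y"), c(50, 50)),
                            c(x = 0.5, y = 0.5))
  expect_equal(res0$statistic, 0)
  # hand-forced value: (10-5)^2/5 + (0-5)^2/5 = 10
  res10 <- category_analysis(rep("x", 10), c(x = 0.5, y = 0.5))
  expect_equal(res10$statistic, 10)
  expect_equal(res10$df, 1)
  expect_error(category_analysis("x", c(x = 1, y = 0)), "expected count 0")
})

test_that("the full chain recovers planted fold changes on noise-free tables", {
  tab <- generate_probe_table(array_params(noise_cv = 0), seed = 6)
  res <- expression_pipeline(tab$spots$strain, tab$spots$control,
                             tab$annotation)
  fold <- tab$truth$fold[res$gene]
  expect_lt(max(abs(res$ratio - fold) / fold), 1e-6)
  sets <- fold_change_sets(data.frame(gene = res$gene, s = res$ratio), "s")
  expect_setequal(sets$up, tab$truth$up_genes)
  expect_setequal(sets$down, tab$truth$down_genes)
  # background genes are flagged undetected
  expect_true(all(!res$detected[res$gene %in% tab$truth$background_genes]))
})

test_that("surrogate values override corrected intensities", {
  tab <- generate_probe_table(array_params(noise_cv = 0), seed = 8)
  g <- tab$annotation$gene[1]
  res <- expression_pipeline(tab$spots$strain, tab$spots$control,
                             tab$annotation,
                             surrogate_values = setNames(1234, g))
  expect_equal(res$strain_combined[res$gene == g], 1234)
})
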