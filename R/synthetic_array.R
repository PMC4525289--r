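#' Parameters of the synthetic one-colour microarray generator
#'
#' Emulates the structure of the Agilent-style one-colour arrays used for
#' the expression analysis: each probe spotted multiply, spot-level
#' `gProcessedSignal` values, `gIsWellAboveBG` detection flags, probes for
#' paralogous gene pairs that cross-hybridize with attenuation
#' `alpha^mismatches`, correction probes carrying one extra mismatch,
#' duplicated genes with copy number > 1, two biological replicates and a
#' control strain.
#'
#' @param n_genes Number of genes.
#' @param spots_per_probe Spots per probe on the array.
#' @param replicates Biological replicates per strain.
#' @param n_pairs Number of paralog pairs (pair members are unplanted,
#'   single-copy genes).
#' @param pair_mismatches Mismatches between paired probe sequences.
#' @param alpha True mismatch attenuation in `[0, 1)`.
#' @param n_duplicated Number of duplicated genes.
#' @param copy_number Copy number of duplicated genes.
#' @param n_up,up_fold Number and fold of genes upregulated in the test
#'   strain (drawn from the high-abundance tail so the 75th percentile
#'   anchor is unaffected).
#' @param n_down,down_fold Number and fold (< 1) of downregulated genes
#'   (drawn from the low-abundance half).
#' @param background_frac Fraction of genes below the detection limit
#'   (their spot flags average ~0.2).
#' @param noise_cv Lognormal coefficient of variation of spot signals
#'   (0 = noise-free).
#' @param meanlog,sdlog Lognormal abundance distribution parameters.
#' @return An `array_params` list.
#' @export
array_params <- function(n_genes = 600, spots_per_probe = 9, replicates = 2,
                         n_pairs = 3, pair_mismatches = 3, alpha = 0.1,
                         n_duplicated = 10, copy_number = 2,
                         n_up = 12, up_fold = 4,
                         n_down = 10, down_fold = 0.25,
                         background_frac = 0.1,
                         noise_cv = 0.1,
                         meanlog = 7, sdlog = 1) {
  stopifnot(n_genes >= 2 * n_pairs + n_duplicated + n_up + n_down,
            spots_per_probe >= 1, replicates >= 1, n_pairs >= 0,
            pair_mismatches >= 1, alpha >= 0, alpha < 1,
            copy_number >= 1, copy_number == round(copy_number),
            up_fold > 1, down_fold > 0, down_fold < 1, noise_cv >= 0)
  structure(as.list(environment()), class = "array_params")
}

#' Generate synthetic spot-level microarray tables with ground truth
#'
#' Forward model: each gene has a per-copy transcript abundance (lognormal
#' across genes); the transcript level is abundance x copy number. A
#' perfect-match probe for gene A of a paralog pair (A, B) measures
#' `T_A + alpha^m T_B`; its two correction probes (one extra mismatch,
#' either alternate base) measure `alpha (T_A + alpha^m T_B)` each.
#' Unpaired probes measure their own transcript. Spot values are the model
#' value times a per-replicate array scale factor and lognormal spot noise
#' (`noise_cv`); detection flags are 1 for expressed genes and Bernoulli
#' (p = 0.2) for background genes. Planted fold changes distinguish the
#' test strain from the control; up-genes are drawn from above the 85th
#' abundance percentile and down-genes from below the median, so the
#' planted changes do not move the 75-percentile normalization anchor.
#'
#' @param params An [array_params()] object.
#' @param seed Integer seed.
#' @return List with `spots` (`$strain` and `$control`, each a list of
#'   per-replicate spot `data.frame`s), `annotation` (probe -> gene map
#'   with `copy_number`, `probe_type`, `pair_id`, `mismatches`, `variant`)
#'   and `truth` (abundances, folds, up/down gene sets, `alpha`,
#'   background genes, per-replicate scale factors).
#' @export
generate_probe_table <- function(params = array_params(), seed = 1) {
  stopifnot(inherits(params, "array_params"))
  p <- params
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(p$n_genes))
    abundance <- rlnorm(p$n_genes, p$meanlog, p$sdlog)
    names(abundance) <- genes

    copy_number <- setNames(rep(1L, p$n_genes), genes)
    special <- character(0)
    dup_genes <- character(0)
    if (p$n_duplicated > 0) {
      dup_genes <- sample(genes, p$n_duplicated)
      copy_number[dup_genes] <- as.integer(p$copy_number)
      special <- dup_genes
    }
    pair_genes <- character(0)
    pairs <- NULL
    if (p$n_pairs > 0) {
      pair_genes <- sample(setdiff(genes, special), 2 * p$n_pairs)
      pairs <- matrix(pair_genes, ncol = 2, byrow = TRUE)
      special <- c(special, pair_genes)
    }
    free <- setdiff(genes, special)
    up_pool <- free[abundance[free] > quantile(abundance, 0.85)]
    down_pool <- free[abundance[free] < quantile(abundance, 0.5)]
    up_genes <- sample(up_pool, min(p$n_up, length(up_pool)))
    down_pool <- setdiff(down_pool, up_genes)
    down_genes <- sample(down_pool, min(p$n_down, length(down_pool)))
    fold <- setNames(rep(1, p$n_genes), genes)
    fold[up_genes] <- p$up_fold
    fold[down_genes] <- p$down_fold
    bg_pool <- setdiff(free, c(up_genes, down_genes))
    bg_genes <- sample(bg_pool, round(p$background_frac * p$n_genes))

    # probe annotation
    ann <- data.frame(probe_id = paste0("P_", genes), gene = genes,
                      copy_number = unname(copy_number[genes]),
                      probe_type = "pm", pair_id = NA_integer_,
                      mismatches = 0L, variant = NA_integer_)
    if (p$n_pairs > 0) {
      for (k in seq_len(p$n_pairs)) {
        ga <- pairs[k, 1]; gb <- pairs[k, 2]
        ann$pair_id[ann$gene %in% c(ga, gb)] <- k
        ann$mismatches[ann$gene %in% c(ga, gb)] <- p$pair_mismatches
        for (g in c(ga, gb)) for (v in 1:2) {
          ann <- rbind(ann, data.frame(
            probe_id = sprintf("C_%s_v%d", g, v), gene = g,
            copy_number = unname(copy_number[g]),
            probe_type = "correction", pair_id = k,
            mismatches = p$pair_mismatches + 1L, variant = v))
        }
      }
    }

    transcript <- function(ab) ab * copy_number  # per-gene transcript level
    model_values <- function(ab) {
      tr <- transcript(ab)
      val <- setNames(tr[ann$gene], ann$probe_id)
      if (p$n_pairs > 0) {
        am <- p$alpha^p$pair_mismatches
        for (k in seq_len(p$n_pairs)) {
          ga <- pairs[k, 1]; gb <- pairs[k, 2]
          pm_a <- tr[ga] + am * tr[gb]
          pm_b <- tr[gb] + am * tr[ga]
          val[paste0("P_", ga)] <- pm_a
          val[paste0("P_", gb)] <- pm_b
          val[sprintf("C_%s_v%d", ga, 1:2)] <- p$alpha * pm_a
          val[sprintf("C_%s_v%d", gb, 1:2)] <- p$alpha * pm_b
        }
      }
      val
    }

    spot_table <- function(ab) {
      scale_rep <- exp(rnorm(1, sd = 0.2))
      val <- model_values(ab)
      nspot <- p$spots_per_probe
      df <- data.frame(
        probe_id = rep(ann$probe_id, each = nspot),
        gProcessedSignal = rep(unname(val), each = nspot) * scale_rep,
        gIsWellAboveBG = 1)
      if (p$noise_cv > 0)
        df$gProcessedSignal <- df$gProcessedSignal *
          exp(rnorm(nrow(df), sd = sqrt(log(1 + p$noise_cv^2))))
      bg_probes <- paste0("P_", bg_genes)
      idx <- df$probe_id %in% bg_probes
      df$gIsWellAboveBG[idx] <- rbinom(sum(idx), 1, 0.2)
      attr(df, "scale") <- scale_rep
      df
    }

    ab_strain <- abundance * fold
    strain <- lapply(seq_len(p$replicates), function(r) spot_table(ab_strain))
    control <- lapply(seq_len(p$replicates), function(r) spot_table(abundance))

    list(spots = list(strain = strain, control = control),
         annotation = ann,
         truth = list(abundance_control = abundance,
                      abundance_strain = ab_strain,
                      fold = fold, alpha = p$alpha,
                      up_genes = sort(up_genes), down_genes = sort(down_genes),
                      background_genes = sort(bg_genes),
                      duplicated_genes = sort(dup_genes),
                      pair_genes = pair_genes,
                      scale_strain = vapply(strain, attr, numeric(1), "scale"),
                      scale_control = vapply(control, attr, numeric(1),
                                             "scale"),
                      seed = seed))
  })
}
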