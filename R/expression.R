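#' Summarize spot-level microarray signals to probe level
#'
#' Each probe is spotted multiple times on the one-colour array. The probe
#' intensity is the median of its spots' `gProcessedSignal` values (mean of
#' the middle two for an even spot count), and the probe is flagged
#' detected when the mean of its spots' `gIsWellAboveBG` flags exceeds
#' 0.55.
#'
#' @param spots `data.frame` with columns `probe_id`, `gProcessedSignal`
#'   (>= 0) and `gIsWellAboveBG` (0/1).
#' @return `data.frame` with one row per probe: `probe_id`, `intensity`,
#'   `detected`.
#' @export
summarize_probes <- function(spots) {
  stopifnot(is.data.frame(spots),
            all(c("probe_id", "gProcessedSignal", "gIsWellAboveBG") %in%
                  names(spots)))
  if (nrow(spots) == 0) stop("no spots")
  if (any(spots$gProcessedSignal < 0)) stop("signals must be >= 0")
  ids <- unique(spots$probe_id)
  sig <- split(spots$gProcessedSignal, spots$probe_id)[as.character(ids)]
  flg <- split(spots$gIsWellAboveBG, spots$probe_id)[as.character(ids)]
  data.frame(probe_id = ids,
             intensity = vapply(sig, median, numeric(1)),
             detected = vapply(flg, mean, numeric(1)) > 0.55,
             row.names = NULL)
}

#' Percentile normalization of probe intensities
#'
#' Scales all intensities by a single factor so that the `q`-th percentile
#' of the result equals `target` (default: the 75th percentile is set to
#' 2,500). The percentile uses linear interpolation between order
#' statistics; the anchor holds exactly under any percentile definition
#' because a single scalar factor is applied.
#'
#' @param values Non-empty numeric vector of probe intensities.
#' @param q Percentile in (0, 100]; default 75.
#' @param target Target value of that percentile; default 2500.
#' @return Scaled values (same order), with the factor in attribute
#'   `"factor"`.
#' @export
percentile_normalize <- function(values, q = 75, target = 2500) {
  stopifnot(length(values) > 0, q > 0, q <= 100, target > 0)
  p <- unname(quantile(values, q / 100, type = 7))
  if (p <= 0) stop("percentile of the input is not positive")
  out <- values * (target / p)
  attr(out, "factor") <- target / p
  out
}

#' Correct a paralog pair for cross-hybridization
#'
#' Probes for two paralogous genes sit at identical coding positions, so
#' each perfect-match probe also captures the paralogous transcript,
#' attenuated by the `m` mismatches between the paralogs. Assuming every
#' mismatch attenuates hybridization by the same factor `alpha`, the
#' signals follow the linear model
#' \deqn{I_{PA} = s_A + \alpha^m s_B, \quad I_{PB} = s_B + \alpha^m s_A,}
#' and each correction probe (the perfect-match sequence with one extra
#' mismatch, made with either of the two other bases) sees
#' \eqn{\alpha s_A + \alpha^{m+1} s_B} (and symmetrically for B). Since the
#' correction-probe value is exactly `alpha` times the perfect-match value
#' under the model, `alpha` is estimated as the mean ratio of correction
#' probes to their perfect-match probes when not supplied; the two
#' equations are then solved for the cross-hybridization-free signals
#' `s_A`, `s_B`.
#'
#' @param pm_a,pm_b Perfect-match probe intensities for genes A and B.
#' @param corr_a,corr_b Optional numeric vectors of correction-probe
#'   intensities (the two base variants) for A and B; required when
#'   `alpha` is not supplied.
#' @param mismatches Number of mismatches `m >= 1` between the paralogous
#'   probe sequences (`m = 0` means identical probes: singular system).
#' @param alpha Mismatch attenuation in `[0, 1)`; estimated from the
#'   correction probes when `NULL`.
#' @return List with `s_a`, `s_b` (negative solutions floored at 0 and
#'   flagged), `alpha`, `flagged`.
#' @examples
#' # forward model: s_a = 1000, s_b = 500, alpha = 0.1, m = 3
#' a <- 0.1; m <- 3
#' paralog_correct(1000 + a^m * 500, 500 + a^m * 1000,
#'                 corr_a = a * (1000 + a^m * 500),
#'                 corr_b = a * (500 + a^m * 1000), mismatches = m)
#' @export
paralog_correct <- function(pm_a, pm_b, corr_a = NULL, corr_b = NULL,
                            mismatches, alpha = NULL) {
  stopifnot(length(pm_a) == 1, length(pm_b) == 1,
            mismatches == round(mismatches), mismatches >= 0)
  if (mismatches == 0)
    stop("singular system: 0 mismatches between paralog probes")
  if (is.null(alpha)) {
    if (is.null(corr_a) && is.null(corr_b))
      stop("either 'alpha' or correction probes must be supplied")
    ratios <- c(if (!is.null(corr_a) && pm_a > 0) mean(corr_a) / pm_a,
                if (!is.null(corr_b) && pm_b > 0) mean(corr_b) / pm_b)
    alpha <- mean(ratios)
  }
  if (is.na(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha estimate outside [0, 1): ", format(alpha))
  am <- alpha^mismatches
  det <- 1 - am^2
  s_a <- (pm_a - am * pm_b) / det
  s_b <- (pm_b - am * pm_a) / det
  flagged <- s_a < 0 || s_b < 0
  list(s_a = max(s_a, 0), s_b = max(s_b, 0), alpha = alpha,
       flagged = flagged)
}

#' Apply paralog correction across an annotated probe table
#'
#' @param probes `data.frame` from [summarize_probes()] (columns `probe_id`,
#'   `intensity`) merged with gene assignments.
#' @param annotation Probe annotation `data.frame` with columns `probe_id`,
#'   `gene`, `probe_type` (`"pm"` or `"correction"`), `pair_id` (NA for
#'   unpaired probes) and `mismatches`.
#' @param alpha `"fit"` (estimate per pair from correction probes) or a
#'   fixed numeric value in `[0, 1)`.
#' @return `data.frame` with one row per gene: `gene`, `intensity`
#'   (corrected for paired genes, pass-through otherwise), `corrected`,
#'   `flagged`, and the `alpha` used.
#' @export
apply_paralog_corrections <- function(probes, annotation, alpha = "fit") {
  stopifnot(all(c("probe_id", "gene", "probe_type", "pair_id", "mismatches")
                %in% names(annotation)))
  tab <- merge(annotation, probes[, c("probe_id", "intensity")],
               by = "probe_id")
  pm <- tab[tab$probe_type == "pm", ]
  out <- data.frame(gene = pm$gene, intensity = pm$intensity,
                    corrected = FALSE, flagged = FALSE,
                    alpha = NA_real_, row.names = NULL)
  for (pid in unique(stats::na.omit(tab$pair_id))) {
    sub <- tab[!is.na(tab$pair_id) & tab$pair_id == pid, ]
    genes <- unique(sub$gene[sub$probe_type == "pm"])
    if (length(genes) != 2) stop("pair ", pid, " must have 2 pm genes")
    m <- unique(sub$mismatches[sub$probe_type == "pm"])
    ga <- genes[1]; gb <- genes[2]
    ia <- sub$intensity[sub$probe_type == "pm" & sub$gene == ga]
    ib <- sub$intensity[sub$probe_type == "pm" & sub$gene == gb]
    ca <- sub$intensity[sub$probe_type == "correction" & sub$gene == ga]
    cb <- sub$intensity[sub$probe_type == "correction" & sub$gene == gb]
    fit <- paralog_correct(ia, ib,
                           corr_a = if (length(ca)) ca else NULL,
                           corr_b = if (length(cb)) cb else NULL,
                           mismatches = m,
                           alpha = if (identical(alpha, "fit")) NULL else alpha)
    out$intensity[out$gene == ga] <- fit$s_a
    out$intensity[out$gene == gb] <- fit$s_b
    out$corrected[out$gene %in% genes] <- TRUE
    out$flagged[out$gene %in% genes] <- fit$flagged
    out$alpha[out$gene %in% genes] <- fit$alpha
  }
  out
}

#' Divide duplicated-gene intensities by gene copy number
#'
#' @param values Numeric intensities per gene.
#' @param copy_numbers Integer copy numbers (>= 1), recycled checkwise.
#' @return `values / copy_numbers`.
#' @export
copy_number_adjust <- function(values, copy_numbers) {
  if (any(copy_numbers != round(copy_numbers)))
    stop("copy numbers must be integers")
  if (any(copy_numbers < 1)) stop("copy numbers must be >= 1")
  values / copy_numbers
}

#' Combine replicates and form strain/control expression ratios
#'
#' Biological replicates are combined by geometric mean (so fold changes
#' compose symmetrically), then divided by the combined values of the
#' control strain; the log2 ratio is reported alongside.
#'
#' @param strain_reps,control_reps Numeric matrices (genes x replicates)
#'   or data.frames of per-gene intensities on matched gene sets; row
#'   names (or a `gene` attribute) identify genes.
#' @return `data.frame` with per-gene combined values, `ratio`,
#'   `log2_ratio`, and `ratio_defined` (FALSE where the control combined
#'   value is 0).
#' @export
differential_ratios <- function(strain_reps, control_reps) {
  s <- as.matrix(strain_reps)
  c_ <- as.matrix(control_reps)
  if (nrow(s) != nrow(c_)) stop("gene sets must match")
  geom <- function(m) exp(rowMeans(log(m)))
  gs <- ifelse(apply(s == 0, 1, any), 0, geom(pmax(s, .Machine$double.xmin)))
  gc <- ifelse(apply(c_ == 0, 1, any), 0, geom(pmax(c_, .Machine$double.xmin)))
  defined <- gc > 0
  ratio <- ifelse(defined, gs / gc, NA_real_)
  data.frame(gene = rownames(s) %||% seq_len(nrow(s)),
             strain_combined = gs, control_combined = gc,
             ratio = ratio, log2_ratio = log2(ratio),
             ratio_defined = defined, row.names = NULL)
}

#' Genes consistently beyond a fold-change threshold in several strains
#'
#' Returns the genes whose expression ratio exceeds `fold` in every listed
#' strain (up set) or falls below `1/fold` in every strain (down set).
#' Inequalities are strict ("greater than twofold"), so a ratio of exactly
#' 2 is excluded at the default fold.
#'
#' @param ratios `data.frame` (genes in rows, identified by column `gene`
#'   or row names) with one numeric ratio column per strain.
#' @param strains Character vector of strain column names to intersect.
#' @param fold Fold-change threshold (default 2).
#' @return List with `up`, `down` (character gene vectors: the
#'   intersections across strains) and `per_strain` (lists of up/down
#'   genes per strain).
#' @export
fold_change_sets <- function(ratios, strains, fold = 2) {
  stopifnot(all(strains %in% names(ratios)), fold > 0)
  genes <- if ("gene" %in% names(ratios)) as.character(ratios$gene)
           else rownames(ratios)
  per_strain <- lapply(setNames(strains, strains), function(s) {
    r <- ratios[[s]]
    list(up = genes[!is.na(r) & r > fold],
         down = genes[!is.na(r) & r < 1 / fold])
  })
  list(up = Reduce(intersect, lapply(per_strain, `[[`, "up")),
       down = Reduce(intersect, lapply(per_strain, `[[`, "down")),
       per_strain = per_strain)
}

#' Category composition of a gene set with a chi-squared test
#'
#' Tabulates a gene set over exhaustive, disjoint categories, reports the
#' fraction per category as integer-rounded percent, and tests the
#' observed counts against expected proportions (e.g. the category mix of
#' all probes on the array, i.e. a random-selection expectation) with a
#' chi-squared goodness-of-fit test.
#'
#' @param categories Character/factor vector: the category of each gene in
#'   the set.
#' @param expected_proportions Named numeric vector over all categories,
#'   summing to 1.
#' @return List with `table` (`data.frame`: category, n, percent,
#'   expected), `statistic`, `df`, `p_value`.
#' @examples
#' category_analysis(rep(c("coding", "ncRNA", "pseudogene"), c(89, 44, 9)),
#'                   c(coding = 0.8, ncRNA = 0.15, pseudogene = 0.05))
#' @export
category_analysis <- function(categories, expected_proportions) {
  stopifnot(abs(sum(expected_proportions) - 1) < 1e-8,
            !is.null(names(expected_proportions)))
  cats <- names(expected_proportions)
  if (!all(categories %in% cats))
    stop("categories outside the expected set: ",
         paste(setdiff(unique(categories), cats), collapse = ", "))
  n <- as.integer(table(factor(categories, levels = cats)))
  total <- length(categories)
  expected <- total * expected_proportions
  if (any(expected == 0)) stop("expected count 0 in a category")
  test <- suppressWarnings(chisq.test(n, p = expected_proportions))
  list(table = data.frame(category = cats, n = n,
                          percent = round(100 * n / total),
                          expected = unname(expected), row.names = NULL),
       statistic = unname(test$statistic),
       df = unname(test$parameter),
       p_value = unname(test$p.value))
}

#' Run the full expression chain on spot tables
#'
#' Convenience wrapper over the whole microarray analysis: spot -> probe
#' summarization, 75-percentile normalization (anchor 2,500), copy-number
#' division, paralog cross-hybridization correction, geometric-mean
#' replicate combination and division by the control strain.
#'
#' @param strain_spots,control_spots Lists of spot `data.frame`s, one per
#'   biological replicate.
#' @param annotation Probe annotation as in [apply_paralog_corrections()],
#'   plus a `copy_number` column per probe.
#' @param alpha Paralog-correction attenuation: `"fit"` or a number.
#' @param surrogate_values Optional named numeric vector of per-gene
#'   overrides applied after correction (used when a deleted gene's
#'   residual signal is pure cross-hybridization).
#' @return The [differential_ratios()] data.frame, with per-gene detection
#'   flags (detected in all replicates of either strain) in column
#'   `detected`.
#' @export
expression_pipeline <- function(strain_spots, control_spots, annotation,
                                alpha = "fit", surrogate_values = NULL) {
  process_rep <- function(spots) {
    probes <- summarize_probes(spots)
    probes$intensity <- percentile_normalize(probes$intensity)
    tab <- merge(annotation, probes, by = "probe_id")
    tab$intensity <- copy_number_adjust(tab$intensity, tab$copy_number)
    genes <- apply_paralog_corrections(tab[, c("probe_id", "intensity")],
                                       annotation, alpha = alpha)
    pm_tab <- tab[tab$probe_type == "pm", ]
    det <- pm_tab$detected[match(genes$gene, pm_tab$gene)]
    if (!is.null(surrogate_values)) {
      hit <- match(names(surrogate_values), genes$gene)
      genes$intensity[stats::na.omit(hit)] <-
        surrogate_values[!is.na(hit)]
    }
    list(intensity = setNames(genes$intensity, genes$gene), detected = det)
  }
  s <- lapply(strain_spots, process_rep)
  c_ <- lapply(control_spots, process_rep)
  genes <- names(s[[1]]$intensity)
  smat <- sapply(s, function(r) r$intensity[genes])
  cmat <- sapply(c_, function(r) r$intensity[genes])
  rownames(smat) <- rownames(cmat) <- genes
  res <- differential_ratios(smat, cmat)
  det_s <- Reduce(`&`, lapply(s, `[[`, "detected"))
  det_c <- Reduce(`&`, lapply(c_, `[[`, "detected"))
  res$detected <- det_s | det_c
  res
}
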