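#' Noise and signal-level configuration for the hybridization generator
#'
#' All quantities are on the log2 intensity scale. The generator emulates
#' the structure the probe-level model later removes: a per-probe affinity
#' offset, a per-hybridization shift, and residual measurement noise, on
#' top of piecewise-constant transcription along the chromosome.
#'
#' @param sigma_affinity sd of the per-probe affinity offset `a_p`.
#' @param sigma_shift sd of the per-hybridization shift `s_h`.
#' @param sigma_resid sd of the residual noise per cell.
#' @param background_median centre of the untranscribed (background) signal;
#'   probes outside expressed features sit around this level, so the
#'   "5x above the chromosome median" segment rule is exercisable.
#' @param background_sd sd of the per-probe background level (drawn once per
#'   probe, shared across samples).
#' @param expr_offset mean log2 offset of expressed genes above background.
#' @param expr_sd sd of gene baseline expression.
#' @param segment_offset mean log2 offset of expressed regulatory segments
#'   above background (lower than genes: low-abundance regulatory RNAs).
#' @param expressed_fraction fraction of genes transcriptionally active
#'   (roughly half the genome is active in rich medium).
#' @param segment_expressed_fraction fraction of regulatory segments active.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(sigma_affinity = 0.25, sigma_shift = 0.2,
                         sigma_resid = 0.15,
                         background_median = 4, background_sd = 0.3,
                         expr_offset = 3.5, expr_sd = 0.8,
                         segment_offset = 2.6,
                         expressed_fraction = 0.5,
                         segment_expressed_fraction = 0.8) {
  structure(as.list(environment()), class = "noise_config")
}

#' Planted depletion effect
#'
#' @param gene_id feature id the effect applies to.
#' @param rnase one of `"III"`, `"J1"`, `"Y"`.
#' @param delta_log2 non-zero log2 fold-change in the depleted (-IPTG)
#'   samples of that RNase relative to wild type.
#' @return one-row data.frame with a derived `direction` column.
#' @export
effect_spec <- function(gene_id, rnase, delta_log2) {
  if (!rnase %in% RNASES) stopf("rnase must be one of %s", paste(RNASES, collapse = ", "))
  if (delta_log2 == 0) stopf("delta_log2 must be non-zero")
  data.frame(gene_id = gene_id, rnase = rnase, delta_log2 = delta_log2,
             direction = ifelse(delta_log2 > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Depletion scenario
#'
#' @param fold_reduction dimensionless divisor applied to the depleted
#'   enzyme's activity (default 30, the floor achieved experimentally).
#' @export
depletion_scenario <- function(fold_reduction = 30) {
  assert_scalar_number(fold_reduction, "fold_reduction", lower = 1)
  structure(list(fold_reduction = fold_reduction), class = "depletion_scenario")
}

#' Sample sheet for the depletion experiment
#'
#' Wild type plus the three depletion strains; depletion strains are grown
#' with and (the informative arm) without IPTG, each in `replicates`
#' biological replicates.
#'
#' @param replicates replicates per (condition, IPTG) pair (>= 2).
#' @param include_plus include the fully complemented +IPTG arms.
#' @return data.frame with `sample_id`, `condition`, `iptg`, `replicate`.
#' @export
sample_sheet <- function(replicates = 2, include_plus = TRUE) {
  if (replicates < 2) stopf("the design requires >= 2 replicates")
  rows <- list(data.frame(condition = "wt", iptg = "not_applicable",
                          replicate = seq_len(replicates)))
  for (cond in unname(RNASE_CONDITION)) {
    rows[[length(rows) + 1L]] <- data.frame(condition = cond, iptg = "minus",
                                            replicate = seq_len(replicates))
    if (include_plus)
      rows[[length(rows) + 1L]] <- data.frame(condition = cond, iptg = "plus",
                                              replicate = seq_len(replicates))
  }
  samples <- do.call(rbind, rows)
  tag <- ifelse(samples$iptg == "not_applicable", "",
                paste0("_", samples$iptg))
  samples <- data.frame(sample_id = paste0(samples$condition, tag, "_", samples$replicate),
                        samples, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  samples
}

#' Construct a hybridization set
#'
#' @param intensities probe x sample matrix of raw log2 intensities;
#'   rownames are probe ids, colnames sample ids.
#' @param samples sample sheet matching the columns.
#' @param truth optional generator ground-truth block.
#' @export
hybridization_set <- function(intensities, samples, truth = NULL) {
  if (!all(is.finite(intensities))) stopf("intensities must be finite")
  if (ncol(intensities) != nrow(samples)) stopf("samples do not match columns")
  main <- samples[is_main_sample(samples), ]
  cnt <- table(main$condition)
  if (length(cnt) < 4 || any(cnt < 2))
    stopf("each of the four main (condition, IPTG) experiments needs >= 2 replicates")
  structure(list(intensities = intensities, samples = samples, truth = truth),
            class = "hyb_set")
}

#' @export
print.hyb_set <- function(x, ...) {
  cat(sprintf("<hyb_set> %d probes x %d samples%s\n", nrow(x$intensities),
              ncol(x$intensities), if (is.null(x$truth)) "" else " (+truth)"))
  invisible(x)
}

# Which feature (row index in features) covers each probe fully, same strand.
# Genes (CDS/misc_RNA) take precedence over segments when both cover a probe.
covering_feature <- function(design, features) {
  idx <- rep(NA_integer_, nrow(design))
  if (nrow(features) == 0) return(idx)
  ord <- order(features$kind != "segment")  # segments first, genes overwrite
  for (i in ord) {
    hit <- design$strand == features$strand[i] &
      design$start >= features$start[i] & design$end <= features$end[i]
    idx[hit] <- i
  }
  idx
}

#' Simulate tiling-array hybridizations
#'
#' Probe log2 signal is the baseline expression of the covering feature
#' (background where none), plus any planted depletion effect in the
#' matching RNase's -IPTG samples, plus per-probe affinity, per-sample
#' shift, and residual noise. The `truth` block stores the noiseless
#' expression and the drawn affinity/shift vectors, so tests can invert the
#' generator exactly.
#'
#' @param annotation a [genome_annotation()].
#' @param design a [design_probes()] result.
#' @param effects data.frame of [effect_spec()] rows (or `NULL`).
#' @param scenario a [depletion_scenario()] (recorded in the truth block).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param replicates replicates per experiment.
#' @param include_plus include fully complemented +IPTG samples.
#' @return a [hybridization_set()] with `truth`.
#' @export
simulate_expression <- function(annotation, design, effects = NULL,
                                scenario = depletion_scenario(),
                                noise = noise_config(), seed = 1L,
                                replicates = 2, include_plus = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  feats <- annotation$features
  if (!is.null(effects) && nrow(effects) > 0) {
    unknown <- setdiff(effects$gene_id, feats$id)
    if (length(unknown) > 0)
      stopf("effects reference unknown feature id(s): %s", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  samples <- sample_sheet(replicates, include_plus)
  P <- nrow(design); H <- nrow(samples)

  # baseline landscape (drawn before noise so sigma=0 runs share it by seed)
  is_seg <- feats$kind == "segment"
  expressed <- stats::runif(nrow(feats)) <
    ifelse(is_seg, noise$segment_expressed_fraction, noise$expressed_fraction)
  baseline <- noise$background_median +
    stats::rnorm(nrow(feats),
                 mean = ifelse(is_seg, noise$segment_offset, noise$expr_offset),
                 sd = noise$expr_sd)
  names(baseline) <- names(expressed) <- feats$id
  # features carrying a planted effect are always transcribed, so the
  # planted truth is recoverable
  if (!is.null(effects)) expressed[unique(effects$gene_id)] <- TRUE
  bg <- noise$background_median + stats::rnorm(P, 0, noise$background_sd)

  cover <- covering_feature(design, feats)
  base_p <- ifelse(!is.na(cover) & expressed[cover], baseline[cover], bg)

  expr <- matrix(base_p, nrow = P, ncol = H,
                 dimnames = list(design$id, samples$sample_id))
  if (!is.null(effects)) {
    for (k in seq_len(nrow(effects))) {
      cols <- samples$condition == RNASE_CONDITION[[effects$rnase[k]]] &
        samples$iptg == "minus"
      rows <- !is.na(cover) & feats$id[cover] == effects$gene_id[k]
      if (any(rows) && any(expressed[feats$id == effects$gene_id[k]]))
        expr[rows, cols] <- expr[rows, cols] + effects$delta_log2[k]
    }
  }
  a_p <- stats::rnorm(P, 0, noise$sigma_affinity)
  s_h <- stats::rnorm(H, 0, noise$sigma_shift)
  eps <- matrix(stats::rnorm(P * H, 0, noise$sigma_resid), P, H)
  y <- expr + a_p + rep(s_h, each = P) + eps
  dimnames(y) <- dimnames(expr)
  hybridization_set(y, samples,
                    truth = list(expression = expr, affinity = a_p, shift = s_h,
                                 baseline = baseline, expressed = expressed,
                                 scenario = scenario, effects = effects))
}

#' Simulate an aggregated gene expression matrix directly
#'
#' Skips the probe level: draws gene x sample log2 values for the four main
#' experiments with independent Gaussian noise, planting a depletion effect
#' for a subset of genes in one RNase's samples. Used for calibration
#' studies of the differential-testing stage.
#'
#' @param n_null,n_affected numbers of unaffected / affected genes.
#' @param delta_log2 planted effect for affected genes.
#' @param sigma residual sd on the log2 scale.
#' @param rnase RNase whose depletion carries the effect.
#' @param replicates replicates per condition.
#' @param baseline_mean,baseline_sd distribution of gene baselines.
#' @param seed integer seed.
#' @return an [expression_matrix()]; attribute `affected` holds the ids of
#'   genes carrying the planted effect.
#' @export
simulate_gene_matrix <- function(n_null = 2000, n_affected = 500,
                                 delta_log2 = 1, sigma = 0.2, rnase = "Y",
                                 replicates = 2, baseline_mean = 8,
                                 baseline_sd = 1, seed = 1L) {
  set.seed(seed)
  samples <- sample_sheet(replicates, include_plus = FALSE)
  n <- n_null + n_affected
  ids <- sprintf("gene_%05d", seq_len(n))
  base <- stats::rnorm(n, baseline_mean, baseline_sd)
  vals <- matrix(base, n, nrow(samples),
                 dimnames = list(ids, samples$sample_id))
  affected <- character(0)
  if (n_affected > 0) {
    affected <- ids[sample.int(n, n_affected)]
    cols <- samples$condition == RNASE_CONDITION[[rnase]] & samples$iptg == "minus"
    vals[affected, cols] <- vals[affected, cols] + delta_log2
  }
  vals <- vals + matrix(stats::rnorm(length(vals), 0, sigma), n)
  em <- expression_matrix(vals, samples)
  attr(em, "affected") <- affected
  em
}
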