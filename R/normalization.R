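#' Normalization configuration
#'
#' @param n_strata number of equal-count average-expression strata.
#' @param frac_per_stratum fraction of least-variant genes kept per stratum.
#' @param span loess span used for the per-hybridization correction curve.
#' @export
normalization_config <- function(n_strata = 10L, frac_per_stratum = 0.10,
                                 span = 0.5) {
  assert_scalar_number(n_strata, "n_strata", lower = 1)
  assert_scalar_number(frac_per_stratum, "frac_per_stratum", lower = 1e-12, upper = 1)
  assert_scalar_number(span, "span", lower = 1e-12, upper = 1)
  structure(list(n_strata = as.integer(n_strata),
                 frac_per_stratum = frac_per_stratum, span = span),
            class = "normalization_config")
}

# per-gene means of the four main conditions (replicates averaged first)
condition_means <- function(em) {
  mc <- main_condition(em$samples)
  conds <- c("wt", unname(RNASE_CONDITION))
  out <- vapply(conds, function(cl)
    rowMeans(em$values[, !is.na(mc) & mc == cl, drop = FALSE]),
    numeric(nrow(em$values)))
  matrix(out, nrow = nrow(em$values), dimnames = list(rownames(em$values), conds))
}

#' Select the least-variant gene set
#'
#' Genes are ranked by average expression and split into `n_strata`
#' equal-count intervals; within each stratum the `frac_per_stratum` genes
#' with the lowest variance across the four main-condition means (wild
#' type and the three depletions, replicates averaged first) are kept.
#' Global distribution shifts between conditions leave such genes as
#' usable normalization anchors where quantile normalization would not be.
#'
#' @param em an [expression_matrix()] covering the four main conditions.
#' @param config a [normalization_config()].
#' @return sorted character vector of gene ids,
#'   `floor(frac_per_stratum * stratum size)` per stratum. Ties in variance
#'   are broken lexicographically by gene id.
#' @export
select_least_variant_set <- function(em, config = normalization_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  ok <- !em$low_coverage & stats::complete.cases(em$values)
  vals <- em$values[ok, , drop = FALSE]
  if (nrow(vals) < config$n_strata)
    stopf("fewer usable genes (%d) than strata (%d)", nrow(vals), config$n_strata)
  avg <- rowMeans(vals)
  cm <- condition_means(expression_matrix(vals, em$samples))
  v <- apply(cm, 1, stats::var)
  ids <- rownames(vals)
  strata <- split(seq_along(avg),
                  cut(rank(avg, ties.method = "first"),
                      breaks = config$n_strata, labels = FALSE))
  picked <- unlist(lapply(strata, function(idx) {
    k <- floor(config$frac_per_stratum * length(idx))
    if (k == 0) return(character(0))
    ord <- idx[order(v[idx], ids[idx])]
    ids[ord[seq_len(k)]]
  }), use.names = FALSE)
  sort(picked)
}

#' Fit the per-hybridization normalization transformation
#'
#' For each sample, a loess curve (span `config$span`, locally linear,
#' tricube weights) of `observed - reference` against `reference` over the
#' least-variant genes, where the reference is the per-gene mean over all
#' samples of that set. The curve maps an expression value to a correction
#' offset.
#'
#' @param em an [expression_matrix()].
#' @param lv_set gene ids from [select_least_variant_set()].
#' @param config a [normalization_config()].
#' @return list of class `normalization_model` (per-sample loess fits, the
#'   reference, the anchor set, and the anchor range used for constant
#'   extrapolation).
#' @export
fit_normalization <- function(em, lv_set, config = normalization_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!all(lv_set %in% rownames(em$values)))
    stopf("lv_set contains ids absent from the matrix")
  x <- em$values[lv_set, , drop = FALSE]
  ref <- rowMeans(x)
  if (length(ref) < 10)
    stopf("least-variant set too small (%d genes) for span %.2f",
          length(ref), config$span)
  fits <- lapply(colnames(x), function(h) {
    stats::loess(d ~ r, data = data.frame(d = x[, h] - ref, r = ref),
                 span = config$span, degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
  })
  names(fits) <- colnames(x)
  structure(list(fits = fits, reference = ref, lv_set = lv_set,
                 range = range(ref), config = config),
            class = "normalization_model")
}

#' Apply a fitted normalization model
#'
#' Every unit's value is corrected by its sample's curve evaluated at that
#' value, with constant extrapolation beyond the anchor range.
#'
#' @param em an [expression_matrix()].
#' @param model a [fit_normalization()] result.
#' @return a corrected [expression_matrix()].
#' @export
apply_normalization <- function(em, model) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(model, "normalization_model"))
  missing <- setdiff(colnames(em$values), names(model$fits))
  if (length(missing) > 0)
    stopf("sample(s) absent from the normalization model: %s",
          paste(missing, collapse = ", "))
  out <- em$values
  for (h in colnames(out)) {
    x <- pmin(pmax(out[, h], model$range[1]), model$range[2])
    corr <- stats::predict(model$fits[[h]], newdata = data.frame(r = x))
    out[, h] <- out[, h] - corr
  }
  expression_matrix(out, em$samples, n_probes = em$n_probes,
                    low_coverage = em$low_coverage)
}
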