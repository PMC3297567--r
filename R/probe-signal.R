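#' Estimate probe-level transcriptional profiles
#'
#' Decomposes raw probe x sample log2 intensities as
#' `y_ph = profile_ph + a_p + s_h + r_ph`, where `a_p` is a per-probe
#' affinity offset, `s_h` a per-hybridization shift, and `profile` the
#' condition-level transcription signal. Both nuisance terms are fitted
#' robustly with medians:
#'
#' * the shift is the column effect of a median polish of the deviations
#'   of each value from its probe's per-condition median (so condition-level
#'   biology never leaks into the shift);
#' * the affinity is the per-probe median, across samples, of the deviation
#'   from a per-sample running median over position-adjacent probes of the
#'   same strand - transcription is locally constant along the chromosome,
#'   so a probe's persistent deviation from its neighbours is affinity.
#'
#' Both estimates are centred to median zero; the profile term is the
#' input minus the fitted nuisance terms (per sample, so replicate-level
#' variation is preserved for the downstream linear model), and
#' `profiles + affinity_hat + shift_hat` reconstructs the input exactly.
#' The stored `residual` is the replicate scatter of each profile value
#' around its probe's condition median (a QC quantity).
#'
#' @param raw a [hybridization_set()].
#' @param design optional [design_probes()] table supplying probe order
#'   along the chromosome (strand, then start). Without it the row order of
#'   the intensity matrix is used as the positional order.
#' @param affinity_window odd window width (probes) of the running median.
#' @param polish_tol,polish_maxiter median-polish convergence controls.
#' @return list of class `probe_profile_set` with elements `profiles`
#'   (probe x sample), `affinity_hat`, `shift_hat`, `residual`, `qc`.
#' @export
estimate_probe_profiles <- function(raw, design = NULL, affinity_window = 3L,
                                    polish_tol = 1e-9, polish_maxiter = 20L) {
  stopifnot(inherits(raw, "hyb_set"))
  y <- raw$intensities
  samples <- raw$samples
  if (nrow(y) < 2 || ncol(y) < 2) stopf("need >= 2 probes and >= 2 samples")
  qc <- list(dropped_probes = character(0))
  all_na <- apply(y, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    warnf("dropping %d all-missing probe row(s)", sum(all_na))
    qc$dropped_probes <- rownames(y)[all_na]
    y <- y[!all_na, , drop = FALSE]
  }
  P <- nrow(y); H <- ncol(y)
  cond <- interaction(samples$condition, samples$iptg, drop = TRUE)

  # per-probe condition medians, broadcast back to samples
  cond_med <- vapply(levels(cond), function(cl)
    apply(y[, cond == cl, drop = FALSE], 1, stats::median), numeric(P))
  dev <- y - cond_med[, as.integer(cond), drop = FALSE]

  # median polish of the deviations: column effects are the shifts
  mp <- stats::medpolish(dev, eps = polish_tol, maxiter = polish_maxiter,
                         trace.iter = FALSE, na.rm = TRUE)
  s_hat <- mp$overall + mp$col

  y2 <- sweep(y, 2, s_hat)

  ord <- if (!is.null(design)) {
    m <- match(rownames(y), design$id)
    if (anyNA(m)) stopf("intensity rows missing from the probe design")
    order(design$strand[m], design$start[m])
  } else seq_len(P)
  ref <- y2
  k <- as.integer(affinity_window)
  if (k %% 2L == 0L) k <- k + 1L
  if (P > k) {
    str_of <- if (!is.null(design)) design$strand[match(rownames(y), design$id)][ord]
              else rep("+", P)
    for (h in seq_len(H)) {
      v <- y2[ord, h]
      sm <- v
      for (st in unique(str_of)) {
        i <- which(str_of == st)
        if (length(i) > k) sm[i] <- stats::runmed(v[i], k, endrule = "median")
      }
      ref[ord, h] <- sm
    }
  }
  a_hat <- apply(y2 - ref, 1, stats::median)
  a_hat <- a_hat - stats::median(a_hat)
  s_hat <- s_hat - stats::median(s_hat)

  # per-sample estimated expression: input minus the fitted nuisance terms,
  # so replicate-level variation survives for the downstream linear model
  profiles <- sweep(sweep(y, 1, a_hat), 2, s_hat)
  prof_c <- vapply(levels(cond), function(cl)
    apply(profiles[, cond == cl, drop = FALSE], 1, stats::median), numeric(P))
  prof_c <- matrix(prof_c, nrow = P)
  structure(list(profiles = profiles, affinity_hat = a_hat, shift_hat = s_hat,
                 residual = profiles - prof_c[, as.integer(cond), drop = FALSE],
                 samples = samples, qc = qc),
            class = "probe_profile_set")
}

#' @export
print.probe_profile_set <- function(x, ...) {
  cat(sprintf("<probe_profile_set> %d probes x %d samples\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Construct an aggregated expression matrix
#'
#' @param values unit x sample matrix of aggregated log2 expression.
#' @param samples sample sheet matching the columns.
#' @param n_probes integer vector: probes contributing to each unit.
#' @param low_coverage logical vector flagging units with fewer than the
#'   requested minimum of eligible probes.
#' @export
expression_matrix <- function(values, samples, n_probes = NULL,
                              low_coverage = NULL) {
  structure(list(values = values, samples = samples,
                 n_probes = n_probes %||% rep(NA_integer_, nrow(values)),
                 low_coverage = low_coverage %||% rep(FALSE, nrow(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d units x %d samples (%d low-coverage)\n",
              nrow(x$values), ncol(x$values), sum(x$low_coverage)))
  invisible(x)
}

#' Aggregate probe profiles to gene/segment expression values
#'
#' Per unit and sample, the median of the estimated probe-level values over
#' probes that lie entirely within the unit's interval on the same strand
#' and have a unique match on the genome. Units with fewer than
#' `min_probes` eligible probes are flagged (`low_coverage`), never
#' silently dropped; units with no eligible probe get `NA` values.
#'
#' @param profiles a [estimate_probe_profiles()] result.
#' @param annotation a [genome_annotation()].
#' @param design the [design_probes()] table the profiles were computed on.
#' @param min_probes minimum eligible probes per unit (default 3; shorter
#'   fragments hybridize to one or two probes and are unreliable).
#' @param kinds feature kinds to aggregate (default genes: CDS + misc_RNA).
#' @return an [expression_matrix()].
#' @export
aggregate_expression <- function(profiles, annotation, design, min_probes = 3L,
                                 kinds = c("CDS", "misc_RNA")) {
  stopifnot(inherits(profiles, "probe_profile_set"))
  feats <- annotation$features[annotation$features$kind %in% kinds, , drop = FALSE]
  if (nrow(feats) == 0) stopf("no features of kind %s", paste(kinds, collapse = "/"))
  m <- match(rownames(profiles$profiles), design$id)
  if (anyNA(m)) stopf("profile rows missing from the probe design")
  d <- design[m, , drop = FALSE]
  vals <- matrix(NA_real_, nrow(feats), ncol(profiles$profiles),
                 dimnames = list(feats$id, colnames(profiles$profiles)))
  n_probes <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    elig <- d$unique & d$strand == feats$strand[i] &
      d$start >= feats$start[i] & d$end <= feats$end[i]
    n_probes[i] <- sum(elig)
    if (n_probes[i] > 0)
      vals[i, ] <- apply(profiles$profiles[elig, , drop = FALSE], 2, stats::median)
  }
  if (all(n_probes == 0))
    stopf("no eligible probes for any unit; check strand and coordinate conventions")
  expression_matrix(vals, profiles$samples, n_probes = n_probes,
                    low_coverage = n_probes < min_probes)
}
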