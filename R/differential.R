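#' Fit the per-gene depletion linear model
#'
#' One linear model per gene over the four main experiments: expression in
#' condition i, replicate j is `x_ij = wt + deltaRNase_i + eps_ij`. This is
#' an ordinary one-way layout fitted by least squares with a pooled
#' residual variance; each RNase effect is tested against zero with a
#' two-sided t-test on the pooled residual degrees of freedom
#' (total samples - number of conditions).
#'
#' Genes with zero residual variance get `NA` p-values (flagged, not 0) and
#' are listed in the `qc` attribute.
#'
#' @param em a normalized [expression_matrix()] covering the four main
#'   conditions with >= 2 replicates each.
#' @return data.frame (one row per gene) with columns `unit`, `wt_hat`,
#'   `sigma_hat`, `dof`, and per RNase `delta_*` and `p_*`; attribute `qc`
#'   lists zero-variance and incomplete genes.
#' @export
fit_gene_models <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  mc <- main_condition(em$samples)
  conds <- c("wt", unname(RNASE_CONDITION))
  cols <- lapply(conds, function(cl) which(!is.na(mc) & mc == cl))
  names(cols) <- conds
  nn <- lengths(cols)
  if (any(nn < 2)) stopf("each main condition needs >= 2 replicates")
  vals <- em$values
  n_genes <- nrow(vals)
  means <- vapply(cols, function(ix) rowMeans(vals[, ix, drop = FALSE]),
                  numeric(n_genes))
  means <- matrix(means, nrow = n_genes, dimnames = list(rownames(vals), conds))
  sse <- rowSums(matrix(vapply(conds, function(cl) {
    rowSums((vals[, cols[[cl]], drop = FALSE] - means[, cl])^2)
  }, numeric(n_genes)), nrow = n_genes))
  dof <- sum(nn) - length(conds)
  s2 <- sse / dof
  zero_var <- is.finite(s2) & s2 <= .Machine$double.eps * 100
  incomplete <- !stats::complete.cases(vals[, unlist(cols), drop = FALSE])

  out <- data.frame(unit = rownames(vals), wt_hat = means[, "wt"],
                    sigma_hat = sqrt(s2), dof = dof, stringsAsFactors = FALSE)
  for (r in RNASES) {
    cond <- RNASE_CONDITION[[r]]
    delta <- means[, cond] - means[, "wt"]
    se <- sqrt(s2 * (1 / nn[[cond]] + 1 / nn[["wt"]]))
    p <- 2 * stats::pt(-abs(delta / se), df = dof)
    p[zero_var | incomplete] <- NA_real_
    out[[paste0("delta_", r)]] <- delta
    out[[paste0("p_", r)]] <- p
  }
  rownames(out) <- NULL
  attr(out, "qc") <- list(zero_variance = out$unit[zero_var],
                          incomplete = out$unit[incomplete])
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and
#' mapped back to input order. `NA` p-values (zero-variance genes) yield
#' `NA` q-values and do not count towards `m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
compute_qvalues <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Differential-testing configuration
#'
#' @param fdr q-value cut-off defining significance (default 0.1).
#' @param fc fold-change gates for the U/D/- profile codes (default 2 and 1.5).
#' @export
differential_config <- function(fdr = 0.1, fc = c(2.0, 1.5)) {
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1)
  if (any(fc <= 1)) stopf("fold-change gates must exceed 1")
  structure(list(fdr = fdr, fc = fc), class = "differential_config")
}

profile_code <- function(delta, q, fdr, fc) {
  code <- rep("-", length(delta))
  sig <- !is.na(q) & q <= fdr
  code[sig & delta >= log2(fc)] <- "U"
  code[sig & delta <= -log2(fc)] <- "D"
  code
}

#' Call U/D/- fold-change profiles
#'
#' A gene is called `U` (increased) for an RNase when its q-value is at or
#' below the FDR cut-off and its log2 effect estimate reaches `log2(fc)`;
#' `D` symmetrically for decreases; `-` otherwise. Profiles are computed at
#' both fold-change gates (2x and 1.5x by default).
#'
#' @param fits a [fit_gene_models()] result.
#' @param config a [differential_config()].
#' @return data.frame of class `differential_result`: per gene, per RNase
#'   `delta_*`, `p_*`, `q_*`, and `profile_*_2` / `profile_*_1.5` columns
#'   (suffix from the `fc` gates).
#' @export
call_profiles <- function(fits, config = differential_config()) {
  stopifnot(is.data.frame(fits))
  out <- fits
  for (r in RNASES) out[[paste0("q_", r)]] <- compute_qvalues(fits[[paste0("p_", r)]])
  for (fc in config$fc) {
    suff <- sub("\\.?0+$", "", format(fc))
    for (r in RNASES)
      out[[sprintf("profile_%s_%s", r, suff)]] <-
        profile_code(out[[paste0("delta_", r)]], out[[paste0("q_", r)]],
                     config$fdr, fc)
  }
  attr(out, "config") <- config
  class(out) <- c("differential_result", "data.frame")
  out
}

profile_columns <- function(result, fc = 2) {
  suff <- sub("\\.?0+$", "", format(fc))
  cols <- sprintf("profile_%s_%s", RNASES, suff)
  if (!all(cols %in% names(result)))
    stopf("profiles at fold-change %s not present", suff)
  as.matrix(result[, cols, drop = FALSE])
}

#' Cross-RNase overlap (Venn) summary
#'
#' Counts units in each of the seven disjoint regions of the three-set Venn
#' diagram of affected genes, split by direction: a unit is `up` when all
#' its significant calls are increases, `down` when all are decreases, and
#' `mixed` when it shows both increased and decreased expression depending
#' on the RNase considered.
#'
#' @param result a [call_profiles()] result.
#' @param fc which fold-change gate to use (default 2).
#' @return list of class `venn_summary`: `regions` data.frame
#'   (`region`, `up`, `down`, `mixed`, `total`) and `total_affected`.
#' @export
overlap_sets <- function(result, fc = 2) {
  prof <- profile_columns(result, fc)
  colnames(prof) <- RNASES
  hit <- prof != "-"
  affected <- rowSums(hit) > 0
  region_names <- c("III", "J1", "Y", "III&J1", "III&Y", "J1&Y", "III&J1&Y")
  key <- apply(hit, 1, function(z) paste(RNASES[z], collapse = "&"))
  dir <- apply(prof, 1, function(z) {
    z <- z[z != "-"]
    if (length(z) == 0) NA_character_
    else if (all(z == "U")) "up" else if (all(z == "D")) "down" else "mixed"
  })
  regions <- data.frame(region = region_names, up = 0L, down = 0L, mixed = 0L,
                        stringsAsFactors = FALSE)
  for (i in seq_along(region_names)) {
    in_region <- affected & key == region_names[i]
    regions$up[i] <- sum(in_region & dir == "up", na.rm = TRUE)
    regions$down[i] <- sum(in_region & dir == "down", na.rm = TRUE)
    regions$mixed[i] <- sum(in_region & dir == "mixed", na.rm = TRUE)
  }
  regions$total <- regions$up + regions$down + regions$mixed
  structure(list(regions = regions, total_affected = sum(affected)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> %d units affected by >= 1 RNase\n", x$total_affected))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Assign the primary RNase per unit
#'
#' Among an RNase-affected unit's significant increases, the depletion with
#' the largest log2 effect wins; exact ties break by the fixed order
#' Y > J1 > III. Units with only significant decreases are labelled
#' `"down"`; unaffected units `"none"`.
#'
#' @param result a [call_profiles()] result.
#' @param fc which fold-change gate to use (default 2).
#' @return character vector (one label per unit, named by unit id).
#' @export
assign_primary_rnase <- function(result, fc = 2) {
  prof <- profile_columns(result, fc)
  colnames(prof) <- RNASES
  deltas <- as.matrix(result[, paste0("delta_", RNASES), drop = FALSE])
  tie_order <- c(Y = 1L, J1 = 2L, III = 3L)
  out <- vapply(seq_len(nrow(prof)), function(i) {
    ups <- RNASES[prof[i, ] == "U"]
    if (length(ups) > 0) {
      d <- deltas[i, paste0("delta_", ups)]
      best <- ups[d == max(d)]
      best[order(tie_order[best])][1]
    } else if (any(prof[i, ] == "D")) "down" else "none"
  }, character(1))
  names(out) <- result$unit
  out
}
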