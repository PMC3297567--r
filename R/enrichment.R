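#' Read or build a functional-category table
#'
#' Long-format mapping from hierarchical category paths (levels separated
#' by " * ") to member gene ids. Categories may overlap; empty categories
#' are allowed in the input and skipped at test time with a warning.
#'
#' @param x data.frame with columns `category` and `gene`, or a path to a
#'   two-column TSV with that header.
#' @return data.frame of class `category_table`.
#' @export
category_table <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  if (!all(c("category", "gene") %in% names(x)))
    stopf("category table needs 'category' and 'gene' columns")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  class(x) <- c("category_table", "data.frame")
  x
}

#' Functional-category enrichment screen
#'
#' For each category, the composition of differential calls (%Up, %-,
#' %Down at the 2x / FDR<=0.1 profile) under one RNase, a two-sided Fisher
#' exact test of the 2x2 table (in-category vs rest, flagged vs not, for
#' the stated direction), and a Bonferroni significance flag at level
#' `alpha` over the number of categories examined. Over/under-
#' representation codes follow the `+Up`/`-Up`/`+Down`/`-Down` convention.
#'
#' @param result a [call_profiles()] result, or any data.frame with a
#'   `unit` column and the profile column for the requested RNase.
#' @param categories a [category_table()].
#' @param rnase one of `"III"`, `"J1"`, `"Y"`.
#' @param direction `"up"` or `"down"`.
#' @param alpha family-wise level before Bonferroni division (default 0.05).
#' @param fc fold-change gate of the profile used (default 2).
#' @param n_categories number of categories examined for the Bonferroni
#'   correction; defaults to the number of distinct categories in `categories`.
#' @return data.frame of class `enrichment_table`: per category `n_genes`,
#'   `pct_up`, `pct_unchanged`, `pct_down`, `n_flagged`, `odds_ratio`, `p`,
#'   `significant`, `code`.
#' @export
category_enrichment <- function(result, categories, rnase = "Y",
                                direction = c("up", "down"), alpha = 0.05,
                                fc = 2, n_categories = NULL) {
  direction <- match.arg(direction)
  if (!rnase %in% RNASES) stopf("unknown rnase '%s'", rnase)
  stopifnot(is.data.frame(categories))
  suff <- sub("\\.?0+$", "", format(fc))
  pcol <- sprintf("profile_%s_%s", rnase, suff)
  if (!pcol %in% names(result)) stopf("column '%s' not found in result", pcol)
  prof <- result[[pcol]]
  names(prof) <- result$unit
  genes <- result$unit
  target <- if (direction == "up") "U" else "D"
  flagged <- prof == target
  N <- length(genes)
  K <- sum(flagged)

  cats <- unique(categories$category)
  m <- n_categories %||% length(cats)
  rows <- list()
  for (cat in cats) {
    members <- intersect(unique(categories$gene[categories$category == cat]), genes)
    n_in <- length(members)
    if (n_in == 0) {
      warnf("skipping empty category '%s'", cat)
      next
    }
    k <- sum(flagged[members])
    tab <- matrix(c(k, n_in - k, K - k, N - n_in - (K - k)), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    sig <- ft$p.value <= alpha / m
    over <- (k / n_in) > (K / N)
    code <- if (!sig) "" else paste0(if (over) "+" else "-",
                                     if (direction == "up") "Up" else "Down")
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat, n_genes = n_in,
      pct_up = 100 * sum(prof[members] == "U") / n_in,
      pct_unchanged = 100 * sum(prof[members] == "-") / n_in,
      pct_down = 100 * sum(prof[members] == "D") / n_in,
      n_flagged = k, odds_ratio = unname(ft$estimate), p = ft$p.value,
      significant = sig, code = code, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(category = character(), n_genes = integer(), pct_up = numeric(),
               pct_unchanged = numeric(), pct_down = numeric(),
               n_flagged = integer(), odds_ratio = numeric(), p = numeric(),
               significant = logical(), code = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_categories") <- m
  attr(out, "genome_rate") <- K / N
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Category table from annotation tags
#'
#' Expands the `category_tags` column of an annotation's gene features into
#' the long category-to-gene format used by [category_enrichment()].
#'
#' @param annotation a [genome_annotation()].
#' @return a [category_table()] (possibly zero rows).
#' @export
categories_from_annotation <- function(annotation) {
  f <- annotation$features
  f <- f[f$kind %in% c("CDS", "misc_RNA") & nzchar(f$category_tags), , drop = FALSE]
  if (nrow(f) == 0)
    return(category_table(data.frame(category = character(), gene = character(),
                                     stringsAsFactors = FALSE)))
  tags <- strsplit(f$category_tags, ";", fixed = TRUE)
  category_table(data.frame(category = unlist(tags),
                            gene = rep(f$id, lengths(tags)),
                            stringsAsFactors = FALSE))
}
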