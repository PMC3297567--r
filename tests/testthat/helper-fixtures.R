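# Shared fixtures and independent oracles, all built in code.

# hand-built annotation: two plus-strand genes, one minus-strand gene,
# and an antisense segment inside gene_b on the opposite strand
toy_annotation <- function(glen = 3000L) {
  feats <- data.frame(
    id = c("gene_a", "gene_b", "gene_c", "as_seg"),
    start = c(100L, 900L, 1900L, 1000L),
    end = c(600L, 1500L, 2500L, 1200L),
    strand = c("+", "+", "-", "-"),
    kind = c("CDS", "CDS", "CDS", "segment"),
    category_tags = c("catX", "catX;catY", "catY", ""),
    stringsAsFactors = FALSE)
  genome_annotation(feats, genome_length = glen)
}

# hybridization set from an explicit intensity matrix (duplicates of the
# four main conditions, no +IPTG arms unless asked)
toy_hyb <- function(y, include_plus = FALSE, truth = NULL) {
  samples <- sample_sheet(replicates = ncol(y) / if (include_plus) 7 else 4,
                          include_plus = include_plus)
  colnames(y) <- samples$sample_id
  if (is.null(rownames(y))) rownames(y) <- sprintf("p%03d", seq_len(nrow(y)))
  hybridization_set(y, samples, truth = truth)
}

# expression matrix for the four main conditions from per-condition values
toy_expression <- function(values_by_cond, ids = NULL) {
  samples <- sample_sheet(replicates = 2, include_plus = FALSE)
  stopifnot(ncol(values_by_cond) == 8)
  ids <- ids %||% sprintf("g%04d", seq_len(nrow(values_by_cond)))
  rownames(values_by_cond) <- ids
  colnames(values_by_cond) <- samples$sample_id
  expression_matrix(values_by_cond, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_features_df <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             category_tags = character(), stringsAsFactors = FALSE)
}

# independent step-up FDR oracle (never calls p.adjust)
manual_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# two-sided Fisher p by direct hypergeometric summation: sum of all table
# probabilities not exceeding the observed one (R's fisher.test convention)
hyper_fisher_p <- function(k, n_in, K, N) {
  supp <- max(0, K - (N - n_in)):min(n_in, K)
  probs <- stats::dhyper(supp, K, N - K, n_in)
  obs <- stats::dhyper(k, K, N - K, n_in)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
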