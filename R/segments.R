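#' Segment-detection configuration
#'
#' @param expressed_factor fold over the chromosome median (raw,
#'   pre-normalization) a probe must reach in at least one hybridization
#'   for "S"-type (known catalogue) segments; default 5.
#' @param new_segment_factor fold over background required of "T"-type
#'   (newly discovered) segments; default 10.
#' @param anova_alpha p-value cut-off of the segment-level one-way ANOVA
#'   F-test across the four main experiments (default 0.05).
#' @param min_probes minimum probes per segment (default 3; fragments
#'   hybridizing to one or two probes are not reliably detectable).
#' @param max_gap maximum run of sub-threshold probes bridged inside a
#'   segment (probes, default 1).
#' @param downshift_factor log2 drop between flanking probe windows that
#'   counts as an abrupt signal downshift (default 2).
#' @param shape_window probes per window when assessing boundary shape.
#' @param max_adjacency maximum distance (bases) between a segment boundary
#'   and a same-strand gene for the two to be considered contiguous
#'   (default 44, two probe spacings).
#' @param antisense_min_nt,antisense_min_frac antisense overlap floor: an
#'   opposite-strand feature is recorded when the overlap reaches
#'   `min(antisense_min_nt, antisense_min_frac * segment length)`.
#' @export
segment_config <- function(expressed_factor = 5, new_segment_factor = 10,
                           anova_alpha = 0.05, min_probes = 3L, max_gap = 1L,
                           downshift_factor = 2, shape_window = 3L,
                           max_adjacency = 44L,
                           antisense_min_nt = 50L, antisense_min_frac = 0.25) {
  if (expressed_factor <= 1 || new_segment_factor <= 1)
    stopf("expression thresholds must exceed 1")
  assert_scalar_number(anova_alpha, "anova_alpha", lower = 1e-12, upper = 1 - 1e-12)
  structure(as.list(environment()), class = "segment_config")
}

#' One-way ANOVA across the four main experiments
#'
#' Classic F-test of equal condition means for one segment's aggregated
#' expression values, computed from the between/within sums of squares.
#' Zero within-group variance gives an undefined (NA) p-value rather than
#' a spurious 0 or 1.
#'
#' @param values numeric vector of aggregated expression, one per sample.
#' @param groups factor/character of condition labels (4 conditions,
#'   >= 2 replicates each).
#' @return list `F`, `p`, `df1`, `df2`.
#' @export
segment_anova <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stopf("need >= 2 conditions")
  if (any(table(groups) < 2)) stopf("need >= 2 replicates per condition")
  n <- length(values)
  k <- nlevels(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(tabulate(groups) * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw <= .Machine$double.eps * 100 * max(1, abs(gm))) {
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# chromosome median of raw log2 intensities per hybridization, unique probes only
chromosome_median <- function(raw, design) {
  m <- match(rownames(raw$intensities), design$id)
  uniq <- design$unique[m]
  apply(raw$intensities[uniq, , drop = FALSE], 2, stats::median)
}

# maximal runs of above-threshold probes with gaps <= max_gap, as index lists
expression_runs <- function(above, max_gap, min_probes) {
  hits <- which(above)
  if (length(hits) == 0) return(list())
  grp <- cumsum(c(1L, diff(hits) > max_gap + 1L))
  runs <- unname(split(hits, grp))
  runs <- runs[vapply(runs, length, integer(1)) >= min_probes]
  lapply(runs, function(h) seq(min(h), max(h)))
}

#' Detect transcribed segments outside annotated genes
#'
#' Works on the raw (pre-normalization) intensities for the expression
#' thresholds and on the estimated probe profiles for differential
#' assessment. Maximal same-strand runs of at least `min_probes`
#' above-threshold unique probes (bridging gaps of up to `max_gap` probes)
#' that intersect no same-strand annotated gene become candidates.
#' Candidates overlapping the known segment catalogue (annotation features
#' of kind `segment`) are kept as "S" segments when their raw signal
#' reaches `expressed_factor` x the chromosome median in at least one
#' hybridization; the rest must reach `new_segment_factor` x background
#' and show differential expression between the four main experiments
#' (one-way ANOVA F-test at `anova_alpha`) to be kept as "T" segments.
#'
#' @param raw a [hybridization_set()] (raw intensities).
#' @param profiles matching [estimate_probe_profiles()] result.
#' @param annotation a [genome_annotation()].
#' @param design the probe design.
#' @param config a [segment_config()].
#' @return data.frame of class `segment_set`: `id`, `start`, `end`,
#'   `strand`, `label_prefix` (`S`/`T`), `class`, `antisense_to`
#'   (`;`-separated), `max_fold` (log2 over median), `anova_F`, `anova_p`,
#'   `n_probes`.
#' @export
detect_segments <- function(raw, profiles, annotation, design,
                            config = segment_config()) {
  stopifnot(inherits(raw, "hyb_set"), inherits(profiles, "probe_profile_set"))
  med <- chromosome_median(raw, design)
  feats <- annotation$features
  genes <- feats[feats$kind %in% c("CDS", "misc_RNA"), , drop = FALSE]
  known <- feats[feats$kind == "segment", , drop = FALSE]
  mc <- main_condition(raw$samples)
  main_cols <- which(!is.na(mc))

  m <- match(design$id, rownames(raw$intensities))
  out <- list()
  seg_id <- 0L
  for (st in c("+", "-")) {
    sel <- which(design$strand == st & design$unique & !is.na(m))
    if (length(sel) == 0) next
    sel <- sel[order(design$start[sel])]
    yr <- raw$intensities[m[sel], , drop = FALSE]
    # probe exceeds the S threshold in >= 1 hybridization (before normalization)
    above5 <- apply(sweep(yr, 2, med + log2(config$expressed_factor)) >= 0, 1, any)
    # probes overlapping a same-strand annotated gene are masked out, so an
    # expressed run ends at the gene boundary (a 5' UTR run is not swallowed
    # by its gene)
    g_same <- genes[genes$strand == st, , drop = FALSE]
    genic <- rep(FALSE, length(sel))
    for (gi in seq_len(nrow(g_same)))
      genic <- genic | (design$start[sel] < g_same$end[gi] &
                          design$end[sel] > g_same$start[gi])
    runs <- expression_runs(above5 & !genic, config$max_gap, config$min_probes)
    for (idx in runs) {
      p_sel <- sel[idx]
      s0 <- min(design$start[p_sel]); e0 <- max(design$end[p_sel])
      # a bridged gap could still swallow a genic probe; such runs are not
      # segments
      if (nrow(g_same) > 0 &&
          any(g_same$start < e0 & g_same$end > s0)) next
      max_fold <- max(sweep(yr[idx, , drop = FALSE], 2, med), na.rm = TRUE)
      agg <- apply(profiles$profiles[match(design$id[p_sel], rownames(profiles$profiles)),
                                     main_cols, drop = FALSE], 2, stats::median)
      an <- segment_anova(agg, mc[main_cols])
      is_known <- nrow(known) > 0 &&
        any(known$strand == st & known$start < e0 & known$end > s0)
      if (is_known) {
        prefix <- "S"   # catalogue segment, 5x rule already satisfied
      } else if (max_fold >= log2(config$new_segment_factor) &&
                 !is.na(an$p) && an$p <= config$anova_alpha) {
        prefix <- "T"
      } else next
      seg_id <- seg_id + 1L
      seg <- data.frame(id = sprintf("%s%04d", prefix, seg_id),
                        start = s0, end = e0, strand = st,
                        label_prefix = prefix, class = NA_character_,
                        antisense_to = "", max_fold = max_fold,
                        anova_F = an$F, anova_p = an$p,
                        n_probes = length(idx), stringsAsFactors = FALSE)
      cl <- classify_segment(seg, annotation, profiles, design, config)
      seg$class <- cl$class
      seg$antisense_to <- cl$antisense_to
      out[[length(out) + 1L]] <- seg
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(id = character(), start = integer(), end = integer(),
               strand = character(), label_prefix = character(),
               class = character(), antisense_to = character(),
               max_fold = numeric(), anova_F = numeric(), anova_p = numeric(),
               n_probes = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("segment_set", "data.frame")
  res
}

# mean profile (over samples) of a window of probes on one strand
window_level <- function(profiles, design, strand, lo, hi) {
  sel <- design$strand == strand & design$unique &
    design$start >= lo & design$end <= hi
  ids <- design$id[sel]
  ids <- ids[ids %in% rownames(profiles$profiles)]
  if (length(ids) == 0) return(NA_real_)
  mean(profiles$profiles[ids, , drop = FALSE])
}

#' Classify a transcribed segment
#'
#' Position relative to same-strand neighbouring genes and boundary signal
#' shape determine the class:
#' * contiguous with both flanking genes: `intra` (inside one operon);
#' * contiguous with the downstream gene only (in transcription direction):
#'   `5prime` (5' UTR);
#' * contiguous with the upstream gene only: a 3' class - `3prime` when the
#'   segment ends with an abrupt downshift into background, `3primePT`
#'   when a downshift exists but downstream signal stays elevated (partial
#'   termination), `3primeMT` when the signal tails off without any abrupt
#'   downshift (missing terminator);
#' * isolated: `indep` with a sharp 5' upshift and a 3' downshift
#'   (own promoter and terminator), `indepMT` with an upshift but no
#'   downshift, `inter` otherwise (between two independently transcribed
#'   genes).
#'
#' Antisense relations list every opposite-strand feature whose overlap
#' with the segment reaches `min(antisense_min_nt, antisense_min_frac *
#' segment length)`.
#'
#' @param segment one-row data.frame (`start`, `end`, `strand`).
#' @param annotation a [genome_annotation()].
#' @param profiles a [estimate_probe_profiles()] result.
#' @param design the probe design.
#' @param config a [segment_config()].
#' @return list with `class` and `antisense_to`.
#' @export
classify_segment <- function(segment, annotation, profiles, design,
                             config = segment_config()) {
  if (segment$start < 0 || segment$end > annotation$genome_length)
    stopf("segment outside genome bounds")
  st <- segment$strand
  feats <- annotation$features
  genes <- feats[feats$kind %in% c("CDS", "misc_RNA") & feats$strand == st, , drop = FALSE]
  w <- config$shape_window * attr(design, "spacing") %||% 22L
  lvl_in_left <- window_level(profiles, design, st, segment$start, segment$start + w)
  lvl_in_right <- window_level(profiles, design, st, segment$end - w, segment$end)
  lvl_out_left <- window_level(profiles, design, st, segment$start - w, segment$start)
  lvl_out_right <- window_level(profiles, design, st, segment$end, segment$end + w)

  # transcription direction: left boundary is 5' on '+', right is 5' on '-'
  if (st == "+") {
    up5 <- !is.na(lvl_out_left) &&
      (lvl_in_left - lvl_out_left) >= config$downshift_factor
    down3 <- !is.na(lvl_out_right) &&
      (lvl_in_right - lvl_out_right) >= config$downshift_factor
    lvl_after3 <- lvl_out_right
  } else {
    up5 <- !is.na(lvl_out_right) &&
      (lvl_in_right - lvl_out_right) >= config$downshift_factor
    down3 <- !is.na(lvl_out_left) &&
      (lvl_in_left - lvl_out_left) >= config$downshift_factor
    lvl_after3 <- lvl_out_left
  }

  gap_left <- gap_right <- Inf
  if (nrow(genes) > 0) {
    left <- genes[genes$end <= segment$start + config$max_adjacency, , drop = FALSE]
    if (nrow(left) > 0) gap_left <- segment$start - max(left$end)
    right <- genes[genes$start >= segment$end - config$max_adjacency, , drop = FALSE]
    if (nrow(right) > 0) gap_right <- min(right$start) - segment$end
  }
  adj_left <- gap_left <= config$max_adjacency
  adj_right <- gap_right <= config$max_adjacency
  # orient adjacency in transcription direction
  adj_upstream <- if (st == "+") adj_left else adj_right
  adj_downstream <- if (st == "+") adj_right else adj_left

  bg <- stats::median(profiles$profiles)
  cls <- if (adj_upstream && adj_downstream) {
    "intra"
  } else if (adj_downstream) {
    "5prime"
  } else if (adj_upstream) {
    if (down3) {
      if (!is.na(lvl_after3) && lvl_after3 > bg + 1) "3primePT" else "3prime"
    } else "3primeMT"
  } else {
    if (up5) {
      if (down3) "indep" else "indepMT"
    } else "inter"
  }

  opp <- feats[feats$strand != st, , drop = FALSE]
  anti <- character(0)
  if (nrow(opp) > 0) {
    ov <- pmin(opp$end, segment$end) - pmax(opp$start, segment$start)
    floor_nt <- min(config$antisense_min_nt,
                    config$antisense_min_frac * (segment$end - segment$start))
    anti <- opp$id[ov >= floor_nt]
  }
  list(class = cls, antisense_to = paste(anti, collapse = ";"))
}

#' Aggregate expression of detected segments
#'
#' Median of unique same-strand probes fully inside each segment, per
#' sample - the same rule used for genes - so segments can enter the
#' differential analysis alongside annotated genes.
#'
#' @param segments a [detect_segments()] result.
#' @param profiles a [estimate_probe_profiles()] result.
#' @param design the probe design.
#' @return an [expression_matrix()] (one row per segment).
#' @export
aggregate_segments <- function(segments, profiles, design) {
  if (nrow(segments) == 0)
    return(expression_matrix(matrix(numeric(0), 0, ncol(profiles$profiles),
                                    dimnames = list(NULL, colnames(profiles$profiles))),
                             profiles$samples, integer(0), logical(0)))
  ann <- genome_annotation(
    data.frame(id = segments$id, start = segments$start, end = segments$end,
               strand = segments$strand, kind = "segment",
               category_tags = "", stringsAsFactors = FALSE),
    genome_length = max(segments$end) + 1L)
  aggregate_expression(profiles, ann, design, kinds = "segment")
}
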