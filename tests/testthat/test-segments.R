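# Build a hybridization set over an annotation with hand-planted expressed
# regions: background 4, plus `level` log2 units over [start, end) on
# `strand`, plus `delta_rny` in the RNase Y -IPTG samples.
planted_hyb <- function(ann, design, regions = list(), sigma = 0,
                        seed = 1) {
  set.seed(seed)
  samples <- sample_sheet(replicates = 2, include_plus = FALSE)
  y <- matrix(4, nrow(design), nrow(samples),
              dimnames = list(design$id, samples$sample_id))
  for (rg in regions) {
    rows <- design$strand == rg$strand & design$start >= rg$start &
      design$end <= rg$end
    y[rows, ] <- y[rows, ] + rg$level
    if (!is.null(rg$delta_rny)) {
      cols <- samples$condition == "rny" & samples$iptg == "minus"
      y[rows, cols] <- y[rows, cols] + rg$delta_rny
    }
  }
  if (sigma > 0) y <- y + matrix(rnorm(length(y), 0, sigma), nrow(y))
  hybridization_set(y, samples)
}

bare_annotation <- function(feats = empty_features_df(), glen = 4000L) {
  genome_annotation(feats, glen)
}

test_that("a flat genome at the background median yields zero segments", {
  ann <- bare_annotation()
  d <- design_probes(ann)
  hyb <- planted_hyb(ann, d)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(nrow(segs), 0)
})

test_that("the 5x and 10x thresholds sandwich catalogue vs new segments", {
  # planted intergenic region at 8x the chromosome median, no condition
  # difference: S-like when in the catalogue, rejected as T-like otherwise
  region <- list(start = 1100, end = 1400, strand = "+", level = 3)  # 8x
  d <- design_probes(bare_annotation())
  with_catalog <- bare_annotation(data.frame(
    id = "S_known", start = 1100L, end = 1400L, strand = "+",
    kind = "segment", category_tags = "", stringsAsFactors = FALSE))
  hyb <- planted_hyb(with_catalog, d, list(region), sigma = 0.03, seed = 2)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, with_catalog, d)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$label_prefix, "S")
  expect_lt(segs$max_fold, log2(10))

  no_catalog <- bare_annotation()
  segs2 <- detect_segments(hyb, pp, no_catalog, d)
  expect_equal(nrow(segs2), 0)
})

test_that("a differential 12x segment passes the T rules with a calibrated ANOVA", {
  region <- list(start = 1100, end = 1400, strand = "+", level = 3.6,
                 delta_rny = 1)
  ann <- bare_annotation()
  d <- design_probes(ann)
  hyb <- planted_hyb(ann, d, list(region), sigma = 0.05, seed = 3)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$label_prefix, "T")
  expect_lte(segs$anova_p, 0.05)
  # planted boundaries recovered within one probe spacing
  expect_lte(abs(segs$start - 1100), 22)
  expect_lte(abs(segs$end - 1400), 22)
})

test_that("segment ANOVA matches hand-computed sums of squares", {
  values <- c(1, 1, 1, 1, 1, 1, 3, 3.2)
  groups <- rep(c("wt", "A", "B", "C"), each = 2)
  an <- segment_anova(values, groups)
  gm <- mean(values)
  means <- c(1, 1, 1, 3.1)
  ssb <- sum(2 * (means - gm)^2)
  ssw <- sum((c(3, 3.2) - 3.1)^2)
  f_manual <- (ssb / 3) / (ssw / 4)
  expect_equal(an$F, f_manual, tolerance = 1e-6)
  # independent oracle: the classical equal-variance one-way test
  ow <- oneway.test(values ~ factor(groups), var.equal = TRUE)
  expect_equal(an$F, unname(ow$statistic), tolerance = 1e-9)
  expect_equal(an$p, unname(ow$p.value), tolerance = 1e-9)

  # all values equal: undefined, flagged, not 0 or 1
  an0 <- segment_anova(rep(1, 8), groups)
  expect_true(is.na(an0$p))
  expect_error(segment_anova(1:4, c("a", "a", "b", "b")), NA)
})

test_that("segment ANOVA type-I error is near the nominal level", {
  set.seed(17)
  groups <- rep(c("wt", "A", "B", "C"), each = 2)
  n_sim <- 2000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    an <- segment_anova(rnorm(8, 0, 0.3), groups)
    rej[i] <- !is.na(an$p) && an$p <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("segments contiguous with a downstream gene classify as 5' UTR", {
  # gene at [1500, 2200) on +, expressed; UTR run [1280, 1500) feeding it
  ann <- bare_annotation(data.frame(
    id = "g1", start = 1500L, end = 2200L, strand = "+", kind = "CDS",
    category_tags = "", stringsAsFactors = FALSE))
  d <- design_probes(ann)
  regions <- list(list(start = 1280, end = 1500, strand = "+", level = 3.6,
                       delta_rny = 1),
                  list(start = 1500, end = 2200, strand = "+", level = 3.6))
  hyb <- planted_hyb(ann, d, regions, sigma = 0.05, seed = 4)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$class, "5prime")
  expect_lt(segs$end, 1501)
})

test_that("isolated segments with sharp boundaries classify as independent", {
  ann <- bare_annotation()
  d <- design_probes(ann)
  hyb <- planted_hyb(ann, d, list(list(start = 1100, end = 1400, strand = "+",
                                       level = 3.6, delta_rny = 1)),
                     sigma = 0.05, seed = 5)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(segs$class, "indep")
  # classification is deterministic
  segs2 <- detect_segments(hyb, pp, ann, d)
  expect_identical(as.data.frame(segs), as.data.frame(segs2))
})

test_that("3' segments split by boundary shape", {
  gene <- data.frame(id = "g1", start = 500L, end = 1100L, strand = "+",
                     kind = "CDS", category_tags = "", stringsAsFactors = FALSE)
  ann <- bare_annotation(gene)
  d <- design_probes(ann)
  # sharp 3' downshift after the segment
  regions <- list(list(start = 500, end = 1100, strand = "+", level = 3.6),
                  list(start = 1100, end = 1400, strand = "+", level = 3.6,
                       delta_rny = 1))
  hyb <- planted_hyb(ann, d, regions, sigma = 0.05, seed = 6)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(segs$class, "3prime")

  # no downshift: signal tails off slowly -> missing-terminator class
  ramp <- lapply(0:9, function(k) list(start = 1100 + 110 * k,
                                       end = 1210 + 110 * k, strand = "+",
                                       level = 3.6 - 0.35 * k, delta_rny = 1))
  hyb2 <- planted_hyb(ann, d, c(list(regions[[1]]), ramp), sigma = 0.05, seed = 7)
  pp2 <- estimate_probe_profiles(hyb2, d)
  segs2 <- detect_segments(hyb2, pp2, ann, d)
  expect_gte(nrow(segs2), 1)
  expect_equal(segs2$class[1], "3primeMT")
})

test_that("antisense relations follow the overlap floor (brute-force oracle)", {
  gene <- data.frame(id = "sense_gene", start = 1000L, end = 1600L,
                     strand = "-", kind = "CDS", category_tags = "",
                     stringsAsFactors = FALSE)
  ann <- bare_annotation(gene)
  d <- design_probes(ann)
  # + strand segment overlapping ~70% of its length with the - strand gene
  hyb <- planted_hyb(ann, d, list(list(start = 1400, end = 1700, strand = "+",
                                       level = 3.6, delta_rny = 1)),
                     sigma = 0.05, seed = 8)
  pp <- estimate_probe_profiles(hyb, d)
  segs <- detect_segments(hyb, pp, ann, d)
  expect_equal(nrow(segs), 1)
  expect_true(grepl("sense_gene", segs$antisense_to))
  # oracle: exhaustive interval arithmetic
  ov <- min(1600, segs$end) - max(1000, segs$start)
  floor_nt <- min(50, 0.25 * (segs$end - segs$start))
  expect_gte(ov, floor_nt)

  # an overlap below the floor is not recorded
  seg_far <- data.frame(start = 1580, end = 1900, strand = "+")
  cls <- classify_segment(seg_far, ann, pp, d)
  ov2 <- min(1600, 1900) - max(1000, 1580)
  expect_lt(ov2, min(50, 0.25 * 320))
  expect_equal(cls$antisense_to, "")
  expect_error(classify_segment(data.frame(start = -5, end = 10, strand = "+"),
                                ann, pp, d), "outside genome")
})

test_that("invalid segment configurations are rejected", {
  expect_error(segment_config(expressed_factor = 1), "exceed 1")
  expect_error(segment_config(anova_alpha = 1.2), "anova_alpha")
})
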