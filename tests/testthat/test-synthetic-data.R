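test_that("genome generation is deterministic and handles the empty case", {
  cfg <- generator_config(n_genes = 0, genome_length = 5000)
  ann <- make_genome(cfg, seed = 1)
  expect_equal(nrow(ann$features), 0)
  expect_equal(ann$genome_length, 5000L)

  cfg2 <- generator_config(n_genes = 50)
  a1 <- make_genome(cfg2, seed = 1)
  a2 <- make_genome(cfg2, seed = 1)
  expect_identical(a1, a2)
  a3 <- make_genome(cfg2, seed = 2)
  expect_false(identical(a1$features, a3$features))
})

test_that("generated genomes respect interval invariants and sizing limits", {
  ann <- make_genome(generator_config(n_genes = 80, asRNA_fraction = 0.3,
                                      utr5_fraction = 0.3), seed = 5)
  f <- ann$features
  expect_true(all(f$start >= 0 & f$start < f$end & f$end <= ann$genome_length))
  expect_false(anyDuplicated(f$id) > 0)
  expect_error(make_genome(generator_config(n_genes = 100, genome_length = 1000), 1),
               "cannot pack")
})

test_that("antisense segments overlap an opposite-strand gene (brute-force scan)", {
  ann <- make_genome(generator_config(n_genes = 50, asRNA_fraction = 0.2), seed = 7)
  f <- ann$features
  segs <- f[grepl("^asRNA", f$id), , drop = FALSE]
  expect_gte(nrow(segs), 1)
  genes <- f[f$kind != "segment", , drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    overlaps <- vapply(seq_len(nrow(genes)), function(j) {
      genes$strand[j] != segs$strand[i] &&
        genes$start[j] < segs$end[i] && genes$end[j] > segs$start[i]
    }, logical(1))
    expect_true(any(overlaps), label = sprintf("%s overlaps a gene", segs$id[i]))
  }
})

test_that("probe tiling is arithmetic with modal spacing 22", {
  ann <- genome_annotation(data.frame(id = "g1", start = 0L, end = 220L,
                                      strand = "+", kind = "CDS",
                                      category_tags = ""), 220L)
  d <- design_probes(ann, spacing = 22)
  plus <- d[d$strand == "+", ]
  expect_equal(nrow(plus), 10)
  expect_equal(plus$start, seq(0L, 198L, by = 22L))

  ann2 <- make_genome(generator_config(n_genes = 30), seed = 3)
  d2 <- design_probes(ann2)
  gaps <- diff(d2$start[d2$strand == "+"])
  expect_equal(as.integer(names(which.max(table(gaps)))), 22L)
  expect_error(design_probes(ann, spacing = 1000), "exceeds genome_length")
})

test_that("probes inside a duplicated block are flagged non-unique (substring oracle)", {
  set.seed(42)
  block <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  seqn <- paste0(left, block, mid, block, right)
  glen <- nchar(seqn)
  ann <- genome_annotation(empty_features_df(), glen, sequence = seqn)
  d <- design_probes(ann, spacing = 22, sequence = seqn)

  # oracle: exhaustive fixed substring scan over the genome
  count_occurrences <- function(pat, s) {
    n <- 0L; from <- 1L
    repeat {
      hit <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
      if (hit == -1) break
      n <- n + 1L
      from <- from + hit
    }
    n
  }
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  in_copy <- (d$start >= 300 & d$end <= 500) | (d$start >= 750 & d$end <= 950)
  expect_true(any(in_copy))
  for (i in which(in_copy)) expect_false(d$unique[i])
  # spot-check the oracle against the implementation on a sample of probes
  idx <- seq(1, nrow(d), by = 7)
  for (i in idx) {
    win <- substr(seqn, d$start[i] + 1, d$end[i])
    expected <- count_occurrences(win, seqn) == 1 &&
      count_occurrences(revcomp(win), seqn) == 0
    expect_identical(d$unique[i], expected)
  }
})

test_that("zero-noise simulation plants exact, linear effects", {
  ann <- toy_annotation()
  d <- design_probes(ann)
  noise0 <- noise_config(sigma_affinity = 0, sigma_shift = 0, sigma_resid = 0,
                         background_sd = 0, expressed_fraction = 1,
                         segment_expressed_fraction = 1)
  h0 <- simulate_expression(ann, d, effects = NULL, noise = noise0, seed = 1)
  expect_true(all(apply(h0$intensities, 1, function(r) length(unique(r)) == 1)))

  eff <- effect_spec("gene_a", "Y", 1)
  h1 <- simulate_expression(ann, d, eff, noise = noise0, seed = 1)
  probes <- d$strand == "+" & d$start >= 100 & d$end <= 600
  probes <- d$id[probes]
  wt_cols <- h1$samples$sample_id[h1$samples$condition == "wt"]
  y_cols <- h1$samples$sample_id[h1$samples$condition == "rny" & h1$samples$iptg == "minus"]
  diff1 <- mean(h1$intensities[probes, y_cols]) - mean(h1$intensities[probes, wt_cols])
  expect_equal(diff1, 1.0)

  h2 <- simulate_expression(ann, d, effect_spec("gene_a", "Y", 2), noise = noise0, seed = 1)
  diff2 <- mean(h2$intensities[probes, y_cols]) - mean(h2$intensities[probes, wt_cols])
  expect_equal(diff2, 2 * diff1)

  # +IPTG arms of the depleted strain are fully complemented: no effect
  plus_cols <- h1$samples$sample_id[h1$samples$condition == "rny" & h1$samples$iptg == "plus"]
  expect_equal(mean(h1$intensities[probes, plus_cols]),
               mean(h1$intensities[probes, wt_cols]))
})

test_that("subtracting the truth affinity reproduces the affinity-free run", {
  ann <- toy_annotation()
  d <- design_probes(ann)
  base <- noise_config(sigma_affinity = 0, sigma_shift = 0, sigma_resid = 0,
                       background_sd = 0)
  with_a <- noise_config(sigma_affinity = 0.5, sigma_shift = 0, sigma_resid = 0,
                         background_sd = 0)
  h0 <- simulate_expression(ann, d, noise = base, seed = 3)
  h1 <- simulate_expression(ann, d, noise = with_a, seed = 3)
  expect_equal(h1$intensities - h1$truth$affinity, h0$intensities)
  # truth retrievability: removing a_p and s_h recovers the noiseless signal
  expect_equal(h1$intensities - h1$truth$affinity -
                 rep(h1$truth$shift, each = nrow(h1$intensities)),
               h1$truth$expression)
})

test_that("unknown effect targets and invalid specs are rejected", {
  ann <- toy_annotation()
  d <- design_probes(ann)
  expect_error(simulate_expression(ann, d, effect_spec("nope", "Y", 1), seed = 1),
               "unknown feature")
  expect_error(effect_spec("g", "Y", 0), "non-zero")
  expect_error(effect_spec("g", "Q", 1), "rnase")
})
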