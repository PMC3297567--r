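#' Generator configuration for synthetic genomes
#'
#' Bundles the knobs of [make_genome()]. Coordinates are 0-based, half-open
#' throughout the package; GFF3 export converts to 1-based closed.
#'
#' @param n_genes number of annotated genes to place.
#' @param gene_length length range (bases) genes are drawn from, uniformly.
#' @param gap_length range of intergenic gaps (bases).
#' @param strand_prob probability a gene lands on the plus strand.
#' @param asRNA_fraction fraction of genes that receive an antisense
#'   regulatory segment on the opposite strand, contained in the gene body.
#' @param utr5_fraction fraction of genes that receive a 5' UTR segment
#'   contiguous with, and upstream of, the coding sequence.
#' @param misc_fraction fraction of genes annotated as `misc_RNA` rather
#'   than `CDS` (riboswitch-like annotated regulatory RNAs).
#' @param genome_length total chromosome length; `NULL` sizes the chromosome
#'   to fit the placed features plus a terminal gap.
#' @param category_pool optional character vector of functional-category
#'   paths; genes are tagged with 0-2 categories drawn from it.
#' @param with_sequence if `TRUE`, a random nucleotide sequence of the
#'   chromosome is attached (used for probe-uniqueness calls).
#'
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 50,
                             gene_length = c(300, 1500),
                             gap_length = c(60, 300),
                             strand_prob = 0.5,
                             asRNA_fraction = 0,
                             utr5_fraction = 0,
                             misc_fraction = 0,
                             genome_length = NULL,
                             category_pool = NULL,
                             with_sequence = FALSE) {
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  assert_scalar_number(strand_prob, "strand_prob", 0, 1)
  for (f in c(asRNA_fraction, utr5_fraction, misc_fraction))
    assert_scalar_number(f, "fraction", 0, 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = gene_length, gap_length = gap_length,
                 strand_prob = strand_prob,
                 asRNA_fraction = asRNA_fraction,
                 utr5_fraction = utr5_fraction,
                 misc_fraction = misc_fraction,
                 genome_length = genome_length,
                 category_pool = category_pool,
                 with_sequence = isTRUE(with_sequence)),
            class = "generator_config")
}

empty_features <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
              strand = character(), kind = character(),
              category_tags = character(), stringsAsFactors = FALSE)
}

#' Construct a genome annotation object
#'
#' @param features data.frame with columns `id`, `start`, `end`, `strand`
#'   (`+`/`-`), `kind` (`CDS`, `misc_RNA`, `segment`), `category_tags`
#'   (`;`-separated, possibly empty).
#' @param genome_length chromosome length in bases.
#' @param sequence optional chromosome nucleotide sequence (single string).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(features, genome_length, sequence = NULL) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) == 0 && ncol(features) == 0) features <- empty_features()
  needed <- c("id", "start", "end", "strand", "kind")
  if (!all(needed %in% names(features)))
    stopf("features must have columns: %s", paste(needed, collapse = ", "))
  if (is.null(features$category_tags)) features$category_tags <- ""
  ann <- structure(list(features = features,
                        genome_length = as.integer(genome_length),
                        sequence = sequence),
                   class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  f <- ann$features
  if (anyDuplicated(f$id)) stopf("feature ids must be unique")
  if (nrow(f) > 0) {
    bad <- f$start < 0 | f$start >= f$end | f$end > ann$genome_length
    if (any(bad))
      stopf("invalid feature interval(s): %s", paste(f$id[bad], collapse = ", "))
    if (!all(f$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    if (!all(f$kind %in% c("CDS", "misc_RNA", "segment")))
      stopf("kind must be CDS, misc_RNA or segment")
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d features, %d bp%s\n",
              nrow(x$features), x$genome_length,
              if (is.null(x$sequence)) "" else " (+sequence)"))
  invisible(x)
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping genes along a chromosome with random
#' intergenic gaps, then decorates a configurable fraction of them with
#' antisense segments (opposite strand, contained in the gene body) and
#' 5' UTR segments (same strand, contiguous with the gene start). The same
#' seed and config reproduce the annotation exactly.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a [genome_annotation()] object.
#' @export
make_genome <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_genes
  if (n == 0) {
    return(genome_annotation(empty_features(),
                             genome_length = config$genome_length %||% 0L))
  }
  lens <- round(stats::runif(n, config$gene_length[1], config$gene_length[2]))
  gaps <- round(stats::runif(n + 1, config$gap_length[1], config$gap_length[2]))
  starts <- cumsum(gaps[seq_len(n)] + c(0, lens[-n]))
  ends <- starts + lens
  glen <- config$genome_length
  if (is.null(glen)) {
    glen <- ends[n] + gaps[n + 1]
  } else if (ends[n] + gaps[n + 1] > glen) {
    stopf("cannot pack %d genes into genome_length=%d (need %d)",
          n, glen, ends[n] + gaps[n + 1])
  }
  strand <- ifelse(stats::runif(n) < config$strand_prob, "+", "-")
  kind <- rep("CDS", n)
  n_misc <- floor(config$misc_fraction * n)
  if (n_misc > 0) kind[sample.int(n, n_misc)] <- "misc_RNA"
  tags <- rep("", n)
  if (!is.null(config$category_pool)) {
    for (i in seq_len(n)) {
      k <- sample(0:2, 1)
      if (k > 0)
        tags[i] <- paste(sample(config$category_pool, min(k, length(config$category_pool))),
                         collapse = ";")
    }
  }
  feats <- data.frame(id = sprintf("gene_%04d", seq_len(n)),
                      start = as.integer(starts), end = as.integer(ends),
                      strand = strand, kind = kind, category_tags = tags,
                      stringsAsFactors = FALSE)

  extras <- list()
  n_as <- floor(config$asRNA_fraction * n)
  if (n_as > 0) {
    idx <- sample.int(n, n_as)
    for (j in seq_along(idx)) {
      i <- idx[j]
      L <- max(50L, as.integer(round(stats::runif(1, 0.3, 0.7) * lens[i])))
      s0 <- feats$start[i] + sample.int(max(1L, lens[i] - L), 1) - 1L
      extras[[length(extras) + 1L]] <- data.frame(
        id = sprintf("asRNA_%04d", j), start = s0, end = s0 + L,
        strand = if (feats$strand[i] == "+") "-" else "+",
        kind = "segment", category_tags = "", stringsAsFactors = FALSE)
    }
  }
  n_utr <- floor(config$utr5_fraction * n)
  if (n_utr > 0) {
    idx <- sample.int(n, n_utr)
    for (j in seq_along(idx)) {
      i <- idx[j]
      room <- gaps[i] - 2L  # gap upstream of gene i (placement order = coordinate order)
      if (room < 40L) next
      L <- min(as.integer(round(stats::runif(1, 60, 200))), room)
      utr <- if (feats$strand[i] == "+") {
        data.frame(id = sprintf("utr5_%04d", j),
                   start = feats$start[i] - L, end = feats$start[i],
                   strand = "+", kind = "segment", category_tags = "",
                   stringsAsFactors = FALSE)
      } else {
        # for minus-strand genes the 5' side is the high-coordinate side;
        # use the downstream gap instead
        room2 <- gaps[i + 1L] - 2L
        if (room2 < 40L) next
        L2 <- min(L, room2)
        data.frame(id = sprintf("utr5_%04d", j),
                   start = feats$end[i], end = feats$end[i] + L2,
                   strand = "-", kind = "segment", category_tags = "",
                   stringsAsFactors = FALSE)
      }
      extras[[length(extras) + 1L]] <- utr
    }
  }
  if (length(extras) > 0) feats <- rbind(feats, do.call(rbind, extras))
  feats <- feats[order(feats$start, feats$id), , drop = FALSE]
  rownames(feats) <- NULL
  seqn <- NULL
  if (config$with_sequence)
    seqn <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = "")
  genome_annotation(feats, genome_length = glen, sequence = seqn)
}

#' Design a two-strand tiling probe set
#'
#' Tiles both strands of the chromosome with probes of fixed length at a
#' fixed start-to-start spacing (default 22 nt, the array's resolution).
#' Probes whose genomic window is not unique on the chromosome are flagged
#' `unique = FALSE` but never dropped.
#'
#' @param annotation a [genome_annotation()].
#' @param spacing start-to-start distance between consecutive probes (bases).
#' @param probe_length probe length in bases (default equal to `spacing`).
#' @param sequence chromosome sequence used for uniqueness calls; defaults to
#'   the annotation's sequence if present. A probe is unique when its window
#'   string occurs exactly once on the forward strand and never on the
#'   reverse complement.
#' @param repeat_regions optional data.frame (`start`, `end`, 0-based
#'   half-open) of known repeated regions; probes fully inside any region
#'   are flagged non-unique without sequence matching.
#' @return a `probe_design` data.frame (`id`, `start`, `end`, `strand`,
#'   `unique`) sorted by (strand, start), with attributes `spacing` and
#'   `probe_length`.
#' @export
design_probes <- function(annotation, spacing = 22L, probe_length = spacing,
                          sequence = annotation$sequence,
                          repeat_regions = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  assert_scalar_number(spacing, "spacing", lower = 1)
  glen <- annotation$genome_length
  if (spacing > glen) stopf("spacing (%d) exceeds genome_length (%d)", spacing, glen)
  if (probe_length > glen) stopf("probe_length exceeds genome_length")
  starts <- seq.int(0L, glen - probe_length, by = spacing)
  one <- function(str, tag) {
    data.frame(id = sprintf("probe_%s_%05d", tag, seq_along(starts)),
               start = as.integer(starts),
               end = as.integer(starts + probe_length),
               strand = str, unique = TRUE, stringsAsFactors = FALSE)
  }
  probes <- rbind(one("+", "p"), one("-", "m"))
  if (!is.null(repeat_regions) && nrow(repeat_regions) > 0) {
    for (i in seq_len(nrow(repeat_regions))) {
      inside <- probes$start >= repeat_regions$start[i] &
        probes$end <= repeat_regions$end[i]
      probes$unique[inside] <- FALSE
    }
  }
  if (!is.null(sequence)) {
    genome <- Biostrings::DNAString(sequence)
    rc <- Biostrings::reverseComplement(genome)
    for (i in seq_len(nrow(probes))) {
      win <- Biostrings::subseq(genome, probes$start[i] + 1L, probes$end[i])
      n_fwd <- Biostrings::countPattern(win, genome)
      n_rev <- Biostrings::countPattern(win, rc)
      if (n_fwd != 1L || n_rev != 0L) probes$unique[i] <- FALSE
    }
  }
  probes <- probes[order(probes$strand, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  structure(probes, spacing = as.integer(spacing),
            probe_length = as.integer(probe_length),
            class = c("probe_design", "data.frame"))
}
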