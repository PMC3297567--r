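# Readers/writers for the standard formats. Internal coordinates are
# 0-based half-open; GFF3 and browser formats are converted at the border.

SEQNAME <- "chromosome"

annotation_to_granges <- function(ann) {
  f <- ann$features
  gr <- GenomicRanges::GRanges(
    seqnames = SEQNAME,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$kind
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$category <- f$category_tags
  S4Vectors::mcols(gr)$phase <- ifelse(f$kind == "CDS", 0L, NA_integer_)
  GenomeInfoDb::seqlengths(gr) <- ann$genome_length
  gr
}

#' Write a genome annotation as GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  gr <- annotation_to_granges(annotation)
  rtracklayer::export(gr, path, format = "gff3")
  # rewrite the header: record the chromosome length and drop the date
  # pragma so identical inputs give byte-identical files
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date")]
  ver <- which(startsWith(lines, "##gff-version"))[1]
  lines <- append(lines, sprintf("##sequence-region %s 1 %d", SEQNAME,
                                 annotation$genome_length), after = ver)
  writeLines(lines, path)
  invisible(path)
}

#' Load a genome annotation from GFF3
#'
#' Validates the file line by line first (malformed lines are reported
#' with their line number), then parses with rtracklayer and converts the
#' 1-based closed coordinates to the internal 0-based half-open system.
#'
#' @param path GFF3 file.
#' @return a [genome_annotation()].
#' @export
load_annotation <- function(path) {
  lines <- readLines(path)
  glen <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##sequence-region")) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) >= 4) glen <- as.integer(parts[4])
      next
    }
    if (startsWith(ln, "#") || !nzchar(trimws(ln))) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9)
      stopf("GFF3 parse error at line %d: expected 9 tab-separated fields, got %d",
            i, length(fields))
    s <- suppressWarnings(as.integer(fields[4]))
    e <- suppressWarnings(as.integer(fields[5]))
    if (is.na(s) || is.na(e))
      stopf("GFF3 parse error at line %d: non-numeric coordinates", i)
    if (e < s)
      stopf("GFF3 parse error at line %d: end (%d) < start (%d)", i, e, s)
    if (!fields[7] %in% c("+", "-", ".", "?"))
      stopf("GFF3 parse error at line %d: bad strand '%s'", i, fields[7])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  cat_tags <- if ("category" %in% names(mc)) {
    v <- as.character(mc$category)
    ifelse(is.na(v), "", v)
  } else ""
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("feature_%04d", seq_along(gr))
  feats <- data.frame(id = ids,
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      kind = as.character(mc$type),
                      category_tags = cat_tags,
                      stringsAsFactors = FALSE)
  if (is.na(glen)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    glen <- if (length(sl) && !is.na(sl[1])) sl[1] else max(feats$end)
  }
  genome_annotation(feats, genome_length = glen)
}

#' Write a probe design as BED6
#'
#' The score column carries uniqueness (1 unique, 0 not).
#'
#' @param design a [design_probes()] result.
#' @param path output file.
#' @export
write_probe_design <- function(design, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = SEQNAME,
    ranges = IRanges::IRanges(start = design$start + 1L, end = design$end),
    strand = design$strand)
  S4Vectors::mcols(gr)$name <- design$id
  S4Vectors::mcols(gr)$score <- as.integer(design$unique)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a probe design from BED6
#'
#' @param path BED file written by [write_probe_design()].
#' @return a `probe_design` data.frame; spacing is recovered as the modal
#'   start-to-start difference on the plus strand.
#' @export
read_probe_design <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  d <- data.frame(id = S4Vectors::mcols(gr)$name,
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  unique = S4Vectors::mcols(gr)$score > 0,
                  stringsAsFactors = FALSE)
  d <- d[order(d$strand, d$start), , drop = FALSE]
  rownames(d) <- NULL
  dd <- diff(d$start[d$strand == "+"])
  spacing <- if (length(dd) > 0) as.integer(names(sort(table(dd), decreasing = TRUE))[1])
             else NA_integer_
  structure(d, spacing = spacing,
            probe_length = as.integer(stats::median(d$end - d$start)),
            class = c("probe_design", "data.frame"))
}

#' Write a hybridization set as TSV (+ sample-metadata sidecar)
#'
#' @param hyb a [hybridization_set()].
#' @param path intensity TSV path; sample metadata goes to
#'   `<path>.samples.tsv`. The truth block is not serialized.
#' @export
write_hybridization <- function(hyb, path) {
  df <- data.frame(probe_id = rownames(hyb$intensities), hyb$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hyb$samples, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hybridization set written by [write_hybridization()]
#' @param path intensity TSV path.
#' @export
read_hybridization <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.delim(paste0(path, ".samples.tsv"),
                               stringsAsFactors = FALSE)
  y <- as.matrix(df[, -1, drop = FALSE])
  rownames(y) <- df$probe_id
  hybridization_set(y, samples)
}

#' Export genome-browser tracks
#'
#' Per-strand bedGraph tracks of mean normalized expression per condition
#' and of the -IPTG vs wild-type log2 ratio per RNase, from unique probes
#' only (non-unique probes are omitted). A JSON sidecar records the
#' chromosome-median reference level and its 5x and 10x lines.
#'
#' @param profiles a [estimate_probe_profiles()] result.
#' @param raw the matching [hybridization_set()] (for the reference levels).
#' @param design the probe design.
#' @param outdir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
export_tracks <- function(profiles, raw, design, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- match(rownames(profiles$profiles), design$id)
  d <- design[m, , drop = FALSE]
  mc <- main_condition(profiles$samples)
  files <- character(0)
  med <- stats::median(chromosome_median(raw, design))
  glen <- max(design$end)
  for (st in c("+", "-")) {
    tag <- if (st == "+") "plus" else "minus"
    sel <- which(d$strand == st & d$unique)
    if (length(sel) == 0) next
    sel <- sel[order(d$start[sel])]
    gr0 <- GenomicRanges::GRanges(
      SEQNAME, IRanges::IRanges(start = d$start[sel] + 1L, end = d$end[sel]))
    GenomeInfoDb::seqlengths(gr0) <- glen
    for (cond in c("wt", unname(RNASE_CONDITION))) {
      cols <- which(!is.na(mc) & mc == cond)
      gr <- gr0
      S4Vectors::mcols(gr)$score <-
        rowMeans(profiles$profiles[sel, cols, drop = FALSE])
      f <- file.path(outdir, sprintf("expression_%s_%s.bedGraph", cond, tag))
      rtracklayer::export(gr, f, format = "bedGraph")
      files <- c(files, f)
    }
    wt_cols <- which(!is.na(mc) & mc == "wt")
    for (r in RNASES) {
      cols <- which(!is.na(mc) & mc == RNASE_CONDITION[[r]])
      gr <- gr0
      S4Vectors::mcols(gr)$score <-
        rowMeans(profiles$profiles[sel, cols, drop = FALSE]) -
        rowMeans(profiles$profiles[sel, wt_cols, drop = FALSE])
      f <- file.path(outdir, sprintf("log2ratio_RNase%s_%s.bedGraph", r, tag))
      rtracklayer::export(gr, f, format = "bedGraph")
      files <- c(files, f)
    }
  }
  sidecar <- file.path(outdir, "reference_levels.json")
  jsonlite::write_json(list(chromosome_median = med,
                            level_5x = med + log2(5),
                            level_10x = med + log2(10)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  files <- c(files, sidecar)
  invisible(files)
}
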