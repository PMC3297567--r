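#' Pipeline configuration
#'
#' Bundles either paths to on-disk inputs (GFF3 annotation, BED probe
#' design, TSV intensities) or a generator configuration, together with
#' the per-stage configurations and a seed.
#'
#' @param annotation_path,design_path,intensities_path input files; leave
#'   `NULL` to generate synthetic data instead.
#' @param categories_path optional TSV functional-category map.
#' @param generator a [generator_config()] used when no paths are given.
#' @param effects planted effects for the generator.
#' @param noise a [noise_config()].
#' @param normalization a [normalization_config()].
#' @param differential a [differential_config()].
#' @param segment a [segment_config()].
#' @param seed integer seed.
#' @param outdir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation_path = NULL, design_path = NULL,
                            intensities_path = NULL, categories_path = NULL,
                            generator = generator_config(),
                            effects = NULL,
                            noise = noise_config(),
                            normalization = normalization_config(),
                            differential = differential_config(),
                            segment = segment_config(),
                            seed = 1L, outdir = tempfile("rnasedep_run_")) {
  paths <- c(annotation_path, design_path, intensities_path, categories_path)
  for (p in paths) if (!is.null(p) && !file.exists(p)) stopf("file not found: %s", p)
  structure(as.list(environment())[setdiff(names(formals()), "paths")],
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; nested
#' maps `generator`, `noise`, `normalization`, `differential`, `segment`
#' override the corresponding defaults field by field.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, overrides) {
    if (is.null(overrides)) return(ctor())
    do.call(ctor, overrides)
  }
  effects <- NULL
  if (!is.null(y$effects))
    effects <- do.call(rbind, lapply(y$effects, function(e) {
      # YAML 1.1 reads a bare Y as boolean TRUE; map it back
      rnase <- if (isTRUE(e$rnase)) "Y" else as.character(e$rnase)
      effect_spec(e$gene_id, rnase, e$delta_log2)
    }))
  pipeline_config(
    annotation_path = y$annotation_path, design_path = y$design_path,
    intensities_path = y$intensities_path, categories_path = y$categories_path,
    generator = build(generator_config, y$generator),
    effects = effects,
    noise = build(noise_config, y$noise),
    normalization = build(normalization_config, y$normalization),
    differential = build(differential_config, y$differential),
    segment = build(segment_config, y$segment),
    seed = y$seed %||% 1L,
    outdir = y$outdir %||% tempfile("rnasedep_run_"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

result_table <- function(result) {
  suffixes <- sub("profile_III_", "",
                  grep("^profile_III_", names(result), value = TRUE))
  out <- data.frame(unit = result$unit, WT = result$wt_hat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (r in RNASES) out[[paste0("dRNase", r)]] <- result[[paste0("delta_", r)]]
  for (r in RNASES) out[[paste0("Pval_RNase", r)]] <- result[[paste0("p_", r)]]
  for (r in RNASES) out[[paste0("Qval_RNase", r)]] <- result[[paste0("q_", r)]]
  for (s in suffixes)
    for (r in RNASES)
      out[[sprintf("Profile%s_%s", r, s)]] <- result[[sprintf("profile_%s_%s", r, s)]]
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full depletion analysis pipeline
#'
#' Generate (or load) -> estimate probe profiles -> aggregate -> normalize
#' -> per-gene tests with q-values and profiles -> Venn summary and primary
#' RNase -> segment detection -> enrichment -> result tables and browser
#' tracks. All outputs are plain text with stable column order; identical
#' seeds give byte-identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the intermediate objects
#'   (`annotation`, `design`, `raw`, `profiles`, `expression`, `normalized`,
#'   `result`, `venn`, `primary`, `segments`, `enrichment`, `files`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$intensities_path)) {
    annotation <- stage("generate", make_genome(config$generator, config$seed))
    design <- stage("generate", design_probes(annotation))
    raw <- stage("generate",
                 simulate_expression(annotation, design, config$effects,
                                     noise = config$noise,
                                     seed = derive_seed(config$seed, 1L)))
  } else {
    annotation <- stage("load", load_annotation(config$annotation_path))
    design <- stage("load", read_probe_design(config$design_path))
    raw <- stage("load", read_hybridization(config$intensities_path))
  }

  profiles <- stage("estimate", estimate_probe_profiles(raw, design))
  expression <- stage("aggregate",
                      aggregate_expression(profiles, annotation, design))
  lv <- stage("normalize",
              select_least_variant_set(expression, config$normalization))
  model <- stage("normalize",
                 fit_normalization(expression, lv, config$normalization))
  normalized <- stage("normalize", apply_normalization(expression, model))

  segs <- stage("segments",
                detect_segments(raw, profiles, annotation, design, config$segment))
  seg_expr <- stage("segments", aggregate_segments(segs, profiles, design))
  if (nrow(seg_expr$values) > 0) {
    seg_norm <- stage("segments", apply_normalization(seg_expr, model))
    all_values <- rbind(normalized$values, seg_norm$values)
    combined <- expression_matrix(all_values, normalized$samples,
                                  c(normalized$n_probes, seg_norm$n_probes),
                                  c(normalized$low_coverage, seg_norm$low_coverage))
  } else combined <- normalized

  fits <- stage("test", fit_gene_models(combined))
  result <- stage("test", call_profiles(fits, config$differential))
  venn <- stage("test", overlap_sets(result))
  primary <- stage("test", assign_primary_rnase(result))

  categories <- if (!is.null(config$categories_path))
    stage("enrich", category_table(config$categories_path))
  else categories_from_annotation(annotation)
  enrichment <- list()
  if (nrow(categories) > 0) {
    for (r in RNASES)
      for (dirn in c("up", "down"))
        enrichment[[paste0(r, "_", dirn)]] <-
          stage("enrich", category_enrichment(result, categories, rnase = r,
                                              direction = dirn,
                                              fc = max(config$differential$fc)))
  }

  files <- character(0)
  files <- c(files, write_tsv(result_table(result),
                              file.path(config$outdir, "results_genes.tsv")))
  seg_out <- as.data.frame(segs)
  files <- c(files, write_tsv(seg_out, file.path(config$outdir, "segments.tsv")))
  venn_out <- rbind(venn$regions,
                    data.frame(region = "total_affected", up = NA, down = NA,
                               mixed = NA, total = venn$total_affected))
  files <- c(files, write_tsv(venn_out, file.path(config$outdir, "venn_summary.tsv")))
  files <- c(files, write_tsv(data.frame(unit = names(primary), primary = primary,
                                         stringsAsFactors = FALSE),
                              file.path(config$outdir, "primary_rnase.tsv")))
  for (nm in names(enrichment))
    files <- c(files, write_tsv(enrichment[[nm]],
                                file.path(config$outdir,
                                          sprintf("enrichment_%s.tsv", nm))))
  files <- c(files, export_tracks(profiles, raw, design,
                                  file.path(config$outdir, "tracks")))
  run_info <- list(package = "rnasedep",
                   version = as.character(utils::packageVersion("rnasedep")),
                   seed = config$seed,
                   n_units = nrow(combined$values),
                   n_segments = nrow(segs),
                   lv_set_size = length(lv),
                   fdr = config$differential$fdr,
                   fc = config$differential$fc)
  info_path <- file.path(config$outdir, "run_info.json")
  jsonlite::write_json(run_info, info_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, info_path)

  invisible(list(annotation = annotation, design = design, raw = raw,
                 profiles = profiles, expression = expression,
                 normalized = combined, lv_set = lv, result = result,
                 venn = venn, primary = primary, segments = segs,
                 enrichment = enrichment, files = files))
}
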