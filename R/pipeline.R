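# End-to-end pipeline driver: simulate (or load) reads, align, call,
# annotate, aggregate, filter, quantify isoforms, classify interfaces, and
# write the cohort report. A single configuration carries every threshold
# with the study defaults (2% variant retention, >1% isoform inclusion).

default_pipeline_thresholds <- function() {
  list(min_carrier_fraction = 0.02,
       min_isoform_abundance = 0.01,
       isoform_carrier_threshold = 0.01,
       adjacency_window = 2L,
       min_score_per_base = 1,
       caller = default_caller_params())
}

#' Read a pipeline configuration file
#'
#' YAML with fields `gene_config` (path, or `"packaged"` for the packaged
#' gene set), `seed`, either `cohort` (simulation: `n_animals`, `depth`,
#' `error_rate`, `indel_error_rate`, `genes`, `variants_from_table` or a
#' `variants` list, `isoform_mixture`) or `reads_dir`, optional
#' `quantify_isoforms` (gene ids), `thresholds` overrides, and `out_dir`.
#'
#' @param path Config YAML path.
#' @return Config list (class `fcgr_pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "fcgr_pipeline_config")
}

resolve_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full cohort pipeline
#'
#' Stages, in order: load gene models, simulate reads (or load FASTQ),
#' align + call genotypes, annotate coding effects, aggregate carriers,
#' apply the retention filter, quantify isoform abundances, classify
#' Fc-contact interfaces, and assemble (optionally write) the report.
#' Deterministic for a fixed seed. Counts at every filter boundary are
#' logged via [message()].
#'
#' @param config A config list or path to a YAML config (see
#'   [read_pipeline_config()]).
#' @return Object of class `fcgr_report`: `variant_records` (retained,
#'   annotated cohort records), `variant_records_all` (pre-filter),
#'   `calls` (per-animal), `abundance` (per-gene matrices),
#'   `isoform_carriers`, `truth` (when simulated), `metadata`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  thr <- utils::modifyList(default_pipeline_thresholds(),
                           config$thresholds %||% list())
  seed <- config$seed %||% 1L

  genes <- resolve_stage("gene-models", {
    gc <- config$gene_config %||% "packaged"
    if (identical(gc, "packaged")) fcgr_gene_set()
    else load_gene_config(if (is.null(config$config_path)) gc
                          else file.path(dirname(config$config_path), gc))
  })

  sim <- NULL
  reads <- resolve_stage("reads", {
    if (!is.null(config$reads_dir)) {
      read_cohort_reads(config$reads_dir)
    } else if (!is.null(config$cohort)) {
      co <- config$cohort
      variants <- if (isTRUE(co$variants_from_table)) {
        tab <- fcgr_reported_variants()
        if (!is.null(co$genes)) tab <- tab[tab$gene_id %in% co$genes, ]
        tab
      } else if (!is.null(co[["variants"]])) {  # exact: avoid partial matching
        do.call(rbind, lapply(co[["variants"]], as.data.frame))
      } else NULL
      spec <- if (!is.null(variants) && !is.null(variants$Variant)) {
        cohort_spec_from_table(variants, n_animals = co$n_animals %||% 206L,
                               depth = co$depth %||% 50L,
                               error_rate = co$error_rate %||% 0.002,
                               indel_error_rate = co$indel_error_rate %||% 1e-4,
                               isoform_mixture = co$isoform_mixture %||% list(),
                               seed = seed)
      } else {
        cohort_spec(n_animals = co$n_animals %||% 206L, variants = variants,
                    isoform_mixture = co$isoform_mixture %||% list(),
                    depth = co$depth %||% 50L,
                    error_rate = co$error_rate %||% 0.002,
                    indel_error_rate = co$indel_error_rate %||% 1e-4,
                    seed = seed)
      }
      gene_sub <- if (!is.null(co$genes)) genes[co$genes] else genes
      sim <- simulate_cohort(spec, gene_sub)
      sim$reads
    } else stop("config needs either 'cohort' (simulation) or 'reads_dir'")
  })
  n_animals <- length(reads)

  calls <- resolve_stage("call", {
    call_cohort(reads, genes, params = thr$caller,
                min_score_per_base = thr$min_score_per_base)
  })
  message(sprintf("called %d per-animal variant records across %d animals",
                  nrow(calls), n_animals))

  calls <- resolve_stage("annotate", annotate_calls(calls, genes))

  records <- resolve_stage("aggregate", aggregate_cohort(calls, n_animals))
  retained <- resolve_stage("filter",
                            filter_min_fraction(records,
                                                thr$min_carrier_fraction))
  message(sprintf("retention filter (>= %.3g): %d of %d variants kept",
                  thr$min_carrier_fraction, nrow(retained), nrow(records)))

  retained <- resolve_stage("classify",
    classify_variant_interfaces(retained, genes,
                                window = thr$adjacency_window))

  abund <- list(); carriers <- NULL
  iso_genes <- config$quantify_isoforms %||% character(0)
  for (g in iso_genes) {
    ab <- resolve_stage("isoform-quant", quantify_isoforms(reads, genes[[g]]))
    kept <- filter_isoform_set(ab, thr$min_isoform_abundance)
    message(sprintf("%s: %d of %d isoforms above %.3g abundance",
                    g, ncol(kept), ncol(ab$theta), thr$min_isoform_abundance))
    st <- isoform_carrier_stats(kept, thr$isoform_carrier_threshold,
                                cohort_size = n_animals)
    if (nrow(st)) st$gene_id <- g
    abund[[g]] <- kept
    carriers <- rbind(carriers, st)
  }

  meta <- list(seed = seed, thresholds = thr,
               version = as.character(utils::packageVersion("fcgrdiv")),
               config_digest = if (!is.null(config$config_path))
                 unname(tools::md5sum(config$config_path)) else NA_character_,
               n_animals = n_animals)

  report <- structure(list(variant_records = retained,
                           variant_records_all = records,
                           calls = calls, abundance = abund,
                           isoform_carriers = carriers,
                           truth = if (!is.null(sim)) sim$truth else NULL,
                           metadata = meta),
                      class = "fcgr_report")

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    resolve_stage("report", {
      if (nrow(calls))
        write_variant_vcf(calls, genes, file.path(out, "cohort.vcf.gz"),
                          animals = names(reads))
      for (g in unique(retained$gene_id))
        write_variant_table(retained[retained$gene_id == g, , drop = FALSE],
                            file.path(out, sprintf("variants_%s.tsv", g)))
      if (length(abund))
        write_isoform_tables(abund, carriers %||%
                               data.frame(isoform = character(0),
                                          gene_id = character(0),
                                          carrier_count = integer(0),
                                          cohort_size = integer(0)),
                             genes,
                             file.path(out, "isoform_abundance.tsv"),
                             file.path(out, "isoform_carriers.tsv"))
      yaml::write_yaml(meta, file.path(out, "run_metadata.yaml"))
    })
  }
  report
}

#' @export
print.fcgr_report <- function(x, ...) {
  cat(sprintf("<fcgr_report> %d animals; %d retained variants (%d pre-filter)\n",
              x$metadata$n_animals, nrow(x$variant_records),
              nrow(x$variant_records_all)))
  if (length(x$abundance))
    cat(sprintf("  isoform abundances for: %s\n",
                paste(names(x$abundance), collapse = ", ")))
  invisible(x)
}
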