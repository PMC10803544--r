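# Loading gene-model configuration files.

#' Load gene and isoform models from a configuration file
#'
#' The configuration is YAML with a top-level `reference_fasta` (path,
#' relative to the config file) holding one principal transcript per gene,
#' and a `genes` list; each gene entry carries the fields of [gene_model()].
#' All models are validated on load.
#'
#' @param config_path Path to the YAML gene configuration.
#' @return Named list of `fcgr_gene_model` objects.
#' @export
load_gene_config <- function(config_path) {
  if (!file.exists(config_path)) stop("gene config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$genes)) stop("gene config has no 'genes' entry")
  refs <- NULL
  if (!is.null(cfg$reference_fasta)) {
    fa <- file.path(dirname(config_path), cfg$reference_fasta)
    if (!file.exists(fa)) stop("reference FASTA not found: ", fa)
    set <- Biostrings::readDNAStringSet(fa)
    refs <- stats::setNames(as.character(set), names(set))
  }
  models <- lapply(cfg$genes, function(g) {
    ref <- g$reference_transcript
    if (is.null(ref)) {
      if (is.null(refs) || is.null(refs[[g$gene_id]]))
        stop("no reference transcript for gene ", g$gene_id)
      ref <- refs[[g$gene_id]]
    }
    to_df <- function(x) do.call(rbind, lapply(x, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    gene_model(
      gene_id = g$gene_id, chromosome = g$chromosome, strand = g$strand,
      exons = to_df(g$exons), orf_start = g$orf_start %||% 1L,
      signal_peptide_len = g$signal_peptide_len,
      reference_transcript = ref,
      domain_map = to_df(g$domains),
      contact_residues = unlist(g$contact_residues) %||% integer(),
      contact_source = g$contact_source %||% NA_character_,
      alt_exons = if (length(g$alt_exons)) to_df(g$alt_exons) else NULL,
      isoforms = g$isoforms %||% list(),
      ext5_seqs = unlist(g$ext5_seqs) %||% character()
    )
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged FcgR gene models
#'
#' Loads the four packaged receptor gene models (FCGR1, FCGR2A, FCGR2B,
#' FCGR3). Exon boundaries and reference sequences are synthetic but encode
#' the published per-exon coordinate-mapping constants, signal-peptide
#' offsets, reference/alternate alleles and codons of every reported cohort
#' variant, the domain architecture, the Fc-contact residue sets, and the
#' annotated isoform splice structures.
#'
#' @return Named list of `fcgr_gene_model` objects.
#' @export
fcgr_gene_set <- function() {
  load_gene_config(system.file("extdata", "fcgr_genes.yaml",
                               package = "fcgrdiv", mustWork = TRUE))
}

#' Published cohort variant table
#'
#' The reported variant rows for the four receptor genes in a 206-animal
#' cohort: genomic key, effect description, exon, both ORF-numbered and
#' mature-numbered nucleotide/protein notations, domain, and carrier counts.
#' Used as ground truth for annotation round-trips and as carrier-count input
#' for table-faithful simulations.
#'
#' @return Data frame, one row per reported variant.
#' @export
fcgr_reported_variants <- function() {
  utils::read.delim(system.file("extdata", "reported_variants.tsv",
                                package = "fcgrdiv", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published isoform carrier table
#'
#' Reported isoform accessions per gene with carrier counts in the
#' 206-animal cohort.
#'
#' @return Data frame, one row per reported isoform.
#' @export
fcgr_reported_isoforms <- function() {
  utils::read.delim(system.file("extdata", "reported_isoforms.tsv",
                                package = "fcgrdiv", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
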