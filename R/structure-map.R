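# Sequence-level mapping of variants onto receptor domains and Fc-contact
# interface residue sets. Contact sets are taken from co-crystal structures of
# receptor-IgG Fc complexes and configured per gene; adjacency is measured in
# sequence positions, not 3-D distance.

#' Assign a mature-protein residue to its domain
#'
#' @param mature_index Mature-protein residue index (negative = signal
#'   peptide).
#' @param gm An `fcgr_gene_model`.
#' @param display Return the coarse display label (`"Extracellular"`,
#'   `"Transmembrane"`, `"Cytoplasmic"`, `"Signal peptide"`) instead of the
#'   fine domain label.
#' @return Character scalar domain label.
#' @export
assign_domain <- function(mature_index, gm, display = TRUE) {
  dm <- gm$domain_map
  hit <- which(mature_index >= dm$start & mature_index <= dm$end)
  if (length(hit) != 1L)
    stop(sprintf("residue %d is beyond the %s protein", mature_index, gm$gene_id))
  label <- dm$label[hit]
  if (!display) return(label)
  if (is_extracellular(label)) "Extracellular"
  else switch(label, signal = "Signal peptide", transmembrane = "Transmembrane",
              cytoplasmic = "Cytoplasmic")
}

#' Classify a residue against an Fc-contact interface set
#'
#' A residue in the contact set is `contact`; a residue within `window`
#' sequence positions of the nearest contact residue is `adjacent`; anything
#' else (including residues outside the extracellular region, which are
#' flagged) is `distal`.
#'
#' @param mature_index Mature-protein residue index.
#' @param contact_set Integer vector of contact residues (or an
#'   `fcgr_gene_model`, whose configured set and source are used).
#' @param window Sequence-distance window for `adjacent` (default 2).
#' @param extracellular Logical; whether the residue lies in an
#'   extracellular domain. Non-extracellular residues are distal by
#'   definition.
#' @return List of class `fcgr_interface` with `mature_index`, `class`,
#'   `distance`, `source`, `flag`.
#' @export
classify_interface <- function(mature_index, contact_set, window = 2L,
                               extracellular = TRUE) {
  src <- NA_character_
  if (inherits(contact_set, "fcgr_gene_model")) {
    src <- contact_set$contact_source
    contact_set <- contact_set$contact_residues
  }
  contact_set <- as.integer(contact_set)
  flag <- NA_character_
  if (!length(contact_set)) {
    warning("empty contact set; classifying as distal")
    res <- list(mature_index = mature_index, class = "distal",
                distance = NA_integer_, source = src, flag = "empty-contact-set")
    return(structure(res, class = "fcgr_interface"))
  }
  if (!isTRUE(extracellular)) {
    res <- list(mature_index = mature_index, class = "distal",
                distance = NA_integer_, source = src,
                flag = "not-extracellular")
    return(structure(res, class = "fcgr_interface"))
  }
  d <- min(abs(mature_index - contact_set))
  cls <- if (d == 0L) "contact" else if (d <= window) "adjacent" else "distal"
  structure(list(mature_index = mature_index, class = cls,
                 distance = as.integer(d), source = src, flag = flag),
            class = "fcgr_interface")
}

#' @export
print.fcgr_interface <- function(x, ...) {
  cat(sprintf("<fcgr_interface> residue %d: %s (distance %s, set %s)\n",
              x$mature_index, x$class,
              ifelse(is.na(x$distance), "-", x$distance),
              ifelse(is.na(x$source), "-", x$source)))
  invisible(x)
}

#' Append interface classification columns to an annotated variant table
#'
#' Operates on nonsynonymous variants; synonymous and non-coding rows get
#' `NA`. Adds `InterfaceClass`, `ContactDistance`, `SourcePDB`.
#'
#' @param records Annotated variant records (with `gene_id`, `category`,
#'   `mature_residue_index`, `domain`).
#' @param genes Named list of gene models.
#' @param window Adjacency window in sequence positions.
#' @return `records` with the three columns appended.
#' @export
classify_variant_interfaces <- function(records, genes, window = 2L) {
  n <- nrow(records)
  records$InterfaceClass <- rep(NA_character_, n)
  records$ContactDistance <- rep(NA_integer_, n)
  records$SourcePDB <- rep(NA_character_, n)
  if (n == 0L) return(records)
  for (i in seq_len(n)) {
    if (!identical(records$category[i], "nonsynonymous SNP")) next
    gm <- genes[[records$gene_id[i]]]
    cl <- classify_interface(records$mature_residue_index[i], gm,
                             window = window,
                             extracellular =
                               identical(records$domain[i], "Extracellular"))
    records$InterfaceClass[i] <- cl$class
    records$ContactDistance[i] <- cl$distance
    records$SourcePDB[i] <- cl$source
  }
  records
}

#' Find N-linked glycosylation sequons in a protein
#'
#' Scans for the N-X-S/T motif (X any residue but proline) and returns the
#' positions of the asparagines, in mature numbering when a signal length is
#' given.
#'
#' @param protein Character scalar protein sequence (precursor, ORF order).
#' @param signal_peptide_len Signal length used to shift to mature numbering
#'   (0 keeps ORF numbering).
#' @return Integer vector of sequon positions.
#' @export
find_glyco_sites <- function(protein, signal_peptide_len = 0L) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  pos <- which(aa == "N")
  pos <- pos[pos + 2L <= n]
  pos <- pos[aa[pos + 1L] != "P" & aa[pos + 2L] %in% c("S", "T")]
  if (signal_peptide_len > 0L) pos <- to_mature_aa(pos, signal_peptide_len)
  pos
}

#' Report glycosylation sites destroyed by a nonsynonymous SNP
#'
#' Compares the sequon set of the reference protein with that of the protein
#' carrying the variant codon.
#'
#' @param variant As for [classify_effect()] (an ORF-coordinate SNP).
#' @param gm An `fcgr_gene_model`.
#' @return Integer vector of mature-numbered sequon positions lost (empty if
#'   none).
#' @export
glyco_sites_lost <- function(variant, gm) {
  v <- as.list(variant)
  stopifnot(v$type == "snp")
  prot <- translate_cds(gm$reference_transcript, gm$orf_start)
  loc <- locate_codon(v$orf_pos)
  orf_seq <- orf_sequence(gm)
  alt_codon <- codon_at(orf_seq, loc$codon)
  substr(alt_codon, loc$offset, loc$offset) <- v$talt
  mut <- prot
  substr(mut, loc$codon, loc$codon) <- translate_codon(alt_codon)
  setdiff(find_glyco_sites(prot, gm$signal_peptide_len),
          find_glyco_sites(mut, gm$signal_peptide_len))
}
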