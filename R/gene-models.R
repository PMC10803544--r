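#' @useDynLib fcgrdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- small sequence utilities -----------------------------------------------

rev_comp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation starts at `orf_start` (which must be an ATG codon) and stops at
#' the first in-frame stop codon; the stop itself is not included in the
#' returned protein. Trailing bases that do not fill a codon are ignored.
#'
#' @param transcript_seq Character scalar, nucleotide sequence.
#' @param orf_start 1-based position of the first base of the open reading
#'   frame within `transcript_seq`.
#' @return Character scalar, the translated protein.
#' @export
translate_cds <- function(transcript_seq, orf_start = 1L) {
  stopifnot(is.character(transcript_seq), length(transcript_seq) == 1L)
  orf_start <- as.integer(orf_start)
  len <- nchar(transcript_seq)
  if (orf_start < 1L || orf_start + 2L > len)
    stop("orf_start outside the transcript")
  if (toupper(substr(transcript_seq, orf_start, orf_start + 2L)) != "ATG")
    stop("no ATG codon at orf_start")
  orf <- toupper(substr(transcript_seq, orf_start, len))
  orf <- substr(orf, 1L, 3L * (nchar(orf) %/% 3L))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(orf), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
  aa
}

# ---- gene model constructor & validation ------------------------------------

#' Construct an FcgR gene model
#'
#' A gene model describes one amplicon-sequenced receptor gene: the exon
#' structure of its principal transcript (with genomic coordinates used for
#' variant reporting), the open-reading-frame offset, the signal-peptide
#' length that links ORF numbering to mature-protein numbering, the domain
#' architecture of the mature protein, the set of Fc-contact residues, and
#' the splice structures of its annotated isoforms.
#'
#' Coordinate conventions: genomic positions are 1-based and closed (VCF
#' style, always reported on the plus strand); transcript positions are
#' 1-based from the transcript 5' end; ORF positions are 1-based from the
#' first base of the start codon (`orf_start` in transcript coordinates);
#' mature-protein residues are numbered from the first residue after
#' signal-peptide cleavage, with signal residues carrying negative indices
#' and no residue zero.
#'
#' @param gene_id Short gene name, e.g. `"FCGR2A"`.
#' @param chromosome Reference sequence name, e.g. `"chr1"`.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `label`, `tstart`, `tend` (transcript
#'   coordinates of the principal transcript), `gstart`, `gend` (genomic,
#'   plus strand, closed).
#' @param orf_start ORF offset within the principal transcript.
#' @param signal_peptide_len Number of residues preceding mature position 1.
#' @param reference_transcript Nucleotide sequence of the principal transcript.
#' @param domain_map Data frame with columns `start`, `end` (mature residue
#'   indices, signal region negative) and `label` (one of `signal`,
#'   `extracellular-D1`, `extracellular-D2`, `extracellular-other`,
#'   `transmembrane`, `cytoplasmic`).
#' @param contact_residues Integer vector of mature-protein Fc-contact
#'   residues (may be empty).
#' @param contact_source Identifier for the provenance of the contact set,
#'   e.g. the PDB complex it was read from.
#' @param alt_exons Optional data frame of non-principal (cassette) exons with
#'   columns `label`, `insert_after` (transcript position of the principal
#'   transcript after which the exon is spliced in), `seq`, `gstart`, `gend`.
#' @param isoforms Optional list of isoform descriptions, each a list with
#'   `id`, `protein_id` and `edits` (see [build_isoform()]).
#' @param ext5_seqs Optional named character vector mapping exon labels to the
#'   intron-derived sequence added by an alternative 5' splice-site extension
#'   of that exon.
#' @return An object of class `fcgr_gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, orf_start,
                       signal_peptide_len, reference_transcript,
                       domain_map, contact_residues = integer(),
                       contact_source = NA_character_,
                       alt_exons = NULL, isoforms = list(),
                       ext5_seqs = character()) {
  gm <- structure(list(
    gene_id = gene_id, chromosome = chromosome, strand = strand,
    exons = as.data.frame(exons, stringsAsFactors = FALSE),
    orf_start = as.integer(orf_start),
    signal_peptide_len = as.integer(signal_peptide_len),
    reference_transcript = toupper(reference_transcript),
    domain_map = as.data.frame(domain_map, stringsAsFactors = FALSE),
    contact_residues = sort(unique(as.integer(contact_residues))),
    contact_source = contact_source,
    alt_exons = if (is.null(alt_exons)) NULL else
      as.data.frame(alt_exons, stringsAsFactors = FALSE),
    isoforms = isoforms,
    ext5_seqs = ext5_seqs
  ), class = "fcgr_gene_model")
  validate_gene_model(gm)
  gm
}

DOMAIN_LABELS <- c("signal", "extracellular-D1", "extracellular-D2",
                   "extracellular-other", "transmembrane", "cytoplasmic")

is_extracellular <- function(label) grepl("^extracellular", label)

#' Validate a gene model's internal consistency
#'
#' Checks the invariants of the model: exons tile the transcript without
#' overlap and in the strand-appropriate genomic order, exon lengths agree in
#' both coordinate systems, the ORF starts with ATG and terminates at an
#' in-frame stop codon, domain intervals cover the mature protein without
#' overlap, and contact residues fall inside extracellular domains.
#'
#' @param gm An `fcgr_gene_model`.
#' @return `gm`, invisibly; errors name the offending field.
#' @export
validate_gene_model <- function(gm) {
  ex <- gm$exons
  fail <- function(field, why) stop(sprintf("gene model %s: invalid %s: %s",
                                            gm$gene_id, field, why), call. = FALSE)
  if (!gm$strand %in% c("+", "-")) fail("strand", "must be '+' or '-'")
  need <- c("label", "tstart", "tend", "gstart", "gend")
  if (!all(need %in% names(ex))) fail("exons", "missing columns")
  ex <- ex[order(ex$tstart), , drop = FALSE]
  if (ex$tstart[1] != 1L) fail("exons", "transcript coverage must start at 1")
  if (any(ex$tend < ex$tstart)) fail("exons", "empty transcript interval")
  if (nrow(ex) > 1L && any(ex$tstart[-1] != utils::head(ex$tend, -1) + 1L))
    fail("exons", "transcript intervals must tile contiguously")
  if (any((ex$tend - ex$tstart) != (ex$gend - ex$gstart)))
    fail("exons", "genomic and transcript lengths differ")
  og <- order(ex$gstart)
  if (any(utils::head(ex$gend[og], -1) >= ex$gstart[og][-1]))
    fail("exons", "overlapping genomic intervals")
  if (gm$strand == "+" && is.unsorted(ex$gstart))
    fail("exons", "plus-strand exons must ascend genomically with transcript order")
  if (gm$strand == "-" && is.unsorted(rev(ex$gstart)))
    fail("exons", "minus-strand exons must descend genomically with transcript order")
  tlen <- max(ex$tend)
  if (nchar(gm$reference_transcript) != tlen)
    fail("reference_transcript", sprintf("length %d but exons span %d",
                                         nchar(gm$reference_transcript), tlen))
  prot <- translate_cds(gm$reference_transcript, gm$orf_start)  # errors if no ATG
  orf_nt <- 3L * (nchar(prot) + 1L)
  if (gm$orf_start + orf_nt - 1L > tlen)
    fail("orf", "no in-frame stop codon before transcript end")
  dm <- gm$domain_map
  if (!all(dm$label %in% DOMAIN_LABELS))
    fail("domain_map", paste("unknown label:",
                             paste(setdiff(dm$label, DOMAIN_LABELS), collapse = ", ")))
  mat_len <- nchar(prot) - gm$signal_peptide_len
  dm <- dm[order(dm$start), , drop = FALSE]
  if (any(dm$end < dm$start)) fail("domain_map", "empty interval")
  covered <- unlist(Map(seq.int, dm$start, dm$end))
  mature_idx <- seq_len(mat_len)
  if (anyDuplicated(covered)) fail("domain_map", "overlapping intervals")
  if (!all(mature_idx %in% covered))
    fail("domain_map", "mature protein not fully covered")
  ec <- dm[is_extracellular(dm$label), , drop = FALSE]
  ec_res <- unlist(Map(seq.int, ec$start, ec$end))
  if (!all(gm$contact_residues %in% ec_res))
    fail("contact_residues", "contact residue outside extracellular domains")
  invisible(gm)
}

#' @export
print.fcgr_gene_model <- function(x, ...) {
  prot <- translate_cds(x$reference_transcript, x$orf_start)
  cat(sprintf("<fcgr_gene_model> %s (%s strand, %s)\n", x$gene_id, x$strand,
              x$chromosome))
  cat(sprintf("  transcript %d nt, ORF at %d, precursor %d aa, signal %d aa\n",
              nchar(x$reference_transcript), x$orf_start, nchar(prot),
              x$signal_peptide_len))
  cat(sprintf("  %d exons, %d contact residues (%s), %d isoforms\n",
              nrow(x$exons), length(x$contact_residues),
              ifelse(is.na(x$contact_source), "none", x$contact_source),
              length(x$isoforms)))
  invisible(x)
}

# ---- coordinate mapping -----------------------------------------------------

orf_to_tpos <- function(gm, orf_pos) orf_pos + gm$orf_start - 1L
tpos_to_orf <- function(gm, tpos) tpos - gm$orf_start + 1L

#' Map a genomic position (and alleles) into ORF coordinates
#'
#' For minus-strand genes the transcript position satisfies
#' `gpos + tpos == constant` within each exon and alleles are
#' reverse-complemented; for plus-strand genes `gpos - tpos` is the per-exon
#' constant. Returned positions use ORF numbering (position 1 is the first
#' base of the start codon; 5' UTR positions come back non-positive).
#'
#' @param gm An `fcgr_gene_model`.
#' @param gpos Genomic position (1-based, plus strand).
#' @param ref_allele,alt_allele Plus-strand alleles (optional).
#' @return List with `orf_pos`, `tpos`, `exon` (label), and transcript-strand
#'   `ref`/`alt` when alleles were given.
#' @export
genomic_to_transcript <- function(gm, gpos, ref_allele = NULL, alt_allele = NULL) {
  ex <- gm$exons
  hit <- which(gpos >= ex$gstart & gpos <= ex$gend)
  if (length(hit) != 1L)
    stop(sprintf("position %s:%d is not exonic in %s", gm$chromosome, gpos,
                 gm$gene_id))
  e <- ex[hit, ]
  tpos <- if (gm$strand == "+") e$tstart + (gpos - e$gstart)
          else e$tstart + (e$gend - gpos)
  out <- list(orf_pos = tpos_to_orf(gm, tpos), tpos = tpos, exon = e$label)
  if (!is.null(ref_allele)) {
    if (gm$strand == "-") {
      out$ref <- rev_comp(ref_allele); out$alt <- rev_comp(alt_allele)
    } else {
      out$ref <- ref_allele; out$alt <- alt_allele
    }
  }
  out
}

#' Map an ORF position back to its genomic position
#'
#' Exact inverse of [genomic_to_transcript()] on exonic positions.
#'
#' @param gm An `fcgr_gene_model`.
#' @param orf_pos Position in ORF numbering.
#' @return Genomic position (integer, plus strand).
#' @export
transcript_to_genomic <- function(gm, orf_pos) {
  tpos <- orf_to_tpos(gm, orf_pos)
  ex <- gm$exons
  hit <- which(tpos >= ex$tstart & tpos <= ex$tend)
  if (length(hit) != 1L)
    stop(sprintf("ORF position %d is beyond the %s transcript", orf_pos,
                 gm$gene_id))
  e <- ex[hit, ]
  if (gm$strand == "+") e$gstart + (tpos - e$tstart)
  else e$gend - (tpos - e$tstart)
}

exon_of_orf_pos <- function(gm, orf_pos) {
  tpos <- orf_to_tpos(gm, orf_pos)
  ex <- gm$exons
  hit <- which(tpos >= ex$tstart & tpos <= ex$tend)
  if (length(hit) != 1L) return(NA_character_)
  ex$label[hit]
}

# ---- isoform construction ---------------------------------------------------

#' Build an isoform transcript from a splice structure
#'
#' Splice structures are expressed as edits relative to the principal
#' transcript. Supported edit types:
#' \describe{
#'   \item{`exon_include`}{splice in a non-principal cassette exon (by label,
#'     from the model's `alt_exons`).}
#'   \item{`exon_skip`}{remove a principal exon.}
#'   \item{`splice5_ext`}{alternative 5' splice site extending an exon by
#'     `nt` intron-derived bases (sequence from the model's `ext5_seqs`).}
#'   \item{`residue_del`}{delete one codon, by ORF residue index.}
#'   \item{`residue_ins`}{insert one residue (field `aa`, field `codon`
#'     optional) before the given ORF residue index.}
#' }
#' Edits are applied from 3' to 5' so coordinates remain valid; in-frame
#' edits preserve the downstream reading frame.
#'
#' @param gm An `fcgr_gene_model`.
#' @param edits List of edits (possibly empty, giving the principal isoform).
#' @param id,protein_id Optional labels for the resulting isoform.
#' @return List of class `fcgr_isoform` with `id`, `gene_id`, `edits`,
#'   `transcript_seq`, `protein_seq`, `orf_start`.
#' @export
build_isoform <- function(gm, edits = list(), id = NULL, protein_id = NULL) {
  seqs <- apply_transcript_ops(gm$reference_transcript, isoform_ops(gm, edits))
  structure(list(id = id, protein_id = protein_id, gene_id = gm$gene_id,
                 edits = edits, transcript_seq = seqs,
                 protein_seq = translate_cds(seqs, gm$orf_start),
                 orf_start = gm$orf_start),
            class = "fcgr_isoform")
}

# translate splice-structure edits into transcript operations
# (anchor position `after`, `remove` count, inserted `seq`)
isoform_ops <- function(gm, edits) {
  lapply(edits, function(e) {
    switch(e$type,
      exon_include = {
        ae <- gm$alt_exons
        k <- which(ae$label == e$label)
        if (length(k) != 1L) stop("unknown cassette exon: ", e$label)
        list(after = ae$insert_after[k], remove = 0L, seq = ae$seq[k])
      },
      exon_skip = {
        k <- which(gm$exons$label == e$label)
        if (length(k) != 1L) stop("unknown exon: ", e$label)
        list(after = gm$exons$tstart[k] - 1L,
             remove = gm$exons$tend[k] - gm$exons$tstart[k] + 1L, seq = "")
      },
      splice5_ext = {
        s <- gm$ext5_seqs[[e$label]]
        if (is.null(s)) stop("no 5' extension sequence configured for exon ", e$label)
        if (!is.null(e$nt) && e$nt != nchar(s))
          stop(sprintf("5' extension of exon %s is %d nt, not %d", e$label,
                       nchar(s), e$nt))
        k <- which(gm$exons$label == e$label)
        if (length(k) != 1L) stop("unknown exon: ", e$label)
        list(after = gm$exons$tstart[k] - 1L, remove = 0L, seq = s)
      },
      residue_del = {
        t0 <- orf_to_tpos(gm, 3L * (e$residue - 1L) + 1L)
        list(after = t0 - 1L, remove = 3L, seq = "")
      },
      residue_ins = {
        codon <- if (!is.null(e$codon)) e$codon else aa_to_codon(e$aa)
        t0 <- orf_to_tpos(gm, 3L * (e$residue - 1L) + 1L)
        list(after = t0 - 1L, remove = 0L, seq = codon)
      },
      stop("unknown edit type: ", e$type))
  })
}

# apply transcript operations right-to-left so earlier coordinates stay valid;
# overlapping removals are rejected
apply_transcript_ops <- function(seqs, ops) {
  if (!length(ops)) return(seqs)
  ord <- order(vapply(ops, `[[`, numeric(1), "after"), decreasing = TRUE)
  ops <- ops[ord]
  if (length(ops) > 1L) {
    hi <- vapply(ops, function(o) o$after + o$remove, numeric(1))
    lo <- vapply(ops, `[[`, numeric(1), "after")
    if (any(utils::tail(hi, -1) > utils::head(lo, -1)))
      stop("conflicting overlapping edits on one haplotype")
  }
  for (op in ops) {
    if (op$after < 0L || op$after + op$remove > nchar(seqs))
      stop("edit outside the transcript")
    seqs <- paste0(substr(seqs, 1L, op$after), op$seq,
                   substr(seqs, op$after + op$remove + 1L, nchar(seqs)))
  }
  seqs
}

# representative codon for a residue (used when an edit gives only the amino acid)
aa_to_codon <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  hit <- names(gc)[gc == toupper(aa)][1]
  if (is.na(hit)) stop("no codon for residue ", aa)
  hit
}

#' Locate an insertion or deletion between two protein sequences
#'
#' Utility for comparing a reference protein with an edited one that differs
#' by a single contiguous in-frame insertion or deletion. Returns the 1-based
#' residue index (in the reference protein / ORF numbering) at which the
#' difference starts, its length, and the inserted or deleted residues.
#'
#' @param ref,alt Protein sequences (character scalars).
#' @return List with `type` (`"identical"`, `"insertion"`, `"deletion"`,
#'   `"substitution"`), `at`, `len`, `residues`.
#' @export
diff_proteins <- function(ref, alt) {
  if (identical(ref, alt))
    return(list(type = "identical", at = NA_integer_, len = 0L, residues = ""))
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  n <- length(r); m <- length(a)
  pre <- 0L
  while (pre < min(n, m) && r[pre + 1L] == a[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < min(n, m) - pre && r[n - suf] == a[m - suf]) suf <- suf + 1L
  if (m > n && (m - n) == (m - suf) - pre)
    return(list(type = "insertion", at = pre + 1L, len = m - n,
                residues = paste(a[(pre + 1L):(m - suf)], collapse = "")))
  if (n > m && (n - m) == (n - suf) - pre)
    return(list(type = "deletion", at = pre + 1L, len = n - m,
                residues = paste(r[(pre + 1L):(n - suf)], collapse = "")))
  list(type = "substitution", at = pre + 1L, len = max(n, m) - pre - suf,
       residues = if (m >= pre + 1L)
         paste(a[(pre + 1L):max(pre + 1L, m - suf)], collapse = "") else "")
}
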