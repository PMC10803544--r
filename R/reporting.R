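# File I/O and report assembly: FASTQ/FASTA, VCF 4.x via vcfR, the
# cohort variant and isoform TSV reports, and the end-to-end pipeline driver.
# All writers are atomic (write to a temporary file in the target directory,
# then rename).

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}

#' Write reads to FASTQ (constant base quality)
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  atomic_write(path, function(tmp)
    Biostrings::writeXStringSet(x, tmp, format = "fastq", qualities = q,
                                compress = endsWith(path, ".gz")))
}

#' Read reads from FASTQ or FASTA
#'
#' @param path Input path (gzip-aware).
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Load a directory of per-animal FASTQ files
#'
#' Files must be named `<animal>_<gene>.fastq[.gz]` (as written by
#' [simulate_cohort()]).
#'
#' @param dir Directory of FASTQ files.
#' @return Nested list `reads[[animal]][[gene]]`.
#' @export
read_cohort_reads <- function(dir) {
  files <- list.files(dir, pattern = "\\.f(ast)?q(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no FASTQ files in ", dir)
  out <- list()
  for (f in files) {
    stem <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(f))
    parts <- strsplit(stem, "_(?=[^_]+$)", perl = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("cannot parse animal/gene from filename: ", basename(f))
    out[[parts[1]]][[parts[2]]] <- read_reads(f)
  }
  out
}

# plus-strand reference base at a genomic position (VCF anchor base)
plus_base_at <- function(gm, gpos) {
  tp <- genomic_to_transcript(gm, gpos)$tpos
  b <- substr(gm$reference_transcript, tp, tp)
  if (gm$strand == "-") rev_comp(b) else b
}

#' Write cohort calls as a multi-sample VCF
#'
#' One record per distinct variant, one sample column per animal
#' (`GT:AD:DP`), plus-strand alleles, INFO fields `GENE`, `CARRIERS`, `PCT`.
#'
#' @param calls Per-animal call data frame (from [call_cohort()]).
#' @param genes Named list of gene models.
#' @param path Output path (`.vcf.gz`).
#' @param animals Full cohort animal ids (non-carriers get `0/0`); defaults
#'   to the animals present in `calls`.
#' @export
write_variant_vcf <- function(calls, genes, path, animals = NULL) {
  if (is.null(animals)) animals <- sort(unique(calls$animal))
  keys <- unique(calls$key)
  fix <- matrix(".", nrow = length(keys), ncol = 8L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gtm <- matrix("0/0:.:.", nrow = length(keys), ncol = length(animals) + 1L)
  colnames(gtm) <- c("FORMAT", animals)
  gtm[, "FORMAT"] <- "GT:AD:DP"
  for (r in seq_along(keys)) {
    rows <- calls[calls$key == keys[r], , drop = FALSE]
    v <- rows[1, ]
    gm <- genes[[v$gene_id]]
    if (v$type == "snp") {
      pos <- v$gpos; ref <- v$gref; alt <- v$galt
    } else if (v$type == "ins") {
      pos <- v$gpos
      anchor <- plus_base_at(gm, pos)
      ref <- anchor; alt <- paste0(anchor, v$galt)
    } else {
      pos <- v$gpos - 1L
      anchor <- plus_base_at(gm, pos)
      ref <- paste0(anchor, v$gref); alt <- anchor
    }
    fix[r, ] <- c(v$chrom, as.character(pos), keys[r], ref, alt, ".", "PASS",
                  sprintf("GENE=%s;CARRIERS=%d;PCT=%.4g", v$gene_id,
                          length(unique(rows$animal)),
                          100 * length(unique(rows$animal)) / length(animals)))
    for (i in seq_len(nrow(rows))) {
      gt <- if (rows$zygosity[i] == "hom") "1/1" else "0/1"
      gtm[r, rows$animal[i]] <- sprintf(
        "%s:%d,%d:%d", gt, rows$depth[i] - rows$alt_count[i],
        rows$alt_count[i], rows$depth[i])
    }
  }
  meta <- c("##fileformat=VCFv4.3",
            "##source=fcgrdiv",
            "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
            "##INFO=<ID=CARRIERS,Number=1,Type=Integer,Description=\"Carrier animals\">",
            "##INFO=<ID=PCT,Number=1,Type=Float,Description=\"Percent carriers\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gtm)
  if (!endsWith(path, ".gz")) path <- paste0(path, ".gz")
  atomic_write(path, function(tmp) {
    vcfR::write.vcf(vcf, file = tmp)
  })
  invisible(path)
}

#' Read cohort calls back from a VCF written by [write_variant_vcf()]
#'
#' @param path VCF path.
#' @param genes Named list of gene models (to recover transcript
#'   coordinates).
#' @return Per-animal call data frame with the same identity, zygosity and
#'   depth fields the writer consumed.
#' @export
read_variant_vcf <- function(path, genes) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  animals <- setdiff(colnames(gt), "FORMAT")
  out <- list(); k <- 0L
  for (r in seq_len(nrow(fix))) {
    info <- fix[r, "INFO"]
    gene_id <- sub(".*GENE=([^;]+).*", "\\1", info)
    gm <- genes[[gene_id]]
    if (is.null(gm)) stop("VCF references unknown gene ", gene_id)
    pos <- as.integer(fix[r, "POS"]); ref <- fix[r, "REF"]; alt <- fix[r, "ALT"]
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      mp <- genomic_to_transcript(gm, pos, ref, alt)
      v <- list(type = "snp", pos = mp$tpos, tref = mp$ref, talt = mp$alt,
                seq = "")
    } else if (nchar(alt) > nchar(ref)) {
      ins <- substring(alt, nchar(ref) + 1L)
      if (gm$strand == "+") {
        v <- list(type = "ins", pos = genomic_to_transcript(gm, pos)$tpos,
                  seq = ins)
      } else {
        v <- list(type = "ins",
                  pos = genomic_to_transcript(gm, pos)$tpos - 1L,
                  seq = rev_comp(ins))
      }
    } else {
      del <- substring(ref, nchar(alt) + 1L)
      g1 <- pos + 1L
      tt <- vapply(g1 + seq_len(nchar(del)) - 1L,
                   function(p) genomic_to_transcript(gm, p)$tpos, numeric(1))
      v <- list(type = "del", pos = min(tt),
                seq = if (gm$strand == "-") rev_comp(del) else del)
    }
    v <- normalize_variant(v, gm$reference_transcript)
    gf <- genomic_fields(gm, v)
    orf_pos <- tpos_to_orf(gm, v$pos)
    for (a in animals) {
      cell <- gt[r, a]
      if (is.na(cell) || startsWith(cell, "0/0")) next
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      ad <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
      dp <- as.integer(parts[3])
      k <- k + 1L
      out[[k]] <- data.frame(
        gene_id = gene_id, chrom = fix[r, "CHROM"], gpos = gf$gpos,
        gref = gf$gref, galt = gf$galt, key = gf$key, type = v$type,
        tpos = v$pos, orf_pos = orf_pos,
        tref = if (v$type == "snp") v$tref else "",
        talt = if (v$type == "snp") v$talt else "",
        seq = v$seq, is_dup = isTRUE(v$is_dup),
        exon = exon_of_orf_pos(gm, orf_pos),
        zygosity = if (startsWith(parts[1], "1/1")) "hom" else "het",
        alt_count = ad[2], depth = dp, vaf = ad[2] / dp, animal = a,
        stringsAsFactors = FALSE)
    }
  }
  if (!k) { e <- empty_calls(); e$animal <- character(0); return(e) }
  res <- do.call(rbind, out)
  res <- res[order(res$key, res$animal), , drop = FALSE]
  rownames(res) <- NULL
  res
}

display_category <- function(x) {
  map <- c("frameshift insertion" = "fs insertion",
           "frameshift deletion" = "fs deletion",
           "non-frameshift insertion" = "non-fs insertion",
           "non-frameshift deletion" = "non-fs deletion")
  ifelse(x %in% names(map), map[x], x)
}

VARIANT_TABLE_COLUMNS <- c("Variant", "Description", "Exon", "ANNOVAR NT",
                           "ANNOVAR AA", "Transcript NT", "Mature protein AA",
                           "Domain", "% Carriers")

#' Write a cohort variant report table
#'
#' TSV with the report's column set: Variant, Description, Exon, ANNOVAR
#' NT/AA (ORF numbering), Transcript NT and Mature protein AA (mature
#' numbering), Domain, and `% Carriers` rendered as `pct (count/total)`.
#' Rows are ordered by descending carrier count.
#'
#' @param records Annotated, aggregated cohort records.
#' @param path Output TSV path.
#' @export
write_variant_table <- function(records, path) {
  if (nrow(records)) {
    tab <- data.frame(
      Variant = records$key,
      Description = display_category(records$category),
      Exon = records$exon,
      `ANNOVAR NT` = records$annovar_nt,
      `ANNOVAR AA` = records$annovar_aa,
      `Transcript NT` = records$mature_nt,
      `Mature protein AA` = records$mature_aa,
      Domain = records$domain,
      `% Carriers` = sprintf("%s (%d/%d)",
                             format_percent(records$carrier_count,
                                            records$cohort_size),
                             records$carrier_count, records$cohort_size),
      check.names = FALSE, stringsAsFactors = FALSE)
    tab <- tab[order(-records$carrier_count, records$key), , drop = FALSE]
  } else {
    tab <- as.data.frame(matrix(character(0), 0, length(VARIANT_TABLE_COLUMNS),
                                dimnames = list(NULL, VARIANT_TABLE_COLUMNS)),
                         check.names = FALSE)
  }
  atomic_write(path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Write the isoform abundance matrix and carrier table
#'
#' @param abund Named list of per-gene abundance matrices (animals x
#'   isoforms) or `fcgr_abundance` objects.
#' @param carriers Combined isoform carrier data frame (with `gene_id`,
#'   `isoform`, `carrier_count`, `cohort_size`).
#' @param genes Gene models (for isoform protein accessions).
#' @param abundance_path,carrier_path Output TSV paths.
#' @export
write_isoform_tables <- function(abund, carriers, genes,
                                 abundance_path, carrier_path) {
  mats <- lapply(abund, function(a)
    if (inherits(a, "fcgr_abundance")) a$theta else as.matrix(a))
  wide <- do.call(rbind, lapply(mats, t))   # isoforms x animals
  atomic_write(abundance_path, function(tmp)
    utils::write.table(data.frame(Isoform = rownames(wide), wide,
                                  check.names = FALSE),
                       tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  prot <- do.call(c, unname(lapply(genes, function(gm)
    stats::setNames(vapply(gm$isoforms,
                           function(i) i$protein_id %||% NA_character_,
                           character(1)),
                    vapply(gm$isoforms, `[[`, character(1), "id")))))
  if (nrow(carriers)) {
    carriers <- carriers[order(carriers$gene_id, -carriers$carrier_count), ,
                         drop = FALSE]
    tab <- data.frame(
      `Nucleotide Isoform` = carriers$isoform,
      `Translated Protein Isoform` = unname(prot[carriers$isoform]),
      `% Carriers` = sprintf("%s (%d/%d)",
                             format_percent(carriers$carrier_count,
                                            carriers$cohort_size),
                             carriers$carrier_count, carriers$cohort_size),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(matrix(character(0), 0, 3,
             dimnames = list(NULL, c("Nucleotide Isoform",
                                     "Translated Protein Isoform",
                                     "% Carriers"))), check.names = FALSE)
  }
  atomic_write(carrier_path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Plot an isoform relative-abundance heatmap
#'
#' Rows are isoforms, columns animals. Uses `pheatmap` when available,
#' otherwise falls back to [stats::heatmap()].
#'
#' @param abund Abundance matrix (animals x isoforms) or `fcgr_abundance`.
#' @param ... Passed to the underlying heatmap function.
#' @export
plot_abundance_heatmap <- function(abund, ...) {
  m <- if (inherits(abund, "fcgr_abundance")) abund$theta else as.matrix(abund)
  m <- t(m)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE, ...)
  } else {
    stats::heatmap(m, Rowv = NA, Colv = NA, scale = "none", ...)
  }
}
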