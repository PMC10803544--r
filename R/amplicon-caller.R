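# Desk-scale amplicon variant caller: global affine-gap alignment of
# full-length reads to the gene's principal transcript, per-position pileups,
# and a threshold diploid genotype caller. Global (not local) alignment is
# used because amplicons span the full transcript, so terminal bases are
# informative.

default_scoring <- function() list(match = 2L, mismatch = -4L,
                                   gap_open = -4L, gap_extend = -2L)

default_caller_params <- function() list(min_depth = 10L, min_alt_reads = 3L,
                                         het_fraction_range = c(0.25, 0.75),
                                         hom_fraction_min = 0.8)

#' Globally align one read against a reference transcript
#'
#' Optimal end-to-end alignment under an affine gap model (a gap of length L
#' costs `|gap_open| + L * |gap_extend|`). Reads whose score per base falls
#' below `min_score_per_base` are marked invalid, the single-reference
#' analogue of a mapping-quality filter.
#'
#' @param read Character scalar read sequence (or a named length-1 vector;
#'   the name becomes the read id).
#' @param reference Reference transcript sequence.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults +2/-4/-4/-2).
#' @param min_score_per_base Validity threshold on score / read length.
#' @param score_only Skip the traceback (faster; `cigar` will be `NA`).
#' @param band Optional band half-width around the alignment diagonal
#'   (automatically widened by the length difference). `NULL` runs the
#'   exhaustive DP; a moderate band (e.g. 48) is exact in practice for
#'   full-length amplicon reads, whose optimal path stays near the diagonal,
#'   and much faster.
#' @return Object of class `fcgr_alignment`: `read_id`, `seq`, `score`,
#'   `cigar` (run-length ops over `=`, `X` mismatch, `I` insertion in read,
#'   `D` deletion), `valid`.
#' @export
align_read <- function(read, reference, scoring = default_scoring(),
                       min_score_per_base = 1, score_only = FALSE,
                       band = NULL) {
  id <- names(read) %||% NA_character_
  read <- unname(read)
  stopifnot(nchar(read) > 0L, nchar(reference) > 0L)
  res <- .align_global_cpp(read, reference,
                           as.integer(scoring$match),
                           as.integer(scoring$mismatch),
                           as.integer(-scoring$gap_open),
                           as.integer(-scoring$gap_extend),
                           if (is.null(band)) -1L else as.integer(band),
                           score_only)
  structure(list(read_id = id, seq = read, score = res$score,
                 cigar = if (score_only) NA_character_ else res$cigar,
                 valid = res$score / nchar(read) >= min_score_per_base),
            class = "fcgr_alignment")
}

#' @export
print.fcgr_alignment <- function(x, ...) {
  cat(sprintf("<fcgr_alignment> %s: score %d (%s), %s\n",
              ifelse(is.na(x$read_id), "read", x$read_id), x$score,
              ifelse(x$valid, "valid", "invalid"),
              ifelse(is.na(x$cigar), "score only", x$cigar)))
  invisible(x)
}

parse_cigar <- function(cigar) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  data.frame(len = n, op = op, stringsAsFactors = FALSE)
}

#' Extract aligned (reference, read) coordinate pairs from an alignment
#'
#' @param aln An `fcgr_alignment` (with traceback).
#' @return Data frame with `ref_pos`, `read_pos`, `op` (`match`, `mismatch`,
#'   `insertion`, `deletion`); insertion rows carry the reference position
#'   they follow and `read_pos` of the first inserted base, deletions the
#'   deleted reference positions with `read_pos` `NA`.
#' @export
aligned_pairs <- function(aln) {
  ops <- parse_cigar(aln$cigar)
  ref <- 0L; rd <- 0L
  out <- vector("list", nrow(ops))
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    out[[i]] <- switch(ops$op[i],
      "=" = { d <- data.frame(ref_pos = ref + seq_len(len),
                              read_pos = rd + seq_len(len), op = "match")
              ref <- ref + len; rd <- rd + len; d },
      "X" = { d <- data.frame(ref_pos = ref + seq_len(len),
                              read_pos = rd + seq_len(len), op = "mismatch")
              ref <- ref + len; rd <- rd + len; d },
      "I" = { d <- data.frame(ref_pos = ref, read_pos = rd + 1L,
                              op = "insertion")
              rd <- rd + len; d },
      "D" = { d <- data.frame(ref_pos = ref + seq_len(len), read_pos = NA_integer_,
                              op = "deletion")
              ref <- ref + len; d })
  }
  do.call(rbind, out)
}

#' Build a pileup from alignments to one reference transcript
#'
#' Counts, per transcript position, the read bases observed there plus
#' insertion alleles (keyed `+SEQ`, attributed to the reference position
#' they follow) and deletion alleles (keyed `-SEQ`, attributed to the first
#' deleted position). Invalid alignments are skipped and counted.
#'
#' @param alignments List of `fcgr_alignment` objects.
#' @param reference The reference transcript they were aligned to.
#' @return Object of class `fcgr_pileup`: data frame `alleles` (`pos`,
#'   `allele`, `count`), integer vector `depth` (per position, reads whose
#'   alignment spans it), `n_invalid`, `reference`.
#' @export
build_pileup <- function(alignments, reference) {
  L <- nchar(reference)
  depth <- integer(L)
  pos_acc <- list(); al_acc <- list(); k <- 0L
  n_invalid <- 0L
  for (aln in alignments) {
    if (!isTRUE(aln$valid)) { n_invalid <- n_invalid + 1L; next }
    ops <- parse_cigar(aln$cigar)
    ref_end <- cumsum(ifelse(ops$op %in% c("=", "X", "D"), ops$len, 0L))
    ref_start <- c(0L, utils::head(ref_end, -1))
    read_end <- cumsum(ifelse(ops$op %in% c("=", "X", "I"), ops$len, 0L))
    read_start <- c(0L, utils::head(read_end, -1))
    rb <- strsplit(aln$seq, "")[[1]]
    for (i in seq_len(nrow(ops))) {
      op <- ops$op[i]; len <- ops$len[i]
      if (op %in% c("=", "X")) {
        pp <- ref_start[i] + seq_len(len)
        k <- k + 1L
        pos_acc[[k]] <- pp
        al_acc[[k]] <- rb[read_start[i] + seq_len(len)]
        depth[pp] <- depth[pp] + 1L
      } else if (op == "I") {
        if (ref_start[i] >= 1L) {   # insertions before position 1 are ignored
          k <- k + 1L
          pos_acc[[k]] <- ref_start[i]
          al_acc[[k]] <- paste0("+", paste(rb[read_start[i] + seq_len(len)],
                                           collapse = ""))
        }
      } else { # D
        pp <- ref_start[i] + seq_len(len)
        k <- k + 1L
        pos_acc[[k]] <- pp[1]
        al_acc[[k]] <- paste0("-", substr(reference, pp[1], pp[len]))
        depth[pp] <- depth[pp] + 1L
      }
    }
  }
  if (k == 0L) {
    alleles <- data.frame(pos = integer(0), allele = character(0),
                          count = integer(0))
  } else {
    pos <- unlist(pos_acc); al <- unlist(al_acc)
    keyed <- paste(pos, al, sep = "\r")
    tab <- table(keyed)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    alleles <- data.frame(
      pos = as.integer(vapply(parts, `[[`, character(1), 1)),
      allele = vapply(parts, `[[`, character(1), 2),
      count = as.integer(tab), stringsAsFactors = FALSE)
    alleles <- alleles[order(alleles$pos, -alleles$count), , drop = FALSE]
    rownames(alleles) <- NULL
  }
  structure(list(alleles = alleles, depth = depth, n_invalid = n_invalid,
                 reference = reference), class = "fcgr_pileup")
}

#' @export
print.fcgr_pileup <- function(x, ...) {
  cat(sprintf("<fcgr_pileup> %d positions, median depth %s, %d allele records, %d invalid reads\n",
              length(x$depth), format(stats::median(x$depth)), nrow(x$alleles),
              x$n_invalid))
  invisible(x)
}

#' Left-normalize an indel variant
#'
#' Shifts an insertion or deletion to its leftmost equivalent transcript
#' position and flags insertions that duplicate the reference bases they
#' follow (rendered with `dup` notation downstream). SNPs pass through
#' unchanged; the operation is idempotent.
#'
#' @param variant List with `type` (`"snp"`, `"ins"`, `"del"`), `pos`
#'   (insertion: reference position the insert follows; deletion: first
#'   deleted position), `seq` (inserted/deleted sequence), and for SNPs
#'   `tref`/`talt`.
#' @param reference Reference transcript sequence.
#' @return The variant with normalized `pos`/`seq` and `is_dup` set.
#' @export
normalize_variant <- function(variant, reference) {
  v <- as.list(variant)
  if (v$type == "snp") { v$is_dup <- FALSE; return(v) }
  chars <- strsplit(reference, "")[[1]]
  if (v$type == "ins") {
    s <- strsplit(v$seq, "")[[1]]; p <- v$pos
    while (p >= 1L && chars[p] == s[length(s)]) {
      s <- c(s[length(s)], s[-length(s)])   # rotate right
      p <- p - 1L
    }
    v$pos <- p; v$seq <- paste(s, collapse = "")
    len <- length(s)
    v$is_dup <- p + len <= length(chars) &&
      paste(chars[p + seq_len(len)], collapse = "") == v$seq
  } else {
    len <- nchar(v$seq); p <- v$pos
    while (p > 1L && chars[p - 1L] == chars[p + len - 1L]) p <- p - 1L
    v$pos <- p
    v$seq <- paste(chars[p + seq_len(len) - 1L], collapse = "")
    v$is_dup <- FALSE
  }
  v
}

# rightmost equivalent anchor of a (left-normalized) insertion; used to place
# minus-strand insertions at their plus-strand left-normalized genomic anchor
shift_ins_right <- function(pos, seq, reference) {
  chars <- strsplit(reference, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  while (pos + 1L <= length(chars) && chars[pos + 1L] == s[1]) {
    s <- c(s[-1], s[1])                     # rotate left
    pos <- pos + 1L
  }
  list(pos = pos, seq = paste(s, collapse = ""))
}

tpos_to_genomic <- function(gm, tpos) {
  ex <- gm$exons
  hit <- which(tpos >= ex$tstart & tpos <= ex$tend)
  if (length(hit) != 1L)
    stop(sprintf("transcript position %d outside %s", tpos, gm$gene_id))
  e <- ex[hit, ]
  if (gm$strand == "+") e$gstart + (tpos - e$tstart) else e$gend - (tpos - e$tstart)
}

# express a transcript-space call in plus-strand genomic coordinates and
# build its reporting key
genomic_fields <- function(gm, v) {
  minus <- gm$strand == "-"
  if (v$type == "snp") {
    gpos <- tpos_to_genomic(gm, v$pos)
    gref <- if (minus) rev_comp(v$tref) else v$tref
    galt <- if (minus) rev_comp(v$talt) else v$talt
    key <- sprintf("%s:%d:%s>%s", gm$chromosome, gpos, gref, galt)
  } else if (v$type == "ins") {
    if (minus) {
      r <- shift_ins_right(v$pos, v$seq, gm$reference_transcript)
      gpos <- tpos_to_genomic(gm, r$pos + 1L)   # plus-strand base left of insert
      galt <- rev_comp(r$seq)
    } else {
      gpos <- tpos_to_genomic(gm, v$pos)
      galt <- v$seq
    }
    gref <- ""
    key <- sprintf("%s:%d:>%s", gm$chromosome, gpos, galt)
  } else {
    len <- nchar(v$seq)
    gg <- vapply(v$pos + seq_len(len) - 1L,
                 function(t) tpos_to_genomic(gm, t), numeric(1))
    gpos <- min(gg)
    gref <- if (minus) rev_comp(v$seq) else v$seq
    galt <- ""
    key <- sprintf("%s:%d:%s>", gm$chromosome, gpos, gref)
  }
  list(gpos = gpos, gref = gref, galt = galt, key = key)
}

#' Call diploid genotypes from a pileup
#'
#' At every position covered by at least `min_depth` valid reads, alternate
#' alleles (substitutions, insertions, deletions) supported by at least
#' `min_alt_reads` reads are genotyped by allele fraction: heterozygous
#' within `het_fraction_range`, homozygous at or above `hom_fraction_min`,
#' otherwise no call. At most the two most frequent alternate alleles per
#' position are considered. Indels are left-normalized, and every call is
#' expressed in ORF, mature and plus-strand genomic coordinates.
#'
#' @param pileup An `fcgr_pileup`.
#' @param gm The `fcgr_gene_model` whose principal transcript was the
#'   alignment reference.
#' @param params Caller thresholds; see `default_caller_params()`.
#' @return Data frame of calls (possibly 0 rows): `gene_id`, `chrom`,
#'   `gpos`, `gref`, `galt`, `key`, `type`, `tpos`, `orf_pos`, `tref`,
#'   `talt`, `seq`, `is_dup`, `exon`, `zygosity`, `alt_count`, `depth`,
#'   `vaf`. Positions with depth below `min_depth` are reported in the
#'   `uncallable` attribute rather than dropped silently.
#' @export
call_genotypes <- function(pileup, gm, params = default_caller_params()) {
  stopifnot(inherits(pileup, "fcgr_pileup"))
  ref <- pileup$reference
  low <- which(pileup$depth < params$min_depth & pileup$depth > 0L)
  al <- pileup$alleles
  calls <- list(); k <- 0L
  if (nrow(al)) {
    al <- al[pileup$depth[al$pos] >= params$min_depth, , drop = FALSE]
    refbase <- substr(rep(ref, nrow(al)), al$pos, al$pos)
    al <- al[al$allele != refbase, , drop = FALSE]
    al <- al[al$count >= params$min_alt_reads, , drop = FALSE]
    if (nrow(al)) {
      # top two alternate alleles per position
      al <- al[order(al$pos, -al$count), , drop = FALSE]
      rank <- stats::ave(al$count, al$pos, FUN = seq_along)
      al <- al[rank <= 2L, , drop = FALSE]
      for (i in seq_len(nrow(al))) {
        d <- pileup$depth[al$pos[i]]
        f <- al$count[i] / d
        zyg <- if (f >= params$hom_fraction_min) "hom"
          else if (f >= params$het_fraction_range[1] &&
                   f <= params$het_fraction_range[2]) "het"
          else NA_character_
        if (is.na(zyg)) next
        a <- al$allele[i]
        v <- if (startsWith(a, "+"))
          list(type = "ins", pos = al$pos[i], seq = substring(a, 2L))
        else if (startsWith(a, "-"))
          list(type = "del", pos = al$pos[i], seq = substring(a, 2L))
        else
          list(type = "snp", pos = al$pos[i],
               tref = substr(ref, al$pos[i], al$pos[i]), talt = a, seq = "")
        v <- normalize_variant(v, ref)
        gf <- genomic_fields(gm, v)
        orf_pos <- tpos_to_orf(gm, v$pos)
        k <- k + 1L
        calls[[k]] <- data.frame(
          gene_id = gm$gene_id, chrom = gm$chromosome, gpos = gf$gpos,
          gref = gf$gref, galt = gf$galt, key = gf$key, type = v$type,
          tpos = v$pos, orf_pos = orf_pos,
          tref = if (v$type == "snp") v$tref else "",
          talt = if (v$type == "snp") v$talt else "",
          seq = v$seq, is_dup = isTRUE(v$is_dup),
          exon = exon_of_orf_pos(gm, orf_pos),
          zygosity = zyg, alt_count = al$count[i], depth = d, vaf = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (k) do.call(rbind, calls) else empty_calls()
  # one call per distinct normalized variant (the same normalized indel can
  # surface at two pileup columns only in pathological cases)
  out <- out[!duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "uncallable") <- low
  out
}

empty_calls <- function() {
  data.frame(gene_id = character(0), chrom = character(0), gpos = integer(0),
             gref = character(0), galt = character(0), key = character(0),
             type = character(0), tpos = integer(0), orf_pos = integer(0),
             tref = character(0), talt = character(0), seq = character(0),
             is_dup = logical(0), exon = character(0), zygosity = character(0),
             alt_count = integer(0), depth = integer(0), vaf = numeric(0),
             stringsAsFactors = FALSE)
}

#' Align and genotype every animal of a cohort
#'
#' Runs [align_read()], [build_pileup()] and [call_genotypes()] per animal
#' and gene.
#'
#' @param reads Nested list `reads[[animal]][[gene_id]]` of named read
#'   vectors (as produced by [simulate_cohort()], or read from FASTQ).
#' @param genes Named list of gene models.
#' @param params Caller thresholds.
#' @param scoring Alignment scoring.
#' @param min_score_per_base Alignment validity threshold.
#' @param band Alignment band half-width (see [align_read()]); the default
#'   48 comfortably covers consensus-read error rates plus small indel
#'   variants.
#' @return Data frame of per-animal calls (column `animal` added).
#' @export
call_cohort <- function(reads, genes, params = default_caller_params(),
                        scoring = default_scoring(), min_score_per_base = 1,
                        band = 48L) {
  out <- list(); k <- 0L
  for (a in names(reads)) {
    for (g in names(reads[[a]])) {
      gm <- genes[[g]]
      if (is.null(gm)) stop("no gene model for ", g)
      alns <- lapply(seq_along(reads[[a]][[g]]), function(i)
        align_read(reads[[a]][[g]][i], gm$reference_transcript,
                   scoring = scoring, min_score_per_base = min_score_per_base,
                   band = band))
      pu <- build_pileup(alns, gm$reference_transcript)
      calls <- call_genotypes(pu, gm, params)
      if (nrow(calls)) {
        calls$animal <- a
        k <- k + 1L
        out[[k]] <- calls
      }
    }
  }
  if (!k) {
    e <- empty_calls(); e$animal <- character(0)
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
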