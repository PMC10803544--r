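# Classification of coding effects and rendering of the four coordinate
# notations: ORF-numbered ("ANNOVAR") nucleotide and protein strings, and the
# corresponding mature-protein-numbered strings.

#' Locate the codon containing an ORF nucleotide position
#'
#' @param orf_nt_pos ORF nucleotide position(s), 1-based at the start codon.
#' @return Data frame with `codon` (`ceiling(pos/3)`) and `offset`
#'   (position within the codon, 1-3).
#' @export
locate_codon <- function(orf_nt_pos) {
  p <- as.integer(orf_nt_pos)
  if (any(p < 1L)) stop("ORF positions are 1-based")
  data.frame(codon = (p + 2L) %/% 3L, offset = (p - 1L) %% 3L + 1L)
}

#' Convert an ORF nucleotide position to mature-transcript numbering
#'
#' Mature numbering drops the signal-peptide codons: the result is
#' `orf_nt_pos - 3 * signal_peptide_len`. Values of zero or less indicate a
#' position within the signal-peptide-coding region.
#'
#' @param orf_nt_pos ORF nucleotide position(s).
#' @param gm An `fcgr_gene_model` (or an integer signal-peptide length).
#' @return Integer vector of mature nucleotide indices.
#' @export
to_mature_nt <- function(orf_nt_pos, gm) {
  L <- if (inherits(gm, "fcgr_gene_model")) gm$signal_peptide_len else as.integer(gm)
  as.integer(orf_nt_pos) - 3L * L
}

#' Convert an ORF residue index to mature-protein numbering
#'
#' Residues after the signal peptide map to `index - L`; signal-peptide
#' residues map to negative integers (`index - L - 1`), skipping zero, where
#' `L` is the signal-peptide length.
#'
#' @param annovar_aa_index ORF residue index (position 1 = initiator Met).
#' @param gm An `fcgr_gene_model` (or an integer signal-peptide length).
#' @return Integer vector of mature residue indices (negative in the signal).
#' @export
to_mature_aa <- function(annovar_aa_index, gm) {
  L <- if (inherits(gm, "fcgr_gene_model")) gm$signal_peptide_len else as.integer(gm)
  i <- as.integer(annovar_aa_index)
  if (any(i < 1L)) stop("ORF residue indices are 1-based")
  ifelse(i > L, i - L, i - L - 1L)
}

codon_at <- function(orf_seq, codon_idx) {
  substr(orf_seq, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

orf_sequence <- function(gm) {
  prot <- translate_cds(gm$reference_transcript, gm$orf_start)
  substr(gm$reference_transcript, gm$orf_start,
         gm$orf_start + 3L * (nchar(prot) + 1L) - 1L)
}

#' Classify a variant's coding effect and render all four notations
#'
#' Takes a normalized variant in transcript-strand ORF coordinates and
#' returns its effect category together with ORF-numbered and
#' mature-numbered nucleotide/protein notations. SNPs are compared codon by
#' codon; indel protein effects are derived by translating the full mutant
#' ORF and diffing it against the reference protein, so frameshift naming
#' (`p.X#fs` at the first changed residue) and in-frame insertion naming
#' (`delins`, new residues preceding the anchored residue) fall out of the
#' actual translation rather than positional arithmetic.
#'
#' @param variant List or one-row data frame with fields `type`
#'   (`"snp"`, `"ins"`, `"del"`), `orf_pos` (SNP position, insertion anchor =
#'   position after which the sequence is inserted, or first deleted
#'   position), `tref`/`talt` (transcript-strand SNP alleles), `seq`
#'   (inserted/deleted transcript-strand sequence), `is_dup` (insertions:
#'   whether the left-normalized insertion duplicates the preceding
#'   reference bases).
#' @param gm The `fcgr_gene_model` the coordinates refer to.
#' @return Object of class `fcgr_coding_effect` with fields `category`,
#'   `annovar_nt`, `annovar_aa`, `mature_nt`, `mature_aa`,
#'   `mature_residue_index`, `orf_residue_index`, `signal_region`.
#' @export
classify_effect <- function(variant, gm) {
  v <- as.list(variant)
  orf_seq <- orf_sequence(gm)
  orf_len <- nchar(orf_seq)
  prot <- translate_cds(gm$reference_transcript, gm$orf_start)
  L <- gm$signal_peptide_len

  out <- list(category = NA_character_, annovar_nt = NA_character_,
              annovar_aa = NA_character_, mature_nt = NA_character_,
              mature_aa = NA_character_, mature_residue_index = NA_integer_,
              orf_residue_index = NA_integer_, signal_region = FALSE)

  in_orf <- switch(v$type,
    snp = v$orf_pos >= 1L && v$orf_pos <= orf_len,
    ins = v$orf_pos >= 1L && v$orf_pos < orf_len,
    del = v$orf_pos >= 1L && v$orf_pos <= orf_len)
  if (!in_orf) {
    out$category <- "UTR"
    return(structure(out, class = "fcgr_coding_effect"))
  }

  mat_nt <- function(p) to_mature_nt(p, gm)

  if (v$type == "snp") {
    if (identical(v$tref, v$talt)) stop("reference and alternate alleles are identical")
    loc <- locate_codon(v$orf_pos)
    ref_codon <- codon_at(orf_seq, loc$codon)
    if (substr(ref_codon, loc$offset, loc$offset) != v$tref)
      stop(sprintf("reference allele %s does not match %s ORF position %d",
                   v$tref, gm$gene_id, v$orf_pos))
    alt_codon <- ref_codon
    substr(alt_codon, loc$offset, loc$offset) <- v$talt
    ref_aa <- translate_codon(ref_codon); alt_aa <- translate_codon(alt_codon)
    out$category <- if (ref_aa == alt_aa) "synonymous SNP"
      else if (alt_aa == "*") "stop-gain"
      else if (ref_aa == "*") "stop-loss"
      else "nonsynonymous SNP"
    out$orf_residue_index <- loc$codon
    out$mature_residue_index <- to_mature_aa(loc$codon, gm)
    out$signal_region <- out$mature_residue_index < 0L
    out$annovar_nt <- sprintf("c.%s%d%s", v$tref, v$orf_pos, v$talt)
    out$mature_nt <- sprintf("%s%d%s", v$tref, mat_nt(v$orf_pos), v$talt)
    out$annovar_aa <- sprintf("p.%s%d%s", ref_aa, loc$codon, alt_aa)
    out$mature_aa <- sprintf("%s%d%s", ref_aa, out$mature_residue_index, alt_aa)
    return(structure(out, class = "fcgr_coding_effect"))
  }

  # --- indels: build the mutant ORF and diff the translations ---------------
  len <- nchar(v$seq)
  frameshift <- (len %% 3L) != 0L
  a <- v$orf_pos
  if (v$type == "ins") {
    mutant <- paste0(substr(orf_seq, 1L, a), v$seq,
                     substr(orf_seq, a + 1L, orf_len),
                     # downstream transcript so a shifted frame finds a stop
                     substr(gm$reference_transcript, gm$orf_start + orf_len,
                            nchar(gm$reference_transcript)))
    out$category <- if (frameshift) "frameshift insertion" else "non-frameshift insertion"
    if (isTRUE(v$is_dup)) {
      p1 <- a + 1L; p2 <- a + len
      out$annovar_nt <- if (len == 1L) sprintf("c.%ddup%s", p1, v$seq)
        else sprintf("c.%d_%ddup%s", p1, p2, v$seq)
      out$mature_nt <- if (len == 1L) sprintf("%ddup%s", mat_nt(p1), v$seq)
        else sprintf("%d_%ddup%s", mat_nt(p1), mat_nt(p2), v$seq)
    } else {
      out$annovar_nt <- sprintf("c.%d_%dins%s", a, a + 1L, v$seq)
      out$mature_nt <- sprintf("%d_%dins%s", mat_nt(a), mat_nt(a + 1L), v$seq)
    }
  } else {
    p1 <- a; p2 <- a + len - 1L
    mutant <- paste0(substr(orf_seq, 1L, p1 - 1L),
                     substr(orf_seq, p2 + 1L, orf_len),
                     substr(gm$reference_transcript, gm$orf_start + orf_len,
                            nchar(gm$reference_transcript)))
    out$category <- if (frameshift) "frameshift deletion" else "non-frameshift deletion"
    out$annovar_nt <- if (len == 1L) sprintf("c.%ddel%s", p1, v$seq)
      else sprintf("c.%d_%ddel%s", p1, p2, v$seq)
    out$mature_nt <- if (len == 1L) sprintf("%ddel%s", mat_nt(p1), v$seq)
      else sprintf("%d_%ddel%s", mat_nt(p1), mat_nt(p2), v$seq)
  }

  mut_prot <- translate_cds(paste0("ATG", substr(mutant, 4L, nchar(mutant))), 1L)

  if (frameshift) {
    rp <- strsplit(prot, "")[[1]]; mp <- strsplit(mut_prot, "")[[1]]
    k <- 1L
    while (k <= min(length(rp), length(mp)) && rp[k] == mp[k]) k <- k + 1L
    k <- min(k, length(rp))
    out$orf_residue_index <- k
    out$mature_residue_index <- to_mature_aa(k, gm)
    out$signal_region <- out$mature_residue_index < 0L
    out$annovar_aa <- sprintf("p.%s%dfs", rp[k], k)
    out$mature_aa <- sprintf("%s%dfs", rp[k], out$mature_residue_index)
  } else {
    d <- diff_proteins(prot, mut_prot)
    rp <- strsplit(prot, "")[[1]]
    if (d$type == "insertion") {
      i <- d$at
      anchor_aa <- rp[i]
      out$orf_residue_index <- i
      out$mature_residue_index <- to_mature_aa(i, gm)
      out$signal_region <- out$mature_residue_index < 0L
      out$annovar_aa <- sprintf("p.%s%ddelins%s%s", anchor_aa, i, d$residues, anchor_aa)
      out$mature_aa <- sprintf("%s%ddelins%s%s", anchor_aa,
                               out$mature_residue_index, d$residues, anchor_aa)
    } else if (d$type == "deletion") {
      i <- d$at
      out$orf_residue_index <- i
      out$mature_residue_index <- to_mature_aa(i, gm)
      out$signal_region <- out$mature_residue_index < 0L
      if (d$len == 1L) {
        out$annovar_aa <- sprintf("p.%s%ddel", rp[i], i)
        out$mature_aa <- sprintf("%s%ddel", rp[i], out$mature_residue_index)
      } else {
        j <- i + d$len - 1L
        out$annovar_aa <- sprintf("p.%s%d_%s%ddel", rp[i], i, rp[j], j)
        out$mature_aa <- sprintf("%s%d_%s%ddel", rp[i], out$mature_residue_index,
                                 rp[j], to_mature_aa(j, gm))
      }
    } else {
      # in-frame indel altering residues in place (e.g. not codon-aligned)
      i <- if (is.na(d$at)) 1L else d$at
      out$orf_residue_index <- i
      out$mature_residue_index <- to_mature_aa(i, gm)
      out$annovar_aa <- sprintf("p.%s%ddelins%s", rp[i], i, d$residues)
      out$mature_aa <- sprintf("%s%ddelins%s", rp[i], out$mature_residue_index,
                               d$residues)
    }
  }
  structure(out, class = "fcgr_coding_effect")
}

#' @export
print.fcgr_coding_effect <- function(x, ...) {
  cat(sprintf("<fcgr_coding_effect> %s: %s / %s (mature %s / %s)\n",
              x$category, x$annovar_nt, x$annovar_aa, x$mature_nt, x$mature_aa))
  invisible(x)
}

#' Render the coding-sequence notation of a classified effect
#'
#' @param effect An `fcgr_coding_effect` from [classify_effect()].
#' @param mature Logical; return the mature-transcript rendering instead of
#'   the ORF-numbered (`c.`) one.
#' @return Character scalar.
#' @export
format_hgvs_c <- function(effect, mature = FALSE) {
  stopifnot(inherits(effect, "fcgr_coding_effect"))
  if (mature) effect$mature_nt else effect$annovar_nt
}

#' Render the protein notation of a classified effect
#'
#' Protein naming follows the reported tables' dialect: single-letter
#' residues, `fs` without an extension length, and `delins` for an in-frame
#' insertion anchored at an existing residue.
#'
#' @inheritParams format_hgvs_c
#' @return Character scalar.
#' @export
format_hgvs_p <- function(effect, mature = FALSE) {
  stopifnot(inherits(effect, "fcgr_coding_effect"))
  if (mature) effect$mature_aa else effect$annovar_aa
}

#' Annotate a table of variant calls with coding effects and domains
#'
#' @param calls Data frame of calls as produced by [call_genotypes()] /
#'   [call_cohort()] (one row per animal x variant).
#' @param genes Named list of gene models.
#' @return `calls` with columns `category`, `annovar_nt`, `annovar_aa`,
#'   `mature_nt`, `mature_aa`, `mature_residue_index`, `domain` appended.
#' @export
annotate_calls <- function(calls, genes) {
  if (nrow(calls) == 0L) {
    for (cc in c("category", "annovar_nt", "annovar_aa", "mature_nt",
                 "mature_aa", "domain")) calls[[cc]] <- character(0)
    calls$mature_residue_index <- integer(0)
    return(calls)
  }
  eff <- lapply(seq_len(nrow(calls)), function(i) {
    gm <- genes[[calls$gene_id[i]]]
    e <- classify_effect(calls[i, ], gm)
    dom <- if (is.na(e$mature_residue_index)) NA_character_
      else assign_domain(e$mature_residue_index, gm)
    c(e[c("category", "annovar_nt", "annovar_aa", "mature_nt", "mature_aa")],
      list(mature_residue_index = e$mature_residue_index, domain = dom))
  })
  for (cc in c("category", "annovar_nt", "annovar_aa", "mature_nt", "mature_aa"))
    calls[[cc]] <- vapply(eff, function(e) e[[cc]], character(1))
  calls$mature_residue_index <- vapply(eff, `[[`, integer(1), "mature_residue_index")
  calls$domain <- vapply(eff, `[[`, character(1), "domain")
  calls
}
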