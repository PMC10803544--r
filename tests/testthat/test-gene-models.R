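genes <- fcgr_gene_set()
reported <- fcgr_reported_variants()

parse_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):(\\d+):([ACGT]*)>([ACGT]+)$", key))[[1]]
  list(chrom = m[2], gpos = as.integer(m[3]), ref = m[4], alt = m[5])
}
parse_cnt <- function(s) {
  r <- regmatches(s, regexec("^c\\.([ACGT])(\\d+)([ACGT])$", s))[[1]]
  list(ref = r[2], pos = as.integer(r[3]), alt = r[4])
}

test_that("packaged gene models encode the published numbering offsets", {
  expect_named(genes, c("FCGR1", "FCGR2A", "FCGR2B", "FCGR3"))
  expect_equal(genes$FCGR1$signal_peptide_len, 17L)   # p.V45A <-> V28A
  expect_equal(genes$FCGR2A$signal_peptide_len, 35L)  # p.P38P <-> P3P
  expect_equal(genes$FCGR2B$signal_peptide_len, 45L)
  expect_equal(genes$FCGR3$signal_peptide_len, 54L)
  # nucleotide offset between ORF and mature numbering is 3 * signal length
  expect_equal(to_mature_nt(114, genes$FCGR2A), 9L)   # 105-nt offset
  expect_equal(genes$FCGR3$orf_start, 54L)            # 5' UTR before the ORF
  for (gm in genes) expect_silent(validate_gene_model(gm))
})

test_that("gene model validation rejects malformed structures", {
  gm <- toy_gene()
  bad <- gm$exons; bad$gend[1] <- bad$gend[1] + 5L  # length mismatch
  expect_error(gene_model("BAD", "chrT", "+", bad, 1L, 5L,
                          gm$reference_transcript, gm$domain_map),
               "lengths differ")
  bad2 <- gm$exons; bad2$gstart[2] <- 1050L; bad2$gend[2] <- 1169L
  expect_error(gene_model("BAD", "chrT", "+", bad2, 1L, 5L,
                          gm$reference_transcript, gm$domain_map),
               "overlapping")
  expect_error(gene_model("BAD", "chrT", "+", gm$exons, 2L, 5L,
                          gm$reference_transcript, gm$domain_map),
               "ATG")
  expect_error(gene_model("BAD", "chrT", "+", gm$exons, 1L, 5L,
                          gm$reference_transcript, gm$domain_map,
                          contact_residues = 80L),  # transmembrane residue
               "contact")
})

test_that("genomic-to-transcript mapping reproduces every published coordinate pair", {
  snp <- reported[grepl("^c\\.[ACGT]", reported$annovar_nt), ]
  for (i in seq_len(nrow(snp))) {
    k <- parse_key(snp$Variant[i])
    cn <- parse_cnt(snp$annovar_nt[i])
    mp <- genomic_to_transcript(genes[[snp$gene_id[i]]], k$gpos, k$ref, k$alt)
    expect_equal(mp$orf_pos, cn$pos, info = snp$Variant[i])
    expect_equal(mp$ref, cn$ref, info = snp$Variant[i])
    expect_equal(mp$alt, cn$alt, info = snp$Variant[i])
    expect_equal(mp$exon, as.character(snp$Exon[i]), info = snp$Variant[i])
  }
})

test_that("per-exon affine mapping constants hold across whole exons", {
  for (gm in genes) {
    for (e in seq_len(nrow(gm$exons))) {
      tps <- seq(gm$exons$tstart[e], gm$exons$tend[e], length.out = 5)
      orf <- unique(round(tps)) - gm$orf_start + 1L
      gp <- vapply(orf, function(p) transcript_to_genomic(gm, p), numeric(1))
      cons <- if (gm$strand == "-") gp + orf else gp - orf
      expect_length(unique(cons), 1L)
    }
  }
})

test_that("genomic/transcript mapping is a bijection on exonic positions", {
  for (gm in genes[c("FCGR1", "FCGR3")]) {
    orf_len <- nchar(gm$reference_transcript) - gm$orf_start + 1L
    pos <- seq_len(orf_len)
    gp <- vapply(pos, function(p) transcript_to_genomic(gm, p), numeric(1))
    expect_false(anyDuplicated(gp) > 0)
    back <- vapply(gp, function(g) genomic_to_transcript(gm, g)$orf_pos,
                   numeric(1))
    expect_equal(back, pos)
  }
  expect_error(genomic_to_transcript(genes$FCGR1, 5L), "not exonic")
  expect_error(transcript_to_genomic(genes$FCGR1, 99999L), "beyond")
})

test_that("spot checks against published rows map in both directions", {
  expect_equal(genomic_to_transcript(genes$FCGR1, 101378924L, "A", "G")$orf_pos,
               134L)
  expect_equal(genomic_to_transcript(genes$FCGR1, 101378924L, "A", "G")$ref, "T")
  expect_equal(genomic_to_transcript(genes$FCGR3, 89392794L, "G", "A")$orf_pos,
               805L)
  expect_equal(transcript_to_genomic(genes$FCGR2A, 489L), 89427299)
  expect_equal(transcript_to_genomic(genes$FCGR2B, 532L), 89331119)
})

test_that("translation follows the standard code and stops at the stop codon", {
  expect_equal(translate_cds("ATGGCTTAA"), "MA")
  expect_equal(translate_cds("ATGGCT"), "MA")        # no stop: runs off the end
  expect_equal(translate_cds("CCATGGCTTAAGG", orf_start = 3L), "MA")
  expect_error(translate_cds("GTGGCTTAA"), "ATG")
  expect_error(translate_cds("ATG", orf_start = 5L), "outside")
})

test_that("isoform construction does the published structural arithmetic", {
  gm <- genes$FCGR2B
  p0 <- build_isoform(gm)$protein_seq
  p6 <- build_isoform(gm, list(list(type = "exon_include", label = "6")))
  expect_equal(nchar(p6$transcript_seq) - nchar(gm$reference_transcript), 57L)
  d <- diff_proteins(p0, p6$protein_seq)
  expect_equal(d$type, "insertion")
  expect_equal(d$len, 19L)                       # 57-nt cassette -> 19 aa
  expect_equal(to_mature_aa(d$at, gm), 257L)     # cytoplasmic, position 257

  gm2 <- genes$FCGR2A
  q5 <- build_isoform(gm2, list(list(type = "splice5_ext", label = "5",
                                     nt = 15L)))
  d2 <- diff_proteins(build_isoform(gm2)$protein_seq, q5$protein_seq)
  expect_equal(d2$len, 5L)                       # 15-nt extension -> 5 aa
  expect_equal(to_mature_aa(d2$at, gm2), 207L)   # occupies mature 207-211
  expect_equal(to_mature_aa(d2$at + d2$len - 1L, gm2), 211L)

  expect_equal(build_isoform(gm2)$transcript_seq, gm2$reference_transcript)
  expect_error(build_isoform(gm2, list(list(type = "exon_skip", label = "99"))),
               "unknown exon")
})

test_that("in-frame edits change protein length by net nt / 3", {
  gm <- toy_gene()
  cases <- list(
    list(edits = list(list(type = "exon_include", label = "2b")), nt = 30L),
    list(edits = list(list(type = "exon_skip", label = "2")), nt = -120L),
    list(edits = list(list(type = "residue_del", residue = 10L)), nt = -3L),
    list(edits = list(list(type = "residue_ins", residue = 10L, aa = "W")),
         nt = 3L))
  p0 <- build_isoform(gm)$protein_seq
  for (cs in cases) {
    iso <- build_isoform(gm, cs$edits)
    expect_equal(nchar(iso$protein_seq) - nchar(p0), cs$nt / 3L)
  }
})
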