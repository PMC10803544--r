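# A small synthetic plus-strand gene with three isoforms, built in code, used
# where the packaged receptor fixtures would be needlessly large.

toy_gene <- function(seed = 42) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  codons <- sample(names(gc)[gc != "*"], 100, replace = TRUE)
  codons[1] <- "ATG"; codons[100] <- "TAA"
  ref <- paste(codons, collapse = "")
  cassette <- "GATCTGGAAGTTCGCACCATTCCTAGCAAG"  # 30 nt, in frame, no stop
  gene_model(
    gene_id = "TOY", chromosome = "chrT", strand = "+",
    exons = data.frame(label = c("1", "2", "3"),
                       tstart = c(1L, 91L, 211L), tend = c(90L, 210L, 300L),
                       gstart = c(1001L, 2001L, 3001L),
                       gend = c(1090L, 2120L, 3090L)),
    orf_start = 1L, signal_peptide_len = 5L,
    reference_transcript = ref,
    domain_map = data.frame(start = c(-5L, 1L, 41L, 61L, 76L),
                            end = c(-1L, 40L, 60L, 75L, 94L),
                            label = c("signal", "extracellular-D1",
                                      "extracellular-other", "transmembrane",
                                      "cytoplasmic")),
    contact_residues = c(10L, 20L, 21L, 22L),
    contact_source = "synthetic",
    alt_exons = data.frame(label = "2b", insert_after = 210L, seq = cassette,
                           gstart = 2500L, gend = 2529L),
    isoforms = list(
      list(id = "TOY_A", protein_id = "TOYP_A", edits = list()),
      list(id = "TOY_B", protein_id = "TOYP_B",
           edits = list(list(type = "exon_include", label = "2b"))),
      list(id = "TOY_C", protein_id = "TOYP_C",
           edits = list(list(type = "exon_skip", label = "2"))))
  )
}

toy_variants <- function(gm = toy_gene()) {
  # a SNP in exon 2 and a 3-nt insertion in exon 3 (already left-normalized:
  # its ends differ from the flanking reference bases), in plus-strand terms
  bases <- c("A", "C", "G", "T")
  ref150 <- substr(gm$reference_transcript, 150, 150)
  alt150 <- setdiff(bases, ref150)[1]
  ref230 <- substr(gm$reference_transcript, 230, 230)  # t230 <-> g3020
  ref231 <- substr(gm$reference_transcript, 231, 231)
  ins <- paste0(setdiff(bases, ref231)[1], "C", setdiff(bases, ref230)[1])
  data.frame(gene_id = "TOY", chrom = "chrT",
             gpos = c(2060L, 3020L),
             ref = c(ref150, ""),
             alt = c(alt150, ins),
             stringsAsFactors = FALSE)
}
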