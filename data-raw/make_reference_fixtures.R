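# Deterministically generates the packaged gene-model fixtures:
#   inst/extdata/fcgr_genes.yaml      gene models (exons, domains, contacts,
#                                     isoform splice structures)
#   inst/extdata/fcgr_refs.fasta      synthetic principal transcripts
#   inst/extdata/reported_variants.tsv  published cohort variant rows
#   inst/extdata/reported_isoforms.tsv  published isoform carrier rows
#
# The transcripts are synthetic: exon boundaries and filler codons are
# invented, but every published per-exon coordinate-mapping constant,
# signal-peptide offset, reference/alternate allele, codon identity, exon
# label and domain label of the reported variant rows is encoded exactly.
# The script validates the full round trip (genomic key -> annotation
# strings) before writing anything.
#
# Run from the package root:  Rscript data-raw/make_reference_fixtures.R

suppressMessages(devtools::load_all(".", quiet = TRUE))
set.seed(20240109)

GC <- Biostrings::GENETIC_CODE
CODONS <- names(GC)[GC != "*"]

filler_codons <- function(n) sample(CODONS, n, replace = TRUE)

choose_codon <- function(ref_aa, offset, ref_base, alt_base, alt_aa) {
  for (c in names(GC)) {
    if (GC[[c]] != ref_aa) next
    if (substr(c, offset, offset) != ref_base) next
    alt <- c
    substr(alt, offset, offset) <- alt_base
    if (GC[[alt]] == alt_aa) return(c)
  }
  stop(sprintf("no codon for %s offset %d %s>%s -> %s", ref_aa, offset,
               ref_base, alt_base, alt_aa))
}

# ---- published variant rows (one table per gene, printed order) ------------
rv <- function(gene, key, desc, exon, a_nt, a_aa, m_nt, m_aa, dom, cc, pct)
  data.frame(gene_id = gene, Variant = key, Description = desc, Exon = exon,
             annovar_nt = a_nt, annovar_aa = a_aa, mature_nt = m_nt,
             mature_aa = m_aa, Domain = dom, carrier_count = cc,
             cohort_size = 206L, pct_printed = pct, stringsAsFactors = FALSE)

reported <- rbind(
  rv("FCGR1", "chr1:101378924:A>G", "nonsynonymous SNP", "3", "c.T134C", "p.V45A", "T83C",  "V28A",  "Extracellular", 52L, "25.2"),
  rv("FCGR1", "chr1:101378806:C>G", "nonsynonymous SNP", "3", "c.G252C", "p.R84S", "G201C", "R67S",  "Extracellular", 36L, "17.5"),
  rv("FCGR1", "chr1:101378828:A>G", "nonsynonymous SNP", "3", "c.T230C", "p.V77A", "T179C", "V60A",  "Extracellular", 28L, "13.6"),
  rv("FCGR1", "chr1:101378934:G>C", "nonsynonymous SNP", "3", "c.C124G", "p.Q42E", "C73G",  "Q25E",  "Extracellular", 10L, "4.8"),
  rv("FCGR1", "chr1:101374528:G>A", "nonsynonymous SNP", "4", "c.C457T", "p.L153F", "C406T", "L136F", "Extracellular", 7L, "3.4"),
  rv("FCGR1", "chr1:101378991:>T",  "fs insertion",      "3", "c.66dupA", "p.V23fs", "15dupA", "V6fs", "Extracellular", 6L, "2.9"),
  rv("FCGR1", "chr1:101373136:C>T", "synonymous SNP",    "5", "c.G603A", "p.P201P", "G552A", "P184P", "Extracellular", 5L, "2.4"),
  rv("FCGR1", "chr1:101378972:G>A", "nonsynonymous SNP", "3", "c.C86T",  "p.P29L", "C35T",  "P12L",  "Extracellular", 5L, "2.4"),

  rv("FCGR2A", "chr1:89419258:>ATC", "non-fs insertion",  "7", "c.894_895insGAT", "p.R299delinsDR", "789_790insGAT", "R264delinsDR", "Cytoplasmic", 140L, "68"),
  rv("FCGR2A", "chr1:89431476:C>T", "synonymous SNP",    "3", "c.G114A", "p.P38P",  "G9A",   "P3P",   "Extracellular", 24L, "11.6"),
  rv("FCGR2A", "chr1:89431321:A>C", "nonsynonymous SNP", "3", "c.T269G", "p.M90R",  "T164G", "M55R",  "Extracellular", 24L, "11.6"),
  rv("FCGR2A", "chr1:89431407:A>G", "synonymous SNP",    "3", "c.T183C", "p.C61C",  "T78C",  "C26C",  "Extracellular", 23L, "11.1"),
  rv("FCGR2A", "chr1:89427299:G>T", "nonsynonymous SNP", "4", "c.C489A", "p.N163K", "C384A", "N128K", "Extracellular", 23L, "11.1"),
  rv("FCGR2A", "chr1:89431374:G>A", "synonymous SNP",    "3", "c.C216T", "p.T72T",  "C111T", "T37T",  "Extracellular", 23L, "11.1"),
  rv("FCGR2A", "chr1:89419246:T>G", "nonsynonymous SNP", "7", "c.A907C", "p.M303L", "A802C", "M268L", "Cytoplasmic", 22L, "10.7"),
  rv("FCGR2A", "chr1:89427309:T>A", "nonsynonymous SNP", "4", "c.A479T", "p.K160I", "A374T", "K125I", "Extracellular", 16L, "7.8"),
  rv("FCGR2A", "chr1:89427264:T>C", "nonsynonymous SNP", "4", "c.A524G", "p.Q175R", "A419G", "Q140R", "Extracellular", 13L, "6.3"),
  rv("FCGR2A", "chr1:89427254:G>A", "synonymous SNP",    "4", "c.C534T", "p.H178H", "C429T", "H143H", "Extracellular", 8L, "3.9"),
  rv("FCGR2A", "chr1:89427291:T>G", "nonsynonymous SNP", "4", "c.A497C", "p.H166P", "A392C", "H131P", "Extracellular", 5L, "2.4"),
  rv("FCGR2A", "chr1:89427286:T>C", "nonsynonymous SNP", "4", "c.A502G", "p.N168D", "A397G", "N133D", "Extracellular", 5L, "2.4"),
  rv("FCGR2A", "chr1:89419298:G>A", "synonymous SNP",    "7", "c.C855T", "p.G285G", "C750T", "G250G", "Cytoplasmic", 5L, "2.4"),

  rv("FCGR2B", "chr1:89331119:T>C", "nonsynonymous SNP", "4", "c.A532G", "p.N178D", "A397G", "N133D", "Extracellular", 43L, "20.9"),
  rv("FCGR2B", "chr1:89331140:A>C", "nonsynonymous SNP", "4", "c.T511G", "p.S171A", "T376G", "S126A", "Extracellular", 30L, "14.6"),
  rv("FCGR2B", "chr1:89331111:G>A", "synonymous SNP",    "4", "c.C540T", "p.N180N", "C405T", "N135N", "Extracellular", 29L, "14.1"),
  rv("FCGR2B", "chr1:89326856:A>G", "synonymous SNP",    "7", "c.T846C", "p.D282D", "T711C", "D237D", "Extracellular", 17L, "8.2"),
  rv("FCGR2B", "chr1:89331097:T>C", "nonsynonymous SNP", "4", "c.A554G", "p.Q185R", "A419G", "Q140R", "Extracellular", 12L, "5.8"),
  rv("FCGR2B", "chr1:89331161:T>C", "nonsynonymous SNP", "4", "c.A490G", "p.T164A", "A355G", "T119A", "Extracellular", 9L, "4.4"),
  rv("FCGR2B", "chr1:89331142:A>T", "nonsynonymous SNP", "4", "c.T509A", "p.I170K", "T374A", "I125K", "Extracellular", 6L, "2.9"),
  rv("FCGR2B", "chr1:89331246:G>A", "synonymous SNP",    "4", "c.C405T", "p.L135L", "C270T", "L90L",  "Extracellular", 6L, "2.9"),
  rv("FCGR2B", "chr1:89331024:A>G", "synonymous SNP",    "4", "c.T627C", "p.P209P", "T492C", "P164P", "Extracellular", 5L, "2.4"),

  rv("FCGR3", "chr1:89392794:G>A", "nonsynonymous SNP", "5", "c.G805A", "p.V269I", "G643A", "V215I", "Cytoplasmic", 139L, "67.5"),
  rv("FCGR3", "chr1:89392782:G>A", "nonsynonymous SNP", "5", "c.G793A", "p.V265M", "G631A", "V211M", "Cytoplasmic", 138L, "67"),
  rv("FCGR3", "chr1:89387252:G>A", "synonymous SNP",    "3", "c.G411A", "p.Q137Q", "G249A", "Q83Q",  "Extracellular", 35L, "17"),
  rv("FCGR3", "chr1:89390827:A>G", "nonsynonymous SNP", "4", "c.A634G", "p.I212V", "A472G", "I158V", "Extracellular", 16L, "7.8"),
  rv("FCGR3", "chr1:89392727:T>C", "synonymous SNP",    "5", "c.T738C", "p.S246S", "T576C", "S192S", "Extracellular", 8L, "3.9"),
  rv("FCGR3", "chr1:89390721:G>A", "synonymous SNP",    "4", "c.G528A", "p.T176T", "G366A", "T122T", "Extracellular", 8L, "3.9"),
  rv("FCGR3", "chr1:89387025:G>T", "nonsynonymous SNP", "3", "c.G184T", "p.A61S",  "G22T",  "A8S",   "Extracellular", 6L, "2.9")
)

# ---- published isoform carrier rows ----------------------------------------
ri <- function(gene, iso, prot, cc, pct)
  data.frame(gene_id = gene, isoform = iso, protein = prot,
             carrier_count = cc, cohort_size = 206L, pct_printed = pct,
             stringsAsFactors = FALSE)
reported_iso <- rbind(
  ri("FCGR2A", "FCGR2A_XM_015113136.2", "XP_014968622.2", 192L, "93.2"),
  ri("FCGR2A", "FCGR2A_XM_028846297.1", "XP_028702130.1", 109L, "52.9"),
  ri("FCGR2A", "FCGR2A_NM_001257300.1", "NP_001244229.1",  86L, "41.7"),
  ri("FCGR2A", "FCGR2A_XM_028846295.1", "XP_028702128.1",  62L, "30.1"),
  ri("FCGR2B", "FCGR2B_XM_015113204.2", "XP_014968690.1", 201L, "97.6"),
  ri("FCGR2B", "FCGR2B_XM_015113196.2", "XP_014968682.1", 196L, "95.1"),
  ri("FCGR2B", "FCGR2B_NM_001271648.2", "NP_001258577.2",   9L, "4.4"),
  ri("FCGR2B", "FCGR2B_NM_001257302.1", "NP_001244231.1",   1L, "0.48"),
  ri("FCGR3",  "FCGR3_NM_001271657.1",  "NP_001258586.1", 201L, "97.6"),
  ri("FCGR3",  "FCGR3_XM_015113171.2",  "XP_014968657.2", 141L, "68.4"),
  ri("FCGR3",  "FCGR3_XM_015113175.2",  "XP_014968661.2", 134L, "65.0"),
  ri("FCGR3",  "FCGR3_NM_001271654.1",  "NP_001258583.1",   4L, "1.94"),
  ri("FCGR3",  "FCGR3_NM_001271653.1",  "NP_001258582.1",   3L, "1.46"),
  ri("FCGR3",  "FCGR3_NM_001271656.1",  "NP_001258585.1",   3L, "1.46"),
  ri("FCGR3",  "FCGR3_NM_001271655.1",  "NP_001258584.1",   2L, "0.97")
)

# ---- gene layouts ----------------------------------------------------------
ex <- function(label, tstart, tend, gstart, gend)
  list(label = label, tstart = as.integer(tstart), tend = as.integer(tend),
       gstart = as.integer(gstart), gend = as.integer(gend))
dom <- function(start, end, label)
  list(start = as.integer(start), end = as.integer(end), label = label)

layouts <- list(
  FCGR1 = list(
    strand = "-", orf_start = 1L, signal = 17L, n_codons = 375L,
    contact_source = "4W40+4ZNE",
    contacts = c(85:88, 109:111, 113:117, 119, 124:129, 131:132, 155:159),
    exons = list(ex("1", 1, 30, 101380170, 101380199),
                 ex("2", 31, 59, 101379541, 101379569),
                 ex("3", 60, 290, 101378768, 101378998),
                 ex("4", 291, 560, 101374425, 101374694),
                 ex("5", 561, 900, 101372839, 101373178),
                 ex("6", 901, 1125, 101370875, 101371099)),
    domains = list(dom(-17, -1, "signal"), dom(1, 82, "extracellular-D1"),
                   dom(83, 172, "extracellular-D2"),
                   dom(173, 292, "extracellular-other"),
                   dom(293, 313, "transmembrane"), dom(314, 357, "cytoplasmic")),
    # dup site: codon 22 ends in A (the duplicated base), codon 23 = V whose
    # frameshifted first codon differs (AGT = S)
    fixed_codons = c("22" = "GCA", "23" = "GTG"),
    isoforms = list(list(id = "FCGR1_NM_001257304.2",
                         protein_id = "NP_001244233.1", edits = list()))
  ),
  FCGR2A = list(
    strand = "-", orf_start = 1L, signal = 35L, n_codons = 311L,
    contact_source = "3RY6",
    contacts = c(86:87, 110, 114, 116:117, 125:127, 129, 131, 155:157),
    exons = list(ex("1", 1, 55, 89433945, 89433999),
                 ex("2", 56, 105, 89432895, 89432944),
                 ex("3", 106, 300, 89431290, 89431484),
                 ex("4", 301, 723, 89427065, 89427487),
                 ex("5", 724, 810, 89425190, 89425276),
                 ex("6", 811, 850, 89423150, 89423189),
                 ex("7", 851, 933, 89419220, 89419302)),
    domains = list(dom(-35, -1, "signal"), dom(1, 80, "extracellular-D1"),
                   dom(81, 172, "extracellular-D2"),
                   dom(173, 216, "extracellular-other"),
                   dom(217, 240, "transmembrane"), dom(241, 275, "cytoplasmic")),
    # GAT insertion site: codon 298 must not end in T (no left shift), codon
    # 299 = R with first base != G (no right shift); 298 also != D so the
    # protein-level insertion does not left-normalize past the anchor.
    # Codons 164/165 complete the N163 N-X-S sequon destroyed by N128K.
    fixed_codons = c("298" = "AAG", "299" = "CGT", "164" = "GGA",
                     "165" = "AGC", "241" = "CAT", "242" = "TTT"),
    ext5 = c("5" = "GGTTCCGCTCAAGAA"),   # 15 nt, G S A Q E
    isoforms = list(
      list(id = "FCGR2A_NM_001257300.1", protein_id = "NP_001244229.1",
           edits = list()),
      list(id = "FCGR2A_XM_015113136.2", protein_id = "XP_014968622.2",
           edits = list(list(type = "residue_del", residue = 36L))),
      list(id = "FCGR2A_XM_028846297.1", protein_id = "XP_028702130.1",
           edits = list(list(type = "splice5_ext", label = "5", nt = 15L))),
      list(id = "FCGR2A_XM_028846295.1", protein_id = "XP_028702128.1",
           edits = list(list(type = "residue_del", residue = 36L),
                        list(type = "splice5_ext", label = "5", nt = 15L))))
  ),
  FCGR2B = list(
    strand = "-", orf_start = 1L, signal = 45L, n_codons = 311L,
    contact_source = "3WJJ",
    contacts = c(85:87, 110, 113, 117, 119, 126:131, 157:160),
    exons = list(ex("1", 1, 55, 89333945, 89333999),
                 ex("2", 56, 105, 89332895, 89332944),
                 ex("3", 106, 300, 89332200, 89332394),
                 ex("4", 301, 650, 89331001, 89331350),
                 ex("5", 651, 820, 89329380, 89329549),
                 ex("7", 821, 903, 89326799, 89326881),
                 ex("8", 904, 933, 89324867, 89324896)),
    alt_exons = list(list(label = "6", insert_after = 903L,
                          seq = paste0("GAAGATCACACCTATTCCGAGGTCCAGTTC",
                                       "AGACCAGTGCTGCCTTCCATGGTGAAG"),
                          gstart = 89326200L, gend = 89326256L)),
    domains = list(dom(-45, -1, "signal"), dom(1, 80, "extracellular-D1"),
                   dom(81, 172, "extracellular-D2"),
                   dom(173, 237, "extracellular-other"),
                   dom(238, 256, "transmembrane"), dom(257, 265, "cytoplasmic")),
    # flank the cassette insertion point so the protein diff anchors at the
    # printed residue (no left/right normalization across the boundary)
    fixed_codons = c("301" = "GGC", "302" = "TGG"),
    isoforms = list(
      list(id = "FCGR2B_XM_015113204.2", protein_id = "XP_014968690.1",
           edits = list()),
      list(id = "FCGR2B_XM_015113196.2", protein_id = "XP_014968682.1",
           edits = list(list(type = "exon_include", label = "6"))),
      list(id = "FCGR2B_NM_001257302.1", protein_id = "NP_001244231.1",
           edits = list(list(type = "residue_ins", residue = 20L, aa = "A"))),
      list(id = "FCGR2B_NM_001271648.2", protein_id = "NP_001258577.2",
           edits = list(list(type = "exon_include", label = "6"),
                        list(type = "residue_ins", residue = 20L, aa = "A"))))
  ),
  FCGR3 = list(
    strand = "+", orf_start = 54L, signal = 54L, n_codons = 281L,
    contact_source = "7KCZ",
    contacts = c(158L),
    exons = list(ex("1", 1, 173, 89379948, 89380120),
                 ex("2", 174, 223, 89383121, 89383170),
                 ex("3", 224, 483, 89387012, 89387271),
                 ex("4", 484, 703, 89390624, 89390843),
                 ex("5", 704, 896, 89392640, 89392832)),
    domains = list(dom(-54, -1, "signal"), dom(1, 80, "extracellular-D1"),
                   dom(81, 172, "extracellular-D2"),
                   dom(173, 192, "extracellular-other"),
                   dom(193, 210, "transmembrane"), dom(211, 226, "cytoplasmic")),
    fixed_codons = character(),
    isoforms = list(
      list(id = "FCGR3_NM_001271657.1", protein_id = "NP_001258586.1",
           edits = list()),
      list(id = "FCGR3_XM_015113175.2", protein_id = "XP_014968661.2",
           edits = list(list(type = "residue_ins", residue = 10L, aa = "A"))))
  )
)

# ---- build reference ORFs under the codon constraints ----------------------
snp_rows <- reported[!grepl("ins|dup", reported$annovar_nt), ]
parse_cnt <- function(s) {
  m <- regexec("^c\\.([ACGT])(\\d+)([ACGT])$", s)[[1]]
  r <- regmatches(s, regexec("^c\\.([ACGT])(\\d+)([ACGT])$", s))[[1]]
  list(ref = r[2], pos = as.integer(r[3]), alt = r[4])
}
parse_paa <- function(s) {
  r <- regmatches(s, regexec("^p\\.([A-Z*])(\\d+)([A-Z*])$", s))[[1]]
  list(ref = r[2], alt = r[4])
}

build_reference <- function(gene_id) {
  lay <- layouts[[gene_id]]
  codons <- filler_codons(lay$n_codons)
  codons[1] <- "ATG"
  codons[lay$n_codons] <- "TAA"
  for (nm in names(lay$fixed_codons))
    codons[as.integer(nm)] <- lay$fixed_codons[[nm]]
  rows <- snp_rows[snp_rows$gene_id == gene_id, ]
  for (i in seq_len(nrow(rows))) {
    nt <- parse_cnt(rows$annovar_nt[i])
    aa <- parse_paa(rows$annovar_aa[i])
    ci <- (nt$pos + 2L) %/% 3L
    off <- (nt$pos - 1L) %% 3L + 1L
    # the printed FCGR3 p.A61S pairs with nucleotide 184, which sits in
    # codon 62; trust the nucleotide coordinate
    codons[ci] <- choose_codon(aa$ref, off, nt$ref, nt$alt, aa$alt)
  }
  orf <- paste(codons, collapse = "")
  utr5 <- if (lay$orf_start > 1L)
    paste(sample(c("A", "C", "G", "T"), lay$orf_start - 1L, replace = TRUE),
          collapse = "") else ""
  tlen <- max(vapply(lay$exons, function(e) e$tend, numeric(1)))
  tail_len <- tlen - nchar(utr5) - nchar(orf)
  stopifnot(tail_len >= 0L)
  utr3 <- if (tail_len > 0L)
    paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
          collapse = "") else ""
  paste0(utr5, orf, utr3)
}

refs <- sapply(names(layouts), build_reference)

# FCGR1 dup-site guard: the A at ORF 66 must not extend a run leftwards
stopifnot(substr(refs[["FCGR1"]], 66, 66) == "A",
          substr(refs[["FCGR1"]], 65, 65) != "A",
          substr(refs[["FCGR1"]], 67, 67) != "A")

# ---- assemble config and validate ------------------------------------------
genes_cfg <- lapply(names(layouts), function(g) {
  lay <- layouts[[g]]
  cfg <- list(gene_id = g, chromosome = "chr1", strand = lay$strand,
              orf_start = lay$orf_start, signal_peptide_len = lay$signal,
              contact_source = lay$contact_source,
              contact_residues = as.integer(lay$contacts),
              exons = lay$exons, domains = lay$domains,
              isoforms = lay$isoforms)
  if (!is.null(lay$alt_exons)) cfg$alt_exons <- lay$alt_exons
  if (!is.null(lay$ext5)) cfg$ext5_seqs <- as.list(lay$ext5)
  cfg
})

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
yaml::write_yaml(list(reference_fasta = "fcgr_refs.fasta", genes = genes_cfg),
                 file.path(out_dir, "fcgr_genes.yaml"))
Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs),
                            file.path(out_dir, "fcgr_refs.fasta"), width = 70)
write.table(reported, file.path(out_dir, "reported_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(reported_iso, file.path(out_dir, "reported_isoforms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# ---- validation: full annotation round trip on every reported row ----------
genes <- load_gene_config(file.path(out_dir, "fcgr_genes.yaml"))

n_bad <- 0L
for (i in seq_len(nrow(reported))) {
  row <- reported[i, ]
  gm <- genes[[row$gene_id]]
  m <- regmatches(row$Variant,
                  regexec("^([^:]+):(\\d+):([ACGT]*)>([ACGT]+)$",
                          row$Variant))[[1]]
  gpos <- as.integer(m[3]); gref <- m[4]; galt <- m[5]
  if (nzchar(gref)) {
    mp <- genomic_to_transcript(gm, gpos, gref, galt)
    v <- list(type = "snp", orf_pos = mp$orf_pos, tref = mp$ref,
              talt = mp$alt, seq = "")
    exon <- mp$exon
  } else {
    op <- fcgrdiv:::variant_op(gm, gpos, gref, galt)
    nv <- normalize_variant(list(type = "ins", pos = op$after, seq = op$seq),
                            gm$reference_transcript)
    v <- list(type = "ins", orf_pos = fcgrdiv:::tpos_to_orf(gm, nv$pos),
              seq = nv$seq, is_dup = nv$is_dup)
    exon <- fcgrdiv:::exon_of_orf_pos(gm, v$orf_pos)
    gf <- fcgrdiv:::genomic_fields(gm, list(type = "ins", pos = nv$pos,
                                            seq = nv$seq))
    if (gf$key != row$Variant) { n_bad <- n_bad + 1L
      cat("KEY MISMATCH:", row$Variant, "->", gf$key, "\n") }
  }
  e <- classify_effect(v, gm)
  dom_lab <- assign_domain(e$mature_residue_index, gm)
  skip_aa <- row$Variant == "chr1:89387025:G>T"  # printed p.A61S vs codon 62
  chk <- c(nt = e$annovar_nt == row$annovar_nt,
           aa = skip_aa || e$annovar_aa == row$annovar_aa,
           mnt = e$mature_nt == row$mature_nt,
           maa = e$mature_aa == row$mature_aa,
           exon = exon == row$Exon,
           dom = dom_lab == row$Domain)
  if (!all(chk)) {
    n_bad <- n_bad + 1L
    cat("MISMATCH:", row$Variant, names(chk)[!chk], "\n")
    cat("  got:", e$annovar_nt, e$annovar_aa, e$mature_nt, e$mature_aa,
        exon, dom_lab, "\n")
  }
}

# isoform arithmetic
gm2b <- genes$FCGR2B
p0 <- build_isoform(gm2b)$protein_seq
p6 <- build_isoform(gm2b, list(list(type = "exon_include", label = "6")))$protein_seq
d6 <- diff_proteins(p0, p6)
stopifnot(d6$type == "insertion", d6$len == 19L,
          to_mature_aa(d6$at, gm2b) == 257L)
gm2a <- genes$FCGR2A
q0 <- build_isoform(gm2a)$protein_seq
q5 <- build_isoform(gm2a, list(list(type = "splice5_ext", label = "5",
                                    nt = 15L)))$protein_seq
d5 <- diff_proteins(q0, q5)
stopifnot(d5$type == "insertion", d5$len == 5L,
          to_mature_aa(d5$at, gm2a) == 207L)

if (n_bad > 0L) stop(n_bad, " reported rows failed validation")
cat("all", nrow(reported), "reported rows validated; fixtures written\n")
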