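genes <- fcgr_gene_set()

test_that("codon location and numbering conversions follow the conventions", {
  expect_equal(locate_codon(134)$codon, 45L)
  expect_equal(locate_codon(805)$codon, 269L)
  expect_equal(locate_codon(3), data.frame(codon = 1L, offset = 3L))
  expect_error(locate_codon(0), "1-based")

  expect_equal(to_mature_nt(134, genes$FCGR1), 83L)
  expect_equal(to_mature_nt(532, genes$FCGR2B), 397L)
  expect_equal(to_mature_nt(805, genes$FCGR3), 643L)
  expect_equal(to_mature_nt(10, genes$FCGR1), -41L)  # signal-region: <= 0

  expect_equal(to_mature_aa(45, genes$FCGR1), 28L)
  expect_equal(to_mature_aa(299, genes$FCGR2A), 264L)
  # last signal residue maps to -1: numbering skips zero
  expect_equal(to_mature_aa(17, 17L), -1L)
  expect_equal(to_mature_aa(18, 17L), 1L)
  expect_equal(to_mature_aa(1, 17L), -17L)
})

test_that("effect classification reproduces representative published rows", {
  v <- list(type = "snp", orf_pos = 907L, tref = "A", talt = "C", seq = "")
  e <- classify_effect(v, genes$FCGR2A)
  expect_equal(e$category, "nonsynonymous SNP")
  expect_equal(format_hgvs_c(e), "c.A907C")
  expect_equal(format_hgvs_p(e), "p.M303L")
  expect_equal(format_hgvs_c(e, mature = TRUE), "A802C")
  expect_equal(format_hgvs_p(e, mature = TRUE), "M268L")

  v2 <- list(type = "snp", orf_pos = 846L, tref = "T", talt = "C", seq = "")
  e2 <- classify_effect(v2, genes$FCGR2B)
  expect_equal(e2$category, "synonymous SNP")
  expect_equal(e2$annovar_aa, "p.D282D")

  # single-base duplication -> frameshift at the first changed residue
  dup <- list(type = "ins", orf_pos = 65L, seq = "A", is_dup = TRUE)
  e3 <- classify_effect(dup, genes$FCGR1)
  expect_equal(e3$category, "frameshift insertion")
  expect_equal(e3$annovar_nt, "c.66dupA")
  expect_equal(e3$annovar_aa, "p.V23fs")
  expect_equal(e3$mature_nt, "15dupA")
  expect_equal(e3$mature_aa, "V6fs")

  # in-frame insertion at a codon boundary -> delins naming
  ins <- list(type = "ins", orf_pos = 894L, seq = "GAT", is_dup = FALSE)
  e4 <- classify_effect(ins, genes$FCGR2A)
  expect_equal(e4$category, "non-frameshift insertion")
  expect_equal(e4$annovar_nt, "c.894_895insGAT")
  expect_equal(e4$annovar_aa, "p.R299delinsDR")
  expect_equal(e4$mature_nt, "789_790insGAT")
  expect_equal(e4$mature_aa, "R264delinsDR")
})

test_that("category is invariant across coordinate renderings", {
  for (i in 1:5) {
    v <- list(type = "snp", orf_pos = 100L + 7L * i, seq = "")
    gm <- genes$FCGR2A
    v$tref <- substr(fcgrdiv:::orf_sequence(gm), v$orf_pos, v$orf_pos)
    v$talt <- setdiff(c("A", "C", "G", "T"), v$tref)[1]
    e <- classify_effect(v, gm)
    # the ORF-numbered and mature strings carry the same residue change
    expect_match(e$mature_aa, substr(sub("^p\\.", "", e$annovar_aa), 1, 1),
                 fixed = TRUE)
  }
})

test_that("SNP classification agrees with the brute-force translation oracle", {
  gm <- toy_gene()
  orf <- fcgrdiv:::orf_sequence(gm)
  set.seed(71)
  pos <- sample(4:(nchar(orf) - 3L), 60)  # inside ORF, off the start codon
  for (p in pos) {
    tref <- substr(orf, p, p)
    for (talt in setdiff(c("A", "C", "G", "T"), tref)) {
      e <- classify_effect(list(type = "snp", orf_pos = p, tref = tref,
                                talt = talt, seq = ""), gm)
      expect_equal(e$category, oracle_snp_effect(gm, p, talt),
                   info = sprintf("pos %d %s>%s", p, tref, talt))
    }
  }
})

test_that("edge cases: UTR variants, identical alleles, stop codons", {
  gm <- genes$FCGR3           # 53-nt 5' UTR
  e <- classify_effect(list(type = "snp", orf_pos = -10L, tref = "A",
                            talt = "G", seq = ""), gm)
  expect_equal(e$category, "UTR")
  expect_true(is.na(e$annovar_aa))
  expect_error(classify_effect(list(type = "snp", orf_pos = 10L, tref = "A",
                                    talt = "A", seq = ""), genes$FCGR1),
               "identical")
  # mutating the stop codon of the toy gene is a stop-loss
  tg <- toy_gene()
  orf <- fcgrdiv:::orf_sequence(tg)
  p <- nchar(orf) - 2L          # first base of TAA
  e2 <- classify_effect(list(type = "snp", orf_pos = p, tref = "T",
                             talt = "C", seq = ""), tg)
  expect_equal(e2$category, "stop-loss")
})

test_that("annotate_calls decorates call tables with effects and domains", {
  gm <- toy_gene()
  v <- toy_variants(gm)
  calls <- data.frame(gene_id = "TOY", animal = "a1",
                      type = c("snp", "ins"),
                      orf_pos = c(150L, 230L),
                      tref = c(v$ref[1], ""), talt = c(v$alt[1], ""),
                      seq = c("", v$alt[2]), is_dup = FALSE,
                      key = c("k1", "k2"), stringsAsFactors = FALSE)
  ann <- annotate_calls(calls, list(TOY = gm))
  expect_true(all(c("category", "annovar_nt", "mature_aa", "domain") %in%
                  names(ann)))
  expect_equal(ann$category[2], "non-frameshift insertion")
  expect_equal(ann$domain[1],
               assign_domain(to_mature_aa(50L, gm), gm))
})
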