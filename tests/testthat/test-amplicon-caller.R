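genes <- fcgr_gene_set()

test_that("alignment scores equal the exhaustive DP oracle on random pairs", {
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(40:60, 1); n2 <- sample(40:60, 1)
    a <- random_dna(n1); b <- random_dna(n2)
    aln <- align_read(a, b, min_score_per_base = -Inf)
    expect_equal(aln$score, oracle_align_score(a, b), info = paste("pair", i))
  }
  # related pairs (mutated copies) too
  for (i in 1:10) {
    b <- random_dna(80)
    a <- fcgrdiv:::add_read_errors(b, 0.05, 0.01)
    aln <- align_read(a, b, min_score_per_base = -Inf)
    expect_equal(aln$score, oracle_align_score(a, b))
  }
})

test_that("banded alignment is exact for amplicon-like reads", {
  set.seed(22)
  ref <- genes$FCGR1$reference_transcript
  for (i in 1:5) {
    r <- fcgrdiv:::add_read_errors(ref, 0.01, 0.001)
    full <- align_read(r, ref)
    banded <- align_read(r, ref, band = 48L)
    expect_equal(banded$score, full$score)
    expect_equal(banded$cigar, full$cigar)
  }
})

test_that("perfect and single-substitution reads align as expected", {
  ref <- toy_gene()$reference_transcript
  a <- align_read(ref, ref)
  expect_equal(a$score, 2L * nchar(ref))
  expect_equal(a$cigar, sprintf("%d=", nchar(ref)))
  expect_true(a$valid)
  mut <- ref
  substr(mut, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 150, 150))[1]
  am <- align_read(mut, ref)
  pairs <- aligned_pairs(am)
  expect_equal(sum(pairs$op == "mismatch"), 1L)
  expect_equal(pairs$ref_pos[pairs$op == "mismatch"], 150L)
  # junk reads fall below the score-per-base validity threshold
  junk <- align_read(random_dna(nchar(ref)), ref)
  expect_false(junk$valid)
})

test_that("pileups count alleles and depth per column", {
  ref <- substr(toy_gene()$reference_transcript, 1, 120)
  alns <- lapply(1:10, function(i) align_read(ref, ref))
  pu <- build_pileup(alns, ref)
  expect_true(all(pu$depth == 10L))
  expect_true(all(pu$alleles$count == 10L))
  expect_equal(nrow(pu$alleles), nchar(ref))  # one allele per column
  mut <- ref
  substr(mut, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(ref, 60, 60))[1]
  alns2 <- c(lapply(1:5, function(i) align_read(ref, ref)),
             lapply(1:5, function(i) align_read(mut, ref)))
  pu2 <- build_pileup(alns2, ref)
  col <- pu2$alleles[pu2$alleles$pos == 60, ]
  expect_equal(sort(col$count), c(5L, 5L))
})

test_that("heterozygous sites show balanced allele fractions without errors", {
  gm <- toy_gene()
  v <- toy_variants(gm)[1, ]
  haps <- build_haplotypes(gm, v, matrix(c(1L, 0L), 1, 2))
  set.seed(31)
  er <- emit_reads(haps, c(0.5, 0.5), depth = 60L, error_rate = 0,
                   indel_error_rate = 0)
  alns <- lapply(er$seq, align_read, reference = gm$reference_transcript)
  pu <- build_pileup(alns, gm$reference_transcript)
  col <- pu$alleles[pu$alleles$pos == 150, ]
  frac <- col$count[col$allele == v$alt[1]] / pu$depth[150]
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
})

test_that("the threshold caller recovers spiked genotypes and stays silent otherwise", {
  gm <- toy_gene()
  ref <- gm$reference_transcript
  # all-reference pileup: no calls, positions callable
  alns <- lapply(1:20, function(i) align_read(ref, ref))
  calls0 <- call_genotypes(build_pileup(alns, ref), gm)
  expect_equal(nrow(calls0), 0L)
  expect_length(attr(calls0, "uncallable"), 0L)

  # hom-alt SNP animal at depth 50 with sequencing errors
  v <- toy_variants(gm)[1, ]
  haps <- build_haplotypes(gm, v, matrix(c(1L, 1L), 1, 2))
  set.seed(41)
  er <- emit_reads(haps, c(0.5, 0.5), depth = 50L, error_rate = 0.002,
                   indel_error_rate = 1e-4)
  alns <- lapply(er$seq, align_read, reference = ref, band = 48L)
  calls <- call_genotypes(build_pileup(alns, ref), gm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$zygosity, "hom")
  expect_equal(calls$gpos, v$gpos)
  expect_equal(calls$galt, v$alt)

  # het 3-nt insertion (ACT) recovered at the spiked position
  v2 <- toy_variants(gm)[2, ]
  haps2 <- build_haplotypes(gm, v2, matrix(c(1L, 0L), 1, 2))
  set.seed(42)
  er2 <- emit_reads(haps2, c(0.5, 0.5), depth = 50L, error_rate = 0.002,
                    indel_error_rate = 1e-4)
  alns2 <- lapply(er2$seq, align_read, reference = ref, band = 48L)
  calls2 <- call_genotypes(build_pileup(alns2, ref), gm)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$type, "ins")
  expect_equal(calls2$zygosity, "het")
  expect_equal(calls2$key, sprintf("chrT:%d:>%s", v2$gpos, v2$alt))
})

test_that("low-depth positions are reported uncallable, not silently absent", {
  gm <- toy_gene()
  ref <- gm$reference_transcript
  alns <- lapply(1:5, function(i) align_read(ref, ref))
  calls <- call_genotypes(build_pileup(alns, ref), gm)
  expect_equal(nrow(calls), 0L)
  expect_equal(length(attr(calls, "uncallable")), nchar(ref))
})

test_that("indel normalization left-aligns and flags duplications", {
  ref <- "ACGTAAAGCT"   # A run at 5-7
  v <- normalize_variant(list(type = "ins", pos = 7L, seq = "A"), ref)
  expect_equal(v$pos, 4L)          # shifted to the run start
  expect_true(v$is_dup)
  s <- normalize_variant(list(type = "snp", pos = 3L, tref = "G", talt = "T",
                              seq = ""), ref)
  expect_false(s$is_dup)
  expect_equal(s$pos, 3L)
  d <- normalize_variant(list(type = "del", pos = 7L, seq = "A"), ref)
  expect_equal(d$pos, 5L)          # deletion within the run left-aligns too
  # idempotence on random indels in random references
  set.seed(51)
  for (i in 1:50) {
    r <- random_dna(40)
    if (i %% 2 == 0) {
      vv <- list(type = "ins", pos = sample(1:39, 1), seq = random_dna(sample(1:3, 1)))
    } else {
      vv <- list(type = "del", pos = sample(1:35, 1), seq = NA)
      vv$seq <- substr(r, vv$pos, vv$pos + sample(0:2, 1))
    }
    n1 <- normalize_variant(vv, r)
    n2 <- normalize_variant(n1, r)
    expect_identical(n1[c("type", "pos", "seq", "is_dup")],
                     n2[c("type", "pos", "seq", "is_dup")])
  }
})

test_that("error-free cohorts are recovered exactly (100% genotype recovery)", {
  gm <- toy_gene()
  v <- toy_variants(gm)
  v$af <- c(0.4, 0.4)
  spec <- cohort_spec(12L, v, depth = 15L, error_rate = 0,
                      indel_error_rate = 0, seed = 61L)
  sim <- simulate_cohort(spec, list(TOY = gm))
  calls <- call_cohort(sim$reads, list(TOY = gm))
  truth <- sim$truth$genotypes
  got <- calls[order(calls$key, calls$animal), c("animal", "key")]
  want <- truth[order(truth$key, truth$animal), c("animal", "key")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # zygosity matches the simulated allele count as well
  m <- merge(calls, truth, by = c("animal", "key"))
  expect_equal(nrow(m), nrow(calls))
  expect_equal(m$zygosity, ifelse(m$alleles == 2L, "hom", "het"))
})
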