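genes <- fcgr_gene_set()

test_that("genotype sampling respects degenerate allele frequencies", {
  gm <- toy_gene()
  v <- toy_variants(gm)
  v$af <- c(0, 1)
  spec <- cohort_spec(n_animals = 40L, variants = v, seed = 7L)
  g <- sample_genotypes(spec)
  expect_equal(dim(g), c(40L, 2L, 2L))
  expect_true(all(g[, 1, ] == 0L))   # af 0: nobody carries it
  expect_true(all(g[, 2, ] == 1L))   # af 1: everyone homozygous alternate
})

test_that("Hardy-Weinberg sampling matches the binomial carrier fraction", {
  v <- toy_variants()[1, ]
  v$af <- 0.13
  fracs <- vapply(1:200, function(s) {
    g <- sample_genotypes(cohort_spec(206L, v, seed = s))
    mean(g[, 1, 1] + g[, 1, 2] > 0)
  }, numeric(1))
  p_carrier <- 1 - (1 - 0.13)^2
  se <- sqrt(p_carrier * (1 - p_carrier) / 206) / sqrt(200)
  expect_lt(abs(mean(fracs) - p_carrier), 3 * se)
})

test_that("carrier-count mode assigns exactly the requested carriers", {
  tab <- fcgr_reported_variants()
  spec <- cohort_spec_from_table(tab, gene_id = "FCGR1", seed = 3L)
  g <- sample_genotypes(spec)
  carriers <- apply(g[, , 1] + g[, , 2] > 0, 2L, sum)
  expect_equal(unname(carriers), tab$carrier_count[tab$gene_id == "FCGR1"])
  expect_equal(unname(carriers[1]), 52L)  # most frequent reported variant
  sim <- simulate_cohort(cohort_spec_from_table(tab, "FCGR1", depth = 1L,
                                                seed = 3L),
                         genes["FCGR1"])
  cc <- sim_carrier_counts(sim)
  expect_equal(cc$carrier_count[cc$key == "chr1:101378924:A>G"], 52L)
})

test_that("haplotype construction applies variants at strand-correct positions", {
  gm <- toy_gene()
  v <- toy_variants(gm)
  g0 <- matrix(0L, 2, 2)
  expect_equal(build_haplotypes(gm, v, g0),
               rep(gm$reference_transcript, 2))
  g1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)  # SNP on haplotype 1 only
  haps <- build_haplotypes(gm, v, g1)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              haps, rep(gm$reference_transcript, 2))
  expect_equal(unname(d), c(1L, 0L))
  expect_equal(substr(haps[1], 150, 150), v$alt[1])
  g2 <- matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE)  # insertion on hap 2
  haps2 <- build_haplotypes(gm, v, g2)
  expect_equal(nchar(haps2[2]) - nchar(gm$reference_transcript), 3L)
  expect_equal(substr(haps2[2], 1, 230), substr(gm$reference_transcript, 1, 230))
  expect_equal(substr(haps2[2], 234, nchar(haps2[2])),
               substr(gm$reference_transcript, 231,
                      nchar(gm$reference_transcript)))
  # minus-strand gene: transcript sees the reverse complement
  gm1 <- genes$FCGR1
  vr <- data.frame(gene_id = "FCGR1", chrom = "chr1", gpos = 101378924L,
                   ref = "A", alt = "G")
  h <- build_haplotypes(gm1, vr, matrix(c(1L, 0L), 1, 2))
  expect_equal(substr(h[1], 134, 134), "C")
  # conflicting overlapping variants on one haplotype
  v2 <- rbind(toy_variants(gm)[1, ], toy_variants(gm)[1, ])
  v2$alt[2] <- setdiff(c("A", "C", "G", "T"), c(v2$ref[1], v2$alt[1]))[1]
  expect_error(build_haplotypes(gm, v2, matrix(1L, 2, 2)), "conflicting")
})

test_that("read emission follows the mixture and error model", {
  gm <- toy_gene()
  src <- c(gm$reference_transcript,
           build_isoform(gm, gm$isoforms[[2]]$edits)$transcript_seq)
  set.seed(11)
  er <- emit_reads(src, c(1, 0), depth = 25L, error_rate = 0,
                   indel_error_rate = 0)
  expect_length(er$seq, 25L)
  expect_true(all(er$source == 1L))
  expect_true(all(er$seq == src[1]))   # error-free reads are exact copies
  er1 <- emit_reads(src, c(0.5, 0.5), depth = 1L, error_rate = 0,
                    indel_error_rate = 0)
  expect_length(er1$seq, 1L)
  # substitution count matches the binomial expectation
  set.seed(12)
  n <- 400L; len <- nchar(src[1])
  er2 <- emit_reads(src[1], 1, depth = n, error_rate = 0.002,
                    indel_error_rate = 0)
  mm <- vapply(er2$seq, function(s)
    sum(strsplit(s, "")[[1]] != strsplit(src[1], "")[[1]]), numeric(1))
  expected <- 0.002 * len
  se <- sqrt(len * 0.002 * 0.998 / n)
  expect_lt(abs(mean(mm) - expected), 4 * se)
})

test_that("simulation is deterministic under a fixed seed", {
  v <- toy_variants()
  v$af <- c(0.3, 0.5)
  spec <- cohort_spec(4L, v, isoform_mixture =
                        list(TOY = list(weights = c(TOY_A = 0.6, TOY_B = 0.3,
                                                    TOY_C = 0.1))),
                      depth = 8L, seed = 99L)
  s1 <- simulate_cohort(spec, list(TOY = toy_gene()))
  s2 <- simulate_cohort(spec, list(TOY = toy_gene()))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)
  spec3 <- cohort_spec(4L, v, depth = 8L, seed = 100L)
  s3 <- simulate_cohort(spec3, list(TOY = toy_gene()))
  expect_false(identical(s1$reads, s3$reads))
  # byte-identical FASTQ output
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_fastq <- fcgrdiv:::write_sim_fastq
  write_sim_fastq(s1, d1); write_sim_fastq(s2, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("error-free reads are consistent with the recorded truth", {
  v <- toy_variants()
  v$af <- c(0.5, 0.5)
  spec <- cohort_spec(6L, v, depth = 10L, error_rate = 0,
                      indel_error_rate = 0, seed = 5L)
  gm <- toy_gene()
  sim <- simulate_cohort(spec, list(TOY = gm))
  for (a in sim$animals) {
    lab <- sim$truth$read_sources[[paste(a, "TOY", sep = "|")]]
    gidx <- match(fcgrdiv:::variant_key(v), dimnames(sample_genotypes(spec))[[2]])
    gt <- sample_genotypes(spec)[a, , ]
    haps <- build_haplotypes(gm, v, gt)
    hap_of <- ifelse(grepl("hap1$", lab), 1L, 2L)
    expect_equal(unname(sim$reads[[a]][["TOY"]]), unname(haps[hap_of]))
  }
})
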