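# Independent oracles used to cross-check the implementation.

# Plain-R exhaustive Gotoh score (no traceback), written independently of the
# compiled aligner. Gap of length L costs |gap_open| + L * |gap_extend|.
oracle_align_score <- function(a, b, match = 2, mismatch = -4,
                               gap_open = -4, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- -gap_open; ge <- -gap_extend
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge,
                     Y[i, j - 1] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive grid search over the probability simplex for the mixture
# log-likelihood sum_i log sum_j theta_j w_ij (step 0.01, K = 2 or 3).
oracle_em_grid <- function(w, step = 0.01) {
  K <- ncol(w)
  ll <- function(theta) sum(log(as.vector(w %*% theta)))
  best <- -Inf
  if (K == 2) {
    for (p in seq(0, 1, by = step)) best <- max(best, ll(c(p, 1 - p)))
  } else if (K == 3) {
    for (p in seq(0, 1, by = step)) {
      for (q in seq(0, 1 - p, by = step)) best <- max(best, ll(c(p, q, 1 - p - q)))
    }
  } else stop("grid oracle supports K = 2 or 3")
  best
}

# Brute-force SNP effect: substitute the base in the full ORF, translate both
# proteins, and diff.
oracle_snp_effect <- function(gm, orf_pos, talt) {
  prot <- translate_cds(gm$reference_transcript, gm$orf_start)
  orf_len <- 3 * (nchar(prot) + 1)
  orf <- substr(gm$reference_transcript, gm$orf_start,
                gm$orf_start + orf_len - 1)
  mut <- orf
  substr(mut, orf_pos, orf_pos) <- talt
  mp <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(mut), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", mp, fixed = TRUE)
  mut_prot <- if (stop_at > 0) substr(mp, 1, stop_at - 1) else mp
  if (identical(mut_prot, prot)) "synonymous SNP"
  else if (nchar(mut_prot) < nchar(prot) &&
           identical(mut_prot, substr(prot, 1, nchar(mut_prot)))) "stop-gain"
  else if (nchar(mut_prot) > nchar(prot)) "stop-loss"
  else "nonsynonymous SNP"
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
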