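# Synthetic diploid cohort generator: per-animal CCS-like full-length amplicon
# reads from known haplotypes and isoform mixtures, with the truth returned
# separately. The error model is independent per-base substitutions plus rare
# single-base indels, reflecting consensus-grade long reads; fidelity to
# instrument-specific error structure (homopolymer bias, quality modeling) is
# deliberately out of scope.

#' Specify a synthetic cohort
#'
#' @param n_animals Number of animals.
#' @param variants Data frame of variant specifications with columns
#'   `gene_id`, `gpos`, `ref`, `alt` (plus-strand; empty `ref` denotes an
#'   insertion anchored at the base `gpos`), and either `af` (population
#'   allele frequency, Hardy-Weinberg sampling) or `carrier_count` (exact
#'   number of carrier animals, for table-faithful cohorts). May be `NULL`.
#' @param isoform_mixture Per-gene mixture specification, a named list whose
#'   entries are lists with either `weights` (fixed isoform proportions,
#'   named by isoform id) or `alpha` (Dirichlet concentration parameters for
#'   per-animal random mixtures). Genes absent from the list express only
#'   the principal isoform.
#' @param depth Reads per gene per animal.
#' @param error_rate Per-base substitution probability.
#' @param indel_error_rate Per-base probability of a 1-bp insertion or
#'   deletion error.
#' @param seed Random seed (integer).
#' @return Object of class `fcgr_cohort_spec`.
#' @export
cohort_spec <- function(n_animals, variants = NULL, isoform_mixture = list(),
                        depth = 50L, error_rate = 0.002,
                        indel_error_rate = 1e-4, seed = 1L) {
  stopifnot(n_animals >= 1L, depth >= 1L,
            error_rate >= 0, error_rate <= 1,
            indel_error_rate >= 0, indel_error_rate <= 1)
  if (!is.null(variants)) {
    need <- c("gene_id", "gpos", "ref", "alt")
    if (!all(need %in% names(variants)))
      stop("variants need columns ", paste(need, collapse = ", "))
    if (!is.null(variants$af) &&
        any(variants$af < 0 | variants$af > 1, na.rm = TRUE))
      stop("allele frequencies must lie in [0, 1]")
    if (is.null(variants$af) && is.null(variants$carrier_count))
      stop("variants need either 'af' or 'carrier_count'")
    if (!is.null(variants$carrier_count) &&
        any(variants$carrier_count > n_animals, na.rm = TRUE))
      stop("carrier_count exceeds n_animals")
  }
  for (mx in isoform_mixture) {
    w <- mx$weights %||% mx$alpha
    if (is.null(w) || any(w < 0)) stop("mixture weights must be nonnegative")
  }
  structure(list(n_animals = as.integer(n_animals), variants = variants,
                 isoform_mixture = isoform_mixture, depth = as.integer(depth),
                 error_rate = error_rate, indel_error_rate = indel_error_rate,
                 seed = as.integer(seed)),
            class = "fcgr_cohort_spec")
}

#' Draw per-animal diploid genotypes for a cohort specification
#'
#' Variants with an `af` are sampled under Hardy-Weinberg equilibrium (each
#' haplotype carries the alternate allele with probability `af`,
#' independently). Variants with a `carrier_count` are assigned to exactly
#' that many randomly chosen animals, each heterozygous on a random
#' haplotype, so reported cohorts can be reproduced without sampling noise.
#'
#' @param spec An `fcgr_cohort_spec`.
#' @param reseed Set the spec's seed before sampling (disable when called
#'   from a larger seeded simulation).
#' @return Integer array `n_animals x n_variants x 2` of 0/1 haplotype
#'   alleles; dimnames carry animal ids and variant keys.
#' @export
sample_genotypes <- function(spec, reseed = TRUE) {
  if (reseed) set.seed(spec$seed)
  v <- spec$variants
  n <- spec$n_animals
  animals <- sprintf("animal%03d", seq_len(n))
  if (is.null(v) || nrow(v) == 0L)
    return(array(0L, dim = c(n, 0L, 2L), dimnames = list(animals, NULL, NULL)))
  keys <- variant_key(v)
  g <- array(0L, dim = c(n, nrow(v), 2L),
             dimnames = list(animals, keys, c("hap1", "hap2")))
  for (j in seq_len(nrow(v))) {
    cc <- if (!is.null(v$carrier_count)) v$carrier_count[j] else NA
    if (!is.na(cc)) {
      carriers <- sample.int(n, cc)
      hap <- sample(1:2, cc, replace = TRUE)
      g[cbind(carriers, j, hap)] <- 1L
    } else {
      g[, j, ] <- matrix(stats::rbinom(2L * n, 1L, v$af[j]), n, 2L)
    }
  }
  g
}

variant_key <- function(v) {
  chrom <- v$chrom %||% rep("chr1", nrow(v))
  sprintf("%s:%d:%s>%s", chrom, v$gpos, v$ref, v$alt)
}

# convert a plus-strand variant spec row into a transcript operation on the
# principal transcript of its gene
variant_op <- function(gm, gpos, ref, alt) {
  if (nzchar(ref) && nzchar(alt)) {            # SNP
    mp <- genomic_to_transcript(gm, gpos, ref, alt)
    if (substr(gm$reference_transcript, mp$tpos, mp$tpos) != mp$ref)
      stop(sprintf("reference allele mismatch at %d in %s", gpos, gm$gene_id))
    list(after = mp$tpos - 1L, remove = 1L, seq = mp$alt)
  } else if (!nzchar(ref)) {                   # insertion after plus-strand gpos
    if (gm$strand == "+") {
      t1 <- genomic_to_transcript(gm, gpos)$tpos
      list(after = t1, remove = 0L, seq = alt)
    } else {
      t1 <- genomic_to_transcript(gm, gpos)$tpos  # base left of insert = 3' side
      list(after = t1 - 1L, remove = 0L, seq = rev_comp(alt))
    }
  } else {                                     # deletion of plus-strand ref
    tt <- vapply(gpos + seq_len(nchar(ref)) - 1L,
                 function(p) genomic_to_transcript(gm, p)$tpos, numeric(1))
    list(after = min(tt) - 1L, remove = nchar(ref), seq = "")
  }
}

#' Build the two haplotype sequences of one animal for one isoform
#'
#' Applies the isoform's splice structure and the haplotype's variant
#' alleles to the principal transcript; all edits are applied from 3' to 5'
#' so coordinates remain valid, and conflicting overlapping variants on one
#' haplotype are an error.
#'
#' @param gm An `fcgr_gene_model`.
#' @param variants Variant specification rows (as in [cohort_spec()]) for
#'   this gene.
#' @param genotype Integer matrix `n_variants x 2` of 0/1 haplotype alleles.
#' @param isoform_edits Splice-structure edits (as for [build_isoform()]).
#' @return Character vector of two haplotype sequences.
#' @export
build_haplotypes <- function(gm, variants, genotype, isoform_edits = list()) {
  genotype <- matrix(as.integer(genotype), ncol = 2L)
  base_ops <- isoform_ops(gm, isoform_edits)
  removed <- Filter(function(o) o$remove > 0L, base_ops)
  inside_removed <- function(op) {
    for (r in removed) {
      lo <- r$after + 1L; hi <- r$after + r$remove
      if (op$remove > 0L) {
        if (op$after + 1L >= lo && op$after + op$remove <= hi) return(TRUE)
      } else {
        if (op$after >= lo && op$after <= hi - 1L) return(TRUE)
      }
    }
    FALSE
  }
  vapply(1:2, function(h) {
    idx <- which(genotype[, h] == 1L)
    vops <- lapply(idx, function(j)
      variant_op(gm, variants$gpos[j], variants$ref[j], variants$alt[j]))
    # variants landing inside a spliced-out region do not apply to this isoform
    vops <- Filter(function(op) !inside_removed(op), vops)
    apply_transcript_ops(gm$reference_transcript, c(base_ops, vops))
  }, character(1))
}

random_other_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

add_read_errors <- function(seqs, error_rate, indel_error_rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (error_rate > 0) {
      hit <- which(stats::runif(n) < error_rate)
      if (length(hit)) {
        ch <- strsplit(s, "")[[1]]
        ch[hit] <- random_other_base(ch[hit])
        s <- paste(ch, collapse = "")
      }
    }
    if (indel_error_rate > 0) {
      hit <- which(stats::runif(n) < indel_error_rate)
      for (p in rev(hit)) {
        if (stats::runif(1) < 0.5) {  # 1-bp insertion after p
          s <- paste0(substr(s, 1L, p), sample(c("A", "C", "G", "T"), 1L),
                      substr(s, p + 1L, nchar(s)))
        } else {                      # 1-bp deletion at p
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
        }
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Emit error-bearing full-length reads from a set of source sequences
#'
#' Each read's source is drawn from `weights`; independent per-base
#' substitution and 1-bp indel errors are then applied. Read names carry
#' only a serial number; the source of each read is returned separately as
#' truth.
#'
#' @param sources Character vector of source sequences (haplotype x isoform
#'   combinations).
#' @param weights Sampling weight per source (need not be normalized).
#' @param depth Number of reads.
#' @param error_rate,indel_error_rate Error probabilities per base.
#' @param prefix Prefix for read names.
#' @return List with `seq` (named character vector of reads) and `source`
#'   (integer vector of true source indices).
#' @export
emit_reads <- function(sources, weights, depth, error_rate = 0.002,
                       indel_error_rate = 1e-4, prefix = "read") {
  stopifnot(depth >= 1L, length(sources) == length(weights), all(weights >= 0))
  src <- sample.int(length(sources), depth, replace = TRUE, prob = weights)
  seqs <- add_read_errors(sources[src], error_rate, indel_error_rate)
  names(seqs) <- sprintf("%s_%05d", prefix, seq_len(depth))
  list(seq = seqs, source = src)
}

dirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Simulate a full cohort of per-animal amplicon reads with known truth
#'
#' Composes genotype sampling, per-animal isoform mixtures, haplotype
#' construction and read emission. Deterministic for a fixed spec seed.
#'
#' @param spec An `fcgr_cohort_spec`.
#' @param genes Named list of gene models (only genes appearing in the spec's
#'   variants or mixtures are simulated; pass a subset to restrict).
#' @param out_dir Optional directory; when given, one FASTQ per animal is
#'   written (`<animal>_<gene>.fastq`, constant base quality) along with a
#'   `truth.tsv` sidecar of per-animal genotypes.
#' @param gzip Write gzip-compressed FASTQ.
#' @return List of class `fcgr_sim` with `reads` (`reads[[animal]][[gene]]`,
#'   named character vectors), `truth` (list: `genotypes` data frame with
#'   per-animal allele counts, `proportions` per-gene matrices of true
#'   isoform mixtures, `read_sources`), and `spec`.
#' @export
simulate_cohort <- function(spec, genes, out_dir = NULL, gzip = FALSE) {
  set.seed(spec$seed)
  n <- spec$n_animals
  animals <- sprintf("animal%03d", seq_len(n))
  gt <- sample_genotypes(spec, reseed = FALSE)
  v <- spec$variants

  gene_ids <- unique(c(if (!is.null(v)) v$gene_id, names(spec$isoform_mixture)))
  gene_ids <- intersect(names(genes), gene_ids)
  if (!length(gene_ids)) gene_ids <- names(genes)

  # per-gene isoform sets (principal first) and per-animal mixture truth
  iso_sets <- lapply(gene_ids, function(g) {
    gm <- genes[[g]]
    isos <- gm$isoforms
    if (!length(isos)) isos <- list(list(id = paste0(g, "_principal"), edits = list()))
    isos
  })
  names(iso_sets) <- gene_ids
  proportions <- lapply(gene_ids, function(g) {
    isos <- iso_sets[[g]]
    ids <- vapply(isos, `[[`, character(1), "id")
    mx <- spec$isoform_mixture[[g]]
    if (is.null(mx)) {
      m <- matrix(0, n, length(ids), dimnames = list(animals, ids))
      m[, 1] <- 1
      m
    } else if (!is.null(mx$weights)) {
      w <- mx$weights[ids]; w[is.na(w)] <- 0
      matrix(rep(w / sum(w), each = n), n, length(ids),
             dimnames = list(animals, ids))
    } else {
      a <- mx$alpha[ids]; a[is.na(a)] <- 0
      t(vapply(seq_len(n), function(i) dirichlet1(a), numeric(length(ids)))) ->
        m
      dimnames(m) <- list(animals, ids)
      m
    }
  })
  names(proportions) <- gene_ids

  reads <- stats::setNames(vector("list", n), animals)
  read_sources <- list()
  for (i in seq_len(n)) {
    per_gene <- list()
    for (g in gene_ids) {
      gm <- genes[[g]]
      isos <- iso_sets[[g]]
      vg <- if (!is.null(v)) v[v$gene_id == g, , drop = FALSE] else NULL
      gidx <- if (!is.null(vg) && nrow(vg)) match(variant_key(vg), dimnames(gt)[[2]])
              else integer(0)
      gmat <- if (length(gidx)) gt[i, gidx, , drop = FALSE] else
        array(0L, dim = c(1, 0, 2))
      gmat <- matrix(gmat, ncol = 2L)
      # source sequences: isoform x haplotype, weight = mixture/2
      srcs <- character(0); w <- numeric(0); lab <- character(0)
      for (k in seq_along(isos)) {
        if (proportions[[g]][i, k] <= 0) next
        haps <- build_haplotypes(gm, vg, gmat, isos[[k]]$edits)
        srcs <- c(srcs, haps)
        w <- c(w, rep(proportions[[g]][i, k] / 2, 2L))
        lab <- c(lab, paste0(isos[[k]]$id, c("|hap1", "|hap2")))
      }
      er <- emit_reads(srcs, w, spec$depth, spec$error_rate,
                       spec$indel_error_rate,
                       prefix = sprintf("%s_%s", animals[i], g))
      per_gene[[g]] <- er$seq
      read_sources[[paste(animals[i], g, sep = "|")]] <- lab[er$source]
    }
    reads[[i]] <- per_gene
  }

  truth_gt <- NULL
  if (!is.null(v) && nrow(v)) {
    ac <- gt[, , 1, drop = FALSE] + gt[, , 2, drop = FALSE]
    dim(ac) <- dim(gt)[1:2]
    truth_gt <- data.frame(
      animal = rep(animals, times = ncol(ac)),
      gene_id = rep(v$gene_id, each = n),
      key = rep(dimnames(gt)[[2]], each = n),
      alleles = as.integer(ac), stringsAsFactors = FALSE)
    truth_gt <- truth_gt[truth_gt$alleles > 0L, , drop = FALSE]
    rownames(truth_gt) <- NULL
  }

  sim <- structure(list(
    reads = reads,
    truth = list(genotypes = truth_gt, proportions = proportions,
                 read_sources = read_sources),
    spec = spec, animals = animals, gene_ids = gene_ids), class = "fcgr_sim")

  if (!is.null(out_dir)) write_sim_fastq(sim, out_dir, gzip = gzip)
  sim
}

#' True carrier counts of a simulation
#'
#' @param sim An `fcgr_sim`.
#' @return Data frame with `key`, `gene_id`, `carrier_count`.
#' @export
sim_carrier_counts <- function(sim) {
  g <- sim$truth$genotypes
  if (is.null(g) || !nrow(g))
    return(data.frame(key = character(0), gene_id = character(0),
                      carrier_count = integer(0)))
  agg <- stats::aggregate(animal ~ key + gene_id, data = g,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "carrier_count"
  agg
}

write_sim_fastq <- function(sim, out_dir, gzip = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(sim$reads)) {
    for (g in names(sim$reads[[a]])) {
      seqs <- sim$reads[[a]][[g]]
      path <- file.path(out_dir, sprintf("%s_%s.fastq%s", a, g,
                                         if (gzip) ".gz" else ""))
      write_fastq(seqs, path)
    }
  }
  if (!is.null(sim$truth$genotypes))
    utils::write.table(sim$truth$genotypes,
                       file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Build a carrier-count cohort specification from a reported variant table
#'
#' Turns rows of the packaged reported-variant table (or any table with
#' `Variant` keys and `carrier_count`) into an exact-carrier-count
#' specification, so cohorts matching the published carrier counts can be
#' simulated.
#'
#' @param tab Data frame with columns `gene_id`, `Variant`
#'   (`chr:pos:REF>ALT`, empty REF = insertion) and `carrier_count`.
#' @param gene_id Optional filter to one gene.
#' @param n_animals Cohort size.
#' @param ... Passed to [cohort_spec()] (depth, error rates, seed).
#' @return An `fcgr_cohort_spec`.
#' @export
cohort_spec_from_table <- function(tab, gene_id = NULL, n_animals = 206L, ...) {
  if (!is.null(gene_id)) tab <- tab[tab$gene_id %in% gene_id, , drop = FALSE]
  m <- regmatches(tab$Variant,
                  regexec("^([^:]+):(\\d+):([ACGT]*)>([ACGT]+)$", tab$Variant))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("unparseable variant key: ", tab$Variant[bad][1])
  variants <- data.frame(
    gene_id = tab$gene_id,
    chrom = vapply(m, `[[`, character(1), 2),
    gpos = as.integer(vapply(m, `[[`, character(1), 3)),
    ref = vapply(m, `[[`, character(1), 4),
    alt = vapply(m, `[[`, character(1), 5),
    carrier_count = as.integer(tab$carrier_count),
    stringsAsFactors = FALSE)
  cohort_spec(n_animals = n_animals, variants = variants, ...)
}
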