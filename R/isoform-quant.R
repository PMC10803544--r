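# Isoform relative-abundance estimation: read-to-isoform compatibility
# weights from alignment scores, and an expectation-maximization estimate of
# the mixture proportions. Ambiguous reads are retained with fractional
# weights rather than discarded, so the estimate uses all of the data.

#' Compute a read x isoform compatibility matrix
#'
#' Each read is aligned (score only) against every isoform transcript;
#' compatibility weights are exponentiated score differences,
#' `w_ij = exp(score_ij - best_i)`, with alignments below the validity
#' threshold set to zero. Reads structurally consistent with several
#' isoforms receive equal weights on all of them; reads aligning validly to
#' no isoform are dropped and counted.
#'
#' @param reads Named character vector of read sequences.
#' @param isoform_seqs Named character vector of isoform transcript
#'   sequences.
#' @param scoring Alignment scoring (see [align_read()]).
#' @param min_score_per_base Validity threshold.
#' @param band Alignment band half-width (see [align_read()]).
#' @return Object of class `fcgr_compat`: `w` (reads x isoforms weight
#'   matrix), `read_ids`, `n_dropped`.
#' @export
compatibility_matrix <- function(reads, isoform_seqs,
                                 scoring = default_scoring(),
                                 min_score_per_base = 1, band = 48L) {
  stopifnot(length(isoform_seqs) >= 1L)
  R <- length(reads); K <- length(isoform_seqs)
  scores <- matrix(-Inf, R, K,
                   dimnames = list(names(reads), names(isoform_seqs)))
  for (j in seq_len(K)) {
    for (i in seq_len(R)) {
      a <- align_read(reads[i], isoform_seqs[[j]], scoring = scoring,
                      min_score_per_base = min_score_per_base,
                      score_only = TRUE, band = band)
      if (a$valid) scores[i, j] <- a$score
    }
  }
  best <- apply(scores, 1L, max)
  keep <- is.finite(best)
  w <- exp(scores[keep, , drop = FALSE] - best[keep])
  w[!is.finite(w)] <- 0
  structure(list(w = w, read_ids = names(reads)[keep],
                 n_dropped = sum(!keep)),
            class = "fcgr_compat")
}

#' Estimate isoform proportions by expectation-maximization
#'
#' Maximizes the observed-data log-likelihood
#' `sum_i log sum_j theta_j w_ij` over the probability simplex with the
#' standard mixture update `theta_j <- mean_i (theta_j w_ij / sum_k theta_k
#' w_ik)`. The likelihood is non-decreasing at every iteration; convergence
#' is declared when no proportion moves by more than `tol`.
#'
#' @param mat An `fcgr_compat`, or a plain nonnegative reads x isoforms
#'   weight matrix.
#' @param tol Convergence tolerance on the proportions.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   estimate with `converged = FALSE` and a warning.
#' @return Object of class `fcgr_em`: `theta` (named proportions summing to
#'   1), `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_reads`.
#' @export
em_abundance <- function(mat, tol = 1e-8, max_iter = 1000L) {
  w <- if (inherits(mat, "fcgr_compat")) mat$w else as.matrix(mat)
  if (nrow(w) < 1L) stop("no reads to estimate from")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and nonnegative")
  if (any(rowSums(w) == 0)) stop("every read must be compatible with >= 1 isoform")
  K <- ncol(w)
  theta <- rep(1 / K, K)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(w %*% theta)
    trace[it] <- sum(log(denom))
    resp <- sweep(w, 2L, theta, `*`) / denom
    theta_new <- colMeans(resp)
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
    if (it >= max_iter) break
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  structure(list(theta = stats::setNames(theta, colnames(w)),
                 loglik = sum(log(as.vector(w %*% theta))),
                 loglik_trace = trace, n_iter = it, converged = converged,
                 n_reads = nrow(w)),
            class = "fcgr_em")
}

#' @export
print.fcgr_em <- function(x, ...) {
  cat(sprintf("<fcgr_em> %d reads, %d isoforms, %d iterations (%s), loglik %.4f\n",
              x$n_reads, length(x$theta), x$n_iter,
              ifelse(x$converged, "converged", "not converged"), x$loglik))
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.fcgr_em <- function(object, ...) object$theta

#' Quantify isoform abundances across a cohort
#'
#' Builds the gene's configured isoform transcripts, computes per-animal
#' compatibility matrices, and runs EM per animal.
#'
#' @param reads Nested list `reads[[animal]][[gene_id]]`.
#' @param gm An `fcgr_gene_model` with configured isoforms.
#' @param scoring,min_score_per_base,band Passed to
#'   [compatibility_matrix()].
#' @param tol,max_iter Passed to [em_abundance()].
#' @return Object of class `fcgr_abundance`: `theta` (animals x isoforms
#'   matrix), `n_reads`, `n_dropped` per animal, `gene_id`.
#' @export
quantify_isoforms <- function(reads, gm, scoring = default_scoring(),
                              min_score_per_base = 1, band = 48L,
                              tol = 1e-8, max_iter = 1000L) {
  if (!length(gm$isoforms))
    stop(gm$gene_id, " has no configured isoforms")
  isos <- lapply(gm$isoforms, function(iso) build_isoform(gm, iso$edits,
                                                          id = iso$id))
  iso_seqs <- stats::setNames(
    vapply(isos, `[[`, character(1), "transcript_seq"),
    vapply(isos, `[[`, character(1), "id"))
  animals <- names(reads)
  theta <- matrix(NA_real_, length(animals), length(iso_seqs),
                  dimnames = list(animals, names(iso_seqs)))
  n_reads <- integer(length(animals)); n_dropped <- integer(length(animals))
  for (i in seq_along(animals)) {
    rr <- reads[[animals[i]]][[gm$gene_id]]
    if (is.null(rr) || !length(rr)) next
    cm <- compatibility_matrix(rr, iso_seqs, scoring, min_score_per_base,
                               band = band)
    n_dropped[i] <- cm$n_dropped
    if (nrow(cm$w) == 0L) next
    fit <- em_abundance(cm, tol = tol, max_iter = max_iter)
    theta[i, ] <- fit$theta
    n_reads[i] <- fit$n_reads
  }
  structure(list(theta = theta, n_reads = n_reads, n_dropped = n_dropped,
                 gene_id = gm$gene_id), class = "fcgr_abundance")
}

#' Filter an abundance matrix to expressed isoforms
#'
#' Keeps isoforms whose relative abundance exceeds `min_abundance` in at
#' least one animal. Proportions are not renormalized: the mask is
#' display-only, so the retained values still refer to the full isoform set.
#'
#' @param abund An `fcgr_abundance` or plain animals x isoforms matrix.
#' @param min_abundance Exclusive threshold (default 0.01, i.e. >1%).
#' @return Matrix restricted to the retained isoforms; removed isoform names
#'   in the `removed` attribute.
#' @export
filter_isoform_set <- function(abund, min_abundance = 0.01) {
  m <- if (inherits(abund, "fcgr_abundance")) abund$theta else as.matrix(abund)
  keep <- apply(m, 2L, function(x) any(x > min_abundance, na.rm = TRUE))
  out <- m[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(m)[!keep]
  out
}

#' Per-isoform carrier counts from an abundance matrix
#'
#' An animal carries an isoform when its relative abundance exceeds
#' `carrier_threshold` in that animal. Isoforms with no carriers are absent
#' from the report.
#'
#' @param abund An `fcgr_abundance` or animals x isoforms matrix (typically
#'   already passed through [filter_isoform_set()]).
#' @param carrier_threshold Abundance above which an animal counts as a
#'   carrier.
#' @param cohort_size Cohort size for the percentage (defaults to the number
#'   of rows).
#' @return Data frame: `isoform`, `carrier_count`, `cohort_size`,
#'   `percent_carriers`, ordered by descending carrier count.
#' @export
isoform_carrier_stats <- function(abund, carrier_threshold = 0.01,
                                  cohort_size = NULL) {
  m <- if (inherits(abund, "fcgr_abundance")) abund$theta else as.matrix(abund)
  if (is.null(cohort_size)) cohort_size <- nrow(m)
  cc <- apply(m, 2L, function(x) sum(x > carrier_threshold, na.rm = TRUE))
  out <- data.frame(isoform = colnames(m), carrier_count = as.integer(cc),
                    cohort_size = as.integer(cohort_size),
                    percent_carriers = 100 * cc / cohort_size,
                    stringsAsFactors = FALSE)
  out <- out[out$carrier_count > 0L, , drop = FALSE]
  out <- out[order(-out$carrier_count, out$isoform), , drop = FALSE]
  rownames(out) <- NULL
  out
}
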