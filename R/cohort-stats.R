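# Cohort-level aggregation of per-animal variant calls: carrier counts,
# retention filtering, and percent formatting.

#' Aggregate per-animal calls into cohort variant records
#'
#' A carrier is an animal with at least one alternate allele, irrespective of
#' zygosity; carrier counts therefore count animals, not alleles. One record
#' is produced per distinct normalized variant (genomic key).
#'
#' @param calls Data frame of per-animal calls (columns `animal`, `key`, and
#'   the identity/annotation columns, which must agree within a key), or a
#'   named list of per-animal call data frames (names = animal ids, which
#'   must be unique).
#' @param cohort_size Total number of animals in the cohort (carriers and
#'   non-carriers).
#' @return Data frame of cohort records: one row per variant with
#'   `carrier_count`, `cohort_size`, `percent_carriers`, and the annotation
#'   columns carried through.
#' @export
aggregate_cohort <- function(calls, cohort_size) {
  if (is.list(calls) && !is.data.frame(calls)) {
    ids <- names(calls)
    if (is.null(ids) || anyDuplicated(ids))
      stop("duplicate (or missing) animal identifiers")
    calls <- do.call(rbind, Map(function(df, id) {
      if (nrow(df)) df$animal <- id
      df
    }, calls, ids))
  }
  if (is.null(calls) || nrow(calls) == 0L)
    return(data.frame(key = character(0), carrier_count = integer(0),
                      cohort_size = integer(0), percent_carriers = numeric(0)))
  stopifnot(cohort_size >= 1L)
  keys <- unique(calls$key)
  first <- calls[match(keys, calls$key), , drop = FALSE]
  cnt <- vapply(keys, function(k)
    length(unique(calls$animal[calls$key == k])), integer(1))
  if (any(cnt > cohort_size))
    stop("more carriers than animals in the cohort")
  first$animal <- NULL
  for (cc in c("zygosity", "alt_count", "depth", "vaf"))
    first[[cc]] <- NULL
  first$carrier_count <- unname(cnt)
  first$cohort_size <- as.integer(cohort_size)
  first$percent_carriers <- 100 * first$carrier_count / cohort_size
  first <- first[order(-first$carrier_count, first$key), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Apply the cohort retention filter
#'
#' Keeps variants detected in at least `threshold` (fraction) of the cohort:
#' `carrier_count / cohort_size >= threshold`. At the default 2% in a cohort
#' of 206, the smallest retained carrier count is 5 (4/206 = 1.94%).
#'
#' @param records Cohort records from [aggregate_cohort()].
#' @param threshold Minimum carrier fraction (default 0.02).
#' @return The retained records.
#' @export
filter_min_fraction <- function(records, threshold = 0.02) {
  keep <- records$carrier_count / records$cohort_size >= threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format a carrier percentage for reporting
#'
#' Percentages are rounded half-to-even to one decimal; a trailing `.0` is
#' dropped so whole numbers print bare (140/206 prints as `"68"`).
#'
#' @param count,total Carrier count and cohort size.
#' @return Character vector of display strings.
#' @export
format_percent <- function(count, total) {
  stopifnot(all(total > 0))
  p <- round(100 * count / total, 1)
  ifelse(p == round(p), sprintf("%d", as.integer(round(p))), sprintf("%.1f", p))
}
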