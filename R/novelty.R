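#' Maximum percent identity of a query against a reference set
#'
#' Aligns the query locally (Smith-Waterman, BLOSUM62, affine gap open 11 /
#' extend 1 — the classic protein database-search scoring) against every
#' reference and reports the best percent identity, computed as identical
#' aligned positions over alignment columns (the BLAST identity convention).
#' Alignments whose raw score falls below \code{min_score} are discarded as
#' insignificant — short spurious high-identity segments between unrelated
#' proteins otherwise dominate the maximum; the default of 75 lies far above
#' the scores such segments reach and far below that of any genuinely
#' homologous full-length alignment.
#'
#' @param query protein sequence (character or AAString), non-empty.
#' @param references named character vector or AAStringSet (may be empty).
#' @param min_score minimum raw local-alignment score for a reference to
#'   count as a hit.
#' @return one-row data.frame: \code{query_id} (NA unless set by the caller),
#'   \code{best_ref_id}, \code{best_pct_identity} (NA when no reference
#'   reaches \code{min_score}).
#' @examples
#' max_identity("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA",
#'               c(r1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA"))
#' @export
max_identity <- function(query, references, min_score = 75) {
  query <- as.character(query)
  if (length(query) != 1L || is.na(query) || !nzchar(query))
    stop("input error: query must be a non-empty protein sequence")
  check_aa(query)
  refs <- stats::setNames(as.character(references), names(references))
  if (is.null(names(refs)) && length(refs) > 0L)
    names(refs) <- paste0("ref", seq_along(refs))
  best_id <- NA_character_
  best_pid <- NA_real_
  if (length(refs) > 0L) {
    for (r in refs) check_aa(r)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(rep(query, length(refs))),
      subject = Biostrings::AAStringSet(refs),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    pids <- Biostrings::pid(aln, type = "PID1")
    pids[sc < min_score] <- NA_real_
    if (any(!is.na(pids))) {
      k <- which.max(pids)
      best_id <- names(refs)[k]
      best_pid <- pids[k]
    }
  }
  data.frame(query_id = NA_character_, best_ref_id = best_id,
             best_pct_identity = best_pid, stringsAsFactors = FALSE)
}

check_aa <- function(s) {
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), s))
    stop("input error: sequence contains non-amino-acid characters")
  invisible(s)
}

#' Novelty records for a set of query proteins
#'
#' Runs \code{\link{max_identity}} for each query and attaches the CAZy class
#' of the query when a classification table is supplied.
#'
#' @param queries named character vector or AAStringSet.
#' @param references reference set (named character vector or AAStringSet).
#' @param classifications optional \code{caz_classifications} used to label
#'   each query with its catalytic CAZy class (GH/CE/PL/AA).
#' @param min_score passed to \code{\link{max_identity}}.
#' @return data.frame of novelty records, one row per query.
#' @export
novelty_records <- function(queries, references, classifications = NULL,
                            min_score = 75) {
  qs <- stats::setNames(as.character(queries), names(queries))
  if (is.null(names(qs)) && length(qs) > 0L)
    names(qs) <- paste0("query", seq_along(qs))
  rows <- lapply(seq_along(qs), function(i) {
    r <- max_identity(qs[[i]], references, min_score = min_score)
    r$query_id <- names(qs)[i]
    r
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query_id = character(), best_ref_id = character(),
               best_pct_identity = numeric(), stringsAsFactors = FALSE)
  out$cazy_class <- NA_character_
  if (!is.null(classifications) && nrow(out) > 0L) {
    ix <- match(out$query_id, classifications$protein_id)
    cls <- vapply(seq_along(ix), function(i) {
      if (is.na(ix[i])) return(NA_character_)
      cc <- model_class(split_models(classifications$catalytic_families[ix[i]]))
      cc <- cc[cc %in% c("GH", "CE", "PL", "AA")]
      if (length(cc) > 0L) cc[1L] else NA_character_
    }, character(1))
    out$cazy_class <- cls
  }
  rownames(out) <- NULL
  out
}

#' Summarize a novelty scan: identity histogram and novelty fraction
#'
#' Bins the best percent identities on [0, 100] (overall and per CAZy class)
#' and reports the fraction of records strictly below the novelty threshold
#' among records with a best hit; queries without any hit are counted
#' separately, never in the denominator.
#'
#' @param records data.frame from \code{\link{novelty_records}}.
#' @param threshold novelty threshold in percent, in (0, 100] (default 90).
#' @param bin_width histogram bin width in percentage points (default 10).
#' @return list of class \code{caz_novelty_summary}: \code{fraction_below},
#'   \code{n_with_hit}, \code{n_below}, \code{n_no_hit}, \code{histogram}
#'   (counts per bin), \code{class_histograms}, \code{breaks}.
#' @export
novelty_summary <- function(records, threshold = 90, bin_width = 10) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 100)
    stop("parameter error: threshold must lie in (0, 100]")
  breaks <- unique(c(seq(0, 100, by = bin_width), 100))
  with_hit <- records[!is.na(records$best_pct_identity), , drop = FALSE]
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    stats::setNames(h$counts, paste0("(", head(breaks, -1L), ",",
                                     breaks[-1L], "]"))
  }
  class_h <- lapply(split(with_hit$best_pct_identity,
                          factor(with_hit$cazy_class,
                                 levels = c("GH", "CE", "PL", "AA"))),
                    hist_of)
  n_below <- sum(with_hit$best_pct_identity < threshold)
  structure(list(
    fraction_below = if (nrow(with_hit) > 0L) n_below / nrow(with_hit) else
      NA_real_,
    n_with_hit = nrow(with_hit),
    n_below = n_below,
    n_no_hit = sum(is.na(records$best_pct_identity)),
    threshold = threshold,
    histogram = hist_of(with_hit$best_pct_identity),
    class_histograms = class_h,
    breaks = breaks), class = "caz_novelty_summary")
}

#' @export
print.caz_novelty_summary <- function(x, ...) {
  cat(sprintf(
    "Novelty summary: %d/%d queries (%.1f%%) below %g%% identity; %d without a hit\n",
    x$n_below, x$n_with_hit, 100 * x$fraction_below, x$threshold, x$n_no_hit))
  invisible(x)
}
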