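#' Parse a HMMER3 domtblout-style domain hit table
#'
#' Reads the per-domain tabular output of \code{hmmscan --domtblout} (target =
#' HMM model, query = protein). Lines starting with \code{#} are comments.
#' Each remaining line yields one domain hit; the model class is inferred from
#' the model name via \code{\link{model_class}}.
#'
#' Columns used: target name (1), tlen (3), query name (4), qlen (6),
#' i-Evalue (13), domain bit score (14), hmm from/to (16, 17), ali from/to
#' (18, 19). All coordinates are 1-based inclusive.
#'
#' @param path path to a domtblout file.
#' @return data.frame of class \code{caz_hits} with columns
#'   \code{protein_id, protein_length, model_name, model_class, model_length,
#'   hmm_from, hmm_to, ali_from, ali_to, i_evalue, score}.
#' @export
parse_domtblout <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_hits())
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 22L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed domtblout line %d: expected >= 22 columns, found %d",
                 idx[bad[1]], nf[bad[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    protein_id     = col(4),
    protein_length = as.integer(col(6)),
    model_name     = col(1),
    model_class    = model_class(col(1)),
    model_length   = as.integer(col(3)),
    hmm_from       = as.integer(col(16)),
    hmm_to         = as.integer(col(17)),
    ali_from       = as.integer(col(18)),
    ali_to         = as.integer(col(19)),
    i_evalue       = as.numeric(col(13)),
    score          = as.numeric(col(14)),
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  class(hits) <- c("caz_hits", "data.frame")
  hits
}

empty_hits <- function() {
  hits <- data.frame(
    protein_id = character(), protein_length = integer(),
    model_name = character(), model_class = character(),
    model_length = integer(), hmm_from = integer(), hmm_to = integer(),
    ali_from = integer(), ali_to = integer(),
    i_evalue = numeric(), score = numeric(), stringsAsFactors = FALSE)
  class(hits) <- c("caz_hits", "data.frame")
  hits
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$model_length <= 0L))
    stop("data error: model_length must be positive")
  ok <- hits$hmm_from >= 1L & hits$hmm_from <= hits$hmm_to &
    hits$hmm_to <= hits$model_length &
    hits$ali_from >= 1L & hits$ali_from <= hits$ali_to &
    hits$ali_to <= hits$protein_length &
    hits$i_evalue >= 0
  if (any(!ok))
    stop(sprintf("invalid domain hit coordinates at row %d", which(!ok)[1]))
  invisible(hits)
}

#' Write hits in domtblout layout
#'
#' Emits a 23-column whitespace-delimited table mirroring
#' \code{hmmscan --domtblout} (unused columns are filled with placeholder
#' values; the description column is \code{-}). \code{parse_domtblout} of the
#' result reproduces the input columns exactly.
#'
#' @param hits a \code{caz_hits} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "wb")  # binary connection: fixed \n line endings
  on.exit(close(con))
  hdr <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  writeLines(hdr, con)
  if (nrow(hits) > 0L) {
    lines <- sprintf(
      "%s - %d %s - %d %s %.1f 0.0 1 1 %s %s %.1f 0.0 %d %d %d %d %d %d 0.99 -",
      hits$model_name, hits$model_length, hits$protein_id,
      hits$protein_length,
      format_evalue(hits$i_evalue), hits$score,
      format_evalue(hits$i_evalue), format_evalue(hits$i_evalue), hits$score,
      hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
      pmax(1L, hits$ali_from - 2L),
      pmin(hits$protein_length, hits$ali_to + 2L))
    writeLines(lines, con)
  }
  invisible(path)
}

# E-values formatted like HMMER (%9.2g equivalent); round-trips through
# as.numeric at the precision the pipeline compares at.
format_evalue <- function(x) formatC(x, format = "g", digits = 6)

#' Filter domain hits on E-value and model coverage
#'
#' dbCAN-style hit filtering: a hit is retained iff its per-domain independent
#' E-value is at most \code{evalue_max} and its model-side alignment covers at
#' least \code{coverage_min} of the HMM, with coverage defined as
#' \code{(hmm_to - hmm_from + 1) / model_length}. Input order is preserved and
#' the operation is idempotent.
#'
#' @param hits a \code{caz_hits} data.frame.
#' @param evalue_max maximum i-Evalue retained (default \code{1e-6}; hits at
#'   exactly the cutoff are kept).
#' @param coverage_min minimum HMM coverage fraction retained (default 0.30).
#' @return the retained subset, same class and column order.
#' @examples
#' h <- simulate_bins(sim_config(n_genomes = 2, seed = 1))$hits
#' nrow(filter_hits(h))
#' @export
filter_hits <- function(hits, evalue_max = 1e-6, coverage_min = 0.30) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(hits)
  if (any(hits$model_length == 0L)) stop("data error: model_length of 0")
  cov <- (hits$hmm_to - hits$hmm_from + 1L) / hits$model_length
  keep <- hits$i_evalue <= evalue_max & cov >= coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits on one protein
#'
#' Greedy resolution by significance: hits are ranked by increasing i-Evalue
#' (ties: higher bit score, then lexicographic model name) and accepted unless
#' they overlap an already-accepted hit by more than \code{max_overlap_fraction}
#' of the shorter of the two alignment intervals. Survivors therefore pairwise
#' satisfy the overlap bound.
#'
#' @param hits hits sharing one \code{protein_id}.
#' @param max_overlap_fraction maximum tolerated overlap (default 0.5).
#' @return the accepted subset, in original input order.
#' @export
resolve_overlaps <- function(hits, max_overlap_fraction = 0.5) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) != 1L)
    stop("resolve_overlaps expects hits of a single protein")
  ord <- order(hits$i_evalue, -hits$score, hits$model_name)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      ov <- min(hits$ali_to[i], hits$ali_to[j]) -
        max(hits$ali_from[i], hits$ali_from[j]) + 1L
      if (ov > 0L) {
        shorter <- min(hits$ali_to[i] - hits$ali_from[i],
                       hits$ali_to[j] - hits$ali_from[j]) + 1L
        if (ov / shorter > max_overlap_fraction) { ok <- FALSE; break }
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- hits[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the ordered domain architecture of one protein
#'
#' Domains (assumed filtered and overlap-resolved) are sorted by alignment
#' start; the architecture string joins model names N-to-C with dashes, e.g.
#' \code{"GH5_4-CBM22-CE3-dockerin_I"}. An empty hit set yields an empty
#' architecture.
#'
#' @param hits hits of a single protein.
#' @return list of class \code{caz_architecture}: \code{protein_id},
#'   \code{domains} (data.frame \code{model_name, model_class, ali_from,
#'   ali_to}), \code{architecture_string}.
#' @export
build_architecture <- function(hits) {
  stopifnot(is.data.frame(hits))
  pid <- if (nrow(hits) > 0L) unique(hits$protein_id) else NA_character_
  if (length(pid) != 1L)
    stop("build_architecture expects hits of a single protein")
  ord <- order(hits$ali_from, hits$ali_to, hits$model_name)
  dom <- hits[ord, c("model_name", "model_class", "ali_from", "ali_to"),
              drop = FALSE]
  rownames(dom) <- NULL
  structure(list(
    protein_id = pid,
    domains = dom,
    architecture_string = paste(dom$model_name, collapse = "-")
  ), class = "caz_architecture")
}

#' @export
print.caz_architecture <- function(x, ...) {
  cat(sprintf("<%s> %s (%d domains)\n", x$protein_id,
              if (nzchar(x$architecture_string)) x$architecture_string else
                "(no domains)", nrow(x$domains)))
  invisible(x)
}

#' Build architectures for every protein in a hit table
#'
#' Applies \code{\link{filter_hits}} and \code{\link{resolve_overlaps}} per
#' protein, then assembles one architecture row per protein.
#'
#' @param hits a \code{caz_hits} data.frame (any number of proteins).
#' @param evalue_max,coverage_min passed to \code{\link{filter_hits}}.
#' @param max_overlap_fraction passed to \code{\link{resolve_overlaps}}.
#' @param prefiltered set \code{TRUE} if \code{hits} are already filtered.
#' @return data.frame (\code{caz_arch_table}) with one row per protein:
#'   \code{protein_id, architecture_string, n_domains} and a list column
#'   \code{domains}.
#' @export
build_architectures <- function(hits, evalue_max = 1e-6, coverage_min = 0.30,
                                max_overlap_fraction = 0.5,
                                prefiltered = FALSE) {
  if (!prefiltered) hits <- filter_hits(hits, evalue_max, coverage_min)
  if (nrow(hits) == 0L) {
    out <- data.frame(protein_id = character(),
                      architecture_string = character(),
                      n_domains = integer(), stringsAsFactors = FALSE)
    out$domains <- list()
    class(out) <- c("caz_arch_table", "data.frame")
    return(out)
  }
  parts <- split(seq_len(nrow(hits)), hits$protein_id)
  pids <- names(parts)
  archs <- lapply(parts, function(ix) {
    h <- resolve_overlaps(hits[ix, , drop = FALSE], max_overlap_fraction)
    build_architecture(h)
  })
  out <- data.frame(
    protein_id = pids,
    architecture_string = vapply(archs, `[[`, character(1),
                                 "architecture_string"),
    n_domains = vapply(archs, function(a) nrow(a$domains), integer(1)),
    stringsAsFactors = FALSE
  )
  out$domains <- lapply(archs, `[[`, "domains")
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("caz_arch_table", "data.frame")
  out
}

#' Write an architecture table as TSV
#'
#' @param arch a \code{caz_arch_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_architectures <- function(arch, path) {
  flat <- arch[, c("protein_id", "architecture_string", "n_domains")]
  write_tsv(flat, path)
}
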