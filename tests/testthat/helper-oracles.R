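# Independent oracles. Each is written from the definition, not by calling
# the implementation under test.

# hit-retention predicate applied row by row
oracle_keep_hit <- function(hit, evalue_max = 1e-6, coverage_min = 0.30) {
  cov <- (hit$hmm_to - hit$hmm_from + 1) / hit$model_length
  hit$i_evalue <= evalue_max && cov >= coverage_min
}

# greedy overlap resolution, via explicit position sets
oracle_resolve <- function(hits, max_overlap_fraction = 0.5) {
  ord <- order(hits$i_evalue, -hits$score, hits$model_name)
  accepted <- list()
  keep_idx <- integer(0)
  for (i in ord) {
    pos_i <- seq.int(hits$ali_from[i], hits$ali_to[i])
    clash <- FALSE
    for (pos_j in accepted) {
      ov <- length(intersect(pos_i, pos_j))
      if (ov > max_overlap_fraction * min(length(pos_i), length(pos_j))) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      accepted[[length(accepted) + 1L]] <- pos_i
      keep_idx <- c(keep_idx, i)
    }
  }
  hits[sort(keep_idx), , drop = FALSE]
}

# quadratic-time affine-gap Smith-Waterman with traceback; returns the
# optimal local score and the percent identity (identities / alignment
# columns) of one optimal alignment
oracle_local_align <- function(q, r, gap_open = 11, gap_ext = 1) {
  submat <- get(utils::data("BLOSUM62", package = "Biostrings",
                            envir = environment()))
  qv <- strsplit(q, "")[[1]]
  rv <- strsplit(r, "")[[1]]
  n <- length(qv); m <- length(rv)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)  # gap in query (move along r)
  Iy <- matrix(-Inf, n + 1L, m + 1L)  # gap in reference
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1L)) {
    srow <- submat[qv[i - 1L], ]
    for (j in 2:(m + 1L)) {
      s <- srow[[rv[j - 1L]]]
      M[i, j] <- max(0, s + max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                                Iy[i - 1L, j - 1L]))
      Ix[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext,
                      Ix[i, j - 1L] - gap_ext)
      Iy[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext,
                      Iy[i - 1L, j] - gap_ext)
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(list(score = 0, pid = NA_real_))
  # traceback from the best M cell (all scores are integers: exact compares)
  i <- bi; j <- bj; state <- "M"
  ident <- 0L; cols <- 0L
  while (TRUE) {
    if (state == "M") {
      cols <- cols + 1L
      if (qv[i - 1L] == rv[j - 1L]) ident <- ident + 1L
      s <- submat[qv[i - 1L], rv[j - 1L]]
      prev <- M[i, j] - s
      i <- i - 1L; j <- j - 1L
      if (prev <= 0) break        # local alignment start
      state <- if (prev == M[i, j]) "M"
      else if (prev == Ix[i, j]) "Ix" else "Iy"
    } else if (state == "Ix") {
      cols <- cols + 1L
      state <- if (isTRUE(all.equal(Ix[i, j],
                                    M[i, j - 1L] - gap_open - gap_ext)))
        "M" else "Ix"
      j <- j - 1L
    } else {
      cols <- cols + 1L
      state <- if (isTRUE(all.equal(Iy[i, j],
                                    M[i - 1L, j] - gap_open - gap_ext)))
        "M" else "Iy"
      i <- i - 1L
    }
  }
  list(score = best, pid = 100 * ident / cols)
}

# brute-force scan of a gene table for adjacent SusC/SusD with greedy
# left-to-right matching; architectures supplied as a protein_id -> string map
oracle_arch_token_class <- function(tok) {
  if (grepl("^(SusC|TIGR04056)", tok, ignore.case = TRUE)) return("SUSC")
  if (grepl("^SusD", tok, ignore.case = TRUE)) return("SUSD")
  if (grepl("^(GH|GT|CE|PL|AA|CBM)[0-9]", tok)) return("CAZY")
  "OTHER"
}

oracle_scan_pairs <- function(genes, arch_map) {
  labs <- vapply(genes$protein_id, function(p) {
    a <- arch_map[[p]]
    if (is.null(a) || !nzchar(a)) return("OTHER")
    toks <- strsplit(a, "-")[[1]]
    cls <- vapply(toks, oracle_arch_token_class, character(1))
    if ("SUSC" %in% cls) "SUSC" else if ("SUSD" %in% cls) "SUSD"
    else if ("CAZY" %in% cls) "CAZY" else "OTHER"
  }, character(1))
  out <- list()
  for (ct in unique(genes$contig_id)) {
    sel <- which(genes$contig_id == ct)
    sel <- sel[order(genes$rank[sel])]
    i <- 1L
    while (i < length(sel)) {
      a <- sel[i]; b <- sel[i + 1L]
      if (genes$rank[b] == genes$rank[a] + 1L &&
          setequal(labs[c(a, b)], c("SUSC", "SUSD"))) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = ct,
          susc_rank = genes$rank[if (labs[a] == "SUSC") a else b],
          susd_rank = genes$rank[if (labs[a] == "SUSD") a else b],
          stringsAsFactors = FALSE)
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(), susc_rank = integer(),
                      susd_rank = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# CAZyme gene ranks within `window` of a pair, by exhaustive distance check
oracle_window_cazymes <- function(genes, arch_map, pair, window) {
  sel <- genes$contig_id == pair$contig_id
  lo <- min(pair$susc_rank, pair$susd_rank) - window
  hi <- max(pair$susc_rank, pair$susd_rank) + window
  hits <- character(0)
  for (k in which(sel)) {
    r <- genes$rank[k]
    if (r < lo || r > hi) next
    if (r %in% c(pair$susc_rank, pair$susd_rank)) next
    a <- arch_map[[genes$protein_id[k]]]
    if (is.null(a) || !nzchar(a)) next
    cls <- vapply(strsplit(a, "-")[[1]], oracle_arch_token_class,
                  character(1))
    if ("CAZY" %in% cls && !("SUSC" %in% cls) && !("SUSD" %in% cls))
      hits <- c(hits, genes$protein_id[k])
  }
  sort(hits)
}

arch_map_of <- function(sim) {
  pa <- sim$manifest$planted_architectures
  stats::setNames(as.list(pa$architecture_string), pa$protein_id)
}
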