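#' Attach functional labels to a gene table
#'
#' Joins per-protein domain content onto the gene table and derives one
#' functional label per gene (\code{SUSC, SUSD, CAZYME, PEPTIDASE, REGULATOR,
#' COHESIN, DOCKERIN, OTHER}) from its model names: transporter/binding
#' markers take precedence, then CAZy families, then peptidase and regulator
#' models recognised by name.
#'
#' @param genes gene table (\code{\link{read_genes_gff3}} layout; ranks are
#'   re-derived from coordinates so row order never matters).
#' @param arch_table a \code{caz_arch_table} for the same proteins.
#' @return gene table with \code{label} and \code{models} (semicolon-joined)
#'   columns, ordered by genome, contig, rank.
#' @export
label_genes <- function(genes, arch_table) {
  genes <- assign_ranks(genes[, setdiff(names(genes), "rank"), drop = FALSE])
  ix <- match(genes$protein_id, arch_table$protein_id)
  model_list <- lapply(ix, function(i)
    if (is.na(i)) character(0) else arch_table$domains[[i]]$model_name)
  genes$models <- vapply(model_list, paste, character(1), collapse = ";")
  genes$label <- vapply(model_list, functional_label_one, character(1))
  genes
}

split_models <- function(s) if (nzchar(s)) strsplit(s, ";")[[1]] else
  character(0)

#' Detect tandem susC/susD gene pairs
#'
#' A tandem pair is two rank-adjacent genes on the same contig where one
#' carries a SusC model and the other a SusD model, in either gene order
#' (strand is ignored). Matching is greedy left-to-right along each contig
#' and each gene joins at most one pair.
#'
#' @param genes labeled gene table from \code{\link{label_genes}}.
#' @param strict_order require susC immediately followed by susD in rank
#'   order (default \code{FALSE}).
#' @param same_strand require both genes on the same strand (default
#'   \code{FALSE}).
#' @return data.frame, one row per pair: \code{genome_id, contig_id, susc_id,
#'   susd_id, susc_rank, susd_rank}.
#' @export
detect_sus_pairs <- function(genes, strict_order = FALSE,
                             same_strand = FALSE) {
  out <- list()
  for (ct in unique(genes$contig_id)) {
    gg <- genes[genes$contig_id == ct, , drop = FALSE]
    gg <- gg[order(gg$rank), , drop = FALSE]
    i <- 1L
    while (i < nrow(gg)) {
      a <- gg[i, ]; b <- gg[i + 1L, ]
      lab <- c(a$label, b$label)
      is_pair <- b$rank == a$rank + 1L && setequal(lab, c("SUSC", "SUSD"))
      if (is_pair && strict_order) is_pair <- a$label == "SUSC"
      if (is_pair && same_strand) is_pair <- a$strand == b$strand
      if (is_pair) {
        susc <- if (a$label == "SUSC") a else b
        susd <- if (a$label == "SUSD") a else b
        out[[length(out) + 1L]] <- data.frame(
          genome_id = a$genome_id, contig_id = ct,
          susc_id = susc$protein_id, susd_id = susd$protein_id,
          susc_rank = susc$rank, susd_rank = susd$rank,
          stringsAsFactors = FALSE)
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(genome_id = character(), contig_id = character(),
                      susc_id = character(), susd_id = character(),
                      susc_rank = integer(), susd_rank = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

pul_gene_category <- function(label, models) {
  if (label == "SUSC") return("susC")
  if (label == "SUSD") return("susD")
  if (label == "PEPTIDASE") return("peptidase")
  if (label == "REGULATOR") return("regulator")
  if (label == "CAZYME") {
    cls <- model_class(models)
    for (c0 in c("GH", "PL", "CE")) if (any(cls == c0)) return(c0)
    return("non_PUL")   # GT/AA/CBM-only CAZymes are drawn as non-PUL genes
  }
  "non_PUL"
}

#' Call polysaccharide utilization loci from tandem susCD pairs
#'
#' For each tandem pair the candidate region spans gene ranks
#' \code{[min(pair) - window, max(pair) + window]}, clipped to the contig;
#' regions of different pairs that overlap on the same contig are merged
#' (transitive closure) into a single multi-anchor call. Member genes are the
#' genes inside the window of at least one anchor pair; each is categorized
#' as susC, susD, GH, PL, CE, peptidase, regulator or non-PUL. Calls whose
#' members include no CAZyme gene are still emitted, flagged
#' \code{no_cazyme}.
#'
#' @param genes labeled gene table from \code{\link{label_genes}}.
#' @param pairs pair table from \code{\link{detect_sus_pairs}} (computed from
#'   \code{genes} when omitted).
#' @param window non-negative rank distance searched up- and downstream of
#'   the pair (default 5, i.e. five protein predictions on each side).
#' @return list of class \code{caz_pul_calls}; each element has
#'   \code{pul_id, genome_id, contig_id, anchors} (data.frame),
#'   \code{members} (gene data.frame with a \code{category} column),
#'   \code{region} (rank span) and \code{no_cazyme}.
#' @export
call_puls <- function(genes, pairs = detect_sus_pairs(genes), window = 5L) {
  if (length(window) != 1L || is.na(window) || window < 0)
    stop("parameter error: window must be a non-negative integer")
  window <- as.integer(window)
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$rank), ,
                 drop = FALSE]
  calls <- list()
  for (ct in unique(pairs$contig_id)) {
    pp <- pairs[pairs$contig_id == ct, , drop = FALSE]
    gg <- genes[genes$contig_id == ct, , drop = FALSE]
    max_rank <- max(gg$rank)
    lo <- pmax(0L, pmin(pp$susc_rank, pp$susd_rank) - window)
    hi <- pmin(max_rank, pmax(pp$susc_rank, pp$susd_rank) + window)
    ord <- order(lo, hi)
    pp <- pp[ord, , drop = FALSE]; lo <- lo[ord]; hi <- hi[ord]
    grp <- integer(nrow(pp)); g <- 0L; cur_hi <- -1L
    for (i in seq_len(nrow(pp))) {
      if (lo[i] > cur_hi) { g <- g + 1L; cur_hi <- hi[i] }
      else cur_hi <- max(cur_hi, hi[i])
      grp[i] <- g
    }
    for (gi in unique(grp)) {
      sel <- grp == gi
      member_ranks <- sort(unique(unlist(mapply(
        function(l, h) seq.int(l, h), lo[sel], hi[sel], SIMPLIFY = FALSE))))
      mem <- gg[gg$rank %in% member_ranks, , drop = FALSE]
      mem$category <- vapply(seq_len(nrow(mem)), function(i)
        pul_gene_category(mem$label[i], split_models(mem$models[i])),
        character(1))
      calls[[length(calls) + 1L]] <- list(
        genome_id = pp$genome_id[1L], contig_id = ct,
        anchors = pp[sel, c("susc_id", "susd_id", "susc_rank", "susd_rank"),
                     drop = FALSE],
        members = mem,
        region = c(min(lo[sel]), max(hi[sel])),
        no_cazyme = !any(mem$label == "CAZYME"))
    }
  }
  # stable ordering and ids
  if (length(calls) > 0L) {
    ord <- order(vapply(calls, `[[`, character(1), "genome_id"),
                 vapply(calls, `[[`, character(1), "contig_id"),
                 vapply(calls, function(x) x$region[1L], numeric(1)))
    calls <- calls[ord]
    for (i in seq_along(calls)) calls[[i]]$pul_id <- sprintf("PUL%03d", i)
  }
  structure(calls, class = "caz_pul_calls")
}

#' @export
print.caz_pul_calls <- function(x, ...) {
  cat(sprintf("<caz_pul_calls> %d PUL calls\n", length(x)))
  for (p in x[seq_len(min(5L, length(x)))]) {
    cat(sprintf("  %s %s:%s ranks %d-%d, %d anchors, %d genes%s\n",
                p$pul_id, p$genome_id, p$contig_id, p$region[1], p$region[2],
                nrow(p$anchors), nrow(p$members),
                if (p$no_cazyme) " [no_cazyme]" else ""))
  }
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' Flatten PUL calls into a per-gene table
#'
#' @param calls a \code{caz_pul_calls} list.
#' @return data.frame with one row per member gene, carrying \code{pul_id}
#'   and \code{category}.
#' @export
pul_member_table <- function(calls) {
  rows <- lapply(calls, function(p) {
    m <- p$members
    m$pul_id <- p$pul_id
    m[, c("pul_id", "genome_id", "contig_id", "protein_id", "rank",
          "label", "category")]
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pul_id = character(), genome_id = character(),
               contig_id = character(), protein_id = character(),
               rank = integer(), label = character(), category = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize the composition of one PUL call
#'
#' @param pul one element of a \code{caz_pul_calls} list.
#' @param function_map substrate-category map
#'   (\code{\link{default_function_map}}).
#' @return list: \code{pul_id}, per-category gene counts, distinct CAZy
#'   family vector, substrate-category counts of the CAZy cargo, regulator /
#'   peptidase presence flags and the \code{no_cazyme} flag.
#' @export
summarize_pul <- function(pul, function_map = default_function_map()) {
  cats <- c("susC", "susD", "GH", "PL", "CE", "peptidase", "regulator",
            "non_PUL")
  counts <- stats::setNames(integer(length(cats)), cats)
  tab <- table(factor(pul$members$category, levels = cats))
  counts[names(tab)] <- as.integer(tab)
  caz <- pul$members[pul$members$label == "CAZYME", , drop = FALSE]
  fams <- unique(unlist(lapply(caz$models, function(s) {
    mods <- split_models(s)
    mods[model_class(mods) %in% classes_cazy]
  })))
  fams <- sort(fams %||% character(0))
  subs <- table(substrate_category(fams, function_map))
  list(pul_id = pul$pul_id,
       genome_id = pul$genome_id,
       category_counts = counts,
       n_distinct_cazy_families = length(fams),
       cazy_families = fams,
       substrate_counts = stats::setNames(as.integer(subs), names(subs)),
       has_regulator = counts[["regulator"]] > 0L,
       has_peptidase = counts[["peptidase"]] > 0L,
       no_cazyme = pul$no_cazyme)
}

#' Detect cellulosome components and cellulosome-capable genomes
#'
#' Scaffoldin candidates are cohesin-bearing proteins; dockerin-catalytic
#' proteins pair a dockerin with at least one GH/CE/PL catalytic domain;
#' dockerin-multimodular proteins additionally carry at least one further
#' accessory module beyond the dockerin. A genome is flagged
#' cellulosome-capable iff it encodes at least one scaffoldin candidate and
#' at least one dockerin-multimodular enzyme — cohesin-only or plain
#' dockerin-enzyme genomes are not.
#'
#' @param classifications a \code{caz_classifications} table with a
#'   \code{genome_id} column.
#' @return data.frame of class \code{caz_cellulosome_report}, one row per
#'   genome.
#' @export
detect_cellulosomes <- function(classifications) {
  stopifnot("genome_id" %in% names(classifications))
  cl <- classifications
  acc_n <- vapply(cl$accessory_families, function(s)
    length(split_models(s)), integer(1))
  cat_classes <- lapply(cl$catalytic_families, function(s)
    model_class(split_models(s)))
  dock_cat <- cl$has_dockerin &
    vapply(cat_classes, function(x) any(x %in% c("GH", "CE", "PL")),
           logical(1))
  dock_multi <- dock_cat & acc_n >= 2L
  gl <- sort(unique(stats::na.omit(cl$genome_id)))
  rows <- lapply(gl, function(g) {
    sel <- !is.na(cl$genome_id) & cl$genome_id == g
    scaf <- cl$protein_id[sel & cl$is_scaffoldin_candidate]
    dc <- cl$protein_id[sel & dock_cat]
    dm <- cl$protein_id[sel & dock_multi]
    data.frame(
      genome_id = g,
      n_scaffoldins = length(scaf),
      n_dockerin_catalytic = length(dc),
      n_dockerin_multimodular = length(dm),
      is_cellulosome_capable = length(scaf) > 0L && length(dm) > 0L,
      scaffoldin_ids = paste(sort(scaf), collapse = ";"),
      dockerin_catalytic_ids = paste(sort(dc), collapse = ";"),
      dockerin_multimodular_ids = paste(sort(dm), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(genome_id = character(), n_scaffoldins = integer(),
               n_dockerin_catalytic = integer(),
               n_dockerin_multimodular = integer(),
               is_cellulosome_capable = logical(),
               scaffoldin_ids = character(),
               dockerin_catalytic_ids = character(),
               dockerin_multimodular_ids = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("caz_cellulosome_report", "data.frame")
  out
}
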