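#' Family-by-genome module count matrix
#'
#' Heatmap-ready matrix of CAZy module counts: one row per family, one
#' column per genome (including \code{"unbinned"} when present). A cell
#' counts domain occurrences of that family in that genome, so row sums are
#' consistent with \code{\link{census}} module counts.
#'
#' @param arch_table a \code{caz_arch_table}.
#' @param genes gene table giving \code{genome_id} per protein.
#' @param classes CAZy classes included (default GH/GT/CE/PL/AA/CBM).
#' @param by_subfamily count at subfamily resolution (default \code{FALSE}:
#'   families are collapsed with \code{\link{base_family}}, the resolution a
#'   family heatmap is drawn at).
#' @return integer matrix, families x genomes, rows and columns sorted.
#' @export
genome_matrix <- function(arch_table, genes, classes = classes_cazy,
                          by_subfamily = FALSE) {
  doms <- do.call(rbind, c(
    lapply(seq_len(nrow(arch_table)), function(i) {
      d <- arch_table$domains[[i]]
      if (nrow(d) == 0L) return(NULL)
      d$protein_id <- arch_table$protein_id[i]
      d
    }),
    list(data.frame(model_name = character(), model_class = character(),
                    ali_from = integer(), ali_to = integer(),
                    protein_id = character()))))
  doms <- doms[doms$model_class %in% classes, , drop = FALSE]
  doms$genome_id <- genes$genome_id[match(doms$protein_id, genes$protein_id)]
  doms$family <- if (by_subfamily) doms$model_name else
    base_family(doms$model_name)
  fams <- sort(unique(doms$family))
  gens <- sort(unique(stats::na.omit(doms$genome_id)))
  m <- matrix(0L, length(fams), length(gens),
              dimnames = list(fams, gens))
  if (nrow(doms) > 0L) {
    tt <- table(doms$family, doms$genome_id)
    m[rownames(tt), colnames(tt)] <- as.integer(tt)
  }
  m
}

#' Fraction of CAZyme proteins assigned to named genomes
#'
#' @param classifications a \code{caz_classifications} table with
#'   \code{genome_id} (\code{"unbinned"} marks proteins outside any bin).
#' @return fraction in [0, 1], or \code{NA} when there are no CAZymes.
#' @export
binned_fraction <- function(classifications) {
  caz <- classifications[classifications$is_cazyme, , drop = FALSE]
  if (nrow(caz) == 0L) return(NA_real_)
  sum(!is.na(caz$genome_id) & caz$genome_id != "unbinned") / nrow(caz)
}

#' Read a spectral-count table
#'
#' TSV with columns \code{protein_id, genome_id, spectral_count} and an
#' optional \code{signal_peptide} flag; counts must be non-negative integers.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_spectra <- function(path) {
  sp <- read_tsv(path)
  need <- c("protein_id", "genome_id", "spectral_count")
  if (!all(need %in% names(sp)))
    stop("spectral table must have columns protein_id, genome_id, spectral_count")
  if (any(sp$spectral_count < 0))
    stop("data error: negative spectral_count")
  sp$spectral_count <- as.integer(sp$spectral_count)
  sp
}

#' Integrate a spectral-count metaproteome with genome annotations
#'
#' Joins detected proteins onto their classifications and locus reports:
#' per-genome totals (distinct detected proteins, summed spectral counts),
#' spectral totals per substrate category (a bifunctional protein
#' contributes its full count to every category it matches; a disambiguated
#' total splitting the count equally is also reported), and per-genome
#' evidence flags — cellulosomal machinery detected (any secreted cohesin- or
#' dockerin-bearing protein) and PUL components detected (any secreted
#' SusC/SusD protein). Detected proteins without any annotation are totalled
#' as unannotated, never dropped, so spectral counts are conserved.
#'
#' @param spectra spectral-count data.frame (\code{\link{read_spectra}}).
#' @param classifications \code{caz_classifications} with \code{genome_id}.
#' @param arch_table matching \code{caz_arch_table}.
#' @param function_map substrate-category map.
#' @return list of class \code{caz_integration}: \code{per_genome}
#'   (data.frame), \code{category_totals}, \code{category_totals_split},
#'   \code{unannotated} (data.frame), \code{total_spectra},
#'   \code{n_proteins_detected}.
#' @export
integrate_metaproteome <- function(spectra, classifications, arch_table,
                                   function_map = default_function_map()) {
  if (anyDuplicated(spectra$protein_id)) {
    dup <- spectra[spectra$protein_id %in%
                     spectra$protein_id[duplicated(spectra$protein_id)], ]
    if (any(tapply(dup$genome_id, dup$protein_id,
                   function(x) length(unique(x)) > 1L)))
      stop("data error: duplicate protein_id with conflicting genome_id")
    agg <- stats::aggregate(spectral_count ~ protein_id + genome_id,
                            spectra, sum)
    spectra <- agg
  }
  spectra <- spectra[order(spectra$protein_id), , drop = FALSE]
  ix <- match(spectra$protein_id, classifications$protein_id)
  annotated <- !is.na(ix)

  # per-genome totals
  gl <- sort(unique(spectra$genome_id))
  per_genome <- do.call(rbind, lapply(gl, function(g) {
    sel <- spectra$genome_id == g
    selc <- which(sel & annotated)
    cls <- classifications[ix[selc], , drop = FALSE]
    dom_classes <- unlist(lapply(ix[selc], function(i)
      arch_table$domains[[match(classifications$protein_id[i],
                                arch_table$protein_id)]]$model_class))
    data.frame(
      genome_id = g,
      n_proteins = sum(sel),
      total_spectra = sum(spectra$spectral_count[sel]),
      n_cazyme = sum(cls$is_cazyme),
      cellulosomal_detected = any(cls$has_cohesin | cls$has_dockerin),
      pul_component_detected = any(dom_classes %in% c("SUSC", "SUSD")),
      stringsAsFactors = FALSE)
  }))
  if (is.null(per_genome))
    per_genome <- data.frame(genome_id = character(), n_proteins = integer(),
                             total_spectra = integer(), n_cazyme = integer(),
                             cellulosomal_detected = logical(),
                             pul_component_detected = logical(),
                             stringsAsFactors = FALSE)

  # substrate-category spectral totals
  cats <- c("cellulase", "hemicellulase", "pectinase", "amylase",
            "oligosaccharide-degrading", "other")
  tot <- stats::setNames(numeric(length(cats)), cats)
  tot_split <- tot
  for (k in which(annotated)) {
    dom <- arch_table$domains[[match(spectra$protein_id[k],
                                     arch_table$protein_id)]]
    fams <- dom$model_name[dom$model_class %in% c("GH", "CE", "PL", "AA")]
    if (length(fams) == 0L) next
    cc <- unique(substrate_category(fams, function_map))
    tot[cc] <- tot[cc] + spectra$spectral_count[k]
    tot_split[cc] <- tot_split[cc] + spectra$spectral_count[k] / length(cc)
  }

  unann <- spectra[!annotated, , drop = FALSE]
  rownames(unann) <- NULL
  structure(list(
    per_genome = per_genome,
    category_totals = tot,
    category_totals_split = tot_split,
    unannotated = unann,
    unannotated_spectra = sum(unann$spectral_count),
    total_spectra = sum(spectra$spectral_count),
    n_proteins_detected = nrow(spectra)), class = "caz_integration")
}

#' @export
print.caz_integration <- function(x, ...) {
  cat(sprintf(
    "Metaproteome integration: %d proteins, %d spectra over %d genomes (%d unannotated proteins)\n",
    x$n_proteins_detected, x$total_spectra, nrow(x$per_genome),
    nrow(x$unannotated)))
  top <- x$per_genome[order(-x$per_genome$n_proteins), , drop = FALSE]
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}
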