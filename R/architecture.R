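#' Classify one protein architecture
#'
#' Sets the CAZyme and module flags for a protein from its ordered domain
#' architecture: catalytic families (GH/CE/PL/AA/GT), accessory families
#' (CBM/SLH/dockerin/cohesin), CAZyme membership (any GH/GT/CE/PL/AA/CBM
#' domain), multimodularity (at least one GH/CE/PL catalytic domain plus at
#' least one accessory domain — GT- or AA-only proteins are never counted as
#' multimodular CAZymes), scaffoldin candidacy (any cohesin domain) and
#' DUF-accessory status (DUF plus accessory, no catalytic domain).
#'
#' @param arch a \code{caz_architecture} from \code{\link{build_architecture}}.
#' @return one-row data.frame of class flags and family lists
#'   (semicolon-joined).
#' @export
classify_protein <- function(arch) {
  stopifnot(inherits(arch, "caz_architecture"))
  cls <- arch$domains$model_class
  nm <- arch$domains$model_name
  catalytic <- nm[cls %in% classes_catalytic]
  accessory <- nm[cls %in% classes_accessory]
  has_dockerin <- any(cls == "DOCKERIN")
  has_cohesin <- any(cls == "COHESIN")
  has_slh <- any(cls == "SLH")
  data.frame(
    protein_id = arch$protein_id,
    architecture_string = arch$architecture_string,
    n_domains = nrow(arch$domains),
    catalytic_families = paste(catalytic, collapse = ";"),
    accessory_families = paste(accessory, collapse = ";"),
    is_cazyme = any(cls %in% classes_cazy),
    is_multimodular = any(cls %in% c("GH", "CE", "PL")) &&
      length(accessory) > 0L,
    has_dockerin = has_dockerin,
    has_cohesin = has_cohesin,
    has_slh = has_slh,
    is_scaffoldin_candidate = has_cohesin,
    duf_accessory = any(cls == "DUF") && length(accessory) > 0L &&
      length(catalytic) == 0L,
    stringsAsFactors = FALSE)
}

#' Classify every protein in an architecture table
#'
#' @param arch_table a \code{caz_arch_table} from
#'   \code{\link{build_architectures}}.
#' @param genes optional gene table; when given, a \code{genome_id} column is
#'   joined on (\code{NA} for proteins absent from the gene table).
#' @return data.frame (\code{caz_classifications}), one row per protein.
#' @export
classify_proteins <- function(arch_table, genes = NULL) {
  stopifnot(inherits(arch_table, "caz_arch_table") ||
              is.data.frame(arch_table))
  rows <- lapply(seq_len(nrow(arch_table)), function(i) {
    a <- structure(list(
      protein_id = arch_table$protein_id[i],
      domains = arch_table$domains[[i]],
      architecture_string = arch_table$architecture_string[i]),
      class = "caz_architecture")
    classify_protein(a)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(), architecture_string = character(),
               n_domains = integer(), catalytic_families = character(),
               accessory_families = character(), is_cazyme = logical(),
               is_multimodular = logical(), has_dockerin = logical(),
               has_cohesin = logical(), has_slh = logical(),
               is_scaffoldin_candidate = logical(),
               duf_accessory = logical(), stringsAsFactors = FALSE)
  if (!is.null(genes))
    out$genome_id <- genes$genome_id[match(out$protein_id, genes$protein_id)]
  rownames(out) <- NULL
  class(out) <- c("caz_classifications", "data.frame")
  out
}

#' Screen for DUF domains appended to accessory modules
#'
#' Reports proteins carrying at least one domain of unknown function (DUF)
#' together with at least one accessory module (CBM, dockerin or SLH) and no
#' catalytic CAZy domain — candidate new-function proteins whose only
#' annotated role is carbohydrate binding or complex assembly.
#'
#' @param classifications a \code{caz_classifications} table.
#' @param arch_table the matching \code{caz_arch_table}.
#' @return data.frame: \code{protein_id}, \code{duf_names},
#'   \code{accessory_names} (semicolon-joined), \code{architecture_string}.
#' @export
duf_screen <- function(classifications, arch_table) {
  keep <- classifications$protein_id[classifications$duf_accessory]
  ix <- match(keep, arch_table$protein_id)
  rows <- lapply(seq_along(keep), function(i) {
    dom <- arch_table$domains[[ix[i]]]
    acc <- dom$model_name[dom$model_class %in% c("CBM", "DOCKERIN", "SLH")]
    data.frame(
      protein_id = keep[i],
      duf_names = paste(dom$model_name[dom$model_class == "DUF"],
                        collapse = ";"),
      accessory_names = paste(acc, collapse = ";"),
      architecture_string = arch_table$architecture_string[ix[i]],
      stringsAsFactors = FALSE)
  })
  keep_acc <- vapply(rows, function(r) nzchar(r$accessory_names), logical(1))
  out <- if (length(rows) > 0L) do.call(rbind, rows[keep_acc]) else
    data.frame(protein_id = character(), duf_names = character(),
               accessory_names = character(),
               architecture_string = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Module-level census of a protein set
#'
#' Counts CAZyme and accessory modules the way family profiles are reported
#' for a (meta)genome: module counts per class count domain occurrences (a
#' protein with two CBM6 domains contributes two CBM modules), distinct
#' family counts are per class, distinct architectures are counted among
#' multimodular proteins at exact (subfamily-sensitive) string identity, and
#' the architecture frequency spectrum covers every protein with at least one
#' domain.
#'
#' @param classifications a \code{caz_classifications} table.
#' @param arch_table the matching \code{caz_arch_table}.
#' @return list of class \code{caz_census}: \code{module_counts},
#'   \code{distinct_families} (named integer vectors over classes),
#'   \code{distinct_architectures}, \code{architecture_frequency},
#'   \code{n_proteins}.
#' @export
census <- function(classifications, arch_table) {
  all_classes <- c("GH", "GT", "CE", "PL", "AA", "CBM", "SLH", "COHESIN",
                   "DOCKERIN", "SUSC", "SUSD", "DUF", "OTHER")
  doms <- do.call(rbind, c(arch_table$domains,
                           list(data.frame(model_name = character(),
                                           model_class = character(),
                                           ali_from = integer(),
                                           ali_to = integer()))))
  counts <- stats::setNames(integer(length(all_classes)), all_classes)
  fams <- counts
  if (nrow(doms) > 0L) {
    tab <- table(factor(doms$model_class, levels = all_classes))
    counts[names(tab)] <- as.integer(tab)
    ft <- tapply(doms$model_name, factor(doms$model_class,
                                         levels = all_classes),
                 function(x) length(unique(x)))
    fams[names(ft)][!is.na(ft)] <- as.integer(ft[!is.na(ft)])
  }
  nonempty <- arch_table$architecture_string[arch_table$n_domains > 0L]
  freq <- if (length(nonempty) > 0L) {
    tt <- table(nonempty)
    stats::setNames(as.integer(tt), names(tt))
  } else stats::setNames(integer(0), character(0))
  mm <- classifications$architecture_string[classifications$is_multimodular]
  structure(list(
    module_counts = counts,
    distinct_families = fams,
    distinct_architectures = length(unique(mm)),
    architecture_frequency = freq,
    n_proteins = nrow(arch_table)), class = "caz_census")
}

#' @export
print.caz_census <- function(x, ...) {
  cat("CAZyme module census\n")
  nz <- x$module_counts[x$module_counts > 0L]
  cat("  modules: ",
      paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n", sep = "")
  cat(sprintf("  distinct multimodular architectures: %d\n",
              x$distinct_architectures))
  cat(sprintf("  proteins with >=1 domain: %d\n",
              sum(x$architecture_frequency)))
  invisible(x)
}
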