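# Shared readers/writers. All writers use binary connections or fixed options
# so a given object always serialises to the same bytes (the pipeline's
# end-to-end determinism contract is hash equality of output files).

write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a gene table as GFF3, one file per genome
#'
#' Emits GFF3 version 3 (1-based inclusive coordinates) with one \code{CDS}
#' feature per protein-coding gene; the \code{ID} attribute carries the
#' protein id. Files are named \code{<genome_id>.gff3}.
#'
#' @param genes gene table (\code{genome_id, contig_id, protein_id, start,
#'   end, strand, rank}).
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_genes_gff3 <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- sort(unique(genes$genome_id))
  paths <- character(0)
  for (g in genomes) {
    gg <- genes[genes$genome_id == g, , drop = FALSE]
    gg <- gg[order(gg$contig_id, gg$start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = gg$contig_id,
      ranges = IRanges::IRanges(start = gg$start, end = gg$end),
      strand = gg$strand,
      type = "CDS",
      phase = 0L,
      ID = gg$protein_id)
    p <- file.path(dir, paste0(g, ".gff3"))
    rtracklayer::export(gr, p, format = "gff3")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-genome GFF3 files into a gene table
#'
#' Reads every \code{*.gff3} file in \code{dir} (file basename = genome id)
#' and rebuilds the gene table; gene ranks are (re)derived from coordinate
#' order along each contig via \code{\link{assign_ranks}}.
#'
#' @param dir directory of GFF3 files as written by
#'   \code{\link{write_genes_gff3}}.
#' @return gene table data.frame.
#' @export
read_genes_gff3 <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.gff3$", full.names = TRUE))
  rows <- lapply(files, function(p) {
    gr <- rtracklayer::import(p, format = "gff3")
    data.frame(
      genome_id = sub("\\.gff3$", "", basename(p)),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      protein_id = S4Vectors::mcols(gr)$ID,
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(genome_id = character(), contig_id = character(),
                        protein_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  assign_ranks(genes)
}

#' Assign gene ranks along each contig
#'
#' The rank of a gene is its 0-based ordinal among the protein predictions of
#' its contig in coordinate order; locus windows are measured in ranks, never
#' in base pairs. Row order of the result is genome, contig, rank.
#'
#' @param genes gene table without (or with stale) \code{rank}.
#' @return gene table with a \code{rank} column.
#' @export
assign_ranks <- function(genes) {
  if (nrow(genes) == 0L) { genes$rank <- integer(0); return(genes) }
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$start,
                       genes$end), , drop = FALSE]
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  genes$rank <- stats::ave(seq_len(nrow(genes)), key,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL
  genes
}

write_fasta <- function(seqs, path) {
  # seqs: AAStringSet
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

read_fasta <- function(path) Biostrings::readAAStringSet(path)
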