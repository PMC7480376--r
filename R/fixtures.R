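#' Write a simulated fixture set to disk
#'
#' Emits the plain-text fixture files every pipeline stage consumes: one GFF3
#' per genome under \code{genes/}, protein / query / reference multi-FASTA,
#' a domtblout-style hit table, the spectral-count TSV and the truth manifest
#' as JSON. \code{\link{read_fixtures}} of the result reproduces the
#' in-memory objects.
#'
#' @param sim a \code{caz_sim} from \code{\link{simulate_bins}}.
#' @param dir output directory (created; must be writable).
#' @return \code{dir}, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "caz_sim"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    stop(sprintf("I/O error: cannot create fixture directory %s", dir))
  write_genes_gff3(sim$genes, file.path(dir, "genes"))
  write_fasta(sim$proteins, file.path(dir, "proteins.faa"))
  write_fasta(sim$queries, file.path(dir, "queries.faa"))
  write_fasta(sim$references, file.path(dir, "references.faa"))
  write_domtblout(sim$hits, file.path(dir, "hits.domtbl"))
  write_tsv(sim$spectra, file.path(dir, "spectra.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a fixture set back into memory
#'
#' @param dir directory written by \code{\link{write_fixtures}}.
#' @return list with the \code{\link{simulate_bins}} components
#'   (\code{genes, hits, proteins, queries, references, spectra, manifest}).
#' @export
read_fixtures <- function(dir) {
  stopifnot(dir.exists(dir))
  spectra <- read_spectra(file.path(dir, "spectra.tsv"))
  spectra$signal_peptide <- as.logical(spectra$signal_peptide)
  list(
    genes = read_genes_gff3(file.path(dir, "genes")),
    hits = parse_domtblout(file.path(dir, "hits.domtbl")),
    proteins = read_fasta(file.path(dir, "proteins.faa")),
    queries = read_fasta(file.path(dir, "queries.faa")),
    references = read_fasta(file.path(dir, "references.faa")),
    spectra = spectra,
    manifest = read_manifest(file.path(dir, "manifest.json")))
}

#' Write a truth manifest as JSON
#' @param manifest manifest list from \code{\link{simulate_bins}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write_json_stable(manifest, path)
}

#' Read a truth manifest
#' @param path JSON path written by \code{\link{write_manifest}}.
#' @return manifest list (data.frame fields restored with integer columns).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  as_df <- function(x, cols, int_cols = character(0)) {
    if (is.null(x) || length(x) == 0L) {
      d <- stats::setNames(
        rep(list(character(0)), length(cols)), cols)
      d <- as.data.frame(d, stringsAsFactors = FALSE)
    } else d <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cc in int_cols) d[[cc]] <- as.integer(d[[cc]])
    d
  }
  if (!is.null(m$planted_puls))
    m$planted_puls <- as_df(m$planted_puls,
                            int_cols = c("pul", "susc_rank", "susd_rank",
                                         "decoy_rank"),
                            cols = c("pul", "genome_id", "contig_id",
                                     "susc_rank", "susd_rank", "cargo_ids",
                                     "cargo_ranks", "cargo_models",
                                     "decoy_id", "decoy_rank"))
  if (!is.null(m$planted_cellulosome))
    m$planted_cellulosome <- as_df(m$planted_cellulosome,
                                   cols = c("genome_id", "contig_id",
                                            "scaffoldin_ids",
                                            "dockerin_multimodular_ids",
                                            "dockerin_plain_ids"))
  m$planted_architectures <- as_df(m$planted_architectures,
                                   cols = c("protein_id",
                                            "architecture_string"))
  m$planted_identities <- as_df(m$planted_identities,
                                cols = c("query_id", "ref_id",
                                         "target_identity"))
  if (nrow(m$planted_identities) > 0L)
    m$planted_identities$target_identity <-
      as.numeric(m$planted_identities$target_identity)
  for (nm in c("capable_genomes", "lone_susc_ids", "secreted_ids"))
    m[[nm]] <- as.character(unlist(m[[nm]]) %||% character(0))
  m$decoy_genomes <- lapply(m$decoy_genomes, function(x)
    as.character(unlist(x) %||% character(0)))
  int_fields <- c("n_hits_emitted", "n_hits_filtered")
  for (nm in int_fields) m[[nm]] <- as.integer(m[[nm]])
  m
}

# convenience accessors for semicolon-joined manifest id lists
#' Split a semicolon-joined manifest id field
#' @param s character vector of \code{;}-joined ids.
#' @return list of character vectors.
#' @export
manifest_ids <- function(s) lapply(s, split_models)
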