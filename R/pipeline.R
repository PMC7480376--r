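#' Run the full annotation pipeline on a fixture directory
#'
#' Executes every stage in order on the files of a fixture directory (or any
#' directory with the same layout): parse and filter domain hits, resolve
#' overlaps and build architectures, classify proteins, take the module
#' census, call tandem susCD pairs and PULs, detect cellulosome-capable
#' genomes, score sequence novelty of the query set against the reference
#' set, and integrate the spectral-count table. All reports are written as
#' stable-ordered TSV/JSON under \code{out_dir}; running twice on the same
#' input yields byte-identical files.
#'
#' @param fixture_dir input directory (layout of \code{\link{write_fixtures}}).
#' @param out_dir report directory (created).
#' @param evalue_max,coverage_min domain-hit filter thresholds.
#' @param window PUL window in gene ranks.
#' @param novelty_threshold novelty cutoff in percent identity.
#' @param min_score minimum local-alignment score counting as a hit.
#' @return (invisibly) list of in-memory results: \code{arch, class, census,
#'   pairs, puls, pul_summaries, cellulosomes, novelty, novelty_summary,
#'   integration, genome_matrix, binned_fraction, duf}.
#' @export
run_pipeline <- function(fixture_dir, out_dir,
                         evalue_max = 1e-6, coverage_min = 0.30,
                         window = 5L, novelty_threshold = 90,
                         min_score = 75) {
  fx <- read_fixtures(fixture_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  hits <- filter_hits(fx$hits, evalue_max, coverage_min)
  arch <- build_architectures(hits, prefiltered = TRUE)
  cls <- classify_proteins(arch, fx$genes)
  cen <- census(cls, arch)
  duf <- duf_screen(cls, arch)

  genes_l <- label_genes(fx$genes, arch)
  pairs <- detect_sus_pairs(genes_l)
  puls <- call_puls(genes_l, pairs, window = window)
  pul_sum <- lapply(puls, summarize_pul)
  cell <- detect_cellulosomes(cls)

  nov <- novelty_records(fx$queries, fx$references, cls,
                         min_score = min_score)
  nov_sum <- novelty_summary(nov, threshold = novelty_threshold)

  integ <- integrate_metaproteome(fx$spectra, cls, arch)
  gmat <- genome_matrix(arch, fx$genes)
  bfrac <- binned_fraction(cls)

  # reports
  write_tsv(hits, file.path(out_dir, "filtered_hits.tsv"))
  write_architectures(arch, file.path(out_dir, "architectures.tsv"))
  write_tsv(cls, file.path(out_dir, "classifications.tsv"))
  write_json_stable(list(
    module_counts = as.list(cen$module_counts),
    distinct_families = as.list(cen$distinct_families),
    distinct_architectures = cen$distinct_architectures,
    architecture_frequency = as.list(cen$architecture_frequency),
    n_proteins = cen$n_proteins), file.path(out_dir, "census.json"))
  write_tsv(duf, file.path(out_dir, "duf_screen.tsv"))
  write_tsv(pairs, file.path(out_dir, "sus_pairs.tsv"))
  write_tsv(pul_member_table(puls), file.path(out_dir, "pul_members.tsv"))
  write_json_stable(lapply(pul_sum, function(s) {
    s$category_counts <- as.list(s$category_counts)
    s$substrate_counts <- as.list(s$substrate_counts)
    s
  }), file.path(out_dir, "pul_summary.json"))
  write_tsv(cell, file.path(out_dir, "cellulosomes.tsv"))
  write_tsv(nov, file.path(out_dir, "novelty.tsv"))
  write_json_stable(list(
    fraction_below = nov_sum$fraction_below,
    threshold = nov_sum$threshold,
    n_with_hit = nov_sum$n_with_hit, n_below = nov_sum$n_below,
    n_no_hit = nov_sum$n_no_hit,
    histogram = as.list(nov_sum$histogram)),
    file.path(out_dir, "novelty_summary.json"))
  write_json_stable(list(
    per_genome = integ$per_genome,
    category_totals = as.list(integ$category_totals),
    category_totals_split = as.list(integ$category_totals_split),
    unannotated = integ$unannotated,
    total_spectra = integ$total_spectra,
    n_proteins_detected = integ$n_proteins_detected),
    file.path(out_dir, "metaproteome.json"))
  gm <- data.frame(family = rownames(gmat), gmat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(gm, file.path(out_dir, "genome_matrix.tsv"))
  write_json_stable(list(binned_fraction = bfrac),
                    file.path(out_dir, "binned_fraction.json"))

  invisible(list(arch = arch, class = cls, census = cen, duf = duf,
                 pairs = pairs, puls = puls, pul_summaries = pul_sum,
                 cellulosomes = cell, novelty = nov,
                 novelty_summary = nov_sum, integration = integ,
                 genome_matrix = gmat, binned_fraction = bfrac))
}
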