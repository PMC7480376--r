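# Shared fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

# moderate community for module-level tests
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(n_genomes = 6, genes_per_genome = 120, n_puls = 8,
                      n_cellulosome_loci = 2, n_multimodular = 12,
                      n_decoys = 4, n_duf_accessory = 3,
                      identity_targets = c(0.5, 0.7, 0.9), seed = 101)
    .sim_cache$small <- simulate_bins(cfg)
  }
  .sim_cache$small
}

# full-size community: 10 genomes, ~2,000 genes, 25 planted PULs
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_bins(sim_config(seed = 2024))
  }
  .sim_cache$default
}

# an ad hoc domain hit row
make_hit <- function(protein_id = "p1", model_name = "GH5",
                     protein_length = 400L, model_length = 100L,
                     hmm_from = 1L, hmm_to = 60L,
                     ali_from = 1L, ali_to = 200L,
                     i_evalue = 1e-10, score = 100) {
  h <- data.frame(protein_id = protein_id, protein_length = protein_length,
                  model_name = model_name,
                  model_class = model_class(model_name),
                  model_length = model_length,
                  hmm_from = as.integer(hmm_from),
                  hmm_to = as.integer(hmm_to),
                  ali_from = as.integer(ali_from),
                  ali_to = as.integer(ali_to),
                  i_evalue = i_evalue, score = score,
                  stringsAsFactors = FALSE)
  class(h) <- c("caz_hits", "data.frame")
  h
}

bind_hits <- function(...) {
  h <- do.call(rbind, list(...))
  class(h) <- c("caz_hits", "data.frame")
  h
}

# a minimal labeled gene table: one contig, labels given per rank
make_gene_table <- function(labels, genome = "g1", contig = "g1_c1") {
  n <- length(labels)
  genes <- data.frame(
    genome_id = genome, contig_id = contig,
    protein_id = sprintf("%s_%03d", genome, seq_len(n)),
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+", rank = seq_len(n) - 1L,
    models = vapply(labels, function(l) switch(
      l, SUSC = "SusC", SUSD = "SusD", GH = "GH16", CE = "CE3", PL = "PL1",
      PEPTIDASE = "Peptidase_M16", REGULATOR = "HTH_AraC", ""),
      character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  genes$label <- ifelse(labels %in% c("GH", "CE", "PL"), "CAZYME",
                        ifelse(labels == "", "OTHER", labels))
  genes
}
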