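test_that("the genome matrix counts modules per family and genome", {
  at <- build_architectures(bind_hits(
    make_hit("p1", "GH5", ali_from = 1, ali_to = 100),
    make_hit("p2", "GH5", ali_from = 1, ali_to = 100),
    make_hit("p2", "CBM6", ali_from = 150, ali_to = 220)))
  genes <- data.frame(genome_id = "gA", contig_id = "c",
                      protein_id = c("p1", "p2"),
                      stringsAsFactors = FALSE)
  m <- genome_matrix(at, genes)
  expect_equal(m["GH5", "gA"], 2L)
  expect_equal(m["CBM6", "gA"], 1L)
})

test_that("genome-matrix totals agree with the census and partition additively", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  cls <- classify_proteins(arch, sim$genes)
  cen <- census(cls, arch)
  m <- genome_matrix(arch, sim$genes)
  fam_cls <- model_class(rownames(m))
  for (cl in c("GH", "GT", "CE", "PL", "AA", "CBM"))
    expect_equal(sum(m[fam_cls == cl, ]), unname(cen$module_counts[[cl]]))
  # additive over a genome partition
  gset <- unique(sim$genes$genome_id)
  gA <- gset[1:3]
  mA <- genome_matrix(arch, sim$genes[sim$genes$genome_id %in% gA, ])
  mB <- genome_matrix(arch,
                      sim$genes[!sim$genes$genome_id %in% gA, ])
  expect_equal(sum(mA) + sum(mB), sum(m))
})

test_that("binned fraction counts CAZyme proteins outside the unbinned pool", {
  cls <- data.frame(protein_id = sprintf("p%d", 1:10),
                    is_cazyme = TRUE,
                    genome_id = c(rep("gA", 4), rep("gB", 3),
                                  rep("unbinned", 3)),
                    stringsAsFactors = FALSE)
  expect_equal(binned_fraction(cls), 0.7)
  cls$genome_id <- "gA"
  expect_equal(binned_fraction(cls), 1.0)
  expect_true(is.na(binned_fraction(cls[cls$is_cazyme == FALSE, ])))
})

test_that("metaproteome integration conserves counts and flags evidence", {
  at <- build_architectures(bind_hits(
    make_hit("susd1", "SusD", ali_from = 1, ali_to = 300),
    make_hit("gh1", "GH5", ali_from = 1, ali_to = 150),
    make_hit("gh1", "CE3", ali_from = 180, ali_to = 280),
    make_hit("coh1", "cohesin_I", ali_from = 1, ali_to = 100)))
  cls <- classify_proteins(at)
  cls$genome_id <- unname(c(susd1 = "gB", gh1 = "gA",
                            coh1 = "gC")[cls$protein_id])
  sp <- data.frame(protein_id = c("susd1", "gh1", "coh1", "mystery"),
                   genome_id = c("gB", "gA", "gC", "gA"),
                   spectral_count = c(6L, 10L, 3L, 2L),
                   stringsAsFactors = FALSE)
  it <- integrate_metaproteome(sp, cls, at)
  expect_equal(it$total_spectra, 21)
  # conservation: per-genome totals + nothing lost
  expect_equal(sum(it$per_genome$total_spectra), 21)
  expect_equal(it$unannotated$protein_id, "mystery")
  expect_equal(it$unannotated_spectra, 2)
  # SusD detection flags the genome as producing PUL components
  pg <- it$per_genome
  expect_true(pg$pul_component_detected[pg$genome_id == "gB"])
  expect_false(pg$pul_component_detected[pg$genome_id == "gA"])
  expect_true(pg$cellulosomal_detected[pg$genome_id == "gC"])
  # a bifunctional GH5-CE3 protein contributes fully to both categories
  expect_equal(it$category_totals[["cellulase"]], 10)
  expect_equal(it$category_totals[["hemicellulase"]], 10)
  expect_equal(it$category_totals_split[["cellulase"]], 5)

  # empty table
  it0 <- integrate_metaproteome(sp[0, ], cls, at)
  expect_equal(it0$total_spectra, 0)
  expect_equal(nrow(it0$per_genome), 0)

  # conflicting genome assignment is a data error
  bad <- rbind(sp, data.frame(protein_id = "gh1", genome_id = "gB",
                              spectral_count = 1L))
  expect_error(integrate_metaproteome(bad, cls, at), "data error")
})

test_that("integration on fixtures conserves spectra and is row-order invariant", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  cls <- classify_proteins(arch, sim$genes)
  it <- integrate_metaproteome(sim$spectra, cls, arch)
  expect_equal(it$total_spectra, sum(sim$spectra$spectral_count))
  expect_equal(sum(it$per_genome$total_spectra),
               sum(sim$spectra$spectral_count))
  expect_equal(it$n_proteins_detected, length(sim$manifest$secreted_ids))
  set.seed(4)
  it2 <- integrate_metaproteome(sim$spectra[sample(nrow(sim$spectra)), ],
                                cls, arch)
  expect_equal(it2$per_genome, it$per_genome)
  expect_equal(it2$category_totals, it$category_totals)
})
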