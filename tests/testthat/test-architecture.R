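arch_from_models <- function(models, pid = "p1") {
  n <- length(models)
  if (n == 0L) return(build_architecture(make_hit()[0, ]))
  h <- do.call(bind_hits, lapply(seq_len(n), function(i)
    make_hit(pid, models[i], ali_from = (i - 1) * 60 + 1, ali_to = i * 60,
             protein_length = 60L * n)))
  build_architecture(h)
}

test_that("protein classification follows the multimodular and scaffoldin rules", {
  c1 <- classify_protein(arch_from_models(c("CBM48", "GH13_9")))
  expect_true(c1$is_cazyme)
  expect_true(c1$is_multimodular)
  expect_equal(c1$catalytic_families, "GH13_9")
  expect_equal(c1$accessory_families, "CBM48")

  scaf <- classify_protein(arch_from_models(rep("cohesin_I", 6)))
  expect_true(scaf$is_scaffoldin_candidate)
  expect_false(scaf$is_multimodular)
  expect_false(scaf$is_cazyme)

  none <- classify_protein(arch_from_models(character(0)))
  expect_false(any(unlist(none[c("is_cazyme", "is_multimodular",
                                 "has_dockerin", "has_cohesin", "has_slh",
                                 "is_scaffoldin_candidate",
                                 "duf_accessory")])))

  # GT- and AA-anchored proteins are CAZymes but never multimodular
  gt <- classify_protein(arch_from_models(c("GT2", "CBM6")))
  expect_true(gt$is_cazyme)
  expect_false(gt$is_multimodular)
  cbm_only <- classify_protein(arch_from_models(c("CBM6", "CBM6")))
  expect_true(cbm_only$is_cazyme)
  expect_false(cbm_only$is_multimodular)
})

test_that("DUF screen selects accessory-appended DUFs without catalytic domains", {
  at <- build_architectures(bind_hits(
    make_hit("a", "DUF4832", ali_from = 1, ali_to = 100),
    make_hit("a", "dockerin_I", ali_from = 150, ali_to = 220),
    make_hit("b", "GH5", ali_from = 1, ali_to = 100),
    make_hit("b", "DUF1234", ali_from = 150, ali_to = 220),
    make_hit("b", "CBM6", ali_from = 250, ali_to = 320),
    make_hit("c", "DUF9999", ali_from = 1, ali_to = 100)))
  cls <- classify_proteins(at)
  scr <- duf_screen(cls, at)
  expect_equal(scr$protein_id, "a")
  expect_equal(scr$duf_names, "DUF4832")
  expect_equal(scr$accessory_names, "dockerin_I")
})

test_that("DUF screen recovers exactly the planted DUF-accessory proteins", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  cls <- classify_proteins(arch, sim$genes)
  scr <- duf_screen(cls, arch)
  pa <- sim$manifest$planted_architectures
  toks <- strsplit(pa$architecture_string, "-")
  planted_duf <- pa$protein_id[vapply(toks, function(tk) {
    cl <- model_class(tk)
    any(cl == "DUF") && any(cl %in% c("CBM", "DOCKERIN", "SLH")) &&
      !any(cl %in% c("GH", "GT", "CE", "PL", "AA"))
  }, logical(1))]
  expect_setequal(scr$protein_id, planted_duf)
  expect_equal(nrow(scr), sim$manifest$config$n_duf_accessory)
})

test_that("census counts module occurrences and distinct architectures", {
  at <- build_architectures(bind_hits(
    make_hit("a", "CBM6", ali_from = 1, ali_to = 60),
    make_hit("a", "CBM6", ali_from = 80, ali_to = 140),
    make_hit("a", "GH5", ali_from = 160, ali_to = 260),
    make_hit("b", "GH5", ali_from = 1, ali_to = 100)))
  cls <- classify_proteins(at)
  cen <- census(cls, at)
  expect_equal(cen$module_counts[["GH"]], 2)
  expect_equal(cen$module_counts[["CBM"]], 2)
  expect_equal(cen$distinct_architectures, 1)
  expect_equal(sum(cen$architecture_frequency), 2)
  expect_equal(cen$distinct_families[["GH"]], 1)

  empty <- census(classify_proteins(at[0, ]), at[0, ])
  expect_true(all(empty$module_counts == 0))
  expect_equal(empty$distinct_architectures, 0)
})

test_that("census is additive over disjoint protein sets", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  cls <- classify_proteins(arch, sim$genes)
  set.seed(9)
  in_a <- sample(c(TRUE, FALSE), nrow(arch), TRUE)
  ca <- census(cls[in_a, ], arch[in_a, ])
  cb <- census(cls[!in_a, ], arch[!in_a, ])
  whole <- census(cls, arch)
  expect_equal(ca$module_counts + cb$module_counts, whole$module_counts)
  expect_equal(sum(ca$architecture_frequency) +
                 sum(cb$architecture_frequency),
               sum(whole$architecture_frequency))
})

test_that("fixture census matches totals derived from the truth manifest", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  cls <- classify_proteins(arch, sim$genes)
  cen <- census(cls, arch)
  toks <- unlist(strsplit(sim$manifest$planted_architectures$architecture_string,
                          "-"))
  truth <- table(model_class(toks))
  for (cl in names(truth))
    expect_equal(cen$module_counts[[cl]], unname(truth[[cl]]))
  expect_equal(sum(cen$architecture_frequency),
               nrow(sim$manifest$planted_architectures))
})
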