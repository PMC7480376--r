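test_that("tandem pair detection is adjacent-only and greedy", {
  g <- make_gene_table(c("", "", "", "", "SUSC", "SUSD", "", ""))
  p <- detect_sus_pairs(g)
  expect_equal(nrow(p), 1)
  expect_equal(p$susc_rank, 4)
  expect_equal(p$susd_rank, 5)

  lone <- make_gene_table(c("SUSC", "", "", "SUSD"))
  expect_equal(nrow(detect_sus_pairs(lone)), 0)

  # run of four alternating genes: greedy left-to-right gives two pairs,
  # the same as the exhaustive maximal matching on adjacent complementary
  # gene pairs
  run4 <- make_gene_table(c("SUSC", "SUSD", "SUSC", "SUSD"))
  p4 <- detect_sus_pairs(run4)
  expect_equal(nrow(p4), 2)
  adj_ok <- function(i, j, lab) abs(i - j) == 1 &&
    setequal(lab[c(i, j)], c("SUSC", "SUSD"))
  best <- 0
  lab <- run4$label
  combs <- combn(4, 2)
  for (a in seq_len(ncol(combs))) for (b in seq_len(ncol(combs))) {
    if (a >= b) next
    pa <- combs[, a]; pb <- combs[, b]
    if (length(intersect(pa, pb)) > 0) next
    if (adj_ok(pa[1], pa[2], lab) && adj_ok(pb[1], pb[2], lab))
      best <- max(best, 2)
  }
  expect_equal(nrow(p4), best)

  # strictness flags
  dc <- make_gene_table(c("SUSD", "SUSC"))
  expect_equal(nrow(detect_sus_pairs(dc)), 1)
  expect_equal(nrow(detect_sus_pairs(dc, strict_order = TRUE)), 0)
})

test_that("PUL windows capture cargo within five ranks and flag empty calls", {
  labs <- rep("", 30)
  labs[11] <- "SUSC"; labs[12] <- "SUSD"   # ranks 10, 11
  labs[15] <- "GH"                          # rank 14, distance 3
  labs[8] <- "CE"                           # rank 7, distance 3
  g <- make_gene_table(labs)
  calls <- call_puls(g, window = 5)
  expect_length(calls, 1)
  caz <- calls[[1]]$members[calls[[1]]$members$label == "CAZYME", ]
  expect_setequal(caz$rank, c(7, 14))
  expect_false(calls[[1]]$no_cazyme)

  labs2 <- rep("", 30)
  labs2[11] <- "SUSC"; labs2[12] <- "SUSD"
  labs2[18] <- "GH"                         # rank 17, distance 6: outside
  g2 <- make_gene_table(labs2)
  calls2 <- call_puls(g2, window = 5)
  expect_length(calls2, 1)
  expect_true(calls2[[1]]$no_cazyme)
  expect_false("g1_018" %in% calls2[[1]]$members$protein_id)

  expect_error(call_puls(g, window = -1), "parameter error")
})

test_that("overlapping pair windows merge; random contigs match the interval-merge oracle", {
  set.seed(15)
  for (rep in 1:12) {
    labs <- rep("", 50)
    placed <- c()
    pair_pos <- c()
    while (length(pair_pos) < 4) {
      s <- sample(1:49, 1)
      if (any(abs(s - placed) < 2) || any(abs(s + 1 - placed) < 2)) next
      labs[s] <- "SUSC"; labs[s + 1] <- "SUSD"
      placed <- c(placed, s, s + 1)
      pair_pos <- c(pair_pos, s)
    }
    for (k in sample(setdiff(1:50, placed), 6))
      labs[k] <- sample(c("GH", "CE", "PL"), 1)
    g <- make_gene_table(labs)
    w <- 5L
    calls <- call_puls(g, window = w)

    # oracle: pair windows as explicit rank sets, merged by nonempty
    # intersection to a fixed point
    pr <- detect_sus_pairs(g)
    sets <- lapply(seq_len(nrow(pr)), function(i)
      seq(max(0, min(pr$susc_rank[i], pr$susd_rank[i]) - w),
          min(49, max(pr$susc_rank[i], pr$susd_rank[i]) + w)))
    repeat {
      merged <- FALSE
      for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (i >= j || is.null(sets[[i]]) || is.null(sets[[j]])) next
        if (length(intersect(sets[[i]], sets[[j]])) > 0) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    sets <- Filter(Negate(is.null), sets)
    expect_equal(length(calls), length(sets))
    got <- lapply(calls, function(p) sort(p$members$rank))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(sets, paste, collapse = ","))
  }
})

test_that("PUL calls do not depend on gene-table row order", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  g1 <- label_genes(sim$genes, arch)
  set.seed(3)
  g2 <- label_genes(sim$genes[sample(nrow(sim$genes)), ], arch)
  c1 <- call_puls(g1)
  c2 <- call_puls(g2)
  expect_equal(lapply(c1, `[[`, "anchors"), lapply(c2, `[[`, "anchors"),
               ignore_attr = TRUE)
  expect_equal(lapply(c1, function(p) p$members$protein_id),
               lapply(c2, function(p) p$members$protein_id))
})

test_that("widening the window never loses cargo and can absorb more genes", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  g <- label_genes(sim$genes, arch)
  c5 <- call_puls(g, window = 5)
  c7 <- call_puls(g, window = 7)
  n5 <- sum(vapply(c5, function(p) nrow(p$members), integer(1)))
  n7 <- sum(vapply(c7, function(p) nrow(p$members), integer(1)))
  expect_gte(n7, n5)
  expect_lte(length(c7), length(c5))
})

test_that("PUL composition summaries count categories and substrate classes", {
  labs <- rep("", 24)
  labs[11] <- "SUSC"; labs[12] <- "SUSD"
  g <- make_gene_table(labs)
  fams <- c("GH2", "GH29", "GH31", "GH42", "GH97", "GH5", "GH43")
  slots <- c(6:9, 13:15)
  for (i in seq_along(fams)) {
    g$models[slots[i]] <- fams[i]
    g$label[slots[i]] <- "CAZYME"
  }
  calls <- call_puls(g, window = 5)
  s <- summarize_pul(calls[[1]])
  expect_equal(s$n_distinct_cazy_families, 7)
  expect_equal(s$substrate_counts[["oligosaccharide-degrading"]], 5)
  expect_equal(s$substrate_counts[["cellulase"]], 1)
  expect_equal(s$category_counts[["GH"]], 7)
  expect_false(s$no_cazyme)

  labs0 <- rep("", 24); labs0[11] <- "SUSC"; labs0[12] <- "SUSD"
  s0 <- summarize_pul(call_puls(make_gene_table(labs0), window = 5)[[1]])
  expect_true(s0$no_cazyme)
  expect_equal(sum(s0$category_counts[c("GH", "PL", "CE")]), 0)
  expect_equal(s0$n_distinct_cazy_families, 0)
})

test_that("PUL summaries on fixtures match the manifest cargo lists", {
  sim <- small_sim()
  arch <- build_architectures(sim$hits)
  g <- label_genes(sim$genes, arch)
  calls <- call_puls(g)
  m <- sim$manifest$planted_puls
  for (k in seq_len(nrow(m))) {
    p <- Filter(function(x) x$contig_id == m$contig_id[k] &&
                  m$susc_rank[k] >= x$region[1] &&
                  m$susc_rank[k] <= x$region[2], calls)
    expect_length(p, 1)
    caz <- p[[1]]$members[p[[1]]$members$label == "CAZYME", ]
    expect_setequal(caz$protein_id, strsplit(m$cargo_ids[k], ";")[[1]])
    s <- summarize_pul(p[[1]])
    expect_setequal(s$cazy_families,
                    unique(strsplit(m$cargo_models[k], ";")[[1]]))
  }
})

test_that("cellulosome capability requires cohesin plus multimodular dockerin enzymes", {
  # cohesin scaffoldin present but only plain dockerin catalytic enzymes
  at <- build_architectures(bind_hits(
    make_hit("scaf", "cohesin_I", ali_from = 1, ali_to = 100),
    make_hit("scaf", "cohesin_I", ali_from = 120, ali_to = 220),
    make_hit("enz", "GH5", ali_from = 1, ali_to = 150),
    make_hit("enz", "dockerin_I", ali_from = 200, ali_to = 260)))
  cls <- classify_proteins(at)
  cls$genome_id <- "gA"
  rep1 <- detect_cellulosomes(cls)
  expect_equal(rep1$n_scaffoldins, 1)
  expect_equal(rep1$n_dockerin_catalytic, 1)
  expect_equal(rep1$n_dockerin_multimodular, 0)
  expect_false(rep1$is_cellulosome_capable)

  # neither cohesin nor dockerin
  at2 <- build_architectures(make_hit("x", "GH5"))
  cls2 <- classify_proteins(at2)
  cls2$genome_id <- "gB"
  rep2 <- detect_cellulosomes(cls2)
  expect_equal(rep2$n_scaffoldins, 0)
  expect_false(rep2$is_cellulosome_capable)

  # full complement
  at3 <- build_architectures(bind_hits(
    make_hit("scaf", "cohesin_I", ali_from = 1, ali_to = 100),
    make_hit("enz", "GH5_4", ali_from = 1, ali_to = 120),
    make_hit("enz", "CBM22", ali_from = 140, ali_to = 220),
    make_hit("enz", "dockerin_I", ali_from = 240, ali_to = 300)))
  cls3 <- classify_proteins(at3)
  cls3$genome_id <- "gC"
  expect_true(detect_cellulosomes(cls3)$is_cellulosome_capable)
})
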