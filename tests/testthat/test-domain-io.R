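test_that("domtblout parsing handles comments, classes and malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c("# comment", "#"), tmp)
  expect_length(parse_domtblout(tmp)$protein_id, 0)

  h <- bind_hits(
    make_hit("p1", "dockerin", ali_from = 10, ali_to = 80),
    make_hit("p1", "GH5_4", ali_from = 100, ali_to = 300),
    make_hit("p2", "TIGR04056", ali_from = 1, ali_to = 350))
  write_domtblout(h, tmp)
  back <- parse_domtblout(tmp)
  expect_equal(back$model_class, c("DOCKERIN", "GH", "SUSC"))
  expect_equal(back[, names(h)], as.data.frame(h), ignore_attr = TRUE)

  writeLines(c("# ok", "too few fields here"), tmp)
  expect_error(parse_domtblout(tmp), "line 2")
})

test_that("fixture hit table round-trips with the manifest inventory", {
  sim <- small_sim()
  tmp <- withr::local_tempfile(fileext = ".domtbl")
  write_domtblout(sim$hits, tmp)
  back <- parse_domtblout(tmp)
  expect_equal(nrow(back), sim$manifest$n_hits_emitted)
  expect_equal(as.data.frame(back), as.data.frame(sim$hits),
               ignore_attr = TRUE)
})

test_that("hit filtering enforces both thresholds and matches the per-hit predicate", {
  keep <- make_hit(i_evalue = 1e-8, hmm_from = 1, hmm_to = 60,
                   model_length = 100)
  drop_e <- make_hit(i_evalue = 1e-4)
  drop_cov <- make_hit(i_evalue = 1e-8, hmm_from = 1, hmm_to = 20,
                       model_length = 100)
  at_cut <- make_hit(i_evalue = 1e-6, hmm_from = 1, hmm_to = 30,
                     model_length = 100)
  h <- bind_hits(keep, drop_e, drop_cov, at_cut)
  out <- filter_hits(h)
  expect_equal(nrow(out), 2)              # boundary values are retained
  expect_equal(out$i_evalue, c(1e-8, 1e-6))

  # randomized hits against the independently coded predicate, exactly
  set.seed(41)
  n <- 1000
  ml <- sample(50:300, n, TRUE)
  span <- pmax(1L, pmin(ml, round(runif(n) * ml)))
  hf <- vapply(ml - span + 1L, function(k) sample.int(k, 1L), integer(1))
  rh <- bind_hits(make_hit())[rep(1, n), ]
  rh$model_length <- ml
  rh$hmm_from <- hf
  rh$hmm_to <- hf + span - 1L
  rh$i_evalue <- 10^runif(n, -12, 0)
  expected <- vapply(seq_len(n), function(i) oracle_keep_hit(rh[i, ]),
                     logical(1))
  expect_identical(filter_hits(rh)$i_evalue, rh$i_evalue[expected])

  # idempotence and monotonicity
  once <- filter_hits(rh)
  expect_identical(filter_hits(once), once)
  loose <- filter_hits(rh, evalue_max = 1e-3, coverage_min = 0.1)
  expect_true(all(once$i_evalue %in% loose$i_evalue))
  expect_gte(nrow(loose), nrow(once))
})

test_that("overlap resolution keeps the more significant of clashing hits", {
  a <- make_hit("p", "GH5", ali_from = 1, ali_to = 100, i_evalue = 1e-9)
  b <- make_hit("p", "CBM6", ali_from = 200, ali_to = 300, i_evalue = 1e-7)
  expect_equal(nrow(resolve_overlaps(bind_hits(a, b))), 2)

  c1 <- make_hit("p", "GH5", ali_from = 1, ali_to = 100, i_evalue = 1e-9)
  c2 <- make_hit("p", "GH9", ali_from = 1, ali_to = 100, i_evalue = 1e-7)
  out <- resolve_overlaps(bind_hits(c1, c2))
  expect_equal(out$model_name, "GH5")

  # random per-protein hit sets against the independent greedy oracle
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(2:20, 1)
    af <- sample(1:350, k, TRUE)
    len <- sample(10:120, k, TRUE)
    hs <- bind_hits(make_hit())[rep(1, k), ]
    hs$model_name <- sample(default_family_pool(), k, TRUE)
    hs$ali_from <- af
    hs$ali_to <- pmin(400L, af + len)
    hs$i_evalue <- 10^runif(k, -15, -7)
    hs$score <- round(runif(k, 10, 300), 1)
    rownames(hs) <- NULL
    expect_equal(resolve_overlaps(hs), oracle_resolve(hs),
                 ignore_attr = TRUE)
  }
})

test_that("architectures are ordered N-to-C and invariant to input order", {
  h <- bind_hits(
    make_hit("p", "GH5_4", ali_from = 10, ali_to = 210),
    make_hit("p", "CBM22", ali_from = 230, ali_to = 380),
    make_hit("p", "CE3", ali_from = 400, ali_to = 520, protein_length = 700),
    make_hit("p", "dockerin", ali_from = 540, ali_to = 600,
             protein_length = 700))
  h$protein_length <- 700L
  a <- build_architecture(h)
  expect_equal(a$architecture_string, "GH5_4-CBM22-CE3-dockerin")
  for (rep in 1:5) {
    hp <- h[sample(nrow(h)), ]
    expect_equal(build_architecture(hp)$architecture_string,
                 a$architecture_string)
  }
  single <- build_architecture(make_hit("q", "CBM50"))
  expect_equal(single$architecture_string, "CBM50")
  empty <- build_architecture(make_hit()[0, ])
  expect_equal(empty$architecture_string, "")
  expect_equal(nrow(empty$domains), 0)
})
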