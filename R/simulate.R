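#' Configuration for the synthetic binned-genome generator
#'
#' Describes a simulated enrichment-culture community: a set of binned
#' genomes with protein-coding genes on a fixed coordinate grid, planted
#' polysaccharide utilization loci (PULs), cellulosome loci, multimodular
#' CAZymes, DUF-accessory proteins, decoy structures, sequence-novelty query
#' pairs and a secreted-protein spectral-count table. Defaults produce ten
#' genomes of 200 genes (about 2,000 genes, the scale of a small binned
#' metagenome where individual bins carry 1,200-4,000 genes) with 25 planted
#' PULs and 3 cellulosome loci.
#'
#' @param n_genomes number of binned genomes.
#' @param genes_per_genome protein-coding genes per genome.
#' @param contigs_per_genome contigs each genome is split across.
#' @param n_puls planted PULs (distributed round-robin over genomes).
#' @param n_cellulosome_loci planted cellulosome loci, one per genome in the
#'   first \code{n_cellulosome_loci} genomes.
#' @param n_multimodular free-standing multimodular CAZymes (no dockerin).
#' @param n_decoys isolated SusC genes without an adjacent SusD.
#' @param n_duf_accessory proteins pairing DUF domains with CBM/dockerin/SLH
#'   accessory modules and no catalytic domain.
#' @param decoy_cohesin_only,decoy_dockerin_only plant one genome carrying
#'   only cohesin (respectively only dockerin-multimodular) proteins, so
#'   cellulosome capability calls can be tested against sharp negatives.
#' @param family_pool model names used for background and cargo CAZymes.
#' @param bg_cazyme_rate fraction of unreserved genes receiving a
#'   single-domain CAZyme annotation.
#' @param identity_targets fractions in [0,1]; one novelty query/reference
#'   pair is planted per entry.
#' @param window gene-rank window the planted PUL geometry is built for; the
#'   boundary cargo sits at exactly this rank distance and the distant decoy
#'   CAZyme at one beyond it.
#' @param gene_length,intergenic_gap nucleotide grid for gene coordinates
#'   (coordinates exist for format fidelity; locus calling uses gene ranks).
#' @param unbinned_genes genes assigned to the pseudo-bin \code{"unbinned"}.
#' @param spectral_mean,spectral_size negative-binomial mean and dispersion
#'   for spectral counts of secreted proteins.
#' @param seed integer; fixes every output bit-for-bit.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genomes = 10L,
                       genes_per_genome = 200L,
                       contigs_per_genome = 2L,
                       n_puls = 25L,
                       n_cellulosome_loci = 3L,
                       n_multimodular = 30L,
                       n_decoys = 8L,
                       n_duf_accessory = 4L,
                       decoy_cohesin_only = TRUE,
                       decoy_dockerin_only = TRUE,
                       family_pool = default_family_pool(),
                       bg_cazyme_rate = 0.12,
                       identity_targets = rep(c(0.5, 0.7, 0.9),
                                              length.out = 50L),
                       window = 5L,
                       gene_length = 1200L,
                       intergenic_gap = 100L,
                       unbinned_genes = 120L,
                       spectral_mean = 8,
                       spectral_size = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genes_per_genome = as.integer(genes_per_genome),
    contigs_per_genome = as.integer(contigs_per_genome),
    n_puls = as.integer(n_puls),
    n_cellulosome_loci = as.integer(n_cellulosome_loci),
    n_multimodular = as.integer(n_multimodular),
    n_decoys = as.integer(n_decoys),
    n_duf_accessory = as.integer(n_duf_accessory),
    decoy_cohesin_only = isTRUE(decoy_cohesin_only),
    decoy_dockerin_only = isTRUE(decoy_dockerin_only),
    family_pool = as.character(family_pool),
    bg_cazyme_rate = as.numeric(bg_cazyme_rate),
    identity_targets = as.numeric(identity_targets),
    window = as.integer(window),
    gene_length = as.integer(gene_length),
    intergenic_gap = as.integer(intergenic_gap),
    unbinned_genes = as.integer(unbinned_genes),
    spectral_mean = as.numeric(spectral_mean),
    spectral_size = as.numeric(spectral_size),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genomes", "genes_per_genome", "contigs_per_genome", "n_puls",
              "n_cellulosome_loci", "n_multimodular", "n_decoys",
              "n_duf_accessory", "window", "unbinned_genes")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop(sprintf("sim_config: %s must be a non-negative count", nm))
  if (cfg$n_genomes > 0L && cfg$contigs_per_genome < 1L)
    stop("sim_config: contigs_per_genome must be >= 1")
  if (length(cfg$identity_targets) > 0L &&
      (any(cfg$identity_targets < 0) || any(cfg$identity_targets > 1)))
    stop("sim_config: identity_targets must lie in [0, 1]")
  if (cfg$bg_cazyme_rate < 0 || cfg$bg_cazyme_rate > 1)
    stop("sim_config: bg_cazyme_rate must lie in [0, 1]")
  n_special <- cfg$n_cellulosome_loci +
    (cfg$decoy_cohesin_only && cfg$n_cellulosome_loci > 0L) +
    (cfg$decoy_dockerin_only && cfg$n_cellulosome_loci > 0L)
  if (n_special > cfg$n_genomes)
    stop(sprintf(paste0(
      "sim_config sizing error: %d cellulosome loci plus cohesin-only/",
      "dockerin-only decoy genomes need %d genomes but n_genomes = %d"),
      cfg$n_cellulosome_loci, n_special, cfg$n_genomes))
  invisible(cfg)
}

#' Default CAZy family pool for the generator
#' @return character vector of model names (GH/GT/CE/PL/AA/CBM families,
#'   several at subfamily resolution).
#' @export
default_family_pool <- function() {
  c("GH5", "GH5_4", "GH9", "GH13_9", "GH13_20", "GH16", "GH43", "GH43_35",
    "GH3", "GH31", "GH2", "GH29", "GH42", "GH97", "GH78", "GH10", "GH11",
    "GH26", "GH48", "GT2", "GT4", "CE1", "CE3", "CE10", "PL1", "PL9",
    "AA3", "AA6", "CBM6", "CBM22", "CBM48", "CBM34", "CBM50", "CBM67")
}

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

resample1 <- function(x) x[sample.int(length(x), 1L)]

#' Mutate a protein sequence to a target global identity
#'
#' Introduces substitutions only (length preserved) so the realized identity
#' is exactly controllable: \code{round(n * (1 - target))} positions are
#' substituted, placed stratified along the sequence (one per equal-width
#' block) so identity is uniform locally as well as globally.
#'
#' @param reference protein sequence (character or AAString), non-empty.
#' @param target_identity fraction in [0, 1].
#' @param seed integer seed for the substitution draw.
#' @return character protein sequence of the same length.
#' @examples
#' mutate_to_identity("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 0.9, seed = 7)
#' @export
mutate_to_identity <- function(reference, target_identity, seed = 1L) {
  reference <- as.character(reference)
  if (length(reference) != 1L || is.na(reference) || !nzchar(reference))
    stop("input error: reference sequence must be a non-empty string")
  if (target_identity < 0 || target_identity > 1)
    stop("input error: target_identity must lie in [0, 1]")
  v <- strsplit(reference, "")[[1]]
  if (!all(v %in% AA_ALPHABET20))
    stop("input error: reference contains non-amino-acid characters")
  n <- length(v)
  k <- round(n * (1 - target_identity))
  if (k > 0L) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    blocks <- split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
    pos <- vapply(blocks, resample1, numeric(1))
    for (p in pos) v[p] <- resample1(setdiff(AA_ALPHABET20, v[p]))
  }
  paste(v, collapse = "")
}

random_protein <- function(n) paste(sample(AA_ALPHABET20, n, TRUE),
                                    collapse = "")

# ---- placement bookkeeping -------------------------------------------------

# used: named list of logical vectors (one per contig, 1-based index = rank+1)
free_runs <- function(used, size) {
  r <- rle(!used)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= size
  if (!any(ok)) return(integer(0))
  unlist(lapply(which(ok), function(i)
    seq.int(starts[i], ends[i] - size + 1L)))
}

claim_block <- function(state, genome, size) {
  contigs <- sample(state$contigs_of[[genome]])
  for (ct in contigs) {
    starts <- free_runs(state$used[[ct]], size)
    if (length(starts) > 0L) {
      s <- resample1(starts)
      state$used[[ct]][s:(s + size - 1L)] <- TRUE
      return(list(state = state, contig = ct, start = s))
    }
  }
  stop(sprintf(paste0(
    "sim_config sizing error: cannot place a %d-gene block in genome %s; ",
    "increase genes_per_genome or reduce the number of planted structures"),
    size, genome))
}

# ---- simulation ------------------------------------------------------------

#' Simulate binned genomes with planted loci and ground truth
#'
#' Generates the downstream products of a binned (meta)genome study: per-bin
#' gene tables on a fixed coordinate grid, a domtblout-style domain-hit table
#' (true domains plus hits failing the E-value/coverage filter and redundant
#' overlapping hits), protein sequences, a reference set with planted
#' identities, a spectral-count table for a planted secreted subset, and a
#' truth manifest describing everything planted.
#'
#' Planted structures follow the locus definitions used downstream: every PUL
#' holds a rank-adjacent SusC+SusD pair with cargo inside the configured
#' window (always one cargo gene at exactly the window boundary and one decoy
#' CAZyme one rank beyond it); every cellulosome locus holds a cohesin-bearing
#' scaffoldin and dockerin-bearing multimodular catalytic proteins. Decoys
#' comprise isolated SusC genes, CAZymes beyond window reach of any pair, and
#' (optionally) cohesin-only and dockerin-only genomes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{caz_sim}: \code{genes} (gene table),
#'   \code{hits} (\code{caz_hits}), \code{proteins}, \code{queries},
#'   \code{references} (AAStringSets), \code{spectra} (data.frame),
#'   \code{manifest} (list).
#' @examples
#' sim <- simulate_bins(sim_config(n_genomes = 3, genes_per_genome = 80,
#'                                 n_puls = 4, n_cellulosome_loci = 1,
#'                                 seed = 7))
#' nrow(sim$genes)
#' @export
simulate_bins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  w <- config$window
  m <- w + 2L                      # reserved margin each side of a PUL pair
  pul_block <- 2L * m + 2L

  genomes <- if (config$n_genomes > 0L)
    sprintf("bin%02d", seq_len(config$n_genomes)) else character(0)
  all_genomes <- c(genomes,
                   if (config$unbinned_genes > 0L) "unbinned" else character(0))

  # gene skeleton on a fixed grid
  gene_rows <- list()
  contigs_of <- list()
  used <- list()
  pitch <- config$gene_length + config$intergenic_gap
  for (g in all_genomes) {
    n_genes <- if (g == "unbinned") config$unbinned_genes else
      config$genes_per_genome
    n_ct <- if (g == "unbinned") 1L else config$contigs_per_genome
    per_ct <- diff(round(seq(0, n_genes, length.out = n_ct + 1L)))
    cts <- sprintf("%s_c%d", g, seq_len(n_ct))
    contigs_of[[g]] <- cts
    idx0 <- 0L
    for (ci in seq_len(n_ct)) {
      nk <- per_ct[ci]
      if (nk == 0L) next
      r <- seq_len(nk) - 1L
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        genome_id = g, contig_id = cts[ci],
        protein_id = sprintf("%s_%05d", g, idx0 + seq_len(nk)),
        start = r * pitch + 1L,
        end = r * pitch + config$gene_length,
        strand = sample(c("+", "-"), nk, TRUE),
        rank = r, stringsAsFactors = FALSE)
      used[[cts[ci]]] <- rep(FALSE, nk)
      idx0 <- idx0 + nk
    }
  }
  genes <- if (length(gene_rows) > 0L) do.call(rbind, gene_rows) else
    data.frame(genome_id = character(), contig_id = character(),
               protein_id = character(), start = integer(), end = integer(),
               strand = character(), rank = integer(),
               stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  pid_at <- function(contig, idx1) {   # 1-based index on contig -> protein_id
    genes$protein_id[genes$contig_id == contig & genes$rank == idx1 - 1L]
  }
  arch_of <- new.env(parent = emptyenv())
  plant <- function(contig, idx1, models) {
    assign(pid_at(contig, idx1), models, envir = arch_of)
  }
  state <- list(contigs_of = contigs_of, used = used)

  cargo_pool <- config$family_pool[
    model_class(config$family_pool) %in% c("GH", "CE", "PL")]
  peptidase_models <- c("Peptidase_M16", "Peptidase_S8", "Peptidase_M4")

  # genome roles
  cell_genomes <- head(genomes, config$n_cellulosome_loci)
  remaining <- setdiff(genomes, cell_genomes)
  cohesin_only_genome <- character(0)
  dockerin_only_genome <- character(0)
  if (config$decoy_cohesin_only && config$n_cellulosome_loci > 0L &&
      length(remaining) > 0L) {
    cohesin_only_genome <- remaining[1L]
    remaining <- remaining[-1L]
  }
  if (config$decoy_dockerin_only && config$n_cellulosome_loci > 0L &&
      length(remaining) > 0L) {
    dockerin_only_genome <- remaining[1L]
    remaining <- remaining[-1L]
  }

  multimodular_pool <- list(
    c("CBM48", "GH13_9"), c("CBM67", "GH78"), c("CBM34", "GH13_20"),
    c("CBM48", "CE1"), c("GH43_35", "CBM6"), c("GH10", "CBM22"),
    c("GH9", "CBM3", "SLH"))
  dockerin_enzyme_pool <- list(
    c("GH5_4", "CBM22", "CE3", "dockerin_I"),
    c("GH9", "CBM3", "dockerin_I"),
    c("GH48", "CBM4", "dockerin_I"),
    c("CE1", "CBM6", "dockerin_I"))
  duf_pool <- list(
    c("DUF4832", "dockerin_I"), c("DUF4874", "DUF4832", "dockerin_I"),
    c("SLH", "DUF3869"), c("CBM6", "DUF4978"))

  # --- plant cellulosome loci ---
  planted_cell <- list()
  for (j in seq_len(config$n_cellulosome_loci)) {
    g <- cell_genomes[j]
    n_enz <- resample1(2:3)
    size <- 2L + n_enz
    cl <- claim_block(state, g, size); state <- cl$state
    scaf_k <- resample1(2:6)
    scaf <- c(rep("cohesin_I", scaf_k), if (stats::runif(1) < 0.5) "SLH")
    plant(cl$contig, cl$start, scaf)
    enz_ids <- character(0)
    for (e in seq_len(n_enz)) {
      arch <- multimod <- dockerin_enzyme_pool[[resample1(
        seq_along(dockerin_enzyme_pool))]]
      plant(cl$contig, cl$start + e, arch)
      enz_ids <- c(enz_ids, pid_at(cl$contig, cl$start + e))
    }
    plain_id <- pid_at(cl$contig, cl$start + n_enz + 1L)
    plant(cl$contig, cl$start + n_enz + 1L, c("GH5", "dockerin_I"))
    planted_cell[[j]] <- data.frame(
      genome_id = g, contig_id = cl$contig,
      scaffoldin_ids = pid_at(cl$contig, cl$start),
      dockerin_multimodular_ids = paste(enz_ids, collapse = ";"),
      dockerin_plain_ids = plain_id, stringsAsFactors = FALSE)
  }
  if (length(cohesin_only_genome) == 1L) {
    cl <- claim_block(state, cohesin_only_genome, 1L); state <- cl$state
    plant(cl$contig, cl$start, rep("cohesin_III", resample1(2:4)))
  }
  if (length(dockerin_only_genome) == 1L) {
    cl <- claim_block(state, dockerin_only_genome, 2L); state <- cl$state
    plant(cl$contig, cl$start,
          dockerin_enzyme_pool[[resample1(seq_along(dockerin_enzyme_pool))]])
    plant(cl$contig, cl$start + 1L,
          dockerin_enzyme_pool[[resample1(seq_along(dockerin_enzyme_pool))]])
  }

  # --- plant PULs ---
  planted_puls <- list()
  for (k in seq_len(config$n_puls)) {
    g <- genomes[(k - 1L) %% max(1L, length(genomes)) + 1L]
    cl <- claim_block(state, g, pul_block); state <- cl$state
    pair_lo <- cl$start + m           # 1-based contig indices
    pair_hi <- pair_lo + 1L
    susc_first <- stats::runif(1) < 0.5
    susc_model <- resample1(c("SusC", "TIGR04056"))
    plant(cl$contig, if (susc_first) pair_lo else pair_hi, susc_model)
    plant(cl$contig, if (susc_first) pair_hi else pair_lo, "SusD")
    left_slots <- seq.int(pair_lo - w, pair_lo - 1L)
    right_slots <- seq.int(pair_hi + 1L, pair_hi + w)
    boundary <- resample1(c(pair_lo - w, pair_hi + w))
    n_cargo <- resample1(2:4)
    extra <- setdiff(c(left_slots, right_slots), boundary)
    slots <- c(boundary, sample(extra, n_cargo - 1L))
    cargo_models <- character(0); cargo_ids <- character(0)
    cargo_ranks <- integer(0)
    for (s in slots) {
      fam <- resample1(cargo_pool)
      plant(cl$contig, s, fam)
      cargo_models <- c(cargo_models, fam)
      cargo_ids <- c(cargo_ids, pid_at(cl$contig, s))
      cargo_ranks <- c(cargo_ranks, s - 1L)
    }
    # occasional peptidase / regulator cargo in remaining window slots
    rest <- setdiff(c(left_slots, right_slots), slots)
    if (length(rest) > 0L && stats::runif(1) < 0.5) {
      s <- resample1(rest); rest <- setdiff(rest, s)
      plant(cl$contig, s, resample1(peptidase_models))
    }
    if (length(rest) > 0L && stats::runif(1) < 0.5) {
      s <- resample1(rest)
      plant(cl$contig, s, resample1(regulator_models))
    }
    # distant decoy CAZyme at rank distance window + 1
    decoy_slot <- resample1(c(pair_lo - w - 1L, pair_hi + w + 1L))
    decoy_fam <- resample1(cargo_pool)
    plant(cl$contig, decoy_slot, decoy_fam)
    planted_puls[[k]] <- data.frame(
      pul = k, genome_id = g, contig_id = cl$contig,
      susc_rank = (if (susc_first) pair_lo else pair_hi) - 1L,
      susd_rank = (if (susc_first) pair_hi else pair_lo) - 1L,
      cargo_ids = paste(cargo_ids[order(cargo_ranks)], collapse = ";"),
      cargo_ranks = paste(sort(cargo_ranks), collapse = ";"),
      cargo_models = paste(cargo_models[order(cargo_ranks)], collapse = ";"),
      decoy_id = pid_at(cl$contig, decoy_slot),
      decoy_rank = decoy_slot - 1L, stringsAsFactors = FALSE)
  }

  # --- lone SusC decoys ---
  lone_susc_ids <- character(0)
  for (d in seq_len(config$n_decoys)) {
    g <- resample1(if (length(genomes) > 0L) genomes else all_genomes)
    cl <- claim_block(state, g, 3L); state <- cl$state
    plant(cl$contig, cl$start + 1L, resample1(c("SusC", "TIGR04056")))
    lone_susc_ids <- c(lone_susc_ids, pid_at(cl$contig, cl$start + 1L))
  }

  # --- free-standing multimodular CAZymes (no dockerin) ---
  for (i in seq_len(config$n_multimodular)) {
    g <- resample1(if (length(genomes) > 0L) genomes else all_genomes)
    cl <- claim_block(state, g, 1L); state <- cl$state
    plant(cl$contig, cl$start,
          multimodular_pool[[resample1(seq_along(multimodular_pool))]])
  }

  # --- DUF-accessory proteins (no catalytic domain) ---
  duf_ids <- character(0)
  for (i in seq_len(config$n_duf_accessory)) {
    g <- resample1(if (length(genomes) > 0L) genomes else all_genomes)
    if (length(cohesin_only_genome) == 1L && identical(g, cohesin_only_genome))
      g <- genomes[length(genomes)]
    cl <- claim_block(state, g, 1L); state <- cl$state
    plant(cl$contig, cl$start, duf_pool[[resample1(seq_along(duf_pool))]])
  }

  # --- background single-domain CAZymes in unreserved slots ---
  bg_pool <- config$family_pool
  if (length(cohesin_only_genome) == 1L || length(dockerin_only_genome) == 1L)
    bg_pool <- bg_pool  # pool carries no cohesin/dockerin models by design
  for (ct in names(state$used)) {
    free <- which(!state$used[[ct]])
    if (length(free) == 0L) next
    n_bg <- round(length(free) * config$bg_cazyme_rate)
    if (n_bg == 0L) next
    for (s in sample(free, n_bg)) plant(ct, s, resample1(bg_pool))
  }

  planted_ids <- ls(arch_of)
  planted_arch <- data.frame(
    protein_id = planted_ids,
    architecture_string = vapply(planted_ids, function(p)
      paste(get(p, envir = arch_of), collapse = "-"), character(1)),
    stringsAsFactors = FALSE)
  planted_arch <- planted_arch[order(planted_arch$protein_id), , drop = FALSE]
  rownames(planted_arch) <- NULL

  # --- domain hit table ---
  aa_len <- config$gene_length %/% 3L
  model_names_all <- unique(c(
    config$family_pool, "SusC", "TIGR04056", "SusD", "cohesin_I",
    "cohesin_III", "dockerin_I", "SLH", "CBM3", "CBM4", "GH48",
    "DUF4832", "DUF4874", "DUF3869", "DUF4978",
    peptidase_models, regulator_models))
  model_len <- stats::setNames(sample(80:600, length(model_names_all), TRUE),
                               model_names_all)
  hit_rows <- list()
  add_hit <- function(pid, model, ali_from, ali_to, i_evalue, score,
                      cov = NULL) {
    L <- unname(model_len[model])
    if (is.na(L)) L <- 200L
    if (is.null(cov)) cov <- stats::runif(1, 0.6, 0.95)
    span <- max(1L, min(L, as.integer(ceiling(cov * L))))
    hf <- if (span < L) sample.int(L - span + 1L, 1L) else 1L
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      protein_id = pid, protein_length = aa_len, model_name = model,
      model_class = model_class(model), model_length = L,
      hmm_from = hf, hmm_to = hf + span - 1L,
      ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
      i_evalue = i_evalue, score = score, stringsAsFactors = FALSE)
  }
  for (p in planted_ids) {
    models <- get(p, envir = arch_of)
    kdom <- length(models)
    bounds <- floor(seq(1, aa_len, length.out = kdom + 1L))
    for (i in seq_len(kdom)) {
      a_from <- bounds[i] + if (i > 1L) 4L else 0L
      a_to <- bounds[i + 1L] - if (i < kdom) 4L else 0L
      ev <- 10^stats::runif(1, -30, -8)
      add_hit(p, models[i], a_from, a_to, ev, stats::runif(1, 80, 400))
      # redundant overlapping hit of a different model, worse E-value;
      # removed by the filter or by overlap resolution, never both survive
      if (stats::runif(1) < 0.15) {
        alt <- resample1(setdiff(config$family_pool, models[i]))
        add_hit(p, alt, a_from, a_to, ev * 1e3,
                stats::runif(1, 40, 200))
      }
    }
    # noise hit failing the filter
    if (stats::runif(1) < 0.2) {
      alt <- resample1(config$family_pool)
      if (stats::runif(1) < 0.5)
        add_hit(p, alt, 1L, aa_len, 10^stats::runif(1, -5, -1),
                stats::runif(1, 5, 30))
      else
        add_hit(p, alt, 1L, aa_len, 10^stats::runif(1, -30, -8),
                stats::runif(1, 5, 30), cov = stats::runif(1, 0.05, 0.25))
    }
  }
  # noise hits on otherwise unannotated proteins
  other_ids <- setdiff(genes$protein_id, planted_ids)
  if (length(other_ids) > 0L) {
    for (p in sample(other_ids, min(length(other_ids),
                                    round(0.05 * length(other_ids))))) {
      alt <- resample1(config$family_pool)
      add_hit(p, alt, 1L, aa_len, 10^stats::runif(1, -5, -1),
              stats::runif(1, 5, 30))
    }
  }
  hits <- if (length(hit_rows) > 0L) do.call(rbind, hit_rows) else
    empty_hits()
  if (nrow(hits) > 0L) {
    hits <- hits[order(hits$protein_id, hits$ali_from, hits$model_name), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    # serialisation-stable E-values (printed and reparsed identically)
    hits$i_evalue <- as.numeric(format_evalue(hits$i_evalue))
    hits$score <- round(hits$score, 1)
    class(hits) <- c("caz_hits", "data.frame")
  }
  cov_emitted <- if (nrow(hits) > 0L)
    (hits$hmm_to - hits$hmm_from + 1L) / hits$model_length else numeric(0)
  n_hits_filtered <- sum(hits$i_evalue <= 1e-6 & cov_emitted >= 0.30)

  # --- spectral-count table for a planted secreted subset ---
  cell_protein_ids <- unlist(lapply(planted_cell, function(x)
    c(x$scaffoldin_ids, strsplit(x$dockerin_multimodular_ids, ";")[[1]],
      x$dockerin_plain_ids)))
  sus_ids <- unlist(lapply(planted_puls, function(x) {
    gg <- genes[genes$contig_id == x$contig_id, ]
    gg$protein_id[gg$rank %in% c(x$susc_rank, x$susd_rank)]
  }))
  cargo_ids_all <- unlist(lapply(planted_puls, function(x)
    strsplit(x$cargo_ids, ";")[[1]]))
  secreted_ids <- unique(c(
    cell_protein_ids,
    if (length(sus_ids) > 0L) sample(sus_ids, ceiling(length(sus_ids) / 2)),
    if (length(cargo_ids_all) > 0L)
      sample(cargo_ids_all, ceiling(length(cargo_ids_all) / 3)),
    if (length(other_ids) > 0L) sample(other_ids, min(5L, length(other_ids)))))
  secreted_ids <- sort(as.character(secreted_ids %||% character(0)))
  spectra <- data.frame(
    protein_id = secreted_ids,
    genome_id = genes$genome_id[match(secreted_ids, genes$protein_id)],
    spectral_count = 1L + stats::rnbinom(length(secreted_ids),
                                         mu = config$spectral_mean,
                                         size = config$spectral_size),
    signal_peptide = stats::runif(length(secreted_ids)) < 0.7,
    stringsAsFactors = FALSE)

  # --- protein sequences and novelty pairs (mutation draws come last so the
  #     per-pair seeds never disturb the main stream) ---
  seqs <- vapply(genes$protein_id, function(p) random_protein(aa_len),
                 character(1))
  names(seqs) <- genes$protein_id
  bg_cazyme_ids <- setdiff(
    planted_arch$protein_id[planted_arch$architecture_string %in%
                              config$family_pool],
    c(cargo_ids_all, unlist(lapply(planted_puls, `[[`, "decoy_id"))))
  n_q <- length(config$identity_targets)
  if (n_q > length(bg_cazyme_ids))
    stop(sprintf(paste0(
      "sim_config sizing error: %d identity targets but only %d background ",
      "CAZyme proteins available as queries"), n_q, length(bg_cazyme_ids)))
  query_ids <- if (n_q > 0L) sort(sample(bg_cazyme_ids, n_q)) else character(0)
  targets <- if (n_q > 0L) sample(config$identity_targets) else numeric(0)
  ref_seqs <- character(0)
  planted_identities <- data.frame(query_id = character(),
                                   ref_id = character(),
                                   target_identity = numeric(),
                                   stringsAsFactors = FALSE)
  if (n_q > 0L) {
    ref_ids <- paste0("CAZyREF_", query_ids)
    ref_seqs <- vapply(seq_len(n_q), function(i)
      mutate_to_identity(seqs[[query_ids[i]]], targets[i],
                         seed = (config$seed + 7919L * i) %%
                           .Machine$integer.max),
      character(1))
    names(ref_seqs) <- ref_ids
    planted_identities <- data.frame(
      query_id = query_ids, ref_id = ref_ids,
      target_identity = 100 * targets, stringsAsFactors = FALSE)
  }

  manifest <- list(
    config = unclass(config),
    n_hits_emitted = nrow(hits),
    n_hits_filtered = n_hits_filtered,
    planted_puls = if (length(planted_puls) > 0L)
      do.call(rbind, planted_puls) else NULL,
    planted_cellulosome = if (length(planted_cell) > 0L)
      do.call(rbind, planted_cell) else NULL,
    capable_genomes = cell_genomes,
    decoy_genomes = list(cohesin_only = cohesin_only_genome,
                         dockerin_only = dockerin_only_genome),
    lone_susc_ids = lone_susc_ids,
    planted_architectures = planted_arch,
    planted_identities = planted_identities,
    secreted_ids = secreted_ids)

  structure(list(
    genes = genes,
    hits = hits,
    proteins = Biostrings::AAStringSet(seqs),
    queries = Biostrings::AAStringSet(seqs[query_ids]),
    references = Biostrings::AAStringSet(ref_seqs),
    spectra = spectra,
    manifest = manifest), class = "caz_sim")
}

`%||%` <- function(a, b) if (length(a) == 0L || is.null(a)) b else a

#' @export
print.caz_sim <- function(x, ...) {
  cat(sprintf(
    "<caz_sim> %d genomes, %d genes, %d domain hits, %d planted PULs, %d cellulosome loci\n",
    length(unique(x$genes$genome_id)), nrow(x$genes), nrow(x$hits),
    if (is.null(x$manifest$planted_puls)) 0L else
      nrow(x$manifest$planted_puls),
    if (is.null(x$manifest$planted_cellulosome)) 0L else
      nrow(x$manifest$planted_cellulosome)))
  invisible(x)
}
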