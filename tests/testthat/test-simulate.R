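test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_species = 6, individuals_per_species = 3,
                    seq_length = 200, seed = 99)
  d1 <- simulate_barcode_dataset(cfg)
  d2 <- simulate_barcode_dataset(cfg)
  expect_equal(d1$alignment, d2$alignment)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(d1$alignment, f1)
  write_alignment(d2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
  d3 <- simulate_barcode_dataset(sim_config(n_species = 6,
                                            individuals_per_species = 3,
                                            seq_length = 200, seed = 100))
  expect_false(identical(d1$alignment$seqs, d3$alignment$seqs))
})

test_that("species tree has the configured tips and height", {
  cfg <- sim_config(n_species = 12, inter_scale = 0.2, seed = 5)
  tr <- simulate_species_tree(cfg)
  expect_equal(ape::Ntip(tr), 12L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(12)]
  # ultrametric, root-to-tip height = inter_scale (shallow splits may be
  # floored, which can only deepen internal nodes, never the tips)
  expect_equal(unname(depths), rep(0.2, 12), tolerance = 1e-6)
  # minimum split depth respected: closest species pair is at least
  # 2 * min_split apart
  d <- ape::cophenetic.phylo(tr)
  expect_gte(min(d[upper.tri(d)]), 2 * cfg$min_split - 1e-9)
  # two species: a single split
  tr2 <- simulate_species_tree(sim_config(n_species = 2, seed = 1))
  expect_equal(ape::Ntip(tr2), 2L)
  expect_error(sim_config(n_species = 1))
})

test_that("individual expansion controls leaf counts and pendant lengths", {
  cfg <- sim_config(n_species = 5, individuals_per_species = 4,
                    intra_scale = 0.01, seed = 8)
  itree <- simulate_individuals(simulate_species_tree(cfg), cfg)
  expect_equal(ape::Ntip(itree), 20L)
  sp <- attr(itree, "species")
  expect_equal(sort(unname(table(sp))), rep(4L, 5), ignore_attr = TRUE)

  # ranged individuals per species
  cfg2 <- sim_config(n_species = 10, individuals_per_species = c(1L, 20L),
                     seed = 9)
  itree2 <- simulate_individuals(simulate_species_tree(cfg2), cfg2)
  k <- table(attr(itree2, "species"))
  expect_true(all(k >= 1 & k <= 20))
})

test_that("zero branch lengths and zero intra divergence give identical sequences", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  cfg <- sim_config(n_species = 2, seq_length = 150, seed = 3)
  aln <- evolve_sequences(tr, cfg)
  expect_equal(unname(aln$seqs[["a"]]), unname(aln$seqs[["b"]]))

  cfg0 <- sim_config(n_species = 4, individuals_per_species = 3,
                     intra_scale = 0, seq_length = 200, seed = 4)
  ds <- simulate_barcode_dataset(cfg0)
  for (s in unique(ds$alignment$species)) {
    seqs <- ds$alignment$seqs[ds$alignment$species == s]
    expect_equal(length(unique(seqs)), 1L)
  }
})

test_that("estimated K2P distance is consistent with the simulated path length", {
  # two tips separated by 0.2 substitutions/site, long sequence
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  cfg <- sim_config(n_species = 2, seq_length = 10000L, kappa = 2,
                    seed = 12)
  aln <- evolve_sequences(tr, cfg)
  d <- pairwise_k2p(aln$seqs[["a"]], aln$seqs[["b"]])$distance
  expect_equal(d, 0.2, tolerance = 0.1)
})

test_that("kappa sets the transition/transversion proportion ratio", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg <- sim_config(n_species = 2, seq_length = 60000L, kappa = 0.5,
                    seed = 13)
  aln <- evolve_sequences(tr, cfg)
  a <- strsplit(aln$seqs[["a"]], "")[[1]]
  b <- strsplit(aln$seqs[["b"]], "")[[1]]
  diff <- a != b
  pur <- c("A", "G")
  ts <- sum(diff & ((a %in% pur) == (b %in% pur)))
  tv <- sum(diff) - ts
  expect_equal(ts / tv, 0.5, tolerance = 0.15)
})

test_that("confusable pairs collapse interspecific divergence to the intra level", {
  cfg <- sim_config(n_species = 6, individuals_per_species = 3,
                    n_confusable_pairs = 1, seq_length = 500, seed = 14)
  ds <- simulate_barcode_dataset(cfg)
  pair <- ds$confusable[[1]]
  dm <- distance_matrix(ds$alignment)
  in_a <- dm$species == pair[1]
  in_b <- dm$species == pair[2]
  cross <- dm$d[in_a, in_b]
  intra <- dm$d[in_a, in_a][upper.tri(matrix(0, sum(in_a), sum(in_a)))]
  # cross-pair distances are of the same magnitude as intraspecific ones,
  # far below the species-tree floor
  expect_lt(min(cross), 2 * cfg$min_split)
  expect_lt(max(cross), 4 * cfg$intra_scale + 0.01)
  # while other species remain well separated
  other <- !(in_a | in_b)
  expect_gte(min(dm$d[in_a, other]), 2 * cfg$min_split - 0.01)
})

test_that("the benchmark suite carries constructible truth", {
  suite <- make_benchmark_suite(sim_config(n_species = 8,
                                           individuals_per_species = 3,
                                           seq_length = 400, seed = 15,
                                           missing_fraction = 0.25))
  # clean: every species has a gap, BM is always correct, all monophyletic
  dm <- distance_matrix(suite$clean$alignment)
  expect_equal(gap_percentage(species_gap_records(dm)), 100)
  expect_equal(best_match(dm)$pct_correct, 100)
  mono <- species_monophyly(nj_build(distance_matrix(suite$clean$alignment,
                                                     model = "p")))
  expect_equal(mono$pct_discriminated, 100)

  # confusable: the merged species exist and are flagged in the truth
  truth_sp <- suite$confusable$truth$confusable_species
  expect_equal(length(truth_sp), 2L * 3L)
  expect_true(all(truth_sp %in% suite$confusable$alignment$species))

  # multilocus: two loci over the same individuals, with dropout
  alns <- suite$multilocus$alignments
  expect_equal(length(alns), 2L)
  n0 <- suite$multilocus$truth$n_individuals
  expect_true(all(vapply(alns, length, integer(1)) <= n0))
  cc <- concatenate(alns)
  expect_lte(length(cc), min(vapply(alns, length, integer(1))))
  # sample count after the intersection join is near its expectation
  p_keep <- (1 - suite$multilocus$truth$missing_fraction)^2
  expect_lt(abs(length(cc) - n0 * p_keep),
            4 * sqrt(n0 * p_keep * (1 - p_keep)) + 1)
})
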