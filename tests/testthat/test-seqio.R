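test_that("FASTA parsing applies the header dialect and normalises residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_fixture(list(
    "X1|Dendrobium_nobile" = "acgu-n",
    "X2|Dendrobium_nobile" = "ACGTAN",
    "X3|Coelogyne_ovalis"  = "ACG--T"), f)
  aln <- read_alignment(f, "ITS")
  expect_s3_class(aln, "locus_alignment")
  expect_equal(length(aln), 3L)
  expect_equal(aln$width, 6L)
  expect_equal(aln$sample_id, c("X1", "X2", "X3"))
  expect_equal(aln$species[1], "Dendrobium_nobile")
  expect_equal(unname(aln$seqs[["X1"]]), "ACGT-N")  # uppercased, U -> T

  # reversed field order
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_fixture(list("Genus_sp|S1" = "ACGT"), f2)
  aln2 <- read_alignment(f2, "matK", fields = c("species", "sample"))
  expect_equal(aln2$sample_id, "S1")
  expect_equal(aln2$species, "Genus_sp")
})

test_that("invalid alignments are rejected with informative errors", {
  expect_error(locus_alignment("ITS", c("a", "b"), c("X_y", "X_y"),
                               c("ACGTACGTAC", "ACGTACGTA")),
               "ragged")
  expect_error(locus_alignment("ITS", c("a", "a"), c("X_y", "X_y"),
                               c("ACGT", "ACGT")),
               "duplicate")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_fixture(list("no_separator_here" = "ACGT"), f)
  expect_error(read_alignment(f, "ITS"), "header")
})

test_that("write/read round trip is the identity on random alignments", {
  set.seed(11)
  for (rep in 1:5) {
    aln <- random_alignment(n_species = sample(2:5, 1), k = sample(1:4, 1),
                            width = sample(20:80, 1))
    f <- withr::local_tempfile(fileext = ".fasta")
    write_alignment(aln, f)
    back <- read_alignment(f, aln$locus)
    expect_equal(back, aln)
  }
  expect_error(write_alignment(
    structure(list(sample_id = character(0)), class = "locus_alignment"),
    tempfile()), "empty")
})

test_that("length filter removes short sequences except for exempt loci", {
  mk <- function(locus) locus_alignment(
    locus, c("a", "b", "c"), rep("Genus_sp", 3),
    c(strrep("A", 400),
      paste0(strrep("A", 250), strrep("-", 150)),   # 250 ungapped
      paste0(strrep("A", 320), strrep("N", 80))))   # 320 ungapped
  res <- apply_sampling_filters(mk("matK"), min_len = 300)
  expect_equal(sort(res$alignment$sample_id), c("a", "c"))
  expect_equal(res$log$sample_id, "b")
  expect_equal(res$log$reason, "min_len")

  res2 <- apply_sampling_filters(mk("ITS2"), min_len = 300)
  expect_equal(length(res2$alignment), 3L)  # exempt locus untouched
  expect_equal(nrow(res2$log), 0L)
})

test_that("per-species cap keeps the longest ungapped sequences", {
  n <- 25
  seqs <- vapply(seq_len(n), function(i)
    paste0(strrep("A", 300 + i), strrep("-", 100 - i)), character(1))
  aln <- locus_alignment("ITS", sprintf("s%02d", 1:n),
                         rep("Genus_sp", n), seqs)
  res <- apply_sampling_filters(aln, min_len = 300, max_per_species = 20)
  expect_equal(length(res$alignment), 20L)
  expect_equal(nrow(res$log), 5L)
  expect_setequal(res$log$sample_id, sprintf("s%02d", 1:5))  # the shortest
  expect_true(all(res$log$reason == "max_per_species"))
})

test_that("sampling filters are idempotent and log counts balance", {
  set.seed(21)
  aln <- random_alignment(n_species = 3, k = 8, width = 500, gap_frac = 0.4)
  res <- apply_sampling_filters(aln, min_len = 250, max_per_species = 5)
  expect_equal(nrow(res$log), length(aln) - length(res$alignment))
  res2 <- apply_sampling_filters(res$alignment, min_len = 250,
                                 max_per_species = 5)
  expect_equal(res2$alignment, res$alignment)
  expect_equal(nrow(res2$log), 0L)
})

test_that("singleton species are dropped for similarity matching", {
  aln <- locus_alignment("ITS", c("a1", "a2", "a3", "b1", "c1", "c2"),
                         c("A_a", "A_a", "A_a", "B_b", "C_c", "C_c"),
                         rep("ACGT", 6))
  res <- drop_singleton_species(aln)
  expect_equal(res$removed_species, "B_b")
  expect_true(all(table(res$alignment$species) >= 2))

  res2 <- drop_singleton_species(res$alignment)
  expect_equal(res2$alignment, res$alignment)  # no-op when none left

  only_singles <- locus_alignment("ITS", c("a", "b"), c("A_a", "B_b"),
                                  c("ACGT", "ACGT"))
  res3 <- drop_singleton_species(only_singles)
  expect_equal(length(res3$alignment$sample_id), 0L)
  expect_setequal(res3$removed_species, c("A_a", "B_b"))
})

test_that("concatenation joins on shared samples and records partitions", {
  its <- locus_alignment("ITS", c("s1", "s2", "s3"),
                         c("A_a", "A_a", "B_b"),
                         c("ACGTAC", "ACGTAA", "TTGTAC"))
  matk <- locus_alignment("matK", c("s2", "s3", "s4"),
                          c("A_a", "B_b", "C_c"),
                          c("GGGG", "GGGA", "CCCC"))
  cc <- concatenate(list(its, matk))
  expect_s3_class(cc, "concat_alignment")
  expect_setequal(cc$sample_id, c("s2", "s3"))
  expect_equal(cc$width, its$width + matk$width)
  expect_equal(unname(cc$seqs[["s2"]]), "ACGTAAGGGG")
  expect_equal(cc$partitions$start, c(0L, 6L))
  expect_equal(cc$partitions$end, c(6L, 10L))
  expect_equal(cc$locus, "ITS+matK")

  # partition sidecar file
  f <- withr::local_tempfile(fileext = ".fasta")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(cc, f, partitions_path = p)
  part <- read.delim(p)
  expect_equal(part$locus, c("ITS", "matK"))

  # species conflict and empty intersection
  bad <- locus_alignment("rbcL", "s2", "Z_z", "AAAA")
  expect_error(concatenate(list(its, bad)), "labelled")
  disjoint <- locus_alignment("rbcL", "s9", "A_a", "AAAA")
  expect_error(concatenate(list(its, disjoint)), "no sample")
})

test_that("single shared sample still concatenates", {
  a <- locus_alignment("ITS", c("s1", "s2"), c("A_a", "B_b"),
                       c("ACGT", "ACGA"))
  b <- locus_alignment("matK", c("s2", "s5"), c("B_b", "C_c"),
                       c("GG", "GT"))
  cc <- concatenate(list(a, b))
  expect_equal(cc$sample_id, "s2")
  expect_equal(unname(cc$seqs[[1]]), "ACGAGG")
})
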