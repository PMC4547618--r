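# Sequences engineered for exact identities: length-100 strings with known
# numbers of substitutions give identity k/100 under the default scoring
# (substitution alignments dominate gapped ones here).
engineered_sequences <- function() {
  base <- ampliko:::with_seed(303, random_dna(100))
  flip <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (i in at) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  list(base = base, flip = flip)
}

test_that("association columns follow the nearest-neighbour threshold rule", {
  eng <- engineered_sequences()
  genomes <- c(X = eng$base,
               Y = eng$flip(eng$base, 1),       # 0.99 to base
               Z = eng$flip(eng$base, c(1, 2))) # 0.98 to base
  # ref identical to X only
  assoc <- build_association_matrix(c(r = eng$base), genomes,
                                    min_identity = 0.97)
  col <- assoc$weights[, "r"]
  expect_equal(col[["X"]], 1)
  expect_equal(sum(col), 1)

  # reference below threshold to every genome -> all-zero column
  far <- ampliko:::with_seed(404, random_dna(100))
  assoc2 <- build_association_matrix(c(far = far), genomes,
                                     min_identity = 0.97)
  expect_equal(sum(assoc2$weights[, "far"]), 0)

  # exact tie at 0.99 between X and Y; Z above threshold at 0.98 but not
  # maximal -> uniform split over the tie, zero for Z
  # substitutions at isolated positions: a lone substitution can never be
  # outscored by a gapped alignment under the (+1, -1, -1) scoring
  ref_tie <- eng$base
  genomes_tie <- c(X = eng$flip(eng$base, 10),
                   Y = eng$flip(eng$base, 40),
                   Z = eng$flip(eng$base, c(60, 80)))
  scores <- identity_scores(c(r = ref_tie), genomes_tie)
  expect_equal(scores$identity[scores$organism_id == "X"], 0.99)
  expect_equal(scores$identity[scores$organism_id == "Y"], 0.99)
  expect_equal(scores$identity[scores$organism_id == "Z"], 0.98)
  assoc3 <- build_association_matrix(c(r = ref_tie), genomes_tie,
                                     min_identity = 0.97)
  expect_equal(assoc3$weights[, "r"][["X"]], 0.5)
  expect_equal(assoc3$weights[, "r"][["Y"]], 0.5)
  expect_equal(assoc3$weights[, "r"][["Z"]], 0)
})

test_that("multi-copy genomes score as the max over their 16S copies", {
  eng <- engineered_sequences()
  genome_seqs <- c(g1_a = eng$flip(eng$base, seq(5, 95, by = 10)),  # divergent copy
                   g1_b = eng$base,                                 # perfect copy
                   g2_a = eng$flip(eng$base, c(10, 30, 50, 70, 90)))
  organisms <- c("g1", "g1", "g2")
  scores <- identity_scores(c(r = eng$base), genome_seqs,
                            organisms = organisms)
  expect_equal(scores$identity[scores$organism_id == "g1"], 1)
  expect_equal(scores$identity[scores$organism_id == "g2"], 0.95)
})

test_that("columns are stochastic and mapping shrinks with the threshold", {
  fix <- generate_reference_fixture(fixture_spec(
    n_organisms = 6, n_extra_refs = 3, seq_length = 200,
    mutation_rate = 0.02, seed = 9))
  mapped_sets <- list()
  for (thr in c(0.90, 0.95, 0.97, 0.99)) {
    assoc <- build_association_matrix(fix$marker_sequences,
                                      fix$genome_sequences,
                                      min_identity = thr)
    cs <- Matrix::colSums(assoc$weights)
    expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
    mapped_sets[[as.character(thr)]] <- names(cs)[cs > 0]
  }
  # raising the threshold never maps a previously unmapped reference
  expect_true(all(mapped_sets[["0.95"]] %in% mapped_sets[["0.9"]]))
  expect_true(all(mapped_sets[["0.97"]] %in% mapped_sets[["0.95"]]))
  expect_true(all(mapped_sets[["0.99"]] %in% mapped_sets[["0.97"]]))
})

test_that("builder validates thresholds and inputs", {
  seqs <- c(a = "ACGTACGT")
  expect_error(build_association_matrix(seqs, seqs, min_identity = 0),
               class = "ampliko_bad_threshold")
  expect_error(build_association_matrix(seqs, seqs, min_identity = 1.5),
               class = "ampliko_bad_threshold")
  expect_error(build_association_matrix(character(0), seqs),
               class = "ampliko_bad_input")
  expect_error(build_association_matrix(seqs, character(0)),
               class = "ampliko_bad_input")
})

test_that("organism input order does not affect the built matrix", {
  inp <- toy_inputs()
  a1 <- build_association_matrix(inp$marker_sequences, inp$genome_sequences)
  a2 <- build_association_matrix(inp$marker_sequences,
                                 rev(inp$genome_sequences))
  expect_identical(as.matrix(a1$weights), as.matrix(a2$weights))
})

test_that("reference profiles are row-normalized over the KO union", {
  prof <- build_reference_profiles(tibble::tibble(
    organism_id = c("o1", "o1"), ko_id = c("K00001", "K00002"),
    count = c(3, 1)))
  expect_equal(unname(prof["o1", ]), c(0.75, 0.25))

  disjoint <- build_reference_profiles(tibble::tibble(
    organism_id = c("o1", "o2"), ko_id = c("K00001", "K00002"),
    count = c(2, 5)))
  expect_equal(unname(as.vector(disjoint)), c(1, 0, 0, 1))
  expect_equal(unname(rowSums(disjoint)), c(1, 1))

  expect_error(build_reference_profiles(tibble::tibble(
    organism_id = "o1", ko_id = "K00001", count = 0)),
    class = "ampliko_zero_profile")
  expect_error(build_reference_profiles(tibble::tibble(
    organism_id = character(0), ko_id = character(0), count = numeric(0))),
    class = "ampliko_bad_input")
})

test_that("copy-number tables require positive integers", {
  expect_error(copy_number_table(data.frame(organism_id = "a",
                                            copy_number = 0)),
               class = "ampliko_bad_input")
  expect_error(copy_number_table(data.frame(organism_id = "a",
                                            copy_number = 1.5)),
               class = "ampliko_bad_input")
  ok <- copy_number_table(data.frame(organism_id = c("b", "a"),
                                     copy_number = c(2, 1)))
  expect_identical(ok$organism_id, c("a", "b"))
})

test_that("assemble_database enforces organism agreement and round-trips", {
  inp <- toy_inputs()
  db <- assemble_database(inp$marker_sequences, inp$genome_sequences,
                          inp$ko_counts, inp$copy_numbers)
  expect_s3_class(db, "reference_db")
  cs <- Matrix::colSums(db$association$weights)
  expect_true(all(abs(cs - 1) < 1e-12))

  expect_error(assemble_database(
    inp$marker_sequences, inp$genome_sequences, inp$ko_counts,
    inp$copy_numbers[-1, ]), class = "ampliko_organism_mismatch",
    regexp = "org01")

  # determinism: identical inputs serialize byte-identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference_db(db, d1)
  write_reference_db(assemble_database(
    inp$marker_sequences, inp$genome_sequences, inp$ko_counts,
    inp$copy_numbers), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  # read-back reproduces the database exactly
  db2 <- read_reference_db(d1)
  expect_identical(as.matrix(db2$association$weights),
                   as.matrix(db$association$weights))
  expect_equal(unclass(db2$reference_profiles),
               unclass(db$reference_profiles))
  expect_identical(db2$copy_numbers, db$copy_numbers)
  expect_identical(db2$marker_sequences, db$marker_sequences)
})
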