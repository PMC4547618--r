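test_that("stage 1 maps OTU mass through the association matrix", {
  # identity association: each reference maps to its own organism
  assoc <- manual_association(diag(2) |>
    `dimnames<-`(list(c("X", "Y"), c("r1", "r2"))))
  p <- abundance_profile(c(r1 = 30, r2 = 10), kind = "otu")
  res <- transform_to_organism_profile(p, assoc)
  expect_equal(res$fraction_unmapped, 0)
  expect_equal(res$organism_profile$abundance, c(0.75, 0.25))

  # split column
  split <- manual_association(matrix(c(0.5, 0.5), ncol = 1,
    dimnames = list(c("X", "Y"), "r1")))
  res2 <- transform_to_organism_profile(
    abundance_profile(c(r1 = 100), kind = "otu"), split)
  expect_equal(res2$organism_profile$abundance, c(0.5, 0.5))
  expect_equal(res2$fraction_unmapped, 0)

  # all-zero column contributes to unmapped mass, remainder renormalized
  partial <- manual_association(matrix(c(1, 0), nrow = 1,
    dimnames = list("X", c("r1", "r2"))))
  res3 <- transform_to_organism_profile(
    abundance_profile(c(r1 = 80, r2 = 20), kind = "otu"), partial)
  expect_identical(res3$fraction_unmapped, 0.2)
  expect_equal(res3$organism_profile$abundance, 1)

  # features absent from the matrix behave like all-zero columns
  res4 <- transform_to_organism_profile(
    abundance_profile(c(r1 = 80, rX = 20), kind = "otu"), partial)
  expect_identical(res4$fraction_unmapped, 0.2)

  expect_error(transform_to_organism_profile(
    abundance_profile(c(rX = 5), kind = "otu"), partial),
    class = "ampliko_nothing_mapped")
})

test_that("stage 2 corrects for 16S copy number", {
  cn <- data.frame(organism_id = c("X", "Y"), copy_number = c(1, 4))
  p <- abundance_profile(c(X = 0.5, Y = 0.5), kind = "organism")
  corrected <- normalize_by_copy_number(p, cn)
  expect_equal(corrected$abundance, c(0.8, 0.2))

  # uniform copy numbers leave the profile unchanged
  cn_flat <- data.frame(organism_id = c("X", "Y"), copy_number = c(3, 3))
  p2 <- abundance_profile(c(X = 0.7, Y = 0.3), kind = "organism")
  expect_equal(normalize_by_copy_number(p2, cn_flat)$abundance, c(0.7, 0.3))

  # single organism collapses to 1 for any copy number
  one <- normalize_by_copy_number(
    abundance_profile(c(X = 0.4), kind = "organism"),
    data.frame(organism_id = "X", copy_number = 7))
  expect_equal(one$abundance, 1)

  expect_error(normalize_by_copy_number(p, cn[1, ]),
               class = "ampliko_missing_copy_number", regexp = "Y")
  # the explicit opt-in assumes copy number 1 for missing organisms
  assumed <- normalize_by_copy_number(p, cn[1, ], assume_copy_number_1 = TRUE)
  expect_equal(assumed$abundance, c(0.5, 0.5))
})

test_that("stage 3 is a convex combination of reference KO rows", {
  prof <- build_reference_profiles(tibble::tibble(
    organism_id = c("X", "Y"), ko_id = c("K00001", "K00002"), count = c(1, 1)))
  mix <- abundance_profile(c(X = 0.8, Y = 0.2), kind = "organism")
  ko <- predict_functional_profile(mix, prof)
  expect_equal(ko$abundance, c(0.8, 0.2))
  expect_true(is_normalized(ko))

  pure <- predict_functional_profile(
    abundance_profile(c(X = 1), kind = "organism"), prof)
  expect_equal(setNames(pure$abundance, pure$feature_id),
               prof["X", ])

  expect_error(predict_functional_profile(
    abundance_profile(c(X = 0.5, Q = 0.5), kind = "organism"), prof),
    class = "ampliko_missing_reference_profile", regexp = "Q")
  expect_error(predict_functional_profile(
    abundance_profile(c(X = 0.5), kind = "organism"), prof),
    class = "ampliko_bad_profile")
})

test_that("pure cultures are fixed points of the full pipeline", {
  fix <- generate_reference_fixture(fixture_spec(
    n_organisms = 10, n_extra_refs = 0, seq_length = 200,
    mutation_rate = 0, seed = 2))
  db <- fixture_database(fix)
  for (i in seq_len(10)) {
    org <- fix$truth$organism_id[i]
    ref <- fix$truth$reference_id[i]
    pred <- predict(db, abundance_profile(setNames(1000, ref), kind = "otu"))
    expect_equal(pred$fraction_otus_unmapped, 0)
    expect_lt(max(abs(setNames(pred$ko_profile$abundance,
                               pred$ko_profile$feature_id) -
                      db$reference_profiles[org, ])), 1e-12)
  }
})

test_that("end-to-end prediction equals the hand-computed three-step result", {
  inp <- toy_inputs()
  db <- toy_database()
  otu <- abundance_profile(c(ref01 = 0.5, ref02 = 0.3, ref03 = 0.2),
                           kind = "otu")
  pred <- predict(db, otu)

  # independent recomputation, spreadsheet-style, from the raw toy tables:
  # stage 1 is the identity relabeling (each ref maps to its own organism),
  # stage 2 divides by copy numbers (1, 2, 4) and renormalizes,
  # stage 3 mixes the count-normalized KO rows.
  w <- c(org01 = 0.5 / 1, org02 = 0.3 / 2, org03 = 0.2 / 4)
  w <- w / (0.5 / 1 + 0.3 / 2 + 0.2 / 4)
  rows <- list(
    org01 = c(K00001 = 3 / 4, K00002 = 1 / 4),
    org02 = c(K00002 = 2 / 4, K00003 = 2 / 4),
    org03 = c(K00003 = 1 / 5, K00004 = 4 / 5)
  )
  expected <- c(K00001 = 0, K00002 = 0, K00003 = 0, K00004 = 0)
  for (org in names(w)) {
    expected[names(rows[[org]])] <-
      expected[names(rows[[org]])] + w[org] * rows[[org]]
  }
  got <- setNames(pred$ko_profile$abundance, pred$ko_profile$feature_id)
  expect_lt(max(abs(got[names(expected)] - expected)), 1e-12)
  expect_equal(pred$fraction_otus_unmapped, 0)
  expect_equal(setNames(pred$organism_profile$abundance,
                        pred$organism_profile$feature_id)[names(w)],
               w)
})

test_that("prediction is linear in raw counts when everything maps", {
  inp <- toy_inputs()
  # copy numbers all 1 so stages 2-3 are linear in the organism masses
  db <- assemble_database(inp$marker_sequences, inp$genome_sequences,
                          inp$ko_counts,
                          tibble::tibble(organism_id = paste0("org0", 1:3),
                                         copy_number = c(1L, 1L, 1L)))
  p <- abundance_profile(c(ref01 = 10, ref02 = 30), kind = "otu")
  q <- abundance_profile(c(ref02 = 10, ref03 = 50), kind = "otu")
  blend <- abundance_profile(c(ref01 = 10, ref02 = 40, ref03 = 50),
                             kind = "otu")
  kp <- predict(db, p)$ko_profile
  kq <- predict(db, q)$ko_profile
  kb <- predict(db, blend)$ko_profile
  manual <- (40 * kp$abundance[match(kb$feature_id, kp$feature_id)] +
             60 * kq$abundance[match(kb$feature_id, kq$feature_id)]) / 100
  expect_lt(max(abs(kb$abundance - manual)), 1e-12)
})

test_that("coverage report combines mapping and classification fractions", {
  inp <- toy_inputs()
  db <- toy_database()
  pred <- predict(db, abundance_profile(c(ref01 = 80, nohit = 20),
                                        kind = "otu"))
  cov <- coverage_report(pred, classified_read_fraction = 0.9)
  expect_equal(cov$fraction_otus_mapped, 0.8)
  expect_equal(cov$overall_fraction, 0.72)

  cov2 <- coverage_report(predict(db, abundance_profile(c(ref01 = 1),
                                                        kind = "otu")))
  expect_equal(cov2$fraction_otus_mapped, 1.0)
  expect_true(is.na(cov2$overall_fraction))  # omitted, not guessed
})
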