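#' Specification for a synthetic reference/community fixture
#'
#' Describes a mock marker-reference / annotated-genome universe with known
#' ground truth, emulating the correspondence structure between a large rRNA
#' reference database and a smaller set of sequenced genomes: each genome has
#' a 16S-like sequence, its "database reference" is a point-mutated copy of
#' it, and some references have no genome neighbour at all. Generation is a
#' pure function of the spec (seed included).
#'
#' @param n_organisms Number of annotated genomes (>= 1).
#' @param n_extra_refs Number of unrelated marker references with no genome
#'   neighbour (expected to fall below any sensible identity threshold).
#' @param seq_length Length of the 16S-like sequences in bases.
#' @param mutation_rate Per-site substitution probability between a genome
#'   16S sequence and its derived marker reference, in `[0, 1]`.
#' @param n_kos_per_organism Number of distinct KOs annotated per genome.
#' @param ko_universe_size Size of the KO pool the annotations are drawn from.
#' @param copy_number_range Integer range (length-2) of 16S gene copy numbers.
#' @param seed RNG seed; the whole fixture is deterministic given the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_organisms = 10, n_extra_refs = 5, seq_length = 500,
                         mutation_rate = 0.01, n_kos_per_organism = 20,
                         ko_universe_size = 100,
                         copy_number_range = c(1L, 5L), seed = 1) {
  stopifnot(n_organisms >= 1, n_extra_refs >= 0, seq_length >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            n_kos_per_organism >= 1, ko_universe_size >= n_kos_per_organism,
            length(copy_number_range) == 2L, copy_number_range[1] >= 1,
            copy_number_range[2] >= copy_number_range[1])
  structure(list(
    n_organisms = as.integer(n_organisms),
    n_extra_refs = as.integer(n_extra_refs),
    seq_length = as.integer(seq_length),
    mutation_rate = mutation_rate,
    n_kos_per_organism = as.integer(n_kos_per_organism),
    ko_universe_size = as.integer(ko_universe_size),
    copy_number_range = as.integer(copy_number_range),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

random_sequence <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic reference fixture with known ground truth
#'
#' For every organism `orgNN`: a random 16S-like genome sequence, a derived
#' marker reference `refNN` obtained by independent per-site substitutions at
#' `mutation_rate`, a sparse KO count table and a 16S copy number drawn from
#' `copy_number_range`. Additionally `n_extra_refs` unrelated random
#' references (`xrefNN`) are produced; they have no genome neighbour, so a
#' correctly built association matrix leaves their columns all-zero at any
#' realistic threshold.
#'
#' @param spec A [fixture_spec()].
#' @return A `reference_fixture` list with elements `marker_sequences`,
#'   `genome_sequences`, `ko_counts`, `copy_numbers`, `truth` (tibble
#'   `reference_id` / `organism_id`, `NA` for the unrelated extras) and
#'   `spec`.
#' @export
generate_reference_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    org_ids <- sprintf("org%02d", seq_len(spec$n_organisms))
    ref_ids <- sprintf("ref%02d", seq_len(spec$n_organisms))
    genome_sequences <- setNames(
      vapply(org_ids, function(o) random_sequence(spec$seq_length),
             character(1)), org_ids)
    marker_sequences <- setNames(
      vapply(genome_sequences, mutate_sequence, character(1),
             rate = spec$mutation_rate), ref_ids)
    extra_ids <- character(0)
    if (spec$n_extra_refs > 0L) {
      extra_ids <- sprintf("xref%02d", seq_len(spec$n_extra_refs))
      extras <- setNames(
        vapply(extra_ids, function(i) random_sequence(spec$seq_length),
               character(1)), extra_ids)
      marker_sequences <- c(marker_sequences, extras)
    }
    ko_pool <- sprintf("K%05d", seq_len(spec$ko_universe_size))
    ko_counts <- dplyr::bind_rows(lapply(org_ids, function(o) {
      kos <- sample(ko_pool, spec$n_kos_per_organism)
      tibble(organism_id = o, ko_id = lex_sort(kos),
             count = sample(1:50, spec$n_kos_per_organism, replace = TRUE))
    }))
    copy_numbers <- tibble(
      organism_id = org_ids,
      copy_number = sample(seq(spec$copy_number_range[1],
                               spec$copy_number_range[2]),
                           spec$n_organisms, replace = TRUE)
    )
    truth <- tibble(
      reference_id = c(ref_ids, extra_ids),
      organism_id = c(org_ids, rep(NA_character_, length(extra_ids)))
    )
    structure(list(
      marker_sequences = marker_sequences,
      genome_sequences = genome_sequences,
      ko_counts = ko_counts,
      copy_numbers = copy_numbers,
      truth = truth,
      spec = spec
    ), class = "reference_fixture")
  })
}

#' @rdname generate_reference_fixture
#' @param fixture A `reference_fixture`.
#' @param min_identity Association threshold passed to
#'   [assemble_database()].
#' @return `fixture_database()`: the assembled `reference_db`.
#' @export
fixture_database <- function(fixture, min_identity = 0.97) {
  stopifnot(inherits(fixture, "reference_fixture"))
  assemble_database(
    marker_sequences = fixture$marker_sequences,
    genome_marker_sequences = fixture$genome_sequences,
    ko_counts = fixture$ko_counts,
    copy_numbers = fixture$copy_numbers,
    min_identity = min_identity
  )
}

#' Simulate a paired 16S / shotgun-metagenome sample
#'
#' Draws the two sides of a paired benchmark sample from a fixture with known
#' mixing weights:
#'
#' * 16S side: `n_reads` assignments drawn multinomially over the organisms'
#'   marker references with probabilities proportional to
#'   `mixing_weight * copy_number` — the copy-number bias of amplicon data is
#'   injected deliberately so the predictor's correction stage is exercised;
#' * metagenome side: the exact convex combination of the organisms' relative
#'   KO profiles under `mixing_weights`, optionally perturbed per KO by
#'   multiplicative log-normal noise (`sdlog = noise_rate`) and renormalized.
#'
#' @param fixture A `reference_fixture`.
#' @param mixing_weights Named nonnegative vector over the fixture's organism
#'   ids, summing to 1 (within `1e-9`).
#' @param n_reads Number of 16S assignments to draw (>= 1).
#' @param noise_rate Log-normal `sdlog` of the metagenome-side noise; 0 means
#'   the exact profile.
#' @param seed RNG seed for this sample.
#' @return A list with `otu_table` (single-sample `otu_table`),
#'   `otu_profile` (the same counts as an `"otu"` profile),
#'   `metagenome_profile` (normalized `"ko"` profile) and `mixing_weights`.
#' @export
generate_paired_sample <- function(fixture, mixing_weights, n_reads,
                                   noise_rate = 0, seed = 1) {
  stopifnot(inherits(fixture, "reference_fixture"), n_reads >= 1,
            noise_rate >= 0)
  org_ids <- lex_sort(unique(fixture$truth$organism_id[
    !is.na(fixture$truth$organism_id)]))
  if (is.null(names(mixing_weights)) ||
      !setequal(names(mixing_weights), org_ids) ||
      any(mixing_weights < 0)) {
    stop_ampliko("`mixing_weights` must be a nonnegative vector named by the fixture's organism ids",
                 "ampliko_bad_input")
  }
  if (abs(sum(mixing_weights) - 1) > 1e-9) {
    stop_ampliko("`mixing_weights` must sum to 1", "ampliko_bad_input")
  }
  w <- mixing_weights[org_ids]
  cn <- setNames(fixture$copy_numbers$copy_number,
                 fixture$copy_numbers$organism_id)[org_ids]
  ref_of <- setNames(fixture$truth$reference_id,
                     fixture$truth$organism_id)[org_ids]
  profiles <- build_reference_profiles(fixture$ko_counts)

  with_seed(seed, {
    probs <- w * cn
    probs <- probs / sum(probs)
    reads <- as.numeric(stats::rmultinom(1L, size = n_reads, prob = probs))
    counts <- setNames(reads, unname(ref_of))

    truth_w <- setNames(numeric(nrow(profiles)), rownames(profiles))
    truth_w[names(w)] <- w
    ko <- as.numeric(truth_w %*% unclass(profiles))
    names(ko) <- colnames(profiles)
    if (noise_rate > 0) {
      ko <- ko * exp(stats::rnorm(length(ko), mean = 0, sd = noise_rate))
    }
    ko <- ko / sum(ko)

    otu_tbl <- new_otu_table(tibble(otu_id = lex_sort(names(counts)),
                                    sample1 = unname(counts[lex_sort(names(counts))])))
    list(
      otu_table = otu_tbl,
      otu_profile = abundance_profile(counts, kind = "otu"),
      metagenome_profile = abundance_profile(ko, kind = "ko"),
      mixing_weights = w
    )
  })
}

#' Write a reference fixture as plain input files
#'
#' Emits the fixture in exactly the external formats the builder consumes
#' (marker and genome FASTA, KO-count TSV, copy-number TSV, plus the
#' ground-truth map), so fixtures double as format-conformance tests.
#'
#' @param fixture A `reference_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir) {
  stopifnot(inherits(fixture, "reference_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$marker_sequences,
              file.path(dir, "marker_sequences.fasta"))
  write_fasta(fixture$genome_sequences, file.path(dir, "genome_16s.fasta"))
  write_ko_counts(fixture$ko_counts, file.path(dir, "ko_counts.tsv"))
  write_copy_numbers(fixture$copy_numbers,
                     file.path(dir, "copy_numbers.tsv"))
  truth <- fixture$truth
  writeLines(c("reference_id\torganism_id",
               paste(truth$reference_id,
                     ifelse(is.na(truth$organism_id), "NA", truth$organism_id),
                     sep = "\t")),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}
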