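#' Identity scores between marker references and genomes
#'
#' Computes the global-alignment identity ([pairwise_identity()]) of every
#' marker reference sequence against every genome. A genome with several 16S
#' rRNA copies scores as the maximum identity over its copies, so within-genome
#' copy divergence never penalizes the genome.
#'
#' @param marker_sequences Named character vector of marker (e.g. SILVA-style)
#'   reference sequences.
#' @param genome_marker_sequences Named character vector of genome 16S rRNA
#'   sequences; names are sequence ids.
#' @param organisms Character vector mapping each genome sequence to its
#'   organism id (default: the sequence names, i.e. one 16S copy per genome).
#' @param match,mismatch,gap Alignment scores passed to [pairwise_identity()].
#' @return A tibble with columns `reference_id`, `organism_id`, `identity`.
#' @export
identity_scores <- function(marker_sequences, genome_marker_sequences,
                            organisms = names(genome_marker_sequences),
                            match = 1, mismatch = -1, gap = -1) {
  check_named_sequences(marker_sequences, "marker_sequences")
  check_named_sequences(genome_marker_sequences, "genome_marker_sequences")
  if (length(organisms) != length(genome_marker_sequences)) {
    stop_ampliko("`organisms` must map every genome sequence to an organism",
                 "ampliko_bad_input")
  }
  enc_ref <- lapply(marker_sequences, encode_sequence)
  enc_gen <- lapply(genome_marker_sequences, encode_sequence)
  org_ids <- lex_sort(unique(organisms))
  ref_ids <- lex_sort(names(marker_sequences))

  rows <- lapply(ref_ids, function(r) {
    per_seq <- vapply(enc_gen, function(g) {
      nw_identity_cpp(enc_ref[[r]], g, match, mismatch, gap)[["identity"]]
    }, numeric(1))
    # max over a genome's 16S copies
    per_org <- vapply(split(per_seq, organisms), max, numeric(1))
    tibble(reference_id = r, organism_id = org_ids,
           identity = unname(per_org[org_ids]))
  })
  dplyr::bind_rows(rows)
}

#' Build the reference-to-organism association matrix
#'
#' The core precomputed object of the prediction method: a sparse
#' organisms-by-references matrix that linearly maps marker-reference
#' abundances to genome abundances. Each reference column is assigned to its
#' nearest genome neighbours by alignment identity, subject to a minimum
#' identity threshold:
#'
#' * references whose best identity falls below `min_identity` get an all-zero
#'   column (no genome neighbour -- their abundance mass is unmappable);
#' * otherwise the exact-maximum neighbours (ties resolved within `1e-12`)
#'   share the column weight uniformly, so every mapped column sums to
#'   exactly 1.
#'
#' The builder is fully deterministic.
#'
#' @inheritParams identity_scores
#' @param min_identity Minimum identity fraction in `(0, 1]` for a reference
#'   to be associated with any genome. Default 0.97, the conventional
#'   species-level 16S similarity radius.
#' @return An `association_matrix`: a sparse [Matrix::dgCMatrix-class] with
#'   organism rows and reference columns, carrying `min_identity` as an
#'   attribute.
#' @export
build_association_matrix <- function(marker_sequences, genome_marker_sequences,
                                     min_identity = 0.97,
                                     organisms = names(genome_marker_sequences),
                                     match = 1, mismatch = -1, gap = -1) {
  if (!is.numeric(min_identity) || length(min_identity) != 1L ||
      is.na(min_identity) || min_identity <= 0 || min_identity > 1) {
    stop_ampliko("`min_identity` must be a single value in (0, 1]",
                 "ampliko_bad_threshold")
  }
  scores <- identity_scores(marker_sequences, genome_marker_sequences,
                            organisms = organisms,
                            match = match, mismatch = mismatch, gap = gap)
  org_ids <- lex_sort(unique(scores$organism_id))
  ref_ids <- lex_sort(unique(scores$reference_id))

  triplets <- dplyr::filter(scores, .data$identity >= min_identity)
  if (nrow(triplets) > 0L) {
    triplets <- triplets |>
      dplyr::group_by(.data$reference_id) |>
      dplyr::filter(.data$identity >= max(.data$identity) - 1e-12) |>
      dplyr::mutate(weight = 1 / dplyr::n()) |>
      dplyr::ungroup()
  } else {
    triplets$weight <- numeric(0)
  }

  weights <- Matrix::sparseMatrix(
    i = match(triplets$organism_id, org_ids),
    j = match(triplets$reference_id, ref_ids),
    x = triplets$weight,
    dims = c(length(org_ids), length(ref_ids)),
    dimnames = list(org_ids, ref_ids)
  )
  new_association_matrix(weights, min_identity)
}

# The sparse weights live in a plain dgCMatrix; the S3 wrapper carries the
# build threshold without interfering with Matrix's S4 dispatch.
new_association_matrix <- function(weights, min_identity) {
  structure(list(weights = weights, min_identity = min_identity),
            class = "association_matrix")
}

#' @describeIn build_association_matrix Row (organism) and column (reference)
#'   ids of the matrix.
#' @param association An `association_matrix`.
#' @export
association_organisms <- function(association) {
  rownames(association$weights)
}

#' @rdname build_association_matrix
#' @export
association_references <- function(association) {
  colnames(association$weights)
}

#' @export
print.association_matrix <- function(x, ...) {
  cs <- Matrix::colSums(x$weights)
  cat(sprintf(paste0("<association_matrix: %d organisms x %d references, ",
                     "%d mapped columns, min_identity=%g>\n"),
              nrow(x$weights), ncol(x$weights), sum(cs > 0), x$min_identity))
  invisible(x)
}

#' @describeIn build_association_matrix Triplet (long) view of the nonzero
#'   association weights, one row per `organism_id`/`reference_id` pair.
#' @param x An `association_matrix`.
#' @param ... Unused.
#' @export
tidy.association_matrix <- function(x, ...) {
  tr <- Matrix::summary(methods::as(x$weights, "TsparseMatrix"))
  out <- tibble(
    organism_id = rownames(x$weights)[tr$i],
    reference_id = colnames(x$weights)[tr$j],
    weight = tr$x
  )
  dplyr::arrange(out, .data$reference_id, .data$organism_id)
}

#' Turn per-organism KO counts into relative reference profiles
#'
#' Each organism's KO counts are divided by their total, giving one relative
#' KO profile per genome; the KO universe is the union of all KOs observed,
#' zero-filled. An organism with no positive count has no defined profile and
#' is rejected.
#'
#' @param ko_counts A data frame with columns `organism_id`, `ko_id`, `count`.
#' @return A `reference_profiles` object: a dense organisms-by-KOs matrix whose
#'   rows each sum to 1.
#' @export
build_reference_profiles <- function(ko_counts) {
  if (!is.data.frame(ko_counts) ||
      !all(c("organism_id", "ko_id", "count") %in% names(ko_counts))) {
    stop_ampliko("`ko_counts` needs columns organism_id, ko_id, count",
                 "ampliko_bad_input")
  }
  if (nrow(ko_counts) == 0L) {
    stop_ampliko("`ko_counts` is empty", "ampliko_bad_input")
  }
  if (any(!is.finite(ko_counts$count)) || any(ko_counts$count < 0)) {
    stop_ampliko("KO counts must be finite and nonnegative",
                 "ampliko_bad_input")
  }
  totals <- tapply(ko_counts$count, ko_counts$organism_id, sum)
  zero <- names(totals)[totals <= 0]
  if (length(zero) > 0L) {
    stop_ampliko(sprintf("organisms with all-zero KO counts: %s",
                         paste(zero, collapse = ", ")),
                 "ampliko_zero_profile")
  }
  org_ids <- lex_sort(unique(as.character(ko_counts$organism_id)))
  ko_ids <- lex_sort(unique(as.character(ko_counts$ko_id)))
  profiles <- matrix(0, nrow = length(org_ids), ncol = length(ko_ids),
                     dimnames = list(org_ids, ko_ids))
  agg <- stats::aggregate(count ~ organism_id + ko_id, data = ko_counts, sum)
  profiles[cbind(as.character(agg$organism_id), as.character(agg$ko_id))] <- agg$count
  profiles <- profiles / rowSums(profiles)
  structure(profiles, class = c("reference_profiles", "matrix", "array"))
}

#' @describeIn build_reference_profiles Long view: one row per organism/KO
#'   pair with nonzero relative abundance.
#' @param x A `reference_profiles` object.
#' @param ... Unused.
#' @export
tidy.reference_profiles <- function(x, ...) {
  idx <- which(x > 0, arr.ind = TRUE)
  out <- tibble(
    organism_id = rownames(x)[idx[, 1]],
    ko_id = colnames(x)[idx[, 2]],
    relative_abundance = x[idx]
  )
  dplyr::arrange(out, .data$organism_id, .data$ko_id)
}

#' Validate a 16S rRNA copy-number table
#'
#' @param copy_numbers A data frame with columns `organism_id` and
#'   `copy_number` (positive integers: 16S rRNA gene copies per genome).
#' @return A tibble sorted by `organism_id` with integer copy numbers.
#' @export
copy_number_table <- function(copy_numbers) {
  if (!is.data.frame(copy_numbers) ||
      !all(c("organism_id", "copy_number") %in% names(copy_numbers))) {
    stop_ampliko("`copy_numbers` needs columns organism_id, copy_number",
                 "ampliko_bad_input")
  }
  cn <- copy_numbers$copy_number
  if (any(!is.finite(cn)) || any(cn < 1) || any(cn != round(cn))) {
    stop_ampliko("copy numbers must be integers >= 1", "ampliko_bad_input")
  }
  if (anyDuplicated(copy_numbers$organism_id)) {
    stop_ampliko("duplicate organism ids in copy-number table",
                 "ampliko_bad_input")
  }
  out <- tibble(organism_id = as.character(copy_numbers$organism_id),
                copy_number = as.integer(cn))
  dplyr::arrange(out, .data$organism_id)
}

#' Assemble a reference database
#'
#' Bundles the precomputed objects the predictor needs: the association
#' matrix built from the sequences at `min_identity`, the copy-number table
#' and the per-organism relative KO profiles, with provenance metadata.
#' Organism ids must agree across the three genome-side inputs.
#'
#' @inheritParams build_association_matrix
#' @inheritParams build_reference_profiles
#' @inheritParams copy_number_table
#' @return A `reference_db` object (list with elements `marker_sequences`,
#'   `genome_marker_sequences`, `organisms`, `association`, `copy_numbers`,
#'   `reference_profiles`, `metadata`).
#' @export
assemble_database <- function(marker_sequences, genome_marker_sequences,
                              ko_counts, copy_numbers, min_identity = 0.97,
                              organisms = names(genome_marker_sequences),
                              match = 1, mismatch = -1, gap = -1) {
  profiles <- build_reference_profiles(ko_counts)
  cn <- copy_number_table(copy_numbers)
  genome_orgs <- lex_sort(unique(organisms))
  check_same_organisms(genome_orgs, rownames(profiles), "ko_counts")
  check_same_organisms(genome_orgs, cn$organism_id, "copy_numbers")

  association <- build_association_matrix(
    marker_sequences, genome_marker_sequences, min_identity = min_identity,
    organisms = organisms, match = match, mismatch = mismatch, gap = gap
  )
  db <- structure(
    list(
      marker_sequences = marker_sequences[lex_sort(names(marker_sequences))],
      genome_marker_sequences =
        genome_marker_sequences[lex_sort(names(genome_marker_sequences))],
      organisms = setNames(organisms, names(genome_marker_sequences))[
        lex_sort(names(genome_marker_sequences))],
      association = association,
      copy_numbers = cn,
      reference_profiles = profiles,
      metadata = list(
        min_identity = min_identity,
        scoring = c(match = match, mismatch = mismatch, gap = gap),
        n_organisms = length(genome_orgs),
        n_references = length(marker_sequences),
        marker_digest = fingerprint(marker_sequences),
        genome_digest = fingerprint(genome_marker_sequences)
      )
    ),
    class = "reference_db"
  )
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(paste0("<reference_db: %d organisms, %d marker references, ",
                     "%d KOs, min_identity=%g>\n"),
              nrow(x$reference_profiles), length(x$marker_sequences),
              ncol(x$reference_profiles), x$metadata$min_identity))
  invisible(x)
}

check_named_sequences <- function(seqs, what) {
  if (length(seqs) == 0L) {
    stop_ampliko(sprintf("`%s` is empty", what), "ampliko_bad_input")
  }
  if (is.null(names(seqs)) || any(names(seqs) == "") ||
      anyDuplicated(names(seqs))) {
    stop_ampliko(sprintf("`%s` must have unique nonempty names", what),
                 "ampliko_bad_input")
  }
}

check_same_organisms <- function(expected, got, what) {
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop_ampliko(sprintf(
      "organism ids in `%s` disagree with genome sequences%s%s", what,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""
    ), "ampliko_organism_mismatch")
  }
}
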