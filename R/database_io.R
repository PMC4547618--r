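#' Serialize a reference database to a directory of plain-text files
#'
#' The on-disk layout is fully text-based and deterministic (identical inputs
#' give byte-identical output):
#'
#' * `association.tsv` — sparse triplets `organism_id  reference_id  weight`;
#' * `ref_profiles.tsv` — long table `organism_id  ko_id  relative_abundance`
#'   (nonzero entries only);
#' * `copy_numbers.tsv` — `organism_id  copy_number`;
#' * `marker_sequences.fasta`, `genome_16s.fasta` — the input sequences;
#' * `genome_organisms.tsv` — genome 16S sequence id to organism id map;
#' * `metadata.json` — threshold, scoring and input digests.
#'
#' @param db A `reference_db` from [assemble_database()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- tidy(db$association)
  writeLines(c("organism_id\treference_id\tweight",
               paste(assoc$organism_id, assoc$reference_id,
                     format_full(assoc$weight), sep = "\t")),
             file.path(dir, "association.tsv"))
  prof <- tidy(db$reference_profiles)
  writeLines(c("organism_id\tko_id\trelative_abundance",
               paste(prof$organism_id, prof$ko_id,
                     format_full(prof$relative_abundance), sep = "\t")),
             file.path(dir, "ref_profiles.tsv"))
  write_copy_numbers(db$copy_numbers, file.path(dir, "copy_numbers.tsv"))
  write_fasta(db$marker_sequences, file.path(dir, "marker_sequences.fasta"))
  write_fasta(db$genome_marker_sequences, file.path(dir, "genome_16s.fasta"))
  writeLines(c("sequence_id\torganism_id",
               paste(names(db$organisms), unname(db$organisms), sep = "\t")),
             file.path(dir, "genome_organisms.tsv"))
  meta <- db$metadata
  meta$reference_ids <- association_references(db$association)  # keeps unmapped columns
  meta$ko_ids <- colnames(db$reference_profiles)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_reference_db
#' @return `read_reference_db()`: the reconstructed `reference_db`.
#' @export
read_reference_db <- function(dir) {
  need <- c("association.tsv", "ref_profiles.tsv", "copy_numbers.tsv",
            "marker_sequences.fasta", "genome_16s.fasta",
            "genome_organisms.tsv", "metadata.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop_ampliko(sprintf("not a reference-database directory (%s missing): %s",
                         paste(missing, collapse = ", "), dir),
                 "ampliko_io_error")
  }
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  marker <- read_fasta(file.path(dir, "marker_sequences.fasta"))
  genome <- read_fasta(file.path(dir, "genome_16s.fasta"))
  org_map <- read_plain_tsv(file.path(dir, "genome_organisms.tsv"), 2L,
                            c("sequence_id", "organism_id"))
  organisms <- setNames(
    vapply(org_map$fields, `[[`, character(1), 2L),
    vapply(org_map$fields, `[[`, character(1), 1L))

  cn <- read_copy_numbers(file.path(dir, "copy_numbers.tsv"))
  org_ids <- cn$organism_id

  prof_rows <- read_plain_tsv(file.path(dir, "ref_profiles.tsv"), 3L,
                              c("organism_id", "ko_id", "relative_abundance"))
  prof_long <- tibble(
    organism_id = vapply(prof_rows$fields, `[[`, character(1), 1L),
    ko_id = vapply(prof_rows$fields, `[[`, character(1), 2L),
    value = parse_numeric(vapply(prof_rows$fields, `[[`, character(1), 3L),
                          0L, "relative abundance")
  )
  ko_ids <- meta$ko_ids %||% lex_sort(unique(prof_long$ko_id))
  profiles <- matrix(0, nrow = length(org_ids), ncol = length(ko_ids),
                     dimnames = list(org_ids, ko_ids))
  profiles[cbind(prof_long$organism_id, prof_long$ko_id)] <- prof_long$value
  profiles <- structure(profiles,
                        class = c("reference_profiles", "matrix", "array"))

  assoc_rows <- read_plain_tsv(file.path(dir, "association.tsv"), 3L,
                               c("organism_id", "reference_id", "weight"))
  assoc_long <- tibble(
    organism_id = vapply(assoc_rows$fields, `[[`, character(1), 1L),
    reference_id = vapply(assoc_rows$fields, `[[`, character(1), 2L),
    weight = parse_numeric(vapply(assoc_rows$fields, `[[`, character(1), 3L),
                           0L, "weight")
  )
  ref_ids <- meta$reference_ids %||% lex_sort(names(marker))
  weights <- Matrix::sparseMatrix(
    i = match(assoc_long$organism_id, org_ids),
    j = match(assoc_long$reference_id, ref_ids),
    x = assoc_long$weight,
    dims = c(length(org_ids), length(ref_ids)),
    dimnames = list(org_ids, ref_ids)
  )
  meta$reference_ids <- NULL
  meta$ko_ids <- NULL
  if (!is.null(meta$scoring)) meta$scoring <- unlist(meta$scoring)
  structure(
    list(
      marker_sequences = marker,
      genome_marker_sequences = genome,
      organisms = organisms,
      association = new_association_matrix(weights, meta$min_identity),
      copy_numbers = cn,
      reference_profiles = profiles,
      metadata = meta
    ),
    class = "reference_db"
  )
}
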