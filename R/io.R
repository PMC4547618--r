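# Readers and writers for every external format the tool touches. All errors
# carry the offending record or line number; readers never silently drop rows.

# Split a text file into fields, keeping 1-based line numbers. Empty trailing
# lines are ignored; embedded empty lines are errors for tabular formats.
read_delim_lines <- function(path, delim) {
  if (!file.exists(path)) {
    stop_ampliko(sprintf("file not found: %s", path), "ampliko_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- seq_len(max(which(nzchar(lines)), 0L))
  lines <- lines[keep]
  list(fields = strsplit(lines, delim, fixed = TRUE), lines = lines)
}

parse_numeric <- function(x, line, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop_ampliko(sprintf("non-numeric %s on line %d: %s", what, line,
                         paste(x[is.na(v)], collapse = ", ")),
                 "ampliko_parse_error")
  }
  v
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings that return plain named character vectors.
#' Wrapped and unwrapped records are equivalent; the record id is the header
#' up to the first whitespace (any description after it is dropped);
#' duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_ampliko(sprintf("file not found: %s", path), "ampliko_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_ampliko(sprintf("duplicate FASTA ids: %s",
                         paste(dup, collapse = ", ")),
                 "ampliko_parse_error")
  }
  setNames(as.character(set), ids)
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @param width Line-wrap width for the sequence lines.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  check_named_sequences(sequences, "sequences")
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a QIIME classic OTU table
#'
#' The pre-BIOM tab-separated dialect: comment lines start with `#`, and the
#' header is the first line starting with `#OTU ID`, followed by sample
#' columns and an optional trailing `taxonomy` column (semicolon-separated
#' lineage strings). Counts must be nonnegative; ragged rows, negative values
#' and duplicate OTU ids are errors reported with their line number.
#'
#' @param path Path to the table.
#' @return An `otu_table`: a tibble with column `otu_id` and one numeric
#'   column per sample, plus a `taxonomy` attribute (named character vector
#'   or `NULL`).
#' @export
read_qiime_classic <- function(path) {
  parsed <- read_delim_lines(path, "\t")
  lines <- parsed$lines
  header_at <- which(startsWith(lines, "#OTU ID"))[1]
  if (is.na(header_at)) {
    stop_ampliko("not a QIIME classic OTU table: no '#OTU ID' header line",
                 "ampliko_dialect_error")
  }
  header <- parsed$fields[[header_at]]
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_ids <- header[seq(2L, length(header) - has_tax)]
  if (length(sample_ids) == 0L || anyDuplicated(sample_ids)) {
    stop_ampliko("OTU table header needs unique sample columns",
                 "ampliko_dialect_error")
  }
  data_at <- setdiff(seq_along(lines)[-seq_len(header_at)],
                     which(startsWith(lines, "#")))
  if (length(data_at) == 0L) {
    stop_ampliko("OTU table has no data rows", "ampliko_parse_error")
  }
  rows <- parsed$fields[data_at]
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    bad <- data_at[widths != length(header)][1]
    stop_ampliko(sprintf("ragged row on line %d: %d fields, expected %d",
                         bad, widths[widths != length(header)][1],
                         length(header)),
                 "ampliko_parse_error")
  }
  otu_ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(otu_ids)) {
    dup <- otu_ids[duplicated(otu_ids)][1]
    stop_ampliko(sprintf("duplicate OTU id '%s' on line %d", dup,
                         data_at[which(duplicated(otu_ids))[1]]),
                 "ampliko_parse_error")
  }
  counts <- matrix(0, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    v <- parse_numeric(rows[[i]][seq(2L, 1L + length(sample_ids))],
                       data_at[i], "count")
    if (any(v < 0)) {
      stop_ampliko(sprintf("negative count on line %d", data_at[i]),
                   "ampliko_parse_error")
    }
    counts[i, ] <- v
  }
  out <- as_tibble(as.data.frame(counts, col.names = sample_ids))
  names(out) <- sample_ids
  out <- dplyr::bind_cols(tibble(otu_id = otu_ids), out)
  taxonomy <- NULL
  if (has_tax) {
    taxonomy <- setNames(vapply(rows, `[[`, character(1), length(header)),
                         otu_ids)
  }
  new_otu_table(out, taxonomy)
}

new_otu_table <- function(tbl, taxonomy = NULL) {
  class(tbl) <- c("otu_table", class(tbl))
  attr(tbl, "taxonomy") <- taxonomy
  tbl
}

#' @rdname read_qiime_classic
#' @param table An `otu_table`.
#' @export
write_qiime_classic <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  taxonomy <- attr(table, "taxonomy")
  sample_ids <- setdiff(names(table), "otu_id")
  header <- c("#OTU ID", sample_ids, if (!is.null(taxonomy)) "taxonomy")
  body <- vapply(seq_len(nrow(table)), function(i) {
    vals <- vapply(sample_ids, function(s) format_full(table[[s]][i]),
                   character(1))
    paste(c(table$otu_id[i], vals,
            if (!is.null(taxonomy)) unname(taxonomy[table$otu_id[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname read_qiime_classic
#' @param sample Sample id; default extracts every sample.
#' @return `otu_table_profiles()`: a named list of `"otu"`-kind
#'   [abundance_profile()]s, one per sample.
#' @export
otu_table_profiles <- function(table, sample = NULL) {
  stopifnot(inherits(table, "otu_table"))
  sample_ids <- sample %||% setdiff(names(table), "otu_id")
  out <- lapply(sample_ids, function(s) {
    abundance_profile(setNames(table[[s]], table$otu_id), kind = "otu")
  })
  setNames(out, sample_ids)
}

#' Read a SILVAngs-style reference-assignment export
#'
#' A delimited table of assignment counts per marker reference sequence:
#' first column `reference_id`, then one count column per sample. Two header
#' dialects are accepted and auto-detected: comma-separated and
#' semicolon-separated (a header containing semicolons and no commas selects
#' the semicolon dialect).
#'
#' @param path Path to the export file.
#' @return A named list of `"otu"`-kind [abundance_profile()]s keyed by
#'   sample id (features are marker reference accessions).
#' @export
read_silvangs_export <- function(path) {
  if (!file.exists(path)) {
    stop_ampliko(sprintf("file not found: %s", path), "ampliko_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl(";", first, fixed = TRUE) &&
               !grepl(",", first, fixed = TRUE)) ";" else ","
  parsed <- read_delim_lines(path, delim)
  header <- parsed$fields[[1]]
  if (header[1] != "reference_id" || length(header) < 2L) {
    stop_ampliko(paste0(
      "unknown assignment-export dialect; accepted headers start with ",
      "'reference_id' followed by sample columns, comma- or ",
      "semicolon-separated"), "ampliko_dialect_error")
  }
  sample_ids <- header[-1]
  rows <- parsed$fields[-1]
  if (length(rows) == 0L) {
    stop_ampliko("assignment export has no data rows", "ampliko_parse_error")
  }
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop_ampliko(sprintf("ragged row on line %d", bad + 1L),
                 "ampliko_parse_error")
  }
  ref_ids <- vapply(rows, `[[`, character(1), 1L)
  counts <- vapply(seq_along(sample_ids), function(j) {
    parse_numeric(vapply(rows, `[[`, character(1), j + 1L), j, "count")
  }, numeric(length(rows)))
  counts <- matrix(counts, nrow = length(rows))
  out <- lapply(seq_along(sample_ids), function(j) {
    p <- abundance_profile(setNames(counts[, j], ref_ids), kind = "otu")
    if (sum(p$abundance) <= 0) {
      stop_ampliko(sprintf("empty profile: sample '%s' has no counts",
                           sample_ids[j]), "ampliko_empty_profile")
    }
    p
  })
  setNames(out, sample_ids)
}

#' @rdname read_silvangs_export
#' @param profiles Named list of `"otu"`-kind profiles.
#' @param delim `","` or `";"`.
#' @export
write_silvangs_export <- function(profiles, path, delim = ",") {
  stopifnot(delim %in% c(",", ";"))
  ids <- lex_sort(unique(unlist(lapply(profiles, `[[`, "feature_id"))))
  header <- paste(c("reference_id", names(profiles)), collapse = delim)
  body <- vapply(ids, function(id) {
    vals <- vapply(profiles, function(p) {
      hit <- match(id, p$feature_id)
      format_full(if (is.na(hit)) 0 else p$abundance[hit])
    }, character(1))
    paste(c(id, vals), collapse = delim)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write KO profile tables
#'
#' The predictor's output format: a two-column TSV `ko_id` /
#' `relative_abundance` in lexicographic `ko_id` order, serialized at 17
#' significant digits so a write/read round trip reproduces the profile
#' exactly.
#'
#' @param profile A `"ko"`-kind [abundance_profile()].
#' @param path Output path.
#' @export
write_ko_profile <- function(profile, path) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (profile_kind(profile) != "ko") {
    stop_ampliko("expected a profile of kind 'ko'", "ampliko_kind_mismatch")
  }
  body <- paste(profile$feature_id, format_full(profile$abundance), sep = "\t")
  writeLines(c("ko_id\trelative_abundance", body), path)
  invisible(path)
}

#' @rdname write_ko_profile
#' @export
read_ko_profile <- function(path) {
  parsed <- read_delim_lines(path, "\t")
  rows <- parsed$fields
  if (length(rows) < 1L || !identical(rows[[1]],
                                      c("ko_id", "relative_abundance"))) {
    stop_ampliko("expected header 'ko_id<TAB>relative_abundance'",
                 "ampliko_dialect_error")
  }
  rows <- rows[-1]
  if (any(lengths(rows) != 2L)) {
    bad <- which(lengths(rows) != 2L)[1] + 1L
    stop_ampliko(sprintf("ragged row on line %d", bad), "ampliko_parse_error")
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- parse_numeric(vapply(rows, `[[`, character(1), 2L), 2L, "abundance")
  abundance_profile(setNames(vals, ids), kind = "ko")
}

#' Read per-organism KO count and copy-number tables
#'
#' `read_ko_counts()` expects TSV columns `organism_id`, `ko_id`, `count`
#' (header optional); KO ids must match `K` followed by five digits.
#' `read_copy_numbers()` expects TSV columns `organism_id`, `copy_number`
#' (header optional).
#'
#' @param path Path to the TSV file.
#' @return A tibble (`read_ko_counts()`: organism_id/ko_id/count;
#'   `read_copy_numbers()`: validated [copy_number_table()]).
#' @export
read_ko_counts <- function(path) {
  rows <- read_plain_tsv(path, 3L, c("organism_id", "ko_id", "count"))
  ko <- vapply(rows$fields, `[[`, character(1), 2L)
  bad <- !grepl("^K\\d{5}$", ko)
  if (any(bad)) {
    stop_ampliko(sprintf("malformed KO id on line %d: '%s'",
                         rows$line_numbers[bad][1], ko[bad][1]),
                 "ampliko_parse_error")
  }
  tibble(
    organism_id = vapply(rows$fields, `[[`, character(1), 1L),
    ko_id = ko,
    count = parse_numeric(vapply(rows$fields, `[[`, character(1), 3L),
                          0L, "count")
  )
}

#' @rdname read_ko_counts
#' @export
read_copy_numbers <- function(path) {
  rows <- read_plain_tsv(path, 2L, c("organism_id", "copy_number"))
  copy_number_table(tibble(
    organism_id = vapply(rows$fields, `[[`, character(1), 1L),
    copy_number = parse_numeric(vapply(rows$fields, `[[`, character(1), 2L),
                                0L, "copy number")
  ))
}

# Shared TSV scaffolding: optional header (matched against expected column
# names), fixed column count, ragged rows rejected with line numbers.
read_plain_tsv <- function(path, n_cols, col_names) {
  parsed <- read_delim_lines(path, "\t")
  fields <- parsed$fields
  line_numbers <- seq_along(fields)
  if (length(fields) > 0L && identical(fields[[1]][1], col_names[1])) {
    fields <- fields[-1]
    line_numbers <- line_numbers[-1]
  }
  if (length(fields) == 0L) {
    stop_ampliko(sprintf("no data rows in %s", path), "ampliko_parse_error")
  }
  bad <- lengths(fields) != n_cols
  if (any(bad)) {
    stop_ampliko(sprintf("ragged row on line %d: %d fields, expected %d",
                         line_numbers[bad][1], lengths(fields)[bad][1], n_cols),
                 "ampliko_parse_error")
  }
  list(fields = fields, line_numbers = line_numbers)
}

write_ko_counts <- function(ko_counts, path) {
  writeLines(c("organism_id\tko_id\tcount",
               paste(ko_counts$organism_id, ko_counts$ko_id,
                     format_full(ko_counts$count), sep = "\t")), path)
  invisible(path)
}

write_copy_numbers <- function(copy_numbers, path) {
  writeLines(c("organism_id\tcopy_number",
               paste(copy_numbers$organism_id, copy_numbers$copy_number,
                     sep = "\t")), path)
  invisible(path)
}
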