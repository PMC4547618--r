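#' Map an OTU profile onto genome abundances
#'
#' Stage 1 of the prediction: the marker-reference (OTU) abundance vector is
#' multiplied by the precomputed association matrix, giving the apparent
#' abundance of every genome. Input features that are absent from the matrix,
#' or whose column is all-zero (no genome neighbour above the identity
#' threshold), contribute to the unmapped mass; the mapped remainder is
#' renormalized to sum 1 and the dropped fraction is reported rather than
#' silently redistributed.
#'
#' @param otu_profile An [abundance_profile()] of kind `"otu"` with positive
#'   total mass.
#' @param association An `association_matrix` from
#'   [build_association_matrix()].
#' @return A list with elements `organism_profile` (normalized
#'   `abundance_profile` of kind `"organism"`) and `fraction_unmapped`
#'   (fraction of input mass lost to unmapped references).
#' @export
transform_to_organism_profile <- function(otu_profile, association) {
  stopifnot(inherits(otu_profile, "abundance_profile"))
  if (profile_kind(otu_profile) != "otu") {
    stop_ampliko("expected a profile of kind 'otu'", "ampliko_kind_mismatch")
  }
  total <- sum(otu_profile$abundance)
  if (total <= 0) {
    stop_ampliko("empty OTU profile", "ampliko_empty_profile")
  }
  stopifnot(inherits(association, "association_matrix"))
  w <- association$weights
  hit <- otu_profile$feature_id %in% colnames(w)
  x <- setNames(numeric(ncol(w)), colnames(w))
  x[otu_profile$feature_id[hit]] <- otu_profile$abundance[hit]
  org <- as.numeric(w %*% x)
  names(org) <- rownames(w)
  mapped <- sum(org)
  fraction_unmapped <- (total - mapped) / total
  if (mapped <= 0) {
    stop_ampliko("no OTU mapped to any organism above the identity threshold",
                 "ampliko_nothing_mapped", fraction_unmapped = 1)
  }
  list(
    organism_profile = new_profile(names(org), org / mapped, "organism"),
    fraction_unmapped = fraction_unmapped
  )
}

#' Correct genome abundances for 16S rRNA copy number
#'
#' Stage 2: a genome with many 16S rRNA gene copies looks proportionally more
#' abundant in amplicon data than it is in cells. Each organism's abundance is
#' divided by its copy number and the result renormalized to sum 1. A missing
#' copy number for an abundant organism is an error by default -- silently
#' assuming 1 would corrupt the correction invisibly; set
#' `assume_copy_number_1 = TRUE` to opt in explicitly.
#'
#' @param organism_profile An [abundance_profile()] of kind `"organism"`.
#' @param copy_numbers A [copy_number_table()] (or data frame with columns
#'   `organism_id`, `copy_number`).
#' @param assume_copy_number_1 Use copy number 1 for organisms missing from
#'   the table instead of erroring.
#' @return A normalized `abundance_profile` of kind `"organism"`.
#' @examples
#' p <- abundance_profile(c(X = 0.5, Y = 0.5), kind = "organism")
#' cn <- data.frame(organism_id = c("X", "Y"), copy_number = c(1, 4))
#' normalize_by_copy_number(p, cn)  # X 0.8, Y 0.2
#' @export
normalize_by_copy_number <- function(organism_profile, copy_numbers,
                                     assume_copy_number_1 = FALSE) {
  stopifnot(inherits(organism_profile, "abundance_profile"))
  if (profile_kind(organism_profile) != "organism") {
    stop_ampliko("expected a profile of kind 'organism'",
                 "ampliko_kind_mismatch")
  }
  cn <- copy_number_table(copy_numbers)
  lookup <- setNames(cn$copy_number, cn$organism_id)
  abundant <- organism_profile$feature_id[organism_profile$abundance > 0]
  missing <- setdiff(abundant, names(lookup))
  if (length(missing) > 0L) {
    if (assume_copy_number_1) {
      lookup[missing] <- 1L
    } else {
      stop_ampliko(sprintf("no 16S copy number for abundant organisms: %s",
                           paste(missing, collapse = ", ")),
                   "ampliko_missing_copy_number")
    }
  }
  divisor <- lookup[organism_profile$feature_id]
  divisor[is.na(divisor)] <- 1L  # zero-abundance organisms: value irrelevant
  corrected <- organism_profile$abundance / as.numeric(divisor)
  new_profile(organism_profile$feature_id, corrected / sum(corrected),
              "organism")
}

#' Combine genome KO profiles into a community functional profile
#'
#' Stage 3: the copy-number-corrected genome abundances are used as convex
#' weights over the per-genome relative KO profiles; the community KO profile
#' is the weighted sum of the rows, hence itself a relative profile summing
#' to 1.
#'
#' @param normalized_organisms A normalized [abundance_profile()] of kind
#'   `"organism"`.
#' @param reference_profiles A `reference_profiles` matrix from
#'   [build_reference_profiles()]; every abundant organism needs a row.
#' @return A normalized `abundance_profile` of kind `"ko"`.
#' @export
predict_functional_profile <- function(normalized_organisms,
                                       reference_profiles) {
  stopifnot(inherits(normalized_organisms, "abundance_profile"),
            inherits(reference_profiles, "reference_profiles"))
  if (profile_kind(normalized_organisms) != "organism") {
    stop_ampliko("expected a profile of kind 'organism'",
                 "ampliko_kind_mismatch")
  }
  if (abs(sum(normalized_organisms$abundance) - 1) > 1e-9) {
    stop_ampliko("organism profile must be normalized (sum 1)",
                 "ampliko_bad_profile")
  }
  abundant <- normalized_organisms$feature_id[normalized_organisms$abundance > 0]
  missing <- setdiff(abundant, rownames(reference_profiles))
  if (length(missing) > 0L) {
    stop_ampliko(sprintf("no KO reference profile for abundant organisms: %s",
                         paste(missing, collapse = ", ")),
                 "ampliko_missing_reference_profile")
  }
  w <- setNames(numeric(nrow(reference_profiles)), rownames(reference_profiles))
  w[abundant] <- normalized_organisms$abundance[
    match(abundant, normalized_organisms$feature_id)]
  ko <- as.numeric(w %*% unclass(reference_profiles))
  new_profile(colnames(reference_profiles), ko, "ko")
}

#' Predict a community KO profile from an OTU profile
#'
#' Runs the full three-stage transformation against a [assemble_database()]
#' reference database: (1) map marker-reference abundances to genomes through
#' the association matrix, (2) correct for 16S rRNA copy number,
#' (3) linearly combine the per-genome KO profiles.
#'
#' @param object A `reference_db`.
#' @param otu_profile An [abundance_profile()] of kind `"otu"` (e.g. one
#'   sample of a QIIME classic OTU table or a SILVAngs-style export).
#' @param assume_copy_number_1 Passed to [normalize_by_copy_number()].
#' @param ... Unused.
#' @return A `prediction_result`: list with `ko_profile` (normalized KO
#'   profile), `organism_profile` (post-copy-number genome profile),
#'   `fraction_otus_unmapped`, and `inputs_digest` provenance.
#' @export
predict.reference_db <- function(object, otu_profile,
                                 assume_copy_number_1 = FALSE, ...) {
  stage1 <- transform_to_organism_profile(otu_profile, object$association)
  stage2 <- normalize_by_copy_number(stage1$organism_profile,
                                     object$copy_numbers,
                                     assume_copy_number_1 = assume_copy_number_1)
  ko <- predict_functional_profile(stage2, object$reference_profiles)
  structure(
    list(
      ko_profile = ko,
      organism_profile = stage2,
      fraction_otus_unmapped = stage1$fraction_unmapped,
      inputs_digest = c(profile = fingerprint(setNames(
        otu_profile$abundance, otu_profile$feature_id)),
        database = object$metadata$marker_digest)
    ),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(paste0("<prediction_result: %d KOs, %d organisms, ",
                     "%.1f%% of OTU mass unmapped>\n"),
              sum(x$ko_profile$abundance > 0),
              sum(x$organism_profile$abundance > 0),
              100 * x$fraction_otus_unmapped))
  invisible(x)
}

#' @describeIn predict.reference_db Predicted KO profile as a tibble
#'   (`ko_id`, `relative_abundance`).
#' @param x A `prediction_result`.
#' @export
tidy.prediction_result <- function(x, ...) {
  tibble(ko_id = x$ko_profile$feature_id,
         relative_abundance = x$ko_profile$abundance)
}

#' @describeIn predict.reference_db One-row summary of a prediction.
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(
    n_kos = sum(x$ko_profile$abundance > 0),
    n_organisms = sum(x$organism_profile$abundance > 0),
    fraction_otus_mapped = 1 - x$fraction_otus_unmapped,
    fraction_otus_unmapped = x$fraction_otus_unmapped
  )
}

#' @describeIn predict.reference_db Bar chart of the most abundant predicted
#'   KOs.
#' @param object A `prediction_result`.
#' @param top_n Number of KOs to show.
#' @export
autoplot.prediction_result <- function(object, top_n = 20, ...) {
  df <- tidy(object) |>
    dplyr::slice_max(.data$relative_abundance, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$ko_id, .data$relative_abundance),
    y = .data$relative_abundance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Predicted relative abundance",
                  title = "Top predicted KEGG Orthologs")
}

#' Coverage diagnostics for a prediction
#'
#' A prediction only draws on the OTU mass that survived two filters: the
#' upstream read classification (QIIME / SILVAngs, if its classified-read
#' fraction is known) and the association mapping to genomes. This reports
#' the mapped fraction, and -- when `classified_read_fraction` is supplied --
#' the overall fraction of raw reads informing the prediction (the product).
#' A low coverage flags an unreliable prediction even when correlations look
#' good.
#'
#' @param prediction A `prediction_result`.
#' @param classified_read_fraction Optional fraction in `[0, 1]` of raw reads
#'   classified by the upstream pipeline.
#' @return A one-row tibble with columns `fraction_otus_mapped`,
#'   `fraction_otus_unmapped`, `classified_read_fraction`,
#'   `overall_fraction` (`NA` when the upstream fraction is not given).
#' @export
coverage_report <- function(prediction, classified_read_fraction = NULL) {
  stopifnot(inherits(prediction, "prediction_result"))
  mapped <- 1 - prediction$fraction_otus_unmapped
  if (is.null(classified_read_fraction)) {
    classified <- NA_real_
    overall <- NA_real_
  } else {
    stopifnot(is.numeric(classified_read_fraction),
              classified_read_fraction >= 0, classified_read_fraction <= 1)
    classified <- classified_read_fraction
    overall <- mapped * classified
  }
  tibble(
    fraction_otus_mapped = mapped,
    fraction_otus_unmapped = prediction$fraction_otus_unmapped,
    classified_read_fraction = classified,
    overall_fraction = overall
  )
}
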