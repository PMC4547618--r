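#' Labelled abundance profiles
#'
#' An abundance profile is the basic currency of the prediction pipeline: a
#' nonnegative vector of abundances over a universe of features, which may be
#' OTUs / marker reference sequences (`kind = "otu"`), functionally annotated
#' genomes (`kind = "organism"`), or KEGG Orthologs (`kind = "ko"`).
#' Profiles are tibbles with columns `feature_id` and `abundance`, ordered
#' lexicographically by `feature_id`, carrying the profile kind and a
#' `normalized` flag (`TRUE` iff the abundances sum to 1 within `1e-9`) as
#' attributes.
#'
#' @param x A named numeric vector, or a data frame with columns `feature_id`
#'   and `abundance`.
#' @param kind One of `"otu"`, `"organism"`, `"ko"`.
#' @return An `abundance_profile` tibble.
#' @examples
#' abundance_profile(c(K00001 = 3, K00002 = 1), kind = "ko")
#' @export
abundance_profile <- function(x, kind = c("otu", "organism", "ko")) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    if (!all(c("feature_id", "abundance") %in% names(x))) {
      stop_ampliko("`x` must have columns `feature_id` and `abundance`",
                   "ampliko_bad_profile")
    }
    ids <- as.character(x$feature_id)
    values <- as.numeric(x$abundance)
  } else {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop_ampliko("profile values must be named by feature id",
                   "ampliko_bad_profile")
    }
    ids <- names(x)
    values <- as.numeric(x)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_ampliko(sprintf("duplicate feature ids: %s",
                         paste(head(dup, 5L), collapse = ", ")),
                 "ampliko_bad_profile")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_ampliko("abundances must be finite and nonnegative",
                 "ampliko_bad_profile")
  }
  ord <- lex_order(ids)
  new_profile(ids[ord], values[ord], kind)
}

# Constructor for internal use: assumes ids are unique and already sorted.
new_profile <- function(feature_ids, values, kind) {
  total <- sum(values)
  out <- tibble(feature_id = unname(feature_ids), abundance = unname(values))
  class(out) <- c("abundance_profile", class(out))
  attr(out, "kind") <- kind
  attr(out, "normalized") <- total > 0 && abs(total - 1) <= 1e-9
  out
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile: kind=%s, %d features, total=%s%s>\n",
              profile_kind(x), nrow(x), format(sum(x$abundance)),
              if (is_normalized(x)) ", normalized" else ""))
  NextMethod()
}

#' Query profile metadata
#'
#' @param profile An [abundance_profile()].
#' @return `profile_kind()` returns the feature kind (`"otu"`, `"organism"`
#'   or `"ko"`); `is_normalized()` returns `TRUE` iff the abundances sum to 1
#'   within `1e-9`.
#' @export
profile_kind <- function(profile) attr(profile, "kind")

#' @rdname profile_kind
#' @export
is_normalized <- function(profile) isTRUE(attr(profile, "normalized"))

#' Rescale a profile to relative abundances
#'
#' Divides all abundances by their total so they sum to 1, preserving ratios
#' between features. Idempotent; the feature order is unchanged.
#'
#' @param profile An [abundance_profile()] with at least one positive value.
#' @return A normalized `abundance_profile` of the same kind.
#' @examples
#' normalize_profile(abundance_profile(c(a = 1, b = 0, c = 3), kind = "otu"))
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  total <- sum(profile$abundance)
  if (total <= 0) {
    stop_ampliko("cannot normalize an empty profile (all abundances zero)",
                 "ampliko_empty_profile")
  }
  new_profile(profile$feature_id, profile$abundance / total,
              profile_kind(profile))
}

#' Align two profiles onto their feature union
#'
#' Expands both profiles onto the lexicographically sorted union of their
#' feature ids, filling absent features with 0, so their values are directly
#' comparable (e.g. before a rank correlation). Totals are conserved.
#'
#' @param a,b Two [abundance_profile()]s of the same kind.
#' @return A tibble with columns `feature_id`, `value_a`, `value_b`.
#' @examples
#' a <- abundance_profile(c(K1 = 0.6, K2 = 0.4), kind = "ko")
#' b <- abundance_profile(c(K2 = 1), kind = "ko")
#' align_features(a, b)
#' @export
align_features <- function(a, b) {
  stopifnot(inherits(a, "abundance_profile"), inherits(b, "abundance_profile"))
  if (!identical(profile_kind(a), profile_kind(b))) {
    stop_ampliko(sprintf("profile kind mismatch: %s vs %s",
                         profile_kind(a), profile_kind(b)),
                 "ampliko_kind_mismatch")
  }
  ids <- lex_sort(union(a$feature_id, b$feature_id))
  va <- setNames(numeric(length(ids)), ids)
  vb <- va
  va[a$feature_id] <- a$abundance
  vb[b$feature_id] <- b$abundance
  tibble(feature_id = ids, value_a = unname(va), value_b = unname(vb))
}
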