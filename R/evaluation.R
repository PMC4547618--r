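#' Drop KO dimensions with no signal in either profile
#'
#' Before rank-correlating a predicted and a shotgun-measured KO profile, the
#' two are aligned on their feature union and every dimension that is zero in
#' both is removed; a dimension with positive mass in either profile is always
#' retained.
#'
#' @param a,b Two [abundance_profile()]s of kind `"ko"`.
#' @return A tibble with columns `feature_id`, `value_a`, `value_b` over the
#'   retained dimensions (at least 2, else an error: correlation undefined).
#' @export
exclude_zero_dims <- function(a, b) {
  if (profile_kind(a) != "ko" || profile_kind(b) != "ko") {
    stop_ampliko("expected two profiles of kind 'ko'", "ampliko_kind_mismatch")
  }
  aligned <- align_features(a, b)
  keep <- aligned$value_a != 0 | aligned$value_b != 0
  retained <- aligned[keep, ]
  if (nrow(retained) < 2L) {
    stop_ampliko(sprintf(
      "only %d KO dimension(s) retained after zero-dimension exclusion; correlation undefined",
      nrow(retained)), "ampliko_too_few_dims")
  }
  retained
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Constant
#' input has zero rank variance and no defined coefficient, so it is an
#' explicit error rather than `NA`.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return The Spearman coefficient in `[-1, 1]`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 2L || anyNA(x) || anyNA(y)) {
    stop_ampliko("x and y must be equal-length numeric vectors, length >= 2",
                 "ampliko_bad_input")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_ampliko("zero rank variance: constant input has no defined Spearman coefficient",
                 "ampliko_constant_input")
  }
  cor(x, y, method = "spearman")
}

#' Exact two-sided sign test on paired differences
#'
#' The nonparametric sign test used to compare two methods across paired
#' samples: exact zeros are dropped, and with `k` positive signs among `n`
#' nonzero differences the two-sided p-value is
#' `min(1, 2 * min(P(X <= k), P(X >= k)))` for `X ~ Binomial(n, 1/2)`.
#' Exact binomial tails, no normal approximation.
#'
#' @param deltas Numeric vector of paired differences with at least one
#'   nonzero entry.
#' @return A list with `p_value`, `n` (nonzero pairs), `n_positive`,
#'   `n_negative`, `n_zero`.
#' @examples
#' sign_test(rep(1, 10))$p_value  # 2 * 0.5^10 = 0.001953125
#' @export
sign_test <- function(deltas) {
  if (!is.numeric(deltas) || length(deltas) == 0L || anyNA(deltas)) {
    stop_ampliko("`deltas` must be a nonempty numeric vector without NA",
                 "ampliko_bad_input")
  }
  n_zero <- sum(deltas == 0)
  nonzero <- deltas[deltas != 0]
  n <- length(nonzero)
  if (n == 0L) {
    stop_ampliko("no nonzero differences: sign test undefined",
                 "ampliko_all_zero_differences")
  }
  k <- sum(nonzero > 0)
  # exact binomial tails as coefficient sums: choose() and 2^n are exact
  # doubles for any realistic number of paired samples
  lower <- sum(choose(n, 0:k)) / 2^n    # P(X <= k)
  upper <- sum(choose(n, k:n)) / 2^n    # P(X >= k)
  list(
    p_value = min(1, 2 * min(lower, upper)),
    n = n,
    n_positive = k,
    n_negative = n - k,
    n_zero = n_zero
  )
}

#' Evaluate predictions against paired shotgun metagenome profiles
#'
#' The evaluation protocol for paired amplicon/shotgun datasets: for every
#' shared sample, zero dimensions are excluded and the Spearman correlation
#' between the predicted and the metagenome-derived relative KO profile is
#' computed; the dataset summary is the median coefficient. When a competitor
#' method's predictions are supplied, per-sample coefficient differences
#' (method minus competitor) are tested with the exact [sign_test()].
#'
#' @param predictions,metagenomes Named lists of KO-kind
#'   [abundance_profile()]s; names are sample ids. Samples are matched by
#'   name; the shared set must be nonempty.
#' @param competitor Optional named list of KO profiles from a competing
#'   method, for the paired sign test.
#' @param exclusion_scope `"pair"` (default) excludes zero dimensions per
#'   sample pair; `"dataset"` pools the retained-dimension set over all
#'   shared samples of the dataset first.
#' @return An `evaluation_report`: list with `samples` (per-sample tibble),
#'   `median_rho`, `median_rho_competitor` and `sign_test` (both `NULL`
#'   without a competitor), `exclusion_scope`.
#' @export
evaluate_paired <- function(predictions, metagenomes, competitor = NULL,
                            exclusion_scope = c("pair", "dataset")) {
  exclusion_scope <- match.arg(exclusion_scope)
  check_profile_list(predictions, "predictions")
  check_profile_list(metagenomes, "metagenomes")
  shared <- intersect(names(predictions), names(metagenomes))
  if (length(shared) == 0L) {
    stop_ampliko("no shared sample ids between predictions and metagenomes",
                 "ampliko_no_shared_samples")
  }
  if (!is.null(competitor)) {
    check_profile_list(competitor, "competitor")
    shared <- intersect(shared, names(competitor))
    if (length(shared) == 0L) {
      stop_ampliko("no sample ids shared with the competitor",
                   "ampliko_no_shared_samples")
    }
  }
  shared <- lex_sort(shared)

  pooled_dims <- NULL
  if (exclusion_scope == "dataset") {
    nonzero_ids <- function(p) p$feature_id[p$abundance != 0]
    pooled_dims <- lex_sort(unique(c(
      unlist(lapply(predictions[shared], nonzero_ids)),
      unlist(lapply(metagenomes[shared], nonzero_ids))
    )))
  }

  rho_one <- function(pred, meta) {
    if (exclusion_scope == "pair") {
      kept <- exclude_zero_dims(pred, meta)
    } else {
      aligned <- align_features(pred, meta)
      kept <- aligned[aligned$feature_id %in% pooled_dims, ]
      if (nrow(kept) < 2L) {
        stop_ampliko("fewer than 2 pooled dimensions retained",
                     "ampliko_too_few_dims")
      }
    }
    c(rho = spearman_rho(kept$value_a, kept$value_b), dims = nrow(kept))
  }

  per_sample <- purrr::map(shared, function(s) {
    main <- rho_one(predictions[[s]], metagenomes[[s]])
    row <- tibble(sample_id = s, rho = unname(main["rho"]),
                  dims_used = as.integer(main["dims"]))
    if (!is.null(competitor)) {
      comp <- rho_one(competitor[[s]], metagenomes[[s]])
      row$rho_competitor <- unname(comp["rho"])
      row$delta <- row$rho - row$rho_competitor
    }
    row
  }) |> dplyr::bind_rows()

  st <- NULL
  if (!is.null(competitor)) {
    st <- sign_test(per_sample$delta)
  }
  structure(
    list(
      samples = per_sample,
      median_rho = median(per_sample$rho),
      median_rho_competitor =
        if (is.null(competitor)) NULL else median(per_sample$rho_competitor),
      sign_test = st,
      exclusion_scope = exclusion_scope
    ),
    class = "evaluation_report"
  )
}

check_profile_list <- function(x, what) {
  ok <- is.list(x) && length(x) > 0 && !is.null(names(x)) &&
    all(names(x) != "") &&
    all(vapply(x, inherits, logical(1), "abundance_profile")) &&
    all(vapply(x, profile_kind, character(1)) == "ko")
  if (!ok) {
    stop_ampliko(sprintf("`%s` must be a named list of 'ko' abundance profiles",
                         what), "ampliko_bad_input")
  }
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d samples, median rho = %.4f%s>\n",
              nrow(x$samples), x$median_rho,
              if (!is.null(x$sign_test))
                sprintf(", sign-test p = %.3g", x$sign_test$p_value) else ""))
  invisible(x)
}

#' @describeIn evaluate_paired Per-sample correlation table.
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$samples

#' @describeIn evaluate_paired One-row dataset summary.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    median_rho = x$median_rho,
    median_rho_competitor = x$median_rho_competitor %||% NA_real_,
    sign_test_p = if (is.null(x$sign_test)) NA_real_ else x$sign_test$p_value,
    exclusion_scope = x$exclusion_scope
  )
}

#' @describeIn evaluate_paired Box plot of per-sample Spearman coefficients
#'   (method vs competitor when present).
#' @param object An `evaluation_report`.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- object$samples |>
    dplyr::select(dplyr::any_of(c("sample_id", "rho", "rho_competitor"))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "method", values_to = "rho") |>
    dplyr::mutate(method = dplyr::recode(.data$method, rho = "this method",
                                         rho_competitor = "competitor"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$rho)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Spearman correlation",
                  title = "Predicted vs metagenome KO profiles")
}
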