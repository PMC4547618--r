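# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (exhaustive enumeration,
# explicit loops, closed forms) and never calls the code path under test.

lex_better_triple <- function(a, b) {
  # maximize score, then matches, then minimize columns
  a[1] > b[1] || (a[1] == b[1] && (a[2] > b[2] ||
    (a[2] == b[2] && a[3] < b[3])))
}

# Exhaustive enumeration of every global alignment (exponential; short
# sequences only). Returns matches/columns of the alignment selected by the
# declared tie-break rule.
brute_force_identity <- function(sa, sb, match = 1, mismatch = -1, gap = -1) {
  A <- strsplit(toupper(chartr("uU", "tT", sa)), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(chartr("uU", "tT", sb)), "", fixed = TRUE)[[1]]
  best <- NULL
  rec <- function(i, j, score, matches, columns) {
    if (i > length(A) && j > length(B)) {
      cand <- c(score, matches, columns)
      if (is.null(best) || lex_better_triple(cand, best)) best <<- cand
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      is_m <- A[i] == B[j] && A[i] %in% c("A", "C", "G", "T")
      rec(i + 1, j + 1, score + if (is_m) match else mismatch,
          matches + is_m, columns + 1)
    }
    if (i <= length(A)) rec(i + 1, j, score + gap, matches, columns + 1)
    if (j <= length(B)) rec(i, j + 1, score + gap, matches, columns + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  best[2] / best[3]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Mid-ranks and Pearson by explicit loops: an independent Spearman route.
midranks <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

spearman_oracle <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Closed-form exact two-sided sign test via binomial coefficient sums.
sign_test_oracle <- function(n_positive, n) {
  lower <- sum(choose(n, 0:n_positive)) / 2^n
  upper <- sum(choose(n, n_positive:n)) / 2^n
  min(1, 2 * min(lower, upper))
}

# Hand-built 3-organism toy universe: marker references are exact copies of
# the genome 16S sequences, KO contents and copy numbers are small and easy
# to recompute on paper.
toy_inputs <- function(seed = 101, seq_length = 120) {
  seqs <- ampliko:::with_seed(seed, {
    setNames(vapply(1:3, function(i) random_dna(seq_length), character(1)),
             c("org01", "org02", "org03"))
  })
  list(
    marker_sequences = setNames(unname(seqs), c("ref01", "ref02", "ref03")),
    genome_sequences = seqs,
    ko_counts = tibble::tibble(
      organism_id = c("org01", "org01", "org02", "org02", "org03", "org03"),
      ko_id = c("K00001", "K00002", "K00002", "K00003", "K00003", "K00004"),
      count = c(3, 1, 2, 2, 1, 4)
    ),
    copy_numbers = tibble::tibble(
      organism_id = c("org01", "org02", "org03"),
      copy_number = c(1L, 2L, 4L)
    )
  )
}

toy_database <- function(min_identity = 0.97, ...) {
  inp <- toy_inputs(...)
  assemble_database(inp$marker_sequences, inp$genome_sequences,
                    inp$ko_counts, inp$copy_numbers,
                    min_identity = min_identity)
}

# Association matrix with hand-set weights, bypassing the aligner.
manual_association <- function(weights_matrix, min_identity = 0.97) {
  ampliko:::new_association_matrix(
    methods::as(Matrix::Matrix(weights_matrix, sparse = TRUE), "CsparseMatrix"),
    min_identity
  )
}
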