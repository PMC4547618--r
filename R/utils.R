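# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable lexicographic order, independent of the session locale.
lex_sort <- function(x) x[order(x, method = "radix")]

lex_order <- function(x) order(x, method = "radix")

# Cheap deterministic provenance fingerprint for in-memory inputs.
fingerprint <- function(x) {
  v <- unlist(x, use.names = TRUE)
  sprintf("n=%d;sum=%s;names=%s", length(v),
          format(sum(suppressWarnings(as.numeric(v))[is.finite(suppressWarnings(as.numeric(v)))]),
                 digits = 17),
          substr(paste(names(v), collapse = ","), 1L, 64L))
}

# Full-precision serialization of doubles: 17 significant digits survive a
# write/read round trip exactly.
format_full <- function(x) sprintf("%.17g", x)

stop_ampliko <- function(message, class, ...) {
  abort(message, class = c(class, "ampliko_error"), ...)
}
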