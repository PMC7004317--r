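# Internal helpers shared across modules.

# Gene symbols are upper-cased on ingest everywhere so that labels coming from
# expression files, edge lists and gene-set files agree on case.
norm_symbols <- function(x) toupper(trimws(as.character(x)))

# Run code under a local RNG state seeded from `seed`; the caller's RNG stream
# is left untouched. `offset` derives independent sub-streams per component
# from one global seed.
with_local_seed <- function(seed, code, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, format(x)))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, min = 0, max = 1)

# Canonical unordered pair representation: gene_1 < gene_2 lexicographically.
order_pairs <- function(df) {
  swap <- df$gene_1 > df$gene_2
  if (any(swap)) {
    tmp <- df$gene_1[swap]
    df$gene_1[swap] <- df$gene_2[swap]
    df$gene_2[swap] <- tmp
  }
  df
}
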