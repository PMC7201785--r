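# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer.", class = "tonguetherm_error_input")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-unit sub-seed that stays inside the 32-bit integer range.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(i) * 7L
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
      class = "tonguetherm_error_input"
    )
  }
  invisible(x)
}

# Truncate (not round) to `k` decimals; the convention used for printed
# percentage metrics (e.g. 130/140 = 92.857... -> 92.85).
truncate_decimals <- function(x, k = 2L) {
  trunc(x * 10^k) / 10^k
}

is_rgb_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}
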