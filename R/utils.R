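# Internal helpers: seed substreams and input checks.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from one integer master seed through
#' named substreams (e.g. `"interactome"`, `"baits"`, or a query-set name), so
#' that components are independently reproducible and multi-set results do not
#' depend on the order in which sets are processed. The derivation is a
#' polynomial rolling hash of the label folded into the master seed, reduced
#' modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the substream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42L, "interactome")
#' derive_seed(42L, "baits")
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run `expr` with the RNG seeded from (seed, stream), restoring the caller's
# RNG state afterwards so package functions never disturb the global stream.
with_substream <- function(seed, stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(expr)
}

check_string_ids <- function(x, what) {
  x <- trimws(as.character(x))
  if (any(is.na(x)) || any(!nzchar(x))) {
    abort(sprintf("empty or missing %s identifier", what))
  }
  x
}

check_count <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", what, min))
  }
  as.integer(x)
}
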