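# Bait-usage-matched candidate pools: exact-count matching with an ordered
# widening rule for rare bait counts.

#' Configuration of the matched randomization test
#'
#' @param min_pool Candidate pools must *exceed* this size before widening
#'   stops (strict comparison, so the default 4 demands at least 5
#'   candidates).
#' @param widening_windows Ordered, strictly increasing window sizes applied
#'   when fewer than `min_pool + 1` exact-count candidates exist. Defaults to
#'   `c(20, 150, 250)`.
#' @param window_mode `"multiplicative"`: a window `w` around bait count `b`
#'   admits candidates with counts in `[b/w, b*w]` (the literal reading of
#'   "tested 20 times more or less often"); `"additive"`: counts within
#'   `b - w .. b + w`. The mode is echoed in every result. For `b = 0` the
#'   multiplicative window degenerates and is taken as `[0, w]`.
#' @param statistic Set-level statistic, `"mean"` (default) or `"median"`
#'   degree.
#' @param n_randomizations Number of matched random sets (default 10000).
#' @param seed Integer master seed; all randomness derives from it via named
#'   substreams (see [derive_seed()]).
#' @param within_set_replacement `"with"` (default): each query protein's
#'   replacement is an independent uniform draw from its pool, so the null
#'   variance matches the sampling variance of a set of distinct proteins;
#'   `"without"`: replacements within one randomized set are distinct
#'   (falling back to a duplicate, with a warning, when a pool is exhausted),
#'   which narrows the null when query strata are sizable fractions of their
#'   pools.
#' @param tail `"strict"`: empirical p is the fraction of null statistics
#'   strictly larger than the observed one (p = 0 is possible);
#'   `"plus-one"`: `(#\{null >= observed\} + 1) / (N + 1)`, which cannot be 0
#'   and is the conservative choice at small N.
#' @param alpha Significance level used for flags in [multi_set_test()].
#' @return A list of class `matching_config`.
#' @export
matching_config <- function(min_pool = 4L,
                            widening_windows = c(20, 150, 250),
                            window_mode = c("multiplicative", "additive"),
                            statistic = c("mean", "median"),
                            n_randomizations = 10000L,
                            seed = 1L,
                            within_set_replacement = c("with", "without"),
                            tail = c("strict", "plus-one"),
                            alpha = 0.05) {
  min_pool <- check_count(min_pool, "min_pool", min = 1L)
  if (length(widening_windows) < 1L || any(diff(widening_windows) <= 0)) {
    abort("`widening_windows` must be strictly increasing")
  }
  structure(list(
    min_pool = min_pool,
    widening_windows = as.numeric(widening_windows),
    window_mode = match.arg(window_mode),
    statistic = match.arg(statistic),
    n_randomizations = check_count(n_randomizations, "n_randomizations", 1L),
    seed = check_count(seed, "seed"),
    within_set_replacement = match.arg(within_set_replacement),
    tail = match.arg(tail),
    alpha = alpha
  ), class = "matching_config")
}

window_bounds <- function(b, w, mode) {
  if (mode == "multiplicative") {
    if (b == 0) c(0, w) else c(b / w, b * w)
  } else {
    c(b - w, b + w)
  }
}

#' Build the candidate index for a query set
#'
#' For each distinct bait count among the query proteins, resolves the pool
#' of candidate replacements: tier 0 is the set of non-query proteins tested
#' as baits *exactly* that often; when a tier's pool does not exceed
#' `min_pool` candidates, the window is widened through
#' `config$widening_windows` (tier 1, 2, ...). Query-set members never appear
#' in any pool. If even the widest window leaves the pool at or below
#' `min_pool`, the widest pool is used with a warning (an error only if it is
#' empty).
#'
#' @param baits A [bait_table()]; the candidate universe is every protein in
#'   it except the query (and `exclude_extra`).
#' @param query A [query_set()] or character vector. Query proteins without
#'   bait information are ignored here (the test drops them with a report).
#' @param config A [matching_config()].
#' @param exclude_extra Optional character vector of additional proteins to
#'   exclude from all pools (e.g. members of other disease sets).
#' @return A tibble of class `candidate_index` with columns `bait_count`,
#'   `tier`, `pool_size` and `pool` (list-column of identifiers); the query
#'   name, per-protein counts and config are carried as attributes.
#' @export
build_candidate_index <- function(baits, query, config = matching_config(),
                                  exclude_extra = NULL) {
  stopifnot(inherits(baits, "bait_table"), inherits(config, "matching_config"))
  query <- as_query_set(query)
  drop <- c(query$proteins, exclude_extra)
  cand <- baits[!baits$protein %in% drop, ]
  if (nrow(cand) == 0L) abort("candidate universe is empty")
  q_counts <- bait_count(baits, query$proteins)
  used <- !is.na(q_counts)
  counts <- sort(unique(q_counts[used]))
  rows <- purrr::map_dfr(counts, function(b) {
    pool <- cand$protein[cand$bait_count == b]
    tier <- 0L
    for (w in config$widening_windows) {
      if (length(pool) > config$min_pool) break
      tier <- tier + 1L
      bounds <- window_bounds(b, w, config$window_mode)
      pool <- cand$protein[cand$bait_count >= bounds[1L] &
                             cand$bait_count <= bounds[2L]]
    }
    if (length(pool) == 0L) {
      abort(sprintf("no candidates for bait count %d even at the widest window", b))
    }
    if (length(pool) <= config$min_pool) {
      warn(sprintf(
        "pool for bait count %d has only %d candidate(s) at the widest window",
        b, length(pool)
      ))
    }
    tibble(bait_count = b, tier = tier, pool_size = length(pool),
           pool = list(pool))
  })
  structure(rows,
            class = c("candidate_index", class(tibble())),
            query_name = query$name,
            query_counts = tibble(protein = query$proteins[used],
                                  bait_count = q_counts[used]),
            dropped = query$proteins[!used],
            config = config)
}

#' Draw one bait-usage-matched random set
#'
#' Replaces each (bait-annotated) query protein with a candidate drawn
#' uniformly from the pool resolved for its bait count. Under
#' `within_set_replacement = "without"` the replacements within the set are
#' distinct; when overlapping widened pools make that impossible, a duplicate
#' is kept and a warning is raised once.
#'
#' @param index A [build_candidate_index()] result.
#' @return Character vector of replacement identifiers, one per matched query
#'   protein (possibly with duplicates under `"with"` or pool exhaustion).
#' @note The draw consumes the current RNG state; seed it (or use
#'   [randomization_test()], which manages seeding) for reproducibility.
#' @export
sample_matched_set <- function(index) {
  stopifnot(inherits(index, "candidate_index"))
  sampler <- matched_sampler(index)
  sampler()
}

# Closure performing one matched draw; shared by sample_matched_set and the
# randomization loop so the sampling code exists once.
matched_sampler <- function(index) {
  config <- attr(index, "config")
  q_counts <- attr(index, "query_counts")$bait_count
  grp <- match(q_counts, index$bait_count)
  k_per_pool <- tabulate(grp, nbins = nrow(index))
  pools <- index$pool
  pool_sizes <- index$pool_size
  distinct <- config$within_set_replacement == "without"
  warned <- FALSE
  function() {
    picks <- vector("list", length(pools))
    for (i in seq_along(pools)) {
      k <- k_per_pool[i]
      if (k == 0L) next
      if (distinct && k <= pool_sizes[i]) {
        picks[[i]] <- pools[[i]][sample.int(pool_sizes[i], k)]
      } else {
        if (distinct && !warned) {
          warn(sprintf(
            "pool for bait count %d exhausted (%d needed, %d available); allowing duplicates",
            index$bait_count[i], k, pool_sizes[i]
          ))
          warned <<- TRUE
        }
        picks[[i]] <- pools[[i]][sample.int(pool_sizes[i], k, replace = TRUE)]
      }
    }
    out <- unlist(picks, use.names = FALSE)
    if (distinct && anyDuplicated(out)) {
      # cross-pool collisions possible when widened pools overlap
      for (j in which(duplicated(out))) {
        pool_j <- pools[[min(which(cumsum(k_per_pool) >= j))]]
        alt <- setdiff(pool_j, out)
        if (length(alt) > 0L) {
          out[j] <- alt[sample.int(length(alt), 1L)]
        } else if (!warned) {
          warn("overlapping pools exhausted; allowing a duplicate replacement")
          warned <<- TRUE
        }
      }
    }
    out
  }
}
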