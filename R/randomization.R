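# The core method: empirical significance of a query set's degree given its
# bait usage, via bait-usage-matched random sets.

#' Bait-usage-matched randomization test
#'
#' Decides whether a protein set has more interaction partners than expected
#' given how often its members were tested as baits. Each query protein
#' (after dropping those without bait information) is replaced by a random
#' non-query protein with equal — or, through the widening rule, similar —
#' bait usage; the set-level statistic (mean or median degree) of
#' `n_randomizations` such matched sets forms the null distribution, and the
#' empirical p-value is the fraction of null statistics larger than the
#' observed one. Query proteins present in the bait table but absent from the
#' network count with degree 0 (tested, nothing found).
#'
#' @param network A [ppi_network()].
#' @param baits A [bait_table()].
#' @param query A [query_set()] or character vector of identifiers.
#' @param config A [matching_config()].
#' @param exclude_extra Optional identifiers additionally excluded from
#'   candidate pools.
#' @return An object of class `bm_randomization`: a list with `query`,
#'   `m_used`, `m_dropped`, `dropped` (identifiers without bait info),
#'   `observed` (the observed statistic), `null_stats` (length-N numeric),
#'   `p_value` (per `config$tail`), `n_greater`, `n_ties`, `log2_ratios`
#'   (`log2(observed / null)`, `NA` where a null statistic is 0), `index`
#'   (the [build_candidate_index()] used) and `config`.
#' @seealso [multi_set_test()] for many query sets, [tidy.bm_randomization()]
#'   and [autoplot.bm_randomization()].
#' @export
randomization_test <- function(network, baits, query,
                               config = matching_config(),
                               exclude_extra = NULL) {
  stopifnot(inherits(network, "ppi_network"), inherits(baits, "bait_table"),
            inherits(config, "matching_config"))
  query <- as_query_set(query)
  info <- has_bait_info(baits, query$proteins)
  used <- query$proteins[info]
  dropped <- query$proteins[!info]
  if (length(used) == 0L) {
    abort(sprintf(
      "no query protein has bait information (dropped: %s)",
      paste(head(dropped, 10L), collapse = ", ")
    ))
  }
  stat_fun <- if (config$statistic == "mean") mean else median
  deg_lookup <- setNames(network$degree$degree, network$degree$protein)
  degree_of <- function(ids) {
    d <- unname(deg_lookup[ids])
    d[is.na(d)] <- 0L
    d
  }
  observed <- stat_fun(degree_of(used))
  index <- build_candidate_index(baits, query, config,
                                 exclude_extra = exclude_extra)
  sampler <- matched_sampler(index)
  n <- config$n_randomizations
  null_stats <- with_substream(config$seed, paste0("randomize/", query$name), {
    vapply(seq_len(n), function(i) stat_fun(degree_of(sampler())), numeric(1L))
  })
  n_greater <- sum(null_stats > observed)
  n_ties <- sum(null_stats == observed)
  p_value <- switch(config$tail,
    strict = n_greater / n,
    `plus-one` = (n_greater + n_ties + 1) / (n + 1)
  )
  l2 <- suppressWarnings(log2(observed / null_stats))
  l2[!is.finite(l2)] <- NA_real_
  n_undef <- sum(is.na(l2))
  if (n_undef > 0L) {
    inform(sprintf(
      "%d log2 ratio(s) undefined (zero statistic) and excluded from summaries",
      n_undef
    ))
  }
  structure(list(
    query = query$name,
    m_used = length(used),
    m_dropped = length(dropped),
    dropped = dropped,
    observed = observed,
    null_stats = null_stats,
    p_value = p_value,
    n_greater = n_greater,
    n_ties = n_ties,
    log2_ratios = l2,
    index = index,
    config = config
  ), class = "bm_randomization")
}

#' @export
print.bm_randomization <- function(x, ...) {
  cat(sprintf("<bm_randomization> query '%s'\n", x$query))
  cat(sprintf("  %d proteins used (%d dropped, no bait info)\n",
              x$m_used, x$m_dropped))
  cat(sprintf("  observed %s degree: %.4g; null mean: %.4g\n",
              x$config$statistic, x$observed, mean(x$null_stats)))
  cat(sprintf("  empirical p (%s tail rule, N = %d): %.4g\n",
              x$config$tail, length(x$null_stats), x$p_value))
  invisible(x)
}

#' Tidy the null distribution of a randomization test
#'
#' @param x A `bm_randomization` object.
#' @param ... Unused.
#' @return A tibble with one row per randomization: `draw`, `null_stat`,
#'   `log2_ratio`.
#' @exportS3Method generics::tidy
tidy.bm_randomization <- function(x, ...) {
  tibble(draw = seq_along(x$null_stats),
         null_stat = x$null_stats,
         log2_ratio = x$log2_ratios)
}

#' One-row summary of a randomization test
#'
#' @param x A `bm_randomization` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.bm_randomization <- function(x, ...) {
  l2 <- x$log2_ratios[!is.na(x$log2_ratios)]
  tibble(
    query = x$query,
    m_used = x$m_used,
    m_dropped = x$m_dropped,
    statistic = x$config$statistic,
    observed = x$observed,
    null_mean = mean(x$null_stats),
    p_value = x$p_value,
    log2_median = if (length(l2)) median(l2) else NA_real_,
    log2_q1 = if (length(l2)) quantile(l2, 0.25, names = FALSE) else NA_real_,
    log2_q3 = if (length(l2)) quantile(l2, 0.75, names = FALSE) else NA_real_,
    n_randomizations = length(x$null_stats),
    tail = x$config$tail,
    window_mode = x$config$window_mode
  )
}

#' Histogram of the matched null distribution
#'
#' @param object A `bm_randomization` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot: null distribution of the set statistic with the observed
#'   value as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.bm_randomization <- function(object, bins = 40, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      x = sprintf("%s degree of matched random sets", object$config$statistic),
      y = "count",
      title = sprintf("'%s': observed %.3g, empirical p = %.3g",
                      object$query, object$observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Matched randomization tests for many query sets
#'
#' Runs [randomization_test()] for each query set with an independent seed
#' substream derived from the master seed and the set *name* (so results do
#' not depend on the order of the sets). One failing set does not abort the
#' rest: its row carries `NA` values and the error message.
#'
#' @inheritParams randomization_test
#' @param queries A list of [query_set()]s (or character vectors; unnamed
#'   vectors get names `set1`, `set2`, ...).
#' @param adjust_p If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `p_adj` (no adjustment is applied by default).
#' @return A list of class `bm_multi` with `results` (named list of
#'   `bm_randomization`, or a `bm_failure` stub holding the error message for
#'   sets that failed) and `table` — a tibble with
#'   one row per set: `query`, `m_used`, `observed`, `null_mean`, `p_value`,
#'   `log2_median`, `log2_q1`, `log2_q3`, `significant` (p < alpha), `error`.
#' @export
multi_set_test <- function(network, baits, queries,
                           config = matching_config(),
                           exclude_extra = NULL, adjust_p = FALSE) {
  if (inherits(queries, "query_set")) queries <- list(queries)
  queries <- purrr::imap(queries, function(q, i) {
    as_query_set(q, name = if (is.character(i) && nzchar(i)) i
                 else paste0("set", i))
  })
  names(queries) <- purrr::map_chr(queries, "name")
  results <- purrr::map(queries, function(q) {
    tryCatch(
      randomization_test(network, baits, q, config = config,
                         exclude_extra = exclude_extra),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "bm_failure")
    )
  })
  table <- purrr::map_dfr(names(results), function(nm) {
    r <- results[[nm]]
    if (inherits(r, "bm_failure")) {
      tibble(query = nm, m_used = NA_integer_, m_dropped = NA_integer_,
             observed = NA_real_, null_mean = NA_real_, p_value = NA_real_,
             log2_median = NA_real_, log2_q1 = NA_real_, log2_q3 = NA_real_,
             significant = NA, error = r$message)
    } else {
      g <- glance(r)
      tibble(query = g$query, m_used = g$m_used, m_dropped = g$m_dropped,
             observed = g$observed, null_mean = g$null_mean,
             p_value = g$p_value, log2_median = g$log2_median,
             log2_q1 = g$log2_q1, log2_q3 = g$log2_q3,
             significant = g$p_value < config$alpha, error = NA_character_)
    }
  })
  if (adjust_p) table$p_adj <- p.adjust(table$p_value, method = "BH")
  structure(list(results = results, table = table, config = config),
            class = "bm_multi")
}

#' @export
print.bm_multi <- function(x, ...) {
  cat(sprintf("<bm_multi> %d query sets (alpha = %g, %s statistic)\n",
              nrow(x$table), x$config$alpha, x$config$statistic))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bm_multi <- function(x, ...) x$table

#' Per-set log2 degree-enrichment distributions
#'
#' @param object A `bm_multi` object.
#' @param ... Unused.
#' @return A ggplot: one boxplot of `log2(observed / null)` per query set,
#'   filled by significance at the configured alpha.
#' @exportS3Method ggplot2::autoplot
autoplot.bm_multi <- function(object, ...) {
  ok <- !purrr::map_lgl(object$results, inherits, "bm_failure")
  df <- purrr::map_dfr(object$results[ok], function(r) {
    tibble(query = r$query, log2_ratio = r$log2_ratios)
  })
  df <- df[!is.na(df$log2_ratio), ]
  sig <- setNames(object$table$significant, object$table$query)
  df$significant <- unname(sig[df$query])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query, y = .data$log2_ratio,
                                   fill = .data$significant)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey80"),
                               na.value = "grey95") +
    ggplot2::labs(x = NULL, y = "log2(observed / matched-null degree)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
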