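# Study-bias quantification: degree vs study-frequency correlation with a
# Fisher-Z confidence interval, quartile summaries of the coupling, and the
# uncorrected rank-sum group comparison.

#' Pearson correlation with a Fisher-Z confidence interval
#'
#' Product-moment correlation of two numeric sequences, optionally after a
#' `log1p` transform of both (interaction degrees and study counts are heavily
#' right-skewed, so the log scale is the default elsewhere in the package).
#' The p-value comes from the t statistic `r * sqrt((n-2)/(1-r^2))` and the
#' confidence interval from Fisher's Z transform,
#' `tanh(atanh(r) +/- z_crit / sqrt(n-3))`.
#'
#' @param x,y Equal-length numeric vectors; pairs with a missing value in
#'   either are dropped (with a message).
#' @param transform `"identity"` or `"log1p"` (applied to both sequences;
#'   requires non-negative values).
#' @param conf_level Confidence level for the Fisher-Z interval.
#' @return A one-row tibble: `estimate` (r), `n`, `statistic` (t), `p_value`,
#'   `conf_low`, `conf_high`, `transform`, `conf_level`.
#' @examples
#' pearson_with_ci(1:10, (1:10)^2)
#' @export
pearson_with_ci <- function(x, y, transform = c("identity", "log1p"),
                            conf_level = 0.95) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- !is.na(x) & !is.na(y)
  if (sum(!keep) > 0L) {
    inform(sprintf("dropped %d pair(s) with missing values", sum(!keep)))
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) abort("need at least 4 complete pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite")
  if (transform == "log1p") {
    if (any(x < 0) || any(y < 0)) abort("log1p transform requires non-negative values")
    x <- log1p(x); y <- log1p(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: constant sequence")
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble(
    estimate = unname(ct$estimate),
    n = length(x),
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    conf_low = ct$conf.int[1L],
    conf_high = ct$conf.int[2L],
    transform = transform,
    conf_level = conf_level
  )
}

#' Correlate protein degree with bait usage and/or total study count
#'
#' @param network A [ppi_network()].
#' @param baits A [bait_table()].
#' @param covariate `"bait"`, `"study"` or `"both"`. Proteins lacking the
#'   covariate are dropped pairwise.
#' @param transform,conf_level Passed to [pearson_with_ci()].
#' @return A tibble with one row per covariate (`covariate` column first).
#' @export
correlate_degree_usage <- function(network, baits,
                                   covariate = c("bait", "study", "both"),
                                   transform = c("log1p", "identity"),
                                   conf_level = 0.95) {
  covariate <- match.arg(covariate)
  transform <- match.arg(transform)
  stopifnot(inherits(network, "ppi_network"), inherits(baits, "bait_table"))
  wanted <- if (covariate == "both") c("bait", "study") else covariate
  deg <- node_degrees(network)
  merged <- dplyr::left_join(deg, baits, by = "protein")
  purrr::map_dfr(wanted, function(cv) {
    v <- if (cv == "bait") merged$bait_count else merged$study_count
    res <- pearson_with_ci(merged$degree, v, transform = transform,
                           conf_level = conf_level)
    dplyr::bind_cols(tibble(covariate = cv), res)
  })
}

#' Quartile summary of covariates along the degree distribution
#'
#' Ranks proteins by a primary value (typically degree), splits them at the
#' empirical 25/50/75 percentiles into quartile groups 1.Q-4.Q, and summarises
#' one or more covariates (bait count, total study count) within each group.
#' Ties at a percentile boundary all go to the lower quartile; if ties are so
#' extensive that fewer than four non-empty groups remain, the result is
#' flagged degenerate rather than erroring.
#'
#' @param data A data frame with a `protein` column, the primary column and
#'   the covariate columns. Rows with a missing covariate are dropped with a
#'   message.
#' @param primary Name of the primary (ranking) column, default `"degree"`.
#' @param covariates Character vector of covariate column names.
#' @return A tibble with columns `quartile`, `n`, `covariate`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`; attribute `degenerate` is `TRUE` when the
#'   split produced fewer than 4 groups.
#' @export
quartile_summary <- function(data, primary = "degree",
                             covariates = "bait_count") {
  data <- as_tibble(data)
  if (nrow(data) == 0L) abort("empty input")
  if (!primary %in% names(data)) abort(sprintf("no column `%s`", primary))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    abort(sprintf("no covariate column(s): %s", paste(missing_cov, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, c(primary, covariates)])
  if (any(!keep)) {
    inform(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    data <- data[keep, ]
  }
  if (nrow(data) == 0L) abort("empty input after dropping missing values")
  v <- data[[primary]]
  cuts <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  q <- 1L + (v > cuts[1L]) + (v > cuts[2L]) + (v > cuts[3L])
  data$quartile <- paste0(q, ".Q")
  degenerate <- length(unique(q)) < 4L
  if (degenerate) {
    warn("degenerate quartile split: extensive ties in the primary value")
  }
  out <- purrr::map_dfr(covariates, function(cv) {
    data |>
      dplyr::group_by(.data$quartile) |>
      dplyr::summarise(
        n = dplyr::n(),
        covariate = cv,
        min = min(.data[[cv]]),
        q1 = quantile(.data[[cv]], 0.25, names = FALSE),
        median = median(.data[[cv]]),
        q3 = quantile(.data[[cv]], 0.75, names = FALSE),
        max = max(.data[[cv]]),
        mean = mean(.data[[cv]]),
        .groups = "drop"
      )
  })
  attr(out, "degenerate") <- degenerate
  out
}

#' Wilcoxon-Mann-Whitney rank-sum comparison of two groups
#'
#' The *uncorrected* comparison of a query group's degrees against the
#' background — the contrast the matched randomization test corrects. Uses
#' exact null enumeration when the pooled sample is small (`n1 + n2 <= 20`)
#' and tie-free, and the normal approximation with midrank tie correction
#' otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"two-sided"`, `"greater"` (group_a stochastically
#'   larger) or `"less"`.
#' @return A one-row tibble: `statistic` (Mann-Whitney U for `group_a`),
#'   `p_value`, `alternative`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' rank_sum_compare(c(10, 11, 12), c(1, 2, 3), alternative = "greater")
#' @export
rank_sum_compare <- function(group_a, group_b,
                             alternative = c("two-sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  alt <- if (alternative == "two-sided") "two.sided" else alternative
  n1 <- length(group_a); n2 <- length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- (n1 + n2 <= 20L) && !has_ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = alt, exact = use_exact,
                correct = TRUE)
  )
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    alternative = alternative,
    n1 = n1,
    n2 = n2,
    method = if (use_exact) "exact" else "normal"
  )
}
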