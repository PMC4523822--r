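# Bias-normalized degree: degree divided by bait usage, split at the median,
# and Fisher exact association with a binary functional annotation.

#' Degree / bait-usage ratio table
#'
#' For each protein with a positive bait count, the ratio of its interaction
#' degree to the number of times it was tested as a bait — a rough
#' bias-normalized connectivity estimate. The half of the proteins with the
#' highest ratio (`ceiling(n/2)` of them) is flagged `top_half`; ties at the
#' boundary are broken deterministically by higher degree, then by
#' identifier. Proteins with a zero or missing bait count are listed in the
#' `excluded` attribute, never silently dropped.
#'
#' @param network A [ppi_network()].
#' @param baits A [bait_table()].
#' @param proteins Character vector (or [query_set()]) of proteins to tabulate.
#' @return A tibble of class `ratio_table` with columns `protein`, `degree`,
#'   `bait_count`, `ratio`, `top_half`, sorted by decreasing ratio; attribute
#'   `excluded` is a tibble (`protein`, `reason`).
#' @export
degree_bait_ratio <- function(network, baits, proteins) {
  stopifnot(inherits(network, "ppi_network"), inherits(baits, "bait_table"))
  if (inherits(proteins, "query_set")) proteins <- proteins$proteins
  proteins <- unique(check_string_ids(proteins, "protein"))
  bc <- bait_count(baits, proteins)
  excluded <- tibble(
    protein = proteins[is.na(bc) | bc == 0L],
    reason = ifelse(is.na(bc[is.na(bc) | bc == 0L]), "no_bait_info",
                    "zero_bait_count")
  )
  keep <- !is.na(bc) & bc >= 1L
  if (!any(keep)) abort("no protein with a positive bait count")
  deg <- node_degrees(network, proteins[keep], missing = "zero")$degree
  tab <- tibble(
    protein = proteins[keep],
    degree = deg,
    bait_count = bc[keep],
    ratio = deg / bc[keep]
  )
  ord <- order(-tab$ratio, -tab$degree, tab$protein, method = "radix")
  tab <- tab[ord, ]
  n_top <- ceiling(nrow(tab) / 2)
  tab$top_half <- seq_len(nrow(tab)) <= n_top
  if (nrow(tab) > n_top && tab$ratio[n_top] == tab$ratio[n_top + 1L]) {
    inform("tie at the median ratio broken by degree, then identifier")
  }
  structure(tab, class = c("ratio_table", class(tibble())), excluded = excluded)
}

#' One-sided (or two-sided) Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test of association in a 2x2 contingency table, rows
#' = top/bottom ratio half, columns = in/out of the functional class. For
#' `alternative = "greater"` the p-value is `P(X >= a)` for
#' `X ~ Hypergeometric` with the observed margins; the two-sided p sums the
#' probabilities of all tables no more likely than the observed one.
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative integer
#'   counts, `rbind(c(a, b), c(c, d))`.
#' @param alternative `"greater"` (default; over-representation in the first
#'   row), `"less"` or `"two-sided"`.
#' @return A one-row tibble of class `bm_fisher`: counts `a`, `b`, `c`, `d`,
#'   `odds_ratio` (conditional MLE), `p_value`, `alternative`.
#' @examples
#' fisher_exact_2x2(rbind(c(3, 0), c(0, 3)))  # p = 1/choose(6,3) = 0.05
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("greater", "less", "two-sided")) {
  alternative <- match.arg(alternative)
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) abort("`table` must be 2x2")
  if (anyNA(m) || !is.numeric(m) || any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (sum(m) == 0) abort("at least one count must be positive")
  storage.mode(m) <- "integer"
  alt <- if (alternative == "two-sided") "two.sided" else alternative
  ft <- fisher.test(m, alternative = alt)
  structure(tibble(
    a = m[1L, 1L], b = m[1L, 2L], c = m[2L, 1L], d = m[2L, 2L],
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    alternative = alternative
  ), class = c("bm_fisher", class(tibble())))
}

#' Association between the top ratio half and a functional annotation
#'
#' Builds the 2x2 table (top/bottom ratio half vs annotated/not) from a
#' [degree_bait_ratio()] table and a binary [annotation_table()], and
#' delegates to [fisher_exact_2x2()]. Every retained protein must be covered
#' by the annotation; an uncovered protein is an error naming it.
#'
#' @param ratio_table A `ratio_table`.
#' @param annotation An [annotation_table()].
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return The [fisher_exact_2x2()] result, with the underlying table as the
#'   `contingency` attribute for auditability.
#' @export
annotation_association <- function(ratio_table, annotation,
                                   alternative = c("greater", "less",
                                                   "two-sided")) {
  stopifnot(inherits(ratio_table, "ratio_table"))
  ann <- annotation_lookup(annotation, ratio_table$protein)
  tab <- rbind(
    c(sum(ratio_table$top_half & ann), sum(ratio_table$top_half & !ann)),
    c(sum(!ratio_table$top_half & ann), sum(!ratio_table$top_half & !ann))
  )
  dimnames(tab) <- list(half = c("top", "bottom"),
                        class = c("annotated", "not_annotated"))
  res <- fisher_exact_2x2(tab, alternative = match.arg(alternative))
  attr(res, "contingency") <- tab
  res
}
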