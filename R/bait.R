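#' Bait-usage table
#'
#' The matching covariate of the randomization test: for each protein, the
#' number of distinct studies in which it was used as a bait, optionally
#' accompanied by a total study/abstract count. Absence from the table means
#' "bait usage unknown", which is deliberately distinct from a count of zero:
#' in large curated interactomes roughly half of the proteins lack bait
#' information, and imputing 0 would place never-characterised proteins into
#' the least-tested candidate pools. Proteins without bait information are
#' excluded from candidate pools and dropped from query sets (with a report).
#'
#' @param x A data frame with columns `protein`, `bait_count` and optionally
#'   `study_count`. Counts must be non-negative integers. Duplicate protein
#'   rows with identical counts collapse; conflicting duplicates are an error.
#' @return A tibble of class `bait_table` with columns `protein`,
#'   `bait_count` and (always present, possibly all-`NA`) `study_count`.
#' @examples
#' bait_table(data.frame(protein = c("P1", "P2"), bait_count = c(7, 0)))
#' @export
bait_table <- function(x) {
  x <- as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
  if (!all(c("protein", "bait_count") %in% names(x))) {
    abort("bait table needs columns `protein` and `bait_count`")
  }
  x$protein <- check_string_ids(x$protein, "protein")
  bc <- x$bait_count
  if (!is.numeric(bc) || anyNA(bc) || any(bc != round(bc)) || any(bc < 0)) {
    abort("`bait_count` must be non-negative integers")
  }
  x$bait_count <- as.integer(bc)
  if (!"study_count" %in% names(x)) {
    x$study_count <- NA_integer_
  } else if (!all(is.na(x$study_count))) {
    sc <- x$study_count
    if (!is.numeric(sc) || any(sc[!is.na(sc)] != round(sc[!is.na(sc)])) ||
        any(sc[!is.na(sc)] < 0)) {
      abort("`study_count` must be non-negative integers")
    }
    x$study_count <- as.integer(sc)
  }
  x <- dplyr::distinct(x, .data$protein, .data$bait_count, .data$study_count)
  if (anyDuplicated(x$protein)) {
    bad <- unique(x$protein[duplicated(x$protein)])
    abort(sprintf(
      "conflicting duplicate rows for protein(s): %s",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  x <- x[order(x$protein, method = "radix"), c("protein", "bait_count", "study_count")]
  class(x) <- c("bait_table", class(tibble()))
  x
}

#' Look up bait counts, distinguishing missing from zero
#'
#' @param baits A [bait_table()].
#' @param proteins Character vector of identifiers.
#' @return Integer vector aligned with `proteins`; `NA` for proteins absent
#'   from the table (bait usage unknown), `0L` only for proteins recorded with
#'   a zero count.
#' @export
bait_count <- function(baits, proteins) {
  stopifnot(inherits(baits, "bait_table"))
  proteins <- check_string_ids(proteins, "protein")
  baits$bait_count[match(proteins, baits$protein)]
}

#' @rdname bait_count
#' @export
has_bait_info <- function(baits, proteins) {
  !is.na(bait_count(baits, proteins))
}

#' Query protein set
#'
#' A named, non-empty set of unique protein identifiers — e.g. the genes
#' significantly mutated in one tumor type.
#'
#' @param proteins Character vector of identifiers (deduplicated, trimmed).
#' @param name Label for the set.
#' @return An object of class `query_set` with fields `name` and `proteins`.
#' @export
query_set <- function(proteins, name = "query") {
  proteins <- unique(check_string_ids(proteins, "protein"))
  if (length(proteins) == 0L) abort("query set is empty")
  structure(list(name = as.character(name)[1L], proteins = proteins),
            class = "query_set")
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("<query_set> %s: %d proteins\n", x$name, length(x$proteins)))
  invisible(x)
}

as_query_set <- function(x, name = "query") {
  if (inherits(x, "query_set")) x else query_set(x, name = name)
}

#' Binary functional annotation table
#'
#' Maps proteins to membership in one functional class (e.g. "involved in the
#' activation of leukocytes"). The mapping is total over the proteins it
#' covers: querying an uncovered protein is an error, never silently `FALSE`.
#'
#' @param x A data frame with columns `protein` and `annotated` (logical or
#'   0/1).
#' @return A tibble of class `annotation_table`.
#' @export
annotation_table <- function(x) {
  x <- as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
  if (!all(c("protein", "annotated") %in% names(x))) {
    abort("annotation table needs columns `protein` and `annotated`")
  }
  x$protein <- check_string_ids(x$protein, "protein")
  ann <- x$annotated
  if (is.numeric(ann)) {
    if (!all(ann %in% c(0, 1))) abort("`annotated` must be logical or 0/1")
    ann <- ann == 1
  }
  if (!is.logical(ann) || anyNA(ann)) abort("`annotated` must be logical or 0/1")
  x$annotated <- ann
  x <- dplyr::distinct(x)
  if (anyDuplicated(x$protein)) {
    abort("conflicting duplicate annotation rows")
  }
  class(x) <- c("annotation_table", class(tibble()))
  x
}

#' @rdname annotation_table
#' @param annotation An `annotation_table`.
#' @param proteins Identifiers to look up; any protein not covered by the
#'   table raises an error naming it.
#' @export
annotation_lookup <- function(annotation, proteins) {
  stopifnot(inherits(annotation, "annotation_table"))
  proteins <- check_string_ids(proteins, "protein")
  idx <- match(proteins, annotation$protein)
  if (anyNA(idx)) {
    miss <- proteins[is.na(idx)]
    abort(sprintf(
      "protein(s) not covered by annotation: %s",
      paste(head(miss, 5L), collapse = ", ")
    ))
  }
  setNames(annotation$annotated[idx], proteins)
}
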