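# Readers and writers for the package's plain-text formats:
#   edge list   — 2 columns (TAB default), optional header, '#' comments;
#                 PSI-MI TAB 2.5 dialect takes columns 1-2 and the value
#                 after the last ':' of each identifier
#   bait table  — 2-3 columns: protein, bait_count[, study_count]
#   query set   — one identifier per line; name defaults to the file stem
#   annotation  — 2 columns: protein, 0/1

read_delim_lines <- function(path, delim, comment = "#") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  list(fields = strsplit(lines[keep], delim, fixed = TRUE),
       line_no = which(keep))
}

check_n_fields <- function(parsed, n, path, what) {
  len <- lengths(parsed$fields)
  bad <- !len %in% n
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(
      "malformed %s record in %s at line %d: expected %s fields, got %d",
      what, path, parsed$line_no[i], paste(n, collapse = " or "), len[i]
    ))
  }
}

#' Read a PPI edge list
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default TAB).
#' @param header Does the file start with a header line?
#' @param format `"pairs"` for plain 2-column identifier pairs; `"psimitab"`
#'   for PSI-MI TAB 2.5, where the first two columns hold interactor A/B
#'   identifiers of the form `db:accession` and the value after the last `:`
#'   is taken.
#' @param quiet Passed to [ppi_network()].
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, delim = "\t", header = FALSE,
                           format = c("pairs", "psimitab"), quiet = FALSE) {
  format <- match.arg(format)
  parsed <- read_delim_lines(path, delim)
  if (header && length(parsed$fields) > 0L) {
    parsed$fields <- parsed$fields[-1L]
    parsed$line_no <- parsed$line_no[-1L]
  }
  if (format == "pairs") {
    check_n_fields(parsed, 2L, path, "edge")
    a <- vapply(parsed$fields, `[[`, "", 1L)
    b <- vapply(parsed$fields, `[[`, "", 2L)
  } else {
    len <- lengths(parsed$fields)
    if (any(len < 2L)) {
      i <- which(len < 2L)[1L]
      abort(sprintf(
        "malformed PSI-MI TAB record in %s at line %d: fewer than 2 columns",
        path, parsed$line_no[i]
      ))
    }
    strip_db <- function(x) sub(".*:", "", x)
    a <- strip_db(vapply(parsed$fields, `[[`, "", 1L))
    b <- strip_db(vapply(parsed$fields, `[[`, "", 2L))
  }
  ppi_network(tibble(from = a, to = b), quiet = quiet)
}

#' Write a network's edge list
#'
#' Round-trips with [read_edge_list()]: re-reading the written file yields an
#' identical node and edge set.
#'
#' @param network A [ppi_network()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_edge_list <- function(network, path, delim = "\t") {
  stopifnot(inherits(network, "ppi_network"))
  writeLines(paste(network$edges$from, network$edges$to, sep = delim), path)
  invisible(path)
}

#' Read a bait-usage table
#'
#' @inheritParams read_edge_list
#' @return A [bait_table()].
#' @export
read_bait_table <- function(path, delim = "\t", header = FALSE) {
  parsed <- read_delim_lines(path, delim)
  if (header && length(parsed$fields) > 0L) {
    parsed$fields <- parsed$fields[-1L]
    parsed$line_no <- parsed$line_no[-1L]
  }
  check_n_fields(parsed, c(2L, 3L), path, "bait-table")
  protein <- vapply(parsed$fields, `[[`, "", 1L)
  bc_raw <- vapply(parsed$fields, `[[`, "", 2L)
  bc <- suppressWarnings(as.numeric(bc_raw))
  if (anyNA(bc) || any(bc != round(bc))) {
    i <- which(is.na(bc) | bc != round(bc))[1L]
    abort(sprintf(
      "non-integer bait count %s in %s at line %d",
      dQuote(bc_raw[i]), path, parsed$line_no[i]
    ))
  }
  sc <- vapply(parsed$fields, function(f) {
    if (length(f) >= 3L) f[[3L]] else NA_character_
  }, "")
  bait_table(tibble(
    protein = protein,
    bait_count = as.integer(bc),
    study_count = suppressWarnings(as.integer(sc))
  ))
}

#' @rdname read_bait_table
#' @param baits A [bait_table()].
#' @param path Output path.
#' @export
write_bait_table <- function(baits, path, delim = "\t") {
  stopifnot(inherits(baits, "bait_table"))
  if (all(is.na(baits$study_count))) {
    writeLines(paste(baits$protein, baits$bait_count, sep = delim), path)
  } else {
    writeLines(paste(baits$protein, baits$bait_count, baits$study_count,
                     sep = delim), path)
  }
  invisible(path)
}

#' Read a query protein set (one identifier per line)
#'
#' @param path Path to the file; lines starting with `#` and blank lines are
#'   skipped.
#' @param name Set label; defaults to the file name without extension.
#' @return A [query_set()].
#' @export
read_query_set <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  query_set(lines, name = name)
}

#' @rdname read_query_set
#' @param query A [query_set()].
#' @export
write_query_set <- function(query, path) {
  query <- as_query_set(query)
  writeLines(query$proteins, path)
  invisible(path)
}

#' Read a binary annotation table (protein, 0/1)
#'
#' @inheritParams read_edge_list
#' @return An [annotation_table()].
#' @export
read_annotation <- function(path, delim = "\t", header = FALSE) {
  parsed <- read_delim_lines(path, delim)
  if (header && length(parsed$fields) > 0L) {
    parsed$fields <- parsed$fields[-1L]
    parsed$line_no <- parsed$line_no[-1L]
  }
  check_n_fields(parsed, 2L, path, "annotation")
  protein <- vapply(parsed$fields, `[[`, "", 1L)
  flag <- vapply(parsed$fields, `[[`, "", 2L)
  if (!all(flag %in% c("0", "1"))) {
    i <- which(!flag %in% c("0", "1"))[1L]
    abort(sprintf("annotation value must be 0 or 1 in %s at line %d",
                  path, parsed$line_no[i]))
  }
  annotation_table(tibble(protein = protein, annotated = flag == "1"))
}

#' Read all analysis inputs at once
#'
#' Convenience loader for the full input bundle: network, bait table, one or
#' more query sets and an optional annotation table. Also reports query
#' proteins that are absent from the bait table (no bait-usage information —
#' these are dropped by the randomization test) or absent from the network
#' (degree 0 by convention; kept).
#'
#' @param edges Path to the edge list.
#' @param baits Path to the bait table.
#' @param queries Character vector of query-set file paths.
#' @param annotation Optional path to an annotation table.
#' @param delim Field delimiter for all delimited files.
#' @param header Header flag for the delimited files.
#' @param edge_format Passed to [read_edge_list()].
#' @return A list with elements `network`, `baits`, `queries` (list of
#'   [query_set()]), `annotation` (or `NULL`) and `report` — a tibble with
#'   columns `query`, `protein`, `issue` (`"no_bait_info"` or
#'   `"not_in_network"`).
#' @export
read_inputs <- function(edges, baits, queries, annotation = NULL,
                        delim = "\t", header = FALSE,
                        edge_format = c("pairs", "psimitab")) {
  network <- read_edge_list(edges, delim = delim, header = header,
                            format = match.arg(edge_format))
  bt <- read_bait_table(baits, delim = delim, header = header)
  qs <- lapply(queries, read_query_set)
  ann <- if (!is.null(annotation)) read_annotation(annotation, delim = delim,
                                                  header = header)
  report <- purrr::map_dfr(qs, function(q) {
    dplyr::bind_rows(
      tibble(query = q$name,
             protein = q$proteins[!has_bait_info(bt, q$proteins)],
             issue = "no_bait_info"),
      tibble(query = q$name,
             protein = q$proteins[!q$proteins %in% network$nodes],
             issue = "not_in_network")
    )
  })
  list(network = network, baits = bt, queries = qs, annotation = ann,
       report = report)
}
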