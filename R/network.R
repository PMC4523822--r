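#' Build an undirected protein-protein interaction network from an edge list
#'
#' Takes a two-column data frame (or matrix) of protein identifier pairs and
#' returns a deduplicated undirected network. Repeated pairs and reversed
#' pairs (`A-B` vs `B-A`) collapse to a single edge; aggregated interaction
#' databases repeat pairs routinely, so the number of collapsed duplicates is
#' reported via a message rather than an error. Self-interactions (`A-A`) are
#' kept and stored once.
#'
#' @param edges A data frame or matrix with exactly two columns of protein
#'   identifiers. Identifiers are trimmed of surrounding whitespace; empty
#'   identifiers are an error.
#' @param quiet If `TRUE`, suppress the collapsed-duplicate message.
#' @return An object of class `ppi_network`: a list with `edges` (a tibble
#'   with columns `from`, `to`, canonically ordered so `from <= to`), `nodes`
#'   (sorted character vector, the union of all endpoints) and `degree` (a
#'   tibble with columns `protein`, `degree`).
#' @details Degree follows partner-set semantics: the degree of a protein is
#'   its number of *distinct* interaction partners, and a self-interaction
#'   contributes 1 (the protein is its own partner once).
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
#' net$degree
#' @export
ppi_network <- function(edges, quiet = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) {
    abort(sprintf("edge table must have exactly 2 columns, got %d", ncol(edges)))
  }
  from <- check_string_ids(edges[[1L]], "protein")
  to <- check_string_ids(edges[[2L]], "protein")
  # canonical unordered representation
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_collapsed <- sum(dup)
  if (n_collapsed > 0L && !quiet) {
    inform(sprintf("collapsed %d duplicate edge record(s)", n_collapsed))
  }
  a <- a[!dup]
  b <- b[!dup]
  ord <- order(a, b, method = "radix")
  edge_tbl <- tibble(from = a[ord], to = b[ord])
  nodes <- sort(unique(c(edge_tbl$from, edge_tbl$to)), method = "radix")
  # distinct-partner degree: each non-self edge adds 1 to both endpoints,
  # a self edge adds 1 to its single endpoint
  is_self <- edge_tbl$from == edge_tbl$to
  ends <- c(edge_tbl$from[!is_self], edge_tbl$to[!is_self], edge_tbl$from[is_self])
  deg <- table(factor(ends, levels = nodes))
  structure(
    list(
      edges = edge_tbl,
      nodes = nodes,
      degree = tibble(protein = nodes, degree = as.integer(deg)),
      n_collapsed = n_collapsed
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  n_self <- sum(x$edges$from == x$edges$to)
  cat(sprintf(
    "<ppi_network> %d proteins, %d interactions (%d self)\n",
    length(x$nodes), nrow(x$edges), n_self
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppi_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.ppi_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_self = sum(x$edges$from == x$edges$to),
    mean_degree = mean(x$degree$degree),
    n_collapsed = x$n_collapsed
  )
}

#' Degrees of a set of proteins
#'
#' @param network A [ppi_network()].
#' @param proteins Character vector of protein identifiers; `NULL` (default)
#'   returns all network nodes.
#' @param missing How to treat proteins absent from the network: `"zero"`
#'   assigns degree 0 (the protein has no reported partners), `"error"` raises
#'   an error naming the missing proteins. Proteins that were tested as baits
#'   but for which no interaction was ever reported legitimately have degree 0,
#'   hence the default downstream of the randomization test is `"zero"`.
#' @return A tibble with columns `protein` and `degree`, in the order of
#'   `proteins`.
#' @examples
#' net <- ppi_network(data.frame(a = c("HUB", "HUB"), b = c("P1", "P2")))
#' node_degrees(net, c("HUB", "P1", "ABSENT"), missing = "zero")
#' @export
node_degrees <- function(network, proteins = NULL, missing = c("zero", "error")) {
  stopifnot(inherits(network, "ppi_network"))
  missing <- match.arg(missing)
  if (is.null(proteins)) {
    return(network$degree)
  }
  proteins <- check_string_ids(proteins, "protein")
  idx <- match(proteins, network$degree$protein)
  if (anyNA(idx)) {
    if (missing == "error") {
      miss <- proteins[is.na(idx)]
      abort(sprintf(
        "protein(s) not in network: %s",
        paste(head(miss, 5L), collapse = ", ")
      ))
    }
  }
  deg <- ifelse(is.na(idx), 0L, network$degree$degree[idx])
  tibble(protein = proteins, degree = as.integer(deg))
}
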