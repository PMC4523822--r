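# Generative model of a study-biased interactome: a latent Chung-Lu "true"
# network plus an uneven bait-testing process that produces the observed
# network and the bait-usage table. Used to demonstrate the bias, and to
# check calibration and power of the matched test, without any download.

#' Simulation parameters
#'
#' @param n_proteins Number of proteins.
#' @param gamma Exponent of the discretized power law (support `1..theta_cap`)
#'   from which the latent connectivity weights are drawn; larger values give
#'   a lighter tail.
#' @param theta_cap Upper cap of the weight support.
#' @param mean_degree Target mean true degree; weights are rescaled so the
#'   expected Chung-Lu degree averages to this.
#' @param bait_exponent Exponent `s` of the heavy-tailed bait-count
#'   distribution `P(b) proportional to b^-s`.
#' @param bait_max Maximum bait count. Counts are drawn from a 1-2-5
#'   logarithmic grid (1, 2, 5, 10, 20, 50, ... up to `bait_max`): real bait
#'   counts are massively tied at small values, and a gridded support keeps
#'   exact-count candidate pools populated — the regime the exact-then-widen
#'   matching rule expects. The grid is closed under multiplication by the
#'   default bait inflation factor 10 up to `bait_max`, where inflation
#'   saturates (counts never leave the support).
#' @param q Per-experiment detection sensitivity in `[0, 1]`: a true edge
#'   `{u, v}` is observed with probability `1 - (1-q)^(b_u + b_v)` (pooled
#'   detection; see `detection`).
#' @param eps Per-experiment false-positive rate: each protein `u` acquires
#'   `Poisson(eps * b_u)` spurious partners drawn uniformly.
#' @param m Query-set size.
#' @param phi Bait-usage inflation factor for query proteins (study bias;
#'   applied before detection).
#' @param delta True-connectivity effect for query proteins (their weights
#'   are multiplied by `delta` before the network is generated); `delta = 1`
#'   means no true effect.
#' @param mask_rate Fraction of non-query proteins whose bait information is
#'   withheld from the returned bait table (their edges are kept), emulating
#'   interactomes where only about half the proteins have bait statistics.
#' @param detection `"pooled"`: detection probability uses `b_u + b_v`;
#'   `"bait_only"`: only the more-tested endpoint's experiments can find the
#'   edge, `1 - (1-q)^max(b_u, b_v)`.
#' @param seed Integer master seed; all components draw from named substreams
#'   (`theta`, `query`, `interactome`, `baits`, `detection`, `mask`).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 2000L, gamma = 4.0, theta_cap = 40L,
                       mean_degree = 20, bait_exponent = 0.3, bait_max = 200L,
                       q = 0.05, eps = 0.01, m = 50L, phi = 10, delta = 1,
                       mask_rate = 0.45,
                       detection = c("pooled", "bait_only"), seed = 1L) {
  n_proteins <- check_count(n_proteins, "n_proteins", 2L)
  m <- check_count(m, "m", 1L)
  if (m >= n_proteins) abort("`m` must be smaller than `n_proteins`")
  if (q < 0 || q > 1) abort("`q` must be in [0, 1]")
  if (eps < 0) abort("`eps` must be >= 0")
  if (phi < 1) abort("`phi` must be >= 1")
  if (delta < 1) abort("`delta` must be >= 1")
  if (mask_rate < 0 || mask_rate >= 1) abort("`mask_rate` must be in [0, 1)")
  if (gamma <= 0 || bait_exponent <= 0) abort("exponents must be positive")
  structure(list(
    n_proteins = n_proteins, gamma = gamma,
    theta_cap = check_count(theta_cap, "theta_cap", 1L),
    mean_degree = mean_degree, bait_exponent = bait_exponent,
    bait_max = check_count(bait_max, "bait_max", 1L),
    q = q, eps = eps, m = m, phi = phi, delta = delta,
    mask_rate = mask_rate, detection = match.arg(detection),
    seed = check_count(seed, "seed")
  ), class = "sim_params")
}

# 1-2-5 logarithmic grid up to `max`
bait_grid <- function(max) {
  v <- sort(as.vector(outer(c(1L, 2L, 5L), 10^(0:8))))
  as.integer(v[v <= max])
}

sample_heavy_tail <- function(n, support, exponent) {
  p <- support^(-exponent)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

# latent connectivity weights, rescaled to the target mean expected degree
draw_theta <- function(params) {
  w <- sample_heavy_tail(params$n_proteins, seq_len(params$theta_cap),
                         params$gamma)
  w * params$mean_degree / mean(w)
}

#' Simulate the latent true interactome (Chung-Lu model)
#'
#' Generates an undirected simple network in which the edge `{u, v}` exists
#' independently with probability `min(1, theta_u * theta_v / sum(theta))`,
#' so the expected degree of `u` is approximately `theta_u`. Proteins that
#' end up with no interaction do not appear in the returned network (degree
#' queries for them use the `missing = "zero"` policy).
#'
#' @param theta Named non-negative numeric vector of connectivity weights
#'   (names are the protein identifiers).
#' @param seed Optional integer; if supplied the RNG is seeded for a
#'   reproducible draw.
#' @return A [ppi_network()].
#' @export
simulate_true_interactome <- function(theta, seed = NULL) {
  if (is.null(names(theta))) abort("`theta` must be named by protein")
  if (any(theta < 0) || all(theta == 0)) {
    abort("weights must be non-negative with at least one positive")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta)
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq(2L, n))
  p <- pmin(1, theta[i] * theta[j] / sum(theta))
  keep <- runif(length(p)) < p
  ids <- names(theta)
  ppi_network(tibble(from = ids[i[keep]], to = ids[j[keep]]), quiet = TRUE)
}

#' Simulate the uneven bait-testing process
#'
#' Draws heavy-tailed bait counts for every protein (inflating the query
#' set's counts by `phi`), observes each true edge with probability
#' `1 - (1-q)^(b_u + b_v)` (or the `bait_only` variant), adds
#' `Poisson(eps * b_u)` false-positive partners per protein, and withholds
#' bait information for a `mask_rate` fraction of non-query proteins.
#'
#' @param true_network A [ppi_network()], e.g. from
#'   [simulate_true_interactome()].
#' @param params A [sim_params()].
#' @param proteins Character vector of the full protein universe (isolated
#'   proteins included; they can still be tested as baits).
#' @param query Optional character vector of query proteins whose bait counts
#'   are multiplied by `params$phi`.
#' @param bait_counts Optional named integer vector of bait counts over
#'   `proteins`, overriding the draw from the bait-count model (useful for
#'   controlled experiments on the detection process).
#' @param seed Optional integer seed.
#' @return A list: `observed` (a [ppi_network()]; `NULL` if no edge was
#'   observed), `baits` (a [bait_table()] with masked proteins removed;
#'   `study_count` is the bait count plus additional non-PPI studies),
#'   `bait_counts` (the full named vector, pre-masking), `masked` (the
#'   withheld identifiers).
#' @export
simulate_study_process <- function(true_network, params, proteins,
                                   query = NULL, bait_counts = NULL,
                                   seed = NULL) {
  stopifnot(inherits(true_network, "ppi_network"), inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bait_counts)) {
    b <- sample_heavy_tail(length(proteins), bait_grid(params$bait_max),
                           params$bait_exponent)
    names(b) <- proteins
  } else {
    if (!all(proteins %in% names(bait_counts))) {
      abort("`bait_counts` must cover every protein")
    }
    b <- as.integer(bait_counts[proteins])
    names(b) <- proteins
  }
  if (!is.null(query)) {
    # bait counts live on the model's support: inflation saturates at bait_max
    # (a protein cannot be tested more often than the maximum study count)
    b[query] <- pmin(as.integer(round(b[query] * params$phi)), params$bait_max)
  }
  # detection of true edges
  eu <- true_network$edges$from
  ev <- true_network$edges$to
  expo <- switch(params$detection,
                 pooled = b[eu] + b[ev],
                 bait_only = pmax(b[eu], b[ev]))
  p_det <- 1 - (1 - params$q)^expo
  det <- runif(length(p_det)) < p_det
  detected <- tibble(from = eu[det], to = ev[det])
  # false positives: Poisson(eps * b_u) uniform spurious partners per protein
  k_fp <- rpois(length(b), params$eps * b)
  fp_src <- rep(proteins, k_fp)
  fp <- if (length(fp_src) > 0L) {
    partner <- proteins[sample.int(length(proteins), length(fp_src),
                                   replace = TRUE)]
    same <- partner == fp_src
    while (any(same)) {
      partner[same] <- proteins[sample.int(length(proteins), sum(same),
                                           replace = TRUE)]
      same <- partner == fp_src
    }
    tibble(from = fp_src, to = partner)
  } else {
    tibble(from = character(), to = character())
  }
  all_edges <- dplyr::bind_rows(detected, fp)
  observed <- if (nrow(all_edges) > 0L) ppi_network(all_edges, quiet = TRUE)
  # bait-info masking: non-query proteins only
  maskable <- setdiff(proteins, query)
  masked <- maskable[runif(length(maskable)) < params$mask_rate]
  kept <- setdiff(proteins, masked)
  study_extra <- rpois(length(kept), 1 + b[kept])
  baits <- bait_table(tibble(
    protein = kept,
    bait_count = unname(b[kept]),
    study_count = unname(b[kept]) + study_extra
  ))
  list(observed = observed, baits = baits, bait_counts = b, masked = masked)
}

#' Generate a benchmark dataset under a named scenario
#'
#' Scenarios of the study-bias benchmark:
#' * `"A"` — bias only: the query set is an ordinary random protein sample
#'   but its bait counts are inflated by `phi` (default 10); there is no true
#'   connectivity effect, so the matched test must *not* reject beyond its
#'   nominal level, while the uncorrected rank-sum comparison rejects almost
#'   always.
#' * `"B"` — true effect plus bias: as A, but query weights are additionally
#'   multiplied by `delta > 1`; the matched test should reject.
#' * `"C"` — no bias at all (`phi = 1`, `delta = 1`): both tests are
#'   calibrated.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param params A [sim_params()]; `params$seed` is used unless `seed` is
#'   given.
#' @param seed Optional integer master seed overriding `params$seed`.
#' @return A list of class `bm_bundle`: `true_network`, `observed`
#'   ([ppi_network()]), `baits` ([bait_table()]), `query` ([query_set()]),
#'   `masked`, `scenario`, `params`.
#' @export
make_benchmark <- function(scenario = c("A", "B", "C"),
                           params = sim_params(), seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "sim_params"))
  seed <- if (is.null(seed)) params$seed else check_count(seed, "seed")
  eff <- switch(scenario,
    A = list(phi = params$phi, delta = 1),
    B = list(phi = params$phi, delta = params$delta),
    C = list(phi = 1, delta = 1)
  )
  p_eff <- params
  p_eff$phi <- eff$phi
  p_eff$delta <- eff$delta
  proteins <- sprintf("P%05d", seq_len(params$n_proteins))
  theta <- with_substream(seed, "theta", draw_theta(params))
  names(theta) <- proteins
  query_ids <- with_substream(seed, "query",
    proteins[sample.int(params$n_proteins, params$m)])
  theta[query_ids] <- theta[query_ids] * eff$delta
  true_network <- with_substream(seed, "interactome",
    simulate_true_interactome(theta))
  study <- with_substream(seed, "study",
    simulate_study_process(true_network, p_eff, proteins, query = query_ids))
  structure(list(
    true_network = true_network,
    observed = study$observed,
    baits = study$baits,
    query = query_set(query_ids, name = paste0("scenario_", scenario)),
    masked = study$masked,
    scenario = scenario,
    params = p_eff,
    seed = seed
  ), class = "bm_bundle")
}

#' @export
print.bm_bundle <- function(x, ...) {
  cat(sprintf(
    "<bm_bundle> scenario %s (seed %d): %d proteins, %d observed edges, query %d, phi=%g delta=%g\n",
    x$scenario, x$seed, x$params$n_proteins,
    if (is.null(x$observed)) 0L else nrow(x$observed$edges),
    x$params$m, x$params$phi, x$params$delta
  ))
  invisible(x)
}

#' Write a benchmark bundle in the package's file formats
#'
#' Writes `edges.tsv` (observed edge list), `baits.tsv`, `query.txt` and a
#' flat key/value `params.txt` manifest into `dir`, so the full pipeline
#' (simulate, write, read, test) runs end-to-end through the same readers
#' real data would use.
#'
#' @param bundle A [make_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bm_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(bundle$observed)) abort("bundle has no observed edges to write")
  write_edge_list(bundle$observed, file.path(dir, "edges.tsv"))
  write_bait_table(bundle$baits, file.path(dir, "baits.tsv"))
  write_query_set(bundle$query, file.path(dir, "query.txt"))
  p <- bundle$params
  keys <- c(names(p), "scenario", "master_seed")
  vals <- c(vapply(p, function(v) as.character(v)[1L], ""), bundle$scenario,
            as.character(bundle$seed))
  writeLines(paste(keys, vals, sep = "="), file.path(dir, "params.txt"))
  invisible(dir)
}
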