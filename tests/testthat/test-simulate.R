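test_that("equal weights give the closed-form expected degree", {
  n <- 100
  theta <- setNames(rep(5, n), sprintf("P%03d", 1:n))
  # P(edge) = theta^2 / sum(theta); E[deg] = (n-1) * theta^2 / sum(theta)
  expected <- (n - 1) * 25 / (5 * n)
  set.seed(900)
  means <- replicate(50, {
    net <- simulate_true_interactome(theta)
    sum(node_degrees(net, names(theta), missing = "zero")$degree) / n
  })
  p_edge <- 25 / 500
  var_mean <- 4 * choose(n, 2) * p_edge * (1 - p_edge) / n^2
  se <- sqrt(var_mean / 50)
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("zero-weight proteins are isolated and seeds reproduce edge sets", {
  theta <- setNames(c(0, rep(10, 49)), sprintf("P%02d", 1:50))
  net <- simulate_true_interactome(theta, seed = 1)
  expect_false("P01" %in% net$nodes)
  net2 <- simulate_true_interactome(theta, seed = 1)
  expect_identical(net$edges, net2$edges)
  expect_error(simulate_true_interactome(unname(theta)), "named")
  expect_error(simulate_true_interactome(setNames(rep(0, 3), c("a", "b", "c"))),
               "positive")
})

test_that("perfect detection reproduces the true network when everyone is a bait", {
  theta <- setNames(rep(8, 60), sprintf("P%02d", 1:60))
  net <- simulate_true_interactome(theta, seed = 2)
  params <- sim_params(n_proteins = 60L, m = 5L, q = 1, eps = 0, mask_rate = 0)
  study <- simulate_study_process(net, params, names(theta), seed = 3)
  expect_identical(study$observed$edges, net$edges)
  expect_true(all(study$baits$bait_count >= 1L))
})

test_that("more bait testing strictly increases a protein's observed degree", {
  # one hub with 60 true partners; doubling the hub's bait count raises the
  # detection probability of each of its edges from 1-(1-q)^2 to 1-(1-q)^3
  proteins <- c("HUB", sprintf("L%02d", 1:60))
  net <- ppi_network(data.frame(a = rep("HUB", 60), b = sprintf("L%02d", 1:60)))
  params <- sim_params(n_proteins = 61L, m = 5L, q = 0.1, eps = 0,
                       mask_rate = 0)
  deg_at <- function(b_hub, seed) {
    b <- setNames(c(b_hub, rep(1L, 60)), proteins)
    study <- simulate_study_process(net, params, proteins, bait_counts = b,
                                    seed = seed)
    if (is.null(study$observed)) 0L else
      node_degrees(study$observed, "HUB", missing = "zero")$degree
  }
  d1 <- vapply(1:200, function(i) deg_at(1L, i), numeric(1))
  d2 <- vapply(1:200, function(i) deg_at(2L, 10000 + i), numeric(1))
  expect_gt(mean(d2), mean(d1))
  expect_lt(wilcox.test(d2, d1, alternative = "greater")$p.value, 0.01)
})

test_that("benchmark bundles are reproducible and scenario parameters are applied", {
  p <- sim_params(n_proteins = 300L, m = 10L, seed = 5L)
  b1 <- make_benchmark("A", p)
  b2 <- make_benchmark("A", p)
  expect_identical(b1$observed$edges, b2$observed$edges)
  expect_identical(b1$baits, b2$baits)
  expect_identical(b1$query$proteins, b2$query$proteins)

  expect_equal(b1$params$phi, 10)
  expect_equal(b1$params$delta, 1)
  c1 <- make_benchmark("C", p)
  expect_equal(c1$params$phi, 1)

  # query proteins keep bait info; masking hits only non-query proteins
  expect_true(all(has_bait_info(b1$baits, b1$query$proteins)))
  expect_true(all(!b1$query$proteins %in% b1$masked))
  frac <- length(b1$masked) / (300 - 10)
  expect_lt(abs(frac - 0.45), 0.15)
  # inflation saturates at the support maximum
  expect_true(all(bait_count(b1$baits, b1$query$proteins) <= p$bait_max))
})

test_that("a scenario-B query has inflated latent connectivity", {
  p <- sim_params(n_proteins = 500L, m = 25L, delta = 3, seed = 8L)
  b <- make_benchmark("B", p)
  qd <- node_degrees(b$true_network, b$query$proteins, missing = "zero")$degree
  bgd <- node_degrees(b$true_network,
                      setdiff(sprintf("P%05d", 1:500), b$query$proteins),
                      missing = "zero")$degree
  expect_gt(mean(qd), 2 * mean(bgd))
})

test_that("bundles round-trip through the file formats and drive the pipeline", {
  p <- sim_params(n_proteins = 400L, m = 15L, seed = 12L)
  b <- make_benchmark("A", p)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("edges.tsv", "baits.tsv", "query.txt", "params.txt"))
  inp <- read_inputs(file.path(dir, "edges.tsv"), file.path(dir, "baits.tsv"),
                     file.path(dir, "query.txt"))
  expect_identical(inp$network$edges, b$observed$edges)
  expect_identical(inp$baits$protein, b$baits$protein)
  expect_identical(bait_count(inp$baits, b$baits$protein),
                   b$baits$bait_count)
  expect_setequal(inp$queries[[1]]$proteins, b$query$proteins)

  # written files are bit-identical under the same seed
  dir2 <- withr::local_tempdir()
  write_bundle(make_benchmark("A", p), dir2)
  for (f in c("edges.tsv", "baits.tsv", "query.txt")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }

  cfg <- matching_config(n_randomizations = 200, seed = 99)
  r <- suppressWarnings(
    randomization_test(inp$network, inp$baits, inp$queries[[1]], cfg)
  )
  expect_s3_class(r, "bm_randomization")
  expect_equal(length(r$null_stats), 200L)
})

test_that("zero sensitivity and zero false positives give an empty observed network", {
  theta <- setNames(rep(10, 40), sprintf("P%02d", 1:40))
  net <- simulate_true_interactome(theta, seed = 4)
  params <- sim_params(n_proteins = 40L, m = 4L, q = 0, eps = 0)
  study <- simulate_study_process(net, params, names(theta), seed = 5)
  expect_null(study$observed)
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(q = 1.5), "q")
  expect_error(sim_params(m = 2000, n_proteins = 2000), "smaller")
  expect_error(sim_params(phi = 0.5), "phi")
  expect_error(sim_params(mask_rate = 1), "mask_rate")
  expect_error(sim_params(delta = 0.9), "delta")
})

test_that("named substreams make components independently reproducible", {
  expect_identical(derive_seed(42L, "theta"), derive_seed(42L, "theta"))
  expect_false(derive_seed(42L, "theta") == derive_seed(42L, "baits"))
  expect_false(derive_seed(42L, "theta") == derive_seed(43L, "theta"))
  s <- vapply(letters, derive_seed, integer(1), seed = 1e9)
  expect_true(all(s >= 0 & s < 2^31 - 1))
})

test_that("detection power grows with the query size at a fixed true effect", {
  pow <- function(m, n_rep = 30) {
    mean(vapply(seq_len(n_rep), function(i) {
      p <- sim_params(n_proteins = 1000L, m = m, delta = 2, seed = 3000L + i)
      b <- make_benchmark("B", p)
      cfg <- matching_config(n_randomizations = 400, seed = 3000L + i)
      suppressWarnings(
        randomization_test(b$observed, b$baits, b$query, cfg)
      )$p_value
    }, numeric(1)) < 0.05)
  }
  p_small <- pow(10L)
  p_large <- pow(30L)
  expect_lte(p_small, p_large + 1e-9)
  expect_gt(p_large, 0.5)
})
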