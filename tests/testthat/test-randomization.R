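# Small closed-world fixtures: networks and bait tables built in code so the
# exact null distribution is known or enumerable.

star_net <- function(hubs, leaves_per_hub = 5L) {
  edges <- purrr::map_dfr(seq_along(hubs), function(i) {
    tibble::tibble(a = hubs[i], b = paste0(hubs[i], "_l", seq_len(leaves_per_hub)))
  })
  ppi_network(edges)
}

test_that("p is zero when no matched set can out-degree the query", {
  # query proteins have degree 5; all candidates are leaves with degree 1
  net <- star_net(c("Q1", "Q2"))
  baits <- make_bait_df(c("Q1", "Q2", paste0("Q1_l", 1:5), paste0("Q2_l", 1:5)),
                        rep(2L, 12))
  cfg <- matching_config(n_randomizations = 100, seed = 42)
  r <- randomization_test(net, baits, query_set(c("Q1", "Q2")), cfg)
  expect_equal(r$p_value, 0)
  expect_equal(r$observed, 5)
  expect_true(all(r$null_stats < 5))
  expect_true(all(r$log2_ratios > 0))
})

test_that("single-protein test reproduces the enumerable p = 1/3", {
  # query degree 2; pool degrees {1, 2, 3}; strict rule: P(null > 2) = 1/3
  net <- ppi_network(data.frame(
    a = c("Q", "Q", "C1", "C2", "C2", "C3", "C3", "C3"),
    b = c("x1", "x2", "y1", "y2", "y3", "z1", "z2", "z3")
  ))
  baits <- make_bait_df(c("Q", "C1", "C2", "C3"), rep(4L, 4))
  cfg <- matching_config(min_pool = 2L, n_randomizations = 10000, seed = 1)
  r <- randomization_test(net, baits, query_set("Q"), cfg)
  expect_equal(r$observed, 2)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(r$p_value - 1 / 3), 3 * se)
  # tail identities: P(>) + P(<) + P(=) = 1 on the grid {0, 1/N, ..., 1}
  n <- length(r$null_stats)
  expect_equal(r$n_greater / n + sum(r$null_stats < r$observed) / n +
                 r$n_ties / n, 1)
  expect_true(all(r$null_stats * n == round(r$null_stats * n)))
})

test_that("Monte-Carlo p stays within 3 SE of exhaustive product-of-pools enumeration", {
  set.seed(808)
  # 3 query proteins at distinct bait counts, pools of <= 4 candidates each
  leaves <- function(p, k) if (k == 0) NULL else
    data.frame(a = rep(p, k), b = paste0(p, "_", seq_len(k)))
  prots <- c(q1 = 3, q2 = 1, q3 = 4,
             a1 = 2, a2 = 5, a3 = 1, a4 = 3,
             b1 = 4, b2 = 2, b3 = 6,
             c1 = 1, c2 = 7, c3 = 2, c4 = 3)
  net <- ppi_network(purrr::map_dfr(names(prots), function(p)
    leaves(p, prots[[p]])))
  baits <- make_bait_df(
    names(prots),
    c(10L, 20L, 30L, rep(10L, 4), rep(20L, 3), rep(30L, 4))
  )
  cfg <- matching_config(min_pool = 2L, n_randomizations = 50000, seed = 3,
                         within_set_replacement = "with")
  r <- randomization_test(net, baits, query_set(c("q1", "q2", "q3")), cfg)
  pools <- list(prots[c("a1", "a2", "a3", "a4")],
                prots[c("b1", "b2", "b3")],
                prots[c("c1", "c2", "c3", "c4")])
  p_exact <- oracle_exact_randomization_p(pools, r$observed)
  se <- sqrt(p_exact * (1 - p_exact) / 50000)
  expect_lt(abs(r$p_value - p_exact), 3 * se)
})

test_that("results are bit-identical under identical inputs, config and seed", {
  net <- star_net(c("Q1", "Q2", "C1", "C2", "C3", "C4", "C5"),
                  leaves_per_hub = 3L)
  baits <- make_bait_df(c("Q1", "Q2", "C1", "C2", "C3", "C4", "C5"),
                        c(2L, 2L, 2L, 2L, 2L, 2L, 2L))
  cfg <- matching_config(n_randomizations = 200, seed = 77)
  r1 <- randomization_test(net, baits, query_set(c("Q1", "Q2"), "q"), cfg)
  r2 <- randomization_test(net, baits, query_set(c("Q1", "Q2"), "q"), cfg)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(glance(r1), glance(r2))
})

test_that("the plus-one tail rule shifts p off zero and stays on (0, 1]", {
  net <- star_net("Q1")
  baits <- make_bait_df(c("Q1", paste0("Q1_l", 1:5)), rep(1L, 6))
  strict <- randomization_test(net, baits, query_set("Q1"),
                               matching_config(n_randomizations = 50, seed = 2))
  plus <- randomization_test(net, baits, query_set("Q1"),
                             matching_config(n_randomizations = 50, seed = 2,
                                             tail = "plus-one"))
  expect_equal(strict$p_value, 0)
  expect_equal(plus$p_value, 1 / 51)
  expect_identical(strict$null_stats, plus$null_stats)
})

test_that("query proteins without bait information are dropped with a report", {
  net <- star_net(c("Q1", "Q2"))
  baits <- make_bait_df(c("Q1", paste0("Q1_l", 1:5), paste0("Q2_l", 1:5)),
                        rep(3L, 11))
  cfg <- matching_config(n_randomizations = 50, seed = 9)
  r <- randomization_test(net, baits, query_set(c("Q1", "Q2")), cfg)
  expect_equal(r$m_used, 1L)
  expect_equal(r$dropped, "Q2")
  no_info <- make_bait_df(paste0("Q1_l", 1:5), rep(1L, 5))
  expect_error(
    randomization_test(net, no_info, query_set(c("Q1", "Q2")), cfg),
    "Q1"
  )
})

test_that("median statistic is supported and echoed", {
  net <- star_net(c("Q1", "C1", "C2", "C3", "C4", "C5"), leaves_per_hub = 2L)
  baits <- make_bait_df(c("Q1", "C1", "C2", "C3", "C4", "C5"), rep(1L, 6))
  cfg <- matching_config(statistic = "median", n_randomizations = 100, seed = 4)
  r <- randomization_test(net, baits, query_set("Q1"), cfg)
  expect_equal(glance(r)$statistic, "median")
  expect_equal(r$observed, 2)
})

test_that("undefined log2 ratios from zero null statistics are excluded", {
  # the only candidate has degree 0 (in bait table, not in network)
  net <- star_net("Q1")
  baits <- make_bait_df(c("Q1", "Z0"), c(5L, 5L))
  cfg <- matching_config(n_randomizations = 20, seed = 11)
  expect_message(
    r <- suppressWarnings(randomization_test(net, baits, query_set("Q1"), cfg)),
    "undefined"
  )
  expect_true(all(is.na(r$log2_ratios)))
  expect_true(is.na(glance(r)$log2_median))
})

test_that("multi-set results are independent of query-set order and isolate failures", {
  net <- star_net(c("Q1", "Q2", "C1", "C2", "C3", "C4", "C5", "C6"),
                  leaves_per_hub = 4L)
  all_p <- c("Q1", "Q2", paste0("C", 1:6))
  baits <- make_bait_df(all_p, rep(2L, 8))
  cfg <- matching_config(n_randomizations = 200, seed = 21)
  qs <- list(alpha = "Q1", beta = "Q2", broken = "UNKNOWN")
  fwd <- suppressWarnings(multi_set_test(net, baits, qs, cfg))
  rev <- suppressWarnings(multi_set_test(net, baits, rev(qs), cfg))
  expect_identical(
    fwd$table[order(fwd$table$query), ],
    rev$table[order(rev$table$query), ]
  )
  expect_true(is.na(fwd$table$p_value[fwd$table$query == "broken"]))
  expect_match(fwd$table$error[fwd$table$query == "broken"], "bait")
  expect_false(any(is.na(fwd$table$p_value[fwd$table$query != "broken"])))
})

test_that("two sets with identical degree-constant pools get identical p-values", {
  # all candidates share one degree so the null is degenerate and the p-value
  # depends only on the observed statistic, symmetrically for both sets
  net <- star_net(c("Q1", "Q2", "C1", "C2", "C3", "C4", "C5"),
                  leaves_per_hub = 2L)
  baits <- make_bait_df(c("Q1", "Q2", paste0("C", 1:5)), rep(6L, 7))
  cfg <- matching_config(n_randomizations = 100, seed = 31)
  res <- multi_set_test(net, baits, list(s1 = "Q1", s2 = "Q2"), cfg)
  expect_equal(res$table$p_value[1], res$table$p_value[2])
  expect_equal(res$table$observed, c(2, 2))
})

test_that("a set of pool-maximal degrees yields strictly positive log2 ratios", {
  net <- ppi_network(data.frame(
    a = c(rep("Q", 4), "C1", "C2", "C2"),
    b = c(paste0("x", 1:4), "u1", "u1", "u2")
  ))
  baits <- make_bait_df(c("Q", "C1", "C2"), rep(3L, 3))
  cfg <- matching_config(min_pool = 1L, n_randomizations = 100, seed = 51)
  r <- randomization_test(net, baits, query_set("Q"), cfg)
  expect_true(all(r$log2_ratios > 0))
})

test_that("Benjamini-Hochberg adjustment is opt-in", {
  net <- star_net(c("Q1", "Q2", "C1", "C2", "C3", "C4", "C5"),
                  leaves_per_hub = 2L)
  baits <- make_bait_df(c("Q1", "Q2", paste0("C", 1:5)), rep(1L, 7))
  cfg <- matching_config(n_randomizations = 50, seed = 61)
  plain <- multi_set_test(net, baits, list(a = "Q1", b = "Q2"), cfg)
  expect_false("p_adj" %in% names(plain$table))
  adj <- multi_set_test(net, baits, list(a = "Q1", b = "Q2"), cfg,
                        adjust_p = TRUE)
  expect_equal(adj$table$p_adj, p.adjust(adj$table$p_value, "BH"))
})
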