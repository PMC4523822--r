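# Independent brute-force oracles used to cross-check the package's
# statistical kernels. These deliberately share no code with the package.

# unordered-pair deduplication by sorting each pair and unique()-ing strings
oracle_edge_set <- function(a, b) {
  unique(vapply(seq_along(a), function(i) {
    paste(sort(c(a[i], b[i])), collapse = "|")
  }, ""))
}

# Pearson r straight from the covariance formula
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_fisher_z_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - crit * se, z + crit * se))
}

# Exact Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  switch(alternative,
    greater = mean(us >= u_obs),
    less = mean(us <= u_obs),
    `two-sided` = {
      mu <- n1 * length(b) / 2
      mean(abs(us - mu) >= abs(u_obs - mu))
    }
  )
}

# Exact hypergeometric tail / two-sided p for a 2x2 table by enumerating all
# tables with the observed margins, using choose() only
oracle_fisher_p <- function(m, alternative = "greater") {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  K <- a + c           # column-1 margin
  n1 <- a + b          # row-1 margin
  N <- a + b + c + d
  lo <- max(0, n1 + K - N)
  hi <- min(n1, K)
  support <- lo:hi
  pr <- choose(K, support) * choose(N - K, n1 - support) / choose(N, n1)
  obs <- pr[support == a]
  switch(alternative,
    greater = sum(pr[support >= a]),
    less = sum(pr[support <= a]),
    `two-sided` = sum(pr[pr <= obs + 1e-12])
  )
}

oracle_fisher_point_probs <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  K <- a + c; n1 <- a + b; N <- a + b + c + d
  support <- max(0, n1 + K - N):min(n1, K)
  choose(K, support) * choose(N - K, n1 - support) / choose(N, n1)
}

# Exact randomization p by exhaustive enumeration over the product of pools:
# every combination of one replacement per query protein, equally weighted
# (the product measure of independent uniform draws).
oracle_exact_randomization_p <- function(pool_degrees, observed,
                                         stat = mean) {
  grid <- expand.grid(pool_degrees, KEEP.OUT.ATTRS = FALSE)
  stats <- apply(as.matrix(grid), 1, stat)
  mean(stats > observed)
}

# small convenience used across test files
make_bait_df <- function(proteins, counts) {
  bait_table(data.frame(protein = proteins, bait_count = counts))
}
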