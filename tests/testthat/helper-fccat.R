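# Shared fixtures, all built in code.

# Two-scale bank containing the hand-arithmetic pair (i1 vs k1):
# mu 4 vs 3, loadings 0.8 / 0.6 on different scales, uniqueness 0.5 each,
# so z(eta = (1, -1)) = (1 + 0.8 + 0.6) / 1 = 2.4.
toy_bank2 <- function() {
  fc_bank(data.frame(
    item_id = c("i1", "k1", "i2", "k2", "i3", "k3"),
    scale = c(1L, 2L, 1L, 2L, 1L, 2L),
    mu = c(4, 3, 3.2, 3.4, 2.5, 4.5),
    loading = c(0.8, 0.6, -0.5, 0.7, 0.6, -0.4),
    uniqueness = c(0.5, 0.5, 0.64, 0.51, 0.75, 0.84)
  ), scale_labels = c("S1", "S2"))
}

# random valid bank: `per_scale` items on each of S scales
random_bank <- function(S = 2, per_scale = 4, seed = 1, mu_range = c(2, 5)) {
  set.seed(seed)
  n <- S * per_scale
  lam <- runif(n, 0.3, 0.9) * sample(c(-1, 1), n, replace = TRUE)
  fc_bank(data.frame(
    item_id = sprintf("r%03d", seq_len(n)),
    scale = rep(seq_len(S), each = per_scale),
    mu = runif(n, mu_range[1], mu_range[2]),
    loading = lam,
    uniqueness = 1 - lam^2
  ), scale_labels = paste0("S", seq_len(S)))
}

# 12-item, 6-scale bank with tightly clustered utilities (CLI smoke tests:
# every cross-scale pair is eligible even under the strict threshold)
cli_bank <- function() {
  fc_bank(data.frame(
    item_id = sprintf("t%02d", 1:12),
    scale = rep(1:6, each = 2),
    mu = rep(c(3.5, 3.7), 6),
    loading = rep(c(0.6, -0.5), 6),
    uniqueness = rep(c(0.64, 0.75), 6)
  ))
}

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

expect_psd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -tol))
}
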