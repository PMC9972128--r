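test_that("pair information is a rank-one PSD outer product", {
  bank <- toy_bank2()
  blk <- pair_block("i1", "k1")
  F <- pair_information(blk, c(1, -1), bank)
  expect_equal(F, t(F))
  expect_psd(F)
  expect_lte(qr(F)$rank, 1L)
  expect_gte(sum(diag(F)), 0)

  # identical loading vectors annihilate the information
  same <- fc_bank(data.frame(item_id = c("a", "b", "c"), scale = c(1, 1, 2),
                             mu = c(3, 3.4, 4), loading = c(.6, .6, .5),
                             uniqueness = c(.6, .6, .7)),
                  scale_labels = c("S1", "S2"))
  expect_equal(pair_information(pair_block("a", "b"), c(.5, -.5), same),
               matrix(0, 2, 2))
})

test_that("pair information equals the expected negative Hessian of the log likelihood", {
  set.seed(11)
  for (rep in 1:10) {
    bank <- random_bank(S = 2, per_scale = 3, seed = 100 + rep)
    eta <- rnorm(2)
    ids <- bank$items$item_id
    blk <- pair_block(ids[1], ids[4])  # items on different scales
    F <- pair_information(blk, eta, bank)
    p1 <- pair_probability(blk, eta, bank)
    ll <- function(e, y) {
      p <- pair_probability(blk, e, bank)
      y * log(p) + (1 - y) * log(1 - p)
    }
    h <- 1e-4
    num_hess <- function(y) {
      H <- matrix(0, 2, 2)
      for (a in 1:2) for (b in 1:2) {
        ea <- numeric(2); ea[a] <- h; eb <- numeric(2); eb[b] <- h
        H[a, b] <- (ll(eta + ea + eb, y) - ll(eta + ea - eb, y) -
                      ll(eta - ea + eb, y) + ll(eta - ea - eb, y)) / (4 * h^2)
      }
      H
    }
    expected <- -(p1 * num_hess(1) + (1 - p1) * num_hess(0))
    expect_equal(F, expected, tolerance = 1e-4)
  }
})

test_that("test information accumulates additively and commutatively", {
  bank <- toy_bank2()
  eta <- c(0.3, -0.6)
  empty <- accumulate_test_information(list(), eta, bank)
  expect_equal(empty, matrix(0, 2, 2))

  blocks <- list(pair_block("i1", "k1"), pair_block("i2", "k2"))
  one <- pair_information(blocks[[1]], eta, bank)
  expect_equal(accumulate_test_information(list(blocks[[1]], blocks[[1]]), eta, bank),
               2 * one)
  expect_equal(accumulate_test_information(blocks, eta, bank),
               accumulate_test_information(rev(blocks), eta, bank))
  # data-frame form input works too
  expect_equal(accumulate_test_information(
    data.frame(first = c("i1", "i2"), second = c("k1", "k2")), eta, bank),
    accumulate_test_information(blocks, eta, bank))
})

test_that("posterior information adds the prior precision", {
  S2 <- matrix(c(1, .3, .3, 1), 2)
  prior <- prior_spec(cov = S2)
  expect_equal(posterior_information(matrix(0, 2, 2), prior_spec(cov = diag(2))),
               diag(2))
  # closed-form 2x2 inverse: (1/(1-r^2)) [[1, -r], [-r, 1]]
  expect_equal(posterior_information(matrix(0, 2, 2), prior),
               matrix(c(1, -.3, -.3, 1), 2) / (1 - 0.09), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:10) {
    u <- rnorm(2)
    ti <- tcrossprod(u)  # PSD rank-1 test information
    expect_gte(det(posterior_information(ti, prior)), det(prior$prec) - 1e-12)
  }
  expect_error(prior_spec(cov = matrix(c(1, 2, 2, 1), 2)), "positive-definite")
})

test_that("directional SEMs come from the inverse diagonal and shrink under added information", {
  expect_equal(directional_sem(diag(2)), c(1, 1))
  expect_equal(directional_sem(diag(c(4, 1))), c(0.5, 1))
  # prior-only posterior information with unit trait variances: SEM = 1
  prior <- prior_spec(cov = matrix(c(1, .3, .3, 1), 2))
  expect_equal(directional_sem(posterior_information(matrix(0, 2, 2), prior)),
               c(1, 1))

  # Loewner ordering: any PSD increment lowers every SEM coordinate
  set.seed(8)
  for (rep in 1:20) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3) * .1
    Fm <- tcrossprod(rnorm(3)) * runif(1)
    expect_true(all(directional_sem(A + Fm) <= directional_sem(A) + 1e-12))
  }
  expect_error(directional_sem(matrix(0, 2, 2)), "singular|positive-definite")
})

test_that("information is invariant under joint rescaling of loadings, utilities and uniquenesses", {
  bank <- toy_bank2()
  scaled <- bank
  scaled$items$mu <- 2 * bank$items$mu          # doubles each mu difference
  scaled$items$loading <- 2 * bank$items$loading
  scaled$items$uniqueness <- 4 * bank$items$uniqueness
  eta <- c(0.7, -0.2)
  for (blk in list(pair_block("i1", "k1"), pair_block("i2", "k3"))) {
    expect_equal(pair_z(blk, eta, scaled), pair_z(blk, eta, bank))
    expect_equal(pair_probability(blk, eta, scaled), pair_probability(blk, eta, bank))
    expect_equal(pair_information(blk, eta, scaled), pair_information(blk, eta, bank))
  }
})

test_that("pair information peaks on the even-call locus z = 0", {
  bank <- toy_bank2()
  blk <- pair_block("i1", "k1")
  locus <- information_peak_locus(blk, bank)
  expect_equal(locus$intercept, 1)         # mu_i - mu_k
  expect_equal(locus$coef, c(0.8, -0.6))   # lambda_i at s_i, -lambda_k at s_k

  # pick the locus point along the line eta = t * (1, 1): intercept + (l1 - l2) t = 0
  t_star <- -locus$intercept / sum(locus$coef)
  expect_equal(pair_probability(blk, rep(t_star, 2), bank), 0.5)

  # 1-D grid scan along that line: trace of F is maximal at the locus crossing
  ts <- seq(t_star - 3, t_star + 3, by = 0.01)
  tr <- vapply(ts, function(t) sum(diag(pair_information(blk, rep(t, 2), bank))),
               numeric(1))
  expect_equal(ts[which.max(tr)], t_star, tolerance = 0.011)

  # equal utilities and equal positive loadings on different traits:
  # the locus is eta_{s_i} = eta_{s_k}
  sym <- fc_bank(data.frame(item_id = c("a", "b"), scale = c(1, 2),
                            mu = c(3, 3), loading = c(.6, .6),
                            uniqueness = c(.5, .5)),
                 scale_labels = c("S1", "S2"))
  ls <- information_peak_locus(pair_block("a", "b"), sym)
  expect_equal(ls$intercept, 0)
  expect_equal(ls$coef[1], -ls$coef[2])

  # identical loading vectors leave the locus undefined
  same <- fc_bank(data.frame(item_id = c("a", "b", "c"), scale = c(1, 1, 2),
                             mu = c(3, 3.4, 4), loading = c(.6, .6, .5),
                             uniqueness = c(.6, .6, .7)),
                  scale_labels = c("S1", "S2"))
  expect_error(information_peak_locus(pair_block("a", "b"), same), "undefined")
})

test_that("information matrices export as labeled CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_information(diag(c(2, 3)), path, scale_labels = c("S1", "S2"))
  got <- utils::read.csv(path, row.names = 1)
  expect_equal(as.matrix(got), diag(c(2, 3)), ignore_attr = TRUE)
})
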