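test_that("candidate enumeration honors the desirability threshold and MFC pairing", {
  bank <- fc_bank(data.frame(item_id = c("a1", "a2", "b1", "b2"),
                             scale = c(1, 1, 2, 2),
                             mu = c(3.0, 4.2, 3.6, 2.8),
                             loading = c(.6, .7, .5, -.6),
                             uniqueness = c(.6, .5, .7, .6)),
                  scale_labels = c("S1", "S2"))
  prior <- prior_spec(cov = diag(2))
  state <- new_session(bank, prior)

  # brute-force enumeration of cross-scale pairs under each threshold
  brute <- function(T) {
    out <- 0
    for (i in 1:3) for (k in (i + 1):4) {
      if (bank$items$scale[i] != bank$items$scale[k] &&
          abs(bank$items$mu[i] - bank$items$mu[k]) <= T) out <- out + 1
    }
    out
  }
  for (T in c(0.5, 1.0, Inf)) {
    cands <- enumerate_candidates(state, bank, desirability_constraint(T))
    expect_equal(nrow(cands), brute(T))
    expect_true(all(cands$first < cands$second))  # lexicographic within pair
  }
  # |3.0 - 3.6| = 0.6: eligible under T = 1, excluded under T = 0.5
  len <- enumerate_candidates(state, bank, desirability_constraint(1.0))
  expect_true(any(len$first == "a1" & len$second == "b1"))
  strict <- enumerate_candidates(state, bank, desirability_constraint(0.5))
  expect_false(any(strict$first == "a1" & strict$second == "b1"))
  # T = Inf ("none"): all cross-scale pairs of remaining items
  expect_equal(nrow(enumerate_candidates(state, bank, desirability_constraint("none"))),
               4L)
  # strict set nested inside lenient set
  expect_true(all(paste(strict$first, strict$second) %in%
                    paste(len$first, len$second)))
  expect_error(desirability_constraint(-1), "config error")
})

test_that("A-optimality scores match explicit inversion and rank candidates correctly", {
  bank <- toy_bank2()
  prior <- prior_spec(cov = matrix(c(1, .3, .3, 1), 2))
  state <- new_session(bank, prior)
  state$interim <- c(0.5, -0.5)
  state$test_info <- pair_information(pair_block("i3", "k3"), state$interim, bank)

  cands <- enumerate_candidates(state, bank, desirability_constraint(Inf))
  # remove the administered items by hand to mimic a mid-session state
  base_trace <- sum(diag(solve(prior$prec + state$test_info)))

  explicit <- vapply(seq_len(nrow(cands)), function(j) {
    a_optimality_score(pair_block(cands$first[j], cands$second[j]),
                       state, bank, prior)
  }, numeric(1))
  # every informative candidate strictly reduces total error variance
  expect_true(all(explicit < base_trace))

  # Sherman-Morrison fast path agrees with explicit inversion to 1e-10
  pt <- fccat:::pair_table(bank, desirability_constraint(Inf))
  fast <- fccat:::score_pairs_fast(pt, seq_len(pt$n_pairs), state$interim,
                                   prior$prec + state$test_info)
  key_fast <- paste(bank$items$item_id[pt$i], bank$items$item_id[pt$k])
  fast <- fast[match(paste(cands$first, cands$second), key_fast)]
  expect_equal(fast, explicit, tolerance = 1e-10)
  expect_equal(order(fast), order(explicit))

  # a zero-information candidate leaves the trace unchanged
  flat <- fc_bank(data.frame(item_id = c("a", "b", "c"), scale = c(1, 1, 2),
                             mu = c(3, 3.2, 4), loading = c(.6, .6, .5),
                             uniqueness = c(.6, .6, .7)),
                  scale_labels = c("S1", "S2"))
  st2 <- new_session(flat, prior)
  expect_equal(a_optimality_score(pair_block("a", "b"), st2, flat, prior),
               sum(diag(solve(prior$prec))))
})

test_that("pair selection returns the minimal-score candidate with seeded tie-breaks", {
  bank <- toy_bank2()
  prior <- prior_spec(cov = diag(2))
  state <- new_session(bank, prior)
  cands <- enumerate_candidates(state, bank, desirability_constraint(Inf))
  picked <- local({ set.seed(1); select_next_pair(state, bank, prior, Inf) })
  scores <- vapply(seq_len(nrow(cands)), function(j) {
    a_optimality_score(pair_block(cands$first[j], cands$second[j]),
                       state, bank, prior)
  }, numeric(1))
  expect_equal(attr(picked, "score"), min(scores), tolerance = 1e-10)

  # exactly one eligible candidate: it is returned
  lone <- fc_bank(data.frame(item_id = c("a", "b"), scale = c(1, 2),
                             mu = c(3, 3.2), loading = c(.6, .5),
                             uniqueness = c(.6, .7)),
                  scale_labels = c("S1", "S2"))
  got <- select_next_pair(new_session(lone, prior), lone, prior, 0.5)
  expect_equal(got$first, "a"); expect_equal(got$second, "b")

  # bitwise-equal scores from two clone items: seeded choice is reproducible
  twin <- fc_bank(data.frame(item_id = c("a1", "a2", "b1"), scale = c(1, 1, 2),
                             mu = c(3, 3, 3.1), loading = c(.6, .6, .5),
                             uniqueness = c(.6, .6, .7)),
                  scale_labels = c("S1", "S2"))
  st <- new_session(twin, prior)
  pick1 <- local({ set.seed(9); select_next_pair(st, twin, prior, 1.0) })
  pick2 <- local({ set.seed(9); select_next_pair(st, twin, prior, 1.0) })
  expect_equal(pick1, pick2)

  # exhausted pool signals a classed termination condition
  st$remaining <- character()
  expect_error(select_next_pair(st, twin, prior, 1.0),
               class = "fccat_pool_exhausted")
})

test_that("adaptive sessions respect item reuse, constraint soundness and truncation flags", {
  bank <- synthesize_bank(seed = 1)
  prior <- default_prior()
  res <- run_adaptive_session(bank, prior, 0.5, 40,
                              true_eta = c(1, -1, 0, .5, -.5, 2), seed = 12)
  items <- c(res$form$first, res$form$second)
  expect_equal(length(unique(items)), 2L * res$n_blocks)  # no item reuse
  mu <- bank$items$mu[fccat:::bank_index(bank, res$form$first)] -
    bank$items$mu[fccat:::bank_index(bank, res$form$second)]
  expect_true(all(abs(mu) <= 0.5))                        # constraint soundness
  sc1 <- bank$items$scale[fccat:::bank_index(bank, res$form$first)]
  sc2 <- bank$items$scale[fccat:::bank_index(bank, res$form$second)]
  expect_true(all(sc1 != sc2))                            # MFC pairing
  expect_false(res$truncated)

  # zero-length session: estimate is the prior mean
  res0 <- run_adaptive_session(bank, prior, 0.5, 0, true_eta = rep(0, 6), seed = 1)
  expect_equal(res0$n_blocks, 0L)
  expect_equal(res0$estimate$eta_hat, prior$mean)

  # infeasible pool: a bank whose only eligible pair is consumed first
  tiny <- fc_bank(data.frame(item_id = c("a", "b", "c", "d"),
                             scale = c(1, 2, 1, 2),
                             mu = c(3, 3.1, 1.5, 5.5),
                             loading = c(.6, .5, .7, .6),
                             uniqueness = c(.6, .7, .5, .6)),
                  scale_labels = c("S1", "S2"))
  pr2 <- prior_spec(cov = diag(2))
  trunc <- run_adaptive_session(tiny, pr2, 0.5, 2, true_eta = c(0, 0), seed = 1)
  expect_true(trunc$truncated)
  expect_match(trunc$reason, "exhausted")
  expect_equal(trunc$n_blocks, 1L)

  expect_error(run_adaptive_session(tiny, pr2, 0.5, 3, true_eta = c(0, 0)),
               "exceeds the bank size")
})

test_that("static assembly is a deterministic origin-pinned greedy optimizer", {
  bank <- synthesize_bank(seed = 1)
  prior <- default_prior()
  s1 <- assemble_static_test(bank, prior, 1.0, 30, seed = 4)
  s2 <- assemble_static_test(bank, prior, 1.0, 30, seed = 4)
  expect_equal(s1$form, s2$form)
  expect_equal(attr(s1$form, "provenance"), "static")

  # step-1 block equals the adaptive step-1 block: identical initial state
  ad <- run_adaptive_session(bank, prior, 1.0, 1, true_eta = rep(0, 6), seed = 4)
  expect_equal(s1$form[1, c("first", "second")], ad$form[1, c("first", "second")])

  # greedy property: each chosen block minimizes the origin-evaluated score
  small <- random_bank(S = 2, per_scale = 5, seed = 17, mu_range = c(3, 4))
  pr2 <- prior_spec(cov = diag(2))
  st <- assemble_static_test(small, pr2, Inf, 3, seed = 0)
  state <- new_session(small, pr2)
  for (step in 1:3) {
    cands <- enumerate_candidates(state, small, desirability_constraint(Inf))
    scores <- vapply(seq_len(nrow(cands)), function(j) {
      a_optimality_score(pair_block(cands$first[j], cands$second[j]),
                         state, small, pr2)
    }, numeric(1))
    chosen <- a_optimality_score(
      pair_block(st$form$first[step], st$form$second[step]), state, small, pr2)
    expect_equal(chosen, min(scores), tolerance = 1e-10)
    state$test_info <- state$test_info + pair_information(
      pair_block(st$form$first[step], st$form$second[step]), prior_spec(cov = diag(2))$mean,
      small)
    state$remaining <- setdiff(state$remaining,
                               c(st$form$first[step], st$form$second[step]))
  }

  # origin-pinned SEM trajectory is exactly nonincreasing
  expect_true(all(diff(s1$sem_trajectory) <= 1e-12))
})

test_that("strict-eligible candidates nest inside lenient-eligible sets mid-session", {
  bank <- synthesize_bank(seed = 2)
  prior <- default_prior()
  res <- run_adaptive_session(bank, prior, 1.0, 20, true_eta = rep(0.5, 6), seed = 3)
  state <- new_session(bank, prior)
  state$remaining <- setdiff(state$remaining, c(res$form$first, res$form$second))
  strict <- enumerate_candidates(state, bank, desirability_constraint(0.5))
  lenient <- enumerate_candidates(state, bank, desirability_constraint(1.0))
  expect_true(all(paste(strict$first, strict$second) %in%
                    paste(lenient$first, lenient$second)))
  expect_lt(nrow(strict), nrow(lenient))
})

test_that("forms and session logs round-trip through their file formats", {
  bank <- cli_bank()
  prior <- default_prior()
  res <- run_adaptive_session(bank, prior, 1.0, 3, true_eta = rep(0, 6), seed = 2)
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_form(res$form, fpath)
  expect_equal(read_form(fpath), res$form, ignore_attr = TRUE)

  lpath <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(res, lpath)
  rec <- jsonlite::fromJSON(readLines(lpath)[1])
  expect_equal(rec$first, res$form$first[1])
  expect_equal(rec$y, res$responses$y[1])
  expect_length(rec$eta, 6)
})
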