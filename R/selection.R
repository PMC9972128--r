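#' Social-desirability balancing constraint
#'
#' In lieu of direct desirability ratings, item mean utilities act as the
#' desirability proxy: a pair \{i, k\} is eligible only when
#' |mu_i - mu_k| <= T. \code{"none"} (or \code{Inf}) removes the constraint.
#' The conventional operating points are T = 0.5 (strict) and T = 1.0
#' (lenient).
#'
#' @param threshold Nonnegative number, \code{Inf}, or the string
#'   \code{"none"}.
#' @return A list of class \code{fc_constraint} with elements
#'   \code{threshold} and \code{label} (\code{"strict"}, \code{"lenient"},
#'   \code{"none"}, or \code{"T=<x>"}).
#' @export
desirability_constraint <- function(threshold = 1.0) {
  if (is.character(threshold)) {
    if (!identical(tolower(threshold), "none")) {
      stop("constraint config error: threshold must be a nonnegative number or \"none\"",
           call. = FALSE)
    }
    threshold <- Inf
  }
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("constraint config error: threshold must be a nonnegative number or \"none\"",
         call. = FALSE)
  }
  label <- if (!is.finite(threshold)) "none"
           else if (threshold == 0.5) "strict"
           else if (threshold == 1.0) "lenient"
           else paste0("T=", format(threshold))
  structure(list(threshold = threshold, label = label), class = "fc_constraint")
}

as_constraint <- function(x) {
  if (inherits(x, "fc_constraint")) x else desirability_constraint(x)
}

# Precomputed table of all eligible cross-scale pairs of a bank, in
# lexicographic (first_id, second_id) order with first_id < second_id.
# Built once per session; per-step filtering just masks consumed items
# (output-equivalent to full re-enumeration each step).
pair_table <- function(bank, constraint) {
  constraint <- as_constraint(constraint)
  it <- bank$items
  ord <- order(it$item_id)
  n <- nrow(it)
  ut <- which(upper.tri(matrix(NA_integer_, n, n)), arr.ind = TRUE)
  a <- ord[ut[, 1]]   # lexicographically smaller id
  b <- ord[ut[, 2]]
  keep <- it$scale[a] != it$scale[b] &
    abs(it$mu[a] - it$mu[b]) <= constraint$threshold
  a <- a[keep]; b <- b[keep]
  # upper.tri ordering is column-major over the id-sorted grid, which is
  # lexicographic in (second, first); reorder to (first, second)
  o <- order(it$item_id[a], it$item_id[b])
  a <- a[o]; b <- b[o]
  list(
    i = a, k = b,
    dmu = it$mu[a] - it$mu[b],
    l1 = it$loading[a], s1 = it$scale[a],
    l2 = it$loading[b], s2 = it$scale[b],
    sden = sqrt(it$uniqueness[a] + it$uniqueness[b]),
    n_pairs = length(a)
  )
}

#' Start an adaptive session state
#'
#' @param bank An \code{fc_bank}.
#' @param prior An \code{fc_prior}; the interim estimate starts at its mean
#'   (the origin under the default prior).
#' @return A list of class \code{fc_session} with fields \code{administered}
#'   (data frame of presented blocks), \code{responses}, \code{remaining}
#'   (item ids not yet used), \code{interim}, \code{test_info}, \code{step}.
#' @export
new_session <- function(bank, prior) {
  structure(list(
    administered = data.frame(step = integer(), first = character(),
                              second = character(), stringsAsFactors = FALSE),
    responses = response_records(),
    remaining = sort(bank$items$item_id),
    interim = prior$mean,
    test_info = matrix(0, bank$n_scales, bank$n_scales),
    step = 0L
  ), class = "fc_session")
}

#' Enumerate eligible candidate pairs
#'
#' All unordered cross-scale pairs of remaining items whose utility
#' difference satisfies the desirability constraint, in lexicographic order
#' by item ids (the smaller id is listed first).
#'
#' @param state An \code{fc_session}.
#' @param bank An \code{fc_bank}.
#' @param constraint An \code{fc_constraint} (or a threshold coercible to one).
#' @return A data frame with columns \code{first}, \code{second}; zero rows
#'   signal an exhausted eligible pool.
#' @export
enumerate_candidates <- function(state, bank, constraint) {
  pt <- pair_table(bank, constraint)
  alive <- bank$items$item_id %in% state$remaining
  ok <- alive[pt$i] & alive[pt$k]
  data.frame(first = bank$items$item_id[pt$i[ok]],
             second = bank$items$item_id[pt$k[ok]],
             stringsAsFactors = FALSE)
}

#' Bayesian A-optimality score of a candidate pair
#'
#' The total posterior error variance across traits after (hypothetically)
#' administering the candidate: the trace of the inverse of
#' \eqn{\Sigma^{-1} + I_{test} + F_{cand}(\hat\eta)}, with the candidate's
#' Fisher information evaluated at the interim trait estimate. Lower is
#' better.
#'
#' @param candidate An \code{fc_pair}.
#' @param state An \code{fc_session}.
#' @param bank An \code{fc_bank}.
#' @param prior An \code{fc_prior}.
#' @return Scalar score.
#' @export
a_optimality_score <- function(candidate, state, bank, prior) {
  A <- prior$prec + state$test_info +
    pair_information(candidate, state$interim, bank)
  sum(diag(solve(A)))
}

# Vectorized A-optimality scores for masked rows of a pair table via the
# rank-one (Sherman-Morrison) downdate of trace((A + g u u')^{-1}):
#   trace - g * u'A^{-2}u / (1 + g * u'A^{-1}u),
# where u has two nonzero entries (l1 at s1, -l2 at s2).
score_pairs_fast <- function(pt, idx, eta, A) {
  Ainv <- chol2inv(chol(A))
  G <- Ainv %*% Ainv
  trA <- sum(diag(Ainv))
  s1 <- pt$s1[idx]; s2 <- pt$s2[idx]
  l1 <- pt$l1[idx]; l2 <- pt$l2[idx]
  z <- (pt$dmu[idx] + l1 * eta[s1] - l2 * eta[s2]) / pt$sden[idx]
  p <- clamp_p(stats::pnorm(z))
  g <- stats::dnorm(z)^2 / (p * (1 - p) * pt$sden[idx]^2)
  q1 <- l1 * l1 * Ainv[cbind(s1, s1)] - 2 * l1 * l2 * Ainv[cbind(s1, s2)] +
    l2 * l2 * Ainv[cbind(s2, s2)]
  q2 <- l1 * l1 * G[cbind(s1, s1)] - 2 * l1 * l2 * G[cbind(s1, s2)] +
    l2 * l2 * G[cbind(s2, s2)]
  trA - g * q2 / (1 + g * q1)
}

# index of the minimal score, ties within relative tolerance broken
# uniformly at random from the current RNG stream
pick_min_tied <- function(scores, rel_tol = 1e-12) {
  m <- min(scores)
  tied <- which(scores <= m + rel_tol * max(1, abs(m)))
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

pool_exhausted <- function(step) {
  structure(class = c("fccat_pool_exhausted", "error", "condition"),
            list(message = paste0("no eligible candidate pairs remain at step ", step),
                 call = NULL))
}

#' Select the next forced-choice pair
#'
#' Enumerates the eligible candidate pairs for the current state and returns
#' the one with the minimal Bayesian A-optimality score evaluated at the
#' interim trait estimate. Exact score ties (within relative tolerance 1e-12)
#' are broken uniformly at random from the current RNG stream.
#'
#' @inheritParams enumerate_candidates
#' @param prior An \code{fc_prior}.
#' @return An \code{fc_pair} with attribute \code{"score"}. Signals an error
#'   of class \code{fccat_pool_exhausted} when no candidate is eligible.
#' @export
select_next_pair <- function(state, bank, prior, constraint) {
  pt <- pair_table(bank, constraint)
  alive <- bank$items$item_id %in% state$remaining
  idx <- which(alive[pt$i] & alive[pt$k])
  if (length(idx) == 0L) stop(pool_exhausted(state$step + 1L))
  A <- prior$prec + state$test_info
  scores <- score_pairs_fast(pt, idx, state$interim, A)
  j <- idx[pick_min_tied(scores)]
  out <- pair_block(bank$items$item_id[pt$i[j]], bank$items$item_id[pt$k[j]])
  attr(out, "score") <- min(scores)
  out
}

# Shared greedy driver for adaptive sessions and static assembly.
# adaptive = FALSE pins the interim estimate at the prior mean and skips
# response collection / re-estimation.
run_greedy <- function(bank, prior, constraint, test_length,
                       true_eta = NULL, responder = NULL,
                       adaptive = TRUE, tol = 1e-6, max_iter = 100L) {
  constraint <- as_constraint(constraint)
  S <- bank$n_scales
  if (2L * test_length > bank_size(bank)) {
    stop("test_length * 2 exceeds the bank size", call. = FALSE)
  }
  pt <- pair_table(bank, constraint)
  alive <- rep(TRUE, bank_size(bank))
  eta <- prior$mean
  A <- prior$prec     # posterior information at current interim

  first_i <- integer(test_length); second_i <- integer(test_length)
  y <- integer(test_length); scores <- numeric(test_length)
  eta_traj <- matrix(NA_real_, test_length, S)
  sem_traj <- matrix(NA_real_, test_length, S)
  # growing response design (adaptive only)
  d <- list(n = 0L, dmu = numeric(0), l1 = numeric(0), s1 = integer(0),
            l2 = numeric(0), s2 = integer(0), sden = numeric(0),
            y = integer(0), S = S)
  est <- NULL
  truncated <- FALSE; reason <- NA_character_
  n_done <- 0L

  for (step in seq_len(test_length)) {
    idx <- which(alive[pt$i] & alive[pt$k])
    if (length(idx) == 0L) {
      truncated <- TRUE
      reason <- paste0("eligible pool exhausted at step ", step)
      break
    }
    sc <- score_pairs_fast(pt, idx, eta, A)
    j <- idx[pick_min_tied(sc)]
    i1 <- pt$i[j]; i2 <- pt$k[j]
    alive[i1] <- FALSE; alive[i2] <- FALSE
    first_i[step] <- i1; second_i[step] <- i2
    scores[step] <- min(sc)
    n_done <- step

    if (adaptive) {
      # observe the preference
      z_true <- NULL
      if (!is.null(responder)) {
        yj <- as.integer(responder(pair_block(bank$items$item_id[i1],
                                              bank$items$item_id[i2])))
      } else {
        zt <- (pt$dmu[j] + pt$l1[j] * true_eta[pt$s1[j]] -
                 pt$l2[j] * true_eta[pt$s2[j]]) / pt$sden[j]
        p <- stats::pnorm(max(min(zt, Z_CLAMP), -Z_CLAMP))
        yj <- as.integer(stats::runif(1) < p)
      }
      y[step] <- yj
      d$n <- d$n + 1L
      d$dmu <- c(d$dmu, pt$dmu[j]); d$sden <- c(d$sden, pt$sden[j])
      d$l1 <- c(d$l1, pt$l1[j]); d$s1 <- c(d$s1, pt$s1[j])
      d$l2 <- c(d$l2, pt$l2[j]); d$s2 <- c(d$s2, pt$s2[j])
      d$y <- c(d$y, yj)
      # re-estimate after every block, warm-started at the previous interim
      est <- map_estimate_design(d, prior, start = eta, tol = tol,
                                 max_iter = max_iter)
      eta <- est$eta_hat
      A <- fisher_design(d, eta) + prior$prec
      eta_traj[step, ] <- eta
      sem_traj[step, ] <- est$sem
    } else {
      # static assembly: information accrues at the origin, no responses
      A <- A + pair_information_rows(pt, j, eta, S)
      sem_traj[step, ] <- directional_sem(A)
      eta_traj[step, ] <- eta
    }
  }

  ids <- bank$items$item_id
  used <- seq_len(n_done)
  form <- data.frame(step = used, first = ids[first_i[used]],
                     second = ids[second_i[used]], stringsAsFactors = FALSE)
  if (is.null(est)) {
    est <- structure(list(eta_hat = prior$mean, sem = directional_sem(A),
                          converged = TRUE, n_iter = 0L, grad_norm = 0),
                     class = "fc_estimate")
  }
  list(
    form = form,
    responses = if (adaptive) response_records(form$first, form$second, y[used])
                else NULL,
    eta_trajectory = eta_traj[used, , drop = FALSE],
    sem_trajectory = sem_traj[used, , drop = FALSE],
    scores = scores[used],
    estimate = est,
    n_blocks = n_done,
    truncated = truncated,
    reason = reason,
    constraint = constraint
  )
}

pair_information_rows <- function(pt, j, eta, S) {
  z <- (pt$dmu[j] + pt$l1[j] * eta[pt$s1[j]] - pt$l2[j] * eta[pt$s2[j]]) / pt$sden[j]
  p <- clamp_p(stats::pnorm(z))
  g <- stats::dnorm(z)^2 / (p * (1 - p) * pt$sden[j]^2)
  u <- numeric(S)
  u[pt$s1[j]] <- u[pt$s1[j]] + pt$l1[j]
  u[pt$s2[j]] <- u[pt$s2[j]] - pt$l2[j]
  g * tcrossprod(u)
}

#' Run one adaptive forced-choice session
#'
#' The CAT loop: select the best eligible pair by Bayesian A-optimality at
#' the interim estimate, administer it, append the observed preference,
#' re-estimate the trait profile by MAP (warm-started), and repeat. The
#' interim estimate starts at the prior mean (the origin). If the eligible
#' pool empties before \code{test_length} blocks, the session is truncated
#' and flagged with the reason.
#'
#' @param bank An \code{fc_bank}.
#' @param prior An \code{fc_prior}.
#' @param constraint Desirability constraint (threshold or
#'   \code{fc_constraint}).
#' @param test_length Number of pair blocks to administer.
#' @param true_eta Simulee trait profile generating Bernoulli responses.
#' @param responder Alternatively, a function \code{fc_pair -> 0/1} supplying
#'   live responses (overrides \code{true_eta}).
#' @param seed Optional integer seed governing response draws and score
#'   tie-breaks.
#' @return A list of class \code{fc_cat_result}: \code{form} (the administered
#'   blocks, provenance \code{"adaptive"}), \code{responses},
#'   \code{eta_trajectory} / \code{sem_trajectory} (per-step interim estimate
#'   and SEMs), \code{scores}, final \code{estimate}, \code{n_blocks},
#'   \code{truncated}, \code{reason}.
#' @export
run_adaptive_session <- function(bank, prior, constraint, test_length,
                                 true_eta = NULL, responder = NULL, seed = NULL) {
  if (is.null(true_eta) && is.null(responder)) {
    stop("supply either true_eta or a responder function", call. = FALSE)
  }
  if (!is.null(true_eta)) stopifnot(length(true_eta) == bank$n_scales)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  out <- run_greedy(bank, prior, constraint, test_length,
                    true_eta = true_eta, responder = responder, adaptive = TRUE)
  attr(out$form, "provenance") <- "adaptive"
  attr(out$form, "threshold") <- out$constraint$threshold
  class(out) <- "fc_cat_result"
  out
}

#' Assemble a static-optimal test form
#'
#' Applies the identical greedy A-optimality loop as the adaptive engine but
#' with the interim trait estimate pinned at the prior mean (the origin) and
#' no responses collected: each block maximally reduces total posterior error
#' variance for the average person in the target population. The result is a
#' fixed form, deterministic given bank, constraint and the tie-break seed
#' (recorded on the form).
#'
#' @inheritParams run_adaptive_session
#' @param seed Integer seed for score tie-breaks (recorded in the form).
#' @return A list of class \code{fc_static_result} with \code{form}
#'   (provenance \code{"static"}), \code{sem_trajectory} (origin SEMs after
#'   each block), \code{scores}, \code{n_blocks}, \code{truncated},
#'   \code{reason}.
#' @export
assemble_static_test <- function(bank, prior, constraint, test_length, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- run_greedy(bank, prior, constraint, test_length, adaptive = FALSE)
  out$responses <- NULL
  attr(out$form, "provenance") <- "static"
  attr(out$form, "threshold") <- out$constraint$threshold
  attr(out$form, "seed") <- seed
  class(out) <- "fc_static_result"
  out
}

#' @export
print.fc_cat_result <- function(x, ...) {
  cat("<fc_cat_result>", x$n_blocks, "blocks",
      if (x$truncated) paste0("(TRUNCATED: ", x$reason, ")") else "(complete)", "\n")
  print(x$estimate)
  invisible(x)
}

#' @export
print.fc_static_result <- function(x, ...) {
  cat("<fc_static_result>", x$n_blocks, "blocks, threshold",
      format(attr(x$form, "threshold")),
      if (x$truncated) paste0("(TRUNCATED: ", x$reason, ")") else "(complete)", "\n")
  invisible(x)
}

#' Write / read a test form as CSV
#'
#' Columns \code{step,first_item,second_item}.
#'
#' @param form A form data frame (from a session or assembly result).
#' @param path File path.
#' @return \code{path} (write) or a form data frame (read).
#' @export
write_form <- function(form, path) {
  out <- data.frame(step = form$step, first_item = form$first,
                    second_item = form$second, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_form
#' @export
read_form <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  data.frame(step = raw$step, first = as.character(raw$first_item),
             second = as.character(raw$second_item), stringsAsFactors = FALSE)
}

#' Write a session log as JSON lines
#'
#' One object per step: \code{step}, \code{first}, \code{second}, \code{y}
#' (if adaptive), interim \code{eta}, \code{sem}, and the selection
#' \code{score}.
#'
#' @param result An \code{fc_cat_result} or \code{fc_static_result}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_session_log <- function(result, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  for (j in seq_len(result$n_blocks)) {
    rec <- list(step = j, first = result$form$first[j],
                second = result$form$second[j])
    if (!is.null(result$responses)) rec$y <- result$responses$y[j]
    rec$eta <- round(result$eta_trajectory[j, ], 6)
    rec$sem <- round(result$sem_trajectory[j, ], 6)
    rec$score <- round(result$scores[j], 8)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
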