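#' Define one simulation condition
#'
#' A condition crosses the item-selection mode (\code{"adaptive"} vs
#' \code{"static"}) with a desirability-balancing threshold.
#'
#' @param selection \code{"adaptive"} or \code{"static"}.
#' @param threshold Desirability threshold (0.5, 1.0, \code{"none"}, ...).
#' @return A list of class \code{fc_condition} with a human-readable
#'   \code{label} such as \code{"adaptive_strict"}.
#' @export
sim_condition <- function(selection = c("adaptive", "static"), threshold = 1.0) {
  selection <- match.arg(selection)
  constraint <- as_constraint(threshold)
  structure(list(selection = selection, constraint = constraint,
                 label = paste(selection, constraint$label, sep = "_")),
            class = "fc_condition")
}

#' The full condition grid
#'
#' All crossings of \{adaptive, static\} with the requested thresholds
#' (default: strict 0.5, lenient 1.0, and unconstrained).
#'
#' @param thresholds Thresholds to cross with both selection modes.
#' @return Named list of \code{fc_condition} objects.
#' @export
condition_grid <- function(thresholds = c(0.5, 1.0, Inf)) {
  out <- list()
  for (sel in c("adaptive", "static")) {
    for (th in thresholds) {
      cond <- sim_condition(sel, th)
      out[[cond$label]] <- cond
    }
  }
  out
}

#' Configure a simulation experiment
#'
#' The defaults mirror the reference study design: 2,000 simulees drawn from
#' a multivariate normal trait distribution, 120-pair tests, and precision
#' metrics recorded every 10 blocks.
#'
#' @param bank An \code{fc_bank} (default: the synthetic default bank).
#' @param prior An \code{fc_prior} population/prior distribution.
#' @param n_simulees Number of simulees (default 2000).
#' @param test_length Pairs per test (default 120).
#' @param conditions Named list of \code{fc_condition} objects.
#' @param checkpoints Test lengths at which metrics are recorded; must not
#'   exceed \code{test_length}.
#' @param master_seed Single master seed; every random stream (simulees,
#'   response noise, tie-breaks) is derived from it so that the same simulees
#'   and noise streams are reused across conditions (matched-seed contrasts).
#' @return A list of class \code{fc_sim_config}.
#' @export
simulation_config <- function(bank = synthesize_bank(),
                              prior = default_prior(),
                              n_simulees = 2000L,
                              test_length = 120L,
                              conditions = condition_grid(),
                              checkpoints = if (test_length >= 10L)
                                seq(10L, test_length, by = 10L) else test_length,
                              master_seed = 0L) {
  if (n_simulees < 1L) stop("simulation config error: n_simulees must be >= 1", call. = FALSE)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints > test_length) || any(checkpoints < 0L)) {
    stop("simulation config error: checkpoints must lie in 0..test_length", call. = FALSE)
  }
  structure(list(bank = bank, prior = prior, n_simulees = as.integer(n_simulees),
                 test_length = as.integer(test_length), conditions = conditions,
                 checkpoints = checkpoints, master_seed = as.integer(master_seed)),
            class = "fc_sim_config")
}

# Deterministic sub-seeds derived from the master seed; identical across
# conditions so simulees and their response-noise streams are matched.
derive_seeds <- function(master_seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw simulees from the trait population
#'
#' @param n Number of simulees.
#' @param prior An \code{fc_prior} (population distribution).
#' @param seed Integer seed.
#' @return An n x S matrix of true trait profiles.
#' @export
generate_simulees <- function(n, prior, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- MASS::mvrnorm(n, mu = prior$mean, Sigma = prior$cov)
  if (n == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- colnames(prior$cov)
  m
}

#' Run one simulation condition
#'
#' For a static condition, one form is assembled at the origin and
#' administered to every simulee; for an adaptive condition, a full CAT
#' session is run per simulee. Trait estimates and directional SEMs are
#' recorded at every checkpoint (interim MAP estimates based on the
#' responses administered so far).
#'
#' @param config An \code{fc_sim_config}.
#' @param condition An \code{fc_condition}.
#' @return A list of class \code{fc_condition_result}: \code{condition},
#'   \code{true} (n x S), \code{est} and \code{sem} (n x S x K arrays over
#'   checkpoints), \code{checkpoints}, \code{metrics} (long data frame),
#'   \code{n_truncated}.
#' @export
run_condition <- function(config, condition) {
  bank <- config$bank; prior <- config$prior
  n <- config$n_simulees; K <- length(config$checkpoints)
  S <- bank$n_scales
  seeds <- derive_seeds(config$master_seed, n + 2L)
  simulee_seed <- seeds[1L]; form_seed <- seeds[2L]; resp_seeds <- seeds[-(1:2)]
  true <- generate_simulees(n, prior, seed = simulee_seed)

  est <- array(NA_real_, c(n, S, K))
  sem <- array(NA_real_, c(n, S, K))
  n_truncated <- 0L

  if (condition$selection == "static") {
    stat <- assemble_static_test(bank, prior, condition$constraint,
                                 config$test_length, seed = form_seed)
    if (stat$truncated) n_truncated <- NA_integer_  # form itself truncated
    d_full <- response_design(
      response_records(stat$form$first, stat$form$second,
                       rep(0L, nrow(stat$form))), bank)
    prior_sem <- directional_sem(prior$prec)
    for (i in seq_len(n)) {
      resp <- simulate_session(stat$form, true[i, ], bank, seed = resp_seeds[i])
      start <- prior$mean
      for (kk in seq_len(K)) {
        m <- min(config$checkpoints[kk], d_full$n)
        if (m == 0L) {
          est[i, , kk] <- prior$mean
          sem[i, , kk] <- prior_sem
          next
        }
        dm <- slice_design(d_full, m)
        dm$y <- resp$y[seq_len(m)]
        e <- map_estimate_design(dm, prior, start = start)
        est[i, , kk] <- e$eta_hat
        sem[i, , kk] <- e$sem
        start <- e$eta_hat
      }
    }
  } else {
    prior_sem <- directional_sem(prior$prec)
    for (i in seq_len(n)) {
      res <- run_adaptive_session(bank, prior, condition$constraint,
                                  config$test_length, true_eta = true[i, ],
                                  seed = resp_seeds[i])
      if (res$truncated) n_truncated <- n_truncated + 1L
      for (kk in seq_len(K)) {
        m <- min(config$checkpoints[kk], res$n_blocks)
        if (m == 0L) {
          est[i, , kk] <- prior$mean
          sem[i, , kk] <- prior_sem
        } else {
          est[i, , kk] <- res$eta_trajectory[m, ]
          sem[i, , kk] <- res$sem_trajectory[m, ]
        }
      }
    }
  }

  out <- structure(list(
    condition = condition, true = true, est = est, sem = sem,
    checkpoints = config$checkpoints, scale_labels = bank$scale_labels,
    n_simulees = n, n_truncated = n_truncated
  ), class = "fc_condition_result")
  out$metrics <- compute_metrics(out)
  out
}

slice_design <- function(d, m) {
  list(n = m, dmu = d$dmu[seq_len(m)], l1 = d$l1[seq_len(m)],
       s1 = d$s1[seq_len(m)], l2 = d$l2[seq_len(m)], s2 = d$s2[seq_len(m)],
       sden = d$sden[seq_len(m)], y = d$y[seq_len(m)], S = d$S)
}

# leave-one-out vectors for the three precision statistics, used for
# jackknife Monte-Carlo standard errors
loo_cor <- function(x, y) {
  n <- length(x); n1 <- n - 1
  Sx <- sum(x); Sy <- sum(y); Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
  mx <- (Sx - x) / n1; my <- (Sy - y) / n1
  vx <- pmax((Sxx - x^2) - n1 * mx^2, 0)   # guard rounding below zero
  vy <- pmax((Syy - y^2) - n1 * my^2, 0)
  cxy <- (Sxy - x * y) - n1 * mx * my
  cxy / sqrt(vx * vy)
}

loo_rmse <- function(err) {
  n <- length(err)
  sqrt((sum(err^2) - err^2) / (n - 1))
}

loo_mean <- function(x) {
  n <- length(x)
  (sum(x) - x) / (n - 1)
}

jackknife_se <- function(loo) {
  loo <- loo[is.finite(loo)]   # degenerate leave-one-out subsamples
  n <- length(loo)
  if (n < 2L) return(NA_real_)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Precision metrics of a condition result
#'
#' Per scale and checkpoint: the Pearson correlation between true and
#' estimated scores (COR), the root mean square error (RMSE), and the mean
#' directional SEM, each with a leave-one-simulee-out jackknife Monte-Carlo
#' standard error. A checkpoint whose estimates have zero variance yields a
#' missing COR.
#'
#' @param result An \code{fc_condition_result} (or compatible list with
#'   \code{true}, \code{est}, \code{sem}, \code{checkpoints},
#'   \code{scale_labels}, \code{condition}).
#' @return Long data frame: \code{condition, scale, checkpoint, metric,
#'   value, mc_se}.
#' @export
compute_metrics <- function(result) {
  ck <- result$checkpoints; labs <- result$scale_labels
  rows <- list()
  for (kk in seq_along(ck)) {
    for (s in seq_along(labs)) {
      tr <- result$true[, s]; es <- result$est[, s, kk]; se <- result$sem[, s, kk]
      few <- length(tr) < 2L
      if (few || stats::sd(es) < 1e-12) {
        cor_v <- NA_real_; cor_se <- NA_real_
      } else {
        cor_v <- stats::cor(tr, es)
        cor_se <- jackknife_se(loo_cor(tr, es))
      }
      err <- es - tr
      rows[[length(rows) + 1L]] <- data.frame(
        condition = result$condition$label,
        scale = labs[s], checkpoint = ck[kk],
        metric = c("cor", "rmse", "mean_sem"),
        value = c(cor_v, sqrt(mean(err^2)), mean(se)),
        mc_se = c(cor_se,
                  if (few) NA_real_ else jackknife_se(loo_rmse(err)),
                  if (few) NA_real_ else jackknife_se(loo_mean(se))),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Contrast precision metrics between conditions
#'
#' Computes per-scale, per-checkpoint differences in COR, RMSE, and mean SEM
#' between pairs of condition results run under matched seeds, with paired
#' jackknife Monte-Carlo standard errors (the leave-one-out statistic is the
#' difference, so the pairing by simulee is exploited).
#'
#' @param results Named list of \code{fc_condition_result} objects with
#'   identical simulees and checkpoints.
#' @param pairs Optional list of 2-element character vectors naming the
#'   contrasts (\code{a - b}); default: all unordered pairs of
#'   \code{results}.
#' @return Long data frame: \code{contrast, scale, checkpoint, metric, diff,
#'   mc_se, sign}; one row per contrast x scale x checkpoint x metric.
#' @export
compare_conditions <- function(results, pairs = NULL) {
  if (length(results) < 1L) stop("comparison error: no condition results", call. = FALSE)
  ref <- results[[1L]]
  for (r in results) {
    if (!identical(dim(r$true), dim(ref$true)) ||
        !identical(r$checkpoints, ref$checkpoints) ||
        !identical(r$scale_labels, ref$scale_labels) ||
        !isTRUE(all.equal(r$true, ref$true))) {
      stop("comparison error: condition results are not matched ",
           "(different simulees, checkpoints, or scales)", call. = FALSE)
    }
  }
  if (is.null(pairs)) {
    nm <- names(results)
    pairs <- list()
    if (length(nm) >= 2L) {
      for (a in seq_along(nm)) for (b in seq_along(nm)) {
        if (a < b) pairs[[length(pairs) + 1L]] <- c(nm[a], nm[b])
      }
    } else {
      pairs <- list(c(nm[1L], nm[1L]))
    }
  }
  ck <- ref$checkpoints; labs <- ref$scale_labels
  rows <- list()
  for (pr in pairs) {
    ra <- results[[pr[1]]]; rb <- results[[pr[2]]]
    for (kk in seq_along(ck)) {
      for (s in seq_along(labs)) {
        tr <- ref$true[, s]
        ea <- ra$est[, s, kk]; eb <- rb$est[, s, kk]
        da_cor <- loo_cor(tr, ea); db_cor <- loo_cor(tr, eb)
        da_rmse <- loo_rmse(ea - tr); db_rmse <- loo_rmse(eb - tr)
        da_sem <- loo_mean(ra$sem[, s, kk]); db_sem <- loo_mean(rb$sem[, s, kk])
        diffs <- c(
          cor = stats::cor(tr, ea) - stats::cor(tr, eb),
          rmse = sqrt(mean((ea - tr)^2)) - sqrt(mean((eb - tr)^2)),
          mean_sem = mean(ra$sem[, s, kk]) - mean(rb$sem[, s, kk])
        )
        ses <- c(jackknife_se(da_cor - db_cor),
                 jackknife_se(da_rmse - db_rmse),
                 jackknife_se(da_sem - db_sem))
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste(pr[1], "-", pr[2]),
          scale = labs[s], checkpoint = ck[kk],
          metric = names(diffs), diff = unname(diffs), mc_se = ses,
          sign = sign(unname(diffs)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a whole simulation experiment
#'
#' Runs every configured condition under matched seeds and binds the metric
#' tables.
#'
#' @param config An \code{fc_sim_config}.
#' @param progress Print a line as each condition finishes.
#' @return A list of class \code{fc_sim_result}: \code{results} (named list
#'   of condition results), \code{metrics} (combined long table),
#'   \code{config}.
#' @export
run_simulation <- function(config, progress = FALSE) {
  results <- list()
  for (cond in config$conditions) {
    results[[cond$label]] <- run_condition(config, cond)
    if (progress) message("condition ", cond$label, " done")
  }
  structure(list(results = results,
                 metrics = do.call(rbind, lapply(results, `[[`, "metrics")),
                 config = config),
            class = "fc_sim_result")
}

#' Write a metrics table as long-format CSV
#'
#' Columns \code{condition,scale,checkpoint,metric,value,mc_se}.
#'
#' @param metrics A metrics data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Plot precision trajectories
#'
#' One panel per metric: per-scale trajectories of COR / RMSE / mean SEM
#' against test length for each condition, drawn with base graphics.
#'
#' @param metrics A metrics data frame (possibly several conditions).
#' @param metric Which metric to draw.
#' @return Invisibly, the reshaped plotting table.
#' @export
plot_precision <- function(metrics, metric = c("mean_sem", "cor", "rmse")) {
  metric <- match.arg(metric)
  mm <- metrics[metrics$metric == metric, ]
  conds <- unique(mm$condition); scales <- unique(mm$scale)
  cols <- grDevices::hcl.colors(max(2L, length(conds)), "Dark 3")
  plot(range(mm$checkpoint), range(mm$value, na.rm = TRUE), type = "n",
       xlab = "test length (pairs)", ylab = metric,
       main = paste("Precision trajectory:", metric))
  for (ci in seq_along(conds)) {
    for (s in scales) {
      sub <- mm[mm$condition == conds[ci] & mm$scale == s, ]
      graphics::lines(sub$checkpoint, sub$value, col = cols[ci],
                      lty = match(s, scales))
    }
  }
  graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                   lty = 1, cex = 0.7, bty = "n")
  invisible(mm)
}
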