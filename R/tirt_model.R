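#' Forced-choice pair block
#'
#' A multidimensional forced-choice (MFC) block of size two: the respondent is
#' shown two items measuring different traits and indicates which is more like
#' them. \code{y = 1} codes preference for the first item.
#'
#' @param first,second Item ids (character scalars).
#' @return A list of class \code{fc_pair}.
#' @export
pair_block <- function(first, second) {
  if (identical(first, second)) stop("pair block must contain two distinct items", call. = FALSE)
  structure(list(first = first, second = second), class = "fc_pair")
}

#' @export
print.fc_pair <- function(x, ...) {
  cat("<fc_pair> ", x$first, " vs ", x$second, "\n", sep = "")
  invisible(x)
}

# Internal: per-pair model constants from bank rows i (first), k (second).
# z = (mu_i - mu_k + lam_i * eta[s_i] - lam_k * eta[s_k]) / sden,
# sden = sqrt(psi_i^2 + psi_k^2).
pair_params <- function(bank, i, k) {
  it <- bank$items
  list(
    dmu = it$mu[i] - it$mu[k],
    l1 = it$loading[i], s1 = it$scale[i],
    l2 = it$loading[k], s2 = it$scale[k],
    sden = sqrt(it$uniqueness[i] + it$uniqueness[k])
  )
}

resolve_pair <- function(block, bank) {
  bank_index(bank, c(block$first, block$second))
}

#' Latent comparison variate of a forced-choice pair
#'
#' Under the Thurstonian IRT model each item carries a normally distributed
#' latent utility; the first item is preferred when its utility exceeds the
#' second item's. The standardized difference at trait profile \code{eta} is
#' \deqn{z_{ik} = \frac{\mu_i - \mu_k + (\lambda_i - \lambda_k)^\top \eta}
#'   {\sqrt{\psi_i^2 + \psi_k^2}}.}
#'
#' @param block An \code{fc_pair} (items must be in the bank).
#' @param eta Numeric trait profile of length \code{bank$n_scales}.
#' @param bank An \code{fc_bank}.
#' @return The scalar z value.
#' @export
pair_z <- function(block, eta, bank) {
  stopifnot(length(eta) == bank$n_scales, all(is.finite(eta)))
  ik <- resolve_pair(block, bank)
  p <- pair_params(bank, ik[1], ik[2])
  (p$dmu + p$l1 * eta[p$s1] - p$l2 * eta[p$s2]) / p$sden
}

#' Probability of preferring the first item in a pair
#'
#' The probit item response function \eqn{P(Y_{ik}=1 \mid \eta) = \Phi(z_{ik})}
#' of the Thurstonian IRT model for dominance items.
#'
#' @inheritParams pair_z
#' @return Probability in (0, 1).
#' @export
pair_probability <- function(block, eta, bank) {
  stats::pnorm(pair_z(block, eta, bank))
}

# |z| clamp applied before Bernoulli sampling so simulated sessions never
# produce exactly deterministic response streams
Z_CLAMP <- 8

#' Simulate one forced-choice response
#'
#' Draws \code{y ~ Bernoulli(pnorm(z))} (with |z| clamped to 8) from the
#' current RNG stream, or from \code{seed} if given.
#'
#' @inheritParams pair_z
#' @param seed Optional integer seed for a self-contained draw.
#' @return A one-row response record data frame (\code{first, second, y}).
#' @export
simulate_response <- function(block, eta, bank, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  z <- pair_z(block, eta, bank)
  p <- stats::pnorm(max(min(z, Z_CLAMP), -Z_CLAMP))
  response_records(first = block$first, second = block$second,
                   y = as.integer(stats::runif(1) < p))
}

#' Build a response-record table
#'
#' Responses to administered pairs are kept as a data frame of class
#' \code{fc_responses} with columns \code{first}, \code{second} (item ids) and
#' \code{y} (1 = first item preferred, 0 = second).
#'
#' @param first,second Character vectors of item ids.
#' @param y Integer vector of 0/1 preferences.
#' @return An \code{fc_responses} data frame.
#' @export
response_records <- function(first = character(), second = character(), y = integer()) {
  stopifnot(length(first) == length(second), length(first) == length(y))
  y <- as.integer(y)
  if (length(y) && !all(y %in% c(0L, 1L))) stop("responses must be coded 0/1", call. = FALSE)
  structure(data.frame(first = as.character(first), second = as.character(second),
                       y = y, stringsAsFactors = FALSE),
            class = c("fc_responses", "data.frame"))
}

#' Simulate a full forced-choice session on a fixed form
#'
#' Administers the blocks of \code{form} in order to a simulee with trait
#' profile \code{eta}, drawing one Bernoulli preference per block from a
#' single RNG stream (so concatenating sub-forms reproduces the session of
#' the concatenated form).
#'
#' @param form A test form: data frame with columns \code{first}/\code{second}
#'   (or \code{first_item}/\code{second_item}), one row per block, in
#'   administration order.
#' @param eta Numeric trait profile.
#' @param bank An \code{fc_bank}.
#' @param seed Optional integer seed.
#' @return An \code{fc_responses} data frame with one record per block.
#' @export
simulate_session <- function(form, eta, bank, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  form <- normalize_form(form)
  if (nrow(form) == 0L) return(response_records())
  i <- bank_index(bank, form$first)
  k <- bank_index(bank, form$second)
  z <- pair_z_rows(bank, i, k, eta)
  p <- stats::pnorm(pmax(pmin(z, Z_CLAMP), -Z_CLAMP))
  response_records(form$first, form$second, as.integer(stats::runif(nrow(form)) < p))
}

# vectorized z over rows of (i, k) index vectors
pair_z_rows <- function(bank, i, k, eta) {
  it <- bank$items
  (it$mu[i] - it$mu[k] + it$loading[i] * eta[it$scale[i]] -
     it$loading[k] * eta[it$scale[k]]) / sqrt(it$uniqueness[i] + it$uniqueness[k])
}

normalize_form <- function(form) {
  if (all(c("first_item", "second_item") %in% names(form))) {
    data.frame(first = as.character(form$first_item),
               second = as.character(form$second_item), stringsAsFactors = FALSE)
  } else {
    data.frame(first = as.character(form$first), second = as.character(form$second),
               stringsAsFactors = FALSE)
  }
}

#' Write / read a response stream as JSON lines
#'
#' One JSON object per administered block: \code{{"step": n, "first": id,
#' "second": id, "y": 0/1}}.
#'
#' @param responses An \code{fc_responses} data frame.
#' @param path File path.
#' @return \code{path} (write) or an \code{fc_responses} (read).
#' @export
write_responses <- function(responses, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  for (j in seq_len(nrow(responses))) {
    writeLines(jsonlite::toJSON(
      list(step = j, first = responses$first[j], second = responses$second[j],
           y = responses$y[j]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(response_records())
  recs <- lapply(lines, jsonlite::fromJSON)
  response_records(
    first = vapply(recs, function(r) r$first, ""),
    second = vapply(recs, function(r) r$second, ""),
    y = vapply(recs, function(r) as.integer(r$y), 0L)
  )
}
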