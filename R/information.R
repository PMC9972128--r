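#' Multivariate normal trait prior
#'
#' Specifies the population distribution of the latent traits used both as a
#' Bayesian prior for MAP scoring and as the prior information added to the
#' test Fisher information. The precision matrix is computed once via a
#' Cholesky factorization and cached.
#'
#' @param mean Prior mean vector (default: origin).
#' @param cov Symmetric positive-definite trait covariance matrix.
#' @return An object of class \code{fc_prior} with elements \code{mean},
#'   \code{cov}, \code{prec} (the inverse covariance) and \code{logdet}.
#' @export
prior_spec <- function(mean = rep(0, ncol(cov)), cov = diag(6)) {
  cov <- as.matrix(cov)
  if (!isSymmetric(cov, tol = 1e-10)) {
    stop("prior config error: covariance must be symmetric", call. = FALSE)
  }
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) <= 0)) {
    stop("prior config error: covariance must be positive-definite", call. = FALSE)
  }
  if (length(mean) != ncol(cov)) {
    stop("prior config error: mean length must match covariance dimension", call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), cov = cov,
                 prec = chol2inv(ch), logdet = 2 * sum(log(diag(ch)))),
            class = "fc_prior")
}

#' @export
print.fc_prior <- function(x, ...) {
  cat("<fc_prior> MVN over", length(x$mean), "traits\n")
  invisible(x)
}

#' Default HEXACO-style trait prior
#'
#' Unit trait variances with a modest factor intercorrelation pattern
#' (absolute correlations 0.1-0.3, positive-definite). The published
#' calibration covariances are not available, so this stands in as a
#' realistic population structure for six personality factors.
#'
#' @param scale_labels Trait labels (determines dimension).
#' @return An \code{fc_prior}.
#' @export
default_prior <- function(scale_labels = c("H", "E", "X", "A", "C", "O")) {
  S <- length(scale_labels)
  if (S == 6L) {
    R <- matrix(c(
      #  H     E     X     A     C     O
      1.0,  0.1, -0.1,  0.3,  0.2,  0.1,   # H
      0.1,  1.0, -0.2,  0.1,  0.0,  0.0,   # E
     -0.1, -0.2,  1.0,  0.1,  0.1,  0.2,   # X
      0.3,  0.1,  0.1,  1.0,  0.1,  0.0,   # A
      0.2,  0.0,  0.1,  0.1,  1.0,  0.1,   # C
      0.1,  0.0,  0.2,  0.0,  0.1,  1.0    # O
    ), 6, 6, byrow = TRUE)
    dimnames(R) <- list(scale_labels, scale_labels)
  } else {
    R <- diag(S)
    dimnames(R) <- list(scale_labels, scale_labels)
  }
  prior_spec(mean = rep(0, S), cov = R)
}

# probability clamp used inside information / likelihood denominators
P_EPS <- 1e-10

clamp_p <- function(p) pmin(pmax(p, P_EPS), 1 - P_EPS)

#' Fisher information of one forced-choice pair
#'
#' For a pair \{i, k\} at trait profile \code{eta}, the Fisher information
#' matrix in the trait metric is the rank-one outer product
#' \deqn{F_{ik}(\eta) = \frac{[\phi(z_{ik})]^2}{p_{ik}(1-p_{ik})
#'   (\psi_i^2+\psi_k^2)} (\lambda_i-\lambda_k)(\lambda_i-\lambda_k)^\top,}
#' with rows and columns indexed by traits. The Bernoulli variance in the
#' denominator is clamped away from zero so extreme z never divides by zero.
#'
#' @inheritParams pair_z
#' @return An S x S symmetric positive-semidefinite matrix of rank at most 1.
#' @export
pair_information <- function(block, eta, bank) {
  ik <- resolve_pair(block, bank)
  pp <- pair_params(bank, ik[1], ik[2])
  z <- (pp$dmu + pp$l1 * eta[pp$s1] - pp$l2 * eta[pp$s2]) / pp$sden
  p <- clamp_p(stats::pnorm(z))
  g <- stats::dnorm(z)^2 / (p * (1 - p) * pp$sden^2)
  u <- numeric(bank$n_scales)
  u[pp$s1] <- u[pp$s1] + pp$l1
  u[pp$s2] <- u[pp$s2] - pp$l2
  g * tcrossprod(u)
}

#' Test Fisher information of a set of pairs
#'
#' Sums the per-pair Fisher information matrices over all administered
#' pairwise comparisons.
#'
#' @param blocks A form (data frame with \code{first}/\code{second} columns)
#'   or a list of \code{fc_pair} blocks; may be empty.
#' @inheritParams pair_z
#' @return An S x S positive-semidefinite matrix.
#' @export
accumulate_test_information <- function(blocks, eta, bank) {
  S <- bank$n_scales
  if (is.data.frame(blocks)) {
    form <- normalize_form(blocks)
    blocks <- lapply(seq_len(nrow(form)),
                     function(j) pair_block(form$first[j], form$second[j]))
  }
  out <- matrix(0, S, S)
  for (b in blocks) out <- out + pair_information(b, eta, bank)
  out
}

#' Bayesian posterior information
#'
#' Adds the prior precision to the test Fisher information,
#' \eqn{I_{post} = \Sigma^{-1} + I_{test}}. The prior term keeps the posterior
#' information positive-definite even when the test information is singular,
#' as it necessarily is at the start of an adaptive session.
#'
#' @param test_info S x S test Fisher information matrix.
#' @param prior An \code{fc_prior}.
#' @return An S x S positive-definite matrix.
#' @export
posterior_information <- function(test_info, prior) {
  stopifnot(inherits(prior, "fc_prior"))
  prior$prec + test_info
}

#' Directional standard errors of measurement
#'
#' The SEM along trait axis s is the reciprocal square root of the posterior
#' information in the direction of that trait, i.e.
#' \eqn{\mathrm{SEM}_s = \sqrt{(I_{post}^{-1})_{ss}}}. Computed from the
#' inverse's diagonal (not \eqn{1/\sqrt{I_{ss}}}) so that cross-trait
#' correlations are accounted for.
#'
#' @param post_info Positive-definite S x S posterior information matrix.
#' @return Numeric S-vector of SEMs.
#' @export
directional_sem <- function(post_info) {
  ch <- tryCatch(chol(post_info), error = function(e) NULL)
  if (is.null(ch)) {
    stop("directional_sem: posterior information matrix is singular or not ",
         "positive-definite (reciprocal condition number ~ ",
         format(rcond(post_info), digits = 3), ")", call. = FALSE)
  }
  sqrt(diag(chol2inv(ch)))
}

#' Trait locus of maximal pair information
#'
#' A pair's information (the nonzero eigenvalue of its rank-one Fisher
#' matrix) peaks on the hyperplane where the comparison is an even call,
#' \eqn{z_{ik} = 0}:
#' \deqn{\mu_i - \mu_k + \lambda_{i,s_i}\eta_{s_i} - \lambda_{k,s_k}\eta_{s_k} = 0.}
#' Returned as the constraint \code{intercept + coef' eta = 0}.
#'
#' @inheritParams pair_z
#' @return A list of class \code{fc_locus} with \code{intercept} (mu_i - mu_k)
#'   and \code{coef} (S-vector, lambda_i at scale(i), -lambda_k at scale(k)).
#' @export
information_peak_locus <- function(block, bank) {
  ik <- resolve_pair(block, bank)
  pp <- pair_params(bank, ik[1], ik[2])
  co <- numeric(bank$n_scales)
  co[pp$s1] <- co[pp$s1] + pp$l1
  co[pp$s2] <- co[pp$s2] - pp$l2
  if (all(co == 0)) {
    stop("information peak locus is undefined: the two items have identical ",
         "loading vectors", call. = FALSE)
  }
  structure(list(intercept = pp$dmu, coef = co), class = "fc_locus")
}

#' Export an information matrix as labeled CSV
#'
#' @param info S x S information matrix.
#' @param path Output path.
#' @param scale_labels Row/column labels.
#' @return \code{path}, invisibly.
#' @export
write_information <- function(info, path, scale_labels = colnames(info)) {
  if (is.null(scale_labels)) scale_labels <- paste0("T", seq_len(ncol(info)))
  dimnames(info) <- list(scale_labels, scale_labels)
  utils::write.csv(info, path, row.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
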