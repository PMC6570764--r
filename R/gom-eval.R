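#' Log likelihood of data under a fitted motif model
#'
#' Evaluates the model log likelihood at the fitted parameters. For the
#' multinomial model the multinomial coefficient is omitted: it is constant
#' for a fixed data matrix, and all comparisons in this package (restart
#' ranking, Bayes factors, null-model comparisons) are made on identical
#' data. For the Bernoulli model the value is
#' \eqn{\sum_{ng} m_{ng}\log p_{ng} + (1-m_{ng})\log(1-p_{ng})}.
#'
#' A structural zero (`p = 0` where data demand support) yields `-Inf`, which
#' is returned rather than raised as an error.
#'
#' @param fit A `motif_fit`.
#' @param data The matrix the fit refers to (dimensions and labels must
#'   match).
#' @return A single number, possibly `-Inf`.
#' @export
loglik <- function(fit, data) {
  .check_fit_data(fit, data)
  X <- unclass(data)
  P <- fit$omega %*% fit$theta
  if (fit$model_kind == "multinomial") {
    pos <- X > 0
    if (any(P[pos] == 0)) return(-Inf)
    sum(X[pos] * log(P[pos]))
  } else {
    lp <- ifelse(X == 1, log(P), log1p(-P))
    if (any(is.nan(lp))) return(-Inf)  # log(0) * 0 corner never arises: X binary
    sum(lp)
  }
}

#' Approximate log Bayes factor of a fit against the K = 1 model
#'
#' Ranks fits of different complexity on the same data by a Laplace/BIC-style
#' approximation to the log marginal-likelihood difference against the
#' single-motif model:
#' \deqn{\log \mathrm{BF}(K) = [\mathrm{obj}(K) - \mathrm{obj}(1)]
#'   - \tfrac{1}{2}\,\Delta_{\mathrm{params}}\,\log(\mathrm{n_{obs}})}
#' where obj is the MAP objective, the parameter count is
#' \eqn{N(K-1) + K(G-1)} for the multinomial model and \eqn{N(K-1) + KG} for
#' the Bernoulli model (membership parameters are excluded for
#' partition-constrained fits), and the observation count is the total
#' number of censused individuals (multinomial) or of matrix entries
#' (Bernoulli). By construction the value is exactly 0 at K = 1. Absolute
#' values are approximation-dependent; only comparisons between fits on
#' identical data are meaningful.
#'
#' @inheritParams loglik
#' @return A single number; 0 for K = 1.
#' @export
log_bayes_factor <- function(fit, data) {
  .check_fit_data(fit, data)
  .approx_log_bf(fit, data)
}

.approx_log_bf <- function(fit, data) {
  if (fit$K == 1 && !isTRUE(fit$constrained)) return(0)
  X <- unclass(data)
  N <- nrow(X); G <- ncol(X)
  if (fit$model_kind == "multinomial") {
    obj_k <- .mult_objective(X, fit$omega, fit$theta,
                             fit$prior_omega, fit$prior_theta)
    theta1 <- .map_theta_multinomial_k1(X, fit$prior_theta)
    obj_1 <- .mult_objective(X, matrix(1, N, 1), theta1,
                             fit$prior_omega, fit$prior_theta)
    n_obs <- sum(X)
    p_k <- fit$K * (G - 1) +
      if (isTRUE(fit$constrained)) 0 else N * (fit$K - 1)
    p_1 <- G - 1
  } else {
    a <- fit$prior_theta[1]; b <- fit$prior_theta[2]
    obj_k <- .bern_objective(X, fit$omega, fit$theta, fit$prior_omega, a, b)
    theta1 <- matrix(.clip01((colSums(X) + a - 1) / (N + a + b - 2)), 1, G)
    obj_1 <- .bern_objective(X, matrix(1, N, 1), theta1, fit$prior_omega, a, b)
    n_obs <- N * G
    p_k <- fit$K * G + if (isTRUE(fit$constrained)) 0 else N * (fit$K - 1)
    p_1 <- G
  }
  (obj_k - obj_1) - 0.5 * (p_k - p_1) * log(n_obs)
}

.check_fit_data <- function(fit, data) {
  if (!inherits(fit, "motif_fit")) stop("fit must be a motif_fit")
  X <- unclass(data)
  if (nrow(X) != nrow(fit$omega) || ncol(X) != ncol(fit$theta)) {
    stop("fit dimensions do not match data")
  }
  if (!is.null(rownames(X)) && !identical(rownames(X), rownames(fit$omega))) {
    stop("row ids of data do not match fit")
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), colnames(fit$theta))) {
    stop("feature ids of data do not match fit")
  }
  invisible(TRUE)
}

#' Match motif labels between two fits
#'
#' Mixture likelihoods are invariant to permuting motif labels, so fits from
#' different restarts (or a fit versus simulation ground truth) must be
#' aligned before their parameters are compared. Finds the permutation of
#' `fit_b`'s motifs maximizing the summed Pearson correlation between matched
#' theta rows, by exhaustive search over all K! permutations for K <= 7 and a
#' greedy best-match heuristic beyond. Ties are broken by the
#' lexicographically smallest permutation.
#'
#' @param fit_a,fit_b `motif_fit` objects (or lists with a `theta` matrix)
#'   with equal K and identical feature sets.
#' @return Integer vector `perm` such that motif `perm[k]` of `fit_b`
#'   corresponds to motif `k` of `fit_a`.
#' @seealso [apply_motif_permutation()]
#' @export
align_motifs <- function(fit_a, fit_b) {
  ta <- fit_a$theta; tb <- fit_b$theta
  if (ncol(ta) != ncol(tb)) stop("fits have different feature counts")
  if (nrow(ta) != nrow(tb)) stop("fits have different K")
  K <- nrow(ta)
  if (K == 1) return(1L)
  S <- suppressWarnings(stats::cor(t(ta), t(tb)))
  S[!is.finite(S)] <- 0
  if (K <= 7) {
    perms <- .permutations(K)
    scores <- vapply(perms, function(p) sum(S[cbind(seq_len(K), p)]),
                     numeric(1))
    perms[[which.max(scores)]]   # which.max: first (lexicographic) winner
  } else {
    perm <- integer(K)
    taken <- rep(FALSE, K)
    for (k in seq_len(K)) {
      s <- S[k, ]; s[taken] <- -Inf
      perm[k] <- which.max(s)
      taken[perm[k]] <- TRUE
    }
    perm
  }
}

#' Reorder a fit's motifs by a permutation
#'
#' @param fit A `motif_fit`.
#' @param perm Integer permutation of `1..K`; motif `k` of the result is
#'   motif `perm[k]` of `fit`.
#' @return The fit with omega columns and theta rows reordered and relabelled
#'   `motif_1..motif_K`.
#' @export
apply_motif_permutation <- function(fit, perm) {
  if (!setequal(perm, seq_len(fit$K))) stop("perm must permute 1..K")
  fit$omega <- fit$omega[, perm, drop = FALSE]
  fit$theta <- fit$theta[perm, , drop = FALSE]
  colnames(fit$omega) <- paste0("motif_", seq_len(fit$K))
  rownames(fit$theta) <- paste0("motif_", seq_len(fit$K))
  fit
}

# all permutations of 1..n in lexicographic order
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(n - 1)
    for (p in rest) {
      q <- seq_len(n)[-i][p]
      out[[length(out) + 1]] <- c(i, q)
    }
  }
  out
}
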