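#' Fit a multinomial Grade-of-Membership model by EM
#'
#' Models each row of a count matrix as a multinomial draw whose cell
#' probabilities are a convex mixture of K motif profiles:
#' \eqn{p_{ng} = \sum_k \omega_{nk} \theta_{kg}}, with each membership vector
#' \eqn{\omega_{n\cdot}} and each motif profile \eqn{\theta_{k\cdot}} on the
#' probability simplex. Estimation is MAP EM with a per-individual latent
#' motif indicator; symmetric Dirichlet priors on the \eqn{\omega} rows and
#' \eqn{\theta} rows act as smoothing (concentration 1 = flat, no smoothing).
#'
#' The objective reported in `loglik_trace` is the log posterior: the
#' multinomial log likelihood without the combinatorial coefficient (constant
#' for fixed data) plus the Dirichlet log-prior terms. It is non-decreasing
#' over iterations; fitting stops when the relative change drops below `tol`
#' or after `max_iter` iterations.
#'
#' @param counts A `count_matrix` (see [as_count_matrix()]), N sites by G
#'   features.
#' @param K Number of motifs, `1 <= K <= min(N, G)`.
#' @param prior_omega,prior_theta Symmetric Dirichlet concentrations for the
#'   membership rows and motif profile rows. Default 1 (flat).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative objective-change convergence threshold.
#' @param seed Integer seed for the random initialization; `NULL` uses the
#'   current RNG state.
#' @param init Optional list with `omega` (N x K) and `theta` (K x G) starting
#'   values; overrides the random initialization.
#' @return A `motif_fit` object: `omega` (N x K), `theta` (K x G, rows on the
#'   simplex), `loglik_trace`, `log_bf` (approximate log Bayes factor versus
#'   the K = 1 fit), `converged`, `seed`.
#' @seealso [fit_bernoulli_gom()], [multistart_fit()], [log_bayes_factor()]
#' @export
fit_multinomial_gom <- function(counts, K, prior_omega = 1, prior_theta = 1,
                                max_iter = 1000, tol = 1e-8, seed = NULL,
                                init = NULL) {
  if (!inherits(counts, "count_matrix")) counts <- as_count_matrix(counts)
  .check_K(K, counts)
  .stopifnot_scalar(tol, "tol"); if (tol <= 0) stop("tol must be > 0")
  C <- unclass(counts)
  N <- nrow(C); G <- ncol(C)

  if (K == 1) {
    theta <- .map_theta_multinomial_k1(C, prior_theta)
    omega <- matrix(1, N, 1)
    obj <- .mult_objective(C, omega, theta, prior_omega, prior_theta)
    return(.new_motif_fit("multinomial", omega, theta, counts, obj,
                          prior_omega, prior_theta, seed, TRUE))
  }

  start <- if (is.null(init)) {
    with_seed(seed, list(
      omega = rdirichlet(N, rep(1, K)),
      theta = .normalize_rows(matrix(stats::rgamma(K * G, 1), K, G))
    ))
  } else init
  omega <- start$omega; theta <- start$theta
  stopifnot(nrow(omega) == N, ncol(omega) == K,
            nrow(theta) == K, ncol(theta) == G)

  trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- omega %*% theta
    P[P < 1e-300] <- 1e-300
    W <- C / P
    # expected counts assigned to each motif: A (per site), B (per feature)
    A <- omega * (W %*% t(theta))          # N x K
    B <- theta * (t(omega) %*% W)          # K x G
    omega <- .normalize_rows(pmax(A + prior_omega - 1, 0))
    theta <- .normalize_rows(pmax(B + prior_theta - 1, 0))
    obj <- .mult_objective(C, omega, theta, prior_omega, prior_theta)
    trace <- c(trace, obj)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < tol * (abs(obj_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  .new_motif_fit("multinomial", omega, theta, counts, trace,
                 prior_omega, prior_theta, seed, converged)
}

#' Fit a Bernoulli Grade-of-Membership model by EM
#'
#' Models a binary presence-absence matrix entrywise as
#' \eqn{m_{ng} \sim \mathrm{Ber}(p_{ng})} with
#' \eqn{p_{ng} = \sum_k \omega_{nk} \theta_{kg}}: each map cell (row) mixes K
#' motifs, each motif giving every species an occurrence probability
#' \eqn{\theta_{kg} \in [0,1]}. EM uses a per-entry latent motif indicator
#' \eqn{z_{ng} \sim \mathrm{Cat}(\omega_{n\cdot})} with
#' \eqn{m_{ng} \mid z_{ng}=k \sim \mathrm{Ber}(\theta_{kg})}, whose marginal
#' is exactly the mixture above. Priors: symmetric Dirichlet on
#' \eqn{\omega} rows, independent Beta on each \eqn{\theta_{kg}}.
#'
#' @param presence A `presence_matrix` (see [as_presence_matrix()]).
#' @param prior_theta Length-2 Beta shape parameters `c(a, b)` for each theta
#'   entry; default `c(1, 1)` (flat).
#' @inheritParams fit_multinomial_gom
#' @return A `motif_fit` with `model_kind = "bernoulli"`; theta entries lie in
#'   `[0, 1]` (clipped away from the boundary by 1e-9 for numerical safety).
#' @export
fit_bernoulli_gom <- function(presence, K, prior_omega = 1,
                              prior_theta = c(1, 1), max_iter = 1000,
                              tol = 1e-8, seed = NULL, init = NULL) {
  if (!inherits(presence, "presence_matrix")) {
    presence <- as_presence_matrix(presence)
  }
  .check_K(K, presence)
  .stopifnot_scalar(tol, "tol"); if (tol <= 0) stop("tol must be > 0")
  if (length(prior_theta) != 2) stop("prior_theta must be Beta shapes c(a, b)")
  a <- prior_theta[1]; b <- prior_theta[2]
  M <- unclass(presence)
  N <- nrow(M); G <- ncol(M)

  if (K == 1) {
    theta <- matrix(.clip01((colSums(M) + a - 1) / (N + a + b - 2)), 1, G)
    omega <- matrix(1, N, 1)
    obj <- .bern_objective(M, omega, theta, prior_omega, a, b)
    return(.new_motif_fit("bernoulli", omega, theta, presence, obj,
                          prior_omega, prior_theta, seed, TRUE))
  }

  start <- if (is.null(init)) {
    with_seed(seed, list(
      omega = rdirichlet(N, rep(1, K)),
      theta = matrix(stats::runif(K * G, 0.1, 0.9), K, G)
    ))
  } else init
  omega <- start$omega; theta <- start$theta

  trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- .clip01(omega %*% theta, 1e-12)
    W1 <- M / P                    # weight where present
    W0 <- (1 - M) / (1 - P)        # weight where absent
    A <- omega * (W1 %*% t(theta) + W0 %*% t(1 - theta))   # N x K resp. sums
    S1 <- theta * (t(omega) %*% W1)                        # present mass
    S0 <- (1 - theta) * (t(omega) %*% W0)                  # absent mass
    omega <- .normalize_rows(pmax(A + prior_omega - 1, 0))
    theta <- .clip01((S1 + a - 1) / (S1 + S0 + a + b - 2))
    obj <- .bern_objective(M, omega, theta, prior_omega, a, b)
    trace <- c(trace, obj)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) < tol * (abs(obj_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  .new_motif_fit("bernoulli", omega, theta, presence, trace,
                 prior_omega, prior_theta, seed, converged)
}

#' Fit a partition-constrained competitor model
#'
#' Fixes the membership rows to hard one-hot assignments given by
#' `labels` (for example a preset elevational split of sites) and estimates
#' only the motif profiles, which is closed form: per-group prior-smoothed
#' pooled column proportions (multinomial) or occupancy means (Bernoulli).
#' The approximate log Bayes factor is computed with the same penalized
#' objective as the free model so constrained and unconstrained fits can be
#' compared on identical data; only the theta parameters count as free.
#'
#' @param data A `count_matrix` or `presence_matrix`.
#' @param labels Integer vector (length N) of motif assignments in `1..K`;
#'   every index up to `max(labels)` must occur at least once.
#' @param prior_theta Dirichlet concentration (multinomial) or Beta shapes
#'   (Bernoulli).
#' @param model `"multinomial"` or `"bernoulli"`; default follows the class
#'   of `data`.
#' @return A `motif_fit` with one-hot `omega` and attribute
#'   `constrained = TRUE`.
#' @export
constrained_partition_fit <- function(data, labels, prior_theta = NULL,
                                      model = NULL) {
  model <- .resolve_model(data, model)
  data <- if (model == "multinomial") as_count_matrix(data)
          else as_presence_matrix(data)
  X <- unclass(data)
  N <- nrow(X)
  labels <- as.integer(labels)
  if (length(labels) != N) stop("labels length must equal number of rows")
  K <- max(labels)
  if (any(labels < 1)) stop("labels must be positive motif indices")
  missing_k <- setdiff(seq_len(K), unique(labels))
  if (length(missing_k) > 0) {
    stop("motifs with no assigned rows: ", paste(missing_k, collapse = ", "))
  }
  omega <- matrix(0, N, K)
  omega[cbind(seq_len(N), labels)] <- 1

  if (model == "multinomial") {
    if (is.null(prior_theta)) prior_theta <- 1
    pooled <- rowsum(X, labels)                       # K x G pooled counts
    theta <- .normalize_rows(pmax(pooled + prior_theta - 1, 0))
    obj <- .mult_objective(X, omega, theta, 1, prior_theta)
    fit <- .new_motif_fit("multinomial", omega, theta, data, obj,
                          1, prior_theta, NULL, TRUE)
  } else {
    if (is.null(prior_theta)) prior_theta <- c(1, 1)
    a <- prior_theta[1]; b <- prior_theta[2]
    pooled <- rowsum(X, labels)
    nk <- as.vector(table(factor(labels, levels = seq_len(K))))
    theta <- .clip01((pooled + a - 1) / (nk + a + b - 2))
    obj <- .bern_objective(X, omega, theta, 1, a, b)
    fit <- .new_motif_fit("bernoulli", omega, theta, data, obj,
                          1, prior_theta, NULL, TRUE)
  }
  fit$constrained <- TRUE
  # recompute the BF with omega held fixed (no membership parameters free)
  fit$log_bf <- .approx_log_bf(fit, data)
  fit
}

#' Run multiple random restarts and keep the best fit
#'
#' EM converges to local optima, so the model is refitted from `n_starts`
#' seeded random initializations and the restart with the highest approximate
#' log Bayes factor (ties broken by objective, then by restart index) is
#' returned. Child seeds are `seed + restart_index - 1`, making the whole
#' procedure reproducible from one master seed.
#'
#' @param data A `count_matrix` or `presence_matrix`.
#' @param K Number of motifs.
#' @param n_starts Number of random restarts (>= 1).
#' @param seed Master integer seed.
#' @param model `"multinomial"` or `"bernoulli"`; default follows the class
#'   of `data`.
#' @param ... Passed to the underlying fit function (priors, `max_iter`,
#'   `tol`).
#' @return The best `motif_fit`; its `n_starts` field records the ensemble
#'   size and `restart_index` which start won.
#' @export
multistart_fit <- function(data, K, n_starts = 10, seed = 1, model = NULL,
                           ...) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  model <- .resolve_model(data, model)
  fitter <- if (model == "multinomial") fit_multinomial_gom
             else fit_bernoulli_gom
  best <- NULL
  failures <- character(0)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(fitter(data, K, seed = seed + i - 1, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$log_bf > best$log_bf ||
        (fit$log_bf == best$log_bf && .final_obj(fit) > .final_obj(best))) {
      fit$restart_index <- i
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all restarts failed; first error: ", failures[1])
  }
  best$n_starts <- n_starts
  best$seed <- seed
  best
}

# ---- internals -------------------------------------------------------------

.check_K <- function(K, data) {
  .stopifnot_scalar(K, "K")
  if (K < 1 || K != round(K)) stop("K must be a positive integer")
  if (K > min(dim(data))) {
    stop("K = ", K, " exceeds min(N, G) = ", min(dim(data)))
  }
}

.resolve_model <- function(data, model) {
  if (!is.null(model)) return(match.arg(model, c("multinomial", "bernoulli")))
  if (inherits(data, "presence_matrix")) "bernoulli" else "multinomial"
}

.clip01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

.map_theta_multinomial_k1 <- function(C, prior_theta) {
  matrix(.normalize_rows(matrix(colSums(C) + prior_theta - 1, 1)), 1, ncol(C))
}

.mult_objective <- function(C, omega, theta, a_omega, a_theta) {
  P <- omega %*% theta
  P[P < 1e-300] <- 1e-300
  ll <- sum(C * log(P))
  if (a_omega != 1) ll <- ll + (a_omega - 1) * sum(log(pmax(omega, 1e-300)))
  if (a_theta != 1) ll <- ll + (a_theta - 1) * sum(log(pmax(theta, 1e-300)))
  ll
}

.bern_objective <- function(M, omega, theta, a_omega, a, b) {
  P <- .clip01(omega %*% theta, 1e-12)
  ll <- sum(M * log(P) + (1 - M) * log(1 - P))
  if (a_omega != 1) ll <- ll + (a_omega - 1) * sum(log(pmax(omega, 1e-300)))
  if (a != 1) ll <- ll + (a - 1) * sum(log(theta))
  if (b != 1) ll <- ll + (b - 1) * sum(log(1 - theta))
  ll
}

.final_obj <- function(fit) fit$loglik_trace[length(fit$loglik_trace)]

.new_motif_fit <- function(model_kind, omega, theta, data, trace,
                           prior_omega, prior_theta, seed, converged) {
  dimnames(omega) <- list(rownames(data),
                          paste0("motif_", seq_len(ncol(omega))))
  dimnames(theta) <- list(paste0("motif_", seq_len(ncol(omega))),
                          colnames(data))
  fit <- structure(list(
    model_kind = model_kind,
    K = ncol(omega),
    omega = omega,
    theta = theta,
    loglik_trace = trace,
    log_bf = NA_real_,
    seed = seed,
    converged = converged,
    n_iter = length(trace),
    prior_omega = prior_omega,
    prior_theta = prior_theta,
    constrained = FALSE
  ), class = "motif_fit")
  fit$log_bf <- .approx_log_bf(fit, data)
  fit
}

#' @export
print.motif_fit <- function(x, ...) {
  cat(sprintf("%s grade-of-membership fit: K = %d, %d rows x %d features\n",
              x$model_kind, x$K, nrow(x$omega), ncol(x$theta)))
  cat(sprintf("  objective = %.4f after %d iteration(s)%s\n",
              .final_obj(x), x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  cat(sprintf("  approx. log Bayes factor vs K = 1: %.4f\n", x$log_bf))
  if (isTRUE(x$constrained)) cat("  membership constrained to a preset partition\n")
  invisible(x)
}
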