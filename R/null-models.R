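#' Permute a community matrix under a named null model
#'
#' Implements the four standard community null models used to test whether
#' apparent motif structure exceeds what marginal constraints alone produce:
#'
#' * `frequency` — entries are shuffled independently within each column,
#'   preserving every column's multiset of values (species occurrence
#'   frequencies / abundance distributions).
#' * `richness` — entries are shuffled within each row, preserving every
#'   row's multiset (site richness / abundance distribution).
#' * `independentswap` — repeated 2x2 checkerboard swaps: a submatrix with
#'   occupied diagonal `(i,j), (k,l)` and empty anti-diagonal `(i,l), (k,j)`
#'   has its values moved across the diagonal. `n` counts *successful*
#'   swaps.
#' * `trialswap` — the same move, but `n` counts *attempts*, successful or
#'   not.
#'
#' On binary matrices both swap methods preserve row and column sums exactly
#' (the classic fixed-fixed null); on count matrices they preserve row sums
#' and the occupancy pattern marginals, with each occupied value carried
#' intact across the swap.
#'
#' @param m A `count_matrix` or `presence_matrix`.
#' @param method One of `"frequency"`, `"richness"`, `"independentswap"`,
#'   `"trialswap"`.
#' @param n Number of swap successes (`independentswap`) or attempts
#'   (`trialswap`); default `10 * number of occupied cells`, a common
#'   burn-in heuristic. Ignored by the shuffle methods.
#' @param seed Integer seed.
#' @return A matrix of the same class and dimnames. If a swap method finds
#'   no 2x2 checkerboard unit at all, the input is returned unchanged with
#'   attribute `"swap_warning" = TRUE` and a warning.
#' @export
permute_matrix <- function(m, method = c("frequency", "richness",
                                         "independentswap", "trialswap"),
                           n = NULL, seed = NULL) {
  method <- match.arg(method)
  cls <- class(m)
  X <- unclass(m)
  shuffle <- function(v) v[sample.int(length(v))]  # safe for length-1 vectors
  out <- with_seed(seed, switch(
    method,
    frequency = apply(X, 2, shuffle),
    richness = t(apply(X, 1, shuffle)),
    independentswap = .checkerboard_swap(X, n, count_attempts = FALSE),
    trialswap = .checkerboard_swap(X, n, count_attempts = TRUE)
  ))
  warn <- isTRUE(attr(out, "swap_warning"))
  dimnames(out) <- dimnames(X)
  class(out) <- cls
  if (warn) attr(out, "swap_warning") <- TRUE
  out
}

.checkerboard_swap <- function(X, n, count_attempts) {
  N <- nrow(X); G <- ncol(X)
  occupied <- sum(X > 0)
  if (is.null(n)) n <- 10 * occupied
  if (N < 2 || G < 2 || !.has_checkerboard(X)) {
    warning("matrix has no 2x2 checkerboard unit; returned unchanged")
    attr(X, "swap_warning") <- TRUE
    return(X)
  }
  done <- 0
  attempts <- 0
  max_attempts <- if (count_attempts) n else max(1000, 1000 * n)
  while (done < n && attempts < max_attempts) {
    attempts <- attempts + 1
    rows <- sample.int(N, 2)
    cols <- sample.int(G, 2)
    i <- rows[1]; k <- rows[2]; j <- cols[1]; l <- cols[2]
    if (X[i, j] > 0 && X[k, l] > 0 && X[i, l] == 0 && X[k, j] == 0) {
      X[i, l] <- X[i, j]; X[k, j] <- X[k, l]
      X[i, j] <- 0; X[k, l] <- 0
      done <- done + 1
    }
    if (count_attempts) done <- attempts
  }
  X
}

# does any 2x2 checkerboard submatrix exist?
.has_checkerboard <- function(X) {
  B <- X > 0
  for (j in seq_len(ncol(B) - 1)) {
    for (l in seq((j + 1), ncol(B))) {
      # need one row present only in j and another present only in l
      if (any(B[, j] & !B[, l]) && any(!B[, j] & B[, l])) return(TRUE)
    }
  }
  FALSE
}

#' Null distribution of approximate log Bayes factors
#'
#' Generates `n_null` permuted matrices under one null model, fits the motif
#' model to each (with multistart restarts), and records the approximate log
#' Bayes factor of every replicate. The observed fit is judged against this
#' distribution: permutation destroys co-occurrence structure while keeping
#' the chosen marginals, so an observed BF far above the null distribution
#' indicates structure beyond marginal effects.
#'
#' Replicate `i` uses derived seed `seed + i` for both the permutation and
#' the fits, so the whole ensemble is reproducible from the master seed.
#'
#' @param m A `count_matrix` or `presence_matrix`.
#' @param K Number of motifs fitted to every replicate.
#' @param method Null model passed to [permute_matrix()].
#' @param n_null Number of null replicates.
#' @param n_starts Restarts per replicate fit.
#' @param seed Master seed.
#' @param model `"multinomial"` or `"bernoulli"`; default follows the class
#'   of `m`.
#' @param binarize If `TRUE`, replicates are reduced to presence-absence
#'   after permutation and fitted with the Bernoulli model; recorded in the
#'   result.
#' @param ... Further arguments to [multistart_fit()].
#' @return A `null_ensemble`: `method`, `K`, `n_replicates`, `log_bf`
#'   (length `n_null`, `NA` where a replicate fit failed), `seed`, `model`,
#'   `binarize`.
#' @export
null_bf_distribution <- function(m, K, method, n_null = 100, n_starts = 5,
                                 seed = 1, model = NULL, binarize = FALSE,
                                 ...) {
  if (n_null < 1) stop("n_null must be >= 1")
  model <- if (binarize) "bernoulli" else .resolve_model(m, model)
  bfs <- rep(NA_real_, n_null)
  for (i in seq_len(n_null)) {
    rep_seed <- seed + i
    perm <- permute_matrix(m, method, seed = rep_seed)
    if (binarize) {
      B <- (unclass(perm) > 0) * 1
      dimnames(B) <- dimnames(perm)
      perm <- as_presence_matrix(B)
    }
    fit <- tryCatch(
      multistart_fit(perm, K, n_starts = n_starts, seed = rep_seed,
                     model = model, ...),
      error = function(e) e)
    if (!inherits(fit, "error")) bfs[i] <- fit$log_bf
  }
  if (all(is.na(bfs))) stop("all null replicate fits failed")
  structure(list(method = method, K = K, n_replicates = n_null,
                 log_bf = bfs, seed = seed, model = model,
                 binarize = binarize),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  ok <- sum(!is.na(x$log_bf))
  cat(sprintf("null_ensemble (%s, K = %d): %d/%d replicate fits\n",
              x$method, x$K, ok, x$n_replicates))
  cat(sprintf("  log BF range: [%.3f, %.3f]\n",
              min(x$log_bf, na.rm = TRUE), max(x$log_bf, na.rm = TRUE)))
  invisible(x)
}

#' Compare observed Bayes factors to a null ensemble
#'
#' Reports (a) the empirical tail probability
#' `(1 + #{null >= min(observed)}) / (n_null + 1)` -- the permutation-test
#' p-value for the weakest observed fit -- and (b) a Mann-Whitney (Wilcoxon
#' rank-sum) test of the observed list against the null list, with tie
#' correction, via [stats::wilcox.test()]. Supplying a list of observed BFs
#' (e.g. per-restart values) rather than a single number is what makes the
#' rank-sum test well defined; with a single observed value only the
#' empirical tail probability is meaningful.
#'
#' @param observed_bfs Numeric vector of observed log Bayes factors.
#' @param ensemble A `null_ensemble`, or a numeric vector of null log BFs.
#' @return A `null_comparison` list: `empirical_p`, `mw_U`, `mw_p`,
#'   `n_observed`, `n_null`, `comparison` (which statistic used which
#'   inputs).
#' @export
compare_to_null <- function(observed_bfs, ensemble) {
  null_bfs <- if (inherits(ensemble, "null_ensemble")) ensemble$log_bf
              else as.numeric(ensemble)
  null_bfs <- null_bfs[!is.na(null_bfs)]
  if (length(observed_bfs) == 0 || length(null_bfs) == 0) {
    stop("both observed and null lists must be non-empty")
  }
  emp_p <- (1 + sum(null_bfs >= min(observed_bfs))) / (length(null_bfs) + 1)
  wt <- suppressWarnings(
    stats::wilcox.test(observed_bfs, null_bfs, alternative = "greater"))
  structure(list(
    empirical_p = emp_p,
    mw_U = unname(wt$statistic),
    mw_p = wt$p.value,
    n_observed = length(observed_bfs),
    n_null = length(null_bfs),
    comparison = paste("empirical tail p uses min(observed) vs null;",
                       "Mann-Whitney U compares full observed and null lists")
  ), class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("observed (n = %d) vs null (n = %d)\n", x$n_observed, x$n_null))
  cat(sprintf("  empirical tail p = %.4g\n", x$empirical_p))
  cat(sprintf("  Mann-Whitney U = %g, one-sided p = %.4g\n", x$mw_U, x$mw_p))
  invisible(x)
}

#' Save a null ensemble as CSV plus JSON metadata
#'
#' Writes `<stem>.csv` (columns `replicate`, `seed`, `log_bf`) and
#' `<stem>.json` (method, K, master seed, model, binarize flag).
#'
#' @param ensemble A `null_ensemble`.
#' @param stem Output path without extension.
#' @export
write_null_ensemble <- function(ensemble, stem) {
  utils::write.csv(
    data.frame(replicate = seq_len(ensemble$n_replicates),
               seed = ensemble$seed + seq_len(ensemble$n_replicates),
               log_bf = ensemble$log_bf),
    paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    ensemble[c("method", "K", "n_replicates", "seed", "model", "binarize")],
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(stem)
}
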