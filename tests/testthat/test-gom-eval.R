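test_that("loglik matches hand computation under the stated convention", {
  cm <- as_count_matrix(matrix(c(1, 1), 1, 2,
                               dimnames = list("r", c("a", "b"))))
  fit <- structure(list(model_kind = "multinomial", K = 1,
                        omega = matrix(1, 1, 1,
                                       dimnames = list("r", "motif_1")),
                        theta = matrix(0.5, 1, 2,
                                       dimnames = list("motif_1",
                                                       c("a", "b"))),
                        prior_omega = 1, prior_theta = 1,
                        constrained = FALSE),
                   class = "motif_fit")
  expect_equal(loglik(fit, cm), 2 * log(0.5), tolerance = 1e-12)
})

test_that("K = 1 multinomial loglik is maximized by column proportions", {
  cm <- blocked_counts(3, 4, depth = 50, seed = 21)
  best <- fit_multinomial_gom(cm, K = 1)
  for (i in 1:20) {
    alt <- best
    alt$theta <- ecomotifs:::rdirichlet(1, rep(1, ncol(cm)))
    colnames(alt$theta) <- colnames(cm)
    rownames(alt$theta) <- "motif_1"
    expect_lte(loglik(alt, cm), loglik(best, cm))
  }
})

test_that("loglik equals entrywise brute-force summation", {
  set.seed(31)
  cm <- as_count_matrix(matrix(rpois(12, 4) + 1, 3, 4,
                               dimnames = list(paste0("r", 1:3),
                                               paste0("c", 1:4))))
  fit <- random_fit(3, 4, 2, seed = 8)
  dimnames(fit$omega) <- list(rownames(cm), c("motif_1", "motif_2"))
  dimnames(fit$theta) <- list(c("motif_1", "motif_2"), colnames(cm))
  brute <- 0
  for (n in 1:3) for (g in 1:4) {
    p <- sum(fit$omega[n, ] * fit$theta[, g])
    brute <- brute + cm[n, g] * log(p)
  }
  expect_equal(loglik(fit, cm), brute, tolerance = 1e-10)

  pm <- as_presence_matrix(matrix(c(1, 0, 1, 0,
                                    0, 1, 1, 1,
                                    1, 1, 0, 0), 3, 4, byrow = TRUE,
                                  dimnames = dimnames(cm)))
  bf <- random_fit(3, 4, 2, "bernoulli", seed = 9)
  dimnames(bf$omega) <- list(rownames(pm), c("motif_1", "motif_2"))
  dimnames(bf$theta) <- list(c("motif_1", "motif_2"), colnames(pm))
  brute <- 0
  for (n in 1:3) for (g in 1:4) {
    p <- sum(bf$omega[n, ] * bf$theta[, g])
    brute <- brute + if (pm[n, g] == 1) log(p) else log(1 - p)
  }
  expect_equal(loglik(bf, pm), brute, tolerance = 1e-10)
})

test_that("a structural zero with positive count yields -Inf, not an error", {
  cm <- as_count_matrix(matrix(c(2, 1, 1, 2), 2, 2,
                               dimnames = list(c("r1", "r2"), c("a", "b"))))
  fit <- random_fit(2, 2, 1, seed = 2)
  fit$theta <- matrix(c(1, 0), 1, 2)
  dimnames(fit$omega) <- list(c("r1", "r2"), "motif_1")
  dimnames(fit$theta) <- list("motif_1", c("a", "b"))
  expect_identical(loglik(fit, cm), -Inf)
})

test_that("log Bayes factor is 0 at K = 1 and favours the true K", {
  cm <- blocked_counts(5, 6, depth = 100, seed = 3)
  f1 <- fit_multinomial_gom(cm, K = 1)
  expect_identical(log_bayes_factor(f1, cm), 0)

  wins <- 0
  for (s in 1:10) {
    sim <- simulate_gom(N = 40, G = 30, K = 3, depth = 1000,
                        separation = 0.8, seed = 200 + s)
    f3 <- multistart_fit(sim$data, K = 3, n_starts = 3, seed = s)
    if (f3$log_bf > 0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("structure-free data score lower than structured data at K = 3", {
  sim_flat <- simulate_gom(N = 40, G = 30, K = 1, depth = 1000, seed = 50)
  sim_struct <- simulate_gom(N = 40, G = 30, K = 3, depth = 1000,
                             separation = 0.8, seed = 50)
  bf_flat <- multistart_fit(sim_flat$data, K = 3, n_starts = 3,
                            seed = 1)$log_bf
  bf_struct <- multistart_fit(sim_struct$data, K = 3, n_starts = 3,
                              seed = 1)$log_bf
  expect_lt(bf_flat, bf_struct)
})

test_that("loglik is invariant to motif relabeling", {
  sim <- simulate_gom(N = 25, G = 18, K = 3, depth = 150, seed = 13)
  fit <- fit_multinomial_gom(sim$data, K = 3, seed = 1)
  base <- loglik(fit, sim$data)
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(loglik(apply_motif_permutation(fit, p), sim$data), base,
                 tolerance = 1e-10)
  }
})

test_that("motif alignment matches exhaustive permutation search", {
  expect_identical(align_motifs(random_fit(5, 10, 3, seed = 1),
                                random_fit(5, 10, 3, seed = 1)), 1:3)
  fit <- random_fit(5, 10, 3, seed = 2)
  swapped <- apply_motif_permutation(fit, c(2, 1, 3))
  expect_identical(align_motifs(fit, swapped), c(2L, 1L, 3L))

  for (s in 1:10) {
    a <- random_fit(4, 12, 3, seed = 300 + s)
    b <- random_fit(4, 12, 3, seed = 400 + s)
    S <- cor(t(a$theta), t(b$theta))
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    scores <- sapply(perms, function(p) sum(S[cbind(1:3, p)]))
    expect_identical(align_motifs(a, b),
                     as.integer(perms[[which.max(scores)]]))
  }
  expect_error(align_motifs(random_fit(3, 5, 2), random_fit(3, 6, 2)),
               "feature")
})

test_that("fit/data mismatches are rejected", {
  sim <- simulate_gom(N = 10, G = 8, K = 2, depth = 50, seed = 1)
  fit <- fit_multinomial_gom(sim$data, K = 2, seed = 1)
  other <- simulate_gom(N = 11, G = 8, K = 2, depth = 50, seed = 2)
  expect_error(loglik(fit, other$data), "dimensions")
  expect_error(log_bayes_factor(fit, other$data), "dimensions")
})
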