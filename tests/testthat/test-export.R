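make_fit_and_sites <- function(N = 10, K = 3, seed = 2) {
  sim <- simulate_gom(N, 12, K, depth = 100, seed = seed)
  fit <- fit_multinomial_gom(sim$data, K, seed = seed)
  list(fit = fit, sites = demo_sites(rownames(fit$omega), seed = seed))
}

test_that("block structure ordering groups by region then elevation", {
  x <- make_fit_and_sites()
  lay <- order_block_structure(x$fit, x$sites)
  df <- lay$layout
  expect_identical(df$region, sort(df$region))
  for (r in unique(df$region)) {
    e <- df$elevation_m[df$region == r]
    expect_true(all(diff(e) >= 0))
  }
  expect_identical(rownames(lay$omega), df$site_id)
  # omega values untouched, just reordered
  expect_equal(lay$omega, x$fit$omega[df$site_id, ])

  shuffled <- x$sites[sample(nrow(x$sites)), ]
  lay2 <- order_block_structure(x$fit, shuffled)
  expect_identical(lay2$layout, df)

  expect_error(order_block_structure(x$fit, x$sites[-1, ]), "missing")
})

test_that("elevation ties break by site id, matching a brute-force sort", {
  x <- make_fit_and_sites(N = 8)
  x$sites$elevation_m <- rep(c(1000, 2000), 4)
  x$sites$region <- rep("east", 8)
  lay <- order_block_structure(x$fit, x$sites)
  brute <- x$sites[order(x$sites$region, x$sites$elevation_m,
                         x$sites$site_id), ]
  expect_identical(lay$layout$site_id, brute$site_id)
  # single region reduces to a pure elevation sort
  expect_true(all(diff(lay$layout$elevation_m) >= 0))
})

test_that("block structure plot builds from a layout", {
  x <- make_fit_and_sites(N = 6, K = 2)
  p <- plot_block_structure(order_block_structure(x$fit, x$sites))
  expect_s3_class(p, "ggplot")
})

test_that("top contributors rank correctly in both modes", {
  fit <- random_fit(4, 3, 3, seed = 1)
  fit$theta <- matrix(c(0.7, 0.2, 0.1,
                        0.2, 0.5, 0.3,
                        0.1, 0.3, 0.6), 3, 3, byrow = TRUE)
  colnames(fit$theta) <- c("f1", "f2", "f3")
  rownames(fit$theta) <- paste0("motif_", 1:3)
  for (mode in c("probability", "distinctiveness")) {
    expect_identical(top_contributors(fit, 1, 1, mode)$feature_id, "f1")
  }
  # a feature with equal theta across motifs has distinctiveness zero
  fit$theta[, 2] <- 0.4
  tc <- top_contributors(fit, 1, 3, "distinctiveness")
  expect_equal(tc$score[tc$feature_id == "f2"], 0)

  # brute-force ranking oracle on random profiles
  rf <- random_fit(5, 20, 3, seed = 44)
  colnames(rf$theta) <- sprintf("sp%02d", 1:20)
  for (k in 1:3) {
    tc <- top_contributors(rf, k, 20, "probability")
    brute <- colnames(rf$theta)[order(-rf$theta[k, ], colnames(rf$theta))]
    expect_identical(tc$feature_id, brute)
    td <- top_contributors(rf, k, 20, "distinctiveness")
    sc <- rf$theta[k, ] - colMeans(rf$theta[-k, , drop = FALSE])
    expect_identical(td$feature_id,
                     colnames(rf$theta)[order(-sc, colnames(rf$theta))])
  }
  expect_warning(top_contributors(rf, 1, 50), "exceeds")
  expect_error(top_contributors(rf, 5, 3), "1..K")
})

test_that("pie-map GeoJSON round-trips memberships at coordinates", {
  x <- make_fit_and_sites(N = 7, K = 3)
  coords <- x$sites[, c("site_id", "lon", "lat")]
  path <- withr::local_tempfile(fileext = ".geojson")
  export_pie_map(x$fit, coords, path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  expect_identical(length(gj$features), 7L)
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    id <- ft$properties$site_id
    om <- unlist(ft$properties[paste0("motif_", 1:3)])
    expect_equal(unname(om), unname(x$fit$omega[id, ]), tolerance = 1e-9)
    expect_equal(sum(om), 1, tolerance = 1e-9)
    expect_equal(ft$geometry$coordinates[[1]],
                 coords$lon[coords$site_id == id], tolerance = 1e-9)
  }

  k1 <- fit_multinomial_gom(simulate_gom(4, 6, 1, depth = 50,
                                         seed = 1)$data, 1)
  gj1 <- export_pie_map(k1, data.frame(lon = 1:4, lat = 1:4))
  expect_true(all(sapply(gj1$features,
                         function(f) f$properties$motif_1 == 1)))
  expect_error(export_pie_map(x$fit, coords[-1, ]), "missing")
  p <- plot_pie_map(x$fit, coords)
  expect_s3_class(p, "ggplot")
})

test_that("fit serialization round-trips parameters and metadata", {
  sim <- simulate_gom(8, 10, 2, depth = 80, seed = 6)
  fit <- fit_multinomial_gom(sim$data, 2, seed = 3)
  dir <- file.path(withr::local_tempdir(), "fit_k2")
  write_motif_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("omega.csv", "theta.csv",
                                               "fit.json")))))
  back <- read_motif_fit(dir)
  expect_equal(back$omega, fit$omega, tolerance = 1e-12)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_identical(back$model_kind, "multinomial")
  expect_equal(back$K, 2)
  expect_equal(back$log_bf, fit$log_bf, tolerance = 1e-12)
  expect_equal(loglik(back, sim$data), loglik(fit, sim$data),
               tolerance = 1e-9)
})
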