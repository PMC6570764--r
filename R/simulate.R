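#' Simulate data from a Grade-of-Membership model with known truth
#'
#' Draws membership rows from a symmetric Dirichlet, builds motif profiles
#' with a controllable degree of distinctness, and samples the data matrix
#' exactly from the generative model: multinomial rows of total `depth` with
#' cell probabilities \eqn{\omega_n^\top \theta}, or independent Bernoulli
#' entries with the same mixture probabilities. The true parameters are
#' returned alongside the data so recovery can be measured.
#'
#' `separation` blends each motif profile between a shared baseline profile
#' (`separation = 0`: all motifs identical, no signal) and a motif-private
#' block profile concentrated on its own slice of the feature set
#' (`separation = 1`: near-disjoint motifs). For the Bernoulli model the
#' private component sets high occurrence probability (0.9) inside the
#' motif's feature block and low (0.05) outside.
#'
#' Rows that happen to come out all-zero (possible at small `depth` or
#' sparse Bernoulli draws) are resampled, so returned matrices always pass
#' validation.
#'
#' @param N,G,K Numbers of rows (sites/cells), features (species), motifs.
#' @param model_kind `"multinomial"` or `"bernoulli"`.
#' @param alpha_omega Symmetric Dirichlet concentration for membership rows;
#'   small values give near-hard memberships.
#' @param separation In `[0, 1]`; how distinct the motif profiles are.
#' @param depth Multinomial row total (individuals censused per site);
#'   ignored for Bernoulli.
#' @param seed Integer seed.
#' @return List with `data` (a `count_matrix` or `presence_matrix`) and
#'   `truth` (a `sim_truth`: true `omega`, `theta`, `model_kind`, `depth`,
#'   `seed`).
#' @export
simulate_gom <- function(N, G, K, model_kind = c("multinomial", "bernoulli"),
                         alpha_omega = 0.5, separation = 0.8, depth = 500,
                         seed = 1) {
  model_kind <- match.arg(model_kind)
  if (N < 1 || G < 1 || K < 1) stop("N, G, K must be >= 1")
  if (separation < 0 || separation > 1) stop("separation must be in [0, 1]")
  with_seed(seed, {
    omega <- rdirichlet(N, rep(alpha_omega, K))
    blocks <- split(seq_len(G), ceiling(seq_len(G) * K / G))
    if (model_kind == "multinomial") {
      baseline <- as.vector(rdirichlet(1, rep(1, G)))
      theta <- t(vapply(seq_len(K), function(k) {
        private <- numeric(G)
        private[blocks[[k]]] <- as.vector(
          rdirichlet(1, rep(1, length(blocks[[k]]))))
        (1 - separation) * baseline + separation * private
      }, numeric(G)))
      P <- omega %*% theta
      X <- t(vapply(seq_len(N), function(n) {
        repeat {
          x <- as.vector(stats::rmultinom(1, depth, P[n, ]))
          if (sum(x) > 0) return(x)
        }
      }, numeric(G)))
    } else {
      baseline <- stats::runif(G, 0.2, 0.8)
      theta <- t(vapply(seq_len(K), function(k) {
        private <- rep(0.05, G)
        private[blocks[[k]]] <- 0.9
        (1 - separation) * baseline + separation * private
      }, numeric(G)))
      P <- omega %*% theta
      X <- matrix(stats::rbinom(N * G, 1, as.vector(P)), N, G)
      for (n in which(rowSums(X) == 0)) {
        repeat {
          x <- stats::rbinom(G, 1, P[n, ])
          if (sum(x) > 0) break
        }
        X[n, ] <- x
      }
    }
    rownames(X) <- paste0("site_", seq_len(N))
    colnames(X) <- paste0("sp_", seq_len(G))
    dimnames(omega) <- list(rownames(X), paste0("motif_", seq_len(K)))
    dimnames(theta) <- list(paste0("motif_", seq_len(K)), colnames(X))
    truth <- structure(list(omega = omega, theta = theta,
                            model_kind = model_kind,
                            depth = if (model_kind == "multinomial") depth
                                    else NA_integer_,
                            seed = seed),
                       class = "sim_truth")
    data <- if (model_kind == "multinomial") as_count_matrix(X)
            else as_presence_matrix(X)
    list(data = data, truth = truth)
  })
}

#' Simulate species range grids, sites, and site species lists
#'
#' Generates rectangular binary range grids on a lon/lat frame together with
#' a table of survey sites and the species list observed at each site. With
#' `banded = TRUE` the species pool is split into a southern ("tropical",
#' low-elevation) and a northern ("temperate", high-elevation) band, each
#' species' range confined to its band, and each site draws its species from
#' the pool of its own band -- a two-regime world in which dispersion-field
#' or presence-absence motifs have a known K = 2 ground truth (the band
#' split). With `banded = FALSE` ranges are placed uniformly.
#'
#' @param nrow,ncol Grid dimensions (>= 2 each).
#' @param n_species Number of species.
#' @param n_sites Number of survey sites.
#' @param extent Lon/lat extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param mean_range_cells Average rectangular range extent, in cells per
#'   axis.
#' @param banded Impose the two-band (tropical/temperate) structure?
#' @param species_per_site Number of species drawn per site list.
#' @param seed Integer seed.
#' @return List with `ranges` (a `range_grid_set`), `sites` (a site table
#'   data frame with `site_id`, `lon`, `lat`, `elevation_m`, `region`),
#'   `site_species` (named list of species id vectors), `land` (an all-land
#'   fraction grid), and `truth` (per-species band and per-site band when
#'   `banded`).
#' @export
simulate_ranges <- function(nrow = 10, ncol = 10, n_species = 30,
                            n_sites = 12, extent = c(80, 90, 20, 30),
                            mean_range_cells = 4, banded = TRUE,
                            species_per_site = 8, seed = 1) {
  if (nrow < 2 || ncol < 2) stop("grid must be at least 2 x 2")
  geometry <- grid_geometry(extent, (extent[2] - extent[1]) / ncol)
  if (geometry$nrow != nrow) {
    # non-square cells are not supported; derive extent consistently
    stop("extent/resolution imply ", geometry$nrow,
         " rows; pass matching nrow/ncol/extent")
  }
  with_seed(seed, {
    sp_ids <- sprintf("species_%02d", seq_len(n_species))
    band <- if (banded) {
      rep(c("tropical", "temperate"), length.out = n_species)
    } else rep("all", n_species)
    # tropical = southern half of the grid (high row indices), temperate =
    # northern half, mirroring latitude/elevation sorting of real pools
    row_window <- function(b) switch(b,
      tropical = c(floor(nrow / 2) + 1, nrow),
      temperate = c(1, floor(nrow / 2)),
      all = c(1, nrow))
    grids <- lapply(seq_len(n_species), function(i) {
      w <- row_window(band[i])
      h <- min(max(1, stats::rpois(1, mean_range_cells)), w[2] - w[1] + 1)
      v <- min(max(1, stats::rpois(1, mean_range_cells)), ncol)
      r0 <- sample(w[1]:(w[2] - h + 1), 1)
      c0 <- sample(seq_len(ncol - v + 1), 1)
      gm <- matrix(0, nrow, ncol)
      gm[r0:(r0 + h - 1), c0:(c0 + v - 1)] <- 1
      gm
    })
    names(grids) <- sp_ids
    ranges <- range_grid_set(grids, geometry)

    site_band <- if (banded) {
      rep(c("tropical", "temperate"), length.out = n_sites)
    } else rep("all", n_sites)
    elevation <- ifelse(site_band == "temperate",
                        stats::runif(n_sites, 2000, 4000),
                        stats::runif(n_sites, 200, 1400))
    region <- rep(c("east", "west"), length.out = n_sites)
    cells <- grid_cells(geometry)
    sites <- data.frame(
      site_id = sprintf("site_%02d", seq_len(n_sites)),
      lon = stats::runif(n_sites, extent[1], extent[2]),
      lat = stats::runif(n_sites, extent[3], extent[4]),
      elevation_m = round(elevation),
      region = region
    )
    site_species <- lapply(seq_len(n_sites), function(i) {
      pool <- sp_ids[band == site_band[i] | band == "all"]
      sample(pool, min(species_per_site, length(pool)))
    })
    names(site_species) <- sites$site_id
    land <- matrix(1, nrow, ncol)
    list(ranges = ranges, sites = sites, site_species = site_species,
         land = land,
         truth = list(species_band = stats::setNames(band, sp_ids),
                      site_band = stats::setNames(site_band, sites$site_id)))
  })
}

#' Simulate an ultrametric pure-birth time tree
#'
#' Draws a pure-birth (Yule) tree and rescales all branch lengths so the
#' root sits at `root_age` Myr; the result is exactly ultrametric and
#' round-trips through Newick.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in Myr.
#' @param seed Integer seed.
#' @return An ape `phylo` tree with tip labels `t1..tn`.
#' @export
simulate_timetree <- function(n_tips, root_age = 20, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * root_age / depth
    tree
  })
}
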