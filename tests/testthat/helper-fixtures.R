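# shared fixture builders; everything is generated in code

tiny_counts <- function() {
  as_count_matrix(matrix(c(10, 0, 0, 10), 2, 2, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("g1", "g2"))))
}

# two site blocks with disjoint species sets (strong K = 2 structure)
blocked_counts <- function(n_per_block = 10, g_per_block = 15, depth = 200,
                           seed = 42) {
  ecomotifs:::with_seed(seed, {
    N <- 2 * n_per_block; G <- 2 * g_per_block
    X <- matrix(0, N, G)
    for (n in seq_len(N)) {
      block <- if (n <= n_per_block) seq_len(g_per_block)
               else g_per_block + seq_len(g_per_block)
      X[n, block] <- as.vector(stats::rmultinom(1, depth,
                                                rep(1, g_per_block)))
    }
    rownames(X) <- paste0("site_", seq_len(N))
    colnames(X) <- paste0("sp_", seq_len(G))
    as_count_matrix(X)
  })
}

blocked_presence <- function(n_per_block = 8, g_per_block = 12, seed = 11) {
  cm <- blocked_counts(n_per_block, g_per_block, depth = 40, seed = seed)
  B <- (unclass(cm) > 0) * 1
  dimnames(B) <- dimnames(cm)
  as_presence_matrix(B)
}

# the 4-taxon ultrametric tree used for manual slice checks
four_taxon_tree <- function() {
  ape::read.tree(text = "((A:5,B:5):10,(C:12,D:12):3);")
}

# independent lineage-through-time oracle: lineages alive at age T on an
# ultrametric binary tree = 1 + number of internal nodes at age >= T
# (valid for 0 < T < root age, away from exact node-age ties)
ltt_count <- function(tree, T) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  height <- max(depth[seq_len(ntip)])
  node_ages <- height - depth[(ntip + 1):length(depth)]
  1 + sum(node_ages >= T)
}

# random small valid fit for oracle checks
random_fit <- function(N, G, K, model_kind = "multinomial", seed = 1) {
  ecomotifs:::with_seed(seed, {
    omega <- ecomotifs:::rdirichlet(N, rep(1, K))
    theta <- if (model_kind == "multinomial") {
      ecomotifs:::.normalize_rows(matrix(stats::rgamma(K * G, 1), K, G))
    } else matrix(stats::runif(K * G, 0.05, 0.95), K, G)
    structure(list(model_kind = model_kind, K = K,
                   omega = omega, theta = theta,
                   prior_omega = 1,
                   prior_theta = if (model_kind == "multinomial") 1
                                 else c(1, 1),
                   constrained = FALSE),
              class = "motif_fit")
  })
}

# small site table matching simulate_gom row labels
demo_sites <- function(ids, seed = 3) {
  ecomotifs:::with_seed(seed, data.frame(
    site_id = ids,
    lon = stats::runif(length(ids), 80, 95),
    lat = stats::runif(length(ids), 26, 30),
    elevation_m = sample(200:4000, length(ids)),
    region = rep(c("east", "west"), length.out = length(ids))
  ))
}
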