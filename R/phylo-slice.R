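#' Cut an ultrametric tree at a time slice and map species to lineages
#'
#' Cuts a rooted ultrametric phylogeny (branch lengths in Myr) at `T` Myr
#' before present. The lineages alive at that moment are the edges crossing
#' age `T` (child age `< T <=` parent age, ages measured from the tips); each
#' becomes a clade containing the tip species it subtends. `T = 0` returns
#' the identity map (every species its own clade) and `T >=` root age
#' collapses everything into a single clade; a node falling exactly on the
#' slice is grouped with the lineage above it, which is what makes the root
#' boundary behave as the limiting case.
#'
#' Non-ultrametric trees are rejected (listing the offending tips) rather
#' than silently stretched: tip-depth spread nearly always indicates a
#' dating or import error.
#'
#' @param tree An [ape::read.tree()]-style `phylo` object, rooted, with
#'   branch lengths in Myr.
#' @param T Slice age in Myr before present, `>= 0`.
#' @param tol Ultrametricity tolerance on the max-to-min tip depth spread.
#' @return A `clade_map`: slice age `T`, named character vector `assignment`
#'   (species -> clade id), and `clades` (ids in deterministic sorted order).
#'   Clade ids are `T<T>_<lexicographically smallest member tip>`.
#' @export
slice_tree <- function(tree, T, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (T < 0) stop("T must be >= 0")

  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  spread <- height - min(depth[seq_len(ntip)])
  if (spread > tol) {
    bad <- tree$tip.label[abs(depth[seq_len(ntip)] - height) > tol / 2]
    stop("tree is not ultrametric (tip depth spread ", format(spread),
         "); offending tips: ", paste(bad, collapse = ", "))
  }
  age <- height - depth

  tag <- paste0("T", format(T, trim = TRUE, scientific = FALSE))
  if (T == 0) {
    members <- as.list(tree$tip.label)
  } else if (T >= height - 1e-9) {
    members <- list(tree$tip.label)
  } else {
    parent_age <- age[tree$edge[, 1]]
    child_age <- age[tree$edge[, 2]]
    crossing <- tree$edge[child_age < T & T <= parent_age, 2]
    clade_tips <- ape::prop.part(tree)  # tip sets per internal node
    members <- lapply(crossing, function(node) {
      if (node <= ntip) tree$tip.label[node]
      else tree$tip.label[clade_tips[[node - ntip]]]
    })
  }
  ids <- vapply(members, function(m) paste0(tag, "_", min(sort(m))),
                character(1))
  assignment <- stats::setNames(rep(ids, lengths(members)),
                                unlist(members))[tree$tip.label]
  structure(list(T = T, assignment = assignment, clades = sort(unique(ids))),
            class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  cat(sprintf("clade_map at T = %g Myr: %d species in %d clade(s)\n",
              x$T, length(x$assignment), length(x$clades)))
  invisible(x)
}

#' Collapse species-level counts to lineage-level counts
#'
#' Each clade column is the sum of its member species columns, so per-site
#' abundance totals are preserved exactly; the collapsed matrix is what the
#' multinomial motif model is fitted to for phylogenetic motifs. Every
#' column of `counts` must appear in the map (extra map entries are
#' ignored).
#'
#' @param counts A `count_matrix`, sites by species.
#' @param map A `clade_map` from [slice_tree()].
#' @return A `count_matrix`, sites by clades, columns in the map's clade
#'   order.
#' @export
collapse_counts <- function(counts, map) {
  if (!inherits(counts, "count_matrix")) counts <- as_count_matrix(counts)
  unmapped <- setdiff(colnames(counts), names(map$assignment))
  if (length(unmapped) > 0) {
    stop("species not present in the clade map: ",
         paste(unmapped, collapse = ", "))
  }
  grp <- factor(map$assignment[colnames(counts)],
                levels = map$clades)
  grp <- droplevels(grp)
  collapsed <- t(rowsum(t(unclass(counts)), grp))
  as_count_matrix(collapsed[, levels(grp), drop = FALSE])
}

#' Export a clade map as a two-column CSV
#'
#' @param map A `clade_map`.
#' @param path Destination file with columns `species_id`, `clade_id`.
#' @export
write_clade_map <- function(map, path) {
  utils::write.csv(
    data.frame(species_id = names(map$assignment),
               clade_id = unname(map$assignment)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
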