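#' Order samples for a Block Structure plot
#'
#' The Block Structure plot displays per-sample motif memberships as
#' horizontal stacked bars, with samples grouped into parallel blocks by
#' geographic region and, within each block, ordered by ascending site
#' elevation (ties broken by site id). This layout makes elevational motif
#' turnover directly visible and comparable between regions.
#'
#' @param fit A `motif_fit` whose omega rows are sites.
#' @param sites Site table (see [read_site_table()]) covering every fit row.
#' @return A `structure_layout`: `layout` data frame (`site_id`, `region`,
#'   `elevation_m`, `position`) in plot order, and `omega` reordered to
#'   match (values untouched).
#' @export
order_block_structure <- function(fit, sites) {
  ids <- rownames(fit$omega)
  missing <- setdiff(ids, sites$site_id)
  if (length(missing) > 0) {
    stop("sites missing metadata: ", paste(missing, collapse = ", "))
  }
  meta <- sites[match(ids, sites$site_id), , drop = FALSE]
  ord <- order(meta$region, meta$elevation_m, meta$site_id)
  layout <- data.frame(site_id = meta$site_id[ord],
                       region = meta$region[ord],
                       elevation_m = meta$elevation_m[ord],
                       position = seq_along(ord))
  structure(list(layout = layout,
                 omega = fit$omega[ord, , drop = FALSE]),
            class = "structure_layout")
}

#' Draw a Block Structure plot
#'
#' @param layout A `structure_layout` from [order_block_structure()].
#' @param palette Optional vector of K fill colours.
#' @return A ggplot object (stacked horizontal bars, one facet per region
#'   block, lowest elevation at the bottom).
#' @export
plot_block_structure <- function(layout, palette = NULL) {
  om <- layout$omega
  df <- data.frame(
    site_id = factor(rep(layout$layout$site_id, ncol(om)),
                     levels = layout$layout$site_id),
    region = rep(layout$layout$region, ncol(om)),
    motif = rep(colnames(om), each = nrow(om)),
    proportion = as.vector(om)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
        x = .data$proportion, y = .data$site_id, fill = .data$motif)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "membership proportion", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!is.null(palette)) p <- p + ggplot2::scale_fill_manual(values = palette)
  p
}

#' Top contributing features of a motif
#'
#' Ranks features (species, clades, or map cells) by their contribution to
#' one motif. `"probability"` ranks by the motif profile value
#' \eqn{\theta_{kg}} itself; `"distinctiveness"` ranks by
#' \eqn{\theta_{kg} - \mathrm{mean}_{k' \ne k}\, \theta_{k'g}}, highlighting
#' features associated with this motif rather than merely common everywhere.
#' Ties are broken by feature id.
#'
#' @param fit A `motif_fit`.
#' @param k Motif index in `1..K`.
#' @param n_top Number of features to return; truncated with a warning if it
#'   exceeds the number of features.
#' @param mode `"probability"` or `"distinctiveness"`.
#' @return Data frame `feature_id`, `theta`, `score`, `rank`.
#' @export
top_contributors <- function(fit, k, n_top = 10,
                             mode = c("probability", "distinctiveness")) {
  mode <- match.arg(mode)
  if (k < 1 || k > fit$K) stop("k must be in 1..K")
  th <- fit$theta
  G <- ncol(th)
  if (n_top > G) {
    warning("n_top exceeds number of features; returning all ", G)
    n_top <- G
  }
  score <- if (mode == "probability" || fit$K == 1) th[k, ]
           else th[k, ] - colMeans(th[-k, , drop = FALSE])
  ids <- colnames(th)
  ord <- order(-score, ids)[seq_len(n_top)]
  data.frame(feature_id = ids[ord], theta = unname(th[k, ord]),
             score = unname(score[ord]), rank = seq_len(n_top))
}

#' Export per-sample motif memberships as a GeoJSON pie map
#'
#' Writes one point feature per fit row at its longitude/latitude, with
#' properties `motif_1..motif_K` (the omega row, summing to 1) ready to be
#' rendered as pie charts in any GeoJSON-aware tool.
#'
#' @param fit A `motif_fit`.
#' @param coords Data frame with `site_id` (matching fit rows), `lon`,
#'   `lat`; or just `lon`/`lat` in fit row order.
#' @param path Optional file to write; when `NULL` the GeoJSON list is
#'   returned invisibly without writing.
#' @return The GeoJSON structure (a list), invisibly when written.
#' @export
export_pie_map <- function(fit, coords, path = NULL) {
  ids <- rownames(fit$omega)
  if ("site_id" %in% names(coords)) {
    idx <- match(ids, coords$site_id)
    if (anyNA(idx)) {
      stop("coordinates missing for: ", paste(ids[is.na(idx)], collapse = ", "))
    }
    coords <- coords[idx, , drop = FALSE]
  } else if (nrow(coords) != nrow(fit$omega)) {
    stop("coordinate count does not match number of fit rows")
  }
  features <- lapply(seq_along(ids), function(i) {
    props <- as.list(fit$omega[i, ])
    names(props) <- colnames(fit$omega)
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(coords$lon[i], coords$lat[i])),
      properties = c(list(site_id = ids[i]), props)
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(gj))
  }
  gj
}

#' Quick map of motif memberships
#'
#' Convenience scatter map: one point per sample coloured by its dominant
#' motif, sized by that motif's membership proportion. For full pie-chart
#' rendering use the GeoJSON from [export_pie_map()] in a mapping tool.
#'
#' @inheritParams export_pie_map
#' @return A ggplot object.
#' @export
plot_pie_map <- function(fit, coords) {
  ids <- rownames(fit$omega)
  if ("site_id" %in% names(coords)) {
    coords <- coords[match(ids, coords$site_id), , drop = FALSE]
  }
  dom <- max.col(fit$omega, ties.method = "first")
  df <- data.frame(lon = coords$lon, lat = coords$lat,
                   motif = colnames(fit$omega)[dom],
                   proportion = fit$omega[cbind(seq_along(dom), dom)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   colour = .data$motif,
                                   size = .data$proportion)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Save / load a fitted motif model
#'
#' A fit is stored as a directory holding `omega.csv`, `theta.csv`, and a
#' `fit.json` sidecar with the model kind, K, seed, approximate log Bayes
#' factor and convergence information. [read_motif_fit()] restores a
#' `motif_fit` whose parameters round-trip to 15 significant digits.
#'
#' @param fit A `motif_fit`.
#' @param dir Directory to create/write.
#' @export
write_motif_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(id = rownames(fit$omega), fit$omega,
                              check.names = FALSE),
                   file.path(dir, "omega.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(motif = rownames(fit$theta), fit$theta,
                              check.names = FALSE),
                   file.path(dir, "theta.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- fit[c("model_kind", "K", "seed", "log_bf", "converged", "n_iter",
                "prior_omega", "prior_theta", "constrained")]
  meta$final_objective <- .final_obj(fit)
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_motif_fit
#' @export
read_motif_fit <- function(dir) {
  om <- utils::read.csv(file.path(dir, "omega.csv"), check.names = FALSE)
  th <- utils::read.csv(file.path(dir, "theta.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "fit.json"), simplifyVector = TRUE)
  omega <- as.matrix(om[, -1, drop = FALSE])
  rownames(omega) <- om[[1]]
  theta <- as.matrix(th[, -1, drop = FALSE])
  rownames(theta) <- th[[1]]
  structure(list(
    model_kind = meta$model_kind, K = meta$K, omega = omega, theta = theta,
    loglik_trace = meta$final_objective, log_bf = meta$log_bf,
    seed = meta$seed, converged = meta$converged, n_iter = meta$n_iter,
    prior_omega = meta$prior_omega, prior_theta = meta$prior_theta,
    constrained = isTRUE(meta$constrained)
  ), class = "motif_fit")
}
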