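#' Grid geometry descriptor
#'
#' Fixes the shared lon/lat frame for all gridded objects: geographic
#' coordinates (degrees, longitude east-positive), square cells of
#' `resolution` degrees, and row-major storage starting at the north-west
#' corner (row 1 = northernmost band, column 1 = westernmost). Cell centres
#' are offset half a cell from the extent edges.
#'
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param resolution Cell size in degrees.
#' @return A `grid_geometry` list with `extent`, `resolution`, `nrow`,
#'   `ncol`.
#' @export
grid_geometry <- function(extent, resolution) {
  if (length(extent) != 4) stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  ncol <- round((extent[2] - extent[1]) / resolution)
  nrow <- round((extent[4] - extent[3]) / resolution)
  if (abs(ncol * resolution - (extent[2] - extent[1])) > 1e-9 ||
      abs(nrow * resolution - (extent[4] - extent[3])) > 1e-9) {
    stop("extent is not an integer multiple of resolution")
  }
  structure(list(extent = as.numeric(extent), resolution = resolution,
                 nrow = nrow, ncol = ncol), class = "grid_geometry")
}

.same_geometry <- function(a, b, tol = 1e-9) {
  all(abs(a$extent - b$extent) < tol) &&
    abs(a$resolution - b$resolution) < tol
}

#' Cell ids and centre coordinates of a grid
#'
#' Cells are enumerated row-major from the north-west corner, the same order
#' used when dispersion fields are vectorized into matrix columns.
#'
#' @param geometry A `grid_geometry`.
#' @return Data frame with `cell_id`, `row`, `col`, `lon`, `lat` (centres).
#' @export
grid_cells <- function(geometry) {
  g <- geometry
  row <- rep(seq_len(g$nrow), each = g$ncol)
  col <- rep(seq_len(g$ncol), times = g$nrow)
  data.frame(
    cell_id = paste0("cell_", row, "_", col),
    row = row, col = col,
    lon = g$extent[1] + (col - 0.5) * g$resolution,
    lat = g$extent[4] - (row - 0.5) * g$resolution
  )
}

#' Bundle per-species binary range grids on a shared frame
#'
#' @param grids Named list of binary matrices (`nrow x ncol` of `geometry`),
#'   one per species; 1 marks cells inside the species' breeding range.
#' @param geometry A `grid_geometry` shared by all grids.
#' @return A `range_grid_set`.
#' @export
range_grid_set <- function(grids, geometry) {
  if (is.null(names(grids)) || anyDuplicated(names(grids))) {
    stop("grids must be uniquely named by species id")
  }
  for (nm in names(grids)) {
    gm <- grids[[nm]]
    if (!is.matrix(gm) || nrow(gm) != geometry$nrow ||
        ncol(gm) != geometry$ncol) {
      stop("grid for ", nm, " does not match the shared geometry")
    }
    if (!all(gm %in% c(0, 1))) stop("grid for ", nm, " is not binary")
  }
  structure(list(species_ids = names(grids), grids = grids,
                 geometry = geometry), class = "range_grid_set")
}

#' @export
print.range_grid_set <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("range_grid_set: %d species on a %d x %d grid (%.4g deg)\n",
              length(x$species_ids), g$nrow, g$ncol, g$resolution))
  cat(sprintf("  extent: %g to %g E, %g to %g N\n",
              g$extent[1], g$extent[2], g$extent[3], g$extent[4]))
  invisible(x)
}

#' Build the filtered presence-absence matrix from range grids
#'
#' Converts stacked species ranges into the cell-by-species binary matrix
#' used for bioregionalization, keeping only map cells that (a) contain at
#' least `min_land` fraction of land and (b) are overlapped by at least
#' `min_species` breeding ranges. Both thresholds are inclusive (`>=`).
#'
#' @param ranges A `range_grid_set`.
#' @param land Matrix of land-cover fractions in `[0, 1]` on the same
#'   geometry.
#' @param min_land Minimum land fraction for a cell to be retained.
#' @param min_species Minimum number of overlapping species ranges.
#' @return A `presence_matrix` with retained cells as rows (ids
#'   `cell_<row>_<col>`) and all species as columns; the geometry is attached
#'   as attribute `"geometry"`.
#' @export
build_presence_matrix <- function(ranges, land, min_land = 0.10,
                                  min_species = 3) {
  g <- ranges$geometry
  if (!is.matrix(land) || nrow(land) != g$nrow || ncol(land) != g$ncol) {
    stop("land grid does not match the range-grid geometry")
  }
  occ <- vapply(ranges$grids, function(gm) as.vector(t(gm)),
                numeric(g$nrow * g$ncol))           # cells x species
  cells <- grid_cells(g)
  rownames(occ) <- cells$cell_id
  keep <- as.vector(t(land)) >= min_land & rowSums(occ) >= min_species
  if (!any(keep)) stop("no cells pass the land/richness filters")
  pm <- as_presence_matrix(occ[keep, , drop = FALSE])
  attr(pm, "geometry") <- g
  pm
}

#' Assemblage dispersion field of a community
#'
#' For a community (the species recorded at one survey site) the dispersion
#' field is the grid counting, in each map cell, how many of the community's
#' species have a breeding range covering that cell.
#'
#' Species ids are matched after normalizing case and underscore/space
#' differences; any id that still fails to match raises an error listing all
#' unmatched names (no fuzzy matching).
#'
#' @param species_ids Character vector of species recorded at the site (may
#'   be empty, giving an all-zero field).
#' @param ranges A `range_grid_set`.
#' @param site_id Optional label carried through to stacking.
#' @return A `dispersion_field`: `site_id`, count `grid`, `species_count`,
#'   `geometry`.
#' @export
dispersion_field <- function(species_ids, ranges, site_id = NULL) {
  g <- ranges$geometry
  norm <- function(x) gsub("[ _]+", "_", tolower(trimws(x)))
  idx <- match(norm(species_ids), norm(ranges$species_ids))
  if (anyNA(idx)) {
    stop("species not found in range set: ",
         paste(species_ids[is.na(idx)], collapse = ", "))
  }
  grid <- matrix(0, g$nrow, g$ncol)
  for (i in idx) grid <- grid + ranges$grids[[i]]
  structure(list(site_id = site_id, grid = grid,
                 species_count = length(species_ids), geometry = g),
            class = "dispersion_field")
}

#' Stack dispersion fields into a site-by-cell count matrix
#'
#' Vectorizes each field row-major from the north-west corner and stacks the
#' vectors as matrix rows, producing the count matrix fed to the multinomial
#' motif model (for the Himalayan frame, 50-120 E / 5-50 N at 1/8 degree,
#' this is 38 x 201,600). The operation is invertible: see
#' [unstack_dispersion_row()].
#'
#' @param fields List of `dispersion_field` objects on a shared geometry.
#' @return A `count_matrix` with attribute `"geometry"`; row ids are the
#'   fields' site ids (or `site_<i>` when unset), column ids
#'   `cell_<row>_<col>`.
#' @export
stack_dispersion_fields <- function(fields) {
  if (length(fields) == 0) stop("no fields to stack")
  g <- fields[[1]]$geometry
  for (f in fields) {
    if (!.same_geometry(f$geometry, g)) stop("fields differ in geometry")
  }
  m <- t(vapply(fields, function(f) as.vector(t(f$grid)),
                numeric(g$nrow * g$ncol)))
  ids <- vapply(seq_along(fields), function(i) {
    if (is.null(fields[[i]]$site_id)) paste0("site_", i)
    else as.character(fields[[i]]$site_id)
  }, character(1))
  rownames(m) <- ids
  colnames(m) <- grid_cells(g)$cell_id
  cm <- as_count_matrix(m)
  attr(cm, "geometry") <- g
  cm
}

#' Restore a stacked row (or theta row) to its grid
#'
#' Inverse of the row-major vectorization used by
#' [stack_dispersion_fields()]; also used to map motif profiles over map
#' cells back onto the grid for plotting.
#'
#' @param v Numeric vector of length `nrow * ncol` in row-major NW order.
#' @param geometry The `grid_geometry` of the original grids.
#' @return A `nrow x ncol` matrix.
#' @export
unstack_dispersion_row <- function(v, geometry) {
  if (length(v) != geometry$nrow * geometry$ncol) {
    stop("vector length does not match geometry")
  }
  matrix(v, geometry$nrow, geometry$ncol, byrow = TRUE)
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid Matrix in NW row-major orientation (row 1 = north).
#' @param path Destination `.asc` file.
#' @param geometry The grid's `grid_geometry`.
#' @export
write_ascii_grid <- function(grid, path, geometry) {
  g <- geometry
  header <- c(
    paste("ncols", g$ncol), paste("nrows", g$nrow),
    paste("xllcorner", g$extent[1]), paste("yllcorner", g$extent[3]),
    paste("cellsize", g$resolution), "NODATA_value -9999"
  )
  body <- apply(grid, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path `.asc` file path.
#' @return List with `grid` (matrix, row 1 = north) and `geometry`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  grid <- do.call(rbind, vals)
  if (nrow(grid) != hdr$nrows || ncol(grid) != hdr$ncols) {
    stop("grid body does not match header dimensions")
  }
  geometry <- grid_geometry(
    c(hdr$xllcorner, hdr$xllcorner + hdr$ncols * hdr$cellsize,
      hdr$yllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    hdr$cellsize
  )
  list(grid = grid, geometry = geometry)
}

#' Write/read a whole range-grid set as ASCII rasters
#'
#' One `<species>.asc` file per species in `dir`.
#'
#' @param ranges A `range_grid_set`.
#' @param dir Directory (created if needed).
#' @export
write_range_grid_set <- function(ranges, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in ranges$species_ids) {
    write_ascii_grid(ranges$grids[[sp]], file.path(dir, paste0(sp, ".asc")),
                     ranges$geometry)
  }
  invisible(dir)
}

#' @rdname write_range_grid_set
#' @export
read_range_grid_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) stop("no .asc files in ", dir)
  parsed <- lapply(files, read_ascii_grid)
  grids <- lapply(parsed, `[[`, "grid")
  names(grids) <- sub("\\.asc$", "", basename(files))
  range_grid_set(grids, parsed[[1]]$geometry)
}
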