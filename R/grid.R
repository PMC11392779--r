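#' Define a rectangular analysis grid
#'
#' A grid is anchored at an origin (lower-left corner) and divided into
#' `n_rows * n_cols` square cells of side `cell_size`. Cells are indexed
#' row-major from the origin with zero-based `row`/`col` indices, and each
#' cell covers the half-open intervals `[lo, hi)` on both axes, so a point
#' lying exactly on a cell boundary belongs to the higher-index cell.
#' Coordinates are assumed planar (already projected); see
#' [project_equirectangular()] for a simple lon/lat helper.
#'
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner.
#' @param cell_size Side length of a (square) cell, in coordinate units
#'   (conventionally km).
#' @param n_rows,n_cols Number of rows (y direction) and columns (x).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_rows, n_cols) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("`cell_size` must be a single positive number.",
          class = "divscape_invalid_config")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1) {
    abort("`n_rows` and `n_cols` must be positive integers.",
          class = "divscape_invalid_config")
  }
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g units, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Build the smallest grid covering a set of points
#'
#' @param occurrences Data frame with `x` and `y` columns.
#' @param cell_size Cell side length.
#' @return A [grid_spec()] anchored at the point-cloud minimum.
#' @export
grid_covering <- function(occurrences, cell_size) {
  stopifnot(all(c("x", "y") %in% names(occurrences)))
  x <- occurrences$x; y <- occurrences$y
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Occurrence coordinates must be finite.",
          class = "divscape_invalid_input")
  }
  grid_spec(
    origin_x = min(x), origin_y = min(y), cell_size = cell_size,
    n_rows = floor((max(y) - min(y)) / cell_size) + 1L,
    n_cols = floor((max(x) - min(x)) / cell_size) + 1L
  )
}

#' Equirectangular projection helper for lon/lat fixtures
#'
#' Converts geographic coordinates (degrees) to approximate planar km using
#' the equirectangular approximation about a reference latitude. This is a
#' convenience for small fixtures only; real analyses should supply
#' properly projected coordinates.
#'
#' @param data Data frame with `x` (longitude) and `y` (latitude), degrees.
#' @param ref_lat Reference latitude for the cosine scaling; defaults to
#'   the data's mean latitude.
#' @return The input with `x`/`y` replaced by planar km.
#' @export
project_equirectangular <- function(data, ref_lat = NULL) {
  ref_lat <- ref_lat %||% mean(data$y)
  km_per_deg <- 111.32
  dplyr::mutate(
    tibble::as_tibble(data),
    x = .data$x * km_per_deg * cos(ref_lat * pi / 180),
    y = .data$y * km_per_deg
  )
}

cell_of <- function(x, y, grid) {
  list(row = floor((y - grid$origin_y) / grid$cell_size),
       col = floor((x - grid$origin_x) / grid$cell_size))
}

#' Rasterise occurrence points into a presence matrix
#'
#' Each record at `(x, y)` maps to cell
#' `(floor((y - origin_y)/size), floor((x - origin_x)/size))` (zero-based,
#' half-open cells). Records falling outside the grid extent are dropped
#' with a warning that reports their count. The result records, per cell,
#' the set of species present and the raw record count (sampling effort).
#'
#' @param occurrences Data frame with `species`, `x`, `y`.
#' @param grid A [grid_spec()].
#' @return A `presence_matrix`: list with `grid`, logical `presence`
#'   (cells x species, row-major cell order), integer `samples` per cell,
#'   and `species` labels.
#' @export
assign_to_cells <- function(occurrences, grid) {
  stopifnot(inherits(grid, "grid_spec"),
            all(c("species", "x", "y") %in% names(occurrences)))
  occ <- tibble::as_tibble(occurrences)
  if (!all(is.finite(occ$x)) || !all(is.finite(occ$y))) {
    abort("Occurrence coordinates must be finite.",
          class = "divscape_invalid_input")
  }
  idx <- cell_of(occ$x, occ$y, grid)
  inside <- idx$row >= 0 & idx$row < grid$n_rows &
    idx$col >= 0 & idx$col < grid$n_cols
  n_out <- sum(!inside)
  if (n_out > 0) {
    warn(sprintf("%d occurrence record(s) outside the grid extent dropped.",
                 n_out))
  }
  if (!any(inside)) {
    abort("No occurrence records fall inside the grid extent.",
          class = "divscape_empty_input")
  }
  occ <- occ[inside, ]
  cell <- idx$row[inside] * grid$n_cols + idx$col[inside] + 1L
  species <- sort(unique(as.character(occ$species)))
  n_cells <- grid$n_rows * grid$n_cols
  presence <- matrix(FALSE, n_cells, length(species),
                     dimnames = list(NULL, species))
  presence[cbind(cell, match(as.character(occ$species), species))] <- TRUE
  samples <- tabulate(cell, nbins = n_cells)
  structure(
    list(grid = grid, presence = presence, samples = samples,
         species = species),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  occ <- sum(rowSums(x$presence) > 0)
  cat(sprintf(
    "<presence_matrix> %d x %d grid, %d species, %d occupied cells, %d records\n",
    x$grid$n_rows, x$grid$n_cols, length(x$species), occ, sum(x$samples)))
  invisible(x)
}

#' Tidy a presence matrix into long occupancy records
#'
#' @param pm A `presence_matrix`.
#' @return Tibble with one row per (occupied cell, species): `row`, `col`,
#'   `species`, plus per-cell `samples`.
#' @export
presence_tibble <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  w <- which(pm$presence, arr.ind = TRUE)
  cell <- w[, 1] - 1L
  tibble::tibble(
    row = cell %/% pm$grid$n_cols,
    col = cell %% pm$grid$n_cols,
    species = pm$species[w[, 2]],
    samples = pm$samples[w[, 1]]
  ) |>
    dplyr::arrange(.data$row, .data$col, .data$species)
}

#' Filter occurrences against per-species coordinate bounds
#'
#' Removes records that fall outside a species' declared bounding box
#' (range-based outlier cleaning). Species without declared bounds pass
#' through untouched. Every dropped record is listed in the attached log.
#'
#' @param occurrences Data frame with `species`, `x`, `y`.
#' @param bounds Data frame with `species`, `xmin`, `xmax`, `ymin`, `ymax`
#'   (one row per bounded species), or `NULL` for a no-op.
#' @return The filtered occurrence tibble, with a `drop_log` attribute
#'   holding the removed records.
#' @export
range_filter <- function(occurrences, bounds = NULL) {
  occ <- tibble::as_tibble(occurrences)
  if (is.null(bounds) || nrow(bounds) == 0) {
    attr(occ, "drop_log") <- occ[0, ]
    return(occ)
  }
  b <- tibble::as_tibble(bounds)
  j <- dplyr::left_join(occ, b, by = "species")
  keep <- is.na(j$xmin) |
    (j$x >= j$xmin & j$x <= j$xmax & j$y >= j$ymin & j$y <= j$ymax)
  out <- occ[keep, ]
  attr(out, "drop_log") <- occ[!keep, ]
  out
}

#' Per-cell sampling redundancy
#'
#' Redundancy in a cell is `1 - richness / samples`, a sampling-completeness
#' proxy: 0 means exactly one record per species (poor sampling), values
#' approaching 1 mean species have been recorded many times over. The
#' average redundancy (ARd) is the unweighted mean over non-empty cells;
#' empty cells carry no sampling information and are excluded.
#'
#' @param pm A `presence_matrix`.
#' @return List with `per_cell` (tibble: `row`, `col`, `richness`,
#'   `samples`, `redundancy` for non-empty cells) and scalar
#'   `average_redundancy`.
#' @export
compute_redundancy <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  richness <- rowSums(pm$presence)
  occ <- which(richness > 0)
  if (length(occ) == 0) {
    abort("Presence matrix has no occupied cells.",
          class = "divscape_empty_input")
  }
  red <- 1 - richness[occ] / pm$samples[occ]
  cell <- occ - 1L
  list(
    per_cell = tibble::tibble(
      row = cell %/% pm$grid$n_cols,
      col = cell %% pm$grid$n_cols,
      richness = as.integer(richness[occ]),
      samples = as.integer(pm$samples[occ]),
      redundancy = red
    ),
    average_redundancy = mean(red)
  )
}

#' Select the working grid resolution by sampling redundancy
#'
#' Grids each candidate cell size over the occurrence extent, computes the
#' average redundancy (ARd), and returns the finest (smallest cell size)
#' candidate whose ARd meets the threshold. If no candidate qualifies, the
#' candidate with the highest ARd is returned and flagged.
#'
#' @param occurrences Data frame with `species`, `x`, `y`.
#' @param candidate_sizes Candidate cell sizes; default `c(25, 50, 75, 100)`
#'   (km).
#' @param ard_threshold Minimum acceptable ARd; default 0.6.
#' @return List with `grid` (chosen [grid_spec()]), `cell_size`,
#'   `below_threshold` flag, and `report` (tibble: `cell_size`,
#'   `average_redundancy`, `n_occupied_cells`, `passes`).
#' @export
select_resolution <- function(occurrences,
                              candidate_sizes = c(25, 50, 75, 100),
                              ard_threshold = 0.6) {
  if (length(candidate_sizes) == 0) {
    abort("`candidate_sizes` must contain at least one size.",
          class = "divscape_invalid_config")
  }
  report <- purrr::map_dfr(sort(candidate_sizes), function(size) {
    pm <- assign_to_cells(occurrences, grid_covering(occurrences, size))
    red <- compute_redundancy(pm)
    tibble::tibble(
      cell_size = size,
      average_redundancy = red$average_redundancy,
      n_occupied_cells = nrow(red$per_cell),
      passes = red$average_redundancy >= ard_threshold
    )
  })
  if (any(report$passes)) {
    chosen <- min(report$cell_size[report$passes])
    below <- FALSE
  } else {
    chosen <- report$cell_size[which.max(report$average_redundancy)]
    below <- TRUE
  }
  list(
    grid = grid_covering(occurrences, chosen),
    cell_size = chosen,
    below_threshold = below,
    report = report
  )
}
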