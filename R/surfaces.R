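#' Taxonomic diversity and weighted endemism per cell
#'
#' TD is species richness. WE weights each species in a cell by the
#' inverse of its range size (number of occupied cells), so narrow-ranged
#' species contribute more; summed over cells WE equals the number of
#' occurring species.
#'
#' @param presence A `presence_matrix`.
#' @return Tibble with `row`, `col`, `td`, `we` for occupied cells.
#' @export
taxonomic_surfaces <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  P <- presence$presence
  range_s <- colSums(P)
  td <- rowSums(P)
  we <- as.numeric(P %*% ifelse(range_s > 0, 1 / range_s, 0))
  occ <- which(td > 0)
  cell <- occ - 1L
  tibble::tibble(
    row = cell %/% presence$grid$n_cols,
    col = cell %% presence$grid$n_cols,
    td = as.integer(td[occ]),
    we = we[occ]
  )
}

#' Assemble the six diversity and endemism surfaces
#'
#' Computes TD, WE (taxonomic), PD, PE (phylogenetic, from `tree`) and
#' FD, FE (functional, from `dendrogram`) for every occupied grid cell,
#' and attaches per-cell sampling redundancy with a low-redundancy flag.
#' Empty cells are not zero-filled; they are simply absent from the
#' result. Tree or dendrogram leaves without occurrence records are
#' pruned; occurring species missing from either tree are an error that
#' lists the offending species.
#'
#' @param presence A `presence_matrix`.
#' @param tree Phylogeny (`phylo`) covering the occurring species.
#' @param dendrogram Functional dendrogram (`phylo`) covering the
#'   occurring species.
#' @param mode Branch-sum convention, `"root"` (default) or `"mrca"`.
#' @param redundancy_threshold Cells with redundancy below this are
#'   flagged for interpolation; default 0.6.
#' @return A `divscape_surfaces` tibble: `row`, `col`, `x`, `y` (cell
#'   centroids), `samples`, `redundancy`, `low_redundancy`, `td`, `we`,
#'   `pd`, `pe`, `fd`, `fe`, `interpolated`, with the grid spec as an
#'   attribute.
#' @export
compute_all_surfaces <- function(presence, tree, dendrogram,
                                 mode = c("root", "mrca"),
                                 redundancy_threshold = 0.6) {
  mode <- match.arg(mode)
  stopifnot(inherits(presence, "presence_matrix"))
  for (nm in c("tree", "dendrogram")) {
    tr <- get(nm)
    missing <- setdiff(presence$species, tr$tip.label)
    if (length(missing) > 0) {
      abort(paste0("Occurring species missing from the ", nm, ": ",
                   paste(missing, collapse = ", ")),
            class = "divscape_lookup_error")
    }
  }
  tree <- prune_to(tree, presence$species)
  dendrogram <- prune_to(dendrogram, presence$species)
  grid <- presence$grid
  tw <- taxonomic_surfaces(presence)
  pd <- branch_diversity_surface(tree, presence, mode)
  pe <- range_weighted_endemism(tree, presence, mode)
  fdfe <- fd_fe_surfaces(dendrogram, presence, mode)
  red <- compute_redundancy(presence)
  occ <- which(rowSums(presence$presence) > 0)
  out <- tw |>
    dplyr::mutate(
      pd = pd[occ], pe = pe[occ],
      fd = fdfe$fd, fe = fdfe$fe,
      x = grid$origin_x + (.data$col + 0.5) * grid$cell_size,
      y = grid$origin_y + (.data$row + 0.5) * grid$cell_size
    ) |>
    dplyr::left_join(
      dplyr::select(red$per_cell, "row", "col", "samples", "redundancy"),
      by = c("row", "col")
    ) |>
    dplyr::mutate(
      low_redundancy = .data$redundancy < redundancy_threshold,
      interpolated = FALSE
    ) |>
    dplyr::select("row", "col", "x", "y", "samples", "redundancy",
                  "low_redundancy", "td", "we", "pd", "pe", "fd", "fe",
                  "interpolated")
  structure(out, grid = grid, mode = mode,
            class = c("divscape_surfaces", class(out)))
}

prune_to <- function(tree, species) {
  extra <- setdiff(tree$tip.label, species)
  if (length(extra) > 0) tree <- ape::keep.tip(tree, species)
  tree
}

#' Interpolate poorly sampled cells
#'
#' Replaces the six metric values of each low-redundancy cell by the
#' inverse-distance-squared weighted mean of well-sampled cells within a
#' Chebyshev radius of `neighborhood` cells (distances in cell units).
#' Low-redundancy cells with no qualifying neighbour keep missing metric
#' values and stay flagged. Well-sampled cells are never altered. The
#' original values of every interpolated cell are retained in the
#' `interpolation_log` attribute.
#'
#' @param surfaces A `divscape_surfaces` tibble from
#'   [compute_all_surfaces()].
#' @param neighborhood Chebyshev search radius in cells; default 2.
#' @return The surfaces tibble with interpolated metric values,
#'   `interpolated` flags, and an `interpolation_log` attribute.
#' @export
interpolate_low_redundancy <- function(surfaces, neighborhood = 2) {
  stopifnot(inherits(surfaces, "divscape_surfaces"))
  metrics <- c("td", "we", "pd", "pe", "fd", "fe")
  out <- surfaces
  low <- which(out$low_redundancy)
  good <- which(!out$low_redundancy)
  log <- out[low, c("row", "col", metrics)]
  out$td <- as.numeric(out$td)
  for (i in low) {
    dr <- out$row[good] - out$row[i]
    dc <- out$col[good] - out$col[i]
    near <- good[pmax(abs(dr), abs(dc)) <= neighborhood]
    if (length(near) == 0) {
      out[i, metrics] <- NA_real_
      out$interpolated[i] <- NA
      next
    }
    d2 <- (out$row[near] - out$row[i])^2 + (out$col[near] - out$col[i])^2
    w <- 1 / d2
    for (m in metrics) {
      out[[m]][i] <- sum(w * out[[m]][near]) / sum(w)
    }
    out$interpolated[i] <- TRUE
  }
  attr(out, "interpolation_log") <- log
  out
}

#' Write a surface set as a long CSV
#'
#' @param surfaces A `divscape_surfaces` tibble.
#' @param file Output path.
#' @return The long tibble, invisibly.
#' @export
write_surfaces_csv <- function(surfaces, file) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(surfaces),
    cols = c("td", "we", "pd", "pe", "fd", "fe"),
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::select("row", "col", "metric", "value", "redundancy",
                  "low_redundancy", "interpolated")
  readr::write_csv(long, file)
  invisible(long)
}
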