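#' Configure a full pipeline run
#'
#' Either point the pipeline at input files (occurrences CSV, traits CSV
#' with a metadata sidecar, newick tree, optional per-species coordinate
#' bounds and a species-to-genus map for grafting), or supply a
#' [scenario_config()] to simulate the inputs; exactly one of the two is
#' required.
#'
#' @param occurrences,traits,trait_meta,tree,bounds,species_genus File
#'   paths for the input route (`bounds` and `species_genus` optional).
#' @param scenario A [scenario_config()] for the simulation route.
#' @param candidate_sizes Candidate grid cell sizes for resolution
#'   selection; default `c(25, 50, 75, 100)`. Ignored on the simulation
#'   route, where the scenario's own grid is used.
#' @param ard_threshold Minimum acceptable average redundancy; default
#'   0.6.
#' @param mode Branch-sum convention (`"root"` or `"mrca"`).
#' @param interpolation_radius Chebyshev radius for low-redundancy
#'   interpolation; default 2. `0` disables interpolation.
#' @param models Model list for [run_model_suite()].
#' @param method `"gwr"` or `"mgwr"`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(occurrences = NULL, traits = NULL,
                            trait_meta = NULL, tree = NULL, bounds = NULL,
                            species_genus = NULL, scenario = NULL,
                            candidate_sizes = c(25, 50, 75, 100),
                            ard_threshold = 0.6,
                            mode = c("root", "mrca"),
                            interpolation_radius = 2,
                            models = c("fd ~ td", "pd ~ td", "fd ~ pd",
                                       "we ~ fe", "we ~ pe", "fe ~ pe"),
                            method = c("gwr", "mgwr"),
                            out_dir = NULL, seed = 1) {
  mode <- match.arg(mode); method <- match.arg(method)
  has_paths <- !is.null(occurrences) && !is.null(traits) && !is.null(tree)
  has_scenario <- !is.null(scenario)
  if (has_paths == has_scenario) {
    abort(paste0("Provide either input paths (occurrences, traits, tree) ",
                 "or a scenario, and not both."),
          class = "divscape_invalid_config")
  }
  if (has_scenario) stopifnot(inherits(scenario, "scenario_config"))
  if (ard_threshold < 0 || ard_threshold >= 1) {
    abort("`ard_threshold` must lie in [0, 1).",
          class = "divscape_invalid_config")
  }
  structure(
    list(occurrences = occurrences, traits = traits,
         trait_meta = trait_meta, tree = tree, bounds = bounds,
         species_genus = species_genus, scenario = scenario,
         candidate_sizes = candidate_sizes, ard_threshold = ard_threshold,
         mode = mode, interpolation_radius = interpolation_radius,
         models = models, method = method, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full diversity-surface pipeline
#'
#' Executes, in order: input loading or simulation, optional range-based
#' outlier filtering, grid-resolution selection by sampling redundancy
#' (input route) or the scenario grid (simulation route), grafting of
#' species missing from the phylogeny, weighted Gower + UPGMA functional
#' dendrogram, the six diversity/endemism surfaces with low-redundancy
#' interpolation, and the geographically weighted model suite. All stage
#' outputs are returned (and written as CSV when `out_dir` is set)
#' together with a run manifest; deterministic stages reproduce
#' byte-identical outputs under the same configuration.
#'
#' @param config A [pipeline_config()].
#' @return A `divscape_run` list: `world` (simulation route only),
#'   `occurrences`, `resolution`, `presence`, `tree`, `graft_log`,
#'   `dendrogram`, `surfaces`, `suite`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  world <- NULL
  if (!is.null(config$scenario)) {
    world <- simulate_world(config$scenario)
    occ <- world$occurrences
    traits <- world$traits
    meta <- world$traits_meta
    tree <- world$tree
    bounds <- NULL
    sp_genus <- NULL
  } else {
    occ <- readr::read_csv(config$occurrences, show_col_types = FALSE)
    traits <- readr::read_csv(config$traits, show_col_types = FALSE)
    meta <- if (!is.null(config$trait_meta)) {
      readr::read_csv(config$trait_meta, show_col_types = FALSE)
    }
    tree <- read_newick(file = config$tree)
    bounds <- if (!is.null(config$bounds)) {
      readr::read_csv(config$bounds, show_col_types = FALSE)
    }
    sp_genus <- if (!is.null(config$species_genus)) {
      readr::read_csv(config$species_genus, show_col_types = FALSE)
    }
  }
  n_in <- nrow(occ)
  occ <- range_filter(occ, bounds)
  n_dropped <- nrow(attr(occ, "drop_log"))

  if (!is.null(world)) {
    grid <- world$grid
    resolution <- list(grid = grid, cell_size = grid$cell_size,
                       below_threshold = NA, report = NULL)
  } else {
    resolution <- select_resolution(occ, config$candidate_sizes,
                                    config$ard_threshold)
    grid <- resolution$grid
  }
  presence <- assign_to_cells(occ, grid)

  graft_log <- NULL
  missing <- setdiff(presence$species, tree$tip.label)
  if (length(missing) > 0) {
    if (is.null(sp_genus)) {
      abort(paste0("Species missing from the tree and no genus map ",
                   "supplied: ", paste(missing, collapse = ", ")),
            class = "divscape_lookup_error")
    }
    g <- graft_missing_species(
      tree, dplyr::filter(sp_genus, .data$species %in% missing),
      leaf_genus = dplyr::filter(sp_genus,
                                 .data$species %in% tree$tip.label))
    tree <- g$tree
    graft_log <- g$log
    still <- setdiff(presence$species, tree$tip.label)
    if (length(still) > 0) {
      warn(paste0("Dropping species absent from the tree after ",
                  "grafting: ", paste(still, collapse = ", ")))
      keep <- !(as.character(occ$species) %in% still)
      occ <- occ[keep, ]
      presence <- assign_to_cells(occ, grid)
    }
  }

  D <- weighted_gower_dissimilarity(
    dplyr::filter(traits, .data$species %in% presence$species), meta)
  dendrogram <- upgma(D)

  surfaces <- compute_all_surfaces(presence, tree, dendrogram,
                                   mode = config$mode,
                                   redundancy_threshold = config$ard_threshold)
  if (config$interpolation_radius > 0) {
    surfaces <- interpolate_low_redundancy(surfaces,
                                           config$interpolation_radius)
  }
  suite <- run_model_suite(surfaces, method = config$method,
                           models = config$models)

  manifest <- list(
    seed = config$seed,
    scenario = if (!is.null(config$scenario)) config$scenario$scenario,
    n_records_in = n_in, n_records_dropped = n_dropped,
    n_records_kept = nrow(occ),
    n_species = length(presence$species),
    cell_size = grid$cell_size,
    n_cells_occupied = sum(rowSums(presence$presence) > 0),
    models = names(suite),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  run <- structure(
    list(world = world, occurrences = occ, resolution = resolution,
         presence = presence, tree = tree, graft_log = graft_log,
         dendrogram = dendrogram, surfaces = surfaces, suite = suite,
         manifest = manifest),
    class = "divscape_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$occurrences, file.path(dir, "occurrences_kept.csv"))
  readr::write_csv(presence_tibble(run$presence),
                   file.path(dir, "presence.csv"))
  if (!is.null(run$resolution$report)) {
    readr::write_csv(run$resolution$report,
                     file.path(dir, "redundancy_report.csv"))
  }
  if (!is.null(run$graft_log)) {
    readr::write_csv(run$graft_log, file.path(dir, "graft_log.csv"))
  }
  write_newick(run$dendrogram, file = file.path(dir, "dendrogram.nwk"))
  write_newick(run$tree, file = file.path(dir, "tree_used.nwk"))
  write_surfaces_csv(run$surfaces, file.path(dir, "surfaces.csv"))
  readr::write_csv(tidy(run$suite), file.path(dir, "model_cells.csv"))
  readr::write_csv(glance(run$suite), file.path(dir, "model_summary.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.divscape_run <- function(x, ...) {
  cat("<divscape_run>\n")
  cat(sprintf("  %d species over %d occupied cells (%g-unit grid)\n",
              x$manifest$n_species, x$manifest$n_cells_occupied,
              x$manifest$cell_size))
  cat(sprintf("  models: %s\n", paste(x$manifest$models, collapse = ", ")))
  invisible(x)
}

#' Ranked composition shares
#'
#' Tabulates counts and percentage shares of a grouping column (family,
#' genus, growth form, ...) in a species table, ranked descending, with
#' cumulative shares. Percentages are `100 * count / total` rounded
#' half-up to one decimal, the convention of printed floristic tables.
#' Pre-aggregated tables (one row per group with a count column) are
#' supported via `count_col`.
#'
#' @param data Species table (one row per species) or pre-aggregated
#'   count table.
#' @param group Column to tabulate (tidy-eval).
#' @param count_col Optional column holding pre-aggregated counts.
#' @param total Optional denominator overriding the table total (e.g.
#'   when the table lists only the commonest groups of a larger flora).
#' @return Tibble: group, `n`, `percent`, `cum_n`, `cum_percent`, ranked
#'   by descending count.
#' @export
composition_summary <- function(data, group, count_col = NULL,
                                total = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    abort("Empty species table.", class = "divscape_empty_input")
  }
  group <- rlang::enquo(group)
  count_col <- rlang::enquo(count_col)
  counts <- if (rlang::quo_is_null(count_col)) {
    dplyr::count(data, !!group, name = "n")
  } else {
    dplyr::summarise(dplyr::group_by(data, !!group),
                     n = sum(!!count_col), .groups = "drop")
  }
  total <- total %||% sum(counts$n)
  counts |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    dplyr::mutate(
      percent = round_half_up(100 * .data$n / .env$total, 1),
      cum_n = cumsum(.data$n),
      cum_percent = round_half_up(100 * .data$cum_n / .env$total, 1)
    )
}
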