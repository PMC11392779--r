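#' Configure a synthetic biodiversity scenario
#'
#' Each scenario encodes the statistical signature one eco-evolutionary
#' hypothesis predicts for the diversity/endemism surfaces:
#' `congruent` (all dimensions track the same environmental suitability),
#' `environmental_filter` (trait convergence among arid-adapted species
#' depresses FD where aridity is high), `in_situ_radiation` (one recently
#' radiated clade dominates the arid zone, depressing PD relative to TD),
#' `biotic_exchange` (arid-zone assemblages drawn from scattered,
#' distantly related lineages), and `isolation_endemism` (a configurable
#' fraction of species restricted to single cells, concentrating
#' endemism).
#'
#' @param scenario One of `"congruent"`, `"environmental_filter"`,
#'   `"in_situ_radiation"`, `"biotic_exchange"`,
#'   `"isolation_endemism"`.
#' @param n_species Number of species (>= 2).
#' @param grid_rows,grid_cols Grid dimensions (product >= 4).
#' @param cell_size Cell side length (abstract km).
#' @param effort_range `c(min, max)` occurrence records per occupied
#'   cell; min >= 1.
#' @param range_width_mean Mean species range size in cells; 0 forces
#'   every species to a single cell.
#' @param filter_strength Trait-convergence strength in `[0, 1]` applied
#'   to arid-adapted species under `environmental_filter`.
#' @param endemic_fraction Fraction of species forced to occupy exactly
#'   one cell (used by `isolation_endemism`).
#' @param arid_threshold Aridity above which a species' niche counts as
#'   arid; default 0.7.
#' @param noise Amplitude of the smooth non-gradient component of the
#'   aridity field.
#' @param n_traits Number of traits (default 11: 6 continuous, 3
#'   ordinal, 2 binary).
#' @param trait_weights Per-trait weights in `[0, 1]`; default an evenly
#'   spaced ramp from 1 down to 0.5 (abstract drought-importance
#'   weights).
#' @param radiation_scale Crown-depth compression factor for the
#'   radiated clade under `in_situ_radiation`; default 0.3.
#' @param seed Integer seed; the same configuration always produces the
#'   identical world.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("congruent", "environmental_filter",
                                         "in_situ_radiation",
                                         "biotic_exchange",
                                         "isolation_endemism"),
                            n_species = 200, grid_rows = 20, grid_cols = 20,
                            cell_size = 25, effort_range = c(2, 8),
                            range_width_mean = 25,
                            filter_strength = NULL,
                            endemic_fraction = NULL,
                            arid_threshold = 0.7, noise = 0.15,
                            n_traits = 11, trait_weights = NULL,
                            radiation_scale = 0.3, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_species < 2) {
    abort("`n_species` must be at least 2.",
          class = "divscape_invalid_config")
  }
  if (grid_rows * grid_cols < 4) {
    abort("The grid must contain at least 4 cells.",
          class = "divscape_invalid_config")
  }
  if (effort_range[1] < 1 || effort_range[2] < effort_range[1]) {
    abort("`effort_range` must satisfy 1 <= min <= max.",
          class = "divscape_invalid_config")
  }
  filter_strength <- filter_strength %||%
    if (scenario == "environmental_filter") 0.85 else 0
  endemic_fraction <- endemic_fraction %||%
    if (scenario == "isolation_endemism") 1 else 0
  structure(
    list(scenario = scenario, n_species = n_species,
         grid_rows = grid_rows, grid_cols = grid_cols,
         cell_size = cell_size, effort_range = effort_range,
         range_width_mean = range_width_mean,
         filter_strength = filter_strength,
         endemic_fraction = endemic_fraction,
         arid_threshold = arid_threshold, noise = noise,
         n_traits = n_traits, trait_weights = trait_weights,
         radiation_scale = radiation_scale, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a gridded aridity surface
#'
#' A monotone gradient along one axis (emulating a latitudinal /
#' altitudinal moisture gradient; 1 = most arid) plus a smooth random
#' field, clamped to `[0, 1]`. With `noise = 0` the surface is strictly
#' monotone along the gradient axis.
#'
#' @param rows,cols Grid dimensions (>= 2 each).
#' @param gradient_axis `"y"` (aridity increases with row, default) or
#'   `"x"`.
#' @param noise Amplitude of the smooth random component.
#' @param seed Integer seed.
#' @return Tibble with zero-based `row`, `col` and `aridity`.
#' @export
generate_environment <- function(rows, cols, gradient_axis = c("y", "x"),
                                 noise = 0.15, seed = 1) {
  gradient_axis <- match.arg(gradient_axis)
  if (rows < 1 || cols < 1) {
    abort("Grid dimensions must be positive.",
          class = "divscape_invalid_config")
  }
  if ((gradient_axis == "y" && rows < 2) ||
      (gradient_axis == "x" && cols < 2)) {
    abort("The gradient axis needs at least 2 cells.",
          class = "divscape_invalid_config")
  }
  grid <- tidyr::expand_grid(row = seq_len(rows) - 1L,
                             col = seq_len(cols) - 1L)
  base <- if (gradient_axis == "y") {
    grid$row / (rows - 1)
  } else {
    grid$col / (cols - 1)
  }
  if (noise > 0) {
    withr_seed(seed, {
      k <- 4L
      knots <- matrix(runif(k * k, -1, 1), k, k)
      # bilinear interpolation of the coarse random field
      u <- grid$row / max(rows - 1, 1) * (k - 1)
      v <- grid$col / max(cols - 1, 1) * (k - 1)
      i0 <- pmin(floor(u), k - 2); j0 <- pmin(floor(v), k - 2)
      fu <- u - i0; fv <- v - j0
      field <- knots[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
        knots[cbind(i0 + 2, j0 + 1)] * fu * (1 - fv) +
        knots[cbind(i0 + 1, j0 + 2)] * (1 - fu) * fv +
        knots[cbind(i0 + 2, j0 + 2)] * fu * fv
      base <- base + noise * field
    })
  }
  dplyr::mutate(grid, aridity = pmin(pmax(base, 0), 1))
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(code))
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule process conditioned on `n_species` extant lineages: starting from
#' the root split, the waiting time with `k` lineages is exponential with
#' rate `k * birth`, and the final interval (with all `n` lineages alive)
#' runs until the next speciation would occur. All leaves end at equal
#' depth.
#'
#' @param n_species Number of leaves (>= 2).
#' @param birth Speciation rate; default 1.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` tree with labels `sp001`, `sp002`, ...
#' @export
simulate_phylogeny <- function(n_species, birth = 1, seed = 1) {
  if (n_species < 2) {
    abort("`n_species` must be at least 2.",
          class = "divscape_invalid_config")
  }
  n <- as.integer(n_species)
  withr_seed(seed, {
    node_time <- 0          # root
    node_parent <- NA_integer_
    active_parent <- c(1L, 1L)   # parent internal node of each open lineage
    t <- 0
    k <- 2L
    while (k < n) {
      t <- t + rexp(1, k * birth)
      i <- sample.int(k, 1)
      node_time <- c(node_time, t)
      node_parent <- c(node_parent, active_parent[i])
      new_id <- length(node_time)
      active_parent <- c(active_parent[-i], new_id, new_id)
      k <- k + 1L
    }
    t_end <- t + rexp(1, n * birth)
  })
  n_int <- n - 1L
  lab_w <- max(3L, nchar(n))
  labels <- sprintf(paste0("sp%0", lab_w, "d"), seq_len(n))
  # ape numbering: tips 1..n, internal n+1..n+n_int (creation order)
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  if (n_int >= 2) {
    for (c_id in 2:n_int) {
      edges <- rbind(edges, c(n + node_parent[c_id], n + c_id))
      lens <- c(lens, node_time[c_id] - node_time[node_parent[c_id]])
    }
  }
  for (i in seq_len(n)) {
    p <- active_parent[i]
    edges <- rbind(edges, c(n + p, i))
    lens <- c(lens, t_end - node_time[p])
  }
  tree <- structure(
    list(edge = edges, edge.length = lens, tip.label = labels,
         Nnode = n_int),
    class = "phylo", order = "cladewise"
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Evolve a mixed-type trait matrix on a tree
#'
#' Latent trait values evolve by Brownian motion along the branches
#' (root state 0, per-branch increments Normal(0, branch length)).
#' Continuous traits are the latent values; ordinal traits are the
#' latents cut at their quartiles into 4 levels; binary traits are
#' thresholded at the median. Under environmental filtering, continuous
#' trait values of species whose niche optimum exceeds `arid_threshold`
#' are shrunk toward the trait's pool mean by `filter_strength`
#' (convergence of drought syndromes).
#'
#' @param tree A `phylo` tree whose leaves are the species.
#' @param optima Named numeric vector of per-species aridity-niche
#'   optima in `[0, 1]` (names = leaf labels), or `NULL` to skip
#'   filtering.
#' @param n_traits Number of traits; default 11.
#' @param trait_weights Per-trait weights; default ramp 1 -> 0.5.
#' @param filter_strength Convergence strength in `[0, 1]`; default 0.
#' @param arid_threshold Niche-optimum threshold defining arid-adapted
#'   species; default 0.7.
#' @param seed Integer seed.
#' @return List with `traits` (tibble: `species` + trait columns) and
#'   `meta` ([trait_meta()] tibble).
#' @export
simulate_traits <- function(tree, optima = NULL, n_traits = 11,
                            trait_weights = NULL, filter_strength = 0,
                            arid_threshold = 0.7, seed = 1) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  n_cont <- max(1L, round(n_traits * 6 / 11))
  n_ord <- max(0L, round(n_traits * 3 / 11))
  n_bin <- max(0L, n_traits - n_cont - n_ord)
  types <- c(rep("continuous", n_cont), rep("ordinal", n_ord),
             rep("binary", n_bin))
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_node <- n + tr$Nnode
  lat <- matrix(0, n_node, n_traits)
  withr_seed(seed, {
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      lat[ch, ] <- lat[p, ] + rnorm(n_traits, 0, sqrt(tr$edge.length[e]))
    }
  })
  vals <- lat[seq_len(n), , drop = FALSE]
  rownames(vals) <- tr$tip.label
  if (!is.null(optima) && filter_strength > 0) {
    arid <- tr$tip.label[optima[tr$tip.label] > arid_threshold]
    for (k in which(types == "continuous")) {
      attractor <- mean(vals[, k])
      vals[arid, k] <- attractor +
        (1 - filter_strength) * (vals[arid, k] - attractor)
    }
  }
  out <- matrix(NA_real_, n, n_traits)
  for (k in seq_len(n_traits)) {
    v <- vals[, k]
    out[, k] <- switch(
      types[k],
      continuous = v,
      ordinal = as.numeric(cut(v, breaks = unique(stats::quantile(
        v, probs = seq(0, 1, 0.25))), include.lowest = TRUE,
        labels = FALSE)),
      binary = as.numeric(v > median(v))
    )
  }
  names_k <- sprintf("trait_%02d", seq_len(n_traits))
  traits <- tibble::as_tibble(as.data.frame(out)) |>
    rlang::set_names(names_k) |>
    dplyr::mutate(species = tr$tip.label, .before = 1)
  weights <- trait_weights %||% seq(1, 0.5, length.out = n_traits)
  list(traits = traits, meta = trait_meta(names_k, types, weights))
}

# Compress the crown of one clade (recent radiation) while keeping the
# tree ultrametric: within-clade branch lengths shrink by `scale`, the
# clade stem absorbs the difference.
compress_clade <- function(tree, node, scale) {
  n <- length(tree$tip.label)
  desc_edges <- which(tree$edge[, 1] %in%
                        c(node, phangorn_descendants(tree, node)))
  depths <- node_depths(tree)
  clade_height <- max(depths) - depths[node]
  tree$edge.length[desc_edges] <- tree$edge.length[desc_edges] * scale
  stem <- which(tree$edge[, 2] == node)
  if (length(stem) == 1) {
    tree$edge.length[stem] <- tree$edge.length[stem] +
      (1 - scale) * clade_height
  }
  tree
}

phangorn_descendants <- function(tree, node) {
  # internal descendants of `node` (excluding it), by breadth-first walk
  out <- integer(0)
  frontier <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    kids <- kids[kids > length(tree$tip.label)]
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

clade_members <- function(tree, node) {
  ape::extract.clade(tree, node)$tip.label
}

pick_radiation_clade <- function(tree, target_frac = 1 / 3) {
  n <- length(tree$tip.label)
  nodes <- (n + 2):(n + tree$Nnode)   # exclude root
  sizes <- vapply(nodes, function(nd) length(clade_members(tree, nd)),
                  integer(1))
  nodes[which.min(abs(sizes - target_frac * n))]
}

#' Simulate species ranges and occurrence records
#'
#' Each species receives a niche optimum on the aridity axis and a target
#' range size (cells). Its occupied cells are chosen greedily by a score
#' combining environmental distance from the optimum and a dispersal
#' penalty with distance from a seed cell placed at the most suitable
#' location, which yields spatially clustered, environmentally aligned
#' ranges. Sampling effort per occupied cell is drawn uniformly from
#' `effort_range` and that many occurrence points are scattered within
#' the cell. Scenario hooks: under `isolation_endemism`,
#' `endemic_fraction` of the species are forced to exactly one cell;
#' under `in_situ_radiation` the radiated clade's optima are arid; under
#' `biotic_exchange` the arid-adapted set is phylogenetically scattered.
#'
#' @param env Aridity tibble from [generate_environment()].
#' @param grid The [grid_spec()] the environment lives on.
#' @param tree The species phylogeny (leaves define the species pool).
#' @param config A [scenario_config()].
#' @param radiation_members Leaf labels of the radiated clade (used by
#'   `in_situ_radiation`), or `NULL`.
#' @return List with `occurrences` (tibble: `species`, `x`, `y`) and
#'   `truth` (tibble: `species`, `optimum`, `range_cells`, `endemic`).
#' @export
simulate_ranges <- function(env, grid, tree, config,
                            radiation_members = NULL) {
  species <- tree$tip.label
  n <- length(species)
  n_cells <- nrow(env)
  withr_seed(derive_seed(config$seed, 11L), {
    optima <- runif(n, 0.02, 0.98)
    names(optima) <- species
    if (config$scenario == "in_situ_radiation" &&
        !is.null(radiation_members)) {
      optima[radiation_members] <- runif(length(radiation_members),
                                         config$arid_threshold + 0.02, 0.98)
      others <- setdiff(species, radiation_members)
      optima[others] <- runif(length(others), 0.02,
                              config$arid_threshold - 0.02)
    }
    if (config$scenario == "biotic_exchange") {
      # arid-adapted species spread evenly across the tree (distant
      # lineages immigrating into the arid zone)
      arid_set <- species[seq(1, n, by = 3)]
      optima[arid_set] <- runif(length(arid_set),
                                config$arid_threshold + 0.02, 0.98)
    }
    width <- if (config$range_width_mean <= 1) {
      rep(1L, n)
    } else {
      1L + rpois(n, config$range_width_mean - 1)
    }
    width <- pmin(width, n_cells)
    endemic <- rep(FALSE, n)
    if (config$endemic_fraction > 0) {
      k <- floor(config$endemic_fraction * n)
      endemic[sample.int(n, k)] <- TRUE
      width[endemic] <- 1L
    }
    max_dim <- max(config$grid_rows, config$grid_cols)
    occ_list <- vector("list", n)
    for (i in seq_len(n)) {
      env_dist <- abs(env$aridity - optima[i]) +
        runif(n_cells, 0, 1e-3)  # tie jitter
      seed_cell <- which.min(env_dist)
      cheb <- pmax(abs(env$row - env$row[seed_cell]),
                   abs(env$col - env$col[seed_cell]))
      score <- env_dist + 0.5 * cheb / max_dim
      cells <- order(score)[seq_len(width[i])]
      effort <- sample(seq(config$effort_range[1], config$effort_range[2]),
                       length(cells), replace = TRUE)
      rows <- rep(env$row[cells], effort)
      cols <- rep(env$col[cells], effort)
      m <- length(rows)
      occ_list[[i]] <- tibble::tibble(
        species = species[i],
        x = grid$origin_x + (cols + runif(m)) * grid$cell_size,
        y = grid$origin_y + (rows + runif(m)) * grid$cell_size
      )
    }
    occurrences <- dplyr::bind_rows(occ_list)
  })
  list(
    occurrences = occurrences,
    truth = tibble::tibble(
      species = species, optimum = unname(optima),
      range_cells = as.integer(width), endemic = endemic
    )
  )
}

#' Generate a complete synthetic world
#'
#' Runs the environment, phylogeny, range and trait generators under one
#' configuration, fanning a single seed out to each stage. The same
#' configuration always yields an identical world.
#'
#' @param config A [scenario_config()].
#' @return A `divscape_world`: list with `config`, `grid`, `environment`,
#'   `tree`, `occurrences`, `traits`, `traits_meta`, `truth`.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  env <- generate_environment(config$grid_rows, config$grid_cols,
                              noise = config$noise,
                              seed = derive_seed(config$seed, 1L))
  grid <- grid_spec(0, 0, config$cell_size,
                    config$grid_rows, config$grid_cols)
  tree <- simulate_phylogeny(config$n_species,
                             seed = derive_seed(config$seed, 2L))
  radiation_members <- NULL
  if (config$scenario == "in_situ_radiation") {
    node <- pick_radiation_clade(tree)
    radiation_members <- clade_members(tree, node)
    tree <- compress_clade(tree, node, config$radiation_scale)
  }
  rng <- simulate_ranges(env, grid, tree, config, radiation_members)
  optima <- setNames(rng$truth$optimum, rng$truth$species)
  tr <- simulate_traits(tree, optima = optima, n_traits = config$n_traits,
                        trait_weights = config$trait_weights,
                        filter_strength = config$filter_strength,
                        arid_threshold = config$arid_threshold,
                        seed = derive_seed(config$seed, 3L))
  structure(
    list(config = config, grid = grid, environment = env, tree = tree,
         occurrences = rng$occurrences, traits = tr$traits,
         traits_meta = tr$meta,
         truth = dplyr::mutate(
           rng$truth,
           radiated = .data$species %in% (radiation_members %||% character(0))
         )),
    class = "divscape_world"
  )
}

#' @export
print.divscape_world <- function(x, ...) {
  cat(sprintf(
    "<divscape_world> scenario '%s': %d species, %d x %d grid, %d records\n",
    x$config$scenario, x$config$n_species, x$config$grid_rows,
    x$config$grid_cols, nrow(x$occurrences)))
  invisible(x)
}

#' Mean environmental suitability per cell
#'
#' Gaussian suitability of each cell for each species
#' (`exp(-(aridity - optimum)^2 / (2 * sd^2))`), averaged over the
#' species pool; used to check that generated richness tracks the
#' environment.
#'
#' @param world A `divscape_world`.
#' @param niche_sd Niche breadth on the aridity axis; default 0.2.
#' @return The environment tibble with a `mean_suitability` column.
#' @export
cell_suitability <- function(world, niche_sd = 0.2) {
  stopifnot(inherits(world, "divscape_world"))
  mu <- world$truth$optimum
  suit <- vapply(world$environment$aridity, function(a) {
    mean(exp(-(a - mu)^2 / (2 * niche_sd^2)))
  }, numeric(1))
  dplyr::mutate(world$environment, mean_suitability = suit)
}

#' Write a synthetic world to plain-text files
#'
#' Writes occurrences, traits (with a weights/types sidecar), the
#' environment grid and the truth table as CSV, and the tree as newick,
#' in the layout the pipeline consumes.
#'
#' @param world A `divscape_world`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "divscape_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(world$occurrences, file.path(dir, "occurrences.csv"))
  readr::write_csv(world$traits, file.path(dir, "traits.csv"))
  readr::write_csv(world$traits_meta, file.path(dir, "trait_meta.csv"))
  readr::write_csv(world$environment, file.path(dir, "environment.csv"))
  write_newick(world$tree, file = file.path(dir, "tree.nwk"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}
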