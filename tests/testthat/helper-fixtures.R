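# Worked three-species fixture used across modules: tree ((A:1,B:1):1,C:2)
# with A confined to cell 1, B in cells 1-2, C in cell 2.
worked_tree <- function() read_newick("((A:1,B:1):1,C:2);")

worked_presence <- function() {
  occ <- tibble::tibble(
    species = c("A", "B", "B", "C"),
    x = c(0.5, 0.5, 1.5, 1.5),
    y = rep(0.5, 4)
  )
  assign_to_cells(occ, grid_spec(0, 0, 1, 1, 2))
}

# UPGMA worked dendrogram: D(A,B)=0.2, D(A,C)=D(B,C)=0.6
worked_dissimilarity <- function() {
  matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# Random small fixture: Yule tree + random occupancy in which every
# species occupies at least one cell.
rand_fixture <- function(seed, max_species = 50, max_cells = 100) {
  set.seed(seed)
  n_sp <- sample(3:max_species, 1)
  n_rows <- sample(2:10, 1)
  n_cols <- sample(2:(max_cells %/% n_rows), 1)
  tree <- simulate_phylogeny(n_sp, seed = seed + 1)
  grid <- grid_spec(0, 0, 1, n_rows, n_cols)
  occ <- purrr::map_dfr(tree$tip.label, function(sp) {
    k <- sample(1:4, 1)
    tibble::tibble(species = sp,
                   x = runif(k, 0, n_cols), y = runif(k, 0, n_rows))
  })
  list(tree = tree, presence = assign_to_cells(occ, grid), occ = occ,
       grid = grid)
}

# Tiny scenario used by pipeline-level tests that do not need the
# full-size study grid.
small_scenario <- function(scenario = "congruent", seed = 1,
                           range_width_mean = 8, ...) {
  scenario_config(scenario, n_species = 40, grid_rows = 8, grid_cols = 8,
                  range_width_mean = range_width_mean, seed = seed, ...)
}

leaf_depths <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
}
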