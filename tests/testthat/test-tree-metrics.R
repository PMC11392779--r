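test_that("newick parsing validates and round-trips", {
  tr <- worked_tree()
  expect_equal(length(tr$tip.label), 3)
  expect_equal(sum(tr$edge.length), 5)
  txt <- write_newick(tr)
  expect_equal(write_newick(read_newick(txt)), txt)
  expect_error(read_newick("((A:1,A:1):1);"), class = "divscape_parse_error")
  suppressWarnings(
    expect_error(read_newick("((A:1,B:1):1"),
                 class = "divscape_parse_error"))
  expect_error(read_newick("((A:1,B):1,C:2);"),
               class = "divscape_parse_error")
})

test_that("branch-sum diversity follows the spanning-subtree rules", {
  tr <- worked_tree()
  expect_equal(branch_sum_diversity(tr, c("A", "B"), "mrca"), 2)
  expect_equal(branch_sum_diversity(tr, c("A", "B", "C"), "root"), 5)
  expect_equal(branch_sum_diversity(tr, "C", "mrca"), 0)
  expect_equal(branch_sum_diversity(tr, "C", "root"), 2)
  expect_error(branch_sum_diversity(tr, "Z"), class = "divscape_lookup_error")
})

test_that("per-branch endemism matches hand enumeration and conserves
           total length", {
  tr <- worked_tree()
  pm <- worked_presence()
  pe <- range_weighted_endemism(tr, pm, "root")
  expect_equal(pe, c(2, 3))
  expect_equal(sum(pe), sum(tr$edge.length))
})

test_that("species confined to one cell make endemism equal diversity", {
  occ <- tibble::tibble(species = c("A", "B", "C"), x = 0.5, y = 0.5)
  pm <- assign_to_cells(occ, grid_spec(0, 0, 1, 1, 2))
  tr <- worked_tree()
  for (mode in c("root", "mrca")) {
    pe <- range_weighted_endemism(tr, pm, mode)
    pd <- branch_diversity_surface(tr, pm, mode)
    expect_equal(pe[1], pd[1])
  }
})

test_that("endemism conservation and PE <= PD hold on random fixtures", {
  for (seed in 0:19) {
    fx <- rand_fixture(seed)
    pe <- range_weighted_endemism(fx$tree, fx$presence, "root")
    pd <- branch_diversity_surface(fx$tree, fx$presence, "root")
    occurring <- fx$presence$species
    expect_equal(sum(pe, na.rm = TRUE),
                 branch_sum_diversity(fx$tree, occurring, "root"),
                 tolerance = 1e-10)
    expect_true(all(pe <= pd + 1e-10, na.rm = TRUE))
  }
})

test_that("adding a species to a cell never decreases branch-sum
           diversity", {
  fx <- rand_fixture(5)
  tr <- fx$tree
  set.seed(99)
  for (i in 1:20) {
    k <- sample(seq_len(min(5, length(tr$tip.label) - 1)), 1)
    base <- sample(tr$tip.label, k)
    extra <- sample(setdiff(tr$tip.label, base), 1)
    for (mode in c("root", "mrca")) {
      expect_gte(branch_sum_diversity(tr, c(base, extra), mode),
                 branch_sum_diversity(tr, base, mode) - 1e-12)
    }
  }
})

test_that("phylogenetic diversity agrees with an independent reference
           implementation", {
  skip_if_not_installed("picante")
  fx <- rand_fixture(23)
  comm <- fx$presence$presence * 1
  occ <- rowSums(comm) > 0
  comm <- comm[occ, , drop = FALSE]
  rownames(comm) <- paste0("cell", seq_len(nrow(comm)))
  ref <- picante::pd(comm, fx$tree, include.root = TRUE)$PD
  ours <- branch_diversity_surface(fx$tree, fx$presence, "root")
  expect_equal(unname(ours[which(occ)]), ref, tolerance = 1e-10)
})

test_that("star trees collapse branch metrics onto taxonomic ones", {
  fx <- rand_fixture(31)
  sp <- fx$presence$species
  star <- read_newick(paste0("(", paste0(sp, ":1", collapse = ","), ");"))
  pd <- branch_diversity_surface(star, fx$presence, "root")
  pe <- range_weighted_endemism(star, fx$presence, "root")
  ts <- taxonomic_surfaces(fx$presence)
  occ <- which(rowSums(fx$presence$presence) > 0)
  expect_equal(unname(pd[occ]), as.numeric(ts$td))
  expect_equal(unname(pe[occ]), ts$we, tolerance = 1e-12)
})

test_that("grafting into a multi-leaf genus creates an ultrametric
           polytomy at the genus ancestor", {
  tr <- worked_tree()
  lg <- tibble::tibble(species = c("A", "B", "C"),
                       genus = c("g1", "g1", "g2"))
  g <- graft_missing_species(
    tr, tibble::tibble(species = "X", genus = "g1"), lg)
  expect_equal(sort(g$tree$tip.label), c("A", "B", "C", "X"))
  expect_equal(g$log$action, "grafted")
  d <- leaf_depths(g$tree)
  names(d) <- g$tree$tip.label
  expect_equal(unname(d["X"]), 2)          # same depth as A and B
  expect_equal(unname(d[c("A", "B", "C")]), c(2, 2, 2))
  # X's pendant equals the genus crown depth (1)
  xi <- match("X", g$tree$tip.label)
  expect_equal(g$tree$edge.length[g$tree$edge[, 2] == xi], 1)
})

test_that("grafting into a monotypic genus splits the pendant branch at
           its midpoint", {
  tr <- worked_tree()
  lg <- tibble::tibble(species = c("A", "B", "C"),
                       genus = c("g1", "g1", "g2"))
  g <- graft_missing_species(
    tr, tibble::tibble(species = "Y", genus = "g2"), lg)
  d <- leaf_depths(g$tree)
  names(d) <- g$tree$tip.label
  expect_equal(unname(d["Y"]), 2)
  yi <- match("Y", g$tree$tip.label)
  expect_equal(g$tree$edge.length[g$tree$edge[, 2] == yi], 1)
  # C's pendant is now 1 as well, below a new node at depth 1
  ci <- match("C", g$tree$tip.label)
  expect_equal(g$tree$edge.length[g$tree$edge[, 2] == ci], 1)
})

test_that("species with no genus in the tree are dropped and logged", {
  tr <- worked_tree()
  lg <- tibble::tibble(species = c("A", "B", "C"),
                       genus = c("g1", "g1", "g2"))
  g <- graft_missing_species(
    tr, tibble::tibble(species = "Z", genus = "nowhere"), lg)
  expect_equal(g$log$action, "dropped")
  expect_equal(write_newick(g$tree), write_newick(tr))
})

test_that("grafting preserves ultrametricity on simulated trees", {
  tree <- simulate_phylogeny(30, seed = 4)
  lg <- tibble::tibble(species = tree$tip.label,
                       genus = rep(paste0("g", 1:6), length.out = 30))
  add <- tibble::tibble(species = paste0("new", 1:8),
                        genus = rep(paste0("g", 1:4), 2))
  g <- graft_missing_species(tree, add, lg)
  expect_equal(length(g$tree$tip.label), 38)
  expect_equal(sum(g$log$action == "grafted"), 8)
  d <- leaf_depths(g$tree)
  expect_lt(diff(range(d)), 1e-9 * max(d))
})
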