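test_that("points map to half-open row-major cells", {
  grid <- grid_spec(0, 0, 25, 3, 3)
  occ <- tibble::tibble(
    species = c("a", "a", "a", "b"),
    x = c(12.5, 25.0, 10, 10),
    y = c(37.5, 10.0, 10, 10)
  )
  pm <- assign_to_cells(occ, grid)
  tb <- presence_tibble(pm)
  # (12.5, 37.5) -> row 1, col 0; x = 25 exactly -> column 1, not 0
  expect_true(any(tb$row == 1 & tb$col == 0 & tb$species == "a"))
  expect_true(any(tb$row == 0 & tb$col == 1 & tb$species == "a"))
  # two species, three records in cell (0,0)? a and b at (10,10)
  cell00 <- tb[tb$row == 0 & tb$col == 0, ]
  expect_setequal(cell00$species, c("a", "b"))
})

test_that("sample counts accumulate records and out-of-extent points drop", {
  grid <- grid_spec(0, 0, 25, 1, 1)
  occ <- tibble::tibble(species = rep("a", 3), x = rep(5, 3), y = rep(5, 3))
  pm <- assign_to_cells(occ, grid)
  expect_equal(sum(pm$presence), 1)
  expect_equal(pm$samples[1], 3L)
  expect_warning(
    pm2 <- assign_to_cells(
      dplyr::bind_rows(occ, tibble::tibble(species = "a", x = 99, y = 99)),
      grid),
    "outside the grid extent")
  expect_equal(pm2$samples[1], 3L)
  suppressWarnings(expect_error(
    assign_to_cells(tibble::tibble(species = "a", x = 99, y = 99), grid),
    class = "divscape_empty_input"))
})

test_that("range_filter drops only out-of-bounds records and logs them", {
  occ <- tibble::tibble(species = c("a", "a", "b"),
                        x = c(1, 2, 3), y = c(40, 20, 50))
  bounds <- tibble::tibble(species = "a", xmin = 0, xmax = 10,
                           ymin = 10, ymax = 35)
  out <- range_filter(occ, bounds)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "drop_log")$y, 40)
  # species without bounds pass through; all-covering bounds are identity
  expect_equal(nrow(range_filter(occ, NULL)), 3)
  wide <- tibble::tibble(species = c("a", "b"), xmin = -99, xmax = 99,
                         ymin = -99, ymax = 99)
  expect_equal(range_filter(occ, wide)$x, occ$x)
})

test_that("redundancy follows 1 - richness/samples", {
  grid <- grid_spec(0, 0, 1, 1, 3)
  mk <- function(n_sp, n_rec, col) {
    sp <- paste0("s", col, "_", rep(seq_len(n_sp), length.out = n_rec))
    tibble::tibble(species = sp, x = col + 0.5, y = 0.5)
  }
  occ <- dplyr::bind_rows(mk(5, 20, 0), mk(1, 1, 1), mk(1, 100, 2))
  red <- compute_redundancy(assign_to_cells(occ, grid))
  expect_equal(red$per_cell$redundancy, c(0.75, 0, 0.99))
  expect_equal(red$average_redundancy, mean(c(0.75, 0, 0.99)))
})

test_that("one record per species means zero redundancy", {
  occ <- tibble::tibble(species = c("a", "b", "c"), x = 0.5, y = 0.5)
  red <- compute_redundancy(assign_to_cells(occ, grid_spec(0, 0, 1, 1, 1)))
  expect_equal(red$per_cell$redundancy, 0)
})

test_that("duplicating all records raises redundancy, richness unchanged", {
  fx <- rand_fixture(7)
  red1 <- compute_redundancy(fx$presence)
  dup <- assign_to_cells(dplyr::bind_rows(fx$occ, fx$occ), fx$grid)
  red2 <- compute_redundancy(dup)
  expect_equal(red2$per_cell$richness, red1$per_cell$richness)
  expect_true(all(red2$per_cell$redundancy > red1$per_cell$redundancy -
                    1e-12))
  expect_gt(red2$average_redundancy, red1$average_redundancy)
})

test_that("cell sample counts conserve in-extent record totals", {
  for (seed in c(1, 2, 3)) {
    fx <- rand_fixture(seed)
    expect_equal(sum(fx$presence$samples), nrow(fx$occ))
  }
})

test_that("coarsening never decreases per-cell samples and matches a
           re-gridding oracle", {
  fx <- rand_fixture(11)
  fine <- fx$presence
  coarse_grid <- grid_spec(0, 0, 2, ceiling(fx$grid$n_rows / 2),
                           ceiling(fx$grid$n_cols / 2))
  coarse <- assign_to_cells(fx$occ, coarse_grid)
  # each coarse cell aggregates its four fine children
  ft <- compute_redundancy(fine)$per_cell
  ct <- compute_redundancy(coarse)$per_cell
  agg <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ft, row = row %/% 2, col = col %/% 2),
                    row, col),
    samples = sum(samples), .groups = "drop")
  j <- dplyr::left_join(ct, agg, by = c("row", "col"),
                        suffix = c("", "_fine"))
  expect_equal(j$samples, j$samples_fine)
  # brute-force ARd oracle at the coarse size
  oracle <- mean(1 - ct$richness / ct$samples)
  expect_equal(compute_redundancy(coarse)$average_redundancy, oracle)
})

test_that("select_resolution prefers the finest passing grid", {
  # dense sampling: every candidate passes, smallest wins
  set.seed(42)
  occ <- tibble::tibble(
    species = rep(paste0("s", 1:5), each = 40),
    x = runif(200, 0, 50), y = runif(200, 0, 50))
  sel <- select_resolution(occ, c(25, 50, 75, 100))
  expect_true(all(sel$report$passes))
  expect_equal(sel$cell_size, 25)
  expect_false(sel$below_threshold)
  expect_error(select_resolution(occ, numeric(0)),
               class = "divscape_invalid_config")
})

test_that("sparse sampling falls back to the best candidate,
           verified against brute-force ARd", {
  set.seed(43)
  # singletons nearly everywhere: redundancy only accumulates when cells
  # are large enough to pool records of the same species
  occ <- tibble::tibble(
    species = rep(paste0("s", 1:4), each = 30),
    x = runif(120, 0, 300), y = runif(120, 0, 300))
  sel <- select_resolution(occ, c(25, 50, 100), ard_threshold = 0.6)
  brute <- vapply(c(25, 50, 100), function(size) {
    compute_redundancy(
      assign_to_cells(occ, grid_covering(occ, size)))$average_redundancy
  }, numeric(1))
  expect_equal(sel$report$average_redundancy, brute)
  if (any(brute >= 0.6)) {
    expect_equal(sel$cell_size, c(25, 50, 100)[min(which(brute >= 0.6))])
  } else {
    expect_true(sel$below_threshold)
    expect_equal(sel$cell_size, c(25, 50, 100)[which.max(brute)])
  }
})
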