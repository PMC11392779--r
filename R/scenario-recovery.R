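#' Headline statistic of a scenario's expected spatial signature
#'
#' Runs the relevant slice of the pipeline on one simulated world and
#' returns the quantity that scenario is designed to move:
#' `environmental_filter` — the median FD ~ TD residual in arid cells
#' (aridity above the scenario threshold) and in mesic cells (filtering
#' should push the arid median negative and below the mesic one);
#' `in_situ_radiation` — the same medians for PD ~ TD residuals;
#' `congruent` — the ordinary r-squared between per-cell TD and PD;
#' `isolation_endemism` — the largest absolute difference between WE and
#' TD over cells (zero when every species is a single-cell endemic);
#' `biotic_exchange` — the arid/mesic medians of PD ~ TD residuals
#' (immigration of distant lineages should keep the arid median from
#' sinking).
#'
#' @param scenario Scenario name, as in [scenario_config()].
#' @param seed Integer seed.
#' @param ... Further arguments to [scenario_config()] (grid size,
#'   species pool, ...).
#' @return A one-row tibble; columns depend on the scenario.
#' @export
scenario_signature <- function(scenario, seed, ...) {
  cfg <- scenario_config(scenario, seed = seed, ...)
  w <- simulate_world(cfg)
  pm <- assign_to_cells(w$occurrences, w$grid)
  if (scenario == "congruent") {
    td <- rowSums(pm$presence)
    pd <- branch_diversity_surface(w$tree, pm, "root")
    occ <- td > 0
    return(tibble::tibble(scenario = scenario, seed = seed,
                          td_pd_r2 = cor(td[occ], pd[occ])^2,
                          n_cells = sum(occ)))
  }
  if (scenario == "isolation_endemism") {
    ts <- taxonomic_surfaces(pm)
    return(tibble::tibble(scenario = scenario, seed = seed,
                          max_we_td_gap = max(abs(ts$we - ts$td)),
                          n_cells = nrow(ts)))
  }
  model <- if (scenario == "environmental_filter") "fd ~ td" else "pd ~ td"
  D <- weighted_gower_dissimilarity(w$traits, w$traits_meta)
  dendro <- upgma(D)
  surfaces <- compute_all_surfaces(pm, w$tree, dendro)
  suite <- run_model_suite(surfaces, models = model)
  cl <- dplyr::left_join(tidy(suite), w$environment, by = c("row", "col"))
  arid <- cl$aridity > cfg$arid_threshold
  tibble::tibble(
    scenario = scenario, seed = seed, model = names(suite),
    arid_median_residual = median(cl$residual[arid]),
    mesic_median_residual = median(cl$residual[!arid]),
    n_cells = nrow(cl)
  )
}
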