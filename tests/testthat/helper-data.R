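# Minimal in-code fixtures. tiny_tables() is one CR single-island endemic
# bird with one confirmed rat impact on an uninhabited 500 ha island;
# tests modify the list and rebuild with build_dataset().

tiny_tables <- function() {
  list(
    islands = tibble::tibble(
      island_id = "isl1", name = "Isle One", country = "Atlantis",
      area_ha = 500, human_population = 0L, sensitive = FALSE),
    species = tibble::tibble(
      species_id = "sp1", name = "Petrel A", taxon_class = "bird",
      seabird_flag = TRUE, family = "procellariidae",
      iucn_category = "cr", insularity = "insular"),
    breeding = tibble::tibble(
      species_id = "sp1", island_id = "isl1",
      breeding_status = "confirmed"),
    invasive_populations = tibble::tibble(
      invasive_id = "rattus_rattus", invasive_group = "rodent",
      island_id = "isl1", presence = "confirmed", feral_status = "feral",
      rodent_status_unknown = FALSE, under_eradication = FALSE),
    interactions = tibble::tibble(
      invasive_id = "rattus_rattus", species_id = "sp1",
      island_id = "isl1", impact_class = "confirmed"),
    feasibility_rules = tibble::tibble(
      invasive_group = c("rodent", "cat", "ungulate", "dog"),
      max_area_ha = c(13000, 6500, 60000, 30000),
      max_human_population = c(100, 1000, 3000, 3000)),
    expert_assessments = tibble::tibble(
      island_id = character(), expert_id = character(),
      timeframe = character(), years_experience = integer())
  )
}

build_dataset <- function(tables) do.call(erad_dataset, tables)

tiny_dataset <- function() build_dataset(tiny_tables())

# small random dataset for property loops
small_dataset <- function(seed, n_islands = 10) {
  generate_dataset(generator_params(n_islands = n_islands, seed = seed))
}
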