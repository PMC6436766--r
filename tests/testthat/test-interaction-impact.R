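test_that("candidates are the cross product of breeders and included invasives", {
  tabs <- tiny_tables()
  tabs$species <- tibble::tibble(
    species_id = c("sp1", "sp2"), name = c("A", "B"),
    taxon_class = "bird", seabird_flag = FALSE, family = "f1",
    iucn_category = "en", insularity = "insular")
  tabs$breeding <- tibble::tibble(
    species_id = c("sp1", "sp2"), island_id = "isl1",
    breeding_status = "confirmed")
  tabs$invasive_populations <- tibble::tibble(
    invasive_id = c("rattus_rattus", "felis_catus", "capra_hircus"),
    invasive_group = c("rodent", "cat", "ungulate"),
    island_id = "isl1", presence = "confirmed", feral_status = "feral",
    rodent_status_unknown = FALSE, under_eradication = FALSE)
  tabs$interactions <- tabs$interactions[0, ]
  cand <- enumerate_interactions(build_dataset(tabs))
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$impact_class == "unknown"))

  # an island with only domestic cattle yields no candidates
  tabs$invasive_populations <- tibble::tibble(
    invasive_id = "bos_taurus", invasive_group = "ungulate",
    island_id = "isl1", presence = "confirmed",
    feral_status = "domestic", rodent_status_unknown = FALSE,
    under_eradication = FALSE)
  expect_equal(nrow(enumerate_interactions(build_dataset(tabs))), 0)
})

test_that("candidate count equals sum over islands of species x invasives", {
  for (seed in c(4, 9, 31)) {
    d <- small_dataset(seed, n_islands = 20)
    cand <- enumerate_interactions(d)
    pops <- d$invasive_populations[!d$invasive_populations$excluded, ]
    per_island <- sapply(d$islands$island_id, function(i) {
      n_sp <- length(unique(d$breeding$species_id[d$breeding$island_id == i]))
      n_inv <- length(unique(pops$invasive_id[pops$island_id == i]))
      n_sp * n_inv
    })
    expect_equal(nrow(cand), sum(per_island))
  }
})

test_that("unknown impacts are imputed from family evidence elsewhere", {
  tabs <- tiny_tables()
  # petrel A (isl1) has no record against the rat; petrel B (isl2), same
  # family, has a confirmed rat impact
  tabs$islands <- tibble::tibble(
    island_id = c("isl1", "isl2"), name = c("One", "Two"),
    country = "Atlantis", area_ha = 500, human_population = 0L,
    sensitive = FALSE)
  tabs$species <- dplyr::bind_rows(
    tabs$species,
    tibble::tibble(species_id = "sp2", name = "Petrel B",
                   taxon_class = "bird", seabird_flag = TRUE,
                   family = "procellariidae", iucn_category = "en",
                   insularity = "insular"))
  tabs$breeding <- tibble::tibble(
    species_id = c("sp1", "sp2"), island_id = c("isl1", "isl2"),
    breeding_status = "confirmed")
  tabs$invasive_populations <- tibble::tibble(
    invasive_id = "rattus_rattus", invasive_group = "rodent",
    island_id = c("isl1", "isl2"), presence = "confirmed",
    feral_status = "feral", rodent_status_unknown = FALSE,
    under_eradication = FALSE)
  tabs$interactions <- tibble::tibble(
    invasive_id = "rattus_rattus", species_id = "sp2", island_id = "isl2",
    impact_class = "confirmed")
  d <- build_dataset(tabs)
  done <- impute_impacts(enumerate_interactions(d), d)
  a <- done[done$species_id == "sp1", ]
  expect_equal(a$score, 2L)
  expect_equal(a$provenance, "imputed")

  # no family evidence anywhere -> assumed zero
  tabs$interactions <- tabs$interactions[0, ]
  d <- build_dataset(tabs)
  done <- impute_impacts(enumerate_interactions(d), d)
  expect_true(all(done$score == 0L))
  expect_true(all(done$provenance == "assumed_zero"))
})

test_that("explicit records always beat imputation, including explicit none", {
  tabs <- tiny_tables()
  tabs$species <- dplyr::bind_rows(
    tabs$species,
    tibble::tibble(species_id = "sp2", name = "Petrel B",
                   taxon_class = "bird", seabird_flag = TRUE,
                   family = "procellariidae", iucn_category = "en",
                   insularity = "insular"))
  tabs$breeding <- tibble::tibble(
    species_id = c("sp1", "sp2"), island_id = "isl1",
    breeding_status = "confirmed")
  # sp1 confirmed (2), sp2 explicit none (0) despite family evidence of 2
  tabs$interactions <- tibble::tibble(
    invasive_id = "rattus_rattus", species_id = c("sp1", "sp2"),
    island_id = "isl1", impact_class = c("confirmed", "none"))
  d <- build_dataset(tabs)
  done <- impute_impacts(enumerate_interactions(d), d)
  b <- done[done$species_id == "sp2", ]
  expect_equal(b$score, 0L)
  expect_equal(b$provenance, "direct")

  # precedence agrees with an oracle that only fills unknowns
  fills_unknowns_only <- done$has_record |
    (done$provenance %in% c("imputed", "assumed_zero"))
  expect_true(all(fills_unknowns_only))
})

test_that("imputation is idempotent", {
  d <- small_dataset(13, n_islands = 15)
  once <- impute_impacts(enumerate_interactions(d), d)
  twice <- impute_impacts(once, d)
  expect_equal(twice$score, once$score)
  expect_equal(twice$provenance, once$provenance)
})

test_that("severity is the maximum over contributing populations", {
  tabs <- tiny_tables()
  tabs$invasive_populations <- tibble::tibble(
    invasive_id = c("felis_catus", "rattus_rattus"),
    invasive_group = c("cat", "rodent"), island_id = "isl1",
    presence = "confirmed", feral_status = "feral",
    rodent_status_unknown = FALSE, under_eradication = FALSE)
  tabs$interactions <- tibble::tibble(
    invasive_id = c("felis_catus", "rattus_rattus"), species_id = "sp1",
    island_id = "isl1", impact_class = c("confirmed", "suspected"))
  d <- build_dataset(tabs)
  sev <- severity_matrix(d)
  expect_equal(sev$z, 2L)

  # empty contributing set -> empty matrix (z treated as 0 downstream)
  empty <- severity_matrix(
    d, invasive_filter = tibble::tibble(invasive_id = character(),
                                        island_id = character()))
  expect_equal(nrow(empty), 0)
})

test_that("severity matrix equals a triple-loop recomputation", {
  d <- small_dataset(21, n_islands = 20)
  sev <- severity_matrix(d)
  done <- impute_impacts(enumerate_interactions(d), d)
  for (r in sample.int(nrow(sev), min(40, nrow(sev)))) {
    rows <- done[done$species_id == sev$species_id[r] &
                   done$island_id == sev$island_id[r], ]
    expect_equal(sev$z[r], max(rows$score))
  }
})

test_that("enlarging the contributing population set never decreases z", {
  for (seed in c(6, 17)) {
    d <- small_dataset(seed, n_islands = 15)
    pops <- d$invasive_populations[!d$invasive_populations$excluded,
                                   c("invasive_id", "island_id")]
    set.seed(seed)
    part <- pops[sample.int(nrow(pops), floor(nrow(pops) / 2)), ]
    z_part <- severity_matrix(d, invasive_filter = part)
    z_full <- severity_matrix(d)
    joined <- merge(as.data.frame(z_part), as.data.frame(z_full),
                    by = c("species_id", "island_id"))
    expect_true(all(joined$z.y >= joined$z.x))
    expect_true(all(z_full$z %in% 0:2))
  }
})
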