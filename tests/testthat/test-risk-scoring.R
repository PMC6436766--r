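test_that("extinction risk follows the scheme weights", {
  expect_equal(extinction_risk("CR"), 0.5)
  expect_equal(extinction_risk("EN"), 0.05)
  expect_equal(extinction_risk("cr", risk_scheme("linear")), 4)
  expect_equal(extinction_risk("en", risk_scheme("linear")), 3)
  expect_error(extinction_risk("VU"), class = "erad_value_error")
  expect_error(risk_scheme("custom"), class = "erad_config_error")
  custom <- risk_scheme("custom", cr_score = 1, en_score = 0.1)
  expect_equal(extinction_risk("cr", custom), 1)
})

test_that("irreplaceability is the reciprocal of breeding-island count", {
  br <- tibble::tibble(
    species_id = c("a", "b", "b", "b", "b", "c", "c"),
    island_id = c("i1", "i1", "i2", "i3", "i4", "i1", "i2"),
    breeding_status = "confirmed")
  tab <- irreplaceability(br)
  expect_equal(tab$irreplaceability[tab$species_id == "a"], 1)
  expect_equal(tab$irreplaceability[tab$species_id == "b"], 0.25)
  # insular-and-continental species: only breeding islands count, so a
  # 2-island breeder gets 0.5 no matter what its insularity says
  expect_equal(tab$irreplaceability[tab$species_id == "c"], 0.5)
  expect_error(irreplaceability(br, species_id = "ghost"),
               class = "erad_value_error")
})

test_that("CCR matches hand arithmetic on minimal datasets", {
  # one CR single-island endemic with confirmed impact: 0.5 * 1 * 2 = 1
  d <- tiny_dataset()
  expect_equal(compute_ccr(d)$ccr, 1.0)

  # one EN species breeding on 2 islands, suspected impact on one:
  # 0.05 * 0.5 * 1 = 0.025
  tabs <- tiny_tables()
  tabs$islands <- tibble::tibble(
    island_id = c("isl1", "isl2"), name = c("One", "Two"),
    country = "Atlantis", area_ha = 500, human_population = 0L,
    sensitive = FALSE)
  tabs$species$iucn_category <- "en"
  tabs$species$insularity <- "insular_and_continental"
  tabs$breeding <- tibble::tibble(
    species_id = "sp1", island_id = c("isl1", "isl2"),
    breeding_status = c("confirmed", "potential"))
  tabs$interactions$impact_class <- "suspected"
  d <- build_dataset(tabs)
  ccr <- compute_ccr(d)
  expect_equal(ccr$ccr[ccr$island_id == "isl1"], 0.025)
  # no invasives on isl2 at all
  expect_equal(ccr$ccr[ccr$island_id == "isl2"], 0)

  # all impacts none -> zero
  tabs$interactions$impact_class <- "none"
  expect_equal(compute_ccr(build_dataset(tabs))$ccr, c(0, 0))
})

test_that("potential breeding counts the same as confirmed breeding", {
  tabs <- tiny_tables()
  tabs$breeding$breeding_status <- "potential"
  expect_equal(compute_ccr(build_dataset(tabs))$ccr, 1.0)
})

test_that("PCR zeroes only feasible populations, concurrently", {
  d <- tiny_dataset()
  flags <- feasibility_flags(d)

  # the rat is feasible on a 500 ha uninhabited island -> PCR 0
  expect_true(all(flags$feasible))
  expect_equal(compute_pcr(d, feasibility_flags = flags)$pcr, 0)

  # force infeasible -> PCR = CCR, EB = 0
  flags$feasible <- FALSE
  scores <- eradication_benefit(compute_ccr(d),
                                compute_pcr(d, feasibility_flags = flags))
  expect_equal(scores$pcr, scores$ccr)
  expect_equal(scores$eb, 0)

  # feasible rat + infeasible cat, both z = 2: PCR keeps the cat's 2, so
  # the island sees no benefit
  tabs <- tiny_tables()
  tabs$invasive_populations <- tibble::tibble(
    invasive_id = c("rattus_rattus", "felis_catus"),
    invasive_group = c("rodent", "cat"), island_id = "isl1",
    presence = "confirmed", feral_status = "feral",
    rodent_status_unknown = FALSE, under_eradication = FALSE)
  tabs$interactions <- tibble::tibble(
    invasive_id = c("rattus_rattus", "felis_catus"), species_id = "sp1",
    island_id = "isl1", impact_class = "confirmed")
  d2 <- build_dataset(tabs)
  flags2 <- tibble::tibble(invasive_id = c("rattus_rattus", "felis_catus"),
                           invasive_group = c("rodent", "cat"),
                           island_id = "isl1",
                           feasible = c(TRUE, FALSE))
  s2 <- eradication_benefit(compute_ccr(d2),
                            compute_pcr(d2, feasibility_flags = flags2))
  expect_equal(s2$pcr, s2$ccr)
  expect_equal(s2$eb, 0)
})

test_that("eradication benefit subtracts and demands matching islands", {
  ccr <- tibble::tibble(island_id = c("a", "b"), ccr = c(1, 2))
  pcr <- tibble::tibble(island_id = c("a", "b"), pcr = c(0, 2))
  eb <- eradication_benefit(ccr, pcr)
  expect_equal(eb$eb, c(1, 0))
  expect_error(
    eradication_benefit(ccr, tibble::tibble(island_id = "a", pcr = 0)),
    class = "erad_key_error")
})

test_that("ranking is by EB desc with deterministic tie-breaks", {
  scores <- tibble::tibble(
    island_id = c("b", "a", "c", "d"),
    ccr = c(2, 3, 3, 1), pcr = c(0, 1, 1, 1),
    eb = c(2, 2, 2, 0), n_reduced = c(1, 1, 2, 0))
  ranked <- rank_islands(scores)
  # ties: equal EB -> higher CCR first; equal CCR -> more species with
  # reduced severity; then island_id
  expect_equal(ranked$island_id, c("c", "a", "b", "d"))
  expect_equal(ranked$rank, c(1L, 2L, 3L, NA))

  # all EB zero -> nothing ranked
  zero <- rank_islands(tibble::tibble(island_id = c("a", "b"),
                                      ccr = c(1, 1), pcr = c(1, 1),
                                      eb = c(0, 0)))
  expect_true(all(is.na(zero$rank)))
})

test_that("score invariants hold across random datasets and both schemes", {
  for (seed in c(3, 14, 25, 36)) {
    d <- small_dataset(seed, n_islands = 15)
    for (scheme_name in c("default", "linear")) {
      s <- score_islands(d, scheme = risk_scheme(scheme_name))
      expect_true(all(s$pcr >= 0))
      expect_true(all(s$pcr <= s$ccr + 1e-12))
      expect_true(all(s$eb >= 0))
      # CCR upper bound: z <= 2, I <= 1, at most cr_score per species
      n_breeders <- table(unique(d$breeding[, 1:2])$island_id)
      cap <- 2 * risk_scheme(scheme_name)$cr_score *
        as.numeric(n_breeders[s$island_id])
      cap[is.na(cap)] <- 0
      expect_true(all(s$ccr <= cap + 1e-12))
    }
    # feasibility, not the E scheme, decides which islands benefit
    s1 <- score_islands(d, scheme = risk_scheme("default"))
    s2 <- score_islands(d, scheme = risk_scheme("linear"))
    s2 <- s2[match(s1$island_id, s2$island_id), ]
    expect_equal(s1$eb > 0, s2$eb > 0)
  }
})

test_that("adding an impact never decreases CCR", {
  tabs <- tiny_tables()
  tabs$species <- dplyr::bind_rows(
    tabs$species,
    tibble::tibble(species_id = "sp2", name = "Skink", taxon_class = "reptile",
                   seabird_flag = FALSE, family = "scincidae",
                   iucn_category = "en", insularity = "insular"))
  tabs$breeding <- tibble::tibble(
    species_id = c("sp1", "sp2"), island_id = "isl1",
    breeding_status = "confirmed")
  base_ccr <- compute_ccr(build_dataset(tabs))$ccr

  tabs$interactions <- dplyr::bind_rows(
    tabs$interactions,
    tibble::tibble(invasive_id = "rattus_rattus", species_id = "sp2",
                   island_id = "isl1", impact_class = "suspected"))
  with_new <- compute_ccr(build_dataset(tabs))$ccr
  expect_gte(with_new, base_ccr)

  # raising an impact class likewise
  tabs$interactions$impact_class[2] <- "confirmed"
  expect_gte(compute_ccr(build_dataset(tabs))$ccr, with_new)
})

test_that("marking one more population feasible never increases PCR", {
  for (seed in c(8, 19)) {
    d <- small_dataset(seed, n_islands = 12)
    flags <- feasibility_flags(d)
    infeasible_rows <- which(!flags$feasible)
    if (length(infeasible_rows) == 0) next
    pcr0 <- compute_pcr(d, feasibility_flags = flags)$pcr
    flags$feasible[infeasible_rows[1]] <- TRUE
    pcr1 <- compute_pcr(d, feasibility_flags = flags)$pcr
    expect_true(all(pcr1 <= pcr0 + 1e-12))
  }
})
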