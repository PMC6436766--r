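# Benefit accounting, sensitive-island masking, low-complexity flags,
# the rodent sensitivity scenario, percentage formatting and the
# end-to-end pipeline.

#' Species-island pairs that benefit from feasible eradications
#'
#' A population (species s, island i) benefits iff the feasible removal of
#' invasive mammals lowers its maximum impact severity: Z over all
#' included populations exceeds Z over the infeasible-only populations.
#'
#' @param dataset A validated `erad_dataset`.
#' @param feasibility_flags Output of [feasibility_flags()].
#' @param island_set Optional vector of island ids to restrict to.
#' @param completed Optional precomputed [impute_impacts()] output.
#' @return A tibble `species_id`, `island_id`, `z_all`, `z_infeasible`.
#' @export
benefit_records <- function(dataset, feasibility_flags, island_set = NULL,
                            completed = NULL) {
  if (is.null(completed)) {
    completed <- impute_impacts(enumerate_interactions(dataset), dataset)
  }
  z_all <- severity_matrix(dataset, completed = completed)
  infeasible <- dplyr::filter(feasibility_flags, !.data$feasible)
  z_inf <- severity_matrix(dataset, invasive_filter = infeasible,
                           completed = completed) |>
    dplyr::select("species_id", "island_id", z_infeasible = "z")
  out <- z_all |>
    dplyr::select("species_id", "island_id", z_all = "z") |>
    dplyr::left_join(z_inf, by = c("species_id", "island_id")) |>
    dplyr::mutate(z_infeasible = dplyr::coalesce(.data$z_infeasible, 0L)) |>
    dplyr::filter(.data$z_all > .data$z_infeasible)
  if (!is.null(island_set)) {
    out <- dplyr::filter(out, .data$island_id %in% island_set)
  }
  out
}

#' Summarize benefiting populations and species
#'
#' Counts species-island pairs (populations), distinct species, islands
#' and countries among the benefit records, with a per-taxon breakdown.
#' Birds are split into seabirds and landbirds for reporting only; the
#' split never affects scores.
#'
#' @param pairs Benefit records from [benefit_records()].
#' @param dataset The `erad_dataset` the pairs came from.
#' @param label Label for the summary (e.g. the timeframe set name).
#' @return An object of class `erad_summary`: a list with `label`,
#'   `n_islands`, `n_populations`, `n_species`, `n_countries` and a
#'   `breakdown` tibble by taxon group.
#' @export
summarize_benefits <- function(pairs, dataset, label = "all") {
  sp <- dataset$species |>
    dplyr::mutate(taxon_group = dplyr::case_when(
      .data$taxon_class == "bird" & .data$seabird_flag ~ "seabird",
      .data$taxon_class == "bird" ~ "landbird",
      TRUE ~ .data$taxon_class
    )) |>
    dplyr::select("species_id", "taxon_group")
  tagged <- dplyr::left_join(pairs, sp, by = "species_id")
  countries <- dataset$islands$country[
    match(unique(pairs$island_id), dataset$islands$island_id)]
  breakdown <- tagged |>
    dplyr::group_by(.data$taxon_group) |>
    dplyr::summarise(n_populations = dplyr::n(),
                     n_species = dplyr::n_distinct(.data$species_id),
                     .groups = "drop")
  structure(
    list(label = label,
         n_islands = dplyr::n_distinct(pairs$island_id),
         n_populations = nrow(pairs),
         n_species = dplyr::n_distinct(pairs$species_id),
         n_countries = dplyr::n_distinct(countries),
         breakdown = breakdown),
    class = "erad_summary"
  )
}

#' @export
print.erad_summary <- function(x, ...) {
  cat(sprintf("<benefit summary: %s>\n", x$label))
  cat(sprintf("  %d populations of %d species on %d islands in %d countries\n",
              x$n_populations, x$n_species, x$n_islands, x$n_countries))
  if (nrow(x$breakdown) > 0) print(x$breakdown)
  invisible(x)
}

# one-row flat form used by write_results()
.summary_row <- function(s) {
  row <- tibble::tibble(label = s$label, n_islands = s$n_islands,
                        n_populations = s$n_populations,
                        n_species = s$n_species,
                        n_countries = s$n_countries)
  for (i in seq_len(nrow(s$breakdown))) {
    g <- s$breakdown$taxon_group[i]
    row[[paste0("populations_", g)]] <- s$breakdown$n_populations[i]
    row[[paste0("species_", g)]] <- s$breakdown$n_species[i]
  }
  row
}

#' Flag islands where eradication is likely low-complexity (low-cost)
#'
#' Operational cost broadly scales with island size, human habitation and
#' the number of invasive species targeted. An island is flagged iff it is
#' small (< 100 ha, strict), uninhabited, and only one or two feasible
#' invasive mammal species with a positive impact on a breeding highly
#' threatened vertebrate would need to be eradicated.
#'
#' @param dataset A validated `erad_dataset`.
#' @param feasibility_flags Output of [feasibility_flags()].
#' @param island_set Island ids to assess (e.g. the by-2020 set).
#' @param completed Optional precomputed [impute_impacts()] output.
#' @return A tibble `island_id`, `n_target_invasives`, `low_complexity`.
#' @export
low_complexity_flags <- function(dataset, feasibility_flags, island_set,
                                 completed = NULL) {
  if (is.null(completed)) {
    completed <- impute_impacts(enumerate_interactions(dataset), dataset)
  }
  # feasible invasive species with a positive (possibly imputed) impact on
  # at least one breeding species of the island
  targets <- completed |>
    dplyr::filter(.data$score > 0) |>
    dplyr::semi_join(dplyr::filter(feasibility_flags, .data$feasible),
                     by = c("invasive_id", "island_id")) |>
    dplyr::distinct(.data$island_id, .data$invasive_id) |>
    dplyr::count(.data$island_id, name = "n_target_invasives")
  tibble::tibble(island_id = island_set) |>
    dplyr::left_join(targets, by = "island_id") |>
    dplyr::mutate(
      n_target_invasives = dplyr::coalesce(.data$n_target_invasives, 0L)
    ) |>
    dplyr::left_join(dplyr::select(dataset$islands, "island_id", "area_ha",
                                   "human_population"),
                     by = "island_id") |>
    dplyr::mutate(
      low_complexity = .data$area_ha < 100 &
        .data$human_population == 0 &
        .data$n_target_invasives %in% c(1L, 2L)
    ) |>
    dplyr::select("island_id", "n_target_invasives", "low_complexity")
}

#' Mask the names of sensitive islands in an output table
#'
#' To limit information useful for illegal wildlife trafficking, island
#' names are replaced by "unknown" for islands flagged sensitive by
#' experts, or smaller than 100 ha (strict) with at least one breeding
#' reptile. Only the `name` column changes; ids are retained so counts and
#' scores are unaffected.
#'
#' @param rows A data frame with `island_id` and `name` columns.
#' @param dataset The `erad_dataset` providing sensitivity information.
#' @return `rows` with masked names.
#' @export
mask_sensitive <- function(rows, dataset) {
  reptile_ids <- dataset$breeding |>
    dplyr::inner_join(
      dplyr::filter(dataset$species, .data$taxon_class == "reptile"),
      by = "species_id") |>
    dplyr::pull("island_id") |>
    unique()
  isl <- dataset$islands
  masked_ids <- isl$island_id[
    isl$sensitive | (isl$area_ha < 100 & isl$island_id %in% reptile_ids)]
  rows$name[rows$island_id %in% masked_ids] <- "unknown"
  rows
}

#' Sensitivity scenario: assume unknown-status rodents are present
#'
#' The impact of rodents is often under-recorded. This scenario re-includes
#' every rodent population whose presence status was unknown, treating it
#' as a confirmed feral presence; everything else is untouched. Returns a
#' new dataset, the input is never mutated; applying the scenario twice
#' equals applying it once.
#'
#' @param dataset A validated `erad_dataset`.
#' @return A new `erad_dataset`.
#' @export
rodent_scenario <- function(dataset) {
  pops <- dataset$invasive_populations |>
    dplyr::mutate(
      presence = ifelse(.data$rodent_status_unknown, "confirmed",
                        .data$presence),
      rodent_status_unknown = FALSE
    )
  erad_dataset(dataset$islands, dataset$species, dataset$breeding,
               pops, dataset$interactions, dataset$feasibility_rules,
               dataset$expert_assessments)
}

#' Percentage rounded half-away-from-zero
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to the
#' requested number of decimals (so 9.375 at one decimal prints as 9.4 and
#' 25.54 at zero decimals prints as 26, matching conventional reporting of
#' percentages; base `round()` rounds half to even instead).
#'
#' @param numerator,denominator Numerics; the denominator must be
#'   positive.
#' @param decimals Number of decimal places (default 0).
#' @return Numeric percentage(s).
#' @export
round_percent <- function(numerator, denominator, decimals = 0) {
  if (any(denominator <= 0)) {
    rlang::abort("denominator must be positive", class = "erad_value_error")
  }
  p <- 100 * numerator / denominator
  scale <- 10^decimals
  sign(p) * floor(abs(p) * scale + 0.5) / scale
}

.pipeline_stage <- function(stage, expr, log_env, n = NA_integer_,
                            verbose = FALSE) {
  out <- tryCatch(
    force(expr),
    error = function(e) {
      rlang::abort(paste0("pipeline stage '", stage, "' failed: ",
                          conditionMessage(e)),
                   class = "erad_pipeline_error", parent = e)
    }
  )
  n <- if (is.data.frame(out)) nrow(out) else n
  log_env$log <- dplyr::bind_rows(
    log_env$log, tibble::tibble(stage = stage, n_records = as.integer(n)))
  if (verbose) message(sprintf("[%s] %s records", stage, n))
  out
}

#' Run the full prioritization pipeline
#'
#' Executes read, validate, impact completion, CCR, technical feasibility,
#' PCR/EB, ranking, timeframe assignment, benefit summaries, masking and
#' (optionally) writing, logging record counts per stage. Deterministic
#' given its inputs: the same configuration always produces byte-identical
#' outputs.
#'
#' @param config A named list, or the path of a YAML file, with entries:
#'   `input_dir` (directory of the seven tables) or `dataset` (an
#'   in-memory `erad_dataset`); `scheme` ("default" or "linear",
#'   default "default"); `rodent_scenario` (logical, default FALSE);
#'   `mask` (logical, default TRUE); `output_dir` (optional); `verbose`
#'   (logical, default FALSE).
#' @return A list with the dataset, scores (named, masked if requested),
#'   feasibility flags, timeframe decisions and sets, benefit summaries
#'   per timeframe set (plus the deduplicated 2020+2030 union),
#'   low-complexity flags for the by-2020 set, and the stage log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  scheme <- risk_scheme(config$scheme %||% "default")
  verbose <- isTRUE(config$verbose)
  env <- new.env()
  env$log <- tibble::tibble(stage = character(), n_records = integer())

  dataset <- if (!is.null(config$dataset)) {
    .pipeline_stage("read", config$dataset, env,
                    n = nrow(config$dataset$islands), verbose = verbose)
  } else if (!is.null(config$input_dir)) {
    .pipeline_stage("read", read_dataset(config$input_dir), env,
                    verbose = verbose)
  } else {
    rlang::abort("config must name input_dir or carry a dataset",
                 class = "erad_config_error")
  }
  .pipeline_stage("validate", {
    report <- validate_dataset(dataset)
    if (nrow(report) > 0) {
      rlang::abort(paste0(nrow(report), " invariant violation(s); run ",
                          "validate_dataset() for the report"),
                   class = "erad_value_error")
    }
    report
  }, env, verbose = verbose)
  if (isTRUE(config$rodent_scenario)) {
    dataset <- .pipeline_stage("rodent_scenario", rodent_scenario(dataset),
                               env, n = nrow(dataset$invasive_populations),
                               verbose = verbose)
  }
  completed <- .pipeline_stage(
    "impacts", impute_impacts(enumerate_interactions(dataset), dataset),
    env, verbose = verbose)
  flags <- .pipeline_stage("feasibility", feasibility_flags(dataset), env,
                           verbose = verbose)
  scores <- .pipeline_stage("score", {
    ccr <- compute_ccr(dataset, scheme, completed = completed)
    pcr <- compute_pcr(dataset, scheme, flags, completed = completed)
    sc <- eradication_benefit(ccr, pcr)
    reduced <- benefit_records(dataset, flags, completed = completed) |>
      dplyr::count(.data$island_id, name = "n_reduced")
    sc |>
      dplyr::left_join(reduced, by = "island_id") |>
      dplyr::mutate(n_reduced = dplyr::coalesce(.data$n_reduced, 0L)) |>
      rank_islands()
  }, env, verbose = verbose)
  tf <- .pipeline_stage("timeframes", assign_timeframes(dataset, scores),
                        env, n = nrow(scores[scores$eb > 0, ]),
                        verbose = verbose)

  summaries <- .pipeline_stage("summaries", {
    sets <- tf$sets
    sets$by2020_2030_union <- union(sets$by2020, sets$by2030)
    lapply(stats::setNames(names(sets), names(sets)), function(nm) {
      pairs <- benefit_records(dataset, flags, island_set = sets[[nm]],
                               completed = completed)
      summarize_benefits(pairs, dataset, label = nm)
    })
  }, env, n = length(tf$sets) + 1L, verbose = verbose)

  low_complexity <- .pipeline_stage(
    "low_complexity",
    low_complexity_flags(dataset, flags, tf$sets$by2020,
                         completed = completed),
    env, verbose = verbose)

  named_scores <- scores |>
    dplyr::left_join(dplyr::select(dataset$islands, "island_id", "name",
                                   "country"), by = "island_id")
  if (!identical(config$mask, FALSE)) {
    named_scores <- .pipeline_stage("mask",
                                    mask_sensitive(named_scores, dataset),
                                    env, verbose = verbose)
  }

  bundle <- list(dataset = dataset, scores = named_scores,
                 feasibility = flags, timeframes = tf,
                 summaries = summaries, low_complexity = low_complexity,
                 scheme = scheme, log = env$log)
  if (!is.null(config$output_dir)) {
    .pipeline_stage("write", {
      files <- write_results(named_scores, summaries, config$output_dir)
      readr::write_csv(tf$decisions,
                       file.path(config$output_dir,
                                 "timeframe_decisions.csv"),
                       progress = FALSE)
      readr::write_csv(low_complexity,
                       file.path(config$output_dir, "low_complexity.csv"),
                       progress = FALSE)
      tibble::tibble(file = c(files,
                              file.path(config$output_dir,
                                        c("timeframe_decisions.csv",
                                          "low_complexity.csv"))))
    }, env, verbose = verbose)
  }
  bundle$log <- env$log
  bundle
}
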