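# Invasive x native interaction enumeration, family-level impact
# imputation, and the per-(species, island) maximum-severity matrix Z.

#' Enumerate candidate invasive-native interactions
#'
#' Every co-occurrence of an included (non-excluded) invasive mammal
#' population and a breeding highly threatened vertebrate on the same
#' island is a candidate interaction. Candidates backed by an explicit
#' interaction record carry its impact class; the rest are `unknown` and
#' are later resolved by [impute_impacts()]. Suspected presence of an
#' invasive contributes identically to confirmed presence.
#'
#' @param dataset A validated `erad_dataset`.
#' @return A tibble with one row per candidate: `island_id`, `species_id`,
#'   `invasive_id`, `impact_class` (confirmed/suspected/none/unknown) and
#'   `has_record` (whether an explicit record supplied the class).
#' @export
enumerate_interactions <- function(dataset) {
  pops <- included_populations(dataset) |>
    dplyr::distinct(.data$island_id, .data$invasive_id)
  cand <- dataset$breeding |>
    dplyr::distinct(.data$island_id, .data$species_id) |>
    dplyr::inner_join(pops, by = "island_id",
                      relationship = "many-to-many")
  rec <- dataset$interactions |>
    dplyr::distinct(.data$island_id, .data$species_id, .data$invasive_id,
                    .keep_all = TRUE) |>
    dplyr::select("island_id", "species_id", "invasive_id",
                  record_class = "impact_class")
  cand |>
    dplyr::left_join(rec, by = c("island_id", "species_id", "invasive_id")) |>
    dplyr::mutate(
      has_record = !is.na(.data$record_class) &
        .data$record_class != "unknown",
      impact_class = dplyr::if_else(.data$has_record, .data$record_class,
                                    "unknown")
    ) |>
    dplyr::select("island_id", "species_id", "invasive_id", "impact_class",
                  "has_record")
}

# maximum explicit impact score per (invasive species, native family),
# pooled over all islands: the family-level imputation table
.family_impact_table <- function(dataset) {
  rec <- dplyr::filter(dataset$interactions, .data$impact_class != "unknown")
  if (nrow(rec) == 0) {
    return(tibble::tibble(invasive_id = character(), family = character(),
                          family_score = integer()))
  }
  rec |>
    dplyr::left_join(dplyr::select(dataset$species, "species_id", "family"),
                     by = "species_id") |>
    dplyr::mutate(score = .impact_scores[.data$impact_class]) |>
    dplyr::group_by(.data$invasive_id, .data$family) |>
    dplyr::summarise(family_score = max(.data$score), .groups = "drop")
}

#' Resolve unknown impacts by taxonomic family
#'
#' A candidate with no explicit impact record receives the maximum impact
#' score recorded anywhere in the dataset for the same invasive mammal
#' against any highly threatened vertebrate in the same taxonomic family.
#' If no family evidence exists the impact is scored 0 with provenance
#' `assumed_zero`. Explicit records — including explicit "none" — are never
#' overridden. The operation is idempotent.
#'
#' @param candidates Output of [enumerate_interactions()].
#' @param dataset The same `erad_dataset`.
#' @return The candidates with integer `score` in 0..2 and `provenance`
#'   (direct/imputed/assumed_zero) columns.
#' @export
impute_impacts <- function(candidates, dataset) {
  fam_tab <- .family_impact_table(dataset)
  candidates |>
    dplyr::left_join(dplyr::select(dataset$species, "species_id", "family"),
                     by = "species_id") |>
    dplyr::left_join(fam_tab, by = c("invasive_id", "family")) |>
    dplyr::mutate(
      score = dplyr::case_when(
        .data$has_record ~ unname(.impact_scores[.data$impact_class]),
        !is.na(.data$family_score) ~ as.integer(.data$family_score),
        TRUE ~ 0L
      ),
      provenance = dplyr::case_when(
        .data$has_record ~ "direct",
        !is.na(.data$family_score) ~ "imputed",
        TRUE ~ "assumed_zero"
      )
    ) |>
    dplyr::select("island_id", "species_id", "invasive_id", "impact_class",
                  "has_record", "score", "provenance")
}

#' Per-(species, island) maximum impact severity Z
#'
#' For each breeding highly threatened vertebrate on each island carrying
#' at least one contributing invasive population, Z is the maximum impact
#' score over those populations. With all included populations contributing
#' this is the severity used for Current Conservation Risk; restricted to
#' populations not feasible to eradicate it yields the Potential
#' Conservation Risk severity. Pairs absent from the matrix are treated as
#' Z = 0 downstream.
#'
#' @param dataset A validated `erad_dataset`.
#' @param invasive_filter `NULL` for all included populations, or a data
#'   frame with columns `invasive_id` and `island_id` naming the
#'   populations that contribute.
#' @param completed Optionally, precomputed output of [impute_impacts()]
#'   to avoid recomputation across calls.
#' @return A tibble `species_id`, `island_id`, `z` (0, 1 or 2) and
#'   `provenance`; provenance is that of a population attaining the
#'   maximum, preferring direct over imputed over assumed_zero on ties.
#' @export
severity_matrix <- function(dataset, invasive_filter = NULL,
                            completed = NULL) {
  if (is.null(completed)) {
    completed <- impute_impacts(enumerate_interactions(dataset), dataset)
  }
  if (!is.null(invasive_filter)) {
    completed <- dplyr::semi_join(
      completed,
      dplyr::distinct(invasive_filter[, c("invasive_id", "island_id")]),
      by = c("invasive_id", "island_id")
    )
  }
  prov_rank <- c(direct = 1L, imputed = 2L, assumed_zero = 3L)
  completed |>
    dplyr::mutate(.prov_rank = prov_rank[.data$provenance]) |>
    dplyr::group_by(.data$species_id, .data$island_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.prov_rank,
                   .by_group = TRUE) |>
    dplyr::summarise(z = .data$score[1L], provenance = .data$provenance[1L],
                     .groups = "drop")
}
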