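# Per-island risk scores: extinction risk (E), irreplaceability (I),
# Current and Potential Conservation Risk, Eradication Benefit, ranking.
#
# CCR_i = sum over breeding highly threatened species s on island i of
#         E_s * I_s * Z_{s,i}
# where Z is the maximum impact severity over contributing invasive
# populations. PCR is the same sum with only populations that are NOT
# technically feasible to eradicate contributing; EB = CCR - PCR.

#' Extinction-risk scoring scheme
#'
#' The default scheme weights Critically Endangered species 0.5 and
#' Endangered species 0.05, reflecting the relative extinction risk implied
#' by the quantitative IUCN Red List criteria thresholds. The alternative
#' linear scheme scores 4 and 3 and is retained for sensitivity comparison.
#' Custom weights are allowed via `cr_score`/`en_score`.
#'
#' @param scheme_name `"default"`, `"linear"`, or `"custom"`.
#' @param cr_score,en_score Override weights (required for `"custom"`).
#' @return A list with `scheme_name`, `cr_score`, `en_score`.
#' @export
risk_scheme <- function(scheme_name = c("default", "linear", "custom"),
                        cr_score = NULL, en_score = NULL) {
  scheme_name <- match.arg(scheme_name)
  defaults <- switch(scheme_name,
    default = c(cr = 0.5, en = 0.05),
    linear = c(cr = 4, en = 3),
    custom = c(cr = NA_real_, en = NA_real_)
  )
  cr <- if (is.null(cr_score)) defaults[["cr"]] else as.numeric(cr_score)
  en <- if (is.null(en_score)) defaults[["en"]] else as.numeric(en_score)
  if (is.na(cr) || is.na(en)) {
    rlang::abort("custom scheme requires cr_score and en_score",
                 class = "erad_config_error")
  }
  list(scheme_name = scheme_name, cr_score = cr, en_score = en)
}

#' Extinction risk E for an IUCN category
#'
#' @param iucn_category `"CR"` or `"EN"` (case-insensitive).
#' @param scheme A [risk_scheme()].
#' @return Numeric E score(s).
#' @export
extinction_risk <- function(iucn_category, scheme = risk_scheme()) {
  cat <- .norm_token(iucn_category)
  bad <- setdiff(unique(cat), c("cr", "en"))
  if (length(bad) > 0) {
    rlang::abort(paste0("only CR and EN species are in scope, got: ",
                        paste(bad, collapse = ", ")),
                 class = "erad_value_error")
  }
  ifelse(cat == "cr", scheme$cr_score, scheme$en_score)
}

#' Irreplaceability I per species
#'
#' The reciprocal of the number of distinct islands a species breeds on,
#' regardless of island area; a single-island endemic has I = 1.
#' Continental populations of insular-and-continental species are never
#' counted. I is computed from the dataset's own breeding table, so a
#' subsetted dataset remains self-consistent — note that this differs from
#' using a global all-islands count when the dataset is a subset of a
#' larger compilation.
#'
#' @param breeding The breeding table of an `erad_dataset` (or a whole
#'   dataset, from which it is taken).
#' @param species_id Optionally restrict to these species; species with no
#'   breeding record are out of scope and raise an error.
#' @return A tibble `species_id`, `n_islands`, `irreplaceability`.
#' @export
irreplaceability <- function(breeding, species_id = NULL) {
  if (inherits(breeding, "erad_dataset")) breeding <- breeding$breeding
  tab <- breeding |>
    dplyr::distinct(.data$species_id, .data$island_id) |>
    dplyr::count(.data$species_id, name = "n_islands") |>
    dplyr::mutate(irreplaceability = 1 / .data$n_islands)
  if (!is.null(species_id)) {
    missing <- setdiff(species_id, tab$species_id)
    if (length(missing) > 0) {
      rlang::abort(paste0("species with no breeding island are out of ",
                          "scope: ", paste(missing, collapse = ", ")),
                   class = "erad_value_error")
    }
    tab <- tab[match(species_id, tab$species_id), ]
  }
  tab
}

# shared kernel: sum E*I*z over a severity matrix, for every island
.sum_risk <- function(dataset, severity, scheme, value_name) {
  ei <- dataset$species |>
    dplyr::inner_join(irreplaceability(dataset$breeding), by = "species_id") |>
    dplyr::mutate(e = extinction_risk(.data$iucn_category, scheme)) |>
    dplyr::select("species_id", "e", "irreplaceability")
  per_island <- severity |>
    dplyr::inner_join(ei, by = "species_id") |>
    dplyr::group_by(.data$island_id) |>
    dplyr::summarise(
      value = sum(.data$e * .data$irreplaceability * .data$z),
      .groups = "drop"
    )
  out <- dataset$islands |>
    dplyr::select("island_id") |>
    dplyr::left_join(per_island, by = "island_id") |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0))
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Current Conservation Risk per island
#'
#' @param dataset A validated `erad_dataset`.
#' @param scheme A [risk_scheme()].
#' @param completed Optional precomputed [impute_impacts()] output.
#' @return A tibble `island_id`, `ccr` covering every island in the
#'   dataset; islands without impacted breeding species score 0.
#' @export
compute_ccr <- function(dataset, scheme = risk_scheme(), completed = NULL) {
  sev <- severity_matrix(dataset, completed = completed)
  .sum_risk(dataset, sev, scheme, "ccr")
}

#' Potential Conservation Risk per island
#'
#' CCR recomputed with the impact of every technically feasible invasive
#' population set to zero: only populations flagged infeasible contribute
#' to the severity maximum. All feasible populations on an island are
#' treated as removed concurrently.
#'
#' @param dataset A validated `erad_dataset`.
#' @param scheme A [risk_scheme()].
#' @param feasibility_flags Output of [feasibility_flags()]: one row per
#'   included population with a logical `feasible`.
#' @param completed Optional precomputed [impute_impacts()] output.
#' @return A tibble `island_id`, `pcr`.
#' @export
compute_pcr <- function(dataset, scheme = risk_scheme(), feasibility_flags,
                        completed = NULL) {
  infeasible <- dplyr::filter(feasibility_flags, !.data$feasible)
  sev <- severity_matrix(dataset, invasive_filter = infeasible,
                         completed = completed)
  .sum_risk(dataset, sev, scheme, "pcr")
}

#' Eradication Benefit per island
#'
#' @param ccr,pcr Tibbles from [compute_ccr()] and [compute_pcr()] over the
#'   same island set.
#' @return A tibble `island_id`, `ccr`, `pcr`, `eb` with `eb = ccr - pcr`;
#'   differences below 1e-12 are snapped to exactly zero to absorb
#'   floating-point noise.
#' @export
eradication_benefit <- function(ccr, pcr) {
  if (!setequal(ccr$island_id, pcr$island_id) ||
      nrow(ccr) != nrow(pcr)) {
    rlang::abort("CCR and PCR island sets do not match",
                 class = "erad_key_error")
  }
  dplyr::inner_join(ccr, pcr, by = "island_id") |>
    dplyr::mutate(eb = .data$ccr - .data$pcr,
                  eb = ifelse(abs(.data$eb) < 1e-12, 0, .data$eb))
}

#' Rank islands by Eradication Benefit
#'
#' Descending EB is the primary ranking. Ties are broken deterministically
#' by higher CCR, then by the larger number of species whose maximum
#' severity is reduced by feasible eradications (`n_reduced`, if present),
#' then by island_id lexicographically. Islands with EB = 0 receive no rank
#' (`NA`) and are excluded from the ranked list but retained in the output.
#'
#' @param scores A tibble with `island_id`, `ccr`, `pcr`, `eb` and
#'   optionally `n_reduced`.
#' @return The scores with an integer `rank` column, ordered ranked islands
#'   first.
#' @export
rank_islands <- function(scores) {
  if (!"n_reduced" %in% names(scores)) scores$n_reduced <- 0L
  scores <- scores |>
    dplyr::arrange(dplyr::desc(.data$eb), dplyr::desc(.data$ccr),
                   dplyr::desc(.data$n_reduced), .data$island_id)
  ranked <- scores$eb > 0
  scores$rank <- NA_integer_
  scores$rank[ranked] <- seq_len(sum(ranked))
  scores
}

#' Score and rank every island in a dataset
#'
#' End-to-end scoring: severity matrices under the full and
#' infeasible-only population sets, CCR, PCR, EB and ranking.
#'
#' @param dataset A validated `erad_dataset`.
#' @param scheme A [risk_scheme()].
#' @param feasibility_flags Optional precomputed [feasibility_flags()];
#'   computed from the dataset's rules table when `NULL`.
#' @return A ranked tibble `island_id`, `ccr`, `pcr`, `eb`, `n_reduced`,
#'   `rank`.
#' @export
score_islands <- function(dataset, scheme = risk_scheme(),
                          feasibility_flags = NULL) {
  if (is.null(feasibility_flags)) {
    feasibility_flags <- feasibility_flags(dataset)
  }
  completed <- impute_impacts(enumerate_interactions(dataset), dataset)
  ccr <- compute_ccr(dataset, scheme, completed = completed)
  pcr <- compute_pcr(dataset, scheme, feasibility_flags,
                     completed = completed)
  scores <- eradication_benefit(ccr, pcr)
  reduced <- benefit_records(dataset, feasibility_flags,
                             completed = completed) |>
    dplyr::count(.data$island_id, name = "n_reduced")
  scores |>
    dplyr::left_join(reduced, by = "island_id") |>
    dplyr::mutate(n_reduced = dplyr::coalesce(.data$n_reduced, 0L)) |>
    rank_islands()
}
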