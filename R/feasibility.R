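# Technical eradication feasibility (area / human-population thresholds
# per invasive group) and socio-political timeframe aggregation.

# later timeframes are more conservative; unknown is not an informative vote
.timeframe_order <- c(by2020 = 1L, by2030 = 2L, never = 3L)

#' Technical feasibility of eradicating a population from an island
#'
#' A population is technically feasible to eradicate iff its island's area
#' and human population both fall at or below the thresholds configured for
#' its invasive group. Thresholds come from eradication precedent and are a
#' required configuration input; a population whose group has no rule is a
#' configuration error, never silently defaulted.
#'
#' @param populations Data frame with `invasive_group` and `island_id`.
#' @param islands Data frame with `island_id`, `area_ha`,
#'   `human_population`.
#' @param rules Feasibility rules table: `invasive_group`, `max_area_ha`,
#'   `max_human_population` (`Inf` = unbounded).
#' @return Logical vector, one element per population row.
#' @export
technically_feasible <- function(populations, islands, rules) {
  missing <- setdiff(unique(populations$invasive_group),
                     rules$invasive_group)
  if (length(missing) > 0) {
    rlang::abort(paste0("no feasibility rule for invasive group(s): ",
                        paste(missing, collapse = ", ")),
                 class = "erad_config_error")
  }
  ri <- match(populations$invasive_group, rules$invasive_group)
  ii <- match(populations$island_id, islands$island_id)
  islands$area_ha[ii] <= rules$max_area_ha[ri] &
    islands$human_population[ii] <= rules$max_human_population[ri]
}

#' Feasibility flags for every included population in a dataset
#'
#' @param dataset A validated `erad_dataset`.
#' @param rules Optional rules table; defaults to the dataset's own.
#' @return A tibble with one row per included (non-excluded) invasive
#'   population: `invasive_id`, `invasive_group`, `island_id`, `feasible`.
#' @export
feasibility_flags <- function(dataset, rules = NULL) {
  if (is.null(rules)) rules <- dataset$feasibility_rules
  pops <- included_populations(dataset)
  pops |>
    dplyr::mutate(feasible = technically_feasible(pops, dataset$islands,
                                                  rules)) |>
    dplyr::select("invasive_id", "invasive_group", "island_id", "feasible")
}

#' Aggregate expert timeframe votes for one island
#'
#' Experts assess when an eradication project could feasibly be initiated:
#' by 2020, by 2030, or not in the foreseeable future. With no usable
#' (non-unknown) vote the decision is `unknown` with basis `no_response`.
#' A single informative vote stands (`single_expert`); unanimous
#' informative votes give `consensus`; otherwise the most conservative
#' (latest) informative timeframe is taken (`most_conservative`).
#' Unknown votes are ignored whenever at least one informative vote
#' exists. Order-invariant and idempotent.
#'
#' @param timeframes Character vector of votes
#'   (by2020/by2030/never/unknown), possibly empty.
#' @return A list with `timeframe` and `basis`.
#' @export
aggregate_timeframes <- function(timeframes) {
  votes <- .norm_token(timeframes)
  bad <- setdiff(votes, c(names(.timeframe_order), "unknown"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown timeframe token(s): ",
                        paste(bad, collapse = ", ")),
                 class = "erad_value_error")
  }
  informative <- votes[votes != "unknown"]
  if (length(informative) == 0) {
    return(list(timeframe = "unknown", basis = "no_response"))
  }
  if (length(informative) == 1) {
    return(list(timeframe = informative, basis = "single_expert"))
  }
  if (length(unique(informative)) == 1) {
    return(list(timeframe = informative[1], basis = "consensus"))
  }
  latest <- names(.timeframe_order)[max(.timeframe_order[informative])]
  list(timeframe = latest, basis = "most_conservative")
}

#' Timeframe decisions and filtered island sets
#'
#' Socio-political feasibility is assessed only where eradication would
#' help: islands with EB > 0. Each such island gets one aggregated
#' decision; islands whose decision is unknown (no response, or only
#' unknown votes) are excluded from headline results but listed as a
#' priority data gap. The four sets partition the EB > 0 islands exactly.
#'
#' @param dataset A validated `erad_dataset`.
#' @param scores Ranked scores from [score_islands()] (needs `island_id`
#'   and `eb`).
#' @return A list: `decisions` (tibble `island_id`, `timeframe`, `basis`,
#'   `n_votes`), `sets` (named list of island-id vectors for by2020,
#'   by2030, never, unknown) and `data_gap` (= the unknown set).
#' @export
assign_timeframes <- function(dataset, scores) {
  eligible <- scores$island_id[scores$eb > 0]
  votes <- dataset$expert_assessments |>
    dplyr::filter(.data$island_id %in% eligible)
  decisions <- purrr::map(eligible, function(i) {
    agg <- aggregate_timeframes(votes$timeframe[votes$island_id == i])
    tibble::tibble(island_id = i, timeframe = agg$timeframe,
                   basis = agg$basis,
                   n_votes = sum(votes$island_id == i))
  }) |>
    purrr::list_rbind()
  if (nrow(decisions) == 0) {
    decisions <- tibble::tibble(island_id = character(),
                                timeframe = character(),
                                basis = character(), n_votes = integer())
  }
  sets <- lapply(c(by2020 = "by2020", by2030 = "by2030", never = "never",
                   unknown = "unknown"), function(tf) {
    decisions$island_id[decisions$timeframe == tf]
  })
  list(decisions = decisions, sets = sets, data_gap = sets$unknown)
}

#' Illustrative default feasibility rules
#'
#' Thresholds on island area and human population per invasive group,
#' shaped like the precedent-based tables used in global eradication
#' feasibility screening. These defaults are ILLUSTRATIVE ONLY — they are
#' not derived from any eradication database and any real analysis must
#' supply its own rules table. `Inf` marks an unbounded threshold.
#'
#' @return A tibble `invasive_group`, `max_area_ha`,
#'   `max_human_population`.
#' @export
default_feasibility_rules <- function() {
  tibble::tibble(
    invasive_group = c("rodent", "cat", "dog", "ungulate", "mongoose",
                       "rabbit", "other"),
    max_area_ha = c(13000, 6500, 30000, 60000, 1000, 30000, 10000),
    max_human_population = c(100, 1000, 3000, 3000, 0, 1000, 100)
  )
}
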