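# Core data model: domain tables, readers/writers, validation.
#
# A dataset is a named list of seven tibbles (islands, species, breeding,
# invasive_populations, interactions, feasibility_rules, expert_assessments)
# with class "erad_dataset". Enum tokens are stored as lower-case canonical
# strings; readers accept any case and normalize.

# canonical enum vocabularies, one entry per constrained column
.erad_enums <- list(
  taxon_class     = c("amphibian", "reptile", "bird", "mammal"),
  iucn_category   = c("cr", "en"),
  insularity      = c("insular", "insular_and_continental"),
  breeding_status = c("confirmed", "probable", "potential"),
  presence        = c("confirmed", "suspected"),
  feral_status    = c("feral", "domestic", "unknown"),
  impact_class    = c("confirmed", "suspected", "none", "unknown"),
  timeframe       = c("by2020", "by2030", "never", "unknown")
)

# severity scores for explicit impact classes; "unknown" has no score and is
# resolved by family-level imputation
.impact_scores <- c(confirmed = 2L, suspected = 1L, none = 0L)

.erad_schema <- list(
  islands = c("island_id", "name", "country", "area_ha", "human_population",
              "sensitive"),
  species = c("species_id", "name", "taxon_class", "seabird_flag", "family",
              "iucn_category", "insularity"),
  breeding = c("species_id", "island_id", "breeding_status"),
  invasive_populations = c("invasive_id", "invasive_group", "island_id",
                           "presence", "feral_status", "rodent_status_unknown",
                           "under_eradication"),
  interactions = c("invasive_id", "species_id", "island_id", "impact_class"),
  feasibility_rules = c("invasive_group", "max_area_ha",
                        "max_human_population"),
  expert_assessments = c("island_id", "expert_id", "timeframe",
                         "years_experience")
)

.norm_token <- function(x) tolower(trimws(as.character(x)))

.check_enum <- function(x, column, table) {
  x <- .norm_token(x)
  allowed <- .erad_enums[[column]]
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("invalid %s value(s) in table '%s': %s (allowed: %s)",
              column, table, paste(bad, collapse = ", "),
              paste(allowed, collapse = ", ")),
      class = "erad_value_error"
    )
  }
  x
}

.as_flag <- function(x, column, table) {
  if (is.logical(x)) return(x)
  tok <- .norm_token(x)
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1", "yes")] <- TRUE
  out[tok %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out[!is.na(tok)])) {
    rlang::abort(sprintf("column '%s' in table '%s' is not boolean",
                         column, table),
                 class = "erad_value_error")
  }
  as.logical(out)
}

# "inf" sentinel encodes an unbounded feasibility threshold
.as_bound <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  tok <- .norm_token(x)
  out <- suppressWarnings(as.numeric(tok))
  out[tok %in% c("inf", "infinite", "unbounded")] <- Inf
  out
}

#' Assemble a validated dataset from its seven component tables
#'
#' Normalizes enum tokens to lower case, coerces column types, and flags
#' invasive populations that are excluded from scoring. Two kinds of
#' population are excluded: entirely domestic/farmed animals, and rodent
#' populations whose presence status is unknown (these are re-included by
#' [rodent_scenario()]). Excluded populations are retained with an
#' `excluded` flag and `exclusion_reason`, never dropped, so scenario
#' re-runs and audits see the full record.
#'
#' @param islands,species,breeding,invasive_populations,interactions,feasibility_rules,expert_assessments
#'   Data frames with the columns documented in [read_dataset()].
#' @return An object of class `erad_dataset`: a named list of seven tibbles.
#' @export
erad_dataset <- function(islands, species, breeding, invasive_populations,
                         interactions, feasibility_rules,
                         expert_assessments) {
  tables <- list(islands = islands, species = species, breeding = breeding,
                 invasive_populations = invasive_populations,
                 interactions = interactions,
                 feasibility_rules = feasibility_rules,
                 expert_assessments = expert_assessments)
  for (nm in names(.erad_schema)) {
    missing <- setdiff(.erad_schema[[nm]], names(tables[[nm]]))
    if (length(missing) > 0) {
      rlang::abort(sprintf("table '%s' is missing required column(s): %s",
                           nm, paste(missing, collapse = ", ")),
                   class = "erad_schema_error")
    }
  }

  islands <- tibble::as_tibble(islands) |>
    dplyr::mutate(
      island_id = as.character(.data$island_id),
      name = as.character(.data$name),
      country = as.character(.data$country),
      area_ha = as.numeric(.data$area_ha),
      human_population = as.integer(.data$human_population),
      sensitive = .as_flag(.data$sensitive, "sensitive", "islands")
    )
  species <- tibble::as_tibble(species) |>
    dplyr::mutate(
      species_id = as.character(.data$species_id),
      name = as.character(.data$name),
      taxon_class = .check_enum(.data$taxon_class, "taxon_class", "species"),
      seabird_flag = .as_flag(.data$seabird_flag, "seabird_flag", "species"),
      family = as.character(.data$family),
      iucn_category = .check_enum(.data$iucn_category, "iucn_category",
                                  "species"),
      insularity = .check_enum(.data$insularity, "insularity", "species")
    )
  breeding <- tibble::as_tibble(breeding) |>
    dplyr::mutate(
      species_id = as.character(.data$species_id),
      island_id = as.character(.data$island_id),
      breeding_status = .check_enum(.data$breeding_status, "breeding_status",
                                    "breeding")
    )
  invasive_populations <- tibble::as_tibble(invasive_populations) |>
    dplyr::mutate(
      invasive_id = as.character(.data$invasive_id),
      invasive_group = .norm_token(.data$invasive_group),
      island_id = as.character(.data$island_id),
      presence = .check_enum(.data$presence, "presence",
                             "invasive_populations"),
      feral_status = .check_enum(.data$feral_status, "feral_status",
                                 "invasive_populations"),
      rodent_status_unknown = .as_flag(.data$rodent_status_unknown,
                                       "rodent_status_unknown",
                                       "invasive_populations"),
      under_eradication = .as_flag(.data$under_eradication,
                                   "under_eradication",
                                   "invasive_populations")
    )
  # exclusion audit: domestic populations never score; unknown-status rodents
  # score only under the rodent scenario. feral_status "unknown" is treated
  # as feral (conservative inclusion).
  invasive_populations <- invasive_populations |>
    dplyr::mutate(
      excluded = .data$feral_status == "domestic" |
        .data$rodent_status_unknown,
      exclusion_reason = dplyr::case_when(
        .data$feral_status == "domestic" ~ "domestic",
        .data$rodent_status_unknown ~ "rodent_status_unknown",
        TRUE ~ NA_character_
      )
    )
  interactions <- tibble::as_tibble(interactions) |>
    dplyr::mutate(
      invasive_id = as.character(.data$invasive_id),
      species_id = as.character(.data$species_id),
      island_id = as.character(.data$island_id),
      impact_class = .check_enum(.data$impact_class, "impact_class",
                                 "interactions")
    )
  feasibility_rules <- tibble::as_tibble(feasibility_rules) |>
    dplyr::mutate(
      invasive_group = .norm_token(.data$invasive_group),
      max_area_ha = .as_bound(.data$max_area_ha),
      max_human_population = .as_bound(.data$max_human_population)
    )
  expert_assessments <- tibble::as_tibble(expert_assessments) |>
    dplyr::mutate(
      island_id = as.character(.data$island_id),
      expert_id = as.character(.data$expert_id),
      timeframe = .check_enum(.data$timeframe, "timeframe",
                              "expert_assessments"),
      years_experience = as.integer(.data$years_experience)
    )

  structure(
    list(islands = islands, species = species, breeding = breeding,
         invasive_populations = invasive_populations,
         interactions = interactions,
         feasibility_rules = feasibility_rules,
         expert_assessments = expert_assessments),
    class = "erad_dataset"
  )
}

#' @export
print.erad_dataset <- function(x, ...) {
  cat("<erad_dataset>\n")
  for (nm in names(.erad_schema)) {
    cat(sprintf("  %-22s %5d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Check every dataset invariant and report violations
#'
#' Produces a report rather than raising errors, so partially dirty field
#' data can be triaged. An empty report means the dataset satisfies every
#' structural invariant: unique keys, non-negative areas and populations,
#' resolvable foreign keys, one feasibility rule per invasive group, and
#' non-empty taxonomic families.
#'
#' @param dataset An `erad_dataset`.
#' @return A tibble with columns `table`, `rule` and `detail`, one row per
#'   violation; zero rows iff the dataset is clean.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "erad_dataset"))
  v <- list()
  flag <- function(table, rule, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(table = table, rule = rule,
                                          detail = detail)
  }

  isl <- dataset$islands
  dup <- isl$island_id[duplicated(isl$island_id)]
  for (d in unique(dup)) flag("islands", "unique_island_id", d)
  for (d in isl$island_id[!is.na(isl$area_ha) & isl$area_ha < 0]) {
    flag("islands", "area_ha_nonnegative", d)
  }
  for (d in isl$island_id[!is.na(isl$human_population) &
                            isl$human_population < 0]) {
    flag("islands", "human_population_nonnegative", d)
  }

  sp <- dataset$species
  dup <- sp$species_id[duplicated(sp$species_id)]
  for (d in unique(dup)) flag("species", "unique_species_id", d)
  for (d in sp$species_id[is.na(sp$family) | sp$family == ""]) {
    flag("species", "family_nonempty", d)
  }

  br <- dataset$breeding
  key <- paste(br$species_id, br$island_id, sep = "\r")
  for (d in unique(key[duplicated(key)])) {
    flag("breeding", "unique_species_island_pair", gsub("\r", " / ", d))
  }

  check_fk <- function(table, column, universe) {
    bad <- setdiff(dataset[[table]][[column]], universe)
    for (d in unique(bad)) {
      flag(table, paste0("foreign_key_", column), d)
    }
  }
  check_fk("breeding", "island_id", isl$island_id)
  check_fk("breeding", "species_id", sp$species_id)
  check_fk("invasive_populations", "island_id", isl$island_id)
  check_fk("interactions", "island_id", isl$island_id)
  check_fk("interactions", "species_id", sp$species_id)
  check_fk("interactions", "invasive_id",
           dataset$invasive_populations$invasive_id)
  check_fk("expert_assessments", "island_id", isl$island_id)

  fr <- dataset$feasibility_rules
  dup <- fr$invasive_group[duplicated(fr$invasive_group)]
  for (d in unique(dup)) flag("feasibility_rules", "one_rule_per_group", d)
  for (d in fr$invasive_group[!is.na(fr$max_area_ha) & fr$max_area_ha <= 0]) {
    flag("feasibility_rules", "max_area_ha_positive", d)
  }
  for (d in fr$invasive_group[!is.na(fr$max_human_population) &
                                fr$max_human_population < 0]) {
    flag("feasibility_rules", "max_human_population_nonnegative", d)
  }

  ea <- dataset$expert_assessments
  for (d in ea$island_id[!is.na(ea$years_experience) &
                           ea$years_experience < 0]) {
    flag("expert_assessments", "years_experience_nonnegative", d)
  }

  if (length(v) == 0) {
    return(tibble::tibble(table = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Read a dataset from a directory of delimited tables
#'
#' Expects seven comma-separated UTF-8 files with header rows:
#' `islands.csv`, `species.csv`, `breeding.csv`, `invasive_populations.csv`,
#' `interactions.csv`, `feasibility_rules.csv`, `expert_assessments.csv`
#' (alternatively a named list of file paths keyed by table name). Unknown
#' enum tokens, missing columns and unresolvable foreign keys are errors;
#' other invariant violations also abort with the validation report
#' attached, so the returned dataset is always fully validated.
#'
#' @param path Directory containing the seven tables, or a named list/vector
#'   of paths with the table names above.
#' @return A validated `erad_dataset`.
#' @export
read_dataset <- function(path) {
  if (length(path) == 1 && is.character(path) && is.null(names(path))) {
    if (!dir.exists(path)) {
      rlang::abort(paste0("input directory not found: ", path),
                   class = "erad_io_error")
    }
    files <- stats::setNames(
      file.path(path, paste0(names(.erad_schema), ".csv")),
      names(.erad_schema)
    )
  } else {
    files <- unlist(path)
  }
  missing <- setdiff(names(.erad_schema), names(files))
  if (length(missing) > 0) {
    rlang::abort(paste0("no path given for table(s): ",
                        paste(missing, collapse = ", ")),
                 class = "erad_io_error")
  }
  tabs <- lapply(names(.erad_schema), function(nm) {
    f <- files[[nm]]
    if (!file.exists(f)) {
      rlang::abort(paste0("input file not found: ", f),
                   class = "erad_io_error")
    }
    tab <- readr::read_csv(f, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    missing_cols <- setdiff(.erad_schema[[nm]], names(tab))
    if (length(missing_cols) > 0) {
      rlang::abort(sprintf("table '%s' (%s) is missing column(s): %s",
                           nm, f, paste(missing_cols, collapse = ", ")),
                   class = "erad_schema_error")
    }
    tab
  })
  names(tabs) <- names(.erad_schema)
  dataset <- do.call(erad_dataset, tabs)

  report <- validate_dataset(dataset)
  if (nrow(report) > 0) {
    cls <- if (any(grepl("^foreign_key_", report$rule))) {
      "erad_referential_error"
    } else {
      "erad_value_error"
    }
    rlang::abort(
      paste0("dataset failed validation:\n",
             paste(sprintf("  %s: %s (%s)", report$table, report$rule,
                           report$detail),
                   collapse = "\n")),
      class = cls, report = report
    )
  }
  dataset
}

#' Write a dataset to a directory of delimited tables
#'
#' Inverse of [read_dataset()]; unbounded feasibility thresholds are written
#' with the sentinel token `inf`. Audit columns added at construction time
#' (`excluded`, `exclusion_reason`) are not written.
#'
#' @param dataset An `erad_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "erad_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(.erad_schema)) {
    tab <- dataset[[nm]][, .erad_schema[[nm]]]
    if (nm == "feasibility_rules") {
      tab <- tab |>
        dplyr::mutate(
          max_area_ha = ifelse(is.infinite(.data$max_area_ha), "inf",
                               as.character(.data$max_area_ha)),
          max_human_population = ifelse(
            is.infinite(.data$max_human_population), "inf",
            as.character(.data$max_human_population))
        )
    }
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, f, progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write scores and summaries as delimited files
#'
#' Emits `island_scores.csv` (stable column order: island_id, name, country,
#' ccr, pcr, eb, rank, plus any further columns supplied) and one
#' `summary_<label>.csv` per benefit summary. Sensitive-island masking, if
#' wanted, must be applied by the caller before writing (see
#' [mask_sensitive()]).
#'
#' @param scores Data frame of per-island scores (as from [score_islands()]).
#' @param summaries List of benefit summaries (as from
#'   [summarize_benefits()]), possibly empty.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(scores, summaries = list(), dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      rlang::abort(paste0("cannot create output directory: ", dir),
                   class = "erad_io_error")
    }
  }
  lead <- intersect(c("island_id", "name", "country", "ccr", "pcr", "eb",
                      "rank"), names(scores))
  scores <- scores[, c(lead, setdiff(names(scores), lead))]
  files <- file.path(dir, "island_scores.csv")
  readr::write_csv(scores, files, progress = FALSE)
  for (s in summaries) {
    f <- file.path(dir, paste0("summary_", s$label, ".csv"))
    readr::write_csv(.summary_row(s), f, progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a scores table written by [write_results()]
#'
#' @param dir Directory containing `island_scores.csv`.
#' @return A tibble of per-island scores.
#' @export
read_results <- function(dir) {
  f <- file.path(dir, "island_scores.csv")
  if (!file.exists(f)) {
    rlang::abort(paste0("no island_scores.csv under ", dir),
                 class = "erad_io_error")
  }
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}

# invasive populations that contribute to scoring
included_populations <- function(dataset) {
  dplyr::filter(dataset$invasive_populations, !.data$excluded)
}
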