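# Episode-level summary tables and end-to-end pipeline orchestration.

#' Episode cost summary by clinical grouping
#'
#' Per-grouping episode counts and cost statistics: mean, sample SD, median
#' and quartiles (linear interpolation), total cost and share of all episode
#' costs. Rows are ordered by descending total cost; groupings with no
#' episodes close the table with `n = 0` and blank statistics.
#'
#' @param episodes a classified, costed episode table (`grouping`,
#'   `total_cost` columns).
#' @return a `data.table` with `grouping, label, n, percent, mean_cost,
#'   sd_cost, median_cost, q1_cost, q3_cost, total_cost, pct_total`.
#' @export
grouping_summary <- function(episodes) {
  eps <- data.table::as.data.table(episodes)
  .assert(all(c("grouping", "total_cost") %in% names(eps)),
          "episodes must be classified and costed first")
  stats_by <- eps[, .(
    n = .N,
    mean_cost = mean(total_cost),
    sd_cost = sd(total_cost),
    median_cost = quantile_value(total_cost, 0.5, "linear_interpolation"),
    q1_cost = quantile_value(total_cost, 0.25, "linear_interpolation"),
    q3_cost = quantile_value(total_cost, 0.75, "linear_interpolation"),
    total_cost = sum(total_cost)
  ), by = grouping]
  out <- data.table::data.table(grouping = .GROUPINGS)
  out <- merge(out, stats_by, by = "grouping", all.x = TRUE)
  out[is.na(n), `:=`(n = 0L, total_cost = 0)]
  n_all <- sum(out$n)
  total_all <- sum(out$total_cost)
  out[, percent := if (n_all > 0) share_percent(n, n_all) else NA_real_]
  out[, pct_total := if (total_all > 0) share_percent(total_cost, total_all) else NA_real_]
  out[, label := grouping_label(grouping)]
  data.table::setorder(out, -total_cost, grouping)
  data.table::setcolorder(out, c("grouping", "label", "n", "percent", "mean_cost",
                                 "sd_cost", "median_cost", "q1_cost", "q3_cost",
                                 "total_cost", "pct_total"))
  out[]
}

#' Health-service use within episodes, by sector
#'
#' For each sector: the number of episodes containing at least one event of
#' that sector, the total number of in-episode events, the mean and SD of
#' events per using episode, and the total cost attributed within episodes.
#'
#' @param built a costed `pce_built` object.
#' @return a `data.table` with `sector, n_episodes_with_any, total_events,
#'   mean_events, sd_events, total_cost` (one row per sector, vocabulary
#'   order; zero rows where a sector is unused).
#' @export
sector_use_summary <- function(built) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  .assert("allocated_cents" %in% names(built$membership),
          "membership has no cost columns; run episode_costs() first")
  mem <- built$membership[!is.na(episode_key)]
  per_ep <- mem[, .(events = .N, cents = sum(allocated_cents)), by = .(sector, episode_key)]
  agg <- per_ep[, .(
    n_episodes_with_any = .N,
    total_events = sum(events),
    mean_events = mean(events),
    sd_events = if (.N > 1) sd(events) else 0,
    total_cost = cents_to_dollars(sum(cents))
  ), by = sector]
  out <- data.table::data.table(sector = .SECTORS)
  out <- merge(out, agg, by = "sector", all.x = TRUE)
  out[is.na(n_episodes_with_any), `:=`(n_episodes_with_any = 0L, total_events = 0L,
                                       total_cost = 0)]
  out[, sector := factor(sector, levels = .SECTORS)]
  data.table::setorder(out, sector)
  out[, sector := as.character(sector)]
  out[]
}

#' Run the full pipeline
#'
#' Orchestrates the end-to-end analysis: simulate (or read) inputs, compute
#' person-level annual costs, select the high-cost community-dwelling cohort,
#' build and classify episodes for the cohort, attribute costs, and write the
#' report bundle. Every stage is deterministic given the inputs, so two runs
#' over the same scenario and seed produce byte-identical files.
#'
#' @param config a [study_config()].
#' @param scenario a [scenario_config()] to simulate from, or `NULL` when
#'   reading files.
#' @param encounters_path,persons_path input CSVs (ignored when `scenario`
#'   is given).
#' @param codemap a [read_code_map()] object.
#' @param out_dir directory for the report bundle, or `NULL` to skip writing.
#' @return (invisibly) a list with `cohort`, `threshold`, `built`, `census`,
#'   `grouping_summary`, `sector_summary`, `ledger`, `characteristics`,
#'   `uncaptured`, `log`.
#' @export
run_pipeline <- function(config = study_config(), scenario = NULL,
                         encounters_path = NULL, persons_path = NULL,
                         codemap = read_code_map(), out_dir = NULL) {
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  if (!is.null(scenario)) {
    say("simulate: n_persons=%d seed=%d", scenario$n_persons, scenario$seed)
    sim <- simulate_scenario(scenario, codemap, config)
    persons <- sim$persons
    encounters <- sim$encounters
  } else {
    .assert(!is.null(encounters_path) && !is.null(persons_path),
            "provide either a scenario or encounters_path + persons_path")
    say("read: %s, %s", encounters_path, persons_path)
    encounters <- read_encounters(encounters_path, config)
    persons <- read_persons(persons_path, config)
  }
  say("inputs: %d persons, %d encounters", nrow(persons), nrow(encounters))

  costs <- person_annual_costs(encounters, config)
  if (nrow(costs) > 0) {
    threshold <- high_cost_threshold(costs, config$percentile, config)
    cohort <- select_cohort(persons, costs, threshold, config)
  } else {
    threshold <- NA_real_
    cohort <- character(0)
  }
  say("cohort: threshold=%.2f, %d of %d persons selected", threshold, length(cohort), nrow(persons))

  enc_cohort <- data.table::as.data.table(encounters)[person_id %in% cohort]
  per_cohort <- data.table::as.data.table(persons)[person_id %in% cohort]
  built <- build_episodes(enc_cohort, per_cohort, config)
  built <- attach_community_care(built, enc_cohort, config)
  built <- episode_costs(built, enc_cohort, config)
  built <- classify_episodes(built, enc_cohort, codemap)
  say("episodes: %d built for %d persons", nrow(built$episodes),
      length(unique(built$episodes$person_id)))

  census <- grouping_census(built$episodes)
  gsum <- grouping_summary(built$episodes)
  ssum <- sector_use_summary(built)
  ledger <- allocate_costs(built, enc_cohort)
  uncaptured <- unallocated_person_summary(built, cohort)
  characteristics <- if (length(cohort) > 0) {
    characterize_cohort(per_cohort, upc_table(enc_cohort, cohort))
  } else {
    data.table::data.table(characteristic = character(), category = character(),
                           n = integer(), percent = numeric())
  }
  say("allocation: %.1f%% of cohort costs inside episodes",
      ledger[sector == "all_services", percent_allocated])

  bundle <- list(cohort = cohort, threshold = threshold, built = built,
                 census = census, grouping_summary = gsum, sector_summary = ssum,
                 ledger = ledger, characteristics = characteristics,
                 uncaptured = uncaptured, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_table(data.table::data.table(person_id = cohort), file.path(out_dir, "cohort.csv"))
    write_report_table(built$episodes, file.path(out_dir, "episodes.csv"))
    write_report_table(built$membership, file.path(out_dir, "membership.csv"))
    write_report_table(census, file.path(out_dir, "grouping_census.csv"))
    write_report_table(gsum, file.path(out_dir, "grouping_summary.csv"))
    write_report_table(ssum, file.path(out_dir, "sector_summary.csv"))
    write_report_table(ledger, file.path(out_dir, "allocation_ledger.csv"))
    write_report_table(characteristics, file.path(out_dir, "cohort_characteristics.csv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
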