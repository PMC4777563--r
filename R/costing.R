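# Allocation ledger: per-sector costs inside episodes vs. remaining.
#
# Money is carried in integer cents so allocated + remaining equals the grand
# total of encounter costs exactly, on every run. Prorated per-diem stays
# split a single encounter's cost between the allocated and remaining sides.

#' Allocate costs to episodes, per sector
#'
#' Builds the allocation ledger from a costed `pce_built` object: for each
#' sector, the dollars attributed to episodes, the remaining (out-of-episode)
#' dollars, and the percent allocated (half-up, one decimal). A grand-total
#' `all_services` row closes the table. Every encounter passed in must appear
#' in the membership table — otherwise conservation would silently break, so
#' this is an error.
#'
#' @param built a `pce_built` object after [episode_costs()].
#' @param encounters the full encounter table the episodes were built from.
#' @return a `data.table` with `sector, allocated, remaining, total,
#'   percent_allocated` (dollars), one row per sector in the fixed vocabulary
#'   order plus `all_services`.
#' @export
allocate_costs <- function(built, encounters) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  .assert("allocated_cents" %in% names(built$membership),
          "membership has no cost columns; run episode_costs() first")
  enc <- data.table::as.data.table(encounters)
  missing_ids <- setdiff(enc$encounter_id, built$membership$encounter_id)
  .assert(length(missing_ids) == 0,
          sprintf("encounter(s) missing from episode membership (conservation would break): %s",
                  paste(head(missing_ids, 10), collapse = ", ")))
  mem <- built$membership
  per_sector <- mem[, .(allocated = sum(allocated_cents),
                        total = sum(cost_cents)), by = sector]
  out <- data.table::data.table(sector = .SECTORS)
  out <- merge(out, per_sector, by = "sector", all.x = TRUE)
  out[is.na(allocated), `:=`(allocated = 0, total = 0)]
  out[, sector := factor(sector, levels = .SECTORS)]
  data.table::setorder(out, sector)
  out[, sector := as.character(sector)]
  grand <- data.table::data.table(sector = "all_services",
                                  allocated = sum(out$allocated), total = sum(out$total))
  out <- data.table::rbindlist(list(out, grand))
  out[, remaining := total - allocated]
  out[, `:=`(allocated = cents_to_dollars(allocated),
             remaining = cents_to_dollars(remaining),
             total = cents_to_dollars(total))]
  out[, percent_allocated := data.table::fifelse(
    total > 0, allocation_percent(allocated, remaining), NA_real_)]
  data.table::setcolorder(out, c("sector", "allocated", "remaining", "total", "percent_allocated"))
  out[]
}

#' Persons not captured by any episode
#'
#' Count and total annual cost of persons (in the supplied set) with zero
#' episodes.
#'
#' @param built a costed `pce_built` object.
#' @param person_ids the person set of interest (e.g. the selected cohort).
#' @return a list with `n_persons` and `total_cost` (dollars).
#' @export
unallocated_person_summary <- function(built, person_ids) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  .assert("cost_cents" %in% names(built$membership),
          "membership has no cost columns; run episode_costs() first")
  with_ep <- unique(built$episodes$person_id)
  no_ep <- setdiff(person_ids, with_ep)
  cost <- built$membership[person_id %in% no_ep, sum(cost_cents)]
  list(n_persons = length(no_ep), total_cost = cents_to_dollars(if (length(no_ep)) cost else 0))
}
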