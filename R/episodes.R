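# Person-centred episode construction.
#
# An episode opens at the first unconsumed acute-start admission (inpatient
# acute, same-day surgery, inpatient mental health, and — configurably — the
# emergency department). From the running discharge date a rolling window of
# `window_days` is examined: any further institutional admission (any admitted
# sector except inpatient_nonacute) whose admit date falls on or before the
# window end is absorbed, and the window end advances to
# max(window end, its effective discharge + window_days). The episode closes
# when the window elapses with no institutional admission; community care is
# then attached over the closed span [anchor admit, end date].
#
# Effective discharge = min(discharge (missing -> study_end), study_end,
# death_date); episode end = min(final discharge + window_days, death_date,
# study_end). Gap arithmetic is in whole days with a closed boundary: a gap of
# exactly window_days chains, window_days + 1 does not.

# effective (censored) discharge for a set of encounters
.effective_discharge <- function(admit, discharge, study_end, death_date) {
  d <- data.table::fifelse(is.na(discharge), study_end, discharge)
  d <- pmin(d, study_end)
  if (!is.na(death_date)) d <- pmin(d, death_date)
  pmax(d, admit) # guard degenerate records (death before admit etc.)
}

# scan one person's institutional encounters (pre-sorted); returns list of
# episodes (integer index vectors into the input) plus unallocated indices
.scan_person <- function(admit, eff_disch, sector, acute_start, window_days) {
  n <- length(admit)
  assignment <- integer(n) # 0 = unallocated, k = episode number
  ep <- 0L
  window_end <- NA_integer_
  open <- FALSE
  for (i in seq_len(n)) {
    if (sector[i] == "inpatient_nonacute") next # never anchors, extends, or joins
    if (open && admit[i] <= window_end) {
      assignment[i] <- ep
      window_end <- max(window_end, eff_disch[i] + window_days)
    } else if (sector[i] %in% acute_start) {
      ep <- ep + 1L
      assignment[i] <- ep
      open <- TRUE
      window_end <- eff_disch[i] + window_days
    } else {
      open <- FALSE
    }
  }
  assignment
}

#' Build person-centred episodes
#'
#' Chains institutional encounters into episodes with the rolling-window rule,
#' anchored on acute-start admissions; censors at death and study end.
#' Institutional encounters not reachable from an acute anchor — and all
#' `inpatient_nonacute` stays — are returned unallocated.
#'
#' @param encounters validated encounter table (all sectors; community rows are
#'   ignored here and attached by [attach_community_care()]).
#' @param persons validated person table (for death dates).
#' @param config a [study_config()].
#' @return an object of class `pce_built`: a list with
#'   \describe{
#'     \item{episodes}{one row per episode: `episode_key, person_id,
#'       anchor_encounter_id, start_date, final_discharge_date, end_date,
#'       n_institutional`}
#'     \item{membership}{one row per institutional encounter:
#'       `encounter_id, person_id, sector, episode_key` (`NA` = unallocated)}
#'   }
#' @export
#' @examples
#' cfg <- study_config()
#' enc <- data.frame(
#'   encounter_id = "E1", person_id = "P1", sector = "inpatient_acute",
#'   admit_date = as.Date("2010-05-01"), discharge_date = as.Date("2010-05-06"),
#'   cost = 5000, mrd_code = "ACS001", dx_codes = "", admission_type = "unplanned",
#'   service_type = "medical", provider_id = NA_character_, ambulatory_flag = FALSE
#' )
#' per <- data.frame(
#'   person_id = "P1", age_at_index = 70, sex = "female", rurality_score = 10,
#'   primary_care_model = "fee_for_service", drug_benefit_eligible = TRUE,
#'   death_date = as.Date(NA), ltc_resident_at_index = FALSE,
#'   palliative_flag = FALSE, morbidity_adg_count = 5, prior_year_drug_count = 3
#' )
#' built <- build_episodes(enc, per, cfg)
#' built$episodes$end_date # 30 days after discharge
build_episodes <- function(encounters, persons, config = study_config()) {
  enc <- data.table::as.data.table(encounters)
  per <- data.table::as.data.table(persons)
  dup <- enc$encounter_id[duplicated(enc$encounter_id)]
  .assert(length(dup) == 0,
          sprintf("duplicate encounter_id(s): %s", paste(head(unique(dup), 10), collapse = ", ")))

  inst <- enc[sector %in% .INSTITUTIONAL]
  acute_start <- acute_start_sectors(config)
  deaths <- setNames(per$death_date, per$person_id)

  # sort: admit, discharge (open stays last among ties), sector priority, id
  inst[, `:=`(
    .disch_ord = data.table::fifelse(is.na(discharge_date), as.Date("9999-12-31"), discharge_date),
    .secrank = match(sector, .SECTORS)
  )]
  data.table::setorder(inst, person_id, admit_date, .disch_ord, .secrank, encounter_id)

  ep_rows <- list()
  mem_rows <- list()
  for (pid in unique(inst$person_id)) {
    rows <- inst[person_id == pid]
    death <- if (pid %in% names(deaths)) deaths[[pid]] else as.Date(NA)
    eff <- .effective_discharge(rows$admit_date, rows$discharge_date, config$study_end, death)
    assignment <- .scan_person(as.integer(rows$admit_date), as.integer(eff),
                               rows$sector, acute_start, config$window_days)
    keys <- rep(NA_character_, nrow(rows))
    if (any(assignment > 0)) {
      for (k in seq_len(max(assignment))) {
        idx <- which(assignment == k)
        key <- sprintf("%s-E%03d", pid, k)
        keys[idx] <- key
        final_disch <- max(eff[idx])
        end <- min(final_disch + config$window_days, config$study_end,
                   if (is.na(death)) config$study_end else death)
        ep_rows[[length(ep_rows) + 1L]] <- data.table::data.table(
          episode_key = key,
          person_id = pid,
          anchor_encounter_id = rows$encounter_id[idx[1]],
          start_date = rows$admit_date[idx[1]],
          final_discharge_date = as.Date(final_disch, origin = "1970-01-01"),
          end_date = as.Date(end, origin = "1970-01-01"),
          n_institutional = length(idx)
        )
      }
    }
    mem_rows[[length(mem_rows) + 1L]] <- data.table::data.table(
      encounter_id = rows$encounter_id, person_id = pid,
      sector = rows$sector, episode_key = keys
    )
  }
  episodes <- if (length(ep_rows)) data.table::rbindlist(ep_rows) else data.table::data.table(
    episode_key = character(), person_id = character(), anchor_encounter_id = character(),
    start_date = as.Date(character()), final_discharge_date = as.Date(character()),
    end_date = as.Date(character()), n_institutional = integer()
  )
  membership <- if (length(mem_rows)) data.table::rbindlist(mem_rows) else data.table::data.table(
    encounter_id = character(), person_id = character(), sector = character(),
    episode_key = character()
  )
  structure(list(episodes = episodes, membership = membership, config = config),
            class = "pce_built")
}

#' Attach community care to episodes
#'
#' A community-sector encounter (home care, physician, laboratory, drug,
#' outpatient dialysis, outpatient oncology, assistive devices) whose service
#' date falls within the closed span `[start_date, end_date]` of an episode of
#' the same person is attached to that episode — including dates in gaps
#' between chained institutional stays. Community care outside every span
#' remains unallocated. Episode spans of one person are disjoint, so the
#' attachment is unambiguous.
#'
#' @param built a `pce_built` object from [build_episodes()].
#' @param encounters the full encounter table (community rows are used).
#' @param config a [study_config()].
#' @return the `pce_built` object with community rows appended to
#'   `$membership` and an `n_community` column on `$episodes`.
#' @export
attach_community_care <- function(built, encounters, config = built$config) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  enc <- data.table::as.data.table(encounters)
  comm <- enc[sector %in% .COMMUNITY,
              .(encounter_id, person_id, sector, service_date = admit_date)]
  if (nrow(comm) > 0 && nrow(built$episodes) > 0) {
    eps <- built$episodes[, .(episode_key, person_id, start_date, end_date)]
    hit <- eps[comm,
               on = .(person_id, start_date <= service_date, end_date >= service_date),
               .(encounter_id = i.encounter_id, episode_key = x.episode_key)]
    comm <- merge(comm, hit[!is.na(episode_key)], by = "encounter_id", all.x = TRUE)
  } else {
    comm[, episode_key := NA_character_]
  }
  comm_mem <- comm[, .(encounter_id, person_id, sector, episode_key)]
  membership <- data.table::rbindlist(list(
    built$membership[, .(encounter_id, person_id, sector, episode_key)], comm_mem))
  built$membership <- membership
  if (nrow(built$episodes) > 0) {
    ncom <- comm_mem[!is.na(episode_key), .N, by = episode_key]
    built$episodes[, n_community := 0L]
    built$episodes[ncom, n_community := i.N, on = "episode_key"]
  } else if (nrow(built$episodes) == 0) {
    built$episodes[, n_community := integer(0)]
  }
  built
}

#' Compute episode costs
#'
#' Sums member institutional and attached community costs per episode. Money is
#' carried in integer cents so that allocation accounting conserves exactly.
#' Per-diem stays (`long_term_care`, `complex_continuing_care`) whose stay
#' extends past the episode end date contribute
#' `cost * days_within_episode / stay_days`, rounded to cents; the remainder is
#' left unallocated (it falls outside the episode span).
#'
#' @param built a `pce_built` object with community care attached.
#' @param encounters the full encounter table (for costs and dates).
#' @param config a [study_config()].
#' @return the `pce_built` object with:
#'   `$membership` gaining `cost_cents` and `allocated_cents` columns, and
#'   `$episodes` gaining `total_cost` (dollars) plus one `cost_<sector>` column
#'   per sector with nonzero attributed cost.
#' @export
episode_costs <- function(built, encounters, config = built$config) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  enc <- data.table::as.data.table(encounters)
  mem <- merge(built$membership,
               enc[, .(encounter_id, admit_date, discharge_date, cost)],
               by = "encounter_id", all.x = TRUE, sort = FALSE)
  .assert(!anyNA(mem$cost), "membership refers to encounter_id(s) absent from the encounter table")
  mem[, cost_cents := as_cents(cost)]
  mem[, allocated_cents := data.table::fifelse(is.na(episode_key), 0, cost_cents)]

  # per-diem proration for member stays extending past the episode end
  if (nrow(built$episodes) > 0) {
    mem[built$episodes, end_date := i.end_date, on = "episode_key"]
    pd <- mem[!is.na(episode_key) & sector %in% .PER_DIEM]
    if (nrow(pd) > 0) {
      pd[, raw_disch := data.table::fifelse(is.na(discharge_date), config$study_end, discharge_date)]
      pd[, stay_days := days_between(admit_date, raw_disch) + 1L]
      pd[, in_days := pmin(days_between(admit_date, end_date) + 1L, stay_days)]
      pd <- pd[in_days < stay_days]
      if (nrow(pd) > 0) {
        pd[, allocated_cents := round(cost_cents * in_days / stay_days)]
        mem[pd, allocated_cents := i.allocated_cents, on = "encounter_id"]
      }
    }
    mem[, end_date := NULL]
  }
  built$membership <- mem[, .(encounter_id, person_id, sector, episode_key,
                              admit_date, discharge_date, cost_cents, allocated_cents)]

  if (nrow(built$episodes) > 0) {
    tot <- mem[!is.na(episode_key), .(total_cents = sum(allocated_cents)), by = episode_key]
    built$episodes[, total_cost := 0]
    built$episodes[tot, total_cost := cents_to_dollars(i.total_cents), on = "episode_key"]
    sec <- mem[!is.na(episode_key),
               .(cents = sum(allocated_cents)), by = .(episode_key, sector)]
    wide <- data.table::dcast(sec, episode_key ~ sector, value.var = "cents", fill = 0)
    data.table::setnames(wide, setdiff(names(wide), "episode_key"),
                         paste0("cost_", setdiff(names(wide), "episode_key")))
    for (col in setdiff(names(wide), "episode_key")) {
      data.table::set(wide, j = col, value = cents_to_dollars(wide[[col]]))
    }
    drop <- intersect(names(built$episodes), setdiff(names(wide), "episode_key"))
    if (length(drop)) built$episodes[, (drop) := NULL]
    built$episodes <- merge(built$episodes, wide, by = "episode_key", all.x = TRUE, sort = FALSE)
    for (col in setdiff(names(wide), "episode_key")) {
      data.table::set(built$episodes, which(is.na(built$episodes[[col]])), col, 0)
    }
  } else {
    built$episodes[, total_cost := numeric(0)]
  }
  built
}

#' @export
print.pce_built <- function(x, ...) {
  cat("<pce_built>\n")
  cat(sprintf("  episodes   : %d (persons: %d)\n", nrow(x$episodes),
              length(unique(x$episodes$person_id))))
  n_inst <- sum(x$membership$sector %in% .INSTITUTIONAL)
  n_unalloc <- sum(x$membership$sector %in% .INSTITUTIONAL & is.na(x$membership$episode_key))
  cat(sprintf("  membership : %d rows (%d institutional, %d unallocated)\n",
              nrow(x$membership), n_inst, n_unalloc))
  invisible(x)
}
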