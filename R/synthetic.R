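# Seeded synthetic claims generator with planted episode ground truth.
#
# The generator plants episodes first and serializes encounters afterwards; it
# never labels post hoc, so ground truth is exact by construction and serves
# as an oracle for the episode builder. Chains of institutional stays are
# grown with inter-stay gaps drawn on both sides of the stabilization window:
# a gap <= window_days continues the planted episode; a larger gap starts a
# new planted episode (if the next stay's sector can anchor) or a
# planted-unallocated run (if it cannot). inpatient_nonacute strays are only
# planted outside open chains, because that sector neither anchors nor
# extends episodes.

.DEFAULT_GROUPING_MIX <- c(
  pregnancy = 0.026, perinatal_congenital_lbw = 0.015, post_admission_events = 0.108,
  trauma_injury_poisoning = 0.064, mental_illness_addictions = 0.059, acsc = 0.039,
  cancer = 0.074, acute_planned_surgical = 0.352, acute_planned_medical = 0.011,
  acute_unplanned_surgical = 0.041, acute_unplanned_medical = 0.210, other_causes = 0.001
)

# per-sector log-normal cost parameters (meanlog, sdlog); per-diem sectors
# (long_term_care, complex_continuing_care) are daily rates multiplied by days
.DEFAULT_COST_PARAMS <- list(
  inpatient_acute = c(9.2, 0.8), same_day_surgery = c(7.3, 0.6),
  emergency = c(6.0, 0.5), inpatient_mental_health = c(9.5, 0.9),
  inpatient_rehab = c(9.6, 0.6), complex_continuing_care = c(5.6, 0.3),
  long_term_care = c(5.2, 0.3), inpatient_nonacute = c(8.0, 0.5),
  home_care = c(4.7, 0.8), physician = c(4.3, 0.7), laboratory = c(3.0, 0.5),
  drug = c(3.9, 0.9), dialysis_outpatient = c(5.6, 0.4),
  oncology_outpatient = c(6.3, 0.6), assistive_device = c(5.5, 1.0)
)

# mean length of stay in days per institutional sector (0 = point in time)
.DEFAULT_LOS_MEANS <- c(
  inpatient_acute = 6, same_day_surgery = 0, emergency = 0,
  inpatient_mental_health = 18, inpatient_rehab = 14,
  complex_continuing_care = 35, long_term_care = 60, inpatient_nonacute = 10
)

# sample one element from a vector without R's scalar-`sample()` surprise
.pick <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Synthetic scenario configuration
#'
#' Parameters of the synthetic claims generator. Defaults emulate the
#' structure the episode methodology assumes: readmission chains whose
#' inter-stay gaps straddle the 30-day stabilization boundary, heavier-tailed
#' institutional than community costs, and community visits concentrated
#' inside episode spans.
#'
#' @param n_persons number of persons to simulate.
#' @param seed integer seed; identical `(scenario, seed)` yields byte-identical
#'   output files.
#' @param grouping_mix named probability vector over the twelve groupings
#'   (must sum to 1); the intended clinical grouping of each planted episode.
#' @param episode_lambda mean number of planted chain starts per person
#'   (Poisson).
#' @param p_readmit probability that a discharged stay is followed by another
#'   institutional stay in the same chain.
#' @param chain_cap maximum stays per chain.
#' @param gap_range integer range (days) for inter-stay gaps, spanning both
#'   sides of the window (default `c(1, 45)` against a 30-day window).
#' @param los_means named mean length of stay per institutional sector (days).
#' @param cost_params named list of `c(meanlog, sdlog)` per sector.
#' @param community_rate expected community contacts per day, named
#'   `c(in_episode=, out_of_episode=)`.
#' @param mortality_rate probability of death during the study year.
#' @param drug_eligibility_rate probability of drug-benefit eligibility.
#' @param ltc_at_index_rate probability of long-term-care residence at index.
#' @param palliative_rate probability of palliative-care use.
#' @param p_stray probability a person carries an isolated institutional stay
#'   (rehab/LTC/non-acute) with no acute anchor.
#' @return an object of class `pce_scenario`.
#' @export
#' @examples
#' sc <- scenario_config(n_persons = 50, seed = 1)
#' sc$grouping_mix[["acute_planned_surgical"]]
scenario_config <- function(n_persons = 500L,
                            seed = 7L,
                            grouping_mix = .DEFAULT_GROUPING_MIX,
                            episode_lambda = 1.2,
                            p_readmit = 0.35,
                            chain_cap = 6L,
                            gap_range = c(1L, 45L),
                            los_means = .DEFAULT_LOS_MEANS,
                            cost_params = .DEFAULT_COST_PARAMS,
                            community_rate = c(in_episode = 0.4, out_of_episode = 0.12),
                            mortality_rate = 0.05,
                            drug_eligibility_rate = 0.52,
                            ltc_at_index_rate = 0.02,
                            palliative_rate = 0.06,
                            p_stray = 0.08) {
  .assert(is.numeric(n_persons) && n_persons >= 0, "n_persons must be a non-negative integer")
  .assert(setequal(names(grouping_mix), .GROUPINGS),
          "grouping_mix must be named with the twelve grouping keys")
  grouping_mix <- grouping_mix[.GROUPINGS]
  .assert(all(grouping_mix >= 0) && abs(sum(grouping_mix) - 1) < 1e-9,
          "grouping_mix must be non-negative and sum to 1")
  for (r in c(p_readmit, mortality_rate, drug_eligibility_rate, ltc_at_index_rate,
              palliative_rate, p_stray)) {
    .assert(is.numeric(r) && r >= 0 && r <= 1, "rates must lie in [0, 1]")
  }
  .assert(all(community_rate >= 0), "community_rate values must be >= 0")
  .assert(length(gap_range) == 2 && gap_range[1] >= 0 && gap_range[1] <= gap_range[2],
          "gap_range must be an increasing pair of non-negative day counts")
  .assert(all(.INSTITUTIONAL %in% names(los_means)), "los_means must cover institutional sectors")
  .assert(all(.SECTORS %in% names(cost_params)), "cost_params must cover all sectors")
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    grouping_mix = grouping_mix, episode_lambda = episode_lambda,
    p_readmit = p_readmit, chain_cap = as.integer(chain_cap),
    gap_range = as.integer(gap_range), los_means = los_means,
    cost_params = cost_params, community_rate = community_rate,
    mortality_rate = mortality_rate, drug_eligibility_rate = drug_eligibility_rate,
    ltc_at_index_rate = ltc_at_index_rate, palliative_rate = palliative_rate,
    p_stray = p_stray
  ), class = "pce_scenario")
}

#' Generate a synthetic population
#'
#' @param scenario a [scenario_config()].
#' @param config a [study_config()] (death dates fall inside the study year).
#' @return a validated person `data.table` with `n_persons` rows.
#' @export
generate_population <- function(scenario, config = study_config()) {
  .assert(inherits(scenario, "pce_scenario"), "scenario must come from scenario_config()")
  set.seed(scenario$seed)
  n <- scenario$n_persons
  if (n == 0) {
    return(validate_persons(data.table::data.table(
      person_id = character(), age_at_index = numeric(), sex = character(),
      rurality_score = numeric(), primary_care_model = character(),
      drug_benefit_eligible = logical(), death_date = as.Date(character()),
      ltc_resident_at_index = logical(), palliative_flag = logical(),
      morbidity_adg_count = integer(), prior_year_drug_count = integer()
    ), config))
  }
  year_days <- days_between(config$study_start, config$study_end)
  age_bin <- sample(1:5, n, replace = TRUE, prob = c(0.05, 0.15, 0.28, 0.41, 0.11))
  lo <- c(0, 18, 45, 65, 85)[age_bin]
  hi <- c(17, 44, 64, 84, 99)[age_bin]
  age <- lo + floor(runif(n) * (hi - lo + 1))
  rur <- ifelse(runif(n) < 0.10, 40 + floor(runif(n) * 61), floor(runif(n) * 40))
  rur[runif(n) < 0.01] <- NA
  adg <- 1L + rpois(n, 7)
  adg[runif(n) < 0.005] <- 0L
  adg[runif(n) < 0.024] <- NA
  eligible <- runif(n) < scenario$drug_eligibility_rate
  drugs <- ifelse(eligible, rpois(n, 9), NA_integer_)
  died <- runif(n) < scenario$mortality_rate
  death <- as.Date(ifelse(died, config$study_start + floor(runif(n) * (year_days + 1)), NA),
                   origin = "1970-01-01")
  per <- data.table::data.table(
    person_id = sprintf("P%05d", seq_len(n)),
    age_at_index = age,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.535, 0.465)),
    rurality_score = rur,
    primary_care_model = sample(.PRIMARY_CARE_MODELS, n, replace = TRUE,
                                prob = c(0.179, 0.590, 0.214, 0.017)),
    drug_benefit_eligible = eligible,
    death_date = death,
    ltc_resident_at_index = runif(n) < scenario$ltc_at_index_rate,
    palliative_flag = runif(n) < scenario$palliative_rate,
    morbidity_adg_count = adg,
    prior_year_drug_count = drugs
  )
  validate_persons(per, config)
}

# draw a diagnosis code under a category prefix, or a benign unmapped code
.draw_code <- function(prefixes) paste0(.pick(prefixes), sprintf("%03d", sample(0:999, 1)))
.benign_code <- function() sprintf("ZZZ%03d", sample(0:999, 1))

# anchor attributes that classify deterministically into `grouping`; a forced
# `sector` (re-anchoring stays keep their sampled sector) disables the
# mental-health facility-override path
.anchor_attrs <- function(grouping, codemap, acute_start, sector = NULL) {
  forced <- !is.null(sector)
  if (!forced) {
    non_mh <- setdiff(acute_start, "inpatient_mental_health")
    sector <- .pick(non_mh, prob = c(0.65, 0.2, 0.15)[seq_along(non_mh)])
  }
  mrd <- .benign_code()
  dx <- character(0); dxt <- character(0)
  adm <- "unplanned"; srv <- "medical"
  if (grouping %in% .CODE_DRIVEN) {
    mrd <- .draw_code(codemap$categories[[grouping]])
    if (!forced && grouping == "mental_illness_addictions" && runif(1) < 0.5) {
      sector <- "inpatient_mental_health"
      mrd <- .benign_code() # facility override carries the classification
    }
  } else if (grouping == "post_admission_events") {
    dx <- sprintf("CMP%03d", sample(0:999, 1)); dxt <- "post_admission"
  } else if (grouping == "acute_planned_surgical") {
    adm <- "planned"; srv <- "surgical"
  } else if (grouping == "acute_planned_medical") {
    adm <- "planned"; srv <- "medical"
  } else if (grouping == "acute_unplanned_surgical") {
    adm <- "unplanned"; srv <- "surgical"
  } else if (grouping == "acute_unplanned_medical") {
    adm <- "unplanned"; srv <- "medical"
  } else if (grouping == "other_causes") {
    adm <- "not_applicable"; srv <- "not_applicable"
  }
  # a benign secondary diagnosis on some anchors
  if (runif(1) < 0.5) { dx <- c(dx, .benign_code()); dxt <- c(dxt, "other") }
  list(sector = sector, mrd = mrd, dx = serialize_dx(dx, dxt),
       admission_type = adm, service_type = srv)
}

.draw_cost <- function(sector, days, cost_params) {
  p <- cost_params[[sector]]
  x <- rlnorm(1, p[1], p[2])
  if (sector %in% .PER_DIEM) x <- x * max(days, 1)
  round(x, 2)
}

#' Generate synthetic encounters with planted ground truth
#'
#' @param persons output of [generate_population()].
#' @param scenario a [scenario_config()].
#' @param codemap a [read_code_map()] object; every code-driven grouping with
#'   positive mass in `grouping_mix` must have at least one prefix.
#' @param config a [study_config()].
#' @return a list with
#'   \describe{
#'     \item{encounters}{validated encounter `data.table`}
#'     \item{ground_truth}{one row per institutional encounter:
#'       `encounter_id, person_id, planted_episode_key`
#'       (`"unallocated"` where no episode), `planted_grouping`}
#'   }
#' @export
#' @examples
#' sc <- scenario_config(n_persons = 20, seed = 1)
#' sim <- simulate_scenario(sc)
#' table(sim$ground_truth$planted_episode_key == "unallocated")
generate_encounters <- function(persons, scenario, codemap = read_code_map(),
                                config = study_config()) {
  .assert(inherits(scenario, "pce_scenario"), "scenario must come from scenario_config()")
  .assert(inherits(codemap, "pce_codemap"), "codemap must come from read_code_map()")
  need <- intersect(.CODE_DRIVEN, names(scenario$grouping_mix[scenario$grouping_mix > 0]))
  no_codes <- need[!vapply(need, function(g) length(codemap$categories[[g]] %||% character(0)) > 0,
                           logical(1))]
  .assert(length(no_codes) == 0,
          sprintf("grouping(s) with positive mass but no code-map prefixes: %s",
                  paste(no_codes, collapse = ", ")))
  set.seed(scenario$seed + 1L)

  per <- data.table::as.data.table(persons)
  acute_start <- acute_start_sectors(config)
  extenders <- c("inpatient_acute", "emergency", "inpatient_rehab",
                 "complex_continuing_care", "long_term_care")
  ext_w <- c(0.30, 0.15, 0.20, 0.15, 0.20)
  win <- config$window_days
  start_i <- as.integer(config$study_start)
  end_i <- as.integer(config$study_end)
  gaps <- scenario$gap_range[1]:scenario$gap_range[2]
  mix <- scenario$grouping_mix

  enc_list <- vector("list", nrow(per))
  gt_list <- vector("list", nrow(per))

  for (pi in seq_len(nrow(per))) {
    pid <- per$person_id[pi]
    death <- per$death_date[pi]
    horizon <- if (is.na(death)) end_i else min(end_i, as.integer(death))
    if (horizon < start_i) next
    counter <- 0L
    rows <- list()
    gt <- list()
    spans <- list() # planted [span_start, span_end] per episode, for community placement
    ep_n <- 0L

    emit <- function(sector, admit, disch, mrd, dx, adm, srv, key, grouping) {
      counter <<- counter + 1L
      id <- sprintf("%s-%04d", pid, counter)
      rows[[length(rows) + 1L]] <<- list(
        encounter_id = id, sector = sector, admit = admit, disch = disch,
        cost = .draw_cost(sector, disch - admit + 1L, scenario$cost_params),
        mrd = mrd, dx = dx, adm = adm, srv = srv
      )
      gt[[length(gt) + 1L]] <<- list(encounter_id = id, key = key, grouping = grouping)
      id
    }

    n_chains <- rpois(1, scenario$episode_lambda)

    # optional stray stay with no acute anchor, placed before any chain
    stray_admit <- NA_integer_
    if (runif(1) < scenario$p_stray) stray_admit <- start_i + sample(0:40, 1)
    first_anchor <- start_i + sample(5:300, 1)
    if (!is.na(stray_admit)) first_anchor <- max(first_anchor, stray_admit + 81L)
    if (!is.na(stray_admit) && stray_admit <= horizon) {
      sec <- .pick(c("long_term_care", "inpatient_rehab", "inpatient_nonacute"),
                   prob = c(0.45, 0.3, 0.25))
      los <- rpois(1, scenario$los_means[[sec]])
      emit(sec, stray_admit, stray_admit + los, .benign_code(), "",
           "not_applicable", "not_applicable", "unallocated", NA_character_)
    }

    # institutional chains: a state machine over (in_episode, last discharge)
    if (n_chains > 0 && first_anchor <= horizon) {
      chains_done <- 0L
      admit <- first_anchor
      repeat {
        # open a fresh chain with an acute-start anchor
        grouping <- .pick(.GROUPINGS, prob = mix)
        at <- .anchor_attrs(grouping, codemap, acute_start)
        los <- rpois(1, scenario$los_means[[at$sector]])
        disch <- admit + los
        ep_n <- ep_n + 1L
        key <- sprintf("%s-E%03d", pid, ep_n)
        emit(at$sector, admit, disch, at$mrd, at$dx, at$admission_type, at$service_type,
             grouping = grouping, key = key)
        in_episode <- TRUE
        ep_start <- admit
        stay_in_chain <- 1L
        eff_disch <- min(disch, horizon)

        while (stay_in_chain < scenario$chain_cap && runif(1) < scenario$p_readmit) {
          gap <- .pick(gaps)
          nxt <- eff_disch + gap
          if (nxt > horizon) break
          if (in_episode && gap <= win) {
            # continues the planted episode (extender sectors; never non-acute)
            sec <- .pick(extenders, prob = ext_w)
            los <- rpois(1, scenario$los_means[[sec]])
            emit(sec, nxt, nxt + los, .benign_code(), "", "unplanned", "medical",
                 key = key, grouping = grouping)
          } else {
            # beyond the window (or already off-episode): the planted episode
            # ends; the next stay re-anchors only if its sector can
            if (in_episode) {
              spans[[length(spans) + 1L]] <- c(ep_start, min(eff_disch + win, horizon))
              in_episode <- FALSE
            }
            sec <- .pick(extenders, prob = ext_w)
            los <- rpois(1, scenario$los_means[[sec]])
            if (sec %in% acute_start) {
              ep_n <- ep_n + 1L
              key <- sprintf("%s-E%03d", pid, ep_n)
              grouping <- .pick(.GROUPINGS, prob = mix)
              at2 <- .anchor_attrs(grouping, codemap, acute_start, sector = sec)
              emit(sec, nxt, nxt + los, at2$mrd, at2$dx, at2$admission_type, at2$service_type,
                   key = key, grouping = grouping)
              in_episode <- TRUE
              ep_start <- nxt
            } else {
              emit(sec, nxt, nxt + los, .benign_code(), "", "unplanned", "medical",
                   key = "unallocated", grouping = NA_character_)
            }
          }
          stay_in_chain <- stay_in_chain + 1L
          disch <- nxt + los
          eff_disch <- min(disch, horizon)
        }
        if (in_episode) {
          spans[[length(spans) + 1L]] <- c(ep_start, min(eff_disch + win, horizon))
        }
        chains_done <- chains_done + 1L
        if (chains_done >= n_chains) break
        admit <- eff_disch + win + sample(1:90, 1)
        if (admit > horizon) break
      }
    }

    # community encounters: dense inside planted spans, sparse outside
    day_in <- logical(horizon - start_i + 1L)
    for (sp in spans) day_in[(sp[1] - start_i + 1L):(sp[2] - start_i + 1L)] <- TRUE
    in_days <- which(day_in) + start_i - 1L
    out_days <- which(!day_in) + start_i - 1L
    eligible <- isTRUE(per$drug_benefit_eligible[pi])
    comm_mix <- c(physician = 0.50, laboratory = 0.15, drug = 0.18, home_care = 0.09,
                  dialysis_outpatient = 0.02, oncology_outpatient = 0.04,
                  assistive_device = 0.02)
    if (!eligible) {
      comm_mix[["physician"]] <- comm_mix[["physician"]] + comm_mix[["drug"]]
      comm_mix[["drug"]] <- 0
    }
    main_provider <- sprintf("DR%03d", sample(1:200, 1))
    continuity <- runif(1, 0.3, 0.95)
    place_comm <- function(days_pool, rate) {
      if (length(days_pool) == 0 || rate <= 0) return(invisible(NULL))
      k <- rpois(1, rate * length(days_pool))
      if (k == 0) return(invisible(NULL))
      dts <- days_pool[sample.int(length(days_pool), k, replace = TRUE)]
      secs <- sample(names(comm_mix), k, replace = TRUE, prob = comm_mix)
      for (j in seq_len(k)) {
        sec <- secs[j]
        amb <- sec == "physician" && runif(1) < 0.9
        prov <- if (sec == "physician") {
          if (runif(1) < continuity) main_provider else sprintf("DR%03d", sample(1:200, 1))
        } else NA_character_
        counter <<- counter + 1L
        rows[[length(rows) + 1L]] <<- list(
          encounter_id = sprintf("%s-%04d", pid, counter), sector = sec,
          admit = dts[j], disch = dts[j],
          cost = .draw_cost(sec, 1L, scenario$cost_params),
          mrd = NA_character_, dx = "", adm = "not_applicable", srv = "not_applicable",
          amb = amb, prov = prov
        )
      }
    }
    place_comm(in_days, scenario$community_rate[["in_episode"]])
    place_comm(out_days, scenario$community_rate[["out_of_episode"]])

    if (length(rows)) {
      dt <- data.table::rbindlist(rows, fill = TRUE)
      dt[, person_id := pid]
      enc_list[[pi]] <- dt
    }
    if (length(gt)) {
      g <- data.table::rbindlist(gt)
      g[, person_id := pid]
      gt_list[[pi]] <- g
    }
  }

  enc <- data.table::rbindlist(enc_list[!vapply(enc_list, is.null, logical(1))], fill = TRUE)
  if (nrow(enc) == 0) {
    enc <- data.table::data.table(encounter_id = character(), sector = character(),
                                  admit = integer(), disch = integer(), cost = numeric(),
                                  mrd = character(), dx = character(), adm = character(),
                                  srv = character(), amb = logical(), prov = character(),
                                  person_id = character())
  }
  if (!"amb" %in% names(enc)) enc[, amb := NA]
  if (!"prov" %in% names(enc)) enc[, prov := NA_character_]
  out <- data.table::data.table(
    encounter_id = enc$encounter_id,
    person_id = enc$person_id,
    sector = enc$sector,
    admit_date = as.Date(enc$admit, origin = "1970-01-01"),
    discharge_date = as.Date(enc$disch, origin = "1970-01-01"),
    cost = enc$cost,
    mrd_code = enc$mrd,
    dx_codes = data.table::fifelse(is.na(enc$dx), "", enc$dx),
    admission_type = enc$adm,
    service_type = enc$srv,
    provider_id = enc$prov,
    ambulatory_flag = data.table::fifelse(is.na(enc$amb), FALSE, enc$amb)
  )
  # admissions after death are never generated; clip discharges at death
  out <- merge(out, per[, .(person_id, death_date)], by = "person_id", sort = FALSE)
  out[!is.na(death_date) & discharge_date > death_date, discharge_date := death_date]
  out[, death_date := NULL]
  data.table::setorder(out, person_id, admit_date, encounter_id)
  out <- validate_encounters(out, config)

  gt <- data.table::rbindlist(gt_list[!vapply(gt_list, is.null, logical(1))])
  if (nrow(gt) == 0) {
    gt <- data.table::data.table(encounter_id = character(), person_id = character(),
                                 planted_episode_key = character(),
                                 planted_grouping = character())
  } else {
    data.table::setnames(gt, c("key", "grouping"), c("planted_episode_key", "planted_grouping"))
    data.table::setcolorder(gt, c("encounter_id", "person_id", "planted_episode_key",
                                  "planted_grouping"))
  }
  data.table::setorder(gt, person_id, encounter_id)
  list(encounters = out, ground_truth = gt)
}

#' Simulate a full scenario
#'
#' Convenience wrapper: population plus encounters plus planted ground truth.
#'
#' @inheritParams generate_encounters
#' @return list with `persons`, `encounters`, `ground_truth`.
#' @export
simulate_scenario <- function(scenario = scenario_config(), codemap = read_code_map(),
                              config = study_config()) {
  persons <- generate_population(scenario, config)
  sim <- generate_encounters(persons, scenario, codemap, config)
  list(persons = persons, encounters = sim$encounters, ground_truth = sim$ground_truth)
}

#' Per-sector summary of a synthetic encounter stream
#'
#' Counts and cost moments per sector, for eyeballing scenario realism.
#'
#' @param encounters an encounter table.
#' @return a `data.table` with `sector, n, total_cost, mean_cost, sd_cost,
#'   median_cost`.
#' @export
summarize_scenario <- function(encounters) {
  enc <- data.table::as.data.table(encounters)
  .assert(nrow(enc) > 0, "cannot summarize an empty encounter stream")
  out <- enc[, .(n = .N, total_cost = sum(cost), mean_cost = mean(cost),
                 sd_cost = sd(cost), median_cost = stats::median(cost)), by = sector]
  out[, sector := factor(sector, levels = .SECTORS)]
  data.table::setorder(out, sector)
  out[, sector := as.character(sector)]
  out[]
}
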